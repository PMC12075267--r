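#' Run code under a temporary RNG seed
#'
#' Evaluates `code` with the RNG seeded to `seed`, then restores the caller's
#' RNG state, so seeded routines do not perturb the global random stream.
#' With `seed = NULL` the code runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# two-sided normal p-value from an estimate and its se
z_pval <- function(beta, se) {
  p <- 2 * stats::pnorm(-abs(beta / se))
  pmax(p, .Machine$double.xmin)
}

# stage-count log shared by the instrument filters
selection_log <- function(counts, removals = NULL) {
  if (is.null(removals)) {
    removals <- data.frame(snp_id = character(), stage = character(),
                           reason = character(), stringsAsFactors = FALSE)
  }
  structure(list(counts = counts, removals = removals),
            class = "bimr_selection_log")
}

#' @export
print.bimr_selection_log <- function(x, ...) {
  cat("Instrument selection log\n")
  for (nm in names(x$counts)) cat(sprintf("  %-16s %d\n", nm, x$counts[[nm]]))
  if (nrow(x$removals)) {
    cat(sprintf("  %d removal(s); first reasons:\n", nrow(x$removals)))
    utils::head(x$removals, 5L)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
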