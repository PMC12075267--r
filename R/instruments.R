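# Instrumental-variable selection from an exposure summary-statistics table:
# genome-wide significance filter, greedy LD clumping, proxy lookup,
# per-SNP strength (F statistic, variance explained), and exclusion of
# SNPs flagged offline as confounder-associated / pleiotropic.

#' Genome-wide significance filter
#'
#' Retains records with association p-value strictly below the threshold
#' (the conventional genome-wide cut-off 5e-8 by default), preserving input
#' order.
#'
#' @param table A `sumstat_table`.
#' @param p_threshold Significance threshold; strict `<` comparison.
#' @return A `sumstat_table` with the passing records.
#' @export
select_genomewide <- function(table, p_threshold = 5e-8) {
  stopifnot(inherits(table, "sumstat_table"),
            is.numeric(p_threshold), p_threshold > 0)
  keep <- table$pval < p_threshold
  if (!any(keep)) {
    message(sprintf("select_genomewide: no SNP passes p < %g", p_threshold))
  }
  resubset(table, keep)
}

#' Greedy LD clumping
#'
#' Standard p-value-ordered clumping: repeatedly accept the most significant
#' remaining SNP as an index, then discard every remaining SNP on the same
#' chromosome within `window_kb` of it whose pairwise r-squared with the
#' index exceeds `r2_threshold`. Ties on p-value are broken by snp_id so the
#' result does not depend on input row order. Records without chromosome or
#' position are treated as independent (the distance rule cannot be applied;
#' a warning is emitted).
#'
#' @param table A `sumstat_table`.
#' @param ld An `ld_table` or `NULL` (no pair in LD).
#' @param r2_threshold Remove a SNP when its r-squared with the index
#'   strictly exceeds this value.
#' @param window_kb Window half-width around the index SNP in kilobases.
#' @return A list with elements `table` (retained records, p-value order) and
#'   `log` (a selection log with stage counts and per-SNP removal reasons).
#' @export
clump <- function(table, ld = NULL, r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(inherits(table, "sumstat_table"))
  n_in <- nrow(table)
  ord <- order(table$pval, table$snp_id)
  tab <- resubset(table, ord)
  no_pos <- is.na(tab$pos) | is.na(tab$chrom)
  if (any(no_pos) && n_in > 1L) {
    warning(sprintf("clump: %d record(s) lack chrom/pos; treated as independent",
                    sum(no_pos)))
  }
  alive <- rep(TRUE, n_in)
  removed <- character(0); removed_by <- character(0)
  for (i in seq_len(n_in)) {
    if (!alive[i] || no_pos[i]) next
    later <- which(alive & seq_len(n_in) > i & !no_pos &
                     tab$chrom == tab$chrom[i] &
                     abs(tab$pos - tab$pos[i]) <= window_kb * 1000)
    if (!length(later)) next
    r2 <- ld_r2(ld, tab$snp_id[i], tab$snp_id[later])
    kill <- later[r2 > r2_threshold]
    if (length(kill)) {
      alive[kill] <- FALSE
      removed <- c(removed, tab$snp_id[kill])
      removed_by <- c(removed_by, rep(tab$snp_id[i], length(kill)))
    }
  }
  log <- selection_log(
    counts = list(input = n_in, post_clump = sum(alive)),
    removals = data.frame(
      snp_id = removed, stage = rep("clump", length(removed)),
      reason = if (length(removed)) {
        sprintf("r2 > %g with index %s within %g kb",
                r2_threshold, removed_by, window_kb)
      } else character(0),
      stringsAsFactors = FALSE))
  list(table = resubset(tab, alive), log = log)
}

#' Find a proxy SNP in high LD with a missing instrument
#'
#' Returns the candidate with the largest r-squared to `snp_id` among those
#' strictly exceeding `min_r2`, or `NA` if none qualifies. Ties are broken
#' by snp_id for determinism.
#'
#' @param snp_id The missing instrument.
#' @param candidates A `sumstat_table` of candidate variants (typically the
#'   SNPs present in the outcome dataset).
#' @param ld An `ld_table`.
#' @param min_r2 Minimum r-squared (strict `>`), default 0.9.
#' @return A single snp_id, or `NA_character_`.
#' @export
find_proxy <- function(snp_id, candidates, ld, min_r2 = 0.9) {
  stopifnot(inherits(candidates, "sumstat_table"))
  ids <- setdiff(candidates$snp_id, snp_id)
  if (!length(ids)) return(NA_character_)
  r2 <- ld_r2(ld, snp_id, ids)
  ok <- r2 > min_r2
  if (!any(ok)) return(NA_character_)
  ids <- ids[ok]; r2 <- r2[ok]
  ids[order(-r2, ids)][1L]
}

#' Instrument strength: F statistic and variance explained
#'
#' The per-SNP F statistic is `(beta/se)^2`; the fraction of exposure
#' variance explained is recovered through the identity
#' `r2 = F / (F + n - 2)`, which needs no allele frequency. When `eaf` is
#' supplied, the frequency-based approximation `2*beta^2*eaf*(1-eaf)`
#' (standardized exposure) is also returned for comparison.
#'
#' @param beta,se Effect estimate and its standard error (vectors allowed).
#' @param n Exposure sample size, `> 2`.
#' @param eaf Optional effect-allele frequency.
#' @return Data frame with columns `F_stat`, `r2_explained`, and `r2_eaf`
#'   when `eaf` is given.
#' @export
instrument_strength <- function(beta, se, n, eaf = NULL) {
  if (inherits(beta, "sumstat_table")) {
    tab <- beta
    if (missing(se) || is.null(se)) se <- tab$se
    if (missing(n) || is.null(n)) n <- tab$n
    eaf <- eaf %||% tab$eaf
    beta <- tab$beta
  }
  stopifnot(all(se > 0))
  if (any(is.na(n)) || any(n <= 2)) stop("sample size n must exceed 2")
  f <- (beta / se)^2
  out <- data.frame(F_stat = f, r2_explained = f / (f + n - 2))
  if (!is.null(eaf) && !all(is.na(eaf))) {
    out$r2_eaf <- 2 * beta^2 * eaf * (1 - eaf)
  }
  out
}

#' Remove SNPs named in an offline exclusion list
#'
#' Confounder/pleiotropy screening reduced to a reproducible, user-supplied
#' list (snp_id, reason), e.g. assembled from PhenoScanner or GWAS-catalog
#' lookups performed outside the pipeline.
#'
#' @param table A `sumstat_table`.
#' @param exclusion Data frame with columns `snp_id` and optionally
#'   `reason`, or a character vector of snp_ids; `NULL` is a no-op.
#' @return List with `table` (records not excluded) and `log`.
#' @export
exclude_listed <- function(table, exclusion = NULL) {
  stopifnot(inherits(table, "sumstat_table"))
  if (is.null(exclusion) ||
      (is.data.frame(exclusion) && nrow(exclusion) == 0L) ||
      length(exclusion) == 0L) {
    return(list(table = table,
                log = selection_log(list(input = nrow(table),
                                         post_exclusion = nrow(table)))))
  }
  if (!is.data.frame(exclusion)) {
    exclusion <- data.frame(snp_id = as.character(exclusion),
                            stringsAsFactors = FALSE)
  }
  if (is.null(exclusion$reason)) exclusion$reason <- "listed for exclusion"
  hit <- table$snp_id %in% exclusion$snp_id
  absent <- setdiff(exclusion$snp_id, table$snp_id)
  if (length(absent)) {
    warning("exclusion list names SNP(s) not in table: ",
            paste(utils::head(absent, 5L), collapse = ", "))
  }
  reasons <- exclusion$reason[match(table$snp_id[hit], exclusion$snp_id)]
  log <- selection_log(
    counts = list(input = nrow(table), post_exclusion = sum(!hit)),
    removals = data.frame(snp_id = table$snp_id[hit],
                          stage = rep("exclusion", sum(hit)),
                          reason = reasons, stringsAsFactors = FALSE))
  list(table = resubset(table, !hit), log = log)
}

#' Read a tab-separated exclusion list (snp_id, reason)
#' @param path File path.
#' @return Data frame with columns `snp_id`, `reason`.
#' @export
read_exclusions <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"snp_id" %in% names(df)) stop("exclusion file needs a snp_id column")
  if (is.null(df$reason)) df$reason <- "listed for exclusion"
  df[c("snp_id", "reason")]
}
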