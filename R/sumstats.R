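# GWAS summary-statistics tables and LD tables: construction, validation, I/O.
#
# The internal column vocabulary is fixed (snp_id, chrom, pos, effect_allele,
# other_allele, eaf, beta, se, pval, n); files in other dialects are read
# through a user-supplied column_map, since GWAS text files have no single
# standard header.

SUMSTAT_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n")
SUMSTAT_MANDATORY <- c("snp_id", "effect_allele", "other_allele",
                       "beta", "se", "pval")
NA_TOKENS <- c("NA", "", ".")

#' Construct a validated GWAS summary-statistics table
#'
#' One row per variant with per-allele effect estimates. Rows violating the
#' record invariants (positive standard error, distinct alleles, p-value in
#' (0,1], effect-allele frequency in (0,1) when present) are dropped with a
#' per-row reason; the rejects are attached as an attribute and a message
#' reports the count.
#'
#' @param df Data frame holding at least `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`; optionally `chrom`, `pos`, `eaf`,
#'   `n`.
#' @param trait_label Human-readable trait name.
#' @param trait_type `"continuous"` or `"binary"`. For binary traits `beta`
#'   is interpreted as a log odds ratio.
#' @param n_cases,n_controls Optional case/control counts for binary traits.
#' @return An object of class `sumstat_table`: a data frame in the canonical
#'   column order with attributes `trait_label`, `trait_type`, `rejects`.
#' @export
sumstat_table <- function(df, trait_label, trait_type = c("continuous", "binary"),
                          n_cases = NULL, n_controls = NULL) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(SUMSTAT_MANDATORY, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(SUMSTAT_COLS, names(df))) {
    df[[col]] <- if (col %in% c("chrom")) NA_character_ else NA_real_
  }
  df <- df[SUMSTAT_COLS]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) reason[bad & is.na(reason)] <<- why
  flag(is.na(df$snp_id) | df$snp_id == "", "missing snp_id")
  flag(!(df$effect_allele %in% c("A", "C", "G", "T")) |
         !(df$other_allele %in% c("A", "C", "G", "T")), "invalid allele")
  flag(df$effect_allele == df$other_allele, "identical alleles")
  flag(is.na(df$beta), "unparseable beta")
  flag(is.na(df$se) | df$se <= 0, "nonpositive se")
  flag(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "pval outside (0,1]")
  flag(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "eaf outside (0,1)")
  dup <- duplicated(df$snp_id)
  flag(dup, "duplicate snp_id")

  bad <- !is.na(reason)
  rejects <- data.frame(snp_id = df$snp_id[bad], reason = reason[bad],
                        stringsAsFactors = FALSE)
  if (nrow(rejects)) {
    message(sprintf("sumstat_table [%s]: rejected %d of %d row(s) (%s)",
                    trait_label, nrow(rejects), nrow(df),
                    paste(unique(rejects$reason), collapse = "; ")))
  }
  if (all(bad) && nrow(df) > 0) {
    stop("all ", nrow(df), " rows failed validation for trait '", trait_label, "'")
  }
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            trait_label = trait_label, trait_type = trait_type,
            n_cases = n_cases, n_controls = n_controls,
            rejects = rejects,
            class = c("sumstat_table", "data.frame"))
}

trait_label <- function(x) attr(x, "trait_label", exact = TRUE) %||% "trait"
trait_type <- function(x) attr(x, "trait_type", exact = TRUE) %||% "continuous"

# keep sumstat_table class + attributes through row subsetting
resubset <- function(table, keep) {
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("trait_label", "trait_type", "n_cases", "n_controls")) {
    attr(out, a) <- attr(table, a, exact = TRUE)
  }
  class(out) <- c("sumstat_table", "data.frame")
  out
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' @param path Path to a tab-separated file with a header row.
#' @param column_map Named character vector mapping canonical names to the
#'   file's column names, e.g. `c(snp_id = "SNP", pval = "P")`; canonical
#'   names absent from the map are looked up verbatim.
#' @param trait_label,trait_type,n_cases,n_controls Passed to
#'   [sumstat_table()].
#' @return A `sumstat_table`. Invalid rows are dropped with logged reasons.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_label = basename(path),
                          trait_type = c("continuous", "binary"),
                          n_cases = NULL, n_controls = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = NA_TOKENS,
                           check.names = FALSE, stringsAsFactors = FALSE)
  wanted <- stats::setNames(SUMSTAT_COLS, SUMSTAT_COLS)
  if (!is.null(column_map)) wanted[names(column_map)] <- unname(column_map)
  missing_mand <- SUMSTAT_MANDATORY[!(wanted[SUMSTAT_MANDATORY] %in% names(raw))]
  if (length(missing_mand)) {
    stop("column(s) not found in ", path, ": ",
         paste(wanted[missing_mand], collapse = ", "),
         " (check column_map)")
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in SUMSTAT_COLS) {
    src <- wanted[[canon]]
    df[[canon]] <- if (src %in% names(raw)) raw[[src]] else NA
  }
  sumstat_table(df, trait_label = trait_label, trait_type = trait_type,
                n_cases = n_cases, n_controls = n_controls)
}

#' Write a summary-statistics table to a tab-separated file
#'
#' Round-trip contract: `read_sumstats()` on the written file reproduces the
#' table field for field, including missing optional values (written as
#' `NA`).
#'
#' @param table A `sumstat_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstat_table"))
  df <- as.data.frame(table)
  # full precision so the round trip is exact
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "NA",
                        formatC(df[[col]], digits = 17, format = "g"))
  }
  df$chrom[is.na(df$chrom)] <- "NA"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a long-format pairwise LD table
#'
#' Expects tab-separated columns `snp_a`, `snp_b`, `r2`. Lookup through
#' [ld_r2()] is symmetric; pairs absent from the table have r-squared 0 by
#' contract. Duplicated pairs with conflicting r-squared values are an
#' error.
#'
#' @param path Path to the file.
#' @return An `ld_table` data frame.
#' @export
read_ld <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("snp_a", "snp_b", "r2") %in% names(df))) {
    stop("LD file must have columns snp_a, snp_b, r2: ", path)
  }
  ld_table(df)
}

#' Construct an LD table from snp pairs and r-squared values
#'
#' @param df Data frame with columns `snp_a`, `snp_b`, `r2`.
#' @return An `ld_table`.
#' @export
ld_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("snp_a", "snp_b", "r2") %in% names(df)))
  df <- df[c("snp_a", "snp_b", "r2")]
  df$snp_a <- as.character(df$snp_a)
  df$snp_b <- as.character(df$snp_b)
  df$r2 <- as.numeric(df$r2)
  bad <- is.na(df$r2) | df$r2 < 0 | df$r2 > 1
  if (any(bad)) {
    stop("r2 outside [0,1] for pair(s): ",
         paste(utils::head(paste(df$snp_a[bad], df$snp_b[bad], sep = "/"), 5L),
               collapse = ", "))
  }
  key <- ifelse(df$snp_a <= df$snp_b,
                paste(df$snp_a, df$snp_b, sep = "\r"),
                paste(df$snp_b, df$snp_a, sep = "\r"))
  if (anyDuplicated(key)) {
    agg <- tapply(df$r2, key, function(v) diff(range(v)))
    conflict <- names(agg)[agg > 1e-12]
    if (length(conflict)) {
      stop("conflicting duplicate LD entries for pair(s): ",
           paste(gsub("\r", "/", utils::head(conflict, 5L)), collapse = ", "))
    }
    keep <- !duplicated(key)
    df <- df[keep, , drop = FALSE]
    key <- key[keep]
  }
  rownames(df) <- NULL
  structure(df, lookup = stats::setNames(df$r2, key),
            class = c("ld_table", "data.frame"))
}

#' Symmetric LD lookup
#'
#' @param ld An `ld_table` (or `NULL`, treated as empty).
#' @param a,b Character vectors of SNP ids (recycled to a common length).
#' @return Numeric vector of r-squared values; 0 for pairs absent from the
#'   table, 1 for a SNP against itself.
#' @export
ld_r2 <- function(ld, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- ifelse(a == b, 1, 0)
  if (is.null(ld) || nrow(ld) == 0L) return(out)
  stopifnot(inherits(ld, "ld_table"))
  key <- ifelse(a <= b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  hit <- attr(ld, "lookup", exact = TRUE)[key]
  out[!is.na(hit)] <- hit[!is.na(hit)]
  out
}
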