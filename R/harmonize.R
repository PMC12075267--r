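# Allele harmonization: align exposure and outcome summary statistics onto
# the same effect allele. Matching order per SNP: direct match, allele swap
# (sign flip), strand complement (then direct/swap again). Palindromic SNPs
# (A/T, C/G) are dropped by default because their strand cannot be resolved
# from the alleles; an optional frequency rescue infers strand from the
# effect-allele frequency when it is far from 0.5.

#' Complement a nucleotide allele
#' @param a Character vector over A/C/G/T.
#' @return The complementary alleles (A<->T, C<->G).
#' @export
complement_allele <- function(a) {
  a <- toupper(as.character(a))
  bad <- !(a %in% c("A", "C", "G", "T"))
  if (any(bad)) stop("not a nucleotide allele: ", paste(unique(a[bad]), collapse = ", "))
  c(A = "T", C = "G", G = "C", T = "A")[a]
}

#' Is an allele pair palindromic (A/T or C/G)?
#' @param ea,oa Effect and other allele (vectors allowed).
#' @return Logical vector.
#' @export
is_palindromic <- function(ea, oa) {
  ea <- toupper(ea); oa <- toupper(oa)
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Construct a harmonized exposure/outcome effect set directly
#'
#' Low-level constructor for the aligned per-SNP effect pairs that every
#' estimator consumes; [harmonize()] is the file-level front end. SNPs are
#' stored in snp_id order so downstream seeded routines are independent of
#' input ordering.
#'
#' @param snp_id Character vector of variant ids (unique).
#' @param beta_x,se_x Exposure effect and standard error per SNP.
#' @param beta_y,se_y Outcome effect and standard error per SNP (already on
#'   the exposure's effect allele).
#' @param eaf Optional exposure effect-allele frequency.
#' @param exposure,outcome Trait labels.
#' @param outcome_type `"continuous"` or `"binary"` (controls odds-ratio
#'   labelling downstream).
#' @param actions Optional harmonization action log.
#' @return An object of class `harmonized_set`.
#' @export
harmonized_set <- function(snp_id, beta_x, se_x, beta_y, se_y, eaf = NULL,
                           exposure = "exposure", outcome = "outcome",
                           outcome_type = "binary", actions = NULL) {
  J <- length(snp_id)
  stopifnot(J >= 1L,
            length(beta_x) == J, length(se_x) == J,
            length(beta_y) == J, length(se_y) == J,
            all(se_x > 0), all(se_y > 0), !anyDuplicated(snp_id))
  if (is.null(eaf)) eaf <- rep(NA_real_, J)
  o <- order(snp_id)
  if (is.null(actions)) {
    actions <- data.frame(snp_id = snp_id[o], action = "kept", detail = "",
                          stringsAsFactors = FALSE)
  }
  structure(list(snp_id = snp_id[o],
                 beta_x = as.numeric(beta_x)[o], se_x = as.numeric(se_x)[o],
                 beta_y = as.numeric(beta_y)[o], se_y = as.numeric(se_y)[o],
                 eaf = as.numeric(eaf)[o],
                 exposure = exposure, outcome = outcome,
                 outcome_type = outcome_type, actions = actions),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("harmonized_set: %d SNP(s), %s -> %s\n",
              length(x$snp_id), x$exposure, x$outcome))
  if (!is.null(x$actions)) {
    print(table(x$actions$action))
  }
  invisible(x)
}

#' Number of SNPs in a harmonized set
#' @param set A `harmonized_set`.
#' @return Integer count.
#' @export
n_snps <- function(set) length(set$snp_id)

# subset a harmonized_set by logical/integer index
subset_set <- function(set, idx) {
  harmonized_set(set$snp_id[idx], set$beta_x[idx], set$se_x[idx],
                 set$beta_y[idx], set$se_y[idx], set$eaf[idx],
                 exposure = set$exposure, outcome = set$outcome,
                 outcome_type = set$outcome_type,
                 actions = set$actions)
}

#' Harmonize exposure and outcome summary statistics
#'
#' For each exposure SNP, the outcome record is aligned onto the exposure's
#' effect allele: identical orientation is kept as is; swapped alleles flip
#' the sign of the outcome effect (and map its frequency to 1-eaf); alleles
#' matching only after strand complementation are complemented and
#' re-tested; palindromic SNPs are dropped under the default policy (their
#' strand is unresolvable) or rescued from allele frequencies when both are
#' far from 0.5; anything else is dropped as a mismatch. Every decision is
#' logged per SNP.
#'
#' @param exposure,outcome `sumstat_table` objects.
#' @param palindrome_policy `"drop"` (default, conservative) or
#'   `"frequency_rescue"` (use eaf to infer strand; ambiguous SNPs with
#'   `|eaf - 0.5| <= eaf_ambiguity` on either side are still dropped).
#' @param eaf_ambiguity Half-width of the ambiguous frequency zone for the
#'   rescue policy.
#' @return A `harmonized_set` whose action log records one row per exposure
#'   SNP (`kept`, `sign-flipped`, `strand-complemented`,
#'   `dropped:palindromic`, `dropped:mismatch`, `dropped:missing`).
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop", "frequency_rescue"),
                      eaf_ambiguity = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(inherits(exposure, "sumstat_table"), inherits(outcome, "sumstat_table"))
  J <- nrow(exposure)
  if (J == 0L) stop("no exposure SNPs to harmonize")
  act <- character(J); detail <- character(J)
  beta_y <- rep(NA_real_, J); se_y <- rep(NA_real_, J)
  om <- match(exposure$snp_id, outcome$snp_id)

  for (i in seq_len(J)) {
    ea_x <- exposure$effect_allele[i]; oa_x <- exposure$other_allele[i]
    j <- om[i]
    if (is.na(j)) { act[i] <- "dropped:missing"; detail[i] <- "absent from outcome"; next }
    ea_y <- outcome$effect_allele[j]; oa_y <- outcome$other_allele[j]
    by <- outcome$beta[j]; sy <- outcome$se[j]
    fy <- outcome$eaf[j]

    if (is_palindromic(ea_x, oa_x)) {
      if (palindrome_policy == "drop") {
        act[i] <- "dropped:palindromic"
        detail[i] <- paste0(ea_x, "/", oa_x)
        next
      }
      # frequency rescue: alleles of a palindrome always "match"; infer
      # orientation from which allele is the minor one in each study
      fx <- exposure$eaf[i]
      same_pair <- (ea_y == ea_x && oa_y == oa_x) || (ea_y == oa_x && oa_y == ea_x) ||
        (complement_allele(ea_y) == ea_x && complement_allele(oa_y) == oa_x) ||
        (complement_allele(ea_y) == oa_x && complement_allele(oa_y) == ea_x)
      if (!same_pair) { act[i] <- "dropped:mismatch"; detail[i] <- "allele pair differs"; next }
      if (is.na(fx) || is.na(fy) ||
          abs(fx - 0.5) <= eaf_ambiguity || abs(fy - 0.5) <= eaf_ambiguity) {
        act[i] <- "dropped:palindromic"; detail[i] <- "ambiguous frequency"
        next
      }
      # outcome eaf refers to its reported effect allele; put it on the
      # exposure's effect allele label-wise before comparing sides
      f_on_x <- if (ea_y == ea_x || complement_allele(ea_y) == ea_x) fy else 1 - fy
      if ((fx < 0.5) == (f_on_x < 0.5)) {
        act[i] <- "kept"; detail[i] <- "palindrome, frequency-resolved"
        beta_y[i] <- by; se_y[i] <- sy
      } else {
        act[i] <- "sign-flipped"; detail[i] <- "palindrome, frequency-resolved"
        beta_y[i] <- -by; se_y[i] <- sy
      }
      next
    }

    if (ea_y == ea_x && oa_y == oa_x) {
      act[i] <- "kept"; beta_y[i] <- by; se_y[i] <- sy
    } else if (ea_y == oa_x && oa_y == ea_x) {
      act[i] <- "sign-flipped"; detail[i] <- "alleles swapped"
      beta_y[i] <- -by; se_y[i] <- sy
    } else {
      cea <- complement_allele(ea_y); coa <- complement_allele(oa_y)
      if (cea == ea_x && coa == oa_x) {
        act[i] <- "strand-complemented"; detail[i] <- "opposite strand"
        beta_y[i] <- by; se_y[i] <- sy
      } else if (cea == oa_x && coa == ea_x) {
        act[i] <- "strand-complemented"; detail[i] <- "opposite strand, swapped"
        beta_y[i] <- -by; se_y[i] <- sy
      } else {
        act[i] <- "dropped:mismatch"; detail[i] <- "allele pair differs"
      }
    }
  }

  actions <- data.frame(snp_id = exposure$snp_id, action = act,
                        detail = detail, stringsAsFactors = FALSE)
  keep <- !startsWith(act, "dropped")
  if (!any(keep)) {
    tab <- sort(table(act), decreasing = TRUE)
    stop(sprintf("harmonization left no usable SNP (largest drop category: %s, %d SNP(s))",
                 names(tab)[1L], tab[[1L]]))
  }
  harmonized_set(exposure$snp_id[keep],
                 exposure$beta[keep], exposure$se[keep],
                 beta_y[keep], se_y[keep], eaf = exposure$eaf[keep],
                 exposure = trait_label(exposure), outcome = trait_label(outcome),
                 outcome_type = trait_type(outcome),
                 actions = actions[order(actions$snp_id), ])
}

#' Write the harmonization action log to a tab-separated audit file
#' @param set A `harmonized_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_harmonization_log <- function(set, path) {
  utils::write.table(set$actions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
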