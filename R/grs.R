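# Genetic risk scores: individual-level weighted allele-dose scores and
# their association with an outcome, plus the summary-level score
# association, which collapses algebraically to fixed-effect
# inverse-variance weighting and carries its own heterogeneity statistic.

#' Individual-level genetic risk scores
#'
#' `score_i = sum_j beta_j * G_ij` over allele doses `G_ij` in {0, 1, 2}.
#' Missing doses are imputed to `2 * eaf` when frequencies are supplied;
#' otherwise the individual's score is `NA`.
#'
#' @param genotypes Numeric matrix, individuals x SNPs, entries in
#'   {0, 1, 2} (or `NA`).
#' @param betas Per-SNP weights, aligned with the matrix columns (a named
#'   vector is matched against column names when both are present).
#' @param eaf Optional per-SNP effect-allele frequencies for missing-dose
#'   imputation.
#' @return Numeric vector of per-individual scores.
#' @export
grs_individual <- function(genotypes, betas, eaf = NULL) {
  genotypes <- as.matrix(genotypes)
  if (!is.null(names(betas)) && !is.null(colnames(genotypes))) {
    if (!setequal(names(betas), colnames(genotypes))) {
      stop("beta names and genotype columns disagree")
    }
    betas <- betas[colnames(genotypes)]
  }
  if (ncol(genotypes) != length(betas)) {
    stop(sprintf("dimension mismatch: %d genotype column(s) vs %d beta(s)",
                 ncol(genotypes), length(betas)))
  }
  ok <- genotypes %in% c(0, 1, 2) | is.na(genotypes)
  if (!all(ok)) stop("genotype doses must be 0, 1, 2 or NA")
  if (anyNA(genotypes)) {
    if (!is.null(eaf)) {
      stopifnot(length(eaf) == ncol(genotypes))
      for (j in seq_len(ncol(genotypes))) {
        miss <- is.na(genotypes[, j])
        genotypes[miss, j] <- 2 * eaf[j]
      }
      message("grs_individual: imputed missing doses to 2*eaf")
    } else {
      message("grs_individual: missing doses without eaf; affected individuals scored NA")
    }
  }
  drop(genotypes %*% betas)
}

#' Association of a genetic risk score with an outcome
#'
#' Linear regression for a continuous outcome; maximum-likelihood logistic
#' regression (IRLS via `glm`) for a binary outcome, with odds-ratio
#' conversion of the slope.
#'
#' @param scores Per-individual scores.
#' @param outcome Per-individual outcome values; binary outcomes coded 0/1
#'   with both classes present.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param alpha CI level.
#' @return An `mr_estimate` for the per-unit-score effect (method
#'   `"grs_linear"` or `"grs_logistic"`).
#' @export
grs_association <- function(scores, outcome,
                            outcome_type = c("continuous", "binary"),
                            alpha = 0.05) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(length(scores) == length(outcome))
  keep <- !is.na(scores) & !is.na(outcome)
  scores <- scores[keep]; outcome <- outcome[keep]
  if (stats::sd(scores) == 0) stop("constant score: association undefined")
  if (outcome_type == "continuous") {
    fit <- stats::lm(outcome ~ scores)
    co <- summary(fit)$coefficients["scores", ]
    return(mr_estimate("grs_linear", NA_integer_, beta = co[["Estimate"]],
                       se = co[["Std. Error"]], pval = co[["Pr(>|t|)"]],
                       alpha = alpha))
  }
  if (!all(outcome %in% c(0, 1)) || length(unique(outcome)) < 2L) {
    stop("binary outcome must be coded 0/1 with both classes present")
  }
  fit <- stats::glm(outcome ~ scores, family = stats::binomial())
  mu <- stats::fitted(fit)
  if (!fit$converged || any(mu > 1 - 1e-10) || any(mu < 1e-10)) {
    stop("logistic fit did not converge (possible separation: fitted ",
         "probabilities reached 0/1)")
  }
  co <- summary(fit)$coefficients["scores", ]
  mr_estimate("grs_logistic", NA_integer_, beta = co[["Estimate"]],
              se = co[["Std. Error"]], pval = co[["Pr(>|z|)"]], alpha = alpha)
}

#' Summary-level genetic risk score association
#'
#' With per-SNP weights equal to the exposure effects `w_j = beta_xj`, the
#' score-outcome association from summary statistics is
#' `alpha_hat = sum(w_j beta_yj / se_yj^2) / sum(w_j^2 / se_yj^2)` with
#' standard error `sqrt(1 / sum(w_j^2 / se_yj^2))` — algebraically the
#' fixed-effect IVW estimate. The heterogeneity of per-SNP contributions is
#' summarized by `Q_rs = sum((beta_yj - alpha_hat * w_j)^2 / se_yj^2)` on
#' `J - 1` degrees of freedom.
#'
#' For a continuous outcome the reported odds-ratio column is `exp(beta)`,
#' kept for a uniform table shape and labelled as such.
#'
#' @param set A `harmonized_set` with at least 2 SNPs.
#' @param alpha CI level.
#' @return Object of class `grs_result`: `estimate` (an `mr_estimate`),
#'   `q_rs`, `q_df`, `p_het`.
#' @export
grs_summary <- function(set, alpha = 0.05) {
  J <- n_snps(set)
  if (J < 2L) {
    return(structure(list(estimate = NULL, q_rs = NA_real_,
                          q_df = NA_integer_, p_het = NA_real_,
                          note = "fewer than 2 SNPs"),
                     class = "grs_result"))
  }
  w <- set$beta_x
  inv_v <- 1 / set$se_y^2
  denom <- sum(w^2 * inv_v)
  a_hat <- sum(w * set$beta_y * inv_v) / denom
  se <- sqrt(1 / denom)
  q_rs <- sum((set$beta_y - a_hat * w)^2 * inv_v)
  structure(list(estimate = mr_estimate("grs_summary", J, a_hat, se, alpha = alpha),
                 q_rs = q_rs, q_df = J - 1L,
                 p_het = stats::pchisq(q_rs, df = J - 1, lower.tail = FALSE)),
            class = "grs_result")
}

#' @export
print.grs_result <- function(x, ...) {
  if (is.null(x$estimate)) { cat("grs_result:", x$note, "\n"); return(invisible(x)) }
  print(x$estimate)
  cat(sprintf("  Q_rs=%.3f (df=%d), P-Het=%.3g\n", x$q_rs, x$q_df, x$p_het))
  invisible(x)
}

#' Flatten a summary GRS result into a report row
#' @param result A `grs_result`.
#' @param exposure,outcome Trait labels.
#' @return One-row data frame (OR, CI, p, Q_rs, P-Het).
#' @export
grs_table <- function(result, exposure = "exposure", outcome = "outcome") {
  e <- result$estimate
  data.frame(exposure = exposure, outcome = outcome,
             or_ = if (is.null(e)) NA_real_ else e$or_,
             ci_low = if (is.null(e)) NA_real_ else e$ci_low,
             ci_high = if (is.null(e)) NA_real_ else e$ci_high,
             pval = if (is.null(e)) NA_real_ else e$pval,
             q_rs = result$q_rs, p_het = result$p_het,
             stringsAsFactors = FALSE)
}
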