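# Heterogeneity, pleiotropy and outlier diagnostics: Cochran's Q at the
# fixed-effect IVW estimate, Rucker's Q' for the Egger fit, leave-one-out
# sensitivity analysis, and MR-PRESSO (global RSS resampling test, per-SNP
# outlier tests with Bonferroni adjustment, and the distortion test after
# outlier removal). Stochastic routines consume a caller-supplied seed and
# operate on snp_id-sorted sets, so results do not depend on input order.

#' Cochran's Q heterogeneity statistic for the IVW fit
#'
#' `Q = sum((beta_y - beta_hat * beta_x)^2 / se_y^2)` with `J - 1` degrees
#' of freedom and an upper-tail chi-square p-value. `beta_hat` defaults to
#' the fixed-effect IVW estimate, which minimizes Q.
#'
#' @param set A `harmonized_set` with at least 2 SNPs (otherwise all fields
#'   are `NA`).
#' @param beta_hat Causal estimate at which to evaluate Q.
#' @return List with `Q`, `df`, `p`.
#' @export
cochran_q <- function(set, beta_hat = NULL) {
  J <- n_snps(set)
  if (J < 2L) return(list(Q = NA_real_, df = NA_integer_, p = NA_real_))
  if (is.null(beta_hat)) beta_hat <- ivw_sums(set)$beta
  q <- sum((set$beta_y - beta_hat * set$beta_x)^2 / set$se_y^2)
  list(Q = q, df = J - 1L, p = stats::pchisq(q, df = J - 1, lower.tail = FALSE))
}

#' Rucker's Q' heterogeneity statistic for the MR-Egger fit
#'
#' Residual heterogeneity around the Egger line on orientation-fixed data,
#' with `J - 2` degrees of freedom; always bounded above by Cochran's Q.
#'
#' @param set A `harmonized_set` with at least 3 SNPs.
#' @param fit An `egger_fit` from [mr_egger()]; refitted when omitted.
#' @return List with `Q`, `df`, `p`.
#' @export
rucker_q <- function(set, fit = NULL) {
  J <- n_snps(set)
  if (J < 3L) return(list(Q = NA_real_, df = NA_integer_, p = NA_real_))
  if (is.null(fit)) fit <- mr_egger(set)
  flip <- set$beta_x < 0
  x <- ifelse(flip, -set$beta_x, set$beta_x)
  y <- ifelse(flip, -set$beta_y, set$beta_y)
  q <- sum((y - fit$intercept - fit$slope$beta * x)^2 / set$se_y^2)
  list(Q = q, df = J - 2L, p = stats::pchisq(q, df = J - 2, lower.tail = FALSE))
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the default IVW estimate with each SNP removed in turn. An
#' estimate whose removal moves the result far from the full-set estimate
#' flags an influential (possibly pleiotropic) instrument.
#'
#' @param set A `harmonized_set`.
#' @param model IVW variant passed to [mr_ivw()].
#' @param alpha CI level.
#' @return Data frame with one row per left-out SNP (`beta`, `se`, `pval`,
#'   OR and CI; `NA` where the reduced set is too small for the model), with
#'   the full-set estimate attached as attribute `"full"`.
#' @export
leave_one_out <- function(set, model = "multiplicative_random", alpha = 0.05) {
  J <- n_snps(set)
  rows <- lapply(seq_len(J), function(j) {
    sub <- subset_set(set, -j)
    est <- tryCatch(suppressMessages(mr_ivw(sub, model = model, alpha = alpha)),
                    error = function(e) NULL)
    if (is.null(est) || (n_snps(sub) < 2L && model == "multiplicative_random")) {
      return(data.frame(snp_id = set$snp_id[j], beta = NA_real_, se = NA_real_,
                        pval = NA_real_, or_ = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, stringsAsFactors = FALSE))
    }
    data.frame(snp_id = set$snp_id[j], beta = est$beta, se = est$se,
               pval = est$pval, or_ = est$or_, ci_low = est$ci_low,
               ci_high = est$ci_high, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "full") <- tryCatch(suppressMessages(mr_ivw(set, model = model, alpha = alpha)),
                                error = function(e) NULL)
  out
}

# leave-one-out fixed-effect IVW slopes, vectorized:
# theta_(-j) = (Sxy - w_j x_j y_j) / (Sxx - w_j x_j^2)
loo_thetas <- function(x, y, w) {
  sxx <- sum(w * x^2)
  sxy <- sum(w * x * y)
  (sxy - w * x * y) / (sxx - w * x^2)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' (a) Global test: the observed residual sum of squares of each SNP around
#' its leave-one-out fixed-effect IVW prediction is compared with the RSS
#' distribution over `n_sim` simulated datasets drawn from the no-pleiotropy
#' model. (b) Outlier test: per-SNP squared residuals are compared with
#' their simulated counterparts; empirical p-values are
#' Bonferroni-multiplied by J. (c) Distortion test: when outliers are
#' flagged, the displacement of the outlier-free IVW estimate from the full
#' estimate is compared with displacements under random removal of the same
#' number of SNPs. Empirical p-values use the add-one correction and are
#' never exactly zero.
#'
#' @param set A `harmonized_set` with at least 4 SNPs (the method's
#'   minimum); below that, all fields are `NA`.
#' @param n_sim Number of simulated datasets.
#' @param seed Seed for the simulations (caller's RNG state restored).
#' @param outlier_alpha Threshold on the Bonferroni-adjusted per-SNP
#'   p-values.
#' @return Object of class `presso_result`: `global_rss_obs`, `global_p`,
#'   `n_sim`, `outlier_p` (named, adjusted), `outliers`,
#'   `corrected_estimate` (fixed-effect IVW without the outliers, or
#'   `NULL`), `distortion_p`, `seed`.
#' @export
mr_presso <- function(set, n_sim = 1000L, seed = NULL, outlier_alpha = 0.05) {
  J <- n_snps(set)
  if (J < 4L) {
    return(structure(list(global_rss_obs = NA_real_, global_p = NA_real_,
                          n_sim = as.integer(n_sim),
                          outlier_p = stats::setNames(rep(NA_real_, J), set$snp_id),
                          outliers = character(0), corrected_estimate = NULL,
                          distortion_p = NULL, seed = seed,
                          note = "fewer than 4 SNPs: MR-PRESSO not computable"),
                     class = "presso_result"))
  }
  x <- set$beta_x; y <- set$beta_y
  sx <- set$se_x; sy <- set$se_y
  w <- 1 / sy^2
  th_loo <- loo_thetas(x, y, w)
  r_obs <- y - th_loo * x
  rss_obs <- sum(w * r_obs^2)

  sim <- with_seed(seed, {
    bx <- matrix(stats::rnorm(n_sim * J, mean = rep(x, each = n_sim),
                              sd = rep(sx, each = n_sim)), nrow = n_sim)
    by <- matrix(stats::rnorm(n_sim * J, mean = rep(th_loo * x, each = n_sim),
                              sd = rep(sy, each = n_sim)), nrow = n_sim)
    list(bx = bx, by = by)
  })
  wM <- matrix(w, nrow = n_sim, ncol = J, byrow = TRUE)
  sxx_s <- drop(sim$bx^2 %*% w)
  sxy_s <- drop((sim$bx * sim$by) %*% w)
  th_s <- (sxy_s - wM * sim$bx * sim$by) / (sxx_s - wM * sim$bx^2)
  r_sim <- sim$by - th_s * sim$bx
  rss_sim <- rowSums(wM * r_sim^2)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (1 + n_sim)

  r2_obs <- matrix(r_obs^2, nrow = n_sim, ncol = J, byrow = TRUE)
  p_raw <- (1 + colSums(r_sim^2 >= r2_obs)) / (1 + n_sim)
  p_adj <- pmin(1, p_raw * J)
  names(p_adj) <- set$snp_id
  outliers <- set$snp_id[p_adj < outlier_alpha]

  corrected <- NULL; distortion_p <- NULL
  if (length(outliers) && length(outliers) <= J - 2L) {
    keep <- !(set$snp_id %in% outliers)
    corrected <- mr_ivw(subset_set(set, keep), model = "fixed")
    full_beta <- ivw_sums(set)$beta
    d_obs <- corrected$beta - full_beta
    k <- length(outliers)
    d_rand <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
      vapply(seq_len(n_sim), function(b) {
        drop_idx <- sample.int(J, k)
        s <- ivw_sums(subset_set(set, -drop_idx))
        s$beta - full_beta
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_rand) >= abs(d_obs))) / (1 + n_sim)
  }
  structure(list(global_rss_obs = rss_obs, global_p = global_p,
                 n_sim = as.integer(n_sim), outlier_p = p_adj,
                 outliers = outliers, corrected_estimate = corrected,
                 distortion_p = distortion_p, seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS_obs=%.4g, global p=%.4g (%d simulations)\n",
              x$global_rss_obs, x$global_p, x$n_sim))
  if (length(x$outliers)) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
    if (!is.null(x$distortion_p)) {
      cat(sprintf("  corrected IVW beta=%.4f, distortion p=%.4g\n",
                  x$corrected_estimate$beta, x$distortion_p))
    }
  } else cat("  no outliers flagged\n")
  invisible(x)
}

#' Full diagnostics battery for a harmonized set
#'
#' Cochran's Q at the fixed-effect IVW estimate, Rucker's Q' with the Egger
#' intercept test, leave-one-out, and MR-PRESSO.
#'
#' @param set A `harmonized_set`.
#' @param n_sim MR-PRESSO simulation count.
#' @param seed Seed for MR-PRESSO.
#' @param outlier_alpha MR-PRESSO outlier threshold.
#' @return Object of class `diagnostics_report` with fields `q_ivw`,
#'   `q_egger`, `egger_intercept`, `presso`, `loo`.
#' @export
mr_diagnostics <- function(set, n_sim = 1000L, seed = NULL, outlier_alpha = 0.05) {
  fit <- if (n_snps(set) >= 3L) mr_egger(set) else NULL
  structure(list(
    q_ivw = cochran_q(set),
    q_egger = rucker_q(set, fit),
    egger_intercept = if (is.null(fit)) {
      list(value = NA_real_, se = NA_real_, p = NA_real_)
    } else {
      list(value = fit$intercept, se = fit$intercept_se, p = fit$intercept_pval)
    },
    presso = mr_presso(set, n_sim = n_sim, seed = seed,
                       outlier_alpha = outlier_alpha),
    loo = leave_one_out(set)),
    class = "diagnostics_report")
}

#' Flatten a diagnostics report into a one-row table
#'
#' Columns follow the usual heterogeneity/pleiotropy report layout:
#' MR-PRESSO global p, Q with p for IVW and Egger, and the Egger intercept
#' with its standard error and p.
#'
#' @param report A `diagnostics_report`.
#' @param exposure,outcome Trait labels.
#' @return One-row data frame.
#' @export
diagnostics_table <- function(report, exposure = "exposure", outcome = "outcome") {
  data.frame(exposure = exposure, outcome = outcome,
             presso_global_p = report$presso$global_p,
             q_ivw = report$q_ivw$Q, q_ivw_p = report$q_ivw$p,
             q_egger = report$q_egger$Q, q_egger_p = report$q_egger$p,
             egger_intercept = report$egger_intercept$value,
             egger_intercept_se = report$egger_intercept$se,
             egger_intercept_p = report$egger_intercept$p,
             stringsAsFactors = FALSE)
}
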