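# Causal-effect estimators on a harmonized set: Wald ratio, inverse-variance
# weighting (fixed / multiplicative random effects), MR-Egger regression and
# the weighted median, plus odds-ratio conversion of log-scale estimates.

#' Convert a log-scale estimate to an odds ratio with confidence interval
#'
#' @param beta Log odds ratio (or log effect) estimate.
#' @param se Standard error, `> 0`.
#' @param alpha Two-sided level; default 0.05 gives a 95% interval.
#' @return List with `or_`, `ci_low`, `ci_high` (`exp(beta -+ z*se)`).
#' @export
to_odds_ratio <- function(beta, se, alpha = 0.05) {
  stopifnot(all(se >= 0), alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2)
  list(or_ = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se))
}

#' Construct an MR causal-effect estimate
#'
#' @param method Estimator label (e.g. `"ivw_mre"`, `"egger_slope"`).
#' @param n_snp Number of instruments used.
#' @param beta,se Estimate and standard error on the outcome scale.
#' @param pval Two-sided p-value; computed from the normal reference when
#'   omitted.
#' @param alpha Level for the confidence interval.
#' @return Object of class `mr_estimate` with the odds-ratio conversion
#'   attached.
#' @export
mr_estimate <- function(method, n_snp, beta, se, pval = NULL, alpha = 0.05) {
  stopifnot(se > 0 || (se == 0 && !is.null(pval)))
  if (is.null(pval)) pval <- z_pval(beta, se)
  orc <- to_odds_ratio(beta, se, alpha)
  structure(list(method = method, n_snp = as.integer(n_snp),
                 beta = beta, se = se, pval = pval,
                 or_ = orc$or_, ci_low = orc$ci_low, ci_high = orc$ci_high,
                 alpha = alpha),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (J=%d): beta=%.4f se=%.4f p=%.3g | OR=%.3f (%.3f-%.3f)\n",
              x$method, x$n_snp, x$beta, x$se, x$pval,
              x$or_, x$ci_low, x$ci_high))
  invisible(x)
}

#' Wald ratio causal estimate from a single instrument
#'
#' First-order standard error `se_y / |beta_x|` (the uncertainty of the
#' exposure association is ignored, as is standard for strong instruments).
#'
#' @param beta_x,se_x Exposure association and standard error.
#' @param beta_y,se_y Outcome association and standard error.
#' @param alpha CI level.
#' @return An `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y, alpha = 0.05) {
  if (beta_x == 0) stop("Wald ratio undefined for beta_x = 0")
  mr_estimate("wald", 1L, beta = beta_y / beta_x, se = se_y / abs(beta_x),
              alpha = alpha)
}

# shared weighted through-origin regression pieces
ivw_sums <- function(set) {
  w <- 1 / set$se_y^2
  sxx <- sum(w * set$beta_x^2)
  sxy <- sum(w * set$beta_x * set$beta_y)
  list(w = w, sxx = sxx, sxy = sxy, beta = sxy / sxx)
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted regression of outcome on exposure associations through the
#' origin with weights `1/se_y^2`; equivalently the inverse-variance
#' meta-analysis of the per-SNP Wald ratios. The multiplicative
#' random-effects variant (default) inflates the standard error by
#' `max(1, sqrt(Q/(J-1)))` with Cochran's Q evaluated at the fixed-effect
#' estimate, and is the common default in two-sample MR practice.
#'
#' @param set A `harmonized_set` with at least 2 SNPs (1 SNP degenerates to
#'   the Wald ratio, with a message).
#' @param model `"multiplicative_random"` or `"fixed"`.
#' @param alpha CI level.
#' @return An `mr_estimate` (method `"ivw_mre"` or `"ivw_fixed"`).
#' @export
mr_ivw <- function(set, model = c("multiplicative_random", "fixed"),
                   alpha = 0.05) {
  model <- match.arg(model)
  J <- n_snps(set)
  if (J == 0L) stop("no SNPs: estimation impossible")
  if (J == 1L) {
    message("mr_ivw: single SNP, returning the Wald ratio")
    return(wald_ratio(set$beta_x, set$se_x, set$beta_y, set$se_y, alpha))
  }
  s <- ivw_sums(set)
  se_fixed <- sqrt(1 / s$sxx)
  if (model == "fixed") {
    return(mr_estimate("ivw_fixed", J, s$beta, se_fixed, alpha = alpha))
  }
  q <- sum(s$w * (set$beta_y - s$beta * set$beta_x)^2)
  infl <- max(1, sqrt(q / (J - 1)))
  mr_estimate("ivw_mre", J, s$beta, se_fixed * infl, alpha = alpha)
}

#' MR-Egger regression
#'
#' Weighted regression of the outcome on the exposure associations with a
#' free intercept, after orienting every SNP to a non-negative exposure
#' effect. The slope estimates the causal effect; the intercept estimates
#' the average directional pleiotropy. Standard errors use multiplicative
#' residual inflation `max(1, sqrt(Q'/(J-2)))`; p-values use the t
#' reference with `J-2` degrees of freedom, which matters at the small
#' instrument counts typical of MR.
#'
#' @param set A `harmonized_set` with at least 3 SNPs.
#' @param alpha CI level.
#' @return An object of class `egger_fit`: `slope` (an `mr_estimate`),
#'   `intercept`, `intercept_se`, `intercept_pval`, plus the residual
#'   heterogeneity `q_prime` with its degrees of freedom.
#' @export
mr_egger <- function(set, alpha = 0.05) {
  J <- n_snps(set)
  if (J < 3L) stop("MR-Egger needs at least 3 SNPs (slope + intercept + residual df)")
  flip <- set$beta_x < 0
  x <- ifelse(flip, -set$beta_x, set$beta_x)
  y <- ifelse(flip, -set$beta_y, set$beta_y)
  w <- 1 / set$se_y^2
  W <- sum(w)
  xbar <- sum(w * x) / W
  ybar <- sum(w * y) / W
  sxx <- sum(w * (x - xbar)^2)
  if (sxx <= 0) stop("no spread in exposure effects; Egger slope undefined")
  slope <- sum(w * (x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  resid <- y - intercept - slope * x
  qp <- sum(w * resid^2)
  infl <- max(1, sqrt(qp / (J - 2)))
  se_slope <- infl * sqrt(1 / sxx)
  se_int <- infl * sqrt(1 / W + xbar^2 / sxx)
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df = J - 2)
  p_int <- 2 * stats::pt(-abs(intercept / se_int), df = J - 2)
  est <- mr_estimate("egger_slope", J, slope, se_slope, pval = p_slope,
                     alpha = alpha)
  structure(list(slope = est, intercept = intercept, intercept_se = se_int,
                 intercept_pval = p_int, q_prime = qp, df = J - 2L,
                 inflation = infl),
            class = "egger_fit")
}

#' @export
print.egger_fit <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept=%.4f se=%.4f p=%.3g (Q'=%.3f, df=%d)\n",
              x$intercept, x$intercept_se, x$intercept_pval, x$q_prime, x$df))
  invisible(x)
}

# weight-0.5 quantile of ordered ratios with midpoint interpolation;
# clamps to the extreme ratio when 0.5 falls outside the midpoints
weighted_median_point <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]
  ww <- w[o] / sum(w)
  p <- cumsum(ww) - ww / 2
  J <- length(th)
  if (0.5 <= p[1L]) return(th[1L])
  if (0.5 >= p[J]) return(th[J])
  i <- max(which(p <= 0.5))
  if (p[i] == 0.5) return(th[i])
  th[i] + (th[i + 1L] - th[i]) * (0.5 - p[i]) / (p[i + 1L] - p[i])
}

#' Weighted-median causal estimate
#'
#' The weight-0.5 quantile of the ordered per-SNP Wald ratios with inverse
#' variance weights `beta_x^2 / se_y^2`, consistent when at least half of
#' the weight comes from valid instruments. The standard error is the
#' standard deviation of the estimate over parametric-bootstrap replicates
#' that redraw each summary association from its sampling distribution.
#'
#' @param set A `harmonized_set` with at least 3 usable SNPs; SNPs with
#'   `beta_x = 0` are excluded with a warning.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Seed for the bootstrap (the caller's RNG state is restored).
#' @param alpha CI level.
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000L, seed = NULL, alpha = 0.05) {
  if (any(set$beta_x == 0)) {
    warning(sprintf("excluding %d SNP(s) with beta_x = 0 from the weighted median",
                    sum(set$beta_x == 0)))
    set <- subset_set(set, set$beta_x != 0)
  }
  J <- n_snps(set)
  if (J < 3L) stop("weighted median needs at least 3 SNPs with nonzero beta_x")
  est <- weighted_median_point(set$beta_y / set$beta_x,
                               set$beta_x^2 / set$se_y^2)
  boot <- with_seed(seed, {
    bx <- matrix(stats::rnorm(J * n_boot, set$beta_x, set$se_x), nrow = J)
    by <- matrix(stats::rnorm(J * n_boot, set$beta_y, set$se_y), nrow = J)
    vapply(seq_len(n_boot), function(b) {
      ok <- bx[, b] != 0
      weighted_median_point(by[ok, b] / bx[ok, b],
                            bx[ok, b]^2 / set$se_y[ok]^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  mr_estimate("weighted_median", J, est, se, alpha = alpha)
}

#' Run the standard estimator battery on a harmonized set
#'
#' IVW (default multiplicative random effects), MR-Egger slope and weighted
#' median, skipping estimators whose minimum instrument count is not met.
#'
#' @param set A `harmonized_set`.
#' @param n_boot,seed Weighted-median bootstrap controls.
#' @param alpha CI level.
#' @return Named list of `mr_estimate` objects (`ivw`, `egger`,
#'   `weighted_median`); the full `egger_fit` is attached as attribute
#'   `"egger_fit"`.
#' @export
mr_all_estimates <- function(set, n_boot = 1000L, seed = NULL, alpha = 0.05) {
  out <- list(ivw = mr_ivw(set, alpha = alpha))
  fit <- NULL
  if (n_snps(set) >= 3L) {
    fit <- mr_egger(set, alpha = alpha)
    out$egger <- fit$slope
    out$weighted_median <- mr_weighted_median(set, n_boot = n_boot,
                                              seed = seed, alpha = alpha)
  }
  attr(out, "egger_fit") <- fit
  out
}

#' Flatten estimates into a report table
#'
#' One row per method with the columns of a standard MR results table:
#' exposure, outcome, number of SNPs, method, OR with CI, and p-value.
#'
#' @param estimates List of `mr_estimate` objects (e.g. from
#'   [mr_all_estimates()]).
#' @param exposure,outcome Trait labels.
#' @return Data frame.
#' @export
estimates_table <- function(estimates, exposure = "exposure", outcome = "outcome") {
  rows <- lapply(estimates, function(e) {
    data.frame(exposure = exposure, outcome = outcome, n_snp = e$n_snp,
               method = e$method, beta = e$beta, se = e$se,
               or_ = e$or_, ci_low = e$ci_low, ci_high = e$ci_high,
               pval = e$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
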