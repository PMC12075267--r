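# Asymptotic power and sample size for two-sample MR. The IVW z statistic
# has approximate non-centrality |effect| * sqrt(n * r2 * v) where r2 is
# the exposure variance explained by the instruments and v = k(1-k) for a
# binary outcome with case fraction k (v = 1 for a continuous outcome).

#' Asymptotic power of the two-sample MR (IVW) test
#'
#' Two-sided power
#' `Phi(m - z) + Phi(-m - z)` with `m = sqrt(n * r2 * v) * |effect|` and
#' `z` the upper `alpha/2` normal quantile; at `effect = 0` this returns
#' exactly `alpha`. Power is monotone increasing in `n_outcome`, `r2_xz`
#' and `|effect|`, and symmetric in the sign of the effect.
#'
#' @param n_outcome Outcome-study sample size.
#' @param r2_xz Fraction of exposure variance explained by the instruments,
#'   in (0, 1).
#' @param effect Hypothesized causal effect: log odds ratio per SD of
#'   exposure for a binary outcome, standardized beta for a continuous one.
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param case_fraction Case fraction in (0, 1); required for binary
#'   outcomes.
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1); vectorized over the numeric arguments.
#' @export
mr_power <- function(n_outcome, r2_xz, effect,
                     outcome_type = c("binary", "continuous"),
                     case_fraction = NULL, alpha = 0.05) {
  outcome_type <- match.arg(outcome_type)
  if (any(n_outcome <= 0)) stop("n_outcome must be positive")
  if (any(r2_xz <= 0 | r2_xz >= 1)) stop("r2_xz must be in (0,1)")
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must be in (0,1)")
  v <- if (outcome_type == "binary") {
    if (is.null(case_fraction) || any(case_fraction <= 0 | case_fraction >= 1)) {
      stop("binary outcomes need case_fraction in (0,1)")
    }
    case_fraction * (1 - case_fraction)
  } else 1
  z <- stats::qnorm(1 - alpha / 2)
  m <- sqrt(n_outcome * r2_xz * v) * abs(effect)
  stats::pnorm(m - z) + stats::pnorm(-m - z)
}

#' Minimum outcome sample size for a target power
#'
#' Closed-form inversion of the one-sided approximation followed by an
#' integer search, so the returned `n` is the smallest integer with
#' `mr_power(n) >= target_power`.
#'
#' @param target_power Desired power, in `(alpha, 1)`.
#' @param r2_xz,effect,outcome_type,case_fraction,alpha As in [mr_power()].
#' @return Integer sample size.
#' @export
mr_min_n <- function(target_power, r2_xz, effect,
                     outcome_type = c("binary", "continuous"),
                     case_fraction = NULL, alpha = 0.05) {
  outcome_type <- match.arg(outcome_type)
  if (target_power <= alpha || target_power >= 1) {
    stop("target_power must lie strictly between alpha and 1")
  }
  if (effect == 0) stop("unreachable target: zero effect has power alpha at any n")
  v <- if (outcome_type == "binary") case_fraction * (1 - case_fraction) else 1
  z <- stats::qnorm(1 - alpha / 2)
  n0 <- ((stats::qnorm(target_power) + z) / (abs(effect) * sqrt(r2_xz * v)))^2
  n <- max(1L, as.integer(ceiling(n0)))
  pw <- function(nn) mr_power(nn, r2_xz, effect, outcome_type,
                              case_fraction = case_fraction, alpha = alpha)
  while (pw(n) < target_power) n <- n + 1L
  while (n > 1L && pw(n - 1L) >= target_power) n <- n - 1L
  n
}

#' Power table over grids of sample size and effect
#'
#' @param n_grid,effect_grid Numeric grids.
#' @param r2_xz,outcome_type,case_fraction,alpha As in [mr_power()].
#' @return Data frame with one row per (n, effect) combination.
#' @export
power_table <- function(n_grid, effect_grid, r2_xz,
                        outcome_type = c("binary", "continuous"),
                        case_fraction = NULL, alpha = 0.05) {
  outcome_type <- match.arg(outcome_type)
  grid <- expand.grid(n_outcome = n_grid, effect = effect_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$r2_xz <- r2_xz
  grid$power <- mr_power(grid$n_outcome, r2_xz, grid$effect, outcome_type,
                         case_fraction = case_fraction, alpha = alpha)
  grid
}
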