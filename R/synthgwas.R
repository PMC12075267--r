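# Synthetic two-sample GWAS generator with known ground truth.
#
# The sampling model: per SNP j, minor-allele frequency p_j ~ U(maf_range);
# true instrument effect gamma_j ~ N(0, gamma_sd^2) on the standardized
# exposure; pleiotropic effect alpha_j per regime (defined relative to the
# exposure-increasing allele, so a directional mean survives the Egger
# orientation step); standard errors follow the standardized-trait
# approximation se = 1/sqrt(2 n v p(1-p)) with v = k(1-k) for a binary
# outcome; observed associations are drawn as
#   beta_x ~ N(gamma, se_x^2),  beta_y ~ N(theta*gamma + alpha, se_y^2).
# Reporting artifacts (palindromic allele pairs, strand flips, allele
# swaps) and LD blocks exercise harmonization and clumping. Randomness for
# the reporting artifacts is consumed last, so two runs at the same seed
# that differ only in artifact fractions share identical underlying
# effects.

#' Simulation configuration for the two-sample GWAS generator
#'
#' Defaults emulate a two-sample design with a continuous exposure measured
#' in ~40k individuals and a binary outcome from a ~54k case-control study
#' (case fraction 0.314), with strong instruments (per-instrument exposure
#' r-squared around 0.8%).
#'
#' @param J Number of instruments.
#' @param theta True causal effect of the (standardized) exposure on the
#'   outcome (log odds ratio for a binary outcome).
#' @param n_x,n_y Exposure / outcome GWAS sample sizes.
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param case_fraction Case fraction of the outcome study (binary only).
#' @param maf_range Range of minor-allele frequencies.
#' @param gamma_sd SD of the true instrument effects on the exposure.
#' @param pleiotropy `"none"`, `"balanced"` (mean-zero direct effects) or
#'   `"directional"` (mean `mu` relative to the exposure-increasing
#'   allele).
#' @param tau SD of the pleiotropic effects.
#' @param mu Mean of directional pleiotropy.
#' @param frac_pleiotropic Fraction of instruments receiving a pleiotropic
#'   effect (the "invalid" instruments); 1 means all.
#' @param n_outliers Number of SNPs given gross pleiotropy of magnitude
#'   `outlier_scale` outcome standard errors.
#' @param outlier_scale Outlier magnitude in units of the SNP's outcome
#'   standard error.
#' @param frac_palindromic Fraction of SNPs assigned A/T or C/G allele
#'   pairs.
#' @param frac_strand_flipped Fraction of outcome records reported on the
#'   opposite strand.
#' @param frac_allele_swapped Fraction of outcome records reported with
#'   swapped alleles (effect negated).
#' @param ld_blocks Optional list of `list(size =, r2 =)` blocks of
#'   consecutive SNPs in mutual LD (compound-symmetric within block, zero
#'   between).
#' @param exposure_label,outcome_label Trait labels.
#' @param seed Integer seed; the generator is deterministic given the
#'   config.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(J = 12L, theta = 0, n_x = 39883L, n_y = 54162L,
                       outcome_type = c("binary", "continuous"),
                       case_fraction = 0.314,
                       maf_range = c(0.05, 0.5), gamma_sd = 0.15,
                       pleiotropy = c("none", "balanced", "directional"),
                       tau = 0, mu = 0, frac_pleiotropic = 1,
                       n_outliers = 0L, outlier_scale = 10,
                       frac_palindromic = 0, frac_strand_flipped = 0,
                       frac_allele_swapped = 0, ld_blocks = NULL,
                       exposure_label = "exposure", outcome_label = "outcome",
                       seed = 1L) {
  outcome_type <- match.arg(outcome_type)
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(J >= 1, n_x > 2, n_y > 2, gamma_sd >= 0, tau >= 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            frac_pleiotropic >= 0, frac_pleiotropic <= 1,
            frac_palindromic >= 0, frac_palindromic <= 1,
            frac_strand_flipped >= 0, frac_strand_flipped <= 1,
            frac_allele_swapped >= 0, frac_allele_swapped <= 1,
            n_outliers >= 0, n_outliers <= J, outlier_scale >= 0)
  if (outcome_type == "binary") {
    stopifnot(case_fraction > 0, case_fraction < 1)
  }
  structure(list(J = as.integer(J), theta = theta, n_x = n_x, n_y = n_y,
                 outcome_type = outcome_type, case_fraction = case_fraction,
                 maf_range = maf_range, gamma_sd = gamma_sd,
                 pleiotropy = pleiotropy, tau = tau, mu = mu,
                 frac_pleiotropic = frac_pleiotropic,
                 n_outliers = as.integer(n_outliers),
                 outlier_scale = outlier_scale,
                 frac_palindromic = frac_palindromic,
                 frac_strand_flipped = frac_strand_flipped,
                 frac_allele_swapped = frac_allele_swapped,
                 ld_blocks = ld_blocks,
                 exposure_label = exposure_label,
                 outcome_label = outcome_label,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# snp ids padded so lexicographic order equals numeric order
sim_snp_ids <- function(J) sprintf("rs%05d", seq_len(J))

# chromosome/position layout: each LD block (or singleton SNP) is a group;
# groups on the same chromosome sit 25 Mb apart (beyond any clumping
# window), SNPs within a block 10 kb apart
sim_positions <- function(J, ld_blocks) {
  sizes <- integer(0)
  if (!is.null(ld_blocks)) sizes <- vapply(ld_blocks, function(b) as.integer(b$size), 1L)
  stopifnot(sum(sizes) <= J)
  group <- integer(J)
  g <- 0L; i <- 1L
  for (s in sizes) { g <- g + 1L; group[i:(i + s - 1L)] <- g; i <- i + s }
  while (i <= J) { g <- g + 1L; group[i] <- g; i <- i + 1L }
  chrom <- ((group - 1L) %% 22L) + 1L
  rank_on_chrom <- stats::ave(group, chrom, FUN = function(v) match(v, unique(v)))
  offset <- stats::ave(seq_len(J), group, FUN = seq_along) - 1L
  pos <- 1e6 + (rank_on_chrom - 1L) * 2.5e7 + offset * 1e4
  list(chrom = as.character(chrom), pos = pos, group = group,
       block_of = if (length(sizes)) group else integer(0), sizes = sizes)
}

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' @param config A [sim_config()].
#' @return List with `exposure` and `outcome` (`sumstat_table` objects),
#'   `ld` (an `ld_table`, empty unless LD blocks are configured), and
#'   `truth` (class `sim_truth`: `theta`, per-SNP `gamma`, `alpha`, `maf`,
#'   `se_x`, `se_y`, `outlier_ids`, `r2_xz` the realized exposure variance
#'   explained, and the seed).
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  J <- config$J
  with_seed(config$seed, {
    # --- core draws (order fixed; artifacts consume randomness last) ---
    maf <- stats::runif(J, config$maf_range[1], config$maf_range[2])
    gamma <- stats::rnorm(J, 0, config$gamma_sd)
    v <- if (config$outcome_type == "binary") {
      config$case_fraction * (1 - config$case_fraction)
    } else 1
    se_x <- 1 / sqrt(2 * config$n_x * maf * (1 - maf))
    se_y <- 1 / sqrt(2 * config$n_y * v * maf * (1 - maf))

    alpha <- numeric(J)
    if (config$pleiotropy != "none" && config$tau + abs(config$mu) > 0) {
      n_pl <- round(config$frac_pleiotropic * J)
      which_pl <- if (n_pl >= J) seq_len(J) else sample.int(J, n_pl)
      draw <- stats::rnorm(length(which_pl),
                           if (config$pleiotropy == "directional") config$mu else 0,
                           config$tau)
      if (config$pleiotropy == "directional") {
        # directional relative to the exposure-increasing allele
        alpha[which_pl] <- sign(gamma[which_pl]) * draw
      } else {
        alpha[which_pl] <- draw
      }
    }
    outlier_idx <- integer(0)
    if (config$n_outliers > 0) {
      outlier_idx <- sort(sample.int(J, config$n_outliers))
      alpha[outlier_idx] <- sample(c(-1, 1), config$n_outliers, replace = TRUE) *
        config$outlier_scale * se_y[outlier_idx]
    }

    beta_x <- stats::rnorm(J, gamma, se_x)
    beta_y <- stats::rnorm(J, config$theta * gamma + alpha, se_y)

    # --- allele pairs, then reporting artifacts ---
    pal <- stats::runif(J) < config$frac_palindromic
    pal_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                        ncol = 2, byrow = TRUE)
    npal_pairs <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                           "G", "A", "G", "T", "T", "C", "T", "G"),
                         ncol = 2, byrow = TRUE)
    pick_pal <- sample.int(4L, J, replace = TRUE)
    pick_npal <- sample.int(8L, J, replace = TRUE)
    ea <- ifelse(pal, pal_pairs[pick_pal, 1], npal_pairs[pick_npal, 1])
    oa <- ifelse(pal, pal_pairs[pick_pal, 2], npal_pairs[pick_npal, 2])

    layout <- sim_positions(J, config$ld_blocks)
    ids <- sim_snp_ids(J)

    flip <- stats::runif(J) < config$frac_strand_flipped
    swap <- stats::runif(J) < config$frac_allele_swapped
    ea_y <- ea; oa_y <- oa
    beta_y_rep <- beta_y; eaf_y <- maf
    ea_y[flip] <- complement_allele(ea[flip])
    oa_y[flip] <- complement_allele(oa[flip])
    tmp <- ea_y[swap]; ea_y[swap] <- oa_y[swap]; oa_y[swap] <- tmp
    beta_y_rep[swap] <- -beta_y_rep[swap]
    eaf_y[swap] <- 1 - eaf_y[swap]

    exposure <- sumstat_table(
      data.frame(snp_id = ids, chrom = layout$chrom, pos = layout$pos,
                 effect_allele = ea, other_allele = oa, eaf = maf,
                 beta = beta_x, se = se_x, pval = z_pval(beta_x, se_x),
                 n = config$n_x, stringsAsFactors = FALSE),
      trait_label = config$exposure_label, trait_type = "continuous")
    outcome <- sumstat_table(
      data.frame(snp_id = ids, chrom = layout$chrom, pos = layout$pos,
                 effect_allele = ea_y, other_allele = oa_y, eaf = eaf_y,
                 beta = beta_y_rep, se = se_y,
                 pval = z_pval(beta_y_rep, se_y),
                 n = config$n_y, stringsAsFactors = FALSE),
      trait_label = config$outcome_label, trait_type = config$outcome_type,
      n_cases = if (config$outcome_type == "binary") {
        round(config$case_fraction * config$n_y)
      } else NULL)

    ld <- sim_ld_table(ids, layout, config$ld_blocks)
    truth <- structure(list(theta = config$theta, gamma = gamma, alpha = alpha,
                            maf = maf, se_x = se_x, se_y = se_y,
                            outlier_ids = ids[outlier_idx],
                            r2_xz = sum(2 * maf * (1 - maf) * gamma^2),
                            seed = config$seed),
                       class = "sim_truth")
    list(exposure = exposure, outcome = outcome, ld = ld, truth = truth)
  })
}

sim_ld_table <- function(ids, layout, ld_blocks) {
  rows <- list()
  if (!is.null(ld_blocks)) {
    start <- 1L
    for (b in seq_along(ld_blocks)) {
      s <- as.integer(ld_blocks[[b]]$size)
      r2 <- ld_blocks[[b]]$r2
      members <- ids[start:(start + s - 1L)]
      if (s >= 2L) {
        pairs <- utils::combn(members, 2L)
        rows[[length(rows) + 1L]] <-
          data.frame(snp_a = pairs[1, ], snp_b = pairs[2, ], r2 = r2,
                     stringsAsFactors = FALSE)
      }
      start <- start + s
    }
  }
  if (!length(rows)) {
    return(ld_table(data.frame(snp_a = character(), snp_b = character(),
                               r2 = numeric(), stringsAsFactors = FALSE)))
  }
  ld_table(do.call(rbind, rows))
}

#' Simulate individual-level genotype, exposure and outcome data
#'
#' Allele doses are Binomial(2, p); the exposure is the genetic value plus
#' standard normal noise; a continuous outcome is `theta * exposure` plus
#' direct genetic effects plus noise, and a binary outcome follows a
#' logistic model on the same linear predictor with the intercept placed to
#' hit the configured case fraction.
#'
#' @param config A [sim_config()] (sample sizes `n_x`/`n_y` are ignored
#'   here; the reporting-artifact fields do not apply).
#' @param n_individuals Number of individuals.
#' @return List with `genotypes` (n x J dose matrix, columns named by SNP),
#'   `exposure`, `outcome`, `truth`.
#' @export
simulate_individual <- function(config, n_individuals) {
  stopifnot(inherits(config, "sim_config"), n_individuals > 1)
  J <- config$J
  n <- as.integer(n_individuals)
  with_seed(config$seed, {
    maf <- stats::runif(J, config$maf_range[1], config$maf_range[2])
    gamma <- stats::rnorm(J, 0, config$gamma_sd)
    alpha <- numeric(J)
    if (config$pleiotropy != "none" && config$tau + abs(config$mu) > 0) {
      n_pl <- round(config$frac_pleiotropic * J)
      which_pl <- if (n_pl >= J) seq_len(J) else sample.int(J, n_pl)
      draw <- stats::rnorm(length(which_pl),
                           if (config$pleiotropy == "directional") config$mu else 0,
                           config$tau)
      alpha[which_pl] <- if (config$pleiotropy == "directional") {
        sign(gamma[which_pl]) * draw
      } else draw
    }
    G <- matrix(stats::rbinom(n * J, 2L, rep(maf, each = n)), nrow = n)
    colnames(G) <- sim_snp_ids(J)
    exposure <- drop(G %*% gamma) + stats::rnorm(n)
    eta <- config$theta * exposure + drop(G %*% alpha)
    outcome <- if (config$outcome_type == "continuous") {
      eta + stats::rnorm(n)
    } else {
      b0 <- stats::qlogis(config$case_fraction) - mean(eta)
      stats::rbinom(n, 1L, stats::plogis(b0 + eta))
    }
    truth <- structure(list(theta = config$theta, gamma = gamma, alpha = alpha,
                            maf = maf, outlier_ids = character(0),
                            seed = config$seed),
                       class = "sim_truth")
    list(genotypes = G, exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Per-SNP association summary statistics from individual-level data
#'
#' Simple (one SNP at a time) regression of the trait on allele dose:
#' least squares for a continuous trait, logistic regression for a binary
#' one. Produces the same table format as [simulate_two_sample()], letting
#' summary-level methods be checked against their individual-level
#' counterparts.
#'
#' @param genotypes n x J dose matrix with SNP column names.
#' @param trait Per-individual trait vector.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param trait_label Label for the resulting table.
#' @return A `sumstat_table`.
#' @export
summarize_individual <- function(genotypes, trait,
                                 trait_type = c("continuous", "binary"),
                                 trait_label = "trait") {
  trait_type <- match.arg(trait_type)
  G <- as.matrix(genotypes)
  n <- nrow(G)
  stopifnot(length(trait) == n, n > 3)
  J <- ncol(G)
  alleles <- matrix(c("A", "G"), nrow = J, ncol = 2, byrow = TRUE)
  if (trait_type == "continuous") {
    gbar <- colMeans(G)
    sxx <- colSums(G^2) - n * gbar^2
    ybar <- mean(trait)
    sxy <- drop(crossprod(G, trait)) - n * gbar * ybar
    beta <- sxy / sxx
    res_ss <- sum((trait - ybar)^2) - beta * sxy
    se <- sqrt(res_ss / (n - 2) / sxx)
  } else {
    beta <- se <- numeric(J)
    for (j in seq_len(J)) {
      fit <- stats::glm(trait ~ G[, j], family = stats::binomial())
      co <- summary(fit)$coefficients
      beta[j] <- co[2, 1]; se[j] <- co[2, 2]
    }
  }
  sumstat_table(
    data.frame(snp_id = colnames(G), effect_allele = alleles[, 1],
               other_allele = alleles[, 2], eaf = colMeans(G) / 2,
               beta = beta, se = se, pval = z_pval(beta, se), n = n,
               stringsAsFactors = FALSE),
    trait_label = trait_label, trait_type = trait_type)
}

#' Write a simulated dataset to disk
#'
#' Emits the exposure/outcome tables and LD table in the package's
#' tab-separated formats and the ground truth as a JSON sidecar.
#'
#' @param sim Result of [simulate_two_sample()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             outcome = file.path(dir, "outcome.tsv"),
             ld = file.path(dir, "ld.tsv"),
             truth = file.path(dir, "truth.json"))
  write_sumstats(sim$exposure, paths["exposure"])
  write_sumstats(sim$outcome, paths["outcome"])
  utils::write.table(as.data.frame(sim$ld), paths["ld"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$truth), paths["truth"], digits = NA,
                       auto_unbox = TRUE)
  invisible(paths)
}
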