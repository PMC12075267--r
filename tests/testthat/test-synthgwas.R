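test_that("the generator is deterministic given the seed", {
  cfg <- sim_config(J = 25, theta = 0.1, seed = 5, frac_palindromic = 0.2,
                    frac_strand_flipped = 0.2, frac_allele_swapped = 0.2,
                    ld_blocks = list(list(size = 4, r2 = 0.9)))
  a <- simulate_two_sample(cfg)
  b <- simulate_two_sample(cfg)
  expect_identical(as.data.frame(a$exposure), as.data.frame(b$exposure))
  expect_identical(as.data.frame(a$outcome), as.data.frame(b$outcome))
  expect_identical(unclass(a$truth), unclass(b$truth))
  c <- simulate_two_sample(sim_config(J = 25, theta = 0.1, seed = 6))
  expect_false(identical(a$exposure$beta, c$exposure$beta))
})

test_that("observed effects scatter around truth with the stated noise", {
  cfg <- sim_config(J = 4000, theta = 0, seed = 12)
  sim <- simulate_two_sample(cfg)
  zx <- (sim$exposure$beta - sim$truth$gamma) / sim$truth$se_x
  expect_lt(abs(sd(zx) - 1), 0.05)
  zy <- (sim$outcome$beta - 0 * sim$truth$gamma) / sim$truth$se_y
  expect_lt(abs(sd(zy) - 1), 0.05)
  # standard errors follow the 1/sqrt(2 n v p(1-p)) law
  v <- 0.314 * (1 - 0.314)
  expect_equal(sim$exposure$se,
               1 / sqrt(2 * cfg$n_x * sim$truth$maf * (1 - sim$truth$maf)))
  expect_equal(sim$outcome$se,
               1 / sqrt(2 * cfg$n_y * v * sim$truth$maf * (1 - sim$truth$maf)))
})

test_that("palindromic fraction, LD blocks and outliers land as configured", {
  cfg <- sim_config(J = 200, seed = 9, frac_palindromic = 0.3,
                    n_outliers = 5, outlier_scale = 8,
                    ld_blocks = list(list(size = 5, r2 = 0.7),
                                     list(size = 3, r2 = 0.4)))
  sim <- simulate_two_sample(cfg)
  pal <- is_palindromic(sim$exposure$effect_allele, sim$exposure$other_allele)
  expect_gt(mean(pal), 0.2); expect_lt(mean(pal), 0.4)
  expect_identical(length(sim$truth$outlier_ids), 5L)
  big <- abs(sim$truth$alpha[match(sim$truth$outlier_ids, sim$exposure$snp_id)])
  expect_equal(big, 8 * sim$truth$se_y[match(sim$truth$outlier_ids,
                                             sim$exposure$snp_id)])
  # LD table holds exactly the within-block pairs at the block r2
  expect_identical(nrow(sim$ld), 13L)
  expect_equal(ld_r2(sim$ld, "rs00001", "rs00002"), 0.7)
  expect_equal(ld_r2(sim$ld, "rs00006", "rs00008"), 0.4)
  expect_equal(ld_r2(sim$ld, "rs00001", "rs00009"), 0)
  # block members share a chromosome and sit within clumping range
  b1 <- match(sprintf("rs%05d", 1:5), sim$exposure$snp_id)
  expect_identical(length(unique(sim$exposure$chrom[b1])), 1L)
  expect_lt(diff(range(sim$exposure$pos[b1])), 1e6)
})

test_that("reporting artifacts change the files but not the harmonized analysis", {
  base_cfg <- sim_config(J = 40, theta = 0.25, seed = 31)
  art_cfg <- sim_config(J = 40, theta = 0.25, seed = 31,
                        frac_strand_flipped = 0.3, frac_allele_swapped = 0.3)
  clean <- simulate_two_sample(base_cfg)
  messy <- simulate_two_sample(art_cfg)
  expect_identical(clean$exposure$beta, messy$exposure$beta)
  expect_false(identical(clean$outcome$beta, messy$outcome$beta))
  h_clean <- harmonize(clean$exposure, clean$outcome)
  h_messy <- harmonize(messy$exposure, messy$outcome)
  expect_identical(h_clean$beta_y, h_messy$beta_y)
  expect_identical(mr_ivw(h_clean), mr_ivw(h_messy))
})

test_that("directional pleiotropy targets only the configured fraction", {
  cfg <- sim_config(J = 100, seed = 17, pleiotropy = "directional",
                    mu = 0.05, tau = 0.005, frac_pleiotropic = 0.3)
  sim <- simulate_two_sample(cfg)
  hit <- sim$truth$alpha != 0
  expect_identical(sum(hit), 30L)
  # directional relative to the exposure-increasing allele
  oriented <- sign(sim$truth$gamma[hit]) * sim$truth$alpha[hit]
  expect_gt(mean(oriented), 0.03)
})

test_that("individual-level doses, null behavior and recovery are coherent", {
  cfg <- sim_config(J = 10, theta = 0.3, gamma_sd = 0.3,
                    outcome_type = "continuous", seed = 8)
  ind <- simulate_individual(cfg, 2000)
  expect_true(all(ind$genotypes %in% 0:2))
  expect_identical(dim(ind$genotypes), c(2000L, 10L))
  # summary stats derived from the sample recover theta
  xs <- summarize_individual(ind$genotypes, ind$exposure, "continuous")
  ys <- summarize_individual(ind$genotypes, ind$outcome, "continuous")
  s <- harmonized_set(xs$snp_id, xs$beta, xs$se, ys$beta, ys$se)
  est <- mr_ivw(s)
  expect_lt(abs(est$beta - 0.3), 3 * est$se)
  # no genetic effects and no causal effect: association is null-calibrated
  null_cfg <- sim_config(J = 6, theta = 0, gamma_sd = 0,
                         outcome_type = "continuous", seed = 10)
  hits <- 0L
  for (r in 1:150) {
    nul <- simulate_individual(sim_config(J = 6, theta = 0, gamma_sd = 0,
                                          outcome_type = "continuous",
                                          seed = 100 + r), 300)
    p <- summary(lm(nul$outcome ~ nul$genotypes[, 1]))$coefficients[2, 4]
    hits <- hits + (p < 0.05)
  }
  expect_gt(hits / 150, 0.015)
  expect_lt(hits / 150, 0.1)
  # binary outcome hits the configured case fraction
  bin <- simulate_individual(sim_config(J = 5, outcome_type = "binary",
                                        case_fraction = 0.3, seed = 3), 4000)
  expect_lt(abs(mean(bin$outcome) - 0.3), 0.05)
})

test_that("simulated datasets round-trip to disk with their truth sidecar", {
  dir <- withr::local_tempdir()
  sim <- simulate_two_sample(sim_config(J = 8, seed = 2,
                                        ld_blocks = list(list(size = 2, r2 = 0.5))))
  paths <- write_simulation(sim, dir)
  back <- read_sumstats(paths["exposure"], trait_label = "exposure")
  expect_equal(back$beta, sim$exposure$beta)
  ld <- read_ld(paths["ld"])
  expect_equal(ld_r2(ld, "rs00001", "rs00002"), 0.5)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$gamma, sim$truth$gamma)
})
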