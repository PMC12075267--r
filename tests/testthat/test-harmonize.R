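make_pair <- function(ea_x, oa_x, ea_y, oa_y, beta_y = 0.05,
                      eaf_x = 0.2, eaf_y = 0.2) {
  exp_df <- sumstat_df(1)
  exp_df$effect_allele <- ea_x; exp_df$other_allele <- oa_x
  exp_df$beta <- 0.1; exp_df$eaf <- eaf_x
  out_df <- sumstat_df(1)
  out_df$effect_allele <- ea_y; out_df$other_allele <- oa_y
  out_df$beta <- beta_y; out_df$eaf <- eaf_y
  list(exposure = sumstat_table(exp_df, trait_label = "x"),
       outcome = sumstat_table(out_df, trait_label = "y"))
}

test_that("allele complement is the A<->T C<->G involution and rejects junk", {
  expect_identical(complement_allele(c("A", "C", "G", "T")),
                   c(A = "T", C = "G", G = "C", T = "A"))
  for (a in c("A", "C", "G", "T")) {
    expect_identical(unname(complement_allele(complement_allele(a))), a)
  }
  expect_error(complement_allele("N"), "not a nucleotide")
})

test_that("palindrome detection is unordered over {A,T} and {C,G}", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("G", "C"))
  expect_false(is_palindromic("A", "G"))
  expect_equal(is_palindromic(c("A", "T", "C", "G"), c("T", "A", "G", "C")),
               rep(TRUE, 4))
})

test_that("swapped alleles flip the outcome effect sign", {
  p <- make_pair("A", "G", "G", "A", beta_y = 0.05)
  h <- harmonize(p$exposure, p$outcome)
  expect_equal(h$beta_y, -0.05)
  expect_identical(h$actions$action, "sign-flipped")
})

test_that("opposite-strand records are complemented and kept", {
  p <- make_pair("A", "G", "T", "C", beta_y = 0.05)
  h <- harmonize(p$exposure, p$outcome)
  expect_equal(h$beta_y, 0.05)
  expect_identical(h$actions$action, "strand-complemented")
  # opposite strand AND swapped: complement then sign flip
  p2 <- make_pair("A", "G", "C", "T", beta_y = 0.05)
  expect_equal(harmonize(p2$exposure, p2$outcome)$beta_y, -0.05)
})

test_that("palindromic SNPs are dropped under the default policy, with a log", {
  p <- make_pair("A", "T", "A", "T")
  big <- make_pair("C", "G", "C", "G")
  exposure <- sumstat_table(rbind(cbind(as.data.frame(p$exposure)),
                                  transform(as.data.frame(big$exposure),
                                            snp_id = "rs9")),
                            trait_label = "x")
  outcome <- sumstat_table(rbind(as.data.frame(p$outcome),
                                 transform(as.data.frame(big$outcome),
                                           snp_id = "rs9", beta = 0.2)),
                           trait_label = "y")
  nonpal <- make_pair("A", "G", "A", "G")
  exposure2 <- sumstat_table(rbind(as.data.frame(exposure),
                                   transform(as.data.frame(nonpal$exposure),
                                             snp_id = "rs10")),
                             trait_label = "x")
  outcome2 <- sumstat_table(rbind(as.data.frame(outcome),
                                  transform(as.data.frame(nonpal$outcome),
                                            snp_id = "rs10")),
                            trait_label = "y")
  h <- harmonize(exposure2, outcome2)
  expect_identical(h$snp_id, "rs10")
  expect_identical(sum(h$actions$action == "dropped:palindromic"), 2L)
  # all-palindromic input cannot be estimated and names the drop category
  expect_error(harmonize(exposure, outcome), "dropped:palindromic")
})

test_that("missing and irreconcilable records are dropped with reasons", {
  p <- make_pair("A", "G", "A", "C")  # allele pair differs
  h <- tryCatch(harmonize(p$exposure, p$outcome), error = function(e) e)
  expect_match(conditionMessage(h), "dropped:mismatch")
  exp2 <- sumstat_table(sumstat_df(2), trait_label = "x")
  out2 <- sumstat_table(sumstat_df(1), trait_label = "y")
  h2 <- harmonize(exp2, out2)
  expect_identical(h2$actions$action[h2$actions$snp_id == exp2$snp_id[2]],
                   "dropped:missing")
})

test_that("frequency rescue keeps unambiguous palindromes and drops eaf near 0.5", {
  same_side <- make_pair("A", "T", "A", "T", beta_y = 0.05,
                         eaf_x = 0.2, eaf_y = 0.25)
  h <- harmonize(same_side$exposure, same_side$outcome,
                 palindrome_policy = "frequency_rescue")
  expect_equal(h$beta_y, 0.05)
  flipped <- make_pair("A", "T", "A", "T", beta_y = 0.05,
                       eaf_x = 0.2, eaf_y = 0.8)
  h2 <- harmonize(flipped$exposure, flipped$outcome,
                  palindrome_policy = "frequency_rescue")
  expect_equal(h2$beta_y, -0.05)
  ambiguous <- make_pair("A", "T", "A", "T", eaf_x = 0.48, eaf_y = 0.2)
  expect_error(harmonize(ambiguous$exposure, ambiguous$outcome,
                         palindrome_policy = "frequency_rescue"),
               "dropped:palindromic")
})

test_that("flipping the reported outcome allele leaves the harmonized set identical", {
  cfg <- sim_config(J = 15, theta = 0.15, seed = 99)
  sim <- simulate_two_sample(cfg)
  h0 <- harmonize(sim$exposure, sim$outcome)
  flipped <- as.data.frame(sim$outcome)
  flip_rows <- seq(1, 15, by = 2)
  tmp <- flipped$effect_allele[flip_rows]
  flipped$effect_allele[flip_rows] <- flipped$other_allele[flip_rows]
  flipped$other_allele[flip_rows] <- tmp
  flipped$beta[flip_rows] <- -flipped$beta[flip_rows]
  flipped$eaf[flip_rows] <- 1 - flipped$eaf[flip_rows]
  h1 <- harmonize(sim$exposure,
                  sumstat_table(flipped, trait_label = "outcome",
                                trait_type = "binary"))
  expect_identical(h0$beta_y, h1$beta_y)
  expect_identical(h0$se_y, h1$se_y)
  expect_identical(h0$snp_id, h1$snp_id)
})

test_that("harmonizing an already-aligned pair is the identity", {
  cfg <- sim_config(J = 10, theta = 0.1, seed = 7)
  sim <- simulate_two_sample(cfg)
  h0 <- harmonize(sim$exposure, sim$outcome)
  # rebuild the outcome on the exposure's alleles from the harmonized set
  exp_df <- as.data.frame(sim$exposure)
  exp_df <- exp_df[match(h0$snp_id, exp_df$snp_id), ]
  out_df <- exp_df
  out_df$beta <- h0$beta_y
  out_df$se <- h0$se_y
  out_df$pval <- 2 * pnorm(-abs(out_df$beta / out_df$se))
  h1 <- harmonize(sumstat_table(exp_df, trait_label = "x"),
                  sumstat_table(out_df, trait_label = "y"))
  expect_identical(h1$beta_y, h0$beta_y)
  expect_true(all(h1$actions$action == "kept"))
})
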