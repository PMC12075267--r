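test_that("genome-wide filter is a strict p-value cut preserving order", {
  df <- sumstat_df(4)
  df$pval <- c(1e-9, 4.9e-8, 5e-8, 1e-3)
  tab <- sumstat_table(df, trait_label = "t")
  out <- select_genomewide(tab)
  expect_identical(out$snp_id, df$snp_id[1:2])  # boundary 5e-8 excluded
  expect_identical(select_genomewide(out)$snp_id, out$snp_id)  # idempotent
  expect_identical(nrow(select_genomewide(tab, 1.0)), 4L)
  empty <- sumstat_table(sumstat_df(0), trait_label = "t")
  expect_identical(nrow(select_genomewide(empty)), 0L)
})

test_that("clumping keeps the more significant SNP of a correlated close pair", {
  df <- sumstat_df(2)
  df$chrom <- "1"
  df$pos <- c(1e6, 1e6 + 5000)
  df$pval <- c(1e-10, 1e-9)
  tab <- sumstat_table(df, trait_label = "t")
  ld <- ld_table(data.frame(snp_a = df$snp_id[1], snp_b = df$snp_id[2], r2 = 0.8))
  res <- clump(tab, ld)
  expect_identical(res$table$snp_id, df$snp_id[1])
  expect_identical(res$log$counts$post_clump, 1L)
  expect_match(res$log$removals$reason, "r2 > 0.001")
  # same pair on different chromosomes, or with no LD entry: both survive
  df2 <- df; df2$chrom <- c("1", "2")
  expect_identical(nrow(clump(sumstat_table(df2, trait_label = "t"), ld)$table), 2L)
  expect_identical(nrow(clump(tab, NULL)$table), 2L)
})

test_that("greedy clumping matches the brute-force reference on random instances", {
  set.seed(402)
  for (rep in 1:40) {
    J <- sample(2:12, 1)
    df <- sumstat_df(J)
    df$chrom <- as.character(sample(1:2, J, replace = TRUE))
    df$pos <- sample(seq(1e6, 3e7, by = 1e5), J)
    df$pval <- 10^-runif(J, 3, 12)
    pairs <- t(combn(df$snp_id, 2))
    take <- runif(nrow(pairs)) < 0.4
    ld <- if (any(take)) {
      ld_table(data.frame(snp_a = pairs[take, 1], snp_b = pairs[take, 2],
                          r2 = runif(sum(take))))
    } else NULL
    tab <- sumstat_table(df, trait_label = "t")
    got <- clump(tab, ld, r2_threshold = 0.05, window_kb = 10000)$table
    expect_identical(sort(got$snp_id),
                     clump_bruteforce(df, ld, 0.05, 10000))
    # retained set is pairwise independent under the rule
    if (nrow(got) > 1) {
      idx <- t(combn(seq_len(nrow(got)), 2))
      same <- got$chrom[idx[, 1]] == got$chrom[idx[, 2]] &
        abs(got$pos[idx[, 1]] - got$pos[idx[, 2]]) <= 1e7
      r2 <- ld_r2(ld, got$snp_id[idx[, 1]], got$snp_id[idx[, 2]])
      expect_true(all(r2[same] <= 0.05))
    }
    # invariant to input row order
    perm <- sample(J)
    got2 <- clump(sumstat_table(df[perm, ], trait_label = "t"), ld,
                  r2_threshold = 0.05, window_kb = 10000)$table
    expect_identical(got$snp_id, got2$snp_id)
  }
})

test_that("records without positions are treated as independent, with a warning", {
  df <- sumstat_df(3)
  df$pos[2] <- NA
  ld <- ld_table(data.frame(snp_a = df$snp_id[1], snp_b = df$snp_id[2], r2 = 0.99))
  df$pos[c(1, 3)] <- c(1e6, 1.1e6)
  expect_warning(res <- clump(sumstat_table(df, trait_label = "t"), ld),
                 "lack chrom/pos")
  expect_identical(nrow(res$table), 3L)
})

test_that("proxy search returns the argmax above the strict threshold", {
  cand <- sumstat_table(sumstat_df(3), trait_label = "t")
  ld <- ld_table(data.frame(snp_a = "rsX", snp_b = cand$snp_id,
                            r2 = c(0.95, 0.92, 0.5)))
  expect_identical(find_proxy("rsX", cand, ld), cand$snp_id[1])
  ld_low <- ld_table(data.frame(snp_a = "rsX", snp_b = cand$snp_id,
                                r2 = c(0.9, 0.88, 0.5)))
  expect_identical(find_proxy("rsX", cand, ld_low), NA_character_)  # strict >
  empty <- sumstat_table(sumstat_df(0), trait_label = "t")
  expect_identical(find_proxy("rsX", empty, ld), NA_character_)
})

test_that("F statistic and variance explained follow (beta/se)^2 and F/(F+n-2)", {
  s <- instrument_strength(beta = 0.1, se = 0.01, n = 10000)
  expect_equal(s$F_stat, 100)
  expect_equal(s$r2_explained, 100 / 10098)
  expect_equal(instrument_strength(0, 0.3, 100)$F_stat, 0)
  expect_equal(instrument_strength(0, 0.3, 100)$r2_explained, 0)
  expect_equal(instrument_strength(-0.1, 0.01, 10000), s)  # sign-flip invariant
  # strictly increasing in F at fixed n
  f <- instrument_strength(beta = seq(0.01, 0.3, by = 0.01), se = 0.01, n = 500)
  expect_true(all(diff(f$r2_explained) > 0))
  expect_true(all(f$r2_explained >= 0 & f$r2_explained < 1))
  expect_error(instrument_strength(0.1, 0.01, n = 2), "exceed 2")
  # eaf-based r2 is reported alongside when frequencies are available
  tab <- sumstat_table(sumstat_df(3), trait_label = "t")
  expect_true("r2_eaf" %in% names(instrument_strength(tab)))
})

test_that("exclusion lists remove named SNPs with logged reasons", {
  tab <- sumstat_table(sumstat_df(4), trait_label = "t")
  excl <- data.frame(snp_id = tab$snp_id[2],
                     reason = "associated with a confounder trait")
  res <- exclude_listed(tab, excl)
  expect_identical(res$table$snp_id, tab$snp_id[-2])
  expect_identical(res$log$removals$reason, "associated with a confounder trait")
  expect_identical(exclude_listed(tab, NULL)$table$snp_id, tab$snp_id)
  expect_warning(res2 <- exclude_listed(tab, data.frame(snp_id = "rs_absent")),
                 "not in table")
  expect_identical(res2$table$snp_id, tab$snp_id)
})
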