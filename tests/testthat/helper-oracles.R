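# independent brute-force reference for the greedy clumping rule: visit
# SNPs in (pval, snp_id) order; keep one unless a previously kept SNP on
# the same chromosome within the window has r2 above the threshold with it
clump_bruteforce <- function(tab, ld, r2_threshold, window_kb) {
  ord <- order(tab$pval, tab$snp_id)
  kept <- integer(0)
  for (i in ord) {
    blocked <- FALSE
    for (k in kept) {
      if (is.na(tab$pos[i]) || is.na(tab$pos[k])) next
      if (tab$chrom[i] == tab$chrom[k] &&
          abs(tab$pos[i] - tab$pos[k]) <= window_kb * 1000 &&
          ld_r2(ld, tab$snp_id[i], tab$snp_id[k]) > r2_threshold) {
        blocked <- TRUE
        break
      }
    }
    if (!blocked) kept <- c(kept, i)
  }
  sort(tab$snp_id[kept])
}

# random clumping instance: J SNPs on 1-2 chromosomes with random LD
random_clump_instance <- function(J) {
  df <- sumstat_df(J)
  df$chrom <- as.character(sample(1:2, J, replace = TRUE))
  df$pos <- sample(seq(1e6, 3e7, by = 1e5), J)
  df$pval <- 10^-runif(J, 3, 12)
  ld <- NULL
  if (J >= 2) {
    pairs <- t(combn(df$snp_id, 2))
    take <- runif(nrow(pairs)) < 0.4
    if (any(take)) {
      ld <- ld_table(data.frame(snp_a = pairs[take, 1], snp_b = pairs[take, 2],
                                r2 = runif(sum(take))))
    }
  }
  list(df = df, ld = ld)
}
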