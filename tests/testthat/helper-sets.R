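# shared builders for small fixtures, all generated in code

# harmonized set straight from numbers
make_set <- function(beta_x, beta_y, se_x = NULL, se_y = NULL,
                     ids = sprintf("rs%05d", seq_along(beta_x)), ...) {
  J <- length(beta_x)
  if (is.null(se_x)) se_x <- rep(0.05, J)
  if (is.null(se_y)) se_y <- rep(0.05, J)
  harmonized_set(ids, beta_x, se_x, beta_y, se_y, ...)
}

# random valid harmonized set
random_set <- function(J = 8, seed = 1, theta = 0.2) {
  set.seed(seed)
  bx <- rnorm(J, 0, 0.2)
  bx[abs(bx) < 0.02] <- 0.02
  sy <- runif(J, 0.01, 0.1)
  make_set(bx, theta * bx + rnorm(J, 0, sy), se_x = runif(J, 0.005, 0.02),
           se_y = sy)
}

# minimal valid summary-stat data frame
sumstat_df <- function(n = 3, ids = sprintf("rs%05d", seq_len(n))) {
  if (n == 0) return(sumstat_df(1)[0, ])
  data.frame(snp_id = ids, chrom = "1", pos = seq_len(n) * 1e6,
             effect_allele = rep(c("A", "C", "G"), length.out = n),
             other_allele = rep(c("G", "T", "A"), length.out = n),
             eaf = seq(0.1, 0.45, length.out = n),
             beta = seq(0.05, 0.2, length.out = n), se = 0.01,
             pval = 10^-seq(9, 12, length.out = n), n = 10000,
             stringsAsFactors = FALSE)
}

# harmonized set built directly from an artifact-free simulation
set_from_sim <- function(sim) {
  harmonized_set(sim$exposure$snp_id, sim$exposure$beta, sim$exposure$se,
                 sim$outcome$beta, sim$outcome$se, eaf = sim$exposure$eaf,
                 exposure = attr(sim$exposure, "trait_label"),
                 outcome = attr(sim$outcome, "trait_label"))
}
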