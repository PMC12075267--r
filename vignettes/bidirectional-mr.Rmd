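---
title: "Bidirectional two-sample Mendelian randomization with bimr: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional two-sample MR: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimr)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables to ask whether an exposure (here, the motivating case is a
circulating protein such as adiponectin) causally affects an outcome
(case-control neurodegenerative disease status, or a related quantitative
trait). Two-sample MR needs only per-variant GWAS summary statistics: the
association of each instrument with the exposure, $(\hat\beta_{Xj},
\sigma_{Xj})$, from one study, and with the outcome, $(\hat\beta_{Yj},
\sigma_{Yj})$, from another. A *bidirectional* analysis repeats the whole
procedure with the roles of the two traits swapped, re-selecting
instruments from the other trait's own summary statistics, to probe
reverse causation.

The inference rests on three assumptions: instruments are robustly
associated with the exposure; they are independent of confounders of the
exposure-outcome relation; and they affect the outcome only through the
exposure (no horizontal pleiotropy). The package's diagnostics exist
because the third assumption is the fragile one.

## Pipeline and estimators

`mr_run()` chains the stages; each is exported on its own.

**Instrument selection.** Exposure SNPs with $p < 5\times10^{-8}$
(strict inequality) are clumped greedily by p-value: the best remaining
SNP is accepted and every remaining SNP on the same chromosome within
10,000 kb whose $r^2$ with it exceeds 0.001 is discarded. The printed
PLINK-style setting "$r^2 > 0.001$" is interpreted as the removal
condition — the conventional clumping semantics — since retaining only
high-LD pairs would defeat the stated purpose of independence. Ties on
p-value break by snp_id, so the result is independent of input row
order. Records without positions cannot be distance-checked; they are
treated as independent and a warning is logged. Instruments missing from
the outcome study may be replaced by a proxy in high LD ($r^2 > 0.9$,
strict), taking the best-correlated candidate. Confounder screening is an
offline exclusion list (snp_id, reason) rather than a live database
query, for reproducibility. Per-SNP instrument strength is reported as
$F = (\hat\beta/\sigma)^2$ with variance explained through the identity
$r^2 = F/(F + n - 2)$, which needs no allele frequency; when frequencies
are present the approximation $2\hat\beta^2 p(1-p)$ is reported alongside.

**Harmonization.** Outcome records are aligned to the exposure's effect
allele: identical orientation is kept; swapped alleles negate
$\hat\beta_Y$ (and map frequency to $1-f$); pairs matching only after
strand complementation are complemented and re-tested. Palindromic SNPs
(A/T, C/G) are dropped by default — their strand cannot be resolved from
alleles — matching the conservative practice of the motivating analysis.
An optional `frequency_rescue` policy infers strand when both studies'
effect-allele frequencies are at least 0.08 away from 0.5; it is off by
default because some consortium files omit frequencies. Strand matching
is attempted before dropping because only palindromes are truly
unresolvable. Every decision is logged per SNP and exportable as an
audit table.

**Estimation.** With harmonized pairs $(\hat\beta_{Xj}, \hat\beta_{Yj})$:

- *IVW*: weighted regression through the origin,
  $\hat\theta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j
  \hat\beta_{Xj}^2$ with $w_j = 1/\sigma_{Yj}^2$ — algebraically the
  inverse-variance meta-analysis of the per-SNP Wald ratios
  $\hat\beta_{Yj}/\hat\beta_{Xj}$. The default is the multiplicative
  random-effects variant, which inflates the fixed-effect standard error
  by $\max(1, \sqrt{Q/(J-1)})$; the paper-style fixed-effect variant is
  available with `model = "fixed"`. The truncation at 1 means the
  estimator never claims more precision than the fixed-effect model,
  at the cost of mild conservatism under the null.
- *MR-Egger*: the same regression with a free intercept after orienting
  every SNP to $\hat\beta_{Xj} \ge 0$; the slope estimates the causal
  effect, the intercept the average directional pleiotropy. Standard
  errors use $\max(1, \sqrt{Q'/(J-2)})$ inflation, and p-values use the
  $t_{J-2}$ reference — at the 7-15 instruments typical of these
  analyses the normal reference would be anticonservative.
- *Weighted median*: the weight-0.5 quantile of the ordered Wald ratios
  with weights $\hat\beta_{Xj}^2/\sigma_{Yj}^2$, interpolating linearly
  across cumulative-weight midpoints and clamping to the extreme ratio
  when 0.5 falls outside them (defined behavior at tiny $J$). Its
  standard error is a seeded parametric bootstrap (default 1000
  replicates) redrawing each summary association from its sampling
  distribution; nonparametric resampling of SNPs is not meaningful at
  $J \sim 10$.

Wald ratios use the first-order standard error $\sigma_{Yj} /
|\hat\beta_{Xj}|$, ignoring exposure-side noise, as is standard for
genome-wide-significant instruments. Log-scale estimates are reported as
odds ratios with $\exp(\hat\theta \pm z_{1-\alpha/2}\,\mathrm{se})$
intervals; for continuous outcomes the same column is exp(beta), kept
for a uniform table shape and labelled as such.

**Diagnostics.** Cochran's $Q = \sum_j w_j (\hat\beta_{Yj} -
\hat\theta_{\mathrm{fixed}} \hat\beta_{Xj})^2$ on $J-1$ df; Rücker's
$Q'$ around the Egger fit on $J-2$ df ($Q' \le Q$ always); the Egger
intercept test; leave-one-out re-estimation; and MR-PRESSO. The
MR-PRESSO global test compares the observed residual sum of squares
around leave-one-out fixed-effect predictions with its distribution over
`n_sim` datasets simulated under no pleiotropy; per-SNP outlier p-values
are Bonferroni-multiplied by $J$; when outliers are flagged, the
corrected (outlier-free) fixed-effect IVW estimate is reported with a
distortion p-value comparing its displacement against random removals of
the same number of SNPs. All Monte-Carlo p-values use the add-one
correction, so they are never exactly zero and never below
$1/(n_\mathrm{sim}+1)$. Every stochastic routine takes an explicit seed,
draws in snp_id-sorted order, and restores the caller's RNG state, which
makes reports byte-identical across reruns and independent of input
ordering. MR-PRESSO requires $J \ge 4$; below its minimum (and below
$J=2$ for $Q$, $J=3$ for Egger/$Q'$) routines return not-computable
markers rather than numbers.

**Genetic risk score.** The individual-level score is $\mathrm{GRS}_i =
\sum_j \beta_j G_{ij}$ over allele doses $G_{ij} \in \{0,1,2\}$
(missing doses imputed to $2f_j$ when frequencies are supplied,
otherwise the individual is not scored), associated with the outcome by
linear or logistic regression. The summary-level analogue weights by the
exposure effects, $w_j = \hat\beta_{Xj}$:
$\hat\alpha = \sum w_j \hat\beta_{Yj}/\sigma_{Yj}^2 \big/ \sum
w_j^2/\sigma_{Yj}^2$, which is algebraically identical to the
fixed-effect IVW estimate — the package asserts this identity to 1e-10
in its tests rather than maintaining two code paths blindly. Its
heterogeneity statistic $Q_{rs} = \sum_j (\hat\beta_{Yj} - \hat\alpha
w_j)^2/\sigma_{Yj}^2$ is reported on $J-1$ df (one fitted parameter).

**Power.** The IVW z-statistic has approximate non-centrality
$|\theta|\sqrt{n \cdot r^2_{XZ} \cdot v}$, with $r^2_{XZ}$ the exposure
variance explained by the instruments and $v = k(1-k)$ for a binary
outcome with case fraction $k$ (1 for continuous). `mr_power()` returns
the two-sided form $\Phi(m - z_{1-\alpha/2}) + \Phi(-m - z_{1-\alpha/2})$,
which equals exactly $\alpha$ at $\theta = 0$ and is monotone in $n$,
$r^2_{XZ}$ and $|\theta|$. The source the motivating analysis cites for
power is an online calculator without printed formulas; this standard
non-centrality approximation is adopted instead and validated against
simulation (closed form within 0.04 of empirical IVW rejection over an
$(n, \theta)$ grid), a contract a web tool cannot offer.
`mr_min_n()` inverts it in closed form, then verifies minimality by
integer search.

## The synthetic-data generator

No consortium summary data ship with the package, and the motivating
datasets have no printed accessions, so validation runs on
`simulate_two_sample()`, which draws for SNP $j$:

$$p_j \sim U(\mathrm{maf}); \quad \gamma_j \sim N(0, \gamma_{sd}^2);
\quad \hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2); \quad
\hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j, \sigma_{Yj}^2)$$

with the standardized-trait standard errors $\sigma = 1/\sqrt{2 n v
p(1-p)}$. Defaults are fixed once as the study conditions the package
emulates: exposure GWAS $n_X = 39{,}883$ (the scale of the consortium
adiponectin GWAS); outcome a case-control study of $n_Y = 54{,}162$ at
case fraction 0.314 (the scale of a consortium Alzheimer's disease
case-control GWAS); minor-allele frequencies in (0.05, 0.5);
$\gamma_{sd} = 0.15$, giving per-instrument exposure $r^2$ around 0.8%
and mean instrument $F$ in the hundreds — strong cis-dominated
instruments, as for circulating adiponectin; $J = 12$ instruments,
within the 10-15 range such analyses retain.

Pleiotropy regimes: `none`; `balanced`, $\alpha_j \sim N(0, \tau^2)$;
`directional`, $\alpha_j = \mathrm{sign}(\gamma_j)\, N(\mu, \tau^2)$.
Directional pleiotropy is defined **relative to the exposure-increasing
allele**: reported effect alleles are arbitrary labels, and a mean
pleiotropic effect is only a meaningful notion in the oriented frame —
with pleiotropy attached to arbitrary allele labels, the Egger
orientation step would cancel any directional mean by construction.
`frac_pleiotropic` restricts the regime to a subset of "invalid"
instruments; `n_outliers` SNPs instead receive gross effects of
`outlier_scale` outcome standard errors, exercising MR-PRESSO. Instrument
effects are drawn once per seed and shared by both samples: the design
treats instruments as fixed, and winner's curse is deliberately not
modelled.

Reporting artifacts emulate real file heterogeneity: a configurable
fraction of palindromic allele pairs, of outcome records reported on the
opposite strand, and of records with swapped alleles (effect negated,
frequency complemented). Artifact randomness is consumed *after* all
core draws, so two runs at the same seed differing only in artifact
fractions share identical underlying effects — this is what lets the
test suite assert that harmonization absorbs 30% strand flips plus 30%
allele swaps with bit-identical downstream estimates. LD, when
configured, is compound-symmetric within blocks of consecutive SNPs and
zero between blocks: enough structure to exercise clumping and proxy
logic without a coalescent model. `simulate_individual()` produces
genotype-dose, exposure and outcome vectors under the same parameters
(binomial doses, logistic link for binary outcomes with the intercept
placed to hit the case fraction), and `summarize_individual()` turns
them back into summary statistics, closing the loop between the
individual-level and summary-level GRS code paths.

What the generator does **not** emulate — and hence what passing tests
do not certify about real data: realistic LD from a reference panel,
sample overlap between the two studies, winner's curse from in-sample
instrument discovery, population stratification, non-normal effect-size
distributions, and binary-trait summary statistics produced by actual
logistic regressions rather than the variance approximation.

## Numerical choices and edge cases

- Threshold comparisons are strict exactly where the conventions are
  strict: $p < 5\times10^{-8}$, proxy $r^2 > 0.9$, clump removal
  $r^2 > 0.001$, significance $p < 0.05$.
- Clumping ties break by (pval, snp_id); proxy ties by (r2 descending,
  snp_id). Absent LD pairs count as $r^2 = 0$; a SNP against itself is 1.
- Harmonized sets store SNPs in snp_id order; seeded routines therefore
  consume randomness identically whatever the input order.
- Empirical p-values use $(1 + \#\{\cdot\})/(1 + n_\mathrm{sim})$.
- A single instrument degenerates IVW to the Wald ratio (logged);
  `beta_x = 0` SNPs are excluded from ratio-based estimators with a
  warning.
- Human-readable exports round to 3 decimals (p-values to 3 significant
  figures); `report.json` keeps full precision, and the tests assert the
  in-memory and exported numbers agree.

## Validation scale

The statistical acceptance checks in `tests/testthat/test-acceptance.R`
run at: 1000 null replicates for IVW calibration (J=50,
$n_X=n_Y=10^5$) with a KS uniformity check; 500 replicates for recovery
and coverage of $\theta = 0.2$ (J=30); 200 replicates each for Egger
intercept recovery ($\mu = 0.05$) and the weighted-median-vs-IVW bias
comparison under 30% invalid instruments; 100 detection and 200 size
replicates for MR-PRESSO at `n_sim = 1000`; 1000 replicates for the
Cochran-Q null mean; and 1000 replicates per cell of a 3×3
$(n, \theta)$ power grid. The Egger-recovery block applies the
pipeline's genome-wide selection step before estimation: instrument sets
in this design are post-selection objects, and unselected
near-zero-effect SNPs are exactly the ones whose orientation under the
$\hat\beta_X \ge 0$ convention is noise — including them tests a
scenario the method never sees. `scripts/acceptance.R` recomputes the
same families of quantities from scratch at a caller-chosen seed.

## Known limitations

Beyond the generator's simplifications listed above: the pipeline is
biallelic-SNP only (indels and multi-allelics fail validation at
read time); palindrome frequency rescue needs frequencies in both
studies; MR-PRESSO's multi-parameter extensions and $I^2$ for Egger are
not implemented; no multiple-testing correction is applied across a
multi-trait screen (flagged in the report header as a caveat — the
motivating analysis applies none either, and one null trait in the
worked example duly crosses $p < 0.05$ by chance); and the power
formula, like any asymptotic approximation, is only as good as its
agreement with simulation, which is what the grid test measures.
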