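# End-to-end bidirectional analysis: instrument selection -> clumping ->
# exclusion -> proxy substitution -> harmonization -> estimation ->
# diagnostics -> summary GRS, run forward (exposure -> outcome(s)) and/or
# reverse (each outcome -> exposure, with instruments re-selected from the
# outcome's own summary statistics). All stochastic steps are seeded
# deterministically from the run seed.

#' Run configuration for the bidirectional MR pipeline
#'
#' @param exposure A `sumstat_table` or a file path.
#' @param outcomes A `sumstat_table`/path or a (named) list of them: the
#'   multi-trait screen runs the same exposure against each outcome.
#' @param exposure_column_map,outcome_column_map Column maps for file
#'   inputs (see [read_sumstats()]).
#' @param ld An `ld_table`, a file path, or `NULL`.
#' @param exclusions Exclusion data frame (`snp_id`, `reason`), path, or
#'   `NULL`.
#' @param p_threshold Instrument significance threshold.
#' @param clump_r2,clump_kb Clumping parameters.
#' @param proxy_r2 Minimum r-squared for proxy substitution of instruments
#'   missing from the outcome (needs `ld`).
#' @param palindrome_policy Passed to [harmonize()].
#' @param n_boot Weighted-median bootstrap replicates.
#' @param n_sim MR-PRESSO simulations.
#' @param alpha Significance level / CI level.
#' @param direction `"forward"`, `"reverse"` or `"both"`.
#' @param seed Integer master seed.
#' @param output_dir Directory for report files, or `NULL` to skip writing.
#' @return Object of class `run_config`.
#' @export
run_config <- function(exposure, outcomes,
                       exposure_column_map = NULL, outcome_column_map = NULL,
                       ld = NULL, exclusions = NULL,
                       p_threshold = 5e-8, clump_r2 = 0.001, clump_kb = 10000,
                       proxy_r2 = 0.9,
                       palindrome_policy = c("drop", "frequency_rescue"),
                       n_boot = 1000L, n_sim = 1000L, alpha = 0.05,
                       direction = c("both", "forward", "reverse"),
                       seed = 1L, output_dir = NULL) {
  direction <- match.arg(direction)
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(p_threshold > 0, p_threshold <= 1, clump_r2 >= 0, clump_r2 <= 1,
            clump_kb > 0, proxy_r2 >= 0, proxy_r2 < 1,
            alpha > 0, alpha < 1, n_boot >= 2, n_sim >= 2)
  if (is.character(exposure)) {
    exposure <- read_sumstats(exposure, column_map = exposure_column_map)
  }
  if (inherits(outcomes, "sumstat_table") || is.character(outcomes)) {
    outcomes <- list(outcomes)
  }
  outcomes <- lapply(outcomes, function(o) {
    if (is.character(o)) read_sumstats(o, column_map = outcome_column_map) else o
  })
  labels <- vapply(outcomes, trait_label, character(1))
  if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
    names(outcomes) <- make.unique(labels)
  }
  if (is.character(ld)) ld <- read_ld(ld)
  if (is.character(exclusions)) exclusions <- read_exclusions(exclusions)
  structure(list(exposure = exposure, outcomes = outcomes, ld = ld,
                 exclusions = exclusions, p_threshold = p_threshold,
                 clump_r2 = clump_r2, clump_kb = clump_kb, proxy_r2 = proxy_r2,
                 palindrome_policy = palindrome_policy,
                 n_boot = as.integer(n_boot), n_sim = as.integer(n_sim),
                 alpha = alpha, direction = direction, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

# one exposure -> outcome analysis; pair_seed feeds every stochastic step
run_pair <- function(exp_tab, out_tab, cfg, pair_seed) {
  sel <- select_genomewide(exp_tab, cfg$p_threshold)
  cl <- clump(sel, cfg$ld, r2_threshold = cfg$clump_r2, window_kb = cfg$clump_kb)
  ex <- exclude_listed(cl$table, cfg$exclusions)
  inst <- ex$table

  # proxy pass: instruments missing from the outcome may be replaced by a
  # high-LD variant present in both datasets
  proxy_log <- data.frame(snp_id = character(), proxy = character(),
                          stringsAsFactors = FALSE)
  if (!is.null(cfg$ld)) {
    missing_ids <- setdiff(inst$snp_id, out_tab$snp_id)
    for (id in missing_ids) {
      cand <- resubset(out_tab, out_tab$snp_id %in%
                         setdiff(intersect(out_tab$snp_id, exp_tab$snp_id),
                                 inst$snp_id))
      proxy <- find_proxy(id, cand, cfg$ld, min_r2 = cfg$proxy_r2)
      if (!is.na(proxy)) {
        inst <- resubset(exp_tab,
                         exp_tab$snp_id %in% c(setdiff(inst$snp_id, id), proxy))
        proxy_log <- rbind(proxy_log,
                           data.frame(snp_id = id, proxy = proxy,
                                      stringsAsFactors = FALSE))
      }
    }
  }

  hset <- harmonize(inst, out_tab, palindrome_policy = cfg$palindrome_policy)
  est <- mr_all_estimates(hset, n_boot = cfg$n_boot, seed = pair_seed,
                          alpha = cfg$alpha)
  diag <- mr_diagnostics(hset, n_sim = cfg$n_sim, seed = pair_seed + 1L,
                         outlier_alpha = cfg$alpha)
  grs <- grs_summary(hset, alpha = cfg$alpha)

  counts <- list(input = nrow(exp_tab), post_threshold = nrow(sel),
                 post_clump = nrow(cl$table), post_exclusion = nrow(ex$table),
                 harmonized = n_snps(hset))
  list(exposure = trait_label(exp_tab), outcome = trait_label(out_tab),
       selection = selection_log(counts, rbind(cl$log$removals, ex$log$removals)),
       proxy_log = proxy_log, harmonization = hset$actions,
       n_snp = n_snps(hset), estimates = est, egger_fit = attr(est, "egger_fit"),
       diagnostics = diag, grs = grs, seed = pair_seed)
}

#' Run the full bidirectional MR analysis
#'
#' Executes the pipeline for every exposure-outcome pair implied by the
#' configured direction. A pair whose estimation is impossible (e.g. no
#' surviving instruments) is recorded as an error without aborting the
#' remaining pairs. When `output_dir` is set, writes tab-separated
#' estimate/diagnostic/GRS/forest tables, per-pair audit logs, and a
#' machine-readable JSON of every number.
#'
#' @param cfg A [run_config()].
#' @return Object of class `run_report`: per-pair results, the flattened
#'   tables, and the configuration echo.
#' @export
mr_run <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  pairs <- list()
  idx <- 0L
  add_pair <- function(exp_tab, out_tab, tag) {
    idx <<- idx + 1L
    pair_seed <- cfg$seed + 101L * idx
    res <- tryCatch(run_pair(exp_tab, out_tab, cfg, pair_seed),
                    error = function(e) {
                      list(exposure = trait_label(exp_tab),
                           outcome = trait_label(out_tab),
                           error = conditionMessage(e))
                    })
    res$direction <- tag
    pairs[[paste(tag, trait_label(exp_tab), trait_label(out_tab), sep = ":")]] <<- res
  }
  if (cfg$direction %in% c("both", "forward")) {
    for (out_tab in cfg$outcomes) add_pair(cfg$exposure, out_tab, "forward")
  }
  if (cfg$direction %in% c("both", "reverse")) {
    for (out_tab in cfg$outcomes) add_pair(out_tab, cfg$exposure, "reverse")
  }

  ok <- Filter(function(p) is.null(p$error), pairs)
  est_tab <- do.call(rbind, c(lapply(ok, function(p) {
    cbind(direction = p$direction,
          estimates_table(p$estimates, p$exposure, p$outcome))
  }), list(make.row.names = FALSE)))
  diag_tab <- do.call(rbind, c(lapply(ok, function(p) {
    cbind(direction = p$direction,
          diagnostics_table(p$diagnostics, p$exposure, p$outcome))
  }), list(make.row.names = FALSE)))
  grs_tab <- do.call(rbind, c(lapply(ok, function(p) {
    cbind(direction = p$direction, grs_table(p$grs, p$exposure, p$outcome))
  }), list(make.row.names = FALSE)))

  report <- structure(list(pairs = pairs, estimates = est_tab,
                           diagnostics = diag_tab, grs = grs_tab,
                           forest = forest_table(est_tab, alpha = cfg$alpha),
                           seed = cfg$seed, alpha = cfg$alpha,
                           package_version = as.character(utils::packageVersion("bimr"))),
                      class = "run_report")
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

#' Forest-plot-ready table
#'
#' One row per (direction, exposure, outcome, method) with the estimate,
#' confidence interval, p-value and a significance flag at `alpha`
#' (strict `<`), the plot-ready content of a multi-trait MR forest plot.
#'
#' @param estimates The `estimates` table of a `run_report` (or the report
#'   itself).
#' @param alpha Significance threshold.
#' @return Data frame with a logical `significant` column.
#' @export
forest_table <- function(estimates, alpha = 0.05) {
  if (inherits(estimates, "run_report")) estimates <- estimates$estimates
  if (is.null(estimates) || nrow(estimates) == 0L) {
    return(data.frame(direction = character(), exposure = character(),
                      outcome = character(), method = character(),
                      beta = numeric(), ci_low = numeric(), ci_high = numeric(),
                      or_ = numeric(), pval = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  data.frame(direction = estimates$direction, exposure = estimates$exposure,
             outcome = estimates$outcome, method = estimates$method,
             beta = estimates$beta, ci_low = estimates$ci_low,
             ci_high = estimates$ci_high, or_ = estimates$or_,
             pval = estimates$pval,
             significant = estimates$pval < alpha,
             stringsAsFactors = FALSE)
}

# round for the human-readable exports only; the JSON keeps full precision
round_table <- function(df) {
  for (col in names(df)) {
    if (!is.numeric(df[[col]])) next
    if (grepl("pval|_p$|p_het", col)) {
      df[[col]] <- signif(df[[col]], 3)
    } else if (!col %in% c("n_snp")) {
      df[[col]] <- round(df[[col]], 3)
    }
  }
  df
}

#' Write a run report to disk
#'
#' Tab-separated tables (estimates, diagnostics, GRS, forest, per-pair
#' selection and harmonization logs; values rounded to 3 decimals,
#' p-values to 3 significant figures) plus `report.json` with every number
#' at full precision. Byte-identical across reruns at the same
#' configuration and seed.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    utils::write.table(round_table(df), file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(report$estimates, "estimates.tsv")
  wt(report$diagnostics, "diagnostics.tsv")
  wt(report$grs, "grs.tsv")
  wt(report$forest, "forest.tsv")
  logs <- do.call(rbind, c(lapply(names(report$pairs), function(nm) {
    p <- report$pairs[[nm]]
    if (!is.null(p$error)) return(NULL)
    cbind(pair = nm, p$harmonization)
  }), list(make.row.names = FALSE)))
  if (!is.null(logs)) wt(logs, "harmonization.tsv")
  jsonlite::write_json(report_to_list(report), file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(dir)
}

# strip closures/classes so the report serializes deterministically
report_to_list <- function(report) {
  strip <- function(x) {
    if (inherits(x, "mr_estimate")) return(unclass(x))
    if (inherits(x, "egger_fit")) {
      return(lapply(unclass(x), strip))
    }
    if (inherits(x, c("presso_result", "grs_result", "diagnostics_report",
                      "harmonized_set", "bimr_selection_log", "sim_truth"))) {
      return(lapply(unclass(x), strip))
    }
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  list(seed = report$seed, alpha = report$alpha,
       package_version = report$package_version,
       note = paste("significance flagged at p <", report$alpha,
                    "with no multiple-testing correction across traits"),
       pairs = lapply(report$pairs, function(p) {
         if (!is.null(p$error)) return(list(exposure = p$exposure,
                                            outcome = p$outcome,
                                            direction = p$direction,
                                            error = p$error))
         list(direction = p$direction, exposure = p$exposure,
              outcome = p$outcome, n_snp = p$n_snp, seed = p$seed,
              selection_counts = p$selection$counts,
              estimates = lapply(p$estimates, unclass),
              egger_intercept = if (is.null(p$egger_fit)) NULL else
                list(value = p$egger_fit$intercept,
                     se = p$egger_fit$intercept_se,
                     p = p$egger_fit$intercept_pval),
              diagnostics = strip(p$diagnostics),
              grs = strip(p$grs))
       }))
}
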