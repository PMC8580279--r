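# Deterministic per-replicate seed: fold a key string into [0, 2^31 - 62).
# Same (master_seed, key) always gives the same stream regardless of how
# replicates are scheduled, so grid results are independent of worker count.
derive_seed <- function(master_seed, ...) {
  key <- paste(c(master_seed, ...), collapse = "|")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483587
  as.integer(h)
}

#' Run one Monte-Carlo replicate of the two-sample MR pipeline
#'
#' Simulates a cohort, splits it into non-overlapping exposure and outcome
#' halves, computes the per-variant exposure (X) GWAS and outcome (Y) GWAS
#' on the respective halves both with and without adjustment for the
#' covariable W, and runs [run_four_combinations()]. Deterministic given
#' `(config, replicate_index, master_seed)`.
#'
#' @param config A [scenario_config()]; its own `seed` field is ignored in
#'   favour of the derived replicate seed.
#' @param replicate_index Positive integer identifying the replicate.
#' @param master_seed Integer master seed for the whole experiment.
#' @param f_threshold Instrument-strength threshold; default 10.
#' @return A data.frame with one row per adjustment combination and columns
#'   `scenario`, `variant_mode`, `beta_xy_null`, `replicate`, `combination`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `n_instruments`, `mean_f`,
#'   `residual_scale`, `estimable`, `beta_xy_true`.
#' @export
run_replicate <- function(config, replicate_index, master_seed = 1L,
                          f_threshold = 10) {
  seed <- derive_seed(master_seed, scenario_id(config), config$variant_mode,
                      config$beta_xy_null, replicate_index)
  cfg <- config
  cfg$seed <- seed
  cohort <- simulate_cohort(cfg)
  halves <- split_samples(cohort)
  ex <- halves$exposure
  ou <- halves$outcome

  gx_u <- run_gwas(ex$genotypes, ex$phenotypes$X, trait_label = "X")
  gx_a <- run_gwas(ex$genotypes, ex$phenotypes$X, ex$phenotypes$W,
                   trait_label = "X")
  gy_u <- run_gwas(ou$genotypes, ou$phenotypes$Y, trait_label = "Y")
  gy_a <- run_gwas(ou$genotypes, ou$phenotypes$Y, ou$phenotypes$W,
                   trait_label = "Y")

  four <- run_four_combinations(gx_u, gx_a, gy_u, gy_a, f_threshold)
  rows <- lapply(combination_labels, function(lbl) {
    el <- four[[lbl]]
    r <- el$result
    data.frame(scenario = scenario_id(config),
               variant_mode = config$variant_mode,
               beta_xy_null = config$beta_xy_null,
               replicate = as.integer(replicate_index),
               combination = lbl,
               estimate = r$estimate, se = r$se,
               ci_low = r$ci_low, ci_high = r$ci_high,
               n_instruments = el$n_instruments,
               mean_f = el$mean_f,
               residual_scale = r$residual_scale,
               estimable = r$estimable,
               beta_xy_true = cohort$beta_xy_true,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run a Monte-Carlo grid of scenarios
#'
#' Executes `n_replicates` replicates of every scenario and aggregates the
#' per-replicate results into one summary row per scenario x adjustment
#' combination: mean bias (mean estimate minus the true causal effect),
#' empirical coverage of the 95\% confidence interval, mean number of
#' selected instruments, mean instrument F and the fraction of replicates
#' that were non-estimable. Bias and coverage are computed over estimable
#' replicates only. Replicate seeds are derived from `master_seed`
#' independently of scheduling, so results do not depend on `workers`.
#'
#' @param scenarios A list of [scenario_config()] objects (or a single one).
#' @param n_replicates Replicates per scenario; >= 1.
#' @param master_seed Integer master seed.
#' @param f_threshold Instrument-strength threshold; default 10.
#' @param workers Number of parallel workers (forked via the parallel
#'   package when > 1); the output is identical for any value.
#' @return A data.frame of class `cell_summary` with columns `scenario`,
#'   `structure`, `confounding`, `variant_mode`, `beta_xy_null`,
#'   `combination`, `n_replicates`, `mean_bias`, `coverage`,
#'   `mean_n_instruments`, `mean_f_stat`, `non_estimable_fraction`,
#'   `beta_xy_true` (mean realized truth). The per-replicate rows are kept
#'   in the `"replicates"` attribute.
#' @export
run_grid <- function(scenarios, n_replicates, master_seed = 1L,
                     f_threshold = 10, workers = 1L) {
  if (inherits(scenarios, "scenario_config")) scenarios <- list(scenarios)
  stopifnot(n_replicates >= 1L)
  one_scenario <- function(config) {
    reps <- if (workers > 1L) {
      parallel::mclapply(seq_len(n_replicates), function(i) {
        run_replicate(config, i, master_seed, f_threshold)
      }, mc.cores = workers)
    } else {
      lapply(seq_len(n_replicates), function(i) {
        run_replicate(config, i, master_seed, f_threshold)
      })
    }
    do.call(rbind, reps)
  }
  all_reps <- do.call(rbind, lapply(scenarios, one_scenario))

  meta <- do.call(rbind, lapply(scenarios, function(cfg) {
    data.frame(scenario = scenario_id(cfg),
               structure = cfg$structure,
               confounding = cfg$confounding,
               variant_mode = cfg$variant_mode,
               beta_xy_null = cfg$beta_xy_null,
               stringsAsFactors = FALSE)
  }))

  cells <- lapply(seq_len(nrow(meta)), function(j) {
    m <- meta[j, ]
    sub <- all_reps[all_reps$scenario == m$scenario &
                    all_reps$variant_mode == m$variant_mode &
                    all_reps$beta_xy_null == m$beta_xy_null, , drop = FALSE]
    do.call(rbind, lapply(combination_labels, function(lbl) {
      s <- sub[sub$combination == lbl, , drop = FALSE]
      est <- s[s$estimable, , drop = FALSE]
      data.frame(
        m,
        combination = lbl,
        n_replicates = nrow(s),
        mean_bias = if (nrow(est)) mean(est$estimate - est$beta_xy_true)
                    else NA_real_,
        coverage = if (nrow(est)) {
          mean(est$ci_low <= est$beta_xy_true &
               est$beta_xy_true <= est$ci_high)
        } else NA_real_,
        mean_n_instruments = mean(s$n_instruments),
        mean_f_stat = if (nrow(est)) mean(est$mean_f, na.rm = TRUE)
                      else NA_real_,
        non_estimable_fraction = mean(!s$estimable),
        beta_xy_true = if (nrow(est)) mean(est$beta_xy_true) else NA_real_,
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  attr(out, "replicates") <- all_reps
  class(out) <- c("cell_summary", "data.frame")
  out
}

#' Long-format bias/coverage table for publication-style figures
#'
#' Reshapes grid summaries into the long format keyed by structure,
#' confounding setting, adjustment combination and causal-null status, and
#' flags the cells that are conventionally excluded from homogeneous-variant
#' presentations: structures where adjusting the variant-exposure
#' association for W closes every open path between Z and X (structure A
#' with confounding settings 1, 3 and 4), so no instruments are selected.
#'
#' @param cell_summaries A `cell_summary` data.frame from [run_grid()].
#' @return A data.frame with the summary columns plus a logical `excluded`
#'   marker.
#' @export
summarize_bias_table <- function(cell_summaries) {
  stopifnot(nrow(cell_summaries) > 0L)
  out <- as.data.frame(cell_summaries)
  out$excluded <- out$variant_mode == "homogeneous" &
    out$structure == "A" &
    out$confounding %in% c(1L, 3L, 4L) &
    out$combination %in% c("exposure", "both")
  key <- order(out$structure, out$confounding, out$variant_mode,
               !out$beta_xy_null,
               match(out$combination, combination_labels))
  out <- out[key, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a list of scenario configurations
#'
#' Convenience constructor for scenario grids: the cross product of the
#' requested structures, confounding settings, variant modes and
#' null/non-null causal effects.
#'
#' @param structures Character vector of structures, subset of `"A"`..`"F"`.
#' @param confounding Integer vector, subset of 1..5.
#' @param variant_modes Character vector, subset of
#'   `c("homogeneous", "heterogeneous")`.
#' @param beta_xy_null Logical vector, subset of `c(TRUE, FALSE)`.
#' @param ... Passed to [scenario_config()] (e.g. `n_individuals`).
#' @return A list of `scenario_config` objects.
#' @export
scenario_grid <- function(structures = LETTERS[1:6], confounding = 1:5,
                          variant_modes = "homogeneous",
                          beta_xy_null = TRUE, ...) {
  grid <- expand.grid(structure = structures, confounding = confounding,
                      variant_mode = variant_modes,
                      beta_xy_null = beta_xy_null,
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    scenario_config(structure = grid$structure[i],
                    confounding = grid$confounding[i],
                    variant_mode = grid$variant_mode[i],
                    beta_xy_null = grid$beta_xy_null[i], ...)
  })
}
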