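#' Scenario configuration for the covariable-adjustment simulation study
#'
#' A scenario is one cell of the simulation grid: a causal structure among
#' the genetic variants (Z), exposure (X), covariable (W), an optional
#' intermediate trait (R) and the outcome (Y); a confounding setting saying
#' which unmeasured common causes exist; a variant mode (all variants share
#' one causal role, or variants fall into distinct subgroups); and whether
#' the causal effect of X on Y is null.
#'
#' The six structures are:
#' \describe{
#'   \item{A}{Z -> W -> X (W fully mediates the genetic effect on X).}
#'   \item{B}{Z -> X and Z -> W independently.}
#'   \item{C}{Z -> X -> W (X fully mediates the genetic effect on W).}
#'   \item{D}{Z -> R, with R -> X and R -> W (shared intermediate).}
#'   \item{E}{As B, plus a direct effect W -> Y (horizontal pleiotropy).}
#'   \item{F}{As D, plus a direct effect W -> Y (pleiotropy violating InSIDE).}
#' }
#' Confounding settings: 1 = none, 2 = unmeasured common cause of X and W
#' (U_XW), 3 = of W and Y (U_WY), 4 = of X and Y (U_XY), 5 = all three.
#'
#' Effect sizes are parameterized by variance fractions: the additive allele
#' score contributing to a phenotype explains `score_variance_fraction` of
#' its variance (default 10\%), and every phenotypic or unmeasured direct
#' cause explains `direct_effect_variance_fraction` (default 20\%). All
#' direct effects are positive.
#'
#' @param structure One of `"A"`..`"F"`.
#' @param confounding Integer 1..5.
#' @param variant_mode `"homogeneous"` (all variants share the structure's
#'   single causal role) or `"heterogeneous"` (variants split into subgroups
#'   affecting X only, W only, both X and W, or R only).
#' @param beta_xy_null Logical; if `TRUE` the causal effect of X on Y is
#'   exactly zero, otherwise it explains `direct_effect_variance_fraction`
#'   of the variance of Y.
#' @param n_individuals Total cohort size before the two-sample split; must
#'   be even. Default 100000.
#' @param n_variants Number of independent biallelic variants. Default 40.
#' @param score_variance_fraction Fraction of a phenotype's variance
#'   explained by its allele score, in (0, 1). Default 0.10.
#' @param direct_effect_variance_fraction Fraction explained by each
#'   phenotypic/unmeasured direct cause, in (0, 1). Default 0.20.
#' @param allele_freq_range Length-2 numeric, lower/upper bound for the
#'   per-variant effect allele frequency draw. Default `c(0.1, 0.9)`.
#' @param seed Optional integer seed; when set, [simulate_cohort()] is
#'   reproducible.
#'
#' @return An object of class `scenario_config`.
#' @seealso [simulate_cohort()], [assign_variant_groups()], [run_grid()]
#' @export
#' @examples
#' cfg <- scenario_config("B", 1, n_individuals = 2000, seed = 1)
#' cfg
scenario_config <- function(structure,
                            confounding,
                            variant_mode = c("homogeneous", "heterogeneous"),
                            beta_xy_null = TRUE,
                            n_individuals = 100000L,
                            n_variants = 40L,
                            score_variance_fraction = 0.10,
                            direct_effect_variance_fraction = 0.20,
                            allele_freq_range = c(0.1, 0.9),
                            seed = NULL) {
  structure <- match.arg(as.character(structure), LETTERS[1:6])
  confounding <- as.integer(confounding)
  if (length(confounding) != 1L || is.na(confounding) ||
      !confounding %in% 1:5) {
    stop("`confounding` must be a single integer in 1..5", call. = FALSE)
  }
  variant_mode <- match.arg(variant_mode)
  stopifnot(is.logical(beta_xy_null), length(beta_xy_null) == 1L)
  n_individuals <- as.integer(n_individuals)
  n_variants <- as.integer(n_variants)
  if (n_individuals <= 0L || n_variants <= 0L) {
    stop("`n_individuals` and `n_variants` must be positive", call. = FALSE)
  }
  if (n_individuals %% 2L != 0L) {
    stop("`n_individuals` must be even so the two-sample split is exact",
         call. = FALSE)
  }
  for (v in c(score_variance_fraction, direct_effect_variance_fraction)) {
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      stop("variance fractions must be single numbers in (0, 1)",
           call. = FALSE)
    }
  }
  if (length(allele_freq_range) != 2L ||
      allele_freq_range[1] <= 0 || allele_freq_range[2] >= 1 ||
      allele_freq_range[1] > allele_freq_range[2]) {
    stop("`allele_freq_range` must satisfy 0 < lower <= upper < 1",
         call. = FALSE)
  }
  if (!is.null(seed)) seed <- as.integer(seed)

  cfg <- structure(
    list(structure = structure,
         confounding = confounding,
         variant_mode = variant_mode,
         beta_xy_null = beta_xy_null,
         n_individuals = n_individuals,
         n_variants = n_variants,
         score_variance_fraction = score_variance_fraction,
         direct_effect_variance_fraction = direct_effect_variance_fraction,
         allele_freq_range = as.numeric(allele_freq_range),
         seed = seed),
    class = "scenario_config"
  )
  # variance budget: the direct causes of every phenotype must leave room
  # for residual noise
  check_variance_budget(cfg)
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario %s%d (%s variants), causal effect X->Y: %s\n",
              x$structure, x$confounding, x$variant_mode,
              if (x$beta_xy_null) "null" else "non-null"))
  cat(sprintf("  n = %d individuals, %d variants; score R2 = %.0f%%, direct-cause R2 = %.0f%%\n",
              x$n_individuals, x$n_variants,
              100 * x$score_variance_fraction,
              100 * x$direct_effect_variance_fraction))
  if (!is.null(x$seed)) cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

#' Scenario identifier string, e.g. "B1"
#' @param config A `scenario_config`.
#' @return Character scalar like `"B1"`.
#' @export
scenario_id <- function(config) {
  paste0(config$structure, config$confounding)
}

# Which phenotypes receive a direct genetic (allele-score) effect.
# Homogeneous mode: the single role dictated by the structure.
# Heterogeneous mode: X and W always; R when the structure includes R.
score_targets <- function(config) {
  if (config$variant_mode == "homogeneous") {
    switch(config$structure,
           A = "W",
           B = c("X", "W"),
           C = "X",
           D = "R",
           E = c("X", "W"),
           F = "R")
  } else {
    c("X", "W", if (config$structure %in% c("D", "F")) "R")
  }
}

# Direct-cause table for each phenotype under a configuration.
# Returns a named list (in generation order) of data.frames with columns
# `cause` (name of a score, phenotype or confounder) and `fraction`
# (variance fraction of the child explained by that cause).
scenario_parents <- function(config) {
  s <- config$structure
  conf <- config$confounding
  v_g <- config$score_variance_fraction
  v_d <- config$direct_effect_variance_fraction
  targets <- score_targets(config)
  has_R <- s %in% c("D", "F")

  confounders <- list(
    U_XW = c("X", "W"),
    U_WY = c("W", "Y"),
    U_XY = c("X", "Y")
  )
  active_U <- switch(conf, character(0), "U_XW", "U_WY", "U_XY",
                     c("U_XW", "U_WY", "U_XY"))

  parents_of <- function(pheno) {
    cause <- character(0)
    fraction <- numeric(0)
    add <- function(cz, fr) {
      cause <<- c(cause, cz)
      fraction <<- c(fraction, fr)
    }
    if (pheno %in% targets) add(paste0("score_", pheno), v_g)
    if (pheno == "X") {
      if (s == "A") add("W", v_d)
      if (has_R) add("R", v_d)
    }
    if (pheno == "W") {
      if (s == "C") add("X", v_d)
      if (has_R) add("R", v_d)
    }
    if (pheno == "Y") {
      add("X", if (config$beta_xy_null) 0 else v_d)
      if (s %in% c("E", "F")) add("W", v_d)
    }
    for (u in active_U) {
      if (pheno %in% confounders[[u]]) add(u, v_d)
    }
    data.frame(cause = cause, fraction = fraction,
               stringsAsFactors = FALSE)
  }

  # topological order: R first, then W before X in structure A (W -> X),
  # X before W in structure C (X -> W), Y last
  order <- c(if (has_R) "R",
             if (s == "A") c("W", "X") else c("X", "W"),
             "Y")
  stats::setNames(lapply(order, parents_of), order)
}

# error if any phenotype's nominal variance fractions sum to >= 1
check_variance_budget <- function(config) {
  parents <- scenario_parents(config)
  for (pheno in names(parents)) {
    tot <- sum(parents[[pheno]]$fraction)
    if (tot >= 1) {
      stop(sprintf(
        "variance fractions of the direct causes of %s sum to %.2f >= 1 (causes: %s)",
        pheno, tot, paste(parents[[pheno]]$cause, collapse = ", ")),
        call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Assign each variant to its causal role
#'
#' In homogeneous mode every variant takes the single role implied by the
#' causal structure (A: effects on W only; B and E: on both X and W; C: on
#' X only; D and F: on R only). In heterogeneous mode the variants are split
#' into four equal subgroups — direct effects on X only, on W only, on both
#' X and W, and on R only; in structures without R the fourth subgroup
#' consists of null variants with no effect on any trait, preserving the
#' full candidate-instrument count and exercising the instrument-strength
#' filter realistically.
#'
#' @param config A [scenario_config()].
#' @return A factor of length `n_variants` with levels
#'   `c("X_only", "W_only", "X_and_W", "R_only", "null")`; deterministic
#'   given the configuration.
#' @export
#' @examples
#' table(assign_variant_groups(scenario_config("D", 1,
#'   variant_mode = "heterogeneous", n_individuals = 100)))
assign_variant_groups <- function(config) {
  levels <- c("X_only", "W_only", "X_and_W", "R_only", "null")
  m <- config$n_variants
  if (config$variant_mode == "homogeneous") {
    role <- switch(config$structure,
                   A = "W_only", B = "X_and_W", C = "X_only",
                   D = "R_only", E = "X_and_W", F = "R_only")
    return(factor(rep(role, m), levels = levels))
  }
  fourth <- if (config$structure %in% c("D", "F")) "R_only" else "null"
  sizes <- rep(m %/% 4L, 4L)
  rem <- m %% 4L
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  factor(rep(c("X_only", "W_only", "X_and_W", fourth), times = sizes),
         levels = levels)
}

# variant columns contributing to the allele score of a phenotype
score_members <- function(groups, pheno) {
  g <- as.character(groups)
  which(switch(pheno,
               X = g %in% c("X_only", "X_and_W"),
               W = g %in% c("W_only", "X_and_W"),
               R = g == "R_only",
               rep(FALSE, length(g))))
}
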