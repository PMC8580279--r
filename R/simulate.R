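#' Draw independent biallelic genotypes under Hardy-Weinberg equilibrium
#'
#' Each variant gets its own effect allele frequency drawn uniformly from
#' `allele_freq_range`; allele counts are then binomial(2, freq) per
#' individual, independently across variants.
#'
#' @param n_individuals Number of rows.
#' @param n_variants Number of variant columns.
#' @param allele_freq_range Length-2 numeric in (0, 1); when the two bounds
#'   coincide, every variant uses that fixed frequency.
#' @return A numeric matrix of allele counts in `{0, 1, 2}` with columns
#'   named `v01`, `v02`, ... and an `"eaf"` attribute holding the generating
#'   frequency of each variant.
#' @export
#' @examples
#' g <- draw_genotypes(100, 5, c(0.2, 0.8))
#' range(g)
draw_genotypes <- function(n_individuals, n_variants,
                           allele_freq_range = c(0.1, 0.9)) {
  n_individuals <- as.integer(n_individuals)
  n_variants <- as.integer(n_variants)
  if (is.na(n_individuals) || n_individuals <= 0L ||
      is.na(n_variants) || n_variants <= 0L) {
    stop("`n_individuals` and `n_variants` must be positive", call. = FALSE)
  }
  lo <- allele_freq_range[1]; hi <- allele_freq_range[2]
  if (!(lo > 0 || hi < 1) || lo > hi || lo < 0 || hi > 1) {
    stop("`allele_freq_range` must satisfy 0 <= lower <= upper <= 1",
         call. = FALSE)
  }
  eaf <- if (lo == hi) rep(lo, n_variants) else stats::runif(n_variants, lo, hi)
  g <- matrix(stats::rbinom(n_individuals * n_variants, 2L,
                            rep(eaf, each = n_individuals)),
              nrow = n_individuals, ncol = n_variants)
  storage.mode(g) <- "double"  # avoids repeated coercion in matrix algebra
  colnames(g) <- sprintf("v%02d", seq_len(n_variants))
  attr(g, "eaf") <- stats::setNames(eaf, colnames(g))
  g
}

#' Build a standardized additive allele score
#'
#' The score is the unweighted sum of allele counts over the member
#' variants, centred and scaled to unit empirical variance.
#'
#' @param genotypes Allele-count matrix from [draw_genotypes()].
#' @param member_variants Column indices (or names) of the contributing
#'   variants; must be non-empty.
#' @return Numeric vector of length `nrow(genotypes)` with mean 0 and
#'   empirical variance 1.
#' @export
build_allele_score <- function(genotypes, member_variants) {
  if (length(member_variants) == 0L) {
    stop("`member_variants` must be a non-empty set of variant columns",
         call. = FALSE)
  }
  raw <- rowSums(genotypes[, member_variants, drop = FALSE])
  s <- stats::sd(raw)
  if (s == 0) {
    stop("allele score is constant; cannot standardize", call. = FALSE)
  }
  (raw - mean(raw)) / s
}

#' Simulate an individual-level cohort under one scenario
#'
#' Phenotypes are generated in topological order of the scenario's causal
#' graph. Every direct cause enters its child with coefficient
#' `sqrt(variance_fraction) / sd(cause)` and positive sign, so that each
#' cause nominally accounts for its stated fraction of the child's
#' variance; residual Gaussian noise then tops the child's variance up to 1
#' (residual variance `1 - var(systematic part)`, recomputed empirically
#' per cohort and floored at 0.01). Unmeasured confounders are standard
#' normal and independent of the genotypes.
#'
#' @param config A [scenario_config()]. When `config$seed` is set the
#'   cohort is fully reproducible.
#' @return An object of class `cohort`: a list with elements `genotypes`
#'   (n x m allele-count matrix), `phenotypes` (data.frame with columns X,
#'   Y, W and, when present, R and the U confounders), `eaf` (generating
#'   allele frequencies), `groups` (variant role assignment),
#'   `beta_xy_true` (the realized causal coefficient of X on Y; exactly 0
#'   under the null) and `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(scenario_config("B", 1, n_individuals = 2000, seed = 7))
#' round(cor(coh$phenotypes$X, coh$phenotypes$W), 2)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_individuals

  genotypes <- draw_genotypes(n, config$n_variants, config$allele_freq_range)
  groups <- assign_variant_groups(config)

  values <- list()
  for (pheno in score_targets(config)) {
    members <- score_members(groups, pheno)
    if (length(members) > 0L) {
      values[[paste0("score_", pheno)]] <- build_allele_score(genotypes, members)
    }
  }

  parents <- scenario_parents(config)
  active_U <- unique(unlist(lapply(parents, function(p) {
    grep("^U_", p$cause, value = TRUE)
  })))
  for (u in active_U) values[[u]] <- stats::rnorm(n)

  beta_xy_true <- 0
  for (pheno in names(parents)) {
    tab <- parents[[pheno]]
    systematic <- numeric(n)
    for (i in seq_len(nrow(tab))) {
      cause <- tab$cause[i]
      frac <- tab$fraction[i]
      if (is.null(values[[cause]])) {
        if (startsWith(cause, "score_")) next  # no variants in this role
        stop(sprintf("internal: cause %s of %s not yet generated", cause, pheno))
      }
      coef <- if (frac == 0) 0 else sqrt(frac) / stats::sd(values[[cause]])
      if (pheno == "Y" && cause == "X") beta_xy_true <- coef
      systematic <- systematic + coef * values[[cause]]
    }
    resid_var <- max(1 - stats::var(systematic), 0.01)
    values[[pheno]] <- systematic + stats::rnorm(n, sd = sqrt(resid_var))
  }

  pheno_cols <- c(names(parents), active_U)
  structure(
    list(genotypes = genotypes,
         phenotypes = as.data.frame(values[pheno_cols]),
         scores = values[grep("^score_", names(values), value = TRUE)],
         eaf = attr(genotypes, "eaf"),
         groups = groups,
         beta_xy_true = beta_xy_true,
         config = config),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d individuals x %d variants (scenario %s, %s)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              scenario_id(x$config), x$config$variant_mode))
  cat(sprintf("  phenotypes: %s; true X->Y effect = %.4f\n",
              paste(names(x$phenotypes), collapse = ", "), x$beta_xy_true))
  invisible(x)
}

# subset a cohort by individual indices, keeping all columns
subset_cohort <- function(cohort, idx) {
  out <- cohort
  out$genotypes <- cohort$genotypes[idx, , drop = FALSE]
  attr(out$genotypes, "eaf") <- cohort$eaf
  out$phenotypes <- cohort$phenotypes[idx, , drop = FALSE]
  out$scores <- lapply(cohort$scores, function(s) s[idx])
  out
}

#' Split a cohort into two non-overlapping random halves
#'
#' One half is used to estimate instrument-exposure associations and the
#' other instrument-outcome associations, mirroring the two-sample MR
#' design in which the two sets of summary statistics come from
#' non-overlapping samples of the same population.
#'
#' @param cohort A [simulate_cohort()] result with an even number of
#'   individuals.
#' @return A list with elements `exposure` and `outcome`, each a `cohort`
#'   of `n/2` individuals; the index sets are disjoint and exhaustive.
#' @export
split_samples <- function(cohort) {
  n <- nrow(cohort$genotypes)
  if (n %% 2L != 0L) {
    stop("cohort size must be even to split into equal halves", call. = FALSE)
  }
  idx <- sample.int(n)
  first <- sort(idx[seq_len(n %/% 2L)])
  second <- sort(idx[(n %/% 2L + 1L):n])
  list(exposure = subset_cohort(cohort, first),
       outcome = subset_cohort(cohort, second))
}
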