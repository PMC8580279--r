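# Vectorized per-variant least squares.
#
# Each variant is regressed separately: trait ~ genotype, or
# trait ~ genotype + covariable. The adjusted case uses
# Frisch-Waugh-Lovell partialling-out (residualize both the trait and every
# genotype column on the intercept and the covariable), which reproduces
# the genotype coefficient, its standard error and the partial t of the
# full bivariate fit exactly, at a fraction of the cost of looped lm().
per_variant_ols <- function(genotypes, trait, covariable = NULL) {
  n <- length(trait)
  if (nrow(genotypes) != n) {
    stop("genotypes and trait have different lengths", call. = FALSE)
  }
  if (stats::var(trait) == 0) {
    stop("trait has zero variance", call. = FALSE)
  }
  # sufficient statistics only: no n x m temporaries
  yc <- trait - mean(trait)
  gm <- colMeans(genotypes)
  sxx <- colSums(genotypes^2) - n * gm^2
  sxy <- as.numeric(crossprod(genotypes, yc))
  syy <- sum(yc^2)
  if (!is.null(covariable)) {
    if (length(covariable) != n) {
      stop("covariable length does not match trait", call. = FALSE)
    }
    # partial out the covariable from every cross-product
    wc <- covariable - mean(covariable)
    sww <- sum(wc^2)
    sgw <- as.numeric(crossprod(genotypes, wc))
    swy <- sum(wc * yc)
    sxx <- sxx - sgw^2 / sww
    sxy <- sxy - sgw * swy / sww
    syy <- syy - swy^2 / sww
    df <- n - 3L
  } else {
    df <- n - 2L
  }
  constant <- sxx < .Machine$double.eps * n
  beta <- ifelse(constant, NA_real_, sxy / sxx)
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / df / sxx)
  se[constant] <- NA_real_
  tval <- beta / se
  list(beta = beta, se = se, f_stat = tval^2,
       p_value = 2 * stats::pt(-abs(tval), df),
       df = df, constant = constant)
}

#' Per-variant GWAS of one trait, optionally adjusted for a covariable
#'
#' Runs an ordinary least-squares regression of the trait on each variant's
#' allele count separately (plus the covariable when supplied) and returns
#' the genotype coefficient, its standard error, the instrument-strength F
#' statistic (squared Wald t of the genotype term; in the adjusted case
#' this is the partial F) and the two-sided p-value.
#'
#' @param genotypes Allele-count matrix, one column per variant.
#' @param trait Numeric trait vector.
#' @param covariable Optional numeric covariable vector; when supplied each
#'   regression includes it and the summary rows carry the label in
#'   `adjusted_for`.
#' @param trait_label Character label stored in the `trait` column.
#' @param covariable_label Label stored in `adjusted_for` for adjusted rows.
#' @return A data.frame of class `gwas_result` with one row per variant and
#'   columns `variant_id`, `trait`, `beta`, `se`, `f_stat`, `p_value`, `n`,
#'   `eaf` (generating or empirical allele frequency) and `adjusted_for`
#'   (`NA` for unadjusted rows). Variants with a constant genotype column
#'   get `NA` estimates and trigger one warning.
#' @export
run_gwas <- function(genotypes, trait, covariable = NULL,
                     trait_label = "trait", covariable_label = "W") {
  fit <- per_variant_ols(genotypes, trait, covariable)
  if (any(fit$constant)) {
    warning(sprintf("%d constant genotype column(s) returned NA associations",
                    sum(fit$constant)), call. = FALSE)
  }
  eaf <- attr(genotypes, "eaf")
  if (is.null(eaf)) eaf <- colMeans(genotypes) / 2
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- sprintf("v%02d", seq_len(ncol(genotypes)))
  out <- data.frame(
    variant_id = ids,
    trait = trait_label,
    beta = fit$beta,
    se = fit$se,
    f_stat = fit$f_stat,
    p_value = fit$p_value,
    n = length(trait),
    eaf = as.numeric(eaf),
    adjusted_for = if (is.null(covariable)) NA_character_ else covariable_label,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Estimate a single variant-trait summary association
#'
#' Convenience wrapper around [run_gwas()] for one genotype column.
#'
#' @param genotype_column Numeric/integer vector of allele counts.
#' @param trait_values Numeric trait vector of the same length.
#' @param covariable_values Optional covariable vector.
#' @inheritParams run_gwas
#' @param variant_id Identifier stored in the result row.
#' @return One-row `gwas_result` data.frame.
#' @export
estimate_association <- function(genotype_column, trait_values,
                                 covariable_values = NULL,
                                 variant_id = "v01",
                                 trait_label = "trait",
                                 covariable_label = "W") {
  if (length(genotype_column) != length(trait_values)) {
    stop("genotype and trait vectors have different lengths", call. = FALSE)
  }
  g <- matrix(as.numeric(genotype_column), ncol = 1L,
              dimnames = list(NULL, variant_id))
  run_gwas(g, trait_values, covariable_values,
           trait_label = trait_label, covariable_label = covariable_label)
}

#' Select instruments by instrument-strength F statistic
#'
#' Retains, in their original order, exactly the variants whose exposure
#' association reaches `f_threshold` (inclusive: "10 or more"). Variants
#' with undefined F (constant genotype) are dropped.
#'
#' @param exposure_associations A `gwas_result` data.frame for the exposure.
#' @param f_threshold Positive F cut-off; default 10, the conventional
#'   weak-instrument threshold.
#' @return An `instrument_set`: the selected rows, with attributes
#'   `f_threshold` and `selection_basis` (the `adjusted_for` label of the
#'   exposure GWAS used for selection). An empty selection is valid.
#' @export
select_instruments <- function(exposure_associations, f_threshold = 10) {
  if (!is.numeric(f_threshold) || f_threshold <= 0) {
    stop("`f_threshold` must be positive", call. = FALSE)
  }
  keep <- !is.na(exposure_associations$f_stat) &
    exposure_associations$f_stat >= f_threshold
  out <- exposure_associations[keep, , drop = FALSE]
  if (anyDuplicated(out$variant_id)) {
    stop("duplicate variant ids in exposure associations", call. = FALSE)
  }
  attr(out, "f_threshold") <- f_threshold
  attr(out, "selection_basis") <-
    if (all(is.na(exposure_associations$adjusted_for))) "unadjusted"
    else paste0("adjusted_", exposure_associations$adjusted_for[1])
  class(out) <- c("instrument_set", "gwas_result", "data.frame")
  out
}

#' Exclude instruments associated with the covariable
#'
#' Mirrors the sensitivity analysis that drops SNPs associated with the
#' covariable at p below a threshold: instruments whose covariable
#' association has `p_value < p_threshold` are removed; the boundary
#' `p_value >= p_threshold` is retained.
#'
#' @param instruments An `instrument_set` (or `gwas_result` subset).
#' @param covariable_associations A `gwas_result` for the covariable
#'   containing every instrument.
#' @param p_threshold Exclusion p-value threshold in (0, 1); default 0.05.
#' @return The retained instrument rows (possibly empty).
#' @export
filter_by_covariable_association <- function(instruments,
                                             covariable_associations,
                                             p_threshold = 0.05) {
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold >= 1) {
    stop("`p_threshold` must be in (0, 1)", call. = FALSE)
  }
  idx <- match(instruments$variant_id, covariable_associations$variant_id)
  if (anyNA(idx)) {
    missing <- instruments$variant_id[is.na(idx)]
    stop(sprintf("no covariable association for variant(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  keep <- covariable_associations$p_value[idx] >= p_threshold
  out <- instruments[keep, , drop = FALSE]
  attr(out, "f_threshold") <- attr(instruments, "f_threshold")
  attr(out, "selection_basis") <- attr(instruments, "selection_basis")
  class(out) <- class(instruments)
  out
}
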