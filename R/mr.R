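#' Per-variant Wald ratio estimate
#'
#' The causal effect estimate contributed by one variant: the ratio of its
#' outcome association to its exposure association, with the first-order
#' standard error `|se_outcome / beta_exposure|` (uncertainty in the
#' exposure association is ignored, as in standard summary-data IVW).
#'
#' @param beta_exposure,se_exposure Variant-exposure association and SE.
#' @param beta_outcome,se_outcome Variant-outcome association and SE.
#' @return A list with `estimate` and `se`.
#' @export
#' @examples
#' wald_ratio(0.5, 0.01, 0.25, 0.02)
wald_ratio <- function(beta_exposure, se_exposure, beta_outcome, se_outcome) {
  if (any(beta_exposure == 0)) {
    stop("Wald ratio undefined for zero exposure association", call. = FALSE)
  }
  list(estimate = beta_outcome / beta_exposure,
       se = abs(se_outcome / beta_exposure))
}

mr_result <- function(estimate, se, n_instruments, residual_scale,
                      method = "IVW-MRE", estimable = TRUE,
                      z_crit = 1.96) {
  structure(
    list(estimate = estimate, se = se,
         ci_low = if (estimable) estimate - z_crit * se else NA_real_,
         ci_high = if (estimable) estimate + z_crit * se else NA_real_,
         n_instruments = n_instruments,
         residual_scale = residual_scale,
         method = method,
         estimable = estimable),
    class = "mr_result"
  )
}

#' Non-estimable MR result marker
#'
#' Returned (rather than an error) by workflow drivers when an adjustment
#' combination selects zero instruments, so the other combinations of the
#' same run still report.
#' @param method Method label.
#' @return An `mr_result` with `estimable = FALSE` and `NA` estimates.
#' @export
mr_non_estimable <- function(method = "IVW-MRE") {
  mr_result(NA_real_, NA_real_, 0L, NA_real_, method, estimable = FALSE)
}

#' @export
print.mr_result <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf("MR (%s): non-estimable (0 instruments)\n", x$method))
    return(invisible(x))
  }
  cat(sprintf("MR (%s): estimate %.4f (SE %.4f), 95%% CI [%.4f, %.4f], %d instruments, residual scale %.3f\n",
              x$method, x$estimate, x$se, x$ci_low, x$ci_high,
              x$n_instruments, x$residual_scale))
  invisible(x)
}

#' Inverse-variance weighted estimate with multiplicative random effects
#'
#' The point estimate is the slope of the zero-intercept weighted
#' least-squares regression of outcome associations on exposure
#' associations with weights `1/se_outcome^2` (equivalently, the
#' precision-weighted average of the per-variant Wald ratios). The
#' multiplicative random-effects standard error inflates the fixed-effect
#' SE by the square root of the residual mean square of that fit, floored
#' at 1 so that underdispersion never shrinks the SE. The 95\% confidence
#' interval uses the normal approximation (estimate +/- 1.96 SE).
#'
#' @param harmonized A data.frame with columns `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome` (as produced by
#'   [harmonize()] or assembled directly from two [run_gwas()] results).
#' @return An object of class `mr_result`. With a single instrument the
#'   estimate falls back to the Wald ratio with `residual_scale = 1`;
#'   with zero instruments an error is raised (workflow drivers use
#'   [mr_non_estimable()] instead).
#' @export
#' @examples
#' h <- data.frame(beta_exposure = c(0.4, 0.5, 0.6),
#'                 se_exposure = 0.02,
#'                 beta_outcome = c(0.21, 0.24, 0.33),
#'                 se_outcome = c(0.02, 0.03, 0.025))
#' ivw_mre(h)
ivw_mre <- function(harmonized) {
  k <- nrow(harmonized)
  if (is.null(k) || k == 0L) {
    stop("no instruments: IVW estimate is non-estimable", call. = FALSE)
  }
  bx <- harmonized$beta_exposure
  by <- harmonized$beta_outcome
  sy <- harmonized$se_outcome
  if (any(!is.finite(bx)) || any(!is.finite(by)) || any(sy <= 0)) {
    stop("harmonized associations must be finite with positive outcome SE",
         call. = FALSE)
  }
  if (k == 1L) {
    wr <- wald_ratio(bx, harmonized$se_exposure, by, sy)
    return(mr_result(wr$estimate, wr$se, 1L, 1,
                     method = "Wald ratio (single instrument)"))
  }
  w <- 1 / sy^2
  sxx <- sum(w * bx^2)
  estimate <- sum(w * bx * by) / sxx
  se_fixed <- sqrt(1 / sxx)
  rss <- sum(w * (by - estimate * bx)^2)
  residual_scale <- max(1, sqrt(rss / (k - 1)))
  mr_result(estimate, se_fixed * residual_scale, as.integer(k),
            residual_scale)
}

# strand complement for harmonization
flip_allele <- function(a) {
  chartr("ACGT", "TGCA", toupper(a))
}

is_palindromic <- function(a1, a2) {
  flip_allele(a1) == toupper(a2)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns two sets of GWAS summary-statistics records to a common effect
#' allele, variant by variant: records are inner-joined on `variant_id`;
#' when the outcome's effect/other alleles are swapped relative to the
#' exposure (directly or after strand complement) the outcome beta is
#' negated and its allele frequency reflected; palindromic variants (A/T
#' or C/G) are aligned by allele-frequency proximity when both frequencies
#' are available and outside the ambiguity zone, and dropped otherwise;
#' variants whose allele sets cannot be reconciled are dropped.
#'
#' @param exposure_records,outcome_records Data.frames in the
#'   summary-statistics dialect of [read_summary_stats()] (columns
#'   `variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   plus extras). Records produced by [run_gwas()] (no allele columns)
#'   are joined directly without allele checks.
#' @param ambiguity_zone Length-2 numeric; a palindromic variant is dropped
#'   when either allele frequency falls inside this closed interval or is
#'   missing. Default `c(0.42, 0.58)`.
#' @return A data.frame of class `harmonized_data` with columns
#'   `variant_id`, `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`, `eaf_exposure`, `eaf_outcome`, `flipped`, and an
#'   `"audit"` attribute (data.frame of dropped variants and reasons plus
#'   per-action counts). Zero overlapping variants is an error.
#' @export
harmonize <- function(exposure_records, outcome_records,
                      ambiguity_zone = c(0.42, 0.58)) {
  ex <- as.data.frame(exposure_records)
  ou <- as.data.frame(outcome_records)
  if (anyDuplicated(ex$variant_id) || anyDuplicated(ou$variant_id)) {
    stop("duplicate variant ids in summary records", call. = FALSE)
  }
  shared <- intersect(ex$variant_id, ou$variant_id)
  if (length(shared) == 0L) {
    stop("no overlapping variants between exposure and outcome records",
         call. = FALSE)
  }
  ex <- ex[match(shared, ex$variant_id), , drop = FALSE]
  ou <- ou[match(shared, ou$variant_id), , drop = FALSE]
  have_alleles <- all(c("effect_allele", "other_allele") %in% names(ex)) &&
    all(c("effect_allele", "other_allele") %in% names(ou))

  eaf_ex <- if ("eaf" %in% names(ex)) ex$eaf else rep(NA_real_, nrow(ex))
  eaf_ou <- if ("eaf" %in% names(ou)) ou$eaf else rep(NA_real_, nrow(ou))

  n <- length(shared)
  keep <- rep(TRUE, n)
  flipped <- rep(FALSE, n)
  reason <- rep(NA_character_, n)

  if (have_alleles) {
    e1 <- toupper(ex$effect_allele); e2 <- toupper(ex$other_allele)
    o1 <- toupper(ou$effect_allele); o2 <- toupper(ou$other_allele)
    for (i in seq_len(n)) {
      if (is_palindromic(e1[i], e2[i])) {
        same_set <- (o1[i] == e1[i] && o2[i] == e2[i]) ||
          (o1[i] == e2[i] && o2[i] == e1[i])
        if (!same_set) {
          keep[i] <- FALSE; reason[i] <- "incompatible_alleles"
        } else if (is.na(eaf_ex[i]) || is.na(eaf_ou[i]) ||
                   (eaf_ex[i] >= ambiguity_zone[1] && eaf_ex[i] <= ambiguity_zone[2]) ||
                   (eaf_ou[i] >= ambiguity_zone[1] && eaf_ou[i] <= ambiguity_zone[2])) {
          keep[i] <- FALSE; reason[i] <- "palindromic_ambiguous"
        } else if ((eaf_ex[i] < 0.5) != (eaf_ou[i] < 0.5)) {
          flipped[i] <- TRUE  # frequencies disagree: outcome counts the other allele
        }
      } else {
        if (o1[i] == e1[i] && o2[i] == e2[i]) {
          # direct match
        } else if (o1[i] == e2[i] && o2[i] == e1[i]) {
          flipped[i] <- TRUE
        } else if (flip_allele(o1[i]) == e1[i] && flip_allele(o2[i]) == e2[i]) {
          # opposite strand, same orientation
        } else if (flip_allele(o1[i]) == e2[i] && flip_allele(o2[i]) == e1[i]) {
          flipped[i] <- TRUE
        } else {
          keep[i] <- FALSE; reason[i] <- "incompatible_alleles"
        }
      }
    }
  }

  beta_outcome <- ifelse(flipped, -ou$beta, ou$beta)
  eaf_outcome <- ifelse(flipped, 1 - eaf_ou, eaf_ou)
  out <- data.frame(
    variant_id = shared,
    beta_exposure = ex$beta,
    se_exposure = ex$se,
    beta_outcome = beta_outcome,
    se_outcome = ou$se,
    eaf_exposure = eaf_ex,
    eaf_outcome = eaf_outcome,
    flipped = flipped,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  bad_se <- out$se_exposure <= 0 | out$se_outcome <= 0 |
    !is.finite(out$beta_exposure) | !is.finite(out$beta_outcome)
  if (any(bad_se)) {
    reason[match(out$variant_id[bad_se], shared)] <- "invalid_beta_or_se"
    out <- out[!bad_se, , drop = FALSE]
  }
  audit <- data.frame(variant_id = shared[!is.na(reason)],
                      reason = reason[!is.na(reason)],
                      stringsAsFactors = FALSE)
  attr(out, "audit") <- audit
  attr(out, "counts") <- c(shared = n, retained = nrow(out),
                           flipped = sum(out$flipped), dropped = nrow(audit))
  class(out) <- c("harmonized_data", "data.frame")
  out
}

combination_labels <- c("none", "exposure", "outcome", "both")

#' Run the four covariable-adjustment combinations of a two-sample MR
#'
#' Given exposure and outcome GWAS results computed both with and without
#' adjustment for the covariable, runs the IVW analysis for the four
#' possible combinations: neither side adjusted, exposure side only,
#' outcome side only, or both. Instruments are re-selected for each
#' combination from the matching exposure GWAS (combinations using
#' adjusted variant-exposure associations select on the adjusted F
#' statistic, unadjusted combinations on the unadjusted F), so the
#' instrument sets can differ between combinations. A combination with
#' zero selected instruments yields a non-estimable marker rather than an
#' error.
#'
#' @param exposure_unadjusted,exposure_adjusted `gwas_result` data.frames
#'   for the exposure trait without/with covariable adjustment.
#' @param outcome_unadjusted,outcome_adjusted The same for the outcome.
#' @param f_threshold Instrument-strength threshold; default 10.
#' @return A list of class `mr_four` with one element per combination
#'   (`none`, `exposure`, `outcome`, `both`), each a list with the
#'   `mr_result` (`result`), `n_instruments`, `mean_f` (mean F of the
#'   selected instruments on the selection basis) and the instrument ids.
#' @export
run_four_combinations <- function(exposure_unadjusted, exposure_adjusted,
                                  outcome_unadjusted, outcome_adjusted,
                                  f_threshold = 10) {
  pick <- list(
    none = list(exp = exposure_unadjusted, out = outcome_unadjusted),
    exposure = list(exp = exposure_adjusted, out = outcome_unadjusted),
    outcome = list(exp = exposure_unadjusted, out = outcome_adjusted),
    both = list(exp = exposure_adjusted, out = outcome_adjusted)
  )
  out <- lapply(combination_labels, function(lbl) {
    sel <- select_instruments(pick[[lbl]]$exp, f_threshold)
    if (nrow(sel) == 0L) {
      return(list(result = mr_non_estimable(), n_instruments = 0L,
                  mean_f = NA_real_, instruments = character(0)))
    }
    om <- pick[[lbl]]$out
    idx <- match(sel$variant_id, om$variant_id)
    if (anyNA(idx)) {
      stop("outcome associations missing for selected instruments",
           call. = FALSE)
    }
    h <- data.frame(variant_id = sel$variant_id,
                    beta_exposure = sel$beta,
                    se_exposure = sel$se,
                    beta_outcome = om$beta[idx],
                    se_outcome = om$se[idx],
                    stringsAsFactors = FALSE)
    ok <- is.finite(h$beta_exposure) & is.finite(h$beta_outcome) &
      h$se_outcome > 0
    h <- h[ok, , drop = FALSE]
    res <- if (nrow(h) == 0L) mr_non_estimable() else ivw_mre(h)
    list(result = res, n_instruments = nrow(h),
         mean_f = mean(sel$f_stat[ok]), instruments = h$variant_id)
  })
  names(out) <- combination_labels
  class(out) <- "mr_four"
  out
}

#' Two-sample MR from summary-statistics files
#'
#' Runs the file-based workflow: read exposure and outcome summary
#' statistics, select instruments by exposure p-value (genome-wide
#' significance by default; LD independence of the input variants is the
#' caller's responsibility), harmonize alleles, optionally exclude
#' instruments associated with the covariable, and estimate the causal
#' effect by [ivw_mre()].
#'
#' @param exposure_file,outcome_file Paths to tab-delimited
#'   summary-statistics files in the dialect of [read_summary_stats()].
#' @param p_threshold Exposure p-value selection threshold (strictly
#'   below); default `5e-8`.
#' @param f_threshold Optional instrument-strength F threshold used
#'   instead of `p_threshold` when non-`NULL` (selection keeps
#'   `(beta/se)^2 >= f_threshold`).
#' @param exclude_covariable_file Optional path to covariable summary
#'   statistics; instruments with covariable `p_value < exclude_p` are
#'   removed after harmonization.
#' @param exclude_p Covariable-exclusion threshold; default 0.05.
#' @param exposure_adjusted,outcome_adjusted Logical labels recorded in
#'   the returned object (the files themselves carry the estimates).
#' @return A list of class `mr_file_result` with the `mr_result`, the
#'   harmonized data, selection/harmonization counts and the combination
#'   label.
#' @export
mr_from_files <- function(exposure_file, outcome_file,
                          p_threshold = 5e-8, f_threshold = NULL,
                          exclude_covariable_file = NULL, exclude_p = 0.05,
                          exposure_adjusted = FALSE,
                          outcome_adjusted = FALSE) {
  ex <- read_summary_stats(exposure_file)
  ou <- read_summary_stats(outcome_file)
  if (!is.null(f_threshold)) {
    keep <- (ex$beta / ex$se)^2 >= f_threshold
  } else {
    keep <- ex$pval < p_threshold
  }
  ex_sel <- ex[keep & !is.na(keep), , drop = FALSE]
  combination <- combination_labels[
    1L + exposure_adjusted + 2L * outcome_adjusted]
  if (nrow(ex_sel) == 0L) {
    out <- list(result = mr_non_estimable(), harmonized = NULL,
                counts = c(candidates = nrow(ex), selected = 0L),
                combination = combination)
    class(out) <- "mr_file_result"
    return(out)
  }
  h <- harmonize(ex_sel, ou)
  n_excluded <- 0L
  if (!is.null(exclude_covariable_file) && nrow(h) > 0L) {
    cov <- read_summary_stats(exclude_covariable_file)
    idx <- match(h$variant_id, cov$variant_id)
    if (anyNA(idx)) {
      stop(sprintf("no covariable association for variant(s): %s",
                   paste(h$variant_id[is.na(idx)], collapse = ", ")),
           call. = FALSE)
    }
    keep_cov <- cov$pval[idx] >= exclude_p
    n_excluded <- sum(!keep_cov)
    h <- h[keep_cov, , drop = FALSE]
  }
  res <- if (nrow(h) == 0L) mr_non_estimable() else ivw_mre(h)
  out <- list(result = res, harmonized = h,
              counts = c(candidates = nrow(ex), selected = nrow(ex_sel),
                         harmonized = nrow(h) + n_excluded,
                         covariable_excluded = n_excluded,
                         analysed = nrow(h)),
              combination = combination)
  class(out) <- "mr_file_result"
  out
}
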