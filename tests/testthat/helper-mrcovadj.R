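# shared fixtures, all built in code

# minimal gwas_result-style data.frame
make_gwas <- function(ids, beta, se, p = NULL, adjusted_for = NA_character_,
                      trait = "X", eaf = 0.3, n = 1000L) {
  p <- if (is.null(p)) 2 * stats::pnorm(-abs(beta / se)) else p
  out <- data.frame(variant_id = ids, trait = trait, beta = beta, se = se,
                    f_stat = (beta / se)^2, p_value = p, n = n, eaf = eaf,
                    adjusted_for = adjusted_for, stringsAsFactors = FALSE)
  class(out) <- c("gwas_result", "data.frame")
  out
}

# summary-stats records in the file dialect
make_records <- function(ids, beta, se,
                         effect_allele = "A", other_allele = "G",
                         eaf = 0.3, pval = NULL, n = 10000L) {
  data.frame(variant_id = ids,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se,
             pval = if (is.null(pval)) 2 * stats::pnorm(-abs(beta / se))
                    else pval,
             n = n, stringsAsFactors = FALSE)
}

# small cohort for fast structural checks
quick_cohort <- function(structure, confounding = 1, n = 20000,
                         seed = 101, ...) {
  simulate_cohort(scenario_config(structure, confounding,
                                  n_individuals = n, seed = seed, ...))
}
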