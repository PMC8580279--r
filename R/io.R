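summary_stats_columns <- c("variant_id", "effect_allele", "other_allele",
                           "eaf", "beta", "se", "pval", "n")

#' Read GWAS summary statistics in the package's tab-delimited dialect
#'
#' The dialect is one flat tab-delimited table with a header containing
#' (case-insensitively, in any column order) `variant_id`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval` and `n`.
#' Rows with missing/non-numeric `beta` or `se`, or `se <= 0`, are skipped
#' with a single counted warning.
#'
#' @param path Path to the file.
#' @return A data.frame with the dialect columns (lower-case names) and an
#'   attribute `n_skipped` counting rejected rows.
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("summary-statistics file not found: %s", path),
         call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  names(raw) <- tolower(names(raw))
  missing <- setdiff(summary_stats_columns, names(raw))
  if (length(missing) > 0L) {
    stop(sprintf("summary-statistics file %s is missing column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  raw <- raw[, summary_stats_columns, drop = FALSE]
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  raw$variant_id <- as.character(raw$variant_id)
  raw$effect_allele <- toupper(as.character(raw$effect_allele))
  raw$other_allele <- toupper(as.character(raw$other_allele))
  bad <- !is.finite(raw$beta) | !is.finite(raw$se) | raw$se <= 0
  if (any(bad)) {
    warning(sprintf("skipped %d row(s) with invalid beta/se in %s",
                    sum(bad), path), call. = FALSE)
  }
  out <- raw[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Write GWAS summary statistics in the package's dialect
#'
#' Accepts either a data.frame already in the dialect or a
#' [run_gwas()] result (simulated data: alleles are filled with the
#' placeholder pair A/G and `eaf` with the generating allele frequency).
#'
#' @param records A data.frame with at least `variant_id`, `beta`, `se`.
#' @param path Output path.
#' @return Invisibly, the data.frame as written.
#' @export
write_summary_stats <- function(records, path) {
  df <- as.data.frame(records)
  if (!"effect_allele" %in% names(df)) df$effect_allele <- "A"
  if (!"other_allele" %in% names(df)) df$other_allele <- "G"
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  if (!"pval" %in% names(df)) {
    df$pval <- if ("p_value" %in% names(df)) df$p_value else NA_real_
  }
  if (!"n" %in% names(df)) df$n <- NA_integer_
  df <- df[, summary_stats_columns, drop = FALSE]
  utils::write.table(format(df, digits = 17, scientific = NA, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write an MR analysis report
#'
#' Serializes a set of labelled MR results (e.g. the four adjustment
#' combinations) as one tab-delimited table with a fixed column order,
#' followed by optional diagnostic counter lines prefixed with `#` so the
#' table remains machine-readable. Repeated calls with the same inputs
#' produce byte-identical files.
#'
#' @param results A named list of `mr_result` objects (names are the
#'   combination labels), a single `mr_result`, an `mr_four` object or a
#'   list of `mr_file_result`s.
#' @param path Output path.
#' @param diagnostics Optional named vector/list of counters appended as
#'   comment lines.
#' @return Invisibly, the report data.frame.
#' @export
write_report <- function(results, path, diagnostics = NULL) {
  if (inherits(results, "mr_result")) results <- list(result = results)
  if (inherits(results, "mr_four")) {
    results <- lapply(results, function(el) el$result)
  }
  results <- lapply(results, function(r) {
    if (inherits(r, "mr_file_result")) r$result else r
  })
  if (length(results) == 0L) {
    stop("no results to report", call. = FALSE)
  }
  labels <- names(results)
  if (is.null(labels)) labels <- paste0("result_", seq_along(results))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(combination = labels[i],
               method = r$method,
               n_instruments = r$n_instruments,
               estimate = r$estimate, se = r$se,
               ci_low = r$ci_low, ci_high = r$ci_high,
               residual_scale = r$residual_scale,
               estimable = r$estimable,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(format(df, digits = 12, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(diagnostics)) {
    for (nm in names(diagnostics)) {
      writeLines(sprintf("# %s\t%s", nm, diagnostics[[nm]]), con)
    }
  }
  invisible(df)
}

#' Read a scenario configuration from a YAML file
#'
#' The file maps one-to-one onto the arguments of [scenario_config()].
#'
#' @param path Path to a YAML key-value file.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(scenario_config)))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(scenario_config, vals)
}

#' Write a scenario configuration to a YAML file
#'
#' Inverse of [read_scenario_config()]:
#' `read_scenario_config(write_scenario_config(cfg, path))` reproduces the
#' configuration exactly.
#'
#' @param config A `scenario_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scenario_config <- function(config, path) {
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}
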