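#' Classify a regression dilution ratio into attenuation bands
#'
#' Descriptive labels for the practical impact of reporting error on risk
#' estimates: below the lower boundary, substantial attenuation; between the
#' boundaries, slight-to-moderate; above the upper boundary, little or none
#' (an RDR near or above 1 means differential systematic error offsets the
#' random-error attenuation). Boundaries are override-able; the labels are
#' descriptions, not inferential claims.
#'
#' @param rdr Regression dilution ratio(s), >= 0.
#' @param boundaries Length-2 increasing numeric, default `c(0.66, 0.86)`.
#' @return Character vector of labels: `"substantial"`,
#'   `"slight-to-moderate"`, `"little-or-none"`.
#' @export
#' @examples
#' classify_rdr(c(0.44, 0.70, 1.02))
classify_rdr <- function(rdr, boundaries = c(0.66, 0.86)) {
  if (any(rdr < 0)) stop_domain("rdr must be >= 0")
  stopifnot(length(boundaries) == 2L, boundaries[1] < boundaries[2])
  ifelse(rdr < boundaries[1], "substantial",
         ifelse(rdr <= boundaries[2], "slight-to-moderate", "little-or-none"))
}

# Turn a plain list (parsed YAML/JSON) into variable_meta objects.
config_to_metas <- function(config) {
  if (inherits(config, "variable_meta")) return(list(config))
  if (all(vapply(config, inherits, logical(1), "variable_meta"))) return(config)
  vars <- config$variables %||% config
  lapply(names(vars), function(vn) {
    v <- vars[[vn]]
    variable_meta(vn, kind = v$kind %||% "quantitative",
                  units = v$units %||% "",
                  category_edges = if (!is.null(v$category_edges))
                    as.numeric(unlist(v$category_edges)),
                  levels = if (!is.null(v$levels)) as.character(unlist(v$levels)),
                  reference_description = v$reference_description %||% "",
                  integer_years = isTRUE(v$integer_years))
  })
}

#' Read a variable configuration from YAML or JSON
#'
#' The file holds a `variables:` mapping from variable name to `kind`,
#' `units`, `category_edges`, `levels`, `integer_years`,
#' `reference_description`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return List of [variable_meta()] objects.
#' @export
read_variable_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path) else yaml::read_yaml(path)
  config_to_metas(cfg)
}

#' Run the full validation analysis and write the report bundle
#'
#' Orchestrates the whole pipeline for a long-format paired table: for each
#' configured quantitative variable an agreement summary (means, mean
#' difference and t-test, limits of agreement, ICC, Pearson r), a quintile
#' error profile and a category-mean/RDR analysis with percentile-bootstrap
#' confidence interval; for ordinal variables the Spearman/trend analysis;
#' for binary variables kappa and percent agreement. Variables failing their
#' preconditions are skipped with a logged reason; the run aborts only on
#' global failure.
#'
#' Outputs written to `out_dir`: `agreement.csv`, `quintile_errors.csv`,
#' `rdr.json` and per-variable `figure_rdr_<var>.csv` (category, mean self,
#' mean reference, reference CI), `ordinal.csv` and per-variable
#' `figure_ordinal_<var>.csv`, `categorical.csv`, and `manifest.json`
#' recording seed, `n_boot`, package version, and per-variable complete and
#' missing counts — everything needed to reproduce the run.
#'
#' @param config Path to a YAML/JSON variable config, or a list of
#'   [variable_meta()] objects.
#' @param input Path to the long-format paired CSV (see
#'   [load_paired_table()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the RDR bootstrap.
#' @param n_boot Bootstrap replicates per variable.
#' @return Invisibly, a list with the computed result objects (`agreement`,
#'   `quintiles`, `rdr`, `ordinal`, `categorical`), the `manifest`, and
#'   `skipped` (named character vector of reasons).
#' @export
run_pipeline <- function(config, input, out_dir, seed = 1, n_boot = 2000) {
  metas <- if (is.character(config)) read_variable_config(config)
           else config_to_metas(config)
  samples <- load_paired_table(input, metas)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  agreement <- list(); quintiles <- list(); rdr <- list()
  ordinal <- list(); categorical <- list(); skipped <- character()
  for (vn in names(samples)) {
    s <- samples[[vn]]
    res <- tryCatch({
      switch(s$meta$kind,
        quantitative = {
          agreement[[vn]] <- summarize_agreement(s)
          quintiles[[vn]] <- quintile_error_profile(s)
          rdr[[vn]] <- rdr_bootstrap_ci(s, edges = s$meta$category_edges,
                                        n_boot = n_boot, seed = seed)
        },
        ordinal = ordinal[[vn]] <- ordinal_association(s),
        binary = categorical[[vn]] <- kappa_agreement(s))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      skipped[vn] <- res
      message("skipping '", vn, "': ", res)
    }
  }

  if (length(agreement)) {
    utils::write.csv(do.call(rbind, lapply(agreement, as.data.frame)),
                     file.path(out_dir, "agreement.csv"), row.names = FALSE)
  }
  if (length(quintiles)) {
    qtab <- do.call(rbind, lapply(names(quintiles), function(vn) {
      q <- quintiles[[vn]]
      cbind(variable = vn, q$strata,
            anova_p = q$anova_p, degenerate = q$degenerate)
    }))
    utils::write.csv(qtab, file.path(out_dir, "quintile_errors.csv"),
                     row.names = FALSE)
  }
  if (length(rdr)) {
    rdr_json <- lapply(names(rdr), function(vn) {
      r <- rdr[[vn]]
      list(variable = vn, rdr = r$rdr, ci = r$ci,
           classification = classify_rdr(r$rdr),
           attenuation_percent = attenuation_percent(r$rdr),
           n_boot = r$n_boot, n_discarded = r$n_discarded, seed = r$seed,
           category_edges = r$category_means$edges,
           categories = r$category_means$table)
    })
    jsonlite::write_json(rdr_json, file.path(out_dir, "rdr.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (vn in names(rdr))
      utils::write.csv(rdr[[vn]]$category_means$table,
                       file.path(out_dir, paste0("figure_rdr_", vn, ".csv")),
                       row.names = FALSE)
  }
  if (length(ordinal)) {
    otab <- do.call(rbind, lapply(names(ordinal), function(vn) {
      o <- ordinal[[vn]]
      data.frame(variable = vn, n = o$n, spearman_r = o$spearman_r,
                 trend_p = o$trend_p)
    }))
    utils::write.csv(otab, file.path(out_dir, "ordinal.csv"), row.names = FALSE)
    for (vn in names(ordinal))
      utils::write.csv(ordinal[[vn]]$levels,
                       file.path(out_dir, paste0("figure_ordinal_", vn, ".csv")),
                       row.names = FALSE)
  }
  if (length(categorical)) {
    ctab <- do.call(rbind, lapply(names(categorical), function(vn) {
      k <- categorical[[vn]]
      data.frame(variable = vn, n = k$n,
                 percent_agreement = k$percent_agreement, kappa = k$kappa,
                 kappa_band = k$kappa_band, p_vs_chance = k$p_vs_chance)
    }))
    utils::write.csv(ctab, file.path(out_dir, "categorical.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    seed = seed, n_boot = n_boot,
    package_version = as.character(utils::packageVersion("recallval")),
    variables = lapply(samples, function(s)
      list(kind = s$meta$kind, n = s$n, n_missing = s$n_excluded)),
    skipped = as.list(skipped))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(agreement = agreement, quintiles = quintiles, rdr = rdr,
                 ordinal = ordinal, categorical = categorical,
                 manifest = manifest, skipped = skipped))
}
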