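#' Describe one study variable and its analysis plan
#'
#' A `variable_meta` object records, for a single variable of a validation
#' study, how the paired self-report/reference columns should be analysed:
#' whether the variable is quantitative, ordinal or binary, its units, the
#' pre-specified self-report category boundaries used for category-mean plots
#' and regression dilution ratios, and the ordered level labels for ordinal
#' and binary variables.
#'
#' @param name Variable identifier, e.g. `"weight"`.
#' @param kind One of `"quantitative"`, `"ordinal"`, `"binary"`. Determines
#'   which analysis operations are legal for the variable.
#' @param units Free-text units of the values (quantitative variables).
#' @param category_edges For quantitative variables, a strictly increasing
#'   numeric breaks vector (`k + 1` edges for `k` categories; the outermost
#'   edges may be infinite) defining the pre-specified self-report categories.
#'   `NULL` means empirical quintiles are used when categories are needed.
#' @param levels For ordinal/binary variables, the ordered level labels
#'   (lowest first); at least 2.
#' @param reference_description Free text describing the reference measurement.
#' @param integer_years Logical; `TRUE` for ages reported in whole years, to
#'   which [adjust_integer_age()] should be applied before comparison.
#'
#' @return An object of class `variable_meta`.
#' @seealso [paired_sample()], [load_paired_table()]
#' @export
#' @examples
#' variable_meta("weight", "quantitative", units = "kg",
#'               category_edges = c(40, 55, 65, 75, 120))
variable_meta <- function(name, kind = c("quantitative", "ordinal", "binary"),
                          units = "", category_edges = NULL, levels = NULL,
                          reference_description = "", integer_years = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.null(category_edges)) {
    if (!is.numeric(category_edges) || length(category_edges) < 2L ||
        any(diff(category_edges) <= 0))
      stop_domain("category_edges must be a strictly increasing numeric vector ",
                  "of length >= 2 for variable '", name, "'")
  }
  if (kind %in% c("ordinal", "binary")) {
    if (is.null(levels)) levels <- if (kind == "binary") c("no", "yes") else NULL
    if (!is.null(levels) && (anyDuplicated(levels) || length(levels) < 2L))
      stop_domain("levels must be >= 2 distinct ordered labels for variable '",
                  name, "'")
    if (kind == "binary" && !is.null(levels) && length(levels) != 2L)
      stop_domain("binary variable '", name, "' must have exactly 2 levels")
  }
  structure(list(name = name, kind = kind, units = units,
                 category_edges = category_edges, levels = levels,
                 reference_description = reference_description,
                 integer_years = isTRUE(integer_years)),
            class = "variable_meta")
}

#' @export
print.variable_meta <- function(x, ...) {
  cat("<variable_meta> ", x$name, " [", x$kind, "]",
      if (nzchar(x$units)) paste0(" (", x$units, ")"), "\n", sep = "")
  invisible(x)
}

#' Paired self-report/reference observations for one variable
#'
#' Holds the aligned vectors compared throughout a validation study: the
#' self-reported values (the error-prone measurement) and the reference
#' values (the gold or "alloyed gold" standard), one pair per participant.
#' Rows with a missing value in either member are removed (complete-case per
#' variable), and the number excluded is retained for missingness analyses.
#'
#' @param meta A [variable_meta()] object.
#' @param self_report,reference Numeric vectors of equal length (for ordinal
#'   self-reports, integer level ranks: 1 for the lowest category).
#' @param ids Participant identifiers; defaults to `seq_along(self_report)`.
#' @param subgroups Optional data frame (or named list) of per-participant
#'   categorical labels (e.g. social class), same length as the value vectors.
#'
#' @return Object of class `paired_sample` with elements `meta`, `ids`,
#'   `self_report`, `reference`, `subgroups`, `n`, `n_excluded` and
#'   `excluded_subgroups` (subgroup labels of the excluded rows).
#' @export
#' @examples
#' ps <- paired_sample(variable_meta("height", "quantitative", units = "cm"),
#'                     self_report = c(162, 158, NA), reference = c(160, 159, 161))
#' ps$n            # 2 complete pairs
#' ps$n_excluded   # 1 incomplete pair
paired_sample <- function(meta, self_report, reference, ids = NULL,
                          subgroups = NULL) {
  stopifnot(inherits(meta, "variable_meta"))
  self_report <- as.numeric(self_report)
  reference <- as.numeric(reference)
  if (length(self_report) != length(reference))
    stop_domain("self_report and reference must have equal length for '",
                meta$name, "'")
  ids <- ids %||% seq_along(self_report)
  if (length(ids) != length(self_report))
    stop_domain("ids must match the value vectors in length")
  if (!is.null(subgroups)) {
    subgroups <- as.data.frame(subgroups, stringsAsFactors = FALSE)
    if (nrow(subgroups) != length(self_report))
      stop_domain("subgroups must have one row per participant")
  }
  keep <- !is.na(self_report) & !is.na(reference)
  structure(list(
    meta = meta,
    ids = ids[keep],
    self_report = self_report[keep],
    reference = reference[keep],
    subgroups = if (!is.null(subgroups)) subgroups[keep, , drop = FALSE],
    n = sum(keep),
    n_excluded = sum(!keep),
    excluded_subgroups = if (!is.null(subgroups)) subgroups[!keep, , drop = FALSE]
  ), class = "paired_sample")
}

#' @export
print.paired_sample <- function(x, ...) {
  cat("<paired_sample> ", x$meta$name, " [", x$meta$kind, "]: n = ", x$n,
      " complete pairs (", x$n_excluded, " excluded as missing)\n", sep = "")
  invisible(x)
}

#' Differences self-report minus reference
#'
#' @param sample A [paired_sample()].
#' @return Numeric vector of per-participant reporting errors.
#' @export
differences <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  sample$self_report - sample$reference
}

MISSING_TOKENS <- c("", "NA", "na", "N/A", "don't know", "dont know")

#' Load a long-format paired table
#'
#' Reads delimited text with columns `id`, `variable`, `self_report`,
#' `reference` (header required; any further columns are treated as subgroup
#' factors) and returns one [paired_sample()] per configured variable.
#' Complete-case filtering is applied per variable; blank cells, `NA` and
#' "don't know" tokens all count as missing. Values of ordinal/binary
#' variables may be given either as numeric codes or as the level labels
#' declared in the config, which are mapped to integer ranks.
#'
#' @param path Path to a CSV (or TSV, see `sep`) file.
#' @param config A list of [variable_meta()] objects covering every variable
#'   name present in the file.
#' @param sep Field separator, default `","`.
#' @return Named list of `paired_sample` objects, one per config entry that
#'   appears in the file.
#' @export
load_paired_table <- function(path, config, sep = ",") {
  stopifnot(file.exists(path))
  if (inherits(config, "variable_meta")) config <- list(config)
  names(config) <- vapply(config, function(m) m$name, character(1))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character())
  required <- c("id", "variable", "self_report", "reference")
  if (!all(required %in% names(raw)))
    stop_domain("input must have columns: ", paste(required, collapse = ", "))
  subgroup_cols <- setdiff(names(raw), required)
  unknown <- setdiff(unique(raw$variable), names(config))
  if (length(unknown))
    stop_domain("variable(s) not in config: ", paste(unknown, collapse = ", "))

  out <- list()
  for (meta in config) {
    rows <- which(raw$variable == meta$name)
    if (!length(rows)) next
    sr <- parse_values(raw$self_report[rows], meta, rows, "self_report")
    rf <- parse_values(raw$reference[rows], meta, rows, "reference",
                       force_numeric = TRUE)
    sub <- if (length(subgroup_cols)) raw[rows, subgroup_cols, drop = FALSE]
    out[[meta$name]] <- paired_sample(meta, sr, rf, ids = raw$id[rows],
                                      subgroups = sub)
  }
  out
}

# Parse one column of character cells into numeric values, honouring missing
# tokens and ordinal/binary label maps; reports offending row indices.
parse_values <- function(cells, meta, rows, column, force_numeric = FALSE) {
  miss <- cells %in% MISSING_TOKENS
  vals <- rep(NA_real_, length(cells))
  todo <- !miss
  if (!force_numeric && !is.null(meta$levels)) {
    hit <- match(cells, meta$levels)
    vals[todo & !is.na(hit)] <- hit[todo & !is.na(hit)]
    todo <- todo & is.na(hit)
  }
  num <- suppressWarnings(as.numeric(cells[todo]))
  if (anyNA(num)) {
    bad <- rows[todo][is.na(num)]
    stop_domain("non-numeric ", column, " value for ",
                meta$kind, " variable '", meta$name, "' at data row(s) ",
                paste(utils::head(bad, 5), collapse = ", "))
  }
  vals[todo] <- num
  vals
}

#' Write paired samples back to the long tabular format
#'
#' Inverse of [load_paired_table()] for complete cases: values round-trip
#' bit-exactly (numbers are written with full precision).
#'
#' @param samples List of [paired_sample()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_paired_table <- function(samples, path) {
  if (inherits(samples, "paired_sample")) samples <- list(samples)
  blocks <- lapply(samples, function(s) {
    d <- data.frame(id = s$ids, variable = s$meta$name,
                    self_report = format(s$self_report, digits = 17, trim = TRUE),
                    reference = format(s$reference, digits = 17, trim = TRUE),
                    stringsAsFactors = FALSE)
    if (!is.null(s$subgroups)) d <- cbind(d, s$subgroups)
    d
  })
  utils::write.csv(do.call(rbind, blocks), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Reshape a wide per-participant table to the long paired format
#'
#' Convenience for data laid out as one row per participant with
#' `<var>_self` and `<var>_ref` column pairs.
#'
#' @param df Wide data frame with an `id` column.
#' @param variables Character vector of variable names to extract.
#' @param subgroup_cols Columns carried along as subgroup factors.
#' @return Long data frame with columns `id`, `variable`, `self_report`,
#'   `reference` and any subgroup columns, suitable for writing and
#'   re-loading with [load_paired_table()].
#' @export
wide_to_long <- function(df, variables, subgroup_cols = character()) {
  stopifnot("id" %in% names(df))
  blocks <- lapply(variables, function(v) {
    sc <- paste0(v, "_self"); rc <- paste0(v, "_ref")
    if (!all(c(sc, rc) %in% names(df)))
      stop_domain("columns ", sc, " and ", rc, " required for variable '", v, "'")
    cbind(data.frame(id = df$id, variable = v, self_report = df[[sc]],
                     reference = df[[rc]], stringsAsFactors = FALSE),
          df[, subgroup_cols, drop = FALSE])
  })
  do.call(rbind, blocks)
}

#' Unit conversions used when harmonising self-reported records
#'
#' Imperial anthropometry is converted with the international exact factors
#' (1 in = 2.54 cm; 1 lb = 0.45359237 kg); durations recorded in months are
#' converted to years by division by 12 without rounding.
#'
#' @param value Finite, non-negative numeric vector. For
#'   `"stone_lb_to_kg"`, the whole-stone part of the weight.
#' @param conversion One of `"inch_to_cm"`, `"lb_to_kg"`, `"stone_lb_to_kg"`,
#'   `"months_to_years"`.
#' @param pounds Residual pounds for `"stone_lb_to_kg"` (default 0).
#' @return Converted numeric vector.
#' @export
#' @examples
#' convert_units(18, "months_to_years")            # 1.5 years
#' convert_units(10, "inch_to_cm")                 # 25.4 cm
#' convert_units(9, "stone_lb_to_kg", pounds = 4)  # 9 st 4 lb in kg
convert_units <- function(value,
                          conversion = c("inch_to_cm", "lb_to_kg",
                                         "stone_lb_to_kg", "months_to_years"),
                          pounds = 0) {
  conversion <- match.arg(conversion)
  if (any(!is.finite(value)) || any(value < 0))
    stop_domain("value must be finite and non-negative")
  switch(conversion,
    inch_to_cm = value * 2.54,
    lb_to_kg = value * 0.45359237,
    stone_lb_to_kg = {
      if (any(!is.finite(pounds)) || any(pounds < 0))
        stop_domain("pounds must be finite and non-negative")
      (value * 14 + pounds) * 0.45359237
    },
    months_to_years = value / 12)
}

#' Mid-year adjustment for ages reported in whole years
#'
#' An event age recorded only in completed years understates the exact age by
#' six months on average (the mean exact age of "12 year olds" is 12.5), so
#' 0.5 is added before comparison with exact-date reference data. The
#' adjustment is only defined for whole-year reports and is never applied
#' automatically: flag such variables with `integer_years` in
#' [variable_meta()].
#'
#' @param age_years Integer-valued ages in whole years.
#' @return `age_years + 0.5`.
#' @export
#' @examples
#' adjust_integer_age(12)  # 12.5
adjust_integer_age <- function(age_years) {
  ok <- !is.na(age_years)
  if (any(!is.finite(age_years[ok])) ||
      any(age_years[ok] != round(age_years[ok])))
    stop_domain("adjust_integer_age is defined only for whole-year ages")
  age_years + 0.5
}
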