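## Registry of the 44 discriminant formulas. The JSON document shipped in
## inst/extdata/formulas.json is the single source of truth; it is parsed
## once per session into an ordered list of formula_spec objects.

.registry_state <- new.env(parent = emptyenv())

registry_path <- function() {
  system.file("extdata", "formulas.json", package = "thalscreen",
              mustWork = TRUE)
}

load_registry <- function() {
  doc <- jsonlite::fromJSON(registry_path(), simplifyVector = FALSE)
  specs <- lapply(doc$formulas, function(f) {
    spec <- structure(list(
      id = f$id,
      name = f$name,
      year = as.integer(f$year),
      row = as.integer(f$row),
      expression = f$expression,
      comparator = f$comparator,
      cutoff = as.numeric(f$cutoff),
      required_fields = vapply(f$required, identity, character(1)),
      unit_regime = unit_regime(hb = f$hb_unit %||% "g_l",
                                mchc = f$mchc_unit %||% "g_l"),
      provenance = f$provenance
    ), class = "formula_spec")
    free <- sort(all.vars(str2lang(spec$expression)))
    if (!identical(free, sort(spec$required_fields)))
      stop_ts("registry entry '", spec$id,
              "': required fields do not match expression free variables")
    if (!spec$comparator %in% c("<", "<=", ">", ">="))
      stop_ts("registry entry '", spec$id, "': bad comparator")
    spec
  })
  specs <- specs[order(vapply(specs, `[[`, integer(1), "row"))]
  names(specs) <- vapply(specs, `[[`, character(1), "id")
  if (length(specs) != 44L || anyDuplicated(names(specs)))
    stop_ts("registry must contain exactly 44 uniquely named formulas")
  specs
}

registry <- function() {
  if (is.null(.registry_state$specs))
    .registry_state$specs <- load_registry()
  .registry_state$specs
}

#' Retrieve discriminant formula specifications
#'
#' `list_formulas()` returns all 44 registered formulas in their
#' canonical table order; `get_formula()` one formula by its slug id
#' (e.g. `"mentzer"`, `"shine_lal"`, `"xs1"`). Ricerca and Plengsuree are
#' deliberately distinct entries with identical expressions
#' (RDW/RBC < 3.3): both appear in the source catalog under their own
#' names and are kept separately addressable.
#'
#' @param id formula slug.
#' @return `get_formula()`: a `formula_spec`; `list_formulas()`: a named
#'   list of 44 of them; `formula_table()`: a summary data frame.
#' @examples
#' get_formula("mentzer")
#' names(list_formulas())
#' @export
list_formulas <- function() registry()

#' @rdname list_formulas
#' @export
get_formula <- function(id) {
  specs <- registry()
  if (!is_present(id) || !id %in% names(specs))
    stop_ts("unknown formula id: ", paste(id, collapse = ", "),
            " (see list_formulas())")
  specs[[id]]
}

#' @rdname list_formulas
#' @export
formula_table <- function() {
  specs <- registry()
  data.frame(
    row = vapply(specs, `[[`, integer(1), "row"),
    id = names(specs),
    name = vapply(specs, `[[`, character(1), "name"),
    year = vapply(specs, `[[`, integer(1), "year"),
    expression = vapply(specs, `[[`, character(1), "expression"),
    comparator = vapply(specs, `[[`, character(1), "comparator"),
    cutoff = vapply(specs, `[[`, numeric(1), "cutoff"),
    hb_unit = vapply(specs, function(s) s$unit_regime$hb, character(1)),
    mchc_unit = vapply(specs, function(s) s$unit_regime$mchc, character(1)),
    row.names = NULL
  )
}

#' @export
print.formula_spec <- function(x, ...) {
  cat(sprintf("<formula_spec> %s (%s, %d)\n", x$id, x$name, x$year))
  cat(sprintf("  TT if  %s  %s  %g\n", x$expression, x$comparator, x$cutoff))
  cat(sprintf("  fields: %s; published units: hb %s, mchc %s\n",
              paste(x$required_fields, collapse = ", "),
              x$unit_regime$hb, x$unit_regime$mchc))
  invisible(x)
}

#' Export the registry as a JSON string
#'
#' Serializes the in-memory registry (the same content as the shipped
#' JSON document) for interoperability.
#'
#' @return JSON string.
#' @export
registry_json <- function() {
  specs <- registry()
  jsonlite::toJSON(lapply(unname(specs), function(s) list(
    id = s$id, name = s$name, year = s$year, row = s$row,
    expression = s$expression, comparator = s$comparator,
    cutoff = s$cutoff, required_fields = s$required_fields,
    hb_unit = s$unit_regime$hb, mchc_unit = s$unit_regime$mchc,
    provenance = s$provenance
  )), auto_unbox = TRUE, pretty = TRUE)
}

## ---------------------------------------------------------------------
## Evaluation

apply_comparator <- function(score, comparator, cutoff) {
  switch(comparator,
         "<" = score < cutoff,
         "<=" = score <= cutoff,
         ">" = score > cutoff,
         ">=" = score >= cutoff,
         stop_ts("bad comparator: ", comparator))
}

#' Direction of a formula's TT side
#'
#' `"lower"` when the comparator is `<` or `<=` (smaller scores favor
#' TT), `"higher"` otherwise.
#'
#' @param spec `formula_spec` or slug id.
#' @return `"lower"` or `"higher"`.
#' @export
formula_direction <- function(spec) {
  spec <- resolve_spec(spec)
  if (spec$comparator %in% c("<", "<=")) "lower" else "higher"
}

resolve_spec <- function(spec) {
  if (inherits(spec, "formula_spec")) spec else get_formula(spec)
}

## Adapt canonical-unit records to what a formula expects.
## mode "paper": feed canonical analyzer units (hb g/L, mchc g/L) to every
## formula, reproducing the reference study's default evaluation regime.
## mode "as_published": convert hb/mchc to each formula's original units.
adapt_record <- function(spec, records, mode) {
  mode <- match.arg(mode, c("paper", "as_published"))
  if (mode == "as_published")
    records <- convert_units(records, from = unit_regime(),
                             to = spec$unit_regime)
  records
}

#' Evaluate a discriminant formula on CBC records
#'
#' Computes the formula's raw score. Records are expected in canonical
#' units (see [cbc_record()]); with `mode = "as_published"` the hemoglobin
#' and MCHC columns are first converted to the units the formula was
#' originally published in (typically g/dL), while the default
#' `mode = "paper"` feeds the canonical g/L values to every formula,
#' matching the regime of the reference validation study.
#'
#' @param spec `formula_spec` or slug id.
#' @param records cohort data frame (one or more rows) in canonical units.
#' @param mode `"paper"` (default) or `"as_published"`.
#' @return numeric vector of scores, one per row.
#' @examples
#' evaluate_formula("mentzer", cbc_record(mcv = 72, rbc = 4.8))   # 15
#' evaluate_formula("shine_lal", cbc_record(mcv = 72, mch = 23))  # 1192.32
#' @export
evaluate_formula <- function(spec, records, mode = "paper") {
  spec <- resolve_spec(spec)
  records <- as_cbc_cohort(records)
  missing <- spec$required_fields[vapply(spec$required_fields, function(f)
    anyNA(records[[f]]), logical(1))]
  if (length(missing))
    stop_ts("formula '", spec$id, "' requires field(s) missing from record: ",
            paste(missing, collapse = ", "))
  records <- adapt_record(spec, records, mode)
  env <- list2env(records[spec$required_fields], parent = baseenv())
  env$log10 <- log10; env$log <- log; env$abs <- abs; env$exp <- exp
  score <- eval(str2lang(spec$expression), envir = env)
  if (any(!is.finite(score)))
    stop_ts("formula '", spec$id, "' produced a non-finite score ",
            "(division by zero or log of a non-positive value)")
  as.numeric(score)
}

#' Classify records as TT or IDA with one formula
#'
#' The call is TT exactly when `score comparator cutoff` holds as
#' written: strict comparators stay strict (a score equal to a `<`
#' cutoff is called IDA), inclusive ones stay inclusive.
#'
#' @inheritParams evaluate_formula
#' @param cutoff decision threshold; defaults to the published cutoff.
#' @param cutoff_source provenance tag stored in the result
#'   (`"published"`, `"optimal"` or `"custom"`); inferred when `cutoff`
#'   is left at the published default.
#' @return data frame with columns `subject_id`, `formula_id`, `score`,
#'   `cutoff_used`, `comparator`, `call`, `cutoff_source`.
#' @examples
#' classify("mentzer", cbc_record(mcv = 72, rbc = 4.8))  # score 15 -> IDA
#' @export
classify <- function(spec, records, cutoff = NULL, mode = "paper",
                     cutoff_source = NULL) {
  spec <- resolve_spec(spec)
  records <- as_cbc_cohort(records)
  if (is.null(cutoff)) {
    cutoff <- spec$cutoff
    cutoff_source <- cutoff_source %||% "published"
  } else {
    cutoff_source <- cutoff_source %||% "custom"
  }
  score <- evaluate_formula(spec, records, mode)
  tt <- apply_comparator(score, spec$comparator, cutoff)
  data.frame(
    subject_id = records$subject_id,
    formula_id = spec$id,
    score = score,
    cutoff_used = cutoff,
    comparator = spec$comparator,
    call = ifelse(tt, "TT", "IDA"),
    cutoff_source = cutoff_source,
    stringsAsFactors = FALSE
  )
}

#' Run the whole formula panel on one record
#'
#' Evaluates every requested formula at its published cutoff. Formulas
#' whose required fields are absent are reported as skipped with the
#' missing fields named, never as errors.
#'
#' @param record one-row canonical data frame.
#' @param formula_ids subset of slugs (default: all 44).
#' @inheritParams evaluate_formula
#' @return data frame with one row per requested formula: `formula_id`,
#'   `name`, `score`, `cutoff`, `comparator`, `call`, `skipped`,
#'   `skip_reason`.
#' @examples
#' evaluate_panel(cbc_record(rbc = 4.8, hb = 110, hct = 34, mcv = 72,
#'                           mch = 23, mchc = 320, rdw_cv = 15))
#' @export
evaluate_panel <- function(record, formula_ids = NULL, mode = "paper") {
  record <- as_cbc_cohort(record)
  stopifnot(nrow(record) == 1L)
  specs <- registry()
  if (!is.null(formula_ids)) {
    bad <- setdiff(formula_ids, names(specs))
    if (length(bad)) stop_ts("unknown formula id: ", paste(bad, collapse = ", "))
    specs <- specs[formula_ids]
  }
  rows <- lapply(specs, function(spec) {
    missing <- spec$required_fields[vapply(spec$required_fields, function(f)
      is.na(record[[f]]), logical(1))]
    if (length(missing)) {
      data.frame(formula_id = spec$id, name = spec$name, score = NA_real_,
                 cutoff = spec$cutoff, comparator = spec$comparator,
                 call = NA_character_, skipped = TRUE,
                 skip_reason = paste("missing:", paste(missing, collapse = ", ")),
                 stringsAsFactors = FALSE)
    } else {
      cl <- classify(spec, record, mode = mode)
      data.frame(formula_id = spec$id, name = spec$name, score = cl$score,
                 cutoff = spec$cutoff, comparator = spec$comparator,
                 call = cl$call, skipped = FALSE, skip_reason = "",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(formula_id = character(), name = character(),
                      score = numeric(), cutoff = numeric(),
                      comparator = character(), call = character(),
                      skipped = logical(), skip_reason = character())
  rownames(out) <- NULL
  out
}
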