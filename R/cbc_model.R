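## Domain model: one subject = one row of a canonical CBC data frame.
##
## Canonical internal units mirror the hematology-analyzer regime the
## formulas are evaluated in by default: Hb g/L, MCHC g/L, HCT %,
## RBC 10^12/L, MCV fL, MCH pg, RDW-CV %, RDW-SD fL, WBC 10^9/L,
## PLT 10^9/L, MPV fL, serum ferritin ug/L, age years.

#' Canonical CBC analyte and column names
#'
#' `cbc_analytes()` returns the numeric analyte columns; `cbc_columns()`
#' the full canonical column set of a cohort data frame, including the
#' identifier, genotype, pregnancy flags and group label.
#'
#' @return character vector of column names.
#' @export
cbc_analytes <- function() {
  c("age", "wbc", "rbc", "hb", "hct", "mcv", "mch", "mchc",
    "rdw_cv", "rdw_sd", "plt", "mpv", "sf")
}

#' @rdname cbc_analytes
#' @export
cbc_columns <- function() {
  c("subject_id", cbc_analytes(),
    "thal_gene", "twin_or_multiple", "stillbirth", "label")
}

#' Build a single CBC record
#'
#' Returns a one-row data frame in the canonical column layout. Omitted
#' analytes are stored as `NA` (absent), never as 0: zero is a
#' valid-looking but physiologically impossible analyte value.
#'
#' @param subject_id identifier string.
#' @param age age in years.
#' @param wbc white cells, 10^9/L.
#' @param rbc red cells, 10^12/L.
#' @param hb hemoglobin, g/L (canonical regime).
#' @param hct hematocrit, percent.
#' @param mcv mean corpuscular volume, fL.
#' @param mch mean corpuscular hemoglobin, pg.
#' @param mchc mean corpuscular hemoglobin concentration, g/L.
#' @param rdw_cv red-cell distribution width, CV form, percent.
#' @param rdw_sd red-cell distribution width, SD form, fL.
#' @param plt platelets, 10^9/L.
#' @param mpv mean platelet volume, fL.
#' @param sf serum ferritin, ug/L.
#' @param thal_gene `TRUE`/`FALSE`/`NA` thalassemia genotype status
#'   (any positive alpha or beta panel result counts as positive).
#' @param twin_or_multiple logical pregnancy flag.
#' @param stillbirth logical pregnancy flag.
#' @param label group label `"TT"`, `"IDA"` or `NA` (unknown).
#' @return one-row data frame with columns [cbc_columns()].
#' @examples
#' cbc_record(rbc = 4.8, hb = 110, hct = 34)
#' @export
cbc_record <- function(subject_id = "S1", age = NA_real_, wbc = NA_real_,
                       rbc = NA_real_, hb = NA_real_, hct = NA_real_,
                       mcv = NA_real_, mch = NA_real_, mchc = NA_real_,
                       rdw_cv = NA_real_, rdw_sd = NA_real_,
                       plt = NA_real_, mpv = NA_real_, sf = NA_real_,
                       thal_gene = NA, twin_or_multiple = NA,
                       stillbirth = NA, label = NA_character_) {
  df <- data.frame(
    subject_id = as.character(subject_id),
    age = as.numeric(age), wbc = as.numeric(wbc), rbc = as.numeric(rbc),
    hb = as.numeric(hb), hct = as.numeric(hct), mcv = as.numeric(mcv),
    mch = as.numeric(mch), mchc = as.numeric(mchc),
    rdw_cv = as.numeric(rdw_cv), rdw_sd = as.numeric(rdw_sd),
    plt = as.numeric(plt), mpv = as.numeric(mpv), sf = as.numeric(sf),
    thal_gene = as.logical(thal_gene),
    twin_or_multiple = as.logical(twin_or_multiple),
    stillbirth = as.logical(stillbirth),
    label = as.character(label),
    stringsAsFactors = FALSE
  )
  if (!is.na(df$label) && !df$label %in% c("TT", "IDA"))
    stop_ts("label must be \"TT\", \"IDA\" or NA, got \"", df$label, "\"")
  df
}

#' Coerce a data frame to the canonical cohort layout
#'
#' Missing canonical columns are added as `NA`; extra columns are kept.
#'
#' @param df data frame with a subset of [cbc_columns()].
#' @return data frame containing all canonical columns.
#' @export
as_cbc_cohort <- function(df) {
  stopifnot(is.data.frame(df))
  for (col in cbc_analytes()) {
    if (!col %in% names(df)) df[[col]] <- NA_real_ else
      df[[col]] <- as.numeric(df[[col]])
  }
  if (!"subject_id" %in% names(df))
    df$subject_id <- sprintf("S%04d", seq_len(nrow(df)))
  df$subject_id <- as.character(df$subject_id)
  for (col in c("thal_gene", "twin_or_multiple", "stillbirth")) {
    if (!col %in% names(df)) df[[col]] <- NA else
      df[[col]] <- parse_logical(df[[col]])
  }
  if (!"label" %in% names(df)) df$label <- NA_character_ else {
    df$label <- as.character(df$label)
    df$label[!is.na(df$label) & df$label == ""] <- NA_character_
  }
  bad <- !is.na(df$label) & !df$label %in% c("TT", "IDA")
  if (any(bad))
    stop_ts("invalid label(s): ", paste(unique(df$label[bad]), collapse = ", "))
  df[, union(cbc_columns(), names(df))]
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("true", "t", "1", "yes", "y", "positive", "pos")] <- TRUE
  out[s %in% c("false", "f", "0", "no", "n", "negative", "neg")] <- FALSE
  out
}

## ---------------------------------------------------------------------
## Unit regimes

#' Describe the measurement units of a record or formula
#'
#' Hemoglobin and MCHC circulate in two conventions (g/L in SI-reporting
#' laboratories, g/dL in most of the older formula literature), and
#' hematocrit as a percent or a fraction. A `unit_regime` names the
#' convention; [convert_units()] moves records between regimes.
#'
#' @param hb `"g_l"` or `"g_dl"`.
#' @param mchc `"g_l"` or `"g_dl"`.
#' @param hct `"percent"` or `"fraction"`.
#' @return an object of class `"unit_regime"`.
#' @examples
#' unit_regime()                       # canonical: g/L, g/L, percent
#' unit_regime(hb = "g_dl", mchc = "g_dl")
#' @export
unit_regime <- function(hb = "g_l", mchc = "g_l", hct = "percent") {
  hb <- match.arg(hb, c("g_l", "g_dl"))
  mchc <- match.arg(mchc, c("g_l", "g_dl"))
  hct <- match.arg(hct, c("percent", "fraction"))
  structure(list(hb = hb, mchc = mchc, hct = hct), class = "unit_regime")
}

#' @export
print.unit_regime <- function(x, ...) {
  cat(sprintf("<unit_regime> hb: %s, mchc: %s, hct: %s\n",
              x$hb, x$mchc, x$hct))
  invisible(x)
}

#' Convert CBC records between unit regimes
#'
#' Scales `hb` and `mchc` by 10 between g/L and g/dL and `hct` by 100
#' between percent and fraction; every other column is untouched.
#' Conversions are exact powers of ten, so a round trip returns the
#' input bit-for-bit on decimal-representable values.
#'
#' @param x cohort data frame (or one-row record).
#' @param from,to [unit_regime()] objects; `from` must describe `x`.
#' @return `x` expressed in regime `to`.
#' @examples
#' r <- cbc_record(hb = 120, mchc = 340, hct = 36)
#' convert_units(r, unit_regime(), unit_regime(hb = "g_dl", mchc = "g_dl"))
#' @export
convert_units <- function(x, from = unit_regime(), to = unit_regime()) {
  stopifnot(inherits(from, "unit_regime"), inherits(to, "unit_regime"))
  scale_of <- c(g_l = 1, g_dl = 0.1, percent = 1, fraction = 0.01)
  for (col in c("hb", "mchc", "hct")) {
    if (!col %in% names(x)) next
    f <- scale_of[[from[[col]]]]
    t <- scale_of[[to[[col]]]]
    if (f != t) x[[col]] <- x[[col]] * (t / f)
  }
  x
}

## ---------------------------------------------------------------------
## Validation

rel_err <- function(observed, expected) abs(observed - expected) / abs(expected)

#' Validate a CBC record against positivity and consistency rules
#'
#' Checks, for every analyte that is present: strict positivity, and for
#' the percent-scaled fields (`hct`, `rdw_cv`) an upper bound of 100.
#' When all members of a derived-index identity are present, the identity
#' must hold within relative tolerance `tolerance`:
#' MCV = 10 HCT / RBC, MCH = Hb / RBC, MCHC = 100 Hb / HCT
#' (canonical units). Analyzer rounding chains make exact identity
#' impossible, hence a tolerance check rather than an equality.
#'
#' Violations are returned as data, never raised as conditions.
#'
#' @param record one-row canonical data frame (see [cbc_record()]).
#' @param tolerance relative tolerance for the derived-index identities
#'   (default 0.1, i.e. 10%).
#' @return data frame with columns `field`, `rule`, `message` (and, from
#'   `validate_cohort()`, a leading `subject_id`); zero rows when clean.
#' @examples
#' validate_record(cbc_record(rbc = 4.1, hb = 120, hct = 36,
#'                            mcv = 87, mch = 29, mchc = 340))
#' validate_record(cbc_record(rbc = 0))
#' @export
validate_record <- function(record, tolerance = 0.1) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  record <- as_cbc_cohort(record)
  if (all(is.na(unlist(record[cbc_analytes()]))))
    stop_ts("record has no analyte present")
  validate_cohort(record, tolerance)[, c("field", "rule", "message")]
}

#' Validate every record of a cohort
#'
#' Vectorized over rows; see [validate_record()] for the rules.
#'
#' @param cohort canonical cohort data frame.
#' @inheritParams validate_record
#' @return data frame of violations with a leading `subject_id` column.
#' @export
validate_cohort <- function(cohort, tolerance = 0.1) {
  cohort <- as_cbc_cohort(cohort)
  empty <- data.frame(subject_id = character(), field = character(),
                      rule = character(), message = character())
  v <- list(empty)
  flag <- function(bad, field, rule, message)
    v[[length(v) + 1L]] <<- data.frame(
      subject_id = cohort$subject_id[which(bad)], field = field,
      rule = rule, message = message)
  for (col in cbc_analytes()) {
    x <- cohort[[col]]
    bad <- !is.na(x) & x <= 0
    if (any(bad)) flag(bad, col, "positive", paste0(col, " must be positive"))
  }
  for (col in c("hct", "rdw_cv")) {
    x <- cohort[[col]]
    bad <- !is.na(x) & x >= 100
    if (any(bad))
      flag(bad, col, "percent_range", paste0(col, " must lie in (0, 100)"))
  }
  identities <- list(
    mcv = list(members = c("hct", "rbc"),
               expected = function(d) 10 * d$hct / d$rbc),
    mch = list(members = c("hb", "rbc"),
               expected = function(d) d$hb / d$rbc),
    mchc = list(members = c("hb", "hct"),
                expected = function(d) 100 * d$hb / d$hct)
  )
  for (field in names(identities)) {
    id <- identities[[field]]
    members <- c(field, id$members)
    ok <- Reduce(`&`, lapply(cohort[members],
                             function(x) !is.na(x) & x > 0))
    if (!any(ok)) next
    exp_val <- id$expected(cohort)
    err <- rel_err(cohort[[field]], exp_val)
    bad <- ok & err > tolerance
    if (any(bad))
      v[[length(v) + 1L]] <- data.frame(
        subject_id = cohort$subject_id[which(bad)], field = field,
        rule = "consistency",
        message = sprintf(
          "%s = %.4g inconsistent with derived %.4g (rel err %.1f%% > %.0f%%)",
          field, cohort[[field]][bad], exp_val[bad], 100 * err[bad],
          100 * tolerance))
  }
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------
## Tabular I/O

#' Read a CBC cohort from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row and '.' as the
#' decimal separator. `column_map` renames file columns onto canonical
#' names (`c(file_column = "canonical_name")`); unmapped canonical names
#' are read directly when present. Missing cells become absent (`NA`)
#' fields. Units are normalized to the canonical regime (Hb g/L,
#' MCHC g/L, HCT percent) on the way in.
#'
#' @param path CSV file path.
#' @param column_map optional named character vector mapping file columns
#'   to canonical column names.
#' @param regime [unit_regime()] the file's numbers are expressed in.
#' @return canonical cohort data frame.
#' @export
read_cohort <- function(path, column_map = NULL, regime = unit_regime()) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(raw))
    if (length(unknown))
      stop_ts("column_map names absent from file: ",
              paste(unknown, collapse = ", "))
    names(raw)[match(names(column_map), names(raw))] <-
      unname(column_map)
  }
  num_cols <- intersect(cbc_analytes(), names(raw))
  for (col in num_cols) {
    s <- raw[[col]]
    s[s == ""] <- NA
    parsed <- suppressWarnings(as.numeric(s))
    bad <- which(!is.na(s) & is.na(parsed))
    if (length(bad))
      stop_ts(sprintf("unparseable numeric cell \"%s\" in column \"%s\" at data row %d of %s",
                      s[bad[1]], col, bad[1], path))
    raw[[col]] <- parsed
  }
  ## accept a "thal_gene" textual column (true/false/1/0/pos/neg)
  cohort <- as_cbc_cohort(raw)
  dup <- cohort$subject_id[duplicated(cohort$subject_id)]
  if (length(dup))
    stop_ts("duplicate subject_id: ", paste(unique(dup), collapse = ", "))
  convert_units(cohort, from = regime, to = unit_regime())
}

#' Write a CBC cohort to CSV in canonical units and column order
#'
#' Numeric values are written with full double precision so that
#' `read_cohort(write_cohort(x))` round-trips present fields to at least
#' 1e-9 relative accuracy.
#'
#' @param cohort canonical cohort data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cbc_cohort(cohort)[, cbc_columns()]
  for (col in cbc_analytes())
    cohort[[col]] <- ifelse(is.na(cohort[[col]]), "",
                            format(cohort[[col]], digits = 17,
                                   scientific = FALSE, trim = TRUE))
  write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
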