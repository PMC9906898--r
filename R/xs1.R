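## The XS-1 family: linear combinations of the natural logarithms of the
## three directly measured red-cell analytes (RBC, Hb, HCT). The published
## index's exact coefficients were never disclosed; this module implements
## the parameterized family and a fitting routine, and ships an
## illustrative default fit on the packaged synthetic cohort.

#' Parameters of a natural-log CBC index
#'
#' The score is `w_rbc*ln(RBC) + w_hb*ln(Hb) + w_hct*ln(HCT) + intercept`
#' with analytes in canonical units (Hb g/L, HCT percent), and the call
#' is TT when `score < cutoff`. The log transform reflects the
#' natural-growth-limit view of red-cell expansion: proportional (not
#' additive) changes in the red-cell compartment carry the diagnostic
#' signal, and a log-linear score is the canonical way to contrast them.
#'
#' @param weights named numeric vector with entries `rbc`, `hb`, `hct`.
#' @param intercept additive constant.
#' @param cutoff decision threshold (default 4; TT if score < cutoff).
#' @return object of class `log_index_params`.
#' @examples
#' log_index_params(c(rbc = 1, hb = 0, hct = 0), intercept = 0)
#' @export
log_index_params <- function(weights, intercept = 0, cutoff = 4) {
  stopifnot(is.numeric(weights), is.numeric(intercept), is.numeric(cutoff))
  weights <- weights[c("rbc", "hb", "hct")]
  if (anyNA(weights))
    stop_ts("weights must be named with entries rbc, hb, hct")
  structure(list(weights = weights, intercept = unname(intercept),
                 cutoff = unname(cutoff)),
            class = "log_index_params")
}

#' @export
print.log_index_params <- function(x, ...) {
  cat(sprintf(
    "<log_index_params> %.4f*ln(rbc) + %.4f*ln(hb) + %.4f*ln(hct) + %.4f;  TT if score < %.4f\n",
    x$weights["rbc"], x$weights["hb"], x$weights["hct"], x$intercept,
    x$cutoff))
  invisible(x)
}

#' Default XS-1 parameters
#'
#' An illustrative logistic fit on the packaged default synthetic cohort
#' (seed 20230208), with the intercept shifted so that the Youden-optimal
#' decision boundary of that fit sits exactly at the published cutoff 4.
#' These are NOT the original authors' coefficients, which were never
#' published; they instantiate the same ln(RBC)/ln(Hb)/ln(HCT) family on
#' reproducible data.
#'
#' @return `log_index_params`.
#' @export
xs1_default_params <- function() {
  log_index_params(weights = .xs1_default$weights,
                   intercept = .xs1_default$intercept,
                   cutoff = 4)
}

#' Score records with a natural-log index
#'
#' @param records canonical cohort data frame with positive `rbc`, `hb`,
#'   `hct`.
#' @param params [log_index_params()]; defaults to [xs1_default_params()].
#' @return numeric score vector.
#' @examples
#' xs1_score(cbc_record(rbc = exp(1), hb = 1, hct = 1),
#'           log_index_params(c(rbc = 1, hb = 0, hct = 0)))  # ln(e) = 1
#' @export
xs1_score <- function(records, params = xs1_default_params()) {
  stopifnot(inherits(params, "log_index_params"))
  records <- as_cbc_cohort(records)
  for (f in c("rbc", "hb", "hct")) {
    x <- records[[f]]
    if (anyNA(x)) stop_ts("xs1_score requires field: ", f)
    if (any(x <= 0)) stop_ts(f, " must be positive (log undefined)")
  }
  as.numeric(
    params$weights["rbc"] * log(records$rbc) +
    params$weights["hb"] * log(records$hb) +
    params$weights["hct"] * log(records$hct) +
    params$intercept)
}

#' Classify records with a natural-log index
#'
#' TT exactly when `score < cutoff` (strict, matching the published
#' `< 4` rule).
#'
#' @inheritParams xs1_score
#' @return data frame like [classify()]'s.
#' @export
xs1_classify <- function(records, params = xs1_default_params()) {
  records <- as_cbc_cohort(records)
  score <- xs1_score(records, params)
  data.frame(subject_id = records$subject_id, formula_id = "xs1",
             score = score, cutoff_used = params$cutoff, comparator = "<",
             call = ifelse(score < params$cutoff, "TT", "IDA"),
             cutoff_source = "custom", stringsAsFactors = FALSE)
}

empirical_auc_lower_tt <- function(score, is_tt) {
  ## AUC for "lower score favors TT" via the rank statistic, ties 1/2
  r <- rank(score, ties.method = "average")
  m <- sum(is_tt); n <- sum(!is_tt)
  ## P(score_TT < score_IDA) + 0.5 P(=)
  (sum(r[!is_tt]) - n * (n + 1) / 2) / (m * n)
}

#' Fit a natural-log discriminant index to a labeled cohort
#'
#' Fits weights for `ln(rbc)`, `ln(hb)`, `ln(hct)` on a labeled TT/IDA
#' cohort, then sets the cutoff by the Youden-optimal cutpoint of the
#' fitted scores (direction: lower score favors TT).
#'
#' Objectives:
#' \describe{
#'   \item{`"logistic"`}{maximum-likelihood logistic regression of the
#'     TT indicator on the three log-analytes; scores are the negated
#'     linear predictor, so TT lies on the low side.}
#'   \item{`"max_auc"`}{starts from the logistic solution and refines the
#'     weights by direct Nelder-Mead maximization of the empirical AUC
#'     (the single-parameter summary the index family was selected by).}
#' }
#'
#' @param cohort labeled canonical cohort containing both classes, with
#'   `rbc`, `hb`, `hct` present for every subject.
#' @param objective `"logistic"` (default) or `"max_auc"`.
#' @param seed integer seed; the fit is deterministic given the seed.
#' @return `log_index_params` with attributes `auc` (training AUC) and
#'   `youden` (training Youden at the chosen cutoff).
#' @export
fit_log_index <- function(cohort, objective = c("logistic", "max_auc"),
                          seed = 1L) {
  objective <- match.arg(objective)
  cohort <- as_cbc_cohort(cohort)
  if (anyNA(cohort$label))
    stop_ts("fit_log_index requires a fully labeled cohort")
  is_tt <- cohort$label == "TT"
  if (!any(is_tt) || !all(c(FALSE, TRUE) %in% is_tt))
    stop_ts("cohort must contain both TT and IDA subjects")
  for (f in c("rbc", "hb", "hct"))
    if (anyNA(cohort[[f]]) || any(cohort[[f]] <= 0))
      stop_ts("fit_log_index requires positive ", f, " for every subject")
  set.seed(as.integer(seed))
  X <- data.frame(lrbc = log(cohort$rbc), lhb = log(cohort$hb),
                  lhct = log(cohort$hct), y = as.integer(is_tt))
  fit <- suppressWarnings(glm(y ~ lrbc + lhb + lhct, data = X,
                              family = "binomial"))
  b <- coef(fit)
  ## logistic predicts TT on the HIGH side of the linear predictor; the
  ## family's convention is TT below the cutoff, so negate.
  w <- -b[c("lrbc", "lhb", "lhct")]
  intercept <- -b[["(Intercept)"]]
  if (objective == "max_auc") {
    f_obj <- function(wv) -empirical_auc_lower_tt(
      wv[1] * X$lrbc + wv[2] * X$lhb + wv[3] * X$lhct, is_tt)
    opt <- optim(unname(w), f_obj, method = "Nelder-Mead",
                 control = list(maxit = 500))
    if (opt$value <= f_obj(unname(w)))
      w <- setNames(opt$par, c("lrbc", "lhb", "lhct"))
  }
  score <- w[1] * X$lrbc + w[2] * X$lhb + w[3] * X$lhct + intercept
  oc <- youden_optimal_cutpoint(score, cohort$label, direction = "lower")
  params <- log_index_params(
    weights = setNames(as.numeric(w), c("rbc", "hb", "hct")),
    intercept = intercept, cutoff = oc$cutoff)
  attr(params, "auc") <- empirical_auc_lower_tt(score, is_tt)
  attr(params, "youden") <- oc$youden
  params
}
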