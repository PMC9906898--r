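## Seedable synthetic CBC cohort generator.
##
## Primary analytes (age, wbc, rbc, hb, hct, rdw_cv, rdw_sd, plt, mpv)
## are drawn per group from truncated normals calibrated to the
## reference study's group means/SDs; the derived red-cell indices
## (mcv, mch, mchc) are computed from the sampled (rbc, hb, hct) triplet
## through the analyzer identities with small multiplicative noise, so
## every record is internally coherent and passes validate_record().

TABLE1_DEFAULTS <- list(
  TT = list(age = c(28.0, 4.60), wbc = c(8.3, 2.20), rbc = c(4.8, 0.54),
            hb = c(110.0, 14.0), hct = c(34.0, 4.00),
            rdw_cv = c(15.0, 1.80), rdw_sd = c(39.0, 4.40),
            plt = c(240.0, 62.0), mpv = c(9.0, 1.00)),
  IDA = list(age = c(27.0, 4.50), wbc = c(7.8, 1.90), rbc = c(4.1, 0.36),
             hb = c(120.0, 12.0), hct = c(36.0, 3.10),
             rdw_cv = c(14.0, 1.90), rdw_sd = c(44.0, 4.70),
             plt = c(220.0, 52.0), mpv = c(9.0, 1.00))
)

#' Specification of a two-group synthetic CBC cohort
#'
#' Defaults reproduce the reference study's first-trimester cohort: 229
#' TT and 201 IDA subjects with the published per-group analyte means
#' and SDs (e.g. TT RBC 4.8 +/- 0.54 x10^12/L vs IDA 4.1 +/- 0.36; TT Hb
#' 110 +/- 14 g/L vs IDA 120 +/- 12). MPV (9 +/- 1 fL in both groups) is
#' not calibrated to any published table; it exists only so the one
#' MPV-dependent formula is exercisable. Sampling truncates each
#' truncated-normal draw at mean +/- `trunc_sd` SDs and at zero; the
#' derived indices get multiplicative noise with SD `derived_noise_sd`
#' (truncated at +/- 4 of its own SDs, which keeps every record inside
#' the 10% validation tolerance).
#'
#' @param n_tt,n_ida group sizes.
#' @param analytes nested list `group -> analyte -> c(mean, sd)`;
#'   defaults above. Partial overrides are merged over the defaults.
#' @param trunc_sd truncation half-width in SD units (default 4).
#' @param derived_noise_sd SD of the multiplicative noise on mcv/mch/mchc
#'   (default 0.02).
#' @param sf_range_tt,sf_range_ida serum-ferritin sampling intervals,
#'   ug/L; only the side of the 20 ug/L threshold matters downstream.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_tt = 229, n_ida = 201, analytes = NULL,
                        trunc_sd = 4, derived_noise_sd = 0.02,
                        sf_range_tt = c(20, 150), sf_range_ida = c(2, 20)) {
  full <- TABLE1_DEFAULTS
  if (!is.null(analytes))
    for (g in names(analytes))
      full[[g]] <- modifyList(full[[g]], analytes[[g]])
  for (g in names(full))
    for (a in names(full[[g]])) {
      v <- full[[g]][[a]]
      if (length(v) != 2 || v[2] <= 0)
        stop_ts("analyte spec ", g, "$", a, " must be c(mean, sd) with sd > 0")
    }
  stopifnot(n_tt >= 0, n_ida >= 0, trunc_sd > 0, derived_noise_sd >= 0,
            derived_noise_sd * 4 < 0.1)
  structure(list(n_tt = n_tt, n_ida = n_ida, analytes = full,
                 trunc_sd = trunc_sd, derived_noise_sd = derived_noise_sd,
                 sf_range_tt = sf_range_tt, sf_range_ida = sf_range_ida),
            class = "cohort_spec")
}

#' Read / write a cohort specification as YAML
#'
#' @param spec `cohort_spec`.
#' @param path YAML file.
#' @return `write_cohort_spec()`: `path` invisibly; `read_cohort_spec()`:
#'   a `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  analytes <- lapply(raw$analytes, function(g) lapply(g, as.numeric))
  cohort_spec(n_tt = raw$n_tt, n_ida = raw$n_ida, analytes = analytes,
              trunc_sd = raw$trunc_sd,
              derived_noise_sd = raw$derived_noise_sd,
              sf_range_tt = as.numeric(raw$sf_range_tt),
              sf_range_ida = as.numeric(raw$sf_range_ida))
}

## truncated normal via inverse-CDF: deterministic given the RNG stream
rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

sample_analyte <- function(n, ms, trunc_sd) {
  lower <- max(ms[1] - trunc_sd * ms[2], .Machine$double.eps)
  upper <- ms[1] + trunc_sd * ms[2]
  rtruncnorm(n, ms[1], ms[2], lower, upper)
}

generate_group <- function(n, group, spec) {
  an <- spec$analytes[[group]]
  prim <- lapply(an, sample_analyte, n = n, trunc_sd = spec$trunc_sd)
  noise <- function() 1 + rtruncnorm(n, 0, spec$derived_noise_sd,
                                     -4 * spec$derived_noise_sd,
                                     4 * spec$derived_noise_sd)
  mcv <- 10 * prim$hct / prim$rbc * noise()
  mch <- prim$hb / prim$rbc * noise()
  mchc <- 100 * prim$hb / prim$hct * noise()
  sf_range <- if (group == "TT") spec$sf_range_tt else spec$sf_range_ida
  data.frame(
    subject_id = NA_character_,
    age = prim$age, wbc = prim$wbc, rbc = prim$rbc, hb = prim$hb,
    hct = prim$hct, mcv = mcv, mch = mch, mchc = mchc,
    rdw_cv = prim$rdw_cv, rdw_sd = prim$rdw_sd, plt = prim$plt,
    mpv = prim$mpv,
    sf = runif(n, sf_range[1], sf_range[2]),
    thal_gene = group == "TT",
    twin_or_multiple = FALSE, stillbirth = FALSE,
    label = group, stringsAsFactors = FALSE
  )
}

#' Generate a labeled two-group synthetic CBC cohort
#'
#' Output is byte-identical for identical `(spec, seed)`. Serum ferritin
#' and genotype are set consistently with each record's group label, so
#' [assign_group()] recovers the labels exactly.
#'
#' @param spec [cohort_spec()].
#' @param seed integer seed.
#' @return canonical labeled cohort data frame with `n_tt + n_ida` rows
#'   (TT first).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_tt = 5, n_ida = 5), seed = 1)
#' table(cohort$label)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  out <- rbind(generate_group(spec$n_tt, "TT", spec),
               generate_group(spec$n_ida, "IDA", spec))
  out$subject_id <- sprintf("S%04d", seq_len(nrow(out)))
  as_cbc_cohort(out)
}

#' Generate the 546-record eligibility fixture
#'
#' Reconstructs the reference study's enrollment as synthetic data: 546
#' first-trimester records partitioned into strata sized to trigger each
#' cascade rule exactly once per record -- 32 out-of-range ages, 5
#' twin/multiple pregnancies, 1 stillbirth, 53 gene-positive records
#' with ferritin below 20 ug/L, 25 gene-negative records with ferritin
#' at or above 20 ug/L, and the 229 + 201 eligible TT/IDA core. Group
#' labels are left unknown: running [apply_eligibility()] then
#' [assign_group()] must recover 430 included records splitting
#' 229 TT / 201 IDA.
#'
#' @param seed integer seed.
#' @param spec [cohort_spec()] used for the CBC analytes of every
#'   stratum (excluded strata draw analytes from the matching genotype
#'   group).
#' @return canonical cohort data frame with 546 rows in shuffled order
#'   and a `stratum` attribute mapping subject ids to intended strata.
#' @export
generate_eligibility_fixture <- function(seed = 1L, spec = cohort_spec()) {
  set.seed(as.integer(seed))
  take <- function(group, n) {
    df <- generate_group(n, group, spec)
    df$label <- NA_character_
    ## every stratum except the age-outs must pass the age rule: redraw
    ## age from the group distribution truncated to the eligible window
    ms <- spec$analytes[[group]]$age
    df$age <- rtruncnorm(n, ms[1], ms[2],
                         max(20, ms[1] - spec$trunc_sd * ms[2]),
                         min(40, ms[1] + spec$trunc_sd * ms[2]))
    df
  }
  ## eligible core: 229 TT + 201 IDA
  core_tt <- take("TT", spec$n_tt);  core_tt$stratum <- "ELIGIBLE_TT"
  core_ida <- take("IDA", spec$n_ida); core_ida$stratum <- "ELIGIBLE_IDA"
  ## age-outs: otherwise eligible, evenly split young/old and TT/IDA-like
  age_out <- rbind(take("TT", 16), take("IDA", 16))
  age_out$age <- c(runif(16, 16, 19.5), runif(16, 40.5, 45))
  age_out$stratum <- "AGE"
  multi <- take("TT", 5); multi$twin_or_multiple <- TRUE
  multi$stratum <- "MULTIPLE_BIRTH"
  still <- take("IDA", 1); still$stillbirth <- TRUE
  still$stratum <- "STILLBIRTH"
  ## gene-positive but iron-deficient: TT-like analytes, SF below threshold
  gp_lowsf <- take("TT", 53); gp_lowsf$sf <- runif(53, 2, 19.5)
  gp_lowsf$stratum <- "GENE_POS_SF_LOW"
  ## gene-negative, iron-replete: IDA-like analytes, SF at/above threshold
  gn_highsf <- take("IDA", 25); gn_highsf$sf <- runif(25, 20, 150)
  gn_highsf$stratum <- "GENE_NEG_SF_HIGH"
  out <- rbind(core_tt, core_ida, age_out, multi, still, gp_lowsf, gn_highsf)
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  out$subject_id <- sprintf("F%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  stratum <- setNames(out$stratum, out$subject_id)
  out$stratum <- NULL
  structure(as_cbc_cohort(out), stratum = stratum)
}
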