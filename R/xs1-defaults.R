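## Frozen default XS-1 coefficients: logistic fit of the TT indicator on
## (ln rbc, ln hb, ln hct) over generate_cohort(cohort_spec(), seed =
## 20230208), negated so TT lies low, intercept shifted so the fit's
## Youden-optimal boundary sits exactly at the published cutoff 4.
## These are an illustrative instantiation of the log-index family, not
## the undisclosed original coefficients. Regenerate with
## tools/freeze_xs1_defaults.R after changing the generator or the
## default spec.
.xs1_default <- list(
  weights = c(rbc = -18.203110409, hb = 6.68596212634, hct = 6.01345302226),
  intercept = -21.4537217974
)

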