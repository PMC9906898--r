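---
title: "Screening thalassemia trait against iron deficiency anemia from the CBC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening thalassemia trait against iron deficiency anemia from the CBC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalscreen)
```

## The screening problem

Thalassemia trait (TT) and iron deficiency anemia (IDA) are the two
dominant causes of microcytic hypochromic anemia in pregnant women, and
they demand opposite management: iron supplementation treats IDA but
risks iron overload in TT, while an undetected trait carrier needs
genetic counseling. The definitive tests — thalassemia genotyping and
serum ferritin — are expensive and unavailable in many settings, so
since 1973 dozens of arithmetic *discriminant formulas* over routine
complete-blood-count (CBC) analytes have been proposed: each maps a
small set of red-cell parameters to a score, and a published cutoff
turns the score into a TT/IDA call. The biological signal they exploit
is that TT keeps the red-cell count high (RBC up, MCV and MCH down,
iron stores normal) whereas IDA depletes stores (ferritin low, RDW up,
RBC not elevated).

This package implements a catalog of 44 such formulas, the
diagnostic-performance machinery used to compare them on a labeled
cohort, the first-trimester eligibility cascade of the validation study
that motivated the toolkit, and a calibrated synthetic-cohort generator,
so the entire pipeline is reproducible with no patient data. TT is the
positive class throughout.

## Data model and units

A subject is one row of a canonical data frame (`cbc_record()`,
`as_cbc_cohort()`): RBC (10^12/L), Hb (g/L), HCT (%), the derived
indices MCV (fL), MCH (pg), MCHC (g/L), both RDW forms (CV %, SD fL),
WBC, PLT, MPV, serum ferritin (µg/L), age, genotype flag, pregnancy
flags and group label. Absent values are `NA`, never 0 — zero is a
valid-looking but impossible analyte value.

Validation (`validate_record()`) enforces strict positivity, percent
ranges, and the analyzer identities

$$\mathrm{MCV} = 10\,\mathrm{HCT}/\mathrm{RBC},\qquad
  \mathrm{MCH} = \mathrm{Hb}/\mathrm{RBC},\qquad
  \mathrm{MCHC} = 100\,\mathrm{Hb}/\mathrm{HCT}$$

within a relative tolerance, default 10%. A tolerance (not an equality)
is deliberate: analyzers round each reported value independently, and
published group means (e.g. MCHC 340 g/L against a derived 333 g/L)
already deviate by about 2%. Violations are returned as data, not
raised as conditions, so batch QC can proceed.

Two unit conventions circulate for hemoglobin and MCHC (g/L vs g/dL).
The canonical internal regime is the analyzer regime (g/L). Every
formula in the registry records the regime it was originally published
in, and evaluation has two modes:

* **`mode = "paper"`** (default) feeds canonical g/L values to every
  formula — this is the regime the reference validation study applied
  uniformly, and it reproduces that study's characteristic degenerate
  rows (e.g. Hb-sum formulas like Zaghloul's calling every subject TT,
  because an Hb of 110 g/L dwarfs a cutoff meant for 11 g/dL).
* **`mode = "as_published"`** converts Hb/MCHC to each formula's
  original units first, recovering the behavior the original authors
  intended.

Neither mode is silently mixed. The catalog itself is internally
inconsistent in this respect — some validation rows are only plausible
with g/dL inputs (MCHC-threshold formulas), others only with g/L (the
Hb-sum formulas) — which patient-level data would be needed to resolve;
both modes are therefore first-class.

## The formula registry

`inst/extdata/formulas.json` is the single source of truth: id, display
name, year, R arithmetic expression over canonical field names,
comparator, published TT cutoff, required fields, original unit regime
and provenance. `list_formulas()` returns all 44 in catalog order;
`evaluate_formula()`, `classify()` and `evaluate_panel()` operate on
records. Conventions worth noting:

* The TT-positive condition is `score comparator cutoff`, applied
  exactly as published: strict comparators stay strict (a Mentzer score
  of exactly 13 is called IDA); the single inclusive comparator in the
  catalog (Cruise, `>=`) keeps ties on the TT side.
* "RDW" always means RDW-CV (%); RDW-SD is carried in the data model
  but no original formula uses it.
* Implied multiplications in the source catalog ("5 Hb", "10 RBC") are
  read as products, "(RBC × Hb)2" as a square, and Alparslan's
  "10log(...)" as log base 10 (with MCHC in g/dL the group means give
  3.36 against the 3.34 cutoff, confirming the reading).
* Ricerca and Plengsuree are deliberately two registry entries with the
  same expression (RDW/RBC < 3.3): both names appear in the catalog and
  stay independently addressable.

## The XS-1 log-index family

The newest catalog entry scores a subject by a linear combination of
the natural logarithms of the three *measured* red-cell analytes,

$$s = w_1 \ln \mathrm{RBC} + w_2 \ln \mathrm{Hb} + w_3 \ln \mathrm{HCT} + b,
  \qquad \text{TT if } s < 4,$$

motivated by the view that red-cell expansion is bounded by natural
(base-e) growth, so *proportional* changes carry the signal and the
log scale linearizes them. Only the measured triplet enters because
MCV/MCH/MCHC are arithmetic derivatives of it.

The original publication discloses the family, the input analytes and
the cutoff (4) but **not** the fitted coefficients. This package
therefore implements the parameterized family (`log_index_params()`,
`xs1_score()`) plus a fitting routine (`fit_log_index()`): a logistic
regression on the log-analytes (negated so TT lies low), optionally
refined by direct Nelder–Mead maximization of the empirical AUC — the
criterion the family was originally selected by — with the cutoff set
by the Youden-optimal cutpoint of the fitted scores. The packaged
default coefficients (`xs1_default_params()`) are an *illustrative*
logistic fit on the default synthetic cohort (seed 20230208), with the
intercept shifted so that fit's optimal boundary sits exactly at the
published cutoff 4; they are clearly labeled as such and must not be
mistaken for the original authors' values. On its training cohort this
illustrative fit reaches AUC 0.92 and Youden 0.70 — close to the
published index's performance, as expected when the calibration means
drive most of the separation.

## Performance engine

`confusion_counts()` / `metrics_from_counts()` compute sensitivity
TP/(TP+FN), specificity TN/(FP+TN), accuracy (TP+TN)/n (all percent)
and the Youden index J = sens + spec − 1 (fraction). The three
proportions carry exact Clopper–Pearson 95% intervals (via
`stats::binom.test`), whose boundary behavior is exact: a zero
numerator gives a lower bound of exactly 0, a full one an upper bound
of exactly 1. No interval is attached to J itself (no exact interval
exists for a difference of two independent binomial proportions, and
the reference study prints none).

`roc_curve()` places thresholds at midpoints between consecutive
distinct observed scores plus infinite endpoints, so tied subjects
always move together — the pROC convention. The same grid drives
`youden_optimal_cutpoint()`; observed-value grids (the OptimalCutpoints
convention) differ only in the reported threshold, never in the
achievable (sens, spec) pairs, and one convention is used for both for
internal consistency. Cutpoint ties resolve to the highest sensitivity,
then the smallest threshold — in screening, sensitivity is the
operational priority. Each formula's ROC direction comes from its
comparator (`<`/`<=` means lower scores favor TT), never estimated from
data, so noisy small cohorts cannot flip a formula's orientation.

`auc()` integrates the curve by trapezoids, which on this grid equals
the Mann–Whitney concordance probability with ties counted one half;
the 95% CI uses DeLong's placement-value variance. Both identities are
enforced in the test suite against an O(n²) brute-force oracle and
cross-checked against pROC.

`evaluate_cohort()` assembles the per-formula report (AUC with CI,
optimal cutoff, confusion counts and metrics at either the published or
the optimal cutoff), ranks by Youden descending by default, and flags
formulas whose required fields are missing rather than failing.
Rounding (half-up, 2 dp for percent metrics and Youden, 3 dp for AUC)
is applied only at presentation (`write_report_csv()`); internal values
are never rounded.

## Eligibility cascade and grouping

`apply_eligibility()` reproduces the validation study's enrollment
filter, in order: age outside 20–40 (inclusive bounds — the study
excluded "< 20" and "> 40"), twin/multiple pregnancy, stillbirth,
gene-positive with ferritin < 20 µg/L (iron-deficient carriers,
excluded as mixed-picture), gene-negative with ferritin ≥ 20 µg/L
(neither condition). Each excluded record logs exactly the first
matching reason, so a 19-year-old twin pregnancy logs `AGE`. Records
missing a field needed by an applicable rule are excluded as
`MISSING_DATA` — the source study does not say how it handled such
records; silent retention would be worse than explicit exclusion.
Survivors split deterministically: `assign_group()` returns TT for
gene-positive/iron-replete, IDA for gene-negative/iron-deficient, and
treats any other combination as an internal error (the cascade should
have removed it). Ferritin exactly 20 µg/L with a positive genotype is
TT, per the stated ≥ rule.

## Synthetic cohorts

`generate_cohort()` draws the primary analytes (age, WBC, RBC, Hb, HCT,
RDW-CV, RDW-SD, PLT) per group from independent truncated normals whose
means/SDs default to the validation study's group table — TT: RBC
4.8 ± 0.54, Hb 110 ± 14, HCT 34 ± 4.0, RDW-CV 15 ± 1.8; IDA: RBC
4.1 ± 0.36, Hb 120 ± 12, HCT 36 ± 3.1, RDW-CV 14 ± 1.9; group sizes
229/201 — with truncation at mean ± 4 SD and at zero. The derived
triplet (MCV, MCH, MCHC) is then *computed* from the sampled
(RBC, Hb, HCT) through the analyzer identities with 2% multiplicative
truncated-normal noise (capped at ±4 of its own SDs, hence always
inside the 10% validation tolerance), so every record is internally
coherent. Ferritin is uniform on [20, 150] µg/L for TT and [2, 20) for
IDA — only the threshold side matters downstream — and genotype follows
the label. MPV (9 ± 1 fL, both groups) is generated solely so the one
MPV-dependent formula is exercisable; it is not calibrated to any
published value. Everything is deterministic given `(spec, seed)`, and
`cohort_spec()` round-trips through YAML.

What the generator does *not* emulate: the real within-subject
correlation structure. The study reports only marginal means/SDs, so
analytes are independent within group (apart from the derived triplet),
and the derived indices' SDs differ from the published ones (which
embed real correlations). Consequently the synthetic cohort recovers
each formula's *direction* and a realistic ordering of the strong
discriminators (Shine & Lal reaches AUC ≈ 0.9 on default settings),
but published AUCs and confusion counts are not reproducible from
marginals and are never asserted — they enter the package only as the
shipped reference table. Ages are truncated at ±4 SD like every other
analyte, so a default cohort can contain a few subjects outside the
20–40 eligibility window; `generate_eligibility_fixture()` — which must
hit the enrollment counts exactly — redraws ages within the window for
every stratum except the deliberate age-outs.

The 546-record fixture partitions into strata sized to trigger each
cascade rule exactly: 32 age-outs, 5 multiple births, 1 stillbirth, 53
iron-deficient carriers, 25 gene-negative/iron-replete, and the
229 + 201 eligible core; rows are shuffled and labels withheld so that
`apply_eligibility()` + `assign_group()` must rediscover the 430-subject
cohort and its 53.26% TT prevalence.

## Numerical and testing choices

Problem sizes were chosen so the full suite runs in seconds: oracle
comparisons use 100 random tied score sets of n ≤ 50 against an O(n²)
concordance oracle and an exhaustive-partition Youden oracle; every
registry expression is checked against an independent hand
transcription on 1,000 random records at 1e-12 relative tolerance;
generator calibration uses 5,000 subjects per group with a 4-standard-
error band on every primary-analyte mean. Determinism is part of every
contract: identical seeds give byte-identical cohorts, reports and CLI
output.

Known limitations: no partial AUC, no bootstrap or paired DeLong
comparisons, no imputation of missing analytes, no modeling of combined
TT+IDA presentations or gestational-age trajectories, and no
reticulocyte-based indices (excluded from the source catalog). The
default XS-1 coefficients are a reproducible stand-in, not the
published tool's internals; anyone applying these formulas clinically
should recalibrate cutoffs on a local population — the motivating study
itself found most published cutoffs degenerate outside their original
populations.
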