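# Independent oracles. These deliberately avoid the package's own code
# paths: brute-force pairwise concordance for the AUC, an exhaustive
# partition sweep for the best Youden index, and a second, hand-typed
# transcription of every discriminant formula.

# O(n^2) Mann-Whitney concordance; ties count one half.
oracle_auc <- function(scores, labels, direction = "lower") {
  tt <- scores[labels == "TT"]
  ida <- scores[labels == "IDA"]
  total <- 0
  for (x in tt) for (y in ida) {
    hit <- if (direction == "lower") x < y else x > y
    total <- total + hit + 0.5 * (x == y)
  }
  total / (length(tt) * length(ida))
}

# Best achievable Youden index over every possible score partition.
# For direction "lower" the TT side of any threshold is {score <= u} for
# some observed value u, or the empty set; enumerate them all.
oracle_best_youden <- function(scores, labels, direction = "lower") {
  is_tt <- labels == "TT"
  m <- sum(is_tt); n <- sum(!is_tt)
  u <- sort(unique(scores))
  best <- -Inf
  for (k in 0:length(u)) {
    called <- if (k == 0) rep(FALSE, length(scores))
              else if (direction == "lower") scores <= u[k]
              else scores >= u[length(u) + 1 - k]
    j <- sum(called & is_tt) / m - sum(called & !is_tt) / n
    best <- max(best, j)
  }
  best
}

# Second transcription of the formula catalog (canonical-unit regime).
oracle_formulas <- list(
  england_fraser = function(d) d$mcv - d$rbc - 5 * d$hb - 3.4,
  rbc_count = function(d) d$rbc,
  mentzer = function(d) d$mcv / d$rbc,
  srivastava = function(d) d$mch / d$rbc,
  shine_lal = function(d) d$mcv * d$mcv * d$mch / 100,
  bessman = function(d) d$rdw_cv,
  ricerca = function(d) d$rdw_cv / d$rbc,
  green_king = function(d) d$mcv * d$mcv * d$rdw_cv / (100 * d$hb),
  das_gupta = function(d) 1.89 * d$rbc - 0.33 * d$rdw_cv - 3.28,
  rdw_index = function(d) d$mcv * d$rdw_cv / d$rbc,
  ti_mchd = function(d) d$mch / d$mcv,
  ti_mdhl = function(d) d$mch * d$rbc / d$mcv,
  huber_herklotz = function(d) d$mch * d$rdw_cv * 0.1 / d$rbc + d$rdw_cv,
  sirdah = function(d) d$mcv - d$rbc - 3 * d$hb,
  kerman_1 = function(d) d$mcv * d$mch / d$rbc,
  kerman_2 = function(d) d$mcv * d$mch * 10 / (d$rbc * d$mchc),
  ehsani = function(d) d$mcv - 10 * d$rbc,
  keikhaei = function(d) d$hb * d$rdw_cv * 100 / (d$rbc * d$rbc * d$mchc),
  nishad = function(d) 0.615 * d$mcv + 0.518 * d$mch + 0.446 * d$rdw_cv,
  wongprachum = function(d) d$mcv * d$rdw_cv / d$rbc - 10 * d$hb,
  sehgal = function(d) d$mcv * d$mcv / d$rbc,
  sargolzaie = function(d) 125.643 + 44.304 * d$rbc - 20.932 * d$hb -
    2.501 * d$mcv + 20.302 * d$mch - 12.183 * d$mchc,
  pornprasert = function(d) d$mchc,
  sirachainan = function(d) 1.5 * d$hb - 0.05 * d$mcv,
  plengsuree = function(d) d$rdw_cv / d$rbc,
  bordbar = function(d) abs(80 - d$mcv) * abs(27 - d$mch),
  hisham = function(d) d$mch * d$rdw_cv / d$rbc,
  hameed = function(d) d$mch * d$hct * d$rdw_cv / (d$rbc * d$hb)^2,
  chandra = function(d) d$rbc * d$mchc * d$mpv / (d$rdw_cv * d$plt),
  matos_carvalho = function(d) 1.91 * d$rbc + 0.44 * d$mchc,
  ravanbakhsh_f1 = function(d) d$mcv / d$hct,
  ravanbakhsh_f2 = function(d) d$rdw_cv - 3 * d$rbc,
  ravanbakhsh_f3 = function(d) d$mcv * d$rdw_cv - 100 * d$rbc,
  ravanbakhsh_f4 = function(d) d$mcv * d$hb / (d$rdw_cv * d$rbc),
  zaghloul_1 = function(d) d$hb + d$hct + d$rbc,
  zaghloul_2 = function(d) d$hb + d$hct + d$rbc - d$rdw_cv,
  kandhro_1 = function(d) d$rbc / d$hct + 0.5 * d$rdw_cv,
  kandhro_2 = function(d) d$rdw_cv * 5 / d$rbc,
  merdin_1 = function(d) d$rdw_cv * d$rbc / d$mcv,
  merdin_2 = function(d) d$rdw_cv * d$rbc * d$hb / d$mcv,
  alparslan = function(d) log(d$mch * d$mchc * d$rdw_cv / d$rbc, base = 10),
  roth_svm = function(d) 1.45 * (d$mcv - 82.8) / 10.28 +
    0.66 * (d$mch - 27.0) / 3.9 + 0.98,
  cruise = function(d) d$mchc + 0.603 * d$rbc + 0.523 * d$rdw_cv
)

# Random physiologically plausible records, independent of the package's
# generator: uniform draws over wide analyte ranges.
random_records <- function(n, seed) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("R%04d", seq_len(n)),
    age = runif(n, 18, 45), wbc = runif(n, 3, 15),
    rbc = runif(n, 2.5, 6.5), hb = runif(n, 60, 160),
    hct = runif(n, 20, 50), mcv = runif(n, 55, 100),
    mch = runif(n, 15, 35), mchc = runif(n, 280, 380),
    rdw_cv = runif(n, 11, 25), rdw_sd = runif(n, 30, 60),
    plt = runif(n, 100, 450), mpv = runif(n, 7, 12),
    sf = runif(n, 2, 150), stringsAsFactors = FALSE
  )
}

# Random labeled score sets for ROC oracle comparisons.
random_roc_instance <- function(seed, n_max = 50) {
  set.seed(seed)
  m <- sample(2:(n_max / 2), 1)
  n <- sample(2:(n_max / 2), 1)
  # coarse rounding forces plenty of ties
  scores <- round(c(rnorm(m, 1), rnorm(n, 0)), sample(0:1, 1))
  list(scores = scores, labels = rep(c("TT", "IDA"), c(m, n)),
       direction = sample(c("lower", "higher"), 1))
}

table1_tt_record <- function() {
  cbc_record(subject_id = "tt_mean", age = 28, wbc = 8.3, rbc = 4.8,
             hb = 110, hct = 34, mcv = 72, mch = 23, mchc = 320,
             rdw_cv = 15, rdw_sd = 39, plt = 240)
}

table1_ida_record <- function() {
  cbc_record(subject_id = "ida_mean", age = 27, wbc = 7.8, rbc = 4.1,
             hb = 120, hct = 36, mcv = 87, mch = 29, mchc = 340,
             rdw_cv = 14, rdw_sd = 44, plt = 220)
}
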