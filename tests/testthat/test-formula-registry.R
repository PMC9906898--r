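test_that("registry holds the 44 cataloged formulas in table order", {
  specs <- list_formulas()
  expect_length(specs, 44L)
  expect_false(anyDuplicated(names(specs)) > 0)
  expect_identical(vapply(specs, `[[`, integer(1), "row"),
                   setNames(1:44, names(specs)))
  for (spec in specs)
    expect_setequal(spec$required_fields,
                    all.vars(str2lang(spec$expression)))
  expect_error(get_formula("nope"), "unknown formula id")
})

test_that("registry entries carry the published expressions and cutoffs", {
  m <- get_formula("mentzer")
  expect_identical(m$expression, "mcv / rbc")
  expect_identical(m$comparator, "<")
  expect_identical(m$cutoff, 13)
  expect_identical(get_formula("shine_lal")$cutoff, 1530)
  expect_identical(get_formula("cruise")$comparator, ">=")
  # the one inclusive comparator in the catalog is Cruise's
  incl <- Filter(function(s) s$comparator %in% c(">=", "<="),
                 list_formulas())
  expect_identical(names(incl), "cruise")
})

test_that("formula scores match hand arithmetic on the TT group means", {
  r <- cbc_record(mcv = 72, rbc = 4.8, mch = 23)
  expect_equal(evaluate_formula("mentzer", r), 15.0)
  expect_equal(evaluate_formula("shine_lal", r), 1192.32)
  expect_equal(evaluate_formula("srivastava", r), 23 / 4.8)
})

test_that("missing required fields raise named errors outside panels", {
  r <- table1_tt_record() # no mpv
  expect_error(evaluate_formula("chandra", r), "chandra.*mpv")
})

test_that("as-published mode rescales hemoglobin and MCHC per formula", {
  r <- table1_tt_record()
  # England-Fraser was published for Hb in g/dL: 72 - 4.8 - 5*11 - 3.4
  expect_equal(evaluate_formula("england_fraser", r, mode = "as_published"),
               72 - 4.8 - 5 * 11 - 3.4)
  # paper mode feeds g/L straight in
  expect_equal(evaluate_formula("england_fraser", r, mode = "paper"),
               72 - 4.8 - 5 * 110 - 3.4)
  # log10(23 * 32 * 15 / 4.8) ~ 3.36, consistent with the 3.34 cutoff
  expect_equal(evaluate_formula("alparslan", r, mode = "as_published"),
               log10(23 * 32 * 15 / 4.8))
  # unit-free formulas are identical in both modes
  expect_identical(evaluate_formula("mentzer", r, mode = "as_published"),
                   evaluate_formula("mentzer", r, mode = "paper"))
})

test_that("classification follows the comparator strictly as written", {
  r <- cbc_record(mcv = 72, rbc = 4.8, mch = 23)
  expect_identical(classify("shine_lal", r)$call, "TT")   # 1192.32 < 1530
  expect_identical(classify("mentzer", r)$call, "IDA")    # 15 not < 13
  # a score exactly at a strict cutoff goes to IDA...
  expect_identical(classify("mentzer", r, cutoff = 15.0)$call, "IDA")
  # ...but an inclusive comparator keeps the tie on the TT side
  cr <- cbc_record(mchc = 320, rbc = 4.8, rdw_cv = 15)
  s <- evaluate_formula("cruise", cr)
  expect_identical(classify("cruise", cr, cutoff = s)$call, "TT")
})

test_that("raising the cutoff of a lower-direction formula never flips TT to IDA", {
  recs <- random_records(50, seed = 7)
  s <- evaluate_formula("mentzer", recs)
  cuts <- sort(c(10, 13, quantile(s, c(0.25, 0.5, 0.75)), 40))
  prev <- NULL
  for (cut in cuts) {
    calls <- classify("mentzer", recs, cutoff = cut)$call
    if (!is.null(prev)) expect_false(any(prev == "TT" & calls == "IDA"))
    prev <- calls
  }
})

test_that("Ricerca and Plengsuree are distinct entries with identical behavior", {
  expect_false(identical(get_formula("ricerca")$name,
                         get_formula("plengsuree")$name))
  recs <- random_records(200, seed = 11)
  expect_identical(evaluate_formula("ricerca", recs),
                   evaluate_formula("plengsuree", recs))
  expect_identical(classify("ricerca", recs)$call,
                   classify("plengsuree", recs)$call)
})

test_that("every formula agrees with an independent transcription", {
  recs <- random_records(1000, seed = 123)
  for (id in names(oracle_formulas)) {
    got <- evaluate_formula(id, recs)
    want <- oracle_formulas[[id]](recs)
    expect_true(all(abs(got - want) <= 1e-12 * pmax(abs(want), 1)),
                label = id)
  }
})

test_that("the panel runs every evaluable formula and skips the rest", {
  full <- cbc_record(rbc = 4.8, hb = 110, hct = 34, mcv = 72, mch = 23,
                     mchc = 320, rdw_cv = 15, rdw_sd = 39, wbc = 8.3,
                     plt = 240, mpv = 9)
  panel <- evaluate_panel(full)
  expect_identical(nrow(panel), 44L)
  expect_false(any(panel$skipped))

  no_mpv <- cbc_record(rbc = 4.8, hb = 110, hct = 34, mcv = 72, mch = 23,
                       mchc = 320, rdw_cv = 15, plt = 240)
  panel2 <- evaluate_panel(no_mpv)
  expect_identical(sum(panel2$skipped), 1L)
  expect_identical(panel2$formula_id[panel2$skipped], "chandra")
  expect_match(panel2$skip_reason[panel2$skipped], "mpv")

  expect_identical(nrow(evaluate_panel(full, formula_ids = character(0))), 0L)
})

test_that("the minimal web-tool inputs unlock the three-analyte formulas", {
  r <- cbc_record(rbc = 4.8, hb = 110, hct = 34)
  panel <- evaluate_panel(r)
  run <- panel$formula_id[!panel$skipped]
  expect_true(all(c("xs1", "zaghloul_1", "rbc_count") %in% run))
  expect_false("mentzer" %in% run)
})
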