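# expected side of every comparator rule at threshold and threshold +/- eps,
# written directly from the published comparators
boundary_cases <- tibble::tribble(
  ~item_id,              ~at_threshold, ~below, ~above,
  "lci",                 0L, 0L, 1L,  # fail iff <= 21
  "tug_ab",              1L, 1L, 0L,  # fail iff > 14
  "tug_c",               1L, 1L, 0L,  # fail iff > 34
  "amp",                 1L, 0L, 1L,  # fail iff < 25
  "bbt",                 1L, 0L, 1L,  # fail iff < 45
  "lifeh_daily",         1L, 0L, 1L,  # fail iff mean < 7
  "lifeh_social",        1L, 0L, 1L,
  "isel",                1L, 0L, 1L,  # fail iff < 1
  "mos",                 1L, 0L, 1L,  # fail iff < 75
  "wcq_distancing",      1L, 1L, 0L,  # fail iff mean > 1.5
  "wcq_support_seeking", 1L, 0L, 1L,  # fail iff mean < 1.5
  "wcq_reappraisal",     1L, 0L, 1L,
  "bpi_q5",              1L, 1L, 0L,  # fail iff > 5
  "bpi_q9a",             1L, 1L, 0L,  # fail iff > 7
  "bmi",                 1L, 1L, 0L,  # fail iff > 30
  "gds",                 0L, 1L, 0L,  # fail iff >= 11
  "charlson",            0L, 1L, 0L   # fail iff >= 2
)

test_that("every comparator rule classifies its threshold per the printed direction", {
  reg <- default_registry()
  for (i in seq_len(nrow(boundary_cases))) {
    case <- boundary_cases[i, ]
    spec <- reg[reg$item_id == case$item_id, ]
    arch <- switch(spec$applicability, wheelchair = "wheelchair_user",
                   "prosthesis_walker")
    eps <- if (spec$integer_scale) 1 else 0.01
    for (delta in c(0, -eps, eps)) {
      value <- spec$threshold + delta
      out <- dich1(case$item_id, value, archetype = arch)
      expected <- if (delta == 0) case$at_threshold
                  else if (delta < 0) case$below else case$above
      expect_equal(out$outcome, expected,
                   info = sprintf("%s at %g", case$item_id, value))
    }
  }
})

test_that("published worked examples dichotomize correctly", {
  expect_equal(dich1("tug_ab", 15)$outcome, 0L)   # > 14 s fails
  expect_equal(dich1("tug_ab", 14)$outcome, 1L)   # boundary passes
  expect_equal(dich1("tug_c", 34, archetype = "wheelchair_user")$outcome, 1L)
  expect_equal(dich1("tug_c", 34.1, archetype = "wheelchair_user")$outcome, 0L)
  expect_equal(dich1("lci", 21)$outcome, 0L)      # <= 21/42 fails
  expect_equal(dich1("amp", 25)$outcome, 1L)      # under 25/47 fails, 25 passes
  # any monofilament site not felt fails
  expect_equal(dich1("monofilament", sites = c(1, 1, 0, 1))$outcome, 0L)
  expect_equal(dich1("monofilament", sites = c(1, 1, 1, 1))$outcome, 1L)
  # BPI: two items with distinct cuts
  p <- one_participant()
  m <- dplyr::bind_rows(new_measurement("p1", "bpi_q5", 6),
                        new_measurement("p1", "bpi_q9a", 3))
  out <- dichotomize(m, participants = p)
  expect_equal(out$outcome[out$item_id == "bpi_q5"], 0L)
  expect_equal(out$outcome[out$item_id == "bpi_q9a"], 1L)
})

test_that("norm-referenced rules fail strictly below (LSA/HAP) or at/below (grip) the cut", {
  # age 70: lsa cut 56, hap cut 60, grip (M) cut 27 in the built-in tables
  expect_equal(dich1("lsa", 56)$outcome, 1L)
  expect_equal(dich1("lsa", 55)$outcome, 0L)
  expect_equal(dich1("hap", 60)$outcome, 1L)
  expect_equal(dich1("hap", 59)$outcome, 0L)
  expect_equal(dich1("grip", 27)$outcome, 0L)      # 30th percentile or less
  expect_equal(dich1("grip", 27.5)$outcome, 1L)
  expect_equal(dich1("grip", 16, sex = "F")$outcome, 0L)
  expect_equal(dich1("grip", 16.5, sex = "F")$outcome, 1L)
})

test_that("missing codes propagate and archetype gating yields not_applicable", {
  out <- dich1("gds", missing_code = "not_evaluated")
  expect_true(is.na(out$outcome))
  expect_equal(out$missing_reason, "not_evaluated")

  # wheelchair TUG is not applicable to a prosthesis walker even if a value slips in
  out <- dich1("tug_c", 20, archetype = "prosthesis_walker")
  expect_true(is.na(out$outcome))
  expect_equal(out$missing_reason, "not_applicable")
  out <- dich1("tug_ab", 10, archetype = "wheelchair_user")
  expect_equal(out$missing_reason, "not_applicable")
})

test_that("dichotomization is deterministic and validates its input", {
  m <- dplyr::bind_rows(new_measurement("p1", "gds", 12),
                        new_measurement("p1", "bmi", 31.2))
  p <- one_participant()
  expect_identical(dichotomize(m, participants = p),
                   dichotomize(m, participants = p))
  expect_error(dich1("gds", 35), class = "mobscore_validation_error")   # > scale max
  expect_error(dich1("gds", -1), class = "mobscore_validation_error")
  expect_error(
    dichotomize(tibble::tibble(participant_id = "p1", item_id = "xyz",
                               value = 1, site_1 = NA_real_, site_2 = NA_real_,
                               site_3 = NA_real_, site_4 = NA_real_,
                               missing_code = "none"),
                participants = one_participant()),
    class = "mobscore_validation_error")
})

test_that("at most one member of an alternates group contributes", {
  p <- one_participant()
  m <- dplyr::bind_rows(new_measurement("p1", "isel", 0.5),
                        new_measurement("p1", "mos", 80))
  expect_warning(out <- dichotomize(m, participants = p), "alternates")
  expect_equal(sum(!is.na(out$outcome)), 1)
  expect_equal(out$outcome[out$item_id == "isel"], 0L)  # first member kept
})

test_that("fatigue VAS gates a longer pause strictly above 2.5 inches", {
  expect_equal(fatigue_check(2.5), "continue")
  expect_equal(fatigue_check(2.6), "longer_pause")
  expect_equal(fatigue_check(0), "continue")
  expect_error(fatigue_check(5.1), class = "mobscore_validation_error")
  expect_error(fatigue_check(-0.1), class = "mobscore_validation_error")
})
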