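test_that("generation is reproducible: same seed, identical cohort", {
  cfg <- cohort_config(n_participants = 25)
  a <- generate_cohort(cfg, seed = 11)
  b <- generate_cohort(cfg, seed = 11)
  expect_identical(a$participants, b$participants)
  expect_identical(a$measurements, b$measurements)
  c <- generate_cohort(cfg, seed = 12)
  expect_false(identical(a$measurements$value, c$measurements$value))
  expect_error(generate_cohort(cfg), class = "mobscore_config_error")  # no seed
})

test_that("archetype gating is never violated and instrument sets match archetypes", {
  co <- generate_cohort(cohort_config(n_participants = 300), seed = 5)
  m <- dplyr::left_join(co$measurements, co$participants, by = "participant_id")
  assessed <- m[m$missing_code == "none", ]
  # no participant has both TUG variants assessed
  both <- tidyr::pivot_wider(
    dplyr::count(assessed[assessed$item_id %in% c("tug_ab", "tug_c"), ],
                 .data$participant_id, .data$item_id),
    names_from = "item_id", values_from = "n", values_fill = 0L)
  if (all(c("tug_ab", "tug_c") %in% names(both))) {
    expect_true(all(both$tug_ab == 0 | both$tug_c == 0))
  }
  # the inapplicable variant is coded not_applicable
  wheel <- m[m$archetype == "wheelchair_user" & m$item_id == "tug_ab", ]
  expect_true(all(wheel$missing_code == "not_applicable"))
  walk <- m[m$archetype != "wheelchair_user" & m$item_id == "tug_c", ]
  expect_true(all(walk$missing_code == "not_applicable"))
  # walkers carry LCI and an ambulatory TUG measurement
  pros <- m[m$archetype == "prosthesis_walker", ]
  expect_true(all(c("lci", "tug_ab") %in% pros$item_id))
  # generated values respect native scale bounds
  reg <- default_registry()
  chk <- dplyr::left_join(assessed, as.data.frame(reg)[, c("item_id", "scale_min", "scale_max", "value_type")],
                          by = "item_id")
  num <- chk[chk$value_type == "numeric", ]
  expect_true(all(num$value >= num$scale_min & num$value <= num$scale_max))
})

test_that("configured modulator prevalences are recovered at n = 10^4", {
  n <- 10000
  targets <- c(bmi = 0.3, gds = 0.45, grip = 0.4, monofilament = 0.25,
               sdq_lives_alone_or_care = 0.4, wcq_distancing = 0.55,
               charlson = 0.6, mos = 0.35)
  cfg <- cohort_config(n_participants = n, modulator_prevalence = targets,
                       missing_rates = c(not_evaluated = 0, not_collected = 0),
                       alternates_choice = "second")  # administer MOS, AMP
  co <- generate_cohort(cfg, seed = 42)
  keep <- co$measurements$item_id %in% names(targets)
  out <- dichotomize(co$measurements[keep, ], participants = co$participants)
  for (item in names(targets)) {
    p <- targets[[item]]
    rate <- mean(out$outcome[out$item_id == item] == 0, na.rm = TRUE)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(rate - p), 3 * se,
              label = sprintf("|%.4f - %.2f| for %s", rate, p, item))
  }
})

test_that("zero prevalence for every modulator forces a high modulator category", {
  prev <- default_modulator_prevalence()
  prev[] <- 0
  cfg <- cohort_config(n_participants = 40, modulator_prevalence = prev,
                       age_range = c(51, 60),  # age-over-60 flag stays FALSE
                       missing_rates = c(not_evaluated = 0, not_collected = 0))
  co <- generate_cohort(cfg, seed = 3)
  sc <- score_cohort(co)
  expect_true(all(sc$profiles$modulator_category == "high"))
  expect_equal(unique(sc$profiles$modulator_weighted), 4)
})

test_that("monofilament failures always have at least one unfelt site", {
  cfg <- cohort_config(n_participants = 200,
                       modulator_prevalence = c(monofilament = 0.5),
                       missing_rates = c(not_evaluated = 0, not_collected = 0))
  co <- generate_cohort(cfg, seed = 9)
  mono <- co$measurements[co$measurements$item_id == "monofilament" &
                            co$measurements$missing_code == "none", ]
  sites <- as.matrix(mono[, paste0("site_", 1:4)])
  expect_true(all(sites %in% c(0, 1)))
  out <- dichotomize(mono, participants = co$participants)
  expect_equal(out$outcome == 0L, rowSums(sites == 0) > 0)
})

test_that("sample_participant forces the archetype; config validation rejects nonsense", {
  co <- sample_participant("wheelchair_user", seed = 4)
  expect_equal(co$participants$archetype, "wheelchair_user")
  m <- co$measurements
  expect_equal(m$missing_code[m$item_id == "tug_ab"], "not_applicable")
  expect_true(m$missing_code[m$item_id == "tug_c"] %in%
                c("none", "not_evaluated", "not_collected"))

  expect_error(cohort_config(n_participants = 0), class = "mobscore_config_error")
  expect_error(cohort_config(archetype_weights = c(prosthesis_walker = 1)),
               class = "mobscore_config_error")
  expect_error(cohort_config(modulator_prevalence = c(nope = 0.5)),
               class = "mobscore_config_error")
  expect_error(cohort_config(modulator_prevalence = c(bmi = 1.5)),
               class = "mobscore_config_error")
  expect_error(cohort_config(score_distributions = list(bmi = list(sd = -1))),
               class = "mobscore_config_error")
  expect_error(sample_participant("jetpack_user"), class = "mobscore_config_error")
})

test_that("the pilot fixture is seed-free, exact, and reproduces the printed aggregates", {
  fx1 <- pilot_fixture()
  fx2 <- pilot_fixture()
  expect_identical(fx1, fx2)
  expect_equal(length(unique(fx1$participant_id)), 10)
  s <- summarize_cohort(build_profiles(fx1))
  expect_equal(s$n_profiled, 10)
  gs <- tibble::deframe(s$group_sizes)
  expect_equal(gs, c(A = 1L, B = 2L, C = 6L, D = 1L))
})
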