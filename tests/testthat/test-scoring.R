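test_that("outcome counting ignores missing items", {
  expect_equal(count_outcomes(c(1, 0, NA, 1)),
               c(n_success = 2L, n_assessed = 3L))
  expect_equal(count_outcomes(c(NA_integer_, NA_integer_)),
               c(n_success = 0L, n_assessed = 0L))
  expect_equal(count_outcomes(rep(1L, 4)), c(n_success = 4L, n_assessed = 4L))
  expect_equal(count_outcomes(integer(0)), c(n_success = 0L, n_assessed = 0L))
})

test_that("weighted score equals 4k/n exactly for every k <= n <= 24", {
  for (n in 1:24) {
    k <- 0:n
    w <- weighted_score(k, rep(n, n + 1))
    # rational-arithmetic oracle: w*n must recover the integer 4k exactly
    # after removing the single least-significant-bit rounding of the product
    expect_identical(round(w * n), 4 * k)
    expect_true(all(abs(w * n - 4 * k) <= 2^-40))
    expect_true(all(w >= 0 & w <= 4))
    # monotone increasing in successes at fixed denominator
    expect_true(all(diff(w) > 0))
    # the float category agrees with the exact integer-arithmetic rule:
    # low iff 4k < n, high iff 4k >= 3n
    cat_float <- as.character(categorize(w))
    cat_int <- ifelse(4 * k < n, "low", ifelse(4 * k >= 3 * n, "high", "moderate"))
    expect_equal(cat_float, cat_int)
  }
  # strictly decreasing in n at fixed k > 0
  expect_true(all(diff(sapply(3:24, function(n) weighted_score(2, n))) < 0))
  expect_error(weighted_score(1, 0), class = "mobscore_unscorable_error")
  expect_error(weighted_score(5, 4), class = "mobscore_validation_error")
})

test_that("display rounding is half-up to two decimals on the exact rational", {
  expect_equal(format_weighted(1, 3), "1.33")
  expect_equal(format_weighted(7, 16), "1.75")
  expect_equal(format_weighted(4, 4), "4.00")
  expect_equal(format_weighted(0, 5), "0.00")
  expect_equal(format_weighted(19, 24), "3.17")  # 3.1666... rounds up
  expect_equal(format_weighted(17, 24), "2.83")
  expect_equal(format_weighted(2, 3), "2.67")    # 2.666... half-up
  # string oracle via long division for the whole n <= 24 enumeration
  long_division_2dp <- function(k, n) {
    num <- 400 * k
    q <- num %/% n
    if (2 * (num %% n) >= n) q <- q + 1
    paste0(q %/% 100, ".", sprintf("%02d", q %% 100))
  }
  for (n in 1:24) {
    for (k in 0:n) {
      expect_equal(format_weighted(k, n), long_division_2dp(k, n))
    }
  }
})

test_that("category cut-points partition [0, 4] with half-open boundaries", {
  eps <- 1e-9
  expect_equal(
    as.character(categorize(c(0, 1 - eps, 1, 3 - eps, 3, 4))),
    c("low", "low", "moderate", "moderate", "high", "high")
  )
  expect_equal(as.character(categorize(2.66)), "moderate")
  expect_equal(as.character(categorize(3.17)), "high")
  # every weighted value maps to exactly one category
  grid <- seq(0, 4, by = 0.001)
  expect_false(anyNA(categorize(grid)))
  expect_error(categorize(4.01), class = "mobscore_validation_error")
  expect_error(categorize(-0.1), class = "mobscore_validation_error")
})

test_that("score_dimension composes counting, weighting and categorization", {
  # LCI success, ambulatory TUG fail, wheelchair TUG not applicable, AMP fail
  d <- score_dimension(c(1, 0, NA, 0), "potential")
  expect_equal(d$n_success, 1L)
  expect_equal(d$n_assessed, 3L)
  expect_equal(d$display, "1.33")
  expect_equal(as.character(d$category), "moderate")
  expect_equal(as.character(score_dimension(rep(1, 4))$category), "high")
  expect_equal(score_dimension(rep(0, 4))$display, "0.00")
})

test_that("group assignment is effective-first and total over all 27 triplets", {
  expect_equal(as.character(assign_group("high", "high", "high")), "A")
  expect_equal(as.character(assign_group("high", "low", "moderate")), "B")
  expect_equal(as.character(assign_group("moderate", "low", "moderate")), "C")
  expect_equal(as.character(assign_group("low", "low", "moderate")), "D")
  expect_equal(as.character(assign_group("low", "high", "high")), "D")

  cats <- c("low", "moderate", "high")
  grid <- expand.grid(effective = cats, potential = cats, modulator = cats,
                      stringsAsFactors = FALSE)
  g <- assign_group(grid$effective, grid$potential, grid$modulator)
  expect_false(anyNA(g))
  is_b <- grid$effective == "high" &
    !(grid$potential == "high" & grid$modulator == "high")
  expect_equal(as.character(g) == "B", is_b)
  expect_equal(sum(g == "A"), 1)
  expect_equal(sum(g == "C"), 9)
  expect_equal(sum(g == "D"), 9)
  expect_error(assign_group("high", "high", "excellent"),
               class = "mobscore_validation_error")
})

test_that("profiles exclude participants with an unscorable dimension", {
  oc <- dplyr::bind_rows(
    outcomes_tbl("a", "modulator", c(1, 1)),
    outcomes_tbl("a", "potential", c(1, 0)),
    outcomes_tbl("a", "effective", c(1, 1, 1, 1)),
    outcomes_tbl("b", "modulator", c(1, 0)),
    outcomes_tbl("b", "potential", c(0, 1)),
    outcomes_tbl("b", "effective", c(NA, NA))  # all effective items missing
  )
  p <- build_profiles(oc)
  expect_true(p$complete[p$participant_id == "a"])
  expect_false(p$complete[p$participant_id == "b"])
  expect_match(p$exclusion_reason[p$participant_id == "b"], "effective")
  expect_true(is.na(p$group[p$participant_id == "b"]))
  s <- summarize_cohort(p)
  expect_equal(s$n_profiled, 1)
  expect_equal(s$n_excluded, 1)
  expect_equal(sum(s$group_sizes$n), 1)
})

test_that("single-participant cohort summarizes to one non-empty group", {
  oc <- dplyr::bind_rows(
    outcomes_tbl("solo", "modulator", rep(1, 4)),
    outcomes_tbl("solo", "potential", rep(1, 4)),
    outcomes_tbl("solo", "effective", rep(1, 4))
  )
  s <- summarize_cohort(build_profiles(oc))
  expect_equal(s$group_sizes$n[s$group_sizes$group == "A"], 1L)
  expect_equal(sum(s$group_sizes$n), 1L)
  expect_error(summarize_cohort(build_profiles(oc)[0, ]),
               class = "mobscore_validation_error")
})
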