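#' Count dichotomous outcomes for one dimension
#'
#' @param outcomes Integer vector of `1` (success), `0` (fail) and `NA`
#'   (missing) outcomes for one participant and one dimension.
#' @return Named integer vector `c(n_success, n_assessed)`; missing outcomes
#'   are excluded from both counts.
#' @export
#' @examples
#' count_outcomes(c(1, 0, NA, 1))
count_outcomes <- function(outcomes) {
  assessed <- !is.na(outcomes)
  c(n_success = sum(outcomes[assessed] == 1L),
    n_assessed = sum(assessed))
}

#' Weighted dimension score on the 0-4 scale
#'
#' Composite scores are made comparable across participants with different
#' numbers of assessed items by rescaling the success count to a maximum of
#' four: a participant with 1 success out of 3 assessed items scores
#' 4 * 1/3 = 1.33, exactly as if a fourth item had been assessed pro rata.
#' The exact rational value `4 * n_success / n_assessed` is used for all
#' category comparisons; rounding to two decimals (half up) happens only at
#' display time via [format_weighted()].
#'
#' @param n_success,n_assessed Non-negative integer counts with
#'   `n_success <= n_assessed`; `n_assessed` must be at least 1.
#' @return Numeric weighted score in `[0, 4]`.
#' @export
#' @examples
#' weighted_score(7, 16)   # 1.75
weighted_score <- function(n_success, n_assessed) {
  if (any(n_assessed == 0)) {
    rlang::abort("dimension has no assessed items; score undefined",
                 class = "mobscore_unscorable_error")
  }
  check_counts(n_success, n_assessed)
  4 * n_success / n_assessed
}

check_counts <- function(n_success, n_assessed) {
  if (any(n_success < 0) || any(n_assessed < 0) ||
      any(n_success != round(n_success)) || any(n_assessed != round(n_assessed)) ||
      any(n_success > n_assessed)) {
    abort_validation("require integer counts with 0 <= n_success <= n_assessed")
  }
}

#' Display form of a weighted score (two decimals, half up)
#'
#' Rounding is done in exact integer arithmetic on the rational
#' `4 * n_success / n_assessed`, so ties round up deterministically and no
#' floating-point artefact can leak into the printed value.
#'
#' @inheritParams weighted_score
#' @return Character vector like `"1.33"`, `"1.75"`, `"4.00"`.
#' @export
#' @examples
#' format_weighted(1, 3)
format_weighted <- function(n_success, n_assessed) {
  if (any(n_assessed == 0)) {
    rlang::abort("dimension has no assessed items; score undefined",
                 class = "mobscore_unscorable_error")
  }
  check_counts(n_success, n_assessed)
  # hundredths of the weighted score, rounded half up: (400 k) / n
  num <- 400L * as.integer(n_success)
  den <- as.integer(n_assessed)
  hund <- num %/% den + as.integer(2L * (num %% den) >= den)
  sprintf("%d.%02d", hund %/% 100L, hund %% 100L)
}

#' Category of a weighted score
#'
#' Cut-points on the weighted 0-4 scale: low/negative below 1, moderate from
#' 1 up to (but excluding) 3, high/positive from 3 to 4. Applied to the
#' unrounded weighted value.
#'
#' @param weighted Numeric weighted score(s) in `[0, 4]`.
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
#' @examples
#' categorize(c(0, 0.99, 1, 2.66, 3, 4))
categorize <- function(weighted) {
  if (any(is.na(weighted)) || any(weighted < 0 | weighted > 4)) {
    abort_validation("weighted score must be within [0, 4]")
  }
  cut(weighted, breaks = c(-Inf, 1, 3, Inf), right = FALSE,
      labels = c("low", "moderate", "high"))
}

category_levels <- c("low", "moderate", "high")
group_levels <- c("A", "B", "C", "D")

# category from exact integer counts (no floating point): low iff 4k < n,
# high iff 4k >= 3n
categorize_counts <- function(n_success, n_assessed) {
  k4 <- 4L * as.integer(n_success)
  n <- as.integer(n_assessed)
  factor(ifelse(k4 < n, "low", ifelse(k4 >= 3L * n, "high", "moderate")),
         levels = category_levels)
}

#' Score one dimension from its dichotomous outcomes
#'
#' Composes [count_outcomes()], [weighted_score()] and [categorize()].
#'
#' @inheritParams count_outcomes
#' @param dimension Label stored in the result (`"modulator"`, `"potential"`
#'   or `"effective"`).
#' @return One-row tibble: `dimension`, `n_success`, `n_assessed`, `weighted`,
#'   `display`, `category`.
#' @export
#' @examples
#' score_dimension(c(1, 0, NA, 0), "potential")
score_dimension <- function(outcomes, dimension = NA_character_) {
  n <- count_outcomes(outcomes)
  tibble::tibble(
    dimension = dimension,
    n_success = n[["n_success"]],
    n_assessed = n[["n_assessed"]],
    weighted = weighted_score(n[["n_success"]], n[["n_assessed"]]),
    display = format_weighted(n[["n_success"]], n[["n_assessed"]]),
    category = categorize_counts(n[["n_success"]], n[["n_assessed"]])
  )
}

#' Mobility profile group from the three dimension categories
#'
#' Grouping is effective-mobility-first: participants with high effective
#' mobility split into group A (also high potential mobility *and* positive
#' modulators) and group B (all other high-effective patterns); moderate
#' effective mobility is group C and low effective mobility group D,
#' regardless of the other two dimensions. The rule is total over all 27
#' category combinations and reproduces every grouping observed in the
#' ten-participant pilot.
#'
#' @param effective,potential,modulator Categories (`"low"`, `"moderate"`,
#'   `"high"`), vectorized.
#' @return Factor with levels `A`, `B`, `C`, `D`.
#' @export
#' @examples
#' assign_group("high", "high", "high")   # A
#' assign_group("moderate", "low", "moderate")  # C
assign_group <- function(effective, potential, modulator) {
  cats <- list(effective, potential, modulator)
  if (!all(unlist(cats) %in% category_levels)) {
    abort_validation("categories must be low/moderate/high")
  }
  factor(dplyr::case_when(
    effective == "high" & potential == "high" & modulator == "high" ~ "A",
    effective == "high" ~ "B",
    effective == "moderate" ~ "C",
    effective == "low" ~ "D"
  ), levels = group_levels)
}

#' Build per-participant mobility profiles from dichotomous outcomes
#'
#' Scores each participant on the three dimensions and assigns the A-D group.
#' A participant with zero assessed items in any dimension cannot be weighted
#' (weighting rescales partial batteries, it never invents absent ones): the
#' profile is marked incomplete, its group is `NA`, and the reason is
#' recorded.
#'
#' @param outcomes Outcome tibble as returned by [dichotomize()] (columns
#'   `participant_id`, `dimension`, `outcome`; extra columns ignored).
#' @return Tibble, one row per participant: `participant_id`, then for each
#'   dimension `<dim>_success`, `<dim>_assessed`, `<dim>_weighted`,
#'   `<dim>_display`, `<dim>_category`, plus `complete`, `exclusion_reason`
#'   and `group`.
#' @export
build_profiles <- function(outcomes) {
  stopifnot(all(c("participant_id", "dimension", "outcome") %in% names(outcomes)))
  counts <- outcomes |>
    dplyr::group_by(.data$participant_id, .data$dimension) |>
    dplyr::summarise(
      n_success = sum(.data$outcome == 1L, na.rm = TRUE),
      n_assessed = sum(!is.na(.data$outcome)),
      .groups = "drop"
    ) |>
    tidyr::complete(
      participant_id = unique(outcomes$participant_id),
      dimension = dimensions,
      fill = list(n_success = 0L, n_assessed = 0L)
    )
  scorable <- counts$n_assessed > 0
  counts$weighted <- ifelse(scorable, 4 * counts$n_success / counts$n_assessed, NA_real_)
  counts$display <- NA_character_
  counts$display[scorable] <-
    format_weighted(counts$n_success[scorable], counts$n_assessed[scorable])
  counts$category <- factor(NA, levels = category_levels)
  counts$category[scorable] <-
    categorize_counts(counts$n_success[scorable], counts$n_assessed[scorable])

  wide <- counts |>
    tidyr::pivot_wider(
      id_cols = "participant_id",
      names_from = "dimension",
      values_from = c("n_success", "n_assessed", "weighted", "display", "category"),
      names_glue = "{dimension}_{sub('n_', '', .value)}"
    )
  wide$complete <- !is.na(wide$modulator_category) &
    !is.na(wide$potential_category) & !is.na(wide$effective_category)
  wide$exclusion_reason <- ifelse(
    wide$complete, NA_character_,
    paste0("no assessed items in dimension(s): ",
           purrr::pmap_chr(
             list(is.na(wide$modulator_category), is.na(wide$potential_category),
                  is.na(wide$effective_category)),
             function(m, p, e) paste(dimensions[c(m, p, e)], collapse = ", "))))
  wide$group <- factor(NA, levels = group_levels)
  wide$group[wide$complete] <- assign_group(
    as.character(wide$effective_category[wide$complete]),
    as.character(wide$potential_category[wide$complete]),
    as.character(wide$modulator_category[wide$complete])
  )
  dplyr::arrange(wide, .data$participant_id)
}

#' Summarize a profiled cohort
#'
#' @param profiles Profile tibble from [build_profiles()].
#' @return List of class `mob_summary`: `n_profiled`, `n_excluded`,
#'   `category_counts` (dimension x category), `group_sizes` (groups A-D,
#'   zeros included), and `long` — the long-format table (participant,
#'   dimension, weighted, display, category, group) behind the per-participant
#'   profile chart.
#' @export
summarize_cohort <- function(profiles) {
  if (nrow(profiles) == 0) abort_validation("no profiles to summarize")
  complete <- profiles[profiles$complete, ]
  if (nrow(complete) == 0) abort_validation("no complete profiles to summarize")

  category_counts <- purrr::map_dfr(dimensions, function(d) {
    tab <- table(complete[[paste0(d, "_category")]])
    tibble::tibble(dimension = d, category = category_levels,
                   n = as.integer(tab[category_levels]))
  })
  group_sizes <- tibble::tibble(
    group = group_levels,
    n = as.integer(table(complete$group)[group_levels])
  )
  long <- purrr::map_dfr(dimensions, function(d) {
    tibble::tibble(
      participant_id = complete$participant_id,
      dimension = d,
      weighted = complete[[paste0(d, "_weighted")]],
      display = complete[[paste0(d, "_display")]],
      category = as.character(complete[[paste0(d, "_category")]]),
      group = as.character(complete$group)
    )
  }) |> dplyr::arrange(.data$participant_id, .data$dimension)

  structure(
    list(n_profiled = nrow(complete),
         n_excluded = nrow(profiles) - nrow(complete),
         category_counts = category_counts,
         group_sizes = group_sizes,
         long = long),
    class = "mob_summary"
  )
}

#' @export
print.mob_summary <- function(x, ...) {
  cat(sprintf("<mob_summary> %d participant(s) profiled, %d excluded\n",
              x$n_profiled, x$n_excluded))
  gs <- x$group_sizes
  cat("  groups: ", paste(sprintf("%s:%d", gs$group, gs$n), collapse = "  "), "\n")
  cc <- tidyr::pivot_wider(x$category_counts, names_from = "category",
                           values_from = "n")
  for (i in seq_len(nrow(cc))) {
    cat(sprintf("  %-9s low:%d moderate:%d high:%d\n", cc$dimension[i],
                cc$low[i], cc$moderate[i], cc$high[i]))
  }
  invisible(x)
}

#' Score a cohort end to end
#'
#' Dichotomizes every measurement, builds per-participant profiles and the
#' cohort summary.
#'
#' @param cohort A `mob_cohort` (list with `participants` and `measurements`),
#'   e.g. from [generate_cohort()] or [read_cohort()].
#' @inheritParams dichotomize
#' @return List with `outcomes`, `profiles`, `summary`.
#' @export
score_cohort <- function(cohort, registry = default_registry(),
                         norms = default_norms()) {
  outcomes <- dichotomize(cohort$measurements, registry, norms,
                          cohort$participants)
  profiles <- build_profiles(outcomes)
  list(outcomes = outcomes, profiles = profiles,
       summary = summarize_cohort(profiles))
}
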