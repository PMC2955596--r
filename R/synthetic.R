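#' Configuration for the synthetic amputee-cohort generator
#'
#' Builds a validated configuration describing a heterogeneous cohort of
#' older lower-limb amputees of vascular origin: a mixture of mobility
#' archetypes (prosthesis walkers, walking-aid users, wheelchair users), an
#' age/sex distribution mirroring the pilot demography (ages 51-83, 80% male),
#' per-modulator negative prevalences, truncated-normal raw-score
#' distributions on each instrument's native scale, and missingness rates for
#' the "not evaluated" and "not collected" codes.
#'
#' @param n_participants Number of participants to generate.
#' @param seed Optional integer seed recorded in the config (can be overridden
#'   at generation time).
#' @param archetype_weights Named mixture weights over
#'   `prosthesis_walker`, `aid_walker`, `wheelchair_user`; must sum to 1.
#' @param modulator_prevalence Named probabilities that each modulator item is
#'   negative (fails); names are registry `item_id`s. Partial lists override
#'   the defaults. The age-over-60 item is derived from the sampled age, not
#'   from a prevalence.
#' @param age_range Integer range ages are drawn from (discrete uniform).
#' @param p_male Probability of male sex.
#' @param missing_rates Named rates for codes `not_evaluated` and
#'   `not_collected`, applied per instrument administration.
#' @param score_distributions Named list of `c(mean, sd)` (optionally
#'   per-archetype means, see [default_score_distributions()]) overriding the
#'   default raw-score distributions.
#' @param alternates_choice How to pick the administered member of an
#'   alternates group: `"random"`, `"first"` (ISEL, AMP) or `"second"`
#'   (MOS, BBT).
#' @return List of class `mob_cohort_config`.
#' @export
cohort_config <- function(n_participants = 10,
                          seed = NULL,
                          archetype_weights = c(prosthesis_walker = 0.5,
                                                aid_walker = 0.3,
                                                wheelchair_user = 0.2),
                          modulator_prevalence = NULL,
                          age_range = c(51, 83),
                          p_male = 0.8,
                          missing_rates = c(not_evaluated = 0.02,
                                            not_collected = 0.01),
                          score_distributions = NULL,
                          alternates_choice = "random") {
  if (!is.numeric(n_participants) || n_participants < 1 ||
      n_participants != round(n_participants)) {
    abort_config("n_participants must be a positive integer")
  }
  if (!setequal(names(archetype_weights), archetypes) ||
      abs(sum(archetype_weights) - 1) > 1e-8 || any(archetype_weights < 0)) {
    abort_config("archetype_weights must be nonnegative, named over the three archetypes, and sum to 1")
  }
  prev <- default_modulator_prevalence()
  if (!is.null(modulator_prevalence)) {
    bad <- setdiff(names(modulator_prevalence), names(prev))
    if (length(bad) > 0) {
      abort_config(sprintf("unknown modulator item(s) in prevalence config: %s",
                           paste(bad, collapse = ", ")))
    }
    prev[names(modulator_prevalence)] <- modulator_prevalence
  }
  if (any(prev < 0 | prev > 1)) abort_config("prevalences must be in [0, 1]")
  if (any(missing_rates < 0) || sum(missing_rates) > 1) {
    abort_config("missing rates must be nonnegative and sum to at most 1")
  }
  dist <- default_score_distributions()
  if (!is.null(score_distributions)) {
    bad <- setdiff(names(score_distributions), names(dist))
    if (length(bad) > 0) {
      abort_config(sprintf("unknown instrument(s) in score_distributions: %s",
                           paste(bad, collapse = ", ")))
    }
    for (nm in names(score_distributions)) {
      d <- score_distributions[[nm]]
      if (any(!is.finite(unlist(d))) ||
          (!is.null(d[["sd"]]) && d[["sd"]] <= 0)) {
        abort_config(sprintf("invalid distribution parameters for '%s'", nm))
      }
      dist[[nm]][names(d)] <- d
    }
  }
  if (!alternates_choice %in% c("random", "first", "second")) {
    abort_config("alternates_choice must be random, first or second")
  }
  structure(
    list(n_participants = as.integer(n_participants), seed = seed,
         archetype_weights = archetype_weights,
         modulator_prevalence = prev, age_range = age_range, p_male = p_male,
         missing_rates = missing_rates, score_distributions = dist,
         alternates_choice = alternates_choice),
    class = "mob_cohort_config"
  )
}

#' Default negative-modulator prevalences
#'
#' Plausible marginal rates for a community-dwelling vascular-amputee
#' population in the year after hospital discharge; each is the probability
#' that the item is scored negative (fail).
#'
#' @return Named numeric vector keyed by modulator `item_id`.
#' @export
default_modulator_prevalence <- function() {
  c(
    sdq_below_knee_amputation = 0.7,
    sdq_adl_fatigue = 0.5,
    sdq_daily_cigarettes = 0.3,
    sdq_daily_alcohol = 0.2,
    sdq_lives_alone_or_care = 0.4,
    sdq_inaccessible_environment = 0.3,
    sdq_device_dissatisfaction = 0.2,
    sdq_other_physical_problem = 0.6,
    sdq_lack_of_services = 0.5,
    charlson = 0.6,
    isel = 0.3, mos = 0.3,
    wcq_distancing = 0.4, wcq_support_seeking = 0.4, wcq_reappraisal = 0.4,
    bpi_q5 = 0.3, bpi_q9a = 0.15,
    bmi = 0.3,
    gds = 0.3,
    grip = 0.4,
    monofilament = 0.4
  )
}

#' Default raw-score distributions
#'
#' Truncated normals on each instrument's native scale; count scales are
#' rounded. Potential- and effective-mobility instruments take
#' archetype-specific means (prosthesis walker / walking-aid user /
#' wheelchair user) to emulate cohort heterogeneity; modulator instruments
#' take a single mean because their fail rate is controlled directly by the
#' configured prevalence (the distribution only shapes values within the
#' fail/success side of the threshold).
#'
#' @return Named list: each element has `mean` (length 1 or 3) and `sd`.
#' @export
default_score_distributions <- function() {
  list(
    charlson = list(mean = 2, sd = 1.5),
    isel = list(mean = 1.8, sd = 0.6),
    mos = list(mean = 75, sd = 15),
    wcq_distancing = list(mean = 1.5, sd = 0.5),
    wcq_support_seeking = list(mean = 1.5, sd = 0.5),
    wcq_reappraisal = list(mean = 1.5, sd = 0.5),
    bpi_q5 = list(mean = 4, sd = 2.5),
    bpi_q9a = list(mean = 4, sd = 2.5),
    bmi = list(mean = 28, sd = 5),
    gds = list(mean = 9, sd = 5),
    grip = list(mean = 30, sd = 10),
    lci = list(mean = c(prosthesis_walker = 32, aid_walker = 24,
                        wheelchair_user = 14), sd = 8),
    tug_ab = list(mean = c(prosthesis_walker = 16, aid_walker = 22,
                           wheelchair_user = NA), sd = 7),
    tug_c = list(mean = c(prosthesis_walker = NA, aid_walker = NA,
                          wheelchair_user = 34), sd = 12),
    amp = list(mean = c(prosthesis_walker = 32, aid_walker = 24,
                        wheelchair_user = 12), sd = 8),
    bbt = list(mean = c(prosthesis_walker = 42, aid_walker = 34,
                        wheelchair_user = 20), sd = 10),
    lifeh_daily = list(mean = c(prosthesis_walker = 7.5, aid_walker = 6.5,
                                wheelchair_user = 5.5), sd = 1.5),
    lifeh_social = list(mean = c(prosthesis_walker = 7.5, aid_walker = 6.5,
                                 wheelchair_user = 5.5), sd = 1.5),
    lsa = list(mean = c(prosthesis_walker = 70, aid_walker = 50,
                        wheelchair_user = 35), sd = 20),
    hap = list(mean = c(prosthesis_walker = 65, aid_walker = 55,
                        wheelchair_user = 40), sd = 15)
  )
}

# inverse-CDF sampling from a normal truncated to [a, b]; for count scales
# the draw is rounded and clamped back into the integer subinterval
rtrunc_norm <- function(n, mean, sd, a, b, integer = FALSE) {
  if (integer) {
    a <- ceiling(a - 1e-9)
    b <- floor(b + 1e-9)
  }
  if (any(a > b)) abort_config("empty truncation interval")
  pa <- stats::pnorm(a - if (integer) 0.5 else 0, mean, sd)
  pb <- stats::pnorm(b + if (integer) 0.5 else 0, mean, sd)
  # guard against degenerate tails
  pa <- pmin(pa, 1 - 1e-12); pb <- pmax(pb, pa + 1e-12)
  x <- stats::qnorm(stats::runif(n, pa, pb), mean, sd)
  # continuous scales are recorded at 0.001 resolution; interval endpoints are
  # multiples of 0.001 (see rule_interval) so rounding cannot cross a threshold
  x <- if (integer) round(x) else round(x, 3)
  pmin(pmax(x, a), b)
}

# fail/success intervals of a comparator rule on scale [lo, hi]; continuous
# open endpoints are nudged by the 0.001 recording resolution, integer scales
# by 1 unit
rule_interval <- function(kind, threshold, lo, hi, fail, integer) {
  eps <- if (integer) 1 else 0.001
  switch(kind,
    greater_than  = if (fail) c(threshold + eps, hi) else c(lo, threshold),
    greater_equal = if (fail) c(threshold, hi) else c(lo, threshold - eps),
    less_than     = if (fail) c(lo, threshold - eps) else c(threshold, hi),
    less_equal    = if (fail) c(lo, threshold) else c(threshold + eps, hi),
    abort_config(sprintf("no sampling interval for rule kind '%s'", kind))
  )
}

#' Generate a synthetic cohort
#'
#' Draws `n_participants` records reproducibly from a [cohort_config()]:
#' demographics and archetype first, then one raw measurement per applicable
#' registry item. Modulator fail status is drawn as Bernoulli(prevalence) and
#' the raw value is then sampled from the instrument's truncated-normal
#' distribution restricted to the corresponding side of its threshold, so the
#' configured prevalences are recovered exactly in expectation. Potential- and
#' effective-mobility raw scores are drawn unconditionally from their
#' archetype-specific distributions. Archetype gating is enforced (the
#' inapplicable Timed Up and Go variant is coded not-applicable, mirroring the
#' "n.a." convention) and the unadministered member of an alternates group is
#' coded not-collected (the "-" convention).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; overrides `config$seed`. One of the two must be
#'   supplied for reproducibility.
#' @param registry,norms Registry and norm tables the cohort must conform to.
#' @return List of class `mob_cohort`: `participants` (tibble with
#'   `participant_id`, `age`, `sex`, `archetype`) and `measurements` (tibble
#'   in the format accepted by [dichotomize()]).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 5), seed = 1)
#' cohort$participants
generate_cohort <- function(config = cohort_config(), seed = NULL,
                            registry = default_registry(),
                            norms = default_norms()) {
  stopifnot(inherits(config, "mob_cohort_config"))
  seed <- seed %||% config$seed
  if (is.null(seed)) {
    abort_config("a seed is required (config$seed or the seed argument)")
  }
  withr::with_seed(as.integer(seed), generate_cohort_impl(config, registry, norms))
}

generate_cohort_impl <- function(config, registry, norms) {
  n <- config$n_participants
  participants <- tibble::tibble(
    participant_id = sprintf("S%04d", seq_len(n)),
    age = sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE),
    sex = ifelse(stats::runif(n) < config$p_male, "M", "F"),
    archetype = sample(archetypes, n, replace = TRUE,
                       prob = config$archetype_weights[archetypes])
  )
  measurements <- purrr::map_dfr(seq_len(nrow(registry)), function(i) {
    sample_item_measurements(registry[i, ], participants, config, norms)
  }) |>
    dplyr::arrange(.data$participant_id) |>
    apply_alternates(registry, config) |>
    apply_missingness(config)
  structure(list(participants = participants, measurements = measurements,
                 config = config),
            class = "mob_cohort")
}

# one measurement row per participant for a single registry item
sample_item_measurements <- function(item, participants, config, norms) {
  n <- nrow(participants)
  rows <- tibble::tibble(
    participant_id = participants$participant_id,
    instrument_id = item$instrument_id,
    item_id = item$item_id,
    value = NA_real_,
    site_1 = NA_real_, site_2 = NA_real_, site_3 = NA_real_, site_4 = NA_real_,
    missing_code = "none"
  )
  applicable <- applies_to(rep(item$applicability, n), participants$archetype)
  rows$missing_code[!applicable] <- "not_applicable"
  idx <- which(applicable)
  if (length(idx) == 0) return(rows)

  if (item$dimension == "modulator") {
    fails <- sample_modulator_fail(item, participants[idx, ], config)
    if (item$value_type == "boolean") {
      rows$value[idx] <- as.numeric(fails)
    } else if (item$value_type == "sites") {
      sites <- sample_monofilament_sites(fails)
      rows[idx, paste0("site_", 1:4)] <- sites
    } else {
      rows$value[idx] <- sample_conditional_value(item, participants[idx, ],
                                                  fails, config, norms)
    }
  } else {
    dist <- config$score_distributions[[item$item_id]]
    mu <- dist_mean(dist, participants$archetype[idx])
    rows$value[idx] <- rtrunc_norm(length(idx), mu, dist$sd,
                                   item$scale_min, item$scale_max,
                                   integer = item$integer_scale)
  }
  rows
}

dist_mean <- function(dist, archetype) {
  if (length(dist$mean) == 1) rep(dist$mean, length(archetype))
  else unname(dist$mean[archetype])
}

sample_modulator_fail <- function(item, participants, config) {
  if (item$item_id == "sdq_age_over_60") {
    return(participants$age > 60)
  }
  p <- config$modulator_prevalence[[item$item_id]]
  stats::runif(nrow(participants)) < p
}

# raw value on the fail/success side of the item's threshold (or norm cut)
sample_conditional_value <- function(item, participants, fails, config, norms) {
  dist <- config$score_distributions[[item$item_id]]
  n <- nrow(participants)
  value <- numeric(n)
  if (item$rule_kind %in% comparator_kinds) {
    for (side in c(TRUE, FALSE)) {
      sel <- which(fails == side)
      if (length(sel) == 0) next
      iv <- rule_interval(item$rule_kind, item$threshold,
                          item$scale_min, item$scale_max, fail = side,
                          integer = item$integer_scale)
      value[sel] <- rtrunc_norm(length(sel), dist$mean, dist$sd, iv[1], iv[2],
                                integer = item$integer_scale)
    }
  } else {
    # norm-referenced rule: the cut depends on age/sex
    cut <- lookup_norm_vec(norms, item$instrument_id, participants$age,
                           participants$sex)
    eps <- if (item$integer_scale) 1 else 0.001
    if (item$rule_kind == "norm_below") {
      a <- ifelse(fails, item$scale_min, cut)
      b <- ifelse(fails, cut - eps, item$scale_max)
    } else { # norm_percentile_le
      a <- ifelse(fails, item$scale_min, cut + eps)
      b <- ifelse(fails, cut, item$scale_max)
    }
    value <- rtrunc_norm(n, dist$mean, dist$sd, a, b,
                         integer = item$integer_scale)
  }
  value
}

# vectorized norm lookup: loops over the (few) table rows, not participants
lookup_norm_vec <- function(norms, instrument_id, age, sex) {
  rows <- norms[norms$instrument_id == instrument_id, ]
  if (nrow(rows) == 0) {
    abort_validation(sprintf("no norm table for instrument '%s'", instrument_id))
  }
  cuts <- rep(NA_real_, length(age))
  for (i in seq_len(nrow(rows))) {
    sel <- age >= rows$age_min[i] & age <= rows$age_max[i] &
      (is.na(rows$sex[i]) | sex == rows$sex[i])
    cuts[sel] <- rows$cut[i]
  }
  if (anyNA(cuts)) {
    abort_validation(sprintf("no norm stratum for some participants on '%s'",
                             instrument_id))
  }
  cuts
}

# failing participants miss at least one of the four sites
sample_monofilament_sites <- function(fails) {
  n <- length(fails)
  sites <- matrix(1, n, 4)
  idx <- which(fails)
  if (length(idx) > 0) {
    missed <- matrix(stats::runif(length(idx) * 4) < 0.3, length(idx), 4)
    missed[cbind(seq_along(idx), sample.int(4, length(idx), replace = TRUE))] <- TRUE
    sites[idx, ][missed] <- 0
  }
  as.data.frame(sites)
}

# pick one administered member per alternates group; the other is "-"
apply_alternates <- function(measurements, registry, config) {
  groups <- split(registry$item_id[!is.na(registry$alternates_group)],
                  registry$alternates_group[!is.na(registry$alternates_group)])
  pids <- unique(measurements$participant_id)
  for (members in groups) {
    pick <- switch(config$alternates_choice,
      first = rep(1L, length(pids)),
      second = rep(2L, length(pids)),
      random = sample.int(2L, length(pids), replace = TRUE))
    dropped <- members[3L - pick]  # the member NOT administered
    drop_rows <- match(paste(pids, dropped),
                       paste(measurements$participant_id, measurements$item_id))
    drop_rows <- drop_rows[!is.na(drop_rows)]
    measurements$missing_code[drop_rows] <- "not_collected"
    measurements$value[drop_rows] <- NA_real_
  }
  measurements
}

# random not_evaluated / not_collected codes, shared by sub-items of one
# instrument administration
apply_missingness <- function(measurements, config) {
  rates <- config$missing_rates
  if (sum(rates) == 0) return(measurements)
  admin <- unique(measurements[measurements$missing_code == "none",
                               c("participant_id", "instrument_id")])
  u <- stats::runif(nrow(admin))
  admin$code <- ifelse(
    u < rates[["not_evaluated"]], "not_evaluated",
    ifelse(u < sum(rates), "not_collected", "none"))
  admin <- admin[admin$code != "none", ]
  if (nrow(admin) == 0) return(measurements)
  key <- paste(measurements$participant_id, measurements$instrument_id)
  hit <- match(key, paste(admin$participant_id, admin$instrument_id))
  sel <- !is.na(hit) & measurements$missing_code == "none"
  measurements$missing_code[sel] <- admin$code[hit[sel]]
  measurements$value[sel] <- NA_real_
  measurements[sel, paste0("site_", 1:4)] <- NA_real_
  measurements
}

#' @export
print.mob_cohort <- function(x, ...) {
  cat(sprintf("<mob_cohort> %d participant(s), %d measurement rows\n",
              nrow(x$participants), nrow(x$measurements)))
  print(table(x$participants$archetype))
  invisible(x)
}

#' Sample a single participant record
#'
#' Convenience wrapper around [generate_cohort()] with `n_participants = 1`
#' and a forced mobility archetype.
#'
#' @param archetype One of `"prosthesis_walker"`, `"aid_walker"`,
#'   `"wheelchair_user"`.
#' @inheritParams generate_cohort
#' @return A `mob_cohort` with one participant.
#' @export
sample_participant <- function(archetype, config = cohort_config(), seed = NULL) {
  if (!archetype %in% archetypes) {
    abort_config(sprintf("unknown archetype '%s'", archetype))
  }
  w <- stats::setNames(as.numeric(archetypes == archetype), archetypes)
  cfg <- config
  cfg$n_participants <- 1L
  cfg$archetype_weights <- w
  generate_cohort(cfg, seed = seed)
}

#' The deterministic ten-participant pilot fixture
#'
#' A seed-free fixture of dichotomized outcome vectors whose scored output
#' reproduces every published marginal of the ten-participant pilot cohort:
#' potential-mobility categories 6 low / 3 moderate / 1 high (weighted scores
#' 0, 1.33 or 2.66, and 4); effective-mobility weighted scores 4, 4, 3, 2, 2,
#' 2, 1, 1, 1, 0 (3 high / 6 moderate / 1 low); modulators moderate for nine
#' participants (spanning 7/16 = 1.75 to 17/24 = 2.83) and positive for one
#' (19/24 = 3.17); and profile groups A:1, B:2, C:6, D:1. The fixture stores
#' outcome vectors, not raw instrument values: the per-participant raw data
#' behind the published aggregates is not public, and the aggregates are exact
#' at the dichotomized level.
#'
#' @return Tibble with columns `participant_id`, `dimension`, `outcome`
#'   (one row per dichotomous item; successes first within a vector).
#' @export
#' @examples
#' fx <- pilot_fixture()
#' summarize_cohort(build_profiles(fx))
pilot_fixture <- function() {
  # participant_id, then (n_success, n_assessed) per dimension
  spec <- list(
    #      potential  effective  modulator
    P01 = list(c(0, 4), c(1, 4), c(7, 16)),   # group C (truncated battery)
    P02 = list(c(1, 3), c(4, 4), c(17, 24)),  # group B
    P03 = list(c(0, 4), c(3, 4), c(12, 21)),  # group B
    P04 = list(c(2, 3), c(2, 4), c(11, 21)),  # group C
    P05 = list(c(0, 4), c(2, 4), c(10, 21)),  # group C
    P06 = list(c(1, 3), c(1, 4), c(13, 24)),  # group C
    P07 = list(c(0, 4), c(1, 4), c(9, 21)),   # group C
    P08 = list(c(4, 4), c(4, 4), c(19, 24)),  # group A ("subject #8")
    P09 = list(c(0, 4), c(2, 4), c(14, 24)),  # group C
    P10 = list(c(0, 4), c(0, 4), c(8, 21))    # group D
  )
  purrr::imap_dfr(spec, function(dims, pid) {
    purrr::map2_dfr(dims, dimensions[c(2, 3, 1)], function(kn, dim) {
      tibble::tibble(
        participant_id = pid,
        dimension = dim,
        outcome = rep(c(1L, 0L), c(kn[1], kn[2] - kn[1]))
      )
    })
  })
}
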