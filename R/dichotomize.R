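#' Dichotomize raw measurements into success/fail outcomes
#'
#' Applies each registry item's fail rule to the raw measurements of a cohort,
#' producing one dichotomous outcome per scored item: `1` (success/positive),
#' `0` (fail/negative), or `NA` with a recorded missing reason. Missing input
#' propagates its reason; items that do not apply to a participant's mobility
#' archetype (e.g. the wheelchair-adapted Timed Up and Go for a prosthesis
#' walker) come out `missing(not_applicable)`; for an alternates group (ISEL
#' vs MOS social support, Berg Balance vs AMP) at most one member contributes
#' per participant.
#'
#' @param measurements Tibble of raw measurements with columns
#'   `participant_id`, `item_id`, `value`, `site_1`..`site_4` (monofilament
#'   felt = 1 / not felt = 0), `missing_code` (one of `"none"`,
#'   `"not_evaluated"`, `"not_applicable"`, `"not_collected"`).
#' @param registry A `mob_registry` (default: [default_registry()]).
#' @param norms A `mob_norms` table for the age-referenced rules
#'   (default: [default_norms()]).
#' @param participants Tibble with columns `participant_id`, `age`, `sex`,
#'   `archetype`; required for archetype gating and norm lookups.
#' @return Tibble with columns `participant_id`, `instrument_id`, `item_id`,
#'   `dimension`, `outcome` (integer `1`/`0`/`NA`) and `missing_reason`.
#' @export
#' @examples
#' m <- new_measurement("p1", "tug_ab", 15)
#' p <- tibble::tibble(participant_id = "p1", age = 70, sex = "M",
#'                     archetype = "prosthesis_walker")
#' dichotomize(m, participants = p)
dichotomize <- function(measurements, registry = default_registry(),
                        norms = default_norms(), participants) {
  stopifnot(is.data.frame(measurements), is.data.frame(participants))
  unknown <- setdiff(measurements$item_id, registry$item_id)
  if (length(unknown) > 0) {
    abort_validation(sprintf("unknown item_id: %s",
                             paste(unique(unknown), collapse = ", ")))
  }
  missing_pid <- setdiff(measurements$participant_id, participants$participant_id)
  if (length(missing_pid) > 0) {
    abort_validation(sprintf("measurements for unknown participant(s): %s",
                             paste(unique(missing_pid), collapse = ", ")))
  }
  measurements$instrument_id <- NULL  # resolved from the registry
  m <- dplyr::left_join(measurements, as.data.frame(registry), by = "item_id") |>
    dplyr::left_join(participants[, c("participant_id", "age", "sex", "archetype")],
                     by = "participant_id")

  # archetype gating overrides everything else
  applicable <- applies_to(m$applicability, m$archetype)
  code <- m$missing_code
  code[!applicable] <- "not_applicable"

  assessed <- code == "none"
  validate_values(m, assessed)

  out <- rep(NA_integer_, nrow(m))
  idx <- which(assessed)
  if (length(idx) > 0) {
    cuts <- norm_cuts(m[idx, ], norms)
    out[idx] <- as.integer(!eval_fail_rule(
      kind = m$rule_kind[idx], threshold = m$threshold[idx],
      value = m$value[idx], cut = cuts,
      sites = as.matrix(m[idx, paste0("site_", 1:4)])
    ))
  }
  res <- tibble::tibble(
    participant_id = m$participant_id,
    instrument_id = m$instrument_id,
    item_id = m$item_id,
    dimension = m$dimension,
    outcome = out,
    missing_reason = ifelse(code == "none", NA_character_, code)
  )
  drop_extra_alternates(res, m)
}

# row-wise fail indicator; vectorized over rows
eval_fail_rule <- function(kind, threshold, value, cut, sites) {
  dplyr::case_when(
    kind == "greater_than"       ~ value > threshold,
    kind == "greater_equal"      ~ value >= threshold,
    kind == "less_than"          ~ value < threshold,
    kind == "less_equal"         ~ value <= threshold,
    kind == "boolean_flag"       ~ value == 1,
    kind == "any_site_missed"    ~ rowSums(sites == 0) > 0,
    kind == "norm_below"         ~ value < cut,
    kind == "norm_percentile_le" ~ value <= cut
  )
}

norm_cuts <- function(m, norms) {
  cuts <- rep(NA_real_, nrow(m))
  norm_rows <- m$rule_kind %in% c("norm_below", "norm_percentile_le")
  for (iid in unique(m$instrument_id[norm_rows])) {
    sel <- norm_rows & m$instrument_id == iid
    cuts[sel] <- lookup_norm_vec(norms, iid, m$age[sel], m$sex[sel])
  }
  cuts
}

validate_values <- function(m, assessed) {
  numeric_rows <- assessed & m$value_type == "numeric"
  if (any(numeric_rows & is.na(m$value))) {
    bad <- m$item_id[numeric_rows & is.na(m$value)]
    abort_validation(sprintf("assessed measurement without a value: %s",
                             paste(unique(bad), collapse = ", ")))
  }
  oob <- numeric_rows & !is.na(m$value) &
    (m$value < m$scale_min | m$value > m$scale_max)
  if (any(oob)) {
    abort_validation(sprintf(
      "value out of native-scale range: %s",
      paste(sprintf("%s %s=%g", m$participant_id[oob], m$item_id[oob],
                    m$value[oob]), collapse = "; ")))
  }
  bool_rows <- assessed & m$value_type == "boolean"
  if (any(bool_rows & !(m$value %in% c(0, 1)))) {
    abort_validation("boolean item with value not in {0, 1}")
  }
  site_rows <- assessed & m$value_type == "sites"
  if (any(site_rows)) {
    sites <- as.matrix(m[site_rows, paste0("site_", 1:4)])
    if (anyNA(sites) || !all(sites %in% c(0, 1))) {
      abort_validation("monofilament measurement requires site_1..site_4 in {0, 1}")
    }
  }
  invisible(TRUE)
}

# within an alternates group, keep the first assessed member per participant
drop_extra_alternates <- function(res, m) {
  res$.alt <- m$alternates_group
  grouped <- !is.na(res$.alt) & !is.na(res$outcome)
  if (any(grouped)) {
    key <- paste(res$participant_id, res$.alt)[grouped]
    dup <- duplicated(key)
    if (any(dup)) {
      rows <- which(grouped)[dup]
      rlang::warn(sprintf(
        "both members of an alternates group assessed for %s; keeping the first",
        paste(unique(res$participant_id[rows]), collapse = ", ")))
      res$outcome[rows] <- NA_integer_
      res$missing_reason[rows] <- "not_collected"
    }
  }
  res$.alt <- NULL
  res
}

#' Construct raw-measurement rows
#'
#' Convenience constructor used by the cohort generator and in examples/tests.
#'
#' @param participant_id,item_id Identifiers.
#' @param value Numeric value on the native scale (or 0/1 for boolean items);
#'   `NA` when missing or for site-vector items.
#' @param sites Length-4 numeric vector of monofilament felt (1) / not felt
#'   (0), or `NULL`.
#' @param missing_code `"none"`, `"not_evaluated"`, `"not_applicable"` or
#'   `"not_collected"`.
#' @param registry Registry used to resolve `instrument_id` from `item_id`.
#' @return One-row measurement tibble.
#' @export
new_measurement <- function(participant_id, item_id, value = NA_real_,
                            sites = NULL, missing_code = "none",
                            registry = default_registry()) {
  stopifnot(missing_code %in% missing_codes)
  sites <- sites %||% rep(NA_real_, 4)
  i <- match(item_id, registry$item_id)
  if (is.na(i)) abort_validation(sprintf("unknown item_id '%s'", item_id))
  tibble::tibble(
    participant_id = participant_id,
    instrument_id = registry$instrument_id[i],
    item_id = item_id,
    value = as.numeric(value),
    site_1 = sites[1], site_2 = sites[2], site_3 = sites[3], site_4 = sites[4],
    missing_code = missing_code
  )
}

missing_codes <- c("none", "not_evaluated", "not_applicable", "not_collected")

#' Fatigue check during test administration
#'
#' Fatigue is monitored on a 5-inch visual analogue scale (0 = no fatigue,
#' 5 = lots of fatigue) after every block of four tests; a reading above
#' 2.5 inches calls for a longer pause before continuing.
#'
#' @param vas_inches Numeric VAS reading(s) in inches, 0 to 5.
#' @return Character vector: `"continue"` or `"longer_pause"`.
#' @export
#' @examples
#' fatigue_check(c(0, 2.5, 2.6))
fatigue_check <- function(vas_inches) {
  if (any(is.na(vas_inches)) || any(vas_inches < 0 | vas_inches > 5)) {
    abort_validation("fatigue VAS must be within [0, 5] inches")
  }
  ifelse(vas_inches > 2.5, "longer_pause", "continue")
}
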