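#' Built-in norm tables for age-referenced fail rules
#'
#' Three instruments are dichotomized against external age (and, for grip
#' strength, sex) reference values rather than a fixed cut: the Life Space
#' Assessment and the Human Activity Profile fail strictly below the norm for
#' the participant's age band, and grip strength fails at or below the cut
#' placed at the 30th percentile of the age/sex stratum.
#'
#' The published reference standards are external to the scoring model, so the
#' built-in tables are *synthetic placeholders* with plausible magnitudes on
#' each native scale; substitute population-appropriate values via
#' [load_norms()] before interpreting real cohorts.
#'
#' @return A tibble of class `mob_norms` with columns `instrument_id`, `sex`
#'   (`"M"`, `"F"` or `NA` for both), `age_min`, `age_max`, `cut`.
#' @export
#' @examples
#' default_norms()
default_norms <- function() {
  nt <- tibble::tribble(
    ~instrument_id, ~sex, ~age_min, ~age_max, ~cut,
    # LSA (/120): placeholder community-dwelling reference, lower for 65+
    "lsa",  NA,  18,  64,  64,
    "lsa",  NA,  65, 110,  56,
    # HAP maximum activity score (/94): placeholder age-adjusted reference
    "hap",  NA,  18,  54,  74,
    "hap",  NA,  55,  64,  68,
    "hap",  NA,  65,  79,  60,
    "hap",  NA,  80, 110,  50,
    # grip strength (kg): placeholder 30th-percentile cuts by sex and age band
    "grip", "M", 18,  59,  38,
    "grip", "M", 60,  69,  32,
    "grip", "M", 70,  79,  27,
    "grip", "M", 80, 110,  21,
    "grip", "F", 18,  59,  22,
    "grip", "F", 60,  69,  19,
    "grip", "F", 70,  79,  16,
    "grip", "F", 80, 110,  13
  )
  class(nt) <- c("mob_norms", class(nt))
  nt
}

#' Load a norm table from a YAML/JSON config
#'
#' The config holds a list of rows with fields `instrument_id`, `age_min`,
#' `age_max`, `cut` and optionally `sex`. Bands for one instrument (and sex)
#' must not overlap.
#'
#' @param path Path to the config, or `NULL` for [default_norms()].
#' @return A validated `mob_norms` tibble.
#' @export
load_norms <- function(path = NULL) {
  if (is.null(path)) {
    nt <- default_norms()
  } else {
    cfg <- read_config_file(path)
    rows <- cfg[["norms"]] %||% cfg
    if (length(rows) == 0) abort_config("norm config is empty")
    nt <- purrr::map_dfr(rows, function(r) {
      need <- c("instrument_id", "age_min", "age_max", "cut")
      miss <- setdiff(need, names(r))
      if (length(miss) > 0) {
        abort_config(sprintf("norm row missing field(s): %s",
                             paste(miss, collapse = ", ")))
      }
      tibble::tibble(
        instrument_id = r$instrument_id,
        sex = (r$sex %||% NA_character_),
        age_min = as.numeric(r$age_min), age_max = as.numeric(r$age_max),
        cut = as.numeric(r$cut)
      )
    })
    class(nt) <- c("mob_norms", class(nt))
  }
  validate_norms(nt)
  nt
}

validate_norms <- function(nt) {
  if (any(nt$age_min > nt$age_max)) abort_config("norm band with age_min > age_max")
  key <- split(nt, paste(nt$instrument_id, nt$sex, sep = "/"))
  for (grp in key) {
    grp <- grp[order(grp$age_min), ]
    if (nrow(grp) > 1 &&
        any(grp$age_min[-1] <= grp$age_max[-nrow(grp)])) {
      abort_config(sprintf("overlapping age bands for instrument '%s'",
                           grp$instrument_id[1]))
    }
  }
  invisible(nt)
}

#' Look up the norm cut for one participant
#'
#' @param norms A `mob_norms` table.
#' @param instrument_id Instrument to look up (`"lsa"`, `"hap"`, `"grip"`, ...).
#' @param age Participant age in years.
#' @param sex `"M"` or `"F"`; required when the table stratifies by sex.
#' @return The cut value (scalar) on the instrument's native scale.
#' @export
#' @examples
#' lookup_norm(default_norms(), "lsa", age = 70)
lookup_norm <- function(norms, instrument_id, age, sex = NULL) {
  rows <- norms[norms$instrument_id == instrument_id, ]
  if (nrow(rows) == 0) {
    abort_validation(sprintf("no norm table for instrument '%s'", instrument_id))
  }
  if (any(!is.na(rows$sex))) {
    if (is.null(sex) || is.na(sex)) {
      abort_validation(sprintf(
        "norms for '%s' are sex-stratified but sex is missing", instrument_id))
    }
    rows <- rows[is.na(rows$sex) | rows$sex == sex, ]
  }
  hit <- rows[age >= rows$age_min & age <= rows$age_max, ]
  if (nrow(hit) != 1) {
    abort_validation(sprintf(
      "no norm stratum for instrument '%s', age %s%s", instrument_id, age,
      if (!is.null(sex)) sprintf(", sex %s", sex) else ""))
  }
  hit$cut
}
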