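#' Built-in instrument registry
#'
#' The registry encodes, as data, every instrument of the mobility assessment
#' battery together with its dichotomization rule. Each row is one *scored
#' item*: most instruments contribute a single item, but the Ways of Coping
#' Questionnaire contributes three (one per coping aspect), the Brief Pain
#' Inventory two (pain intensity Q5 and pain interference Q9a), the Assessment
#' of Life Habits two (daily activities and social roles), and the
#' sociodemographic questionnaire ten boolean risk-factor items.
#'
#' @details
#' Columns:
#' \describe{
#'   \item{instrument_id}{short identifier of the parent instrument}
#'   \item{item_id}{identifier of the scored item (unique across the registry)}
#'   \item{name}{human-readable description}
#'   \item{dimension}{one of `"modulator"`, `"potential"`, `"effective"`;
#'     the composite this item feeds}
#'   \item{value_type}{`"numeric"`, `"boolean"` or `"sites"` (the
#'     four-site monofilament felt/not-felt vector)}
#'   \item{scale_min,scale_max}{bounds of the native scale (`NA` for boolean
#'     and site-vector items)}
#'   \item{integer_scale}{whether the native scale is a count/sum score}
#'   \item{rule_kind}{comparator of the fail rule: `greater_than`,
#'     `greater_equal`, `less_than`, `less_equal` (against `threshold`),
#'     `boolean_flag` (fail iff `TRUE`), `any_site_missed` (fail iff any
#'     monofilament site not felt), `norm_below` (fail iff value strictly below
#'     the age/sex norm cut) or `norm_percentile_le` (fail iff value at or
#'     below the norm cut placed at the 30th percentile)}
#'   \item{threshold}{numeric cut for the comparator kinds, `NA` otherwise}
#'   \item{applicability}{`"all"`, `"walker"` (prosthesis or walking-aid
#'     users) or `"wheelchair"`}
#'   \item{alternates_group}{instruments that substitute for one another; at
#'     most one member of a group is scored per participant (`NA` if none)}
#' }
#'
#' Fail rules follow the published cut-offs: LCI fails at a total of 21/42 or
#' less; ambulatory TUG fails above 14 s and the wheelchair-adapted TUG above
#' 34 s; AMP fails below 25/47; Berg Balance fails below 45/56; each LIFE-H
#' domain fails below an average of 7/9; ISEL fails below 1/3 and MOS below
#' 75/95 (alternates for the social-support item); WCQ aspect 1
#' (distancing/avoidance) fails above an average of 1.5/3 while aspects 2 and 3
#' fail below 1.5; BPI fails above 5/10 on Q5 or above 7/10 on Q9a; BMI fails
#' above 30; GDS fails at 11/30 or more; Charlson comorbidity fails at 2 or
#' more; grip strength fails at or below the 30th age/sex percentile;
#' monofilament fails as soon as any site is not felt; LSA and HAP fail
#' strictly below the age-norm cut.
#'
#' @return A tibble of class `mob_registry`, one row per scored item.
#' @seealso [load_registry()] to apply configuration overrides,
#'   [dichotomize()] to apply the rules.
#' @export
#' @examples
#' default_registry()
default_registry <- function() {
  it <- function(instrument_id, item_id, name, dimension, value_type,
                 scale_min, scale_max, integer_scale, rule_kind, threshold,
                 applicability = "all", alternates_group = NA_character_) {
    tibble::tibble(
      instrument_id = instrument_id, item_id = item_id, name = name,
      dimension = dimension, value_type = value_type,
      scale_min = scale_min, scale_max = scale_max,
      integer_scale = integer_scale, rule_kind = rule_kind,
      threshold = threshold, applicability = applicability,
      alternates_group = alternates_group
    )
  }
  sdq_items <- c(
    sdq_age_over_60            = "age over 60 years",
    sdq_below_knee_amputation  = "amputation below the knee",
    sdq_adl_fatigue            = "fatigue felt when performing ADL",
    sdq_daily_cigarettes       = "daily consumption of cigarettes",
    sdq_daily_alcohol          = "daily consumption of alcohol",
    sdq_lives_alone_or_care    = "living alone or in a care centre",
    sdq_inaccessible_environment = "physical environment not very accessible",
    sdq_device_dissatisfaction = "dissatisfaction with technical aids used",
    sdq_other_physical_problem = "presence of another physical problem",
    sdq_lack_of_services       = "lack of services (rehabilitation, etc.)"
  )
  reg <- dplyr::bind_rows(
    # -- modulators -----------------------------------------------------
    it("sdq", names(sdq_items), unname(sdq_items), "modulator", "boolean",
       NA_real_, NA_real_, FALSE, "boolean_flag", NA_real_),
    it("charlson", "charlson", "Charlson Comorbidity Scale (geriatric)",
       "modulator", "numeric", 0, 37, TRUE, "greater_equal", 2),
    it("isel", "isel", "Interpersonal Support Evaluation List (mean of 3 supports)",
       "modulator", "numeric", 0, 3, FALSE, "less_than", 1,
       alternates_group = "social_support"),
    it("mos", "mos", "MOS Social Support Survey (total /95)",
       "modulator", "numeric", 0, 95, TRUE, "less_than", 75,
       alternates_group = "social_support"),
    it("wcq", c("wcq_distancing", "wcq_support_seeking", "wcq_reappraisal"),
       c("WCQ aspect 1: distancing and avoidance",
         "WCQ aspect 2: looking for social support",
         "WCQ aspect 3: positive re-evaluation and problem solving"),
       "modulator", "numeric", 0, 3, FALSE,
       c("greater_than", "less_than", "less_than"), c(1.5, 1.5, 1.5)),
    it("bpi", c("bpi_q5", "bpi_q9a"),
       c("BPI Q5: pain intensity", "BPI Q9a: pain interference with activity"),
       "modulator", "numeric", 0, 10, TRUE,
       "greater_than", c(5, 7)),
    it("bmi", "bmi", "Body Mass Index (kg/m^2)",
       "modulator", "numeric", 10, 70, FALSE, "greater_than", 30),
    it("gds", "gds", "Yesavage Geriatric Depression Scale (/30)",
       "modulator", "numeric", 0, 30, TRUE, "greater_equal", 11),
    it("grip", "grip", "Jamar dynamometer grip strength (kg, mean of 2 trials)",
       "modulator", "numeric", 0, 90, FALSE, "norm_percentile_le", NA_real_),
    it("monofilament", "monofilament",
       "Semmes-Weinstein monofilament, 4 sites on intact foot",
       "modulator", "sites", NA_real_, NA_real_, FALSE, "any_site_missed",
       NA_real_),
    # -- potential mobility ---------------------------------------------
    it("lci", "lci", "Locomotor Capabilities Index (total /42)",
       "potential", "numeric", 0, 42, TRUE, "less_equal", 21),
    it("tug_ab", "tug_ab", "Timed Up and Go, prosthesis or walking aid (s)",
       "potential", "numeric", 0, 600, FALSE, "greater_than", 14,
       applicability = "walker"),
    it("tug_c", "tug_c", "Timed Up and Go, wheelchair-adapted (s)",
       "potential", "numeric", 0, 600, FALSE, "greater_than", 34,
       applicability = "wheelchair"),
    it("amp", "amp", "Amputee Mobility Predictor (/47)",
       "potential", "numeric", 0, 47, TRUE, "less_than", 25,
       alternates_group = "balance"),
    it("bbt", "bbt", "Berg Balance Test (/56)",
       "potential", "numeric", 0, 56, TRUE, "less_than", 45,
       alternates_group = "balance"),
    # -- effective mobility ---------------------------------------------
    it("lifeh", c("lifeh_daily", "lifeh_social"),
       c("LIFE-H daily activities (mean /9)", "LIFE-H social roles (mean /9)"),
       "effective", "numeric", 0, 9, FALSE, "less_than", 7),
    it("lsa", "lsa", "Life Space Assessment (/120)",
       "effective", "numeric", 0, 120, TRUE, "norm_below", NA_real_),
    it("hap", "hap", "Human Activity Profile, Maximum Activity Score (/94)",
       "effective", "numeric", 0, 94, TRUE, "norm_below", NA_real_)
  )
  class(reg) <- c("mob_registry", class(reg))
  reg
}

#' Load an instrument registry, optionally overridden by a config file
#'
#' Starts from [default_registry()] and applies per-item overrides from a YAML
#' (or JSON) configuration. Each config entry is keyed by `item_id` and may
#' replace `rule_kind`, `threshold`, `applicability` or `alternates_group` —
#' e.g. to flip the polarity of a contested modulator or recalibrate a cut-off
#' for a new population.
#'
#' @param path Path to a YAML/JSON config file, or `NULL` for the defaults.
#' @return A validated `mob_registry` tibble.
#' @export
#' @examples
#' reg <- load_registry()
#' nrow(reg)
load_registry <- function(path = NULL) {
  reg <- default_registry()
  if (!is.null(path)) {
    cfg <- read_config_file(path)
    if (length(cfg) == 0) {
      abort_config("registry config is empty")
    }
    items <- cfg[["items"]] %||% cfg
    if (is.null(names(items)) || any(names(items) == "")) {
      abort_config("registry config entries must be named by item_id")
    }
    allowed <- c("rule_kind", "threshold", "applicability", "alternates_group")
    for (id in names(items)) {
      if (!id %in% reg$item_id) {
        abort_config(sprintf("registry config names unknown item_id '%s'", id))
      }
      entry <- items[[id]]
      bad <- setdiff(names(entry), allowed)
      if (length(bad) > 0) {
        abort_config(sprintf("item '%s': unknown field(s) %s",
                             id, paste(bad, collapse = ", ")))
      }
      i <- which(reg$item_id == id)
      for (f in names(entry)) {
        value <- entry[[f]]
        if (f == "threshold") value <- as.numeric(value)
        reg[[f]][i] <- value
      }
    }
  }
  validate_registry(reg)
  reg
}

comparator_kinds <- c("greater_than", "greater_equal", "less_than", "less_equal")
rule_kinds <- c(comparator_kinds, "boolean_flag", "any_site_missed",
                "norm_below", "norm_percentile_le")
dimensions <- c("modulator", "potential", "effective")
archetypes <- c("prosthesis_walker", "aid_walker", "wheelchair_user")

validate_registry <- function(reg) {
  if (nrow(reg) == 0) abort_config("registry is empty")
  if (anyDuplicated(reg$item_id)) {
    abort_config(sprintf("duplicate item_id: %s",
                         paste(unique(reg$item_id[duplicated(reg$item_id)]),
                               collapse = ", ")))
  }
  bad_kind <- setdiff(reg$rule_kind, rule_kinds)
  if (length(bad_kind) > 0) {
    abort_config(sprintf("unknown rule_kind: %s", paste(bad_kind, collapse = ", ")))
  }
  bad_dim <- setdiff(reg$dimension, dimensions)
  if (length(bad_dim) > 0) {
    abort_config(sprintf("unknown dimension: %s", paste(bad_dim, collapse = ", ")))
  }
  if (!all(dimensions %in% reg$dimension)) {
    abort_config("registry must cover all three dimensions")
  }
  needs_threshold <- reg$rule_kind %in% comparator_kinds
  if (any(needs_threshold & is.na(reg$threshold))) {
    abort_config(sprintf(
      "comparator rule without threshold: %s",
      paste(reg$item_id[needs_threshold & is.na(reg$threshold)], collapse = ", ")))
  }
  if (any(!needs_threshold & !is.na(reg$threshold))) {
    abort_config("threshold set on a non-comparator rule")
  }
  numeric_rows <- reg$value_type == "numeric"
  if (any(numeric_rows & !(reg$scale_min < reg$scale_max))) {
    abort_config("numeric items require scale_min < scale_max")
  }
  bad_app <- setdiff(reg$applicability, c("all", "walker", "wheelchair"))
  if (length(bad_app) > 0) {
    abort_config(sprintf("unknown applicability: %s", paste(bad_app, collapse = ", ")))
  }
  invisible(reg)
}

#' @export
print.mob_registry <- function(x, ...) {
  cat(sprintf("<mob_registry> %d scored items across %d instruments\n",
              nrow(x), length(unique(x$instrument_id))))
  counts <- table(factor(x$dimension, levels = dimensions))
  cat(sprintf("  modulator: %d items, potential: %d, effective: %d\n",
              counts[["modulator"]], counts[["potential"]], counts[["effective"]]))
  NextMethod()
}

#' Does an item apply to a participant with a given mobility archetype?
#'
#' Archetype gating: the ambulatory Timed Up and Go applies to prosthesis and
#' walking-aid users, its wheelchair-adapted variant to wheelchair users;
#' everything else applies to everyone (the LCI is administered in its adapted
#' form to participants without a prosthesis).
#'
#' @param applicability `"all"`, `"walker"` or `"wheelchair"` (registry column).
#' @param archetype one of `"prosthesis_walker"`, `"aid_walker"`,
#'   `"wheelchair_user"`.
#' @return Logical vector.
#' @export
applies_to <- function(applicability, archetype) {
  if (!all(archetype %in% archetypes)) {
    abort_validation(sprintf("unknown archetype: %s",
                             paste(setdiff(archetype, archetypes), collapse = ", ")))
  }
  dplyr::case_when(
    applicability == "all" ~ TRUE,
    applicability == "walker" ~ archetype %in% c("prosthesis_walker", "aid_walker"),
    applicability == "wheelchair" ~ archetype == "wheelchair_user"
  )
}

read_config_file <- function(path) {
  if (!file.exists(path)) {
    abort_config(sprintf("config file not found: %s", path))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

abort_config <- function(msg) {
  rlang::abort(msg, class = "mobscore_config_error")
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = "mobscore_validation_error")
}
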