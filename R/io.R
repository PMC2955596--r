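#' Write a cohort to the package's CSV dialect
#'
#' One row per participant-item: `participant_id, age, sex, archetype,
#' instrument_id, item_id, value, site_1..site_4, missing_code`, UTF-8 with
#' `"."` decimals. Missing codes are serialized as `""` (assessed), `"ne"`
#' (not evaluated), `"na"` (not applicable) and `"nc"` (not collected).
#'
#' @param cohort A `mob_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  code_map <- c(none = "", not_evaluated = "ne", not_applicable = "na",
                not_collected = "nc")
  out <- dplyr::left_join(cohort$measurements, cohort$participants,
                          by = "participant_id")
  out$missing_code <- unname(code_map[out$missing_code])
  out <- out[, c("participant_id", "age", "sex", "archetype", "instrument_id",
                 "item_id", "value", paste0("site_", 1:4), "missing_code")]
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a cohort from the package's CSV dialect
#'
#' Validates every row against the registry: unknown item ids, unknown
#' missing codes, values outside the native scale and inconsistent
#' demographics are rejected with row-numbered diagnostics.
#'
#' @param path CSV path as written by [write_cohort()].
#' @param registry Registry the rows must conform to.
#' @return A `mob_cohort`.
#' @export
read_cohort <- function(path, registry = default_registry()) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(), age = readr::col_double(),
    sex = readr::col_character(), archetype = readr::col_character(),
    instrument_id = readr::col_character(), item_id = readr::col_character(),
    value = readr::col_double(), site_1 = readr::col_double(),
    site_2 = readr::col_double(), site_3 = readr::col_double(),
    site_4 = readr::col_double(), missing_code = readr::col_character()
  ), na = "", show_col_types = FALSE)
  if ("missing_code" %in% names(raw)) {
    raw$missing_code[is.na(raw$missing_code)] <- ""
  }
  expected <- c("participant_id", "age", "sex", "archetype", "instrument_id",
                "item_id", "value", paste0("site_", 1:4), "missing_code")
  miss <- setdiff(expected, names(raw))
  if (length(miss) > 0) {
    abort_validation(sprintf("cohort CSV missing column(s): %s",
                             paste(miss, collapse = ", ")))
  }
  if (nrow(raw) == 0) abort_validation("cohort CSV has no rows")

  bad_item <- which(!raw$item_id %in% registry$item_id)
  if (length(bad_item) > 0) {
    abort_validation(sprintf("row %d: unknown item_id '%s'",
                             bad_item[1] + 1L, raw$item_id[bad_item[1]]))
  }
  code_in <- c("", "ne", "na", "nc")
  code_out <- c("none", "not_evaluated", "not_applicable", "not_collected")
  bad_code <- which(!raw$missing_code %in% code_in)
  if (length(bad_code) > 0) {
    abort_validation(sprintf("row %d: unknown missing_code '%s'",
                             bad_code[1] + 1L, raw$missing_code[bad_code[1]]))
  }
  spec_row <- match(raw$item_id, registry$item_id)
  assessed <- raw$missing_code == ""
  numeric_item <- registry$value_type[spec_row] == "numeric"
  oob <- which(assessed & numeric_item &
                 (is.na(raw$value) |
                    raw$value < registry$scale_min[spec_row] |
                    raw$value > registry$scale_max[spec_row]))
  if (length(oob) > 0) {
    abort_validation(sprintf(
      "row %d: value %s out of range for item '%s'",
      oob[1] + 1L, format(raw$value[oob[1]]), raw$item_id[oob[1]]))
  }
  participants <- unique(raw[, c("participant_id", "age", "sex", "archetype")])
  if (anyDuplicated(participants$participant_id)) {
    dup <- participants$participant_id[duplicated(participants$participant_id)]
    abort_validation(sprintf("inconsistent demographics for participant(s): %s",
                             paste(unique(dup), collapse = ", ")))
  }
  measurements <- raw[, c("participant_id", "instrument_id", "item_id", "value",
                          paste0("site_", 1:4), "missing_code")]
  measurements$missing_code <- code_out[match(raw$missing_code, code_in)]
  structure(list(participants = participants, measurements = measurements),
            class = "mob_cohort")
}

#' Score a cohort file and write the full report set
#'
#' Reads and validates a cohort CSV, scores it, and writes to `out_dir`:
#' `profiles.json` (per-participant scores as exact fractions and two-decimal
#' display values, categories and group), `summary.json` (category counts and
#' group sizes), `scores_long.csv` (participant x dimension long table for
#' profile charts) and `manifest.json` (tool version, registry checksum,
#' input paths, read/scored/excluded counts, timestamp). Scored outputs
#' contain no timestamp, so repeated runs on the same input are bit-stable;
#' the manifest carries the only timestamp.
#'
#' @param cohort_path Cohort CSV path.
#' @param out_dir Output directory (created if needed).
#' @param registry_path,norms_path Optional YAML/JSON configs; defaults
#'   otherwise.
#' @return Invisibly, the list from [score_cohort()] plus the manifest.
#' @export
run_score <- function(cohort_path, out_dir, registry_path = NULL,
                      norms_path = NULL) {
  registry <- load_registry(registry_path)
  norms <- load_norms(norms_path)
  cohort <- read_cohort(cohort_path, registry)
  scored <- score_cohort(cohort, registry, norms)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  profiles <- scored$profiles
  profile_list <- purrr::map(seq_len(nrow(profiles)), function(i) {
    p <- profiles[i, ]
    dims <- stats::setNames(purrr::map(dimensions, function(d) {
      if (is.na(p[[paste0(d, "_category")]])) return(NULL)
      list(
        n_success = p[[paste0(d, "_success")]],
        n_assessed = p[[paste0(d, "_assessed")]],
        fraction = sprintf("%d/%d", p[[paste0(d, "_success")]],
                           p[[paste0(d, "_assessed")]]),
        weighted = p[[paste0(d, "_weighted")]],
        display = p[[paste0(d, "_display")]],
        category = as.character(p[[paste0(d, "_category")]])
      )
    }), dimensions)
    list(participant_id = p$participant_id,
         scores = dims[!purrr::map_lgl(dims, is.null)],
         complete = p$complete,
         exclusion_reason = p$exclusion_reason,
         group = as.character(p$group))
  })
  jsonlite::write_json(
    list(schema_version = "1.0", profiles = profile_list),
    file.path(out_dir, "profiles.json"),
    auto_unbox = TRUE, null = "null", digits = NA, pretty = TRUE)

  s <- scored$summary
  jsonlite::write_json(
    list(schema_version = "1.0", n_profiled = s$n_profiled,
         n_excluded = s$n_excluded,
         category_counts = s$category_counts, group_sizes = s$group_sizes),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  readr::write_csv(s$long, file.path(out_dir, "scores_long.csv"), na = "")

  excluded <- profiles[!profiles$complete, ]
  manifest <- write_manifest(
    out_dir,
    inputs = list(cohort = cohort_path, registry = registry_path,
                  norms = norms_path),
    registry = registry, seed = NULL,
    counts = list(read = nrow(cohort$participants),
                  scored = s$n_profiled, excluded = s$n_excluded),
    exclusions = purrr::map2(excluded$participant_id,
                             excluded$exclusion_reason,
                             function(id, r) list(participant_id = id, reason = r)))
  invisible(c(scored, list(manifest = manifest)))
}

#' Simulate a cohort and write it to disk
#'
#' @param out_dir Output directory for `cohort.csv` and `manifest.json`.
#' @param config A [cohort_config()], or `config_path` pointing at a YAML/JSON
#'   file of [cohort_config()] arguments.
#' @param config_path Optional config file; fields override nothing in
#'   `config` — supply one or the other.
#' @param seed Integer seed (overrides the config seed).
#' @return Invisibly, the generated `mob_cohort`.
#' @export
run_simulate <- function(out_dir, config = NULL, config_path = NULL,
                         seed = NULL) {
  if (!is.null(config_path)) {
    cfg_args <- read_config_file(config_path)
    known <- names(formals(cohort_config))
    bad <- setdiff(names(cfg_args), known)
    if (length(bad) > 0) {
      abort_config(sprintf("unknown simulation config field(s): %s",
                           paste(bad, collapse = ", ")))
    }
    for (f in c("archetype_weights", "modulator_prevalence", "missing_rates")) {
      if (!is.null(cfg_args[[f]])) cfg_args[[f]] <- unlist(cfg_args[[f]])
    }
    if (!is.null(cfg_args$age_range)) {
      cfg_args$age_range <- as.numeric(unlist(cfg_args$age_range))
    }
    config <- do.call(cohort_config, cfg_args)
  }
  config <- config %||% cohort_config()
  seed <- seed %||% config$seed
  cohort <- generate_cohort(config, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  write_manifest(out_dir,
                 inputs = list(config = config_path),
                 registry = default_registry(), seed = seed,
                 counts = list(generated = nrow(cohort$participants)))
  invisible(cohort)
}

#' Write the deterministic pilot fixture outcomes to disk
#'
#' Writes the dichotomized outcome vectors of [pilot_fixture()] as
#' `fixture_outcomes.csv` plus a manifest.
#'
#' @param out_dir Output directory.
#' @return Invisibly, the fixture tibble.
#' @export
run_fixture <- function(out_dir) {
  fx <- pilot_fixture()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(fx, file.path(out_dir, "fixture_outcomes.csv"), na = "")
  write_manifest(out_dir, inputs = list(), registry = default_registry(),
                 seed = NULL, counts = list(participants = 10L))
  invisible(fx)
}

write_manifest <- function(out_dir, inputs, registry, seed, counts,
                           exclusions = list()) {
  manifest <- list(
    tool = "mobscore",
    version = as.character(utils::packageVersion("mobscore")),
    registry_checksum = rlang::hash(as.data.frame(registry)),
    inputs = inputs,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    counts = counts,
    exclusions = exclusions
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  manifest
}
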