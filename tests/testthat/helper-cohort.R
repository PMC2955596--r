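# shared fixtures built in code

one_participant <- function(id = "p1", age = 70, sex = "M",
                            archetype = "prosthesis_walker") {
  tibble::tibble(participant_id = id, age = age, sex = sex,
                 archetype = archetype)
}

# dichotomize a single (item, value) for a reference participant
dich1 <- function(item_id, value = NA_real_, sites = NULL,
                  missing_code = "none", archetype = "prosthesis_walker",
                  age = 70, sex = "M", norms = default_norms()) {
  m <- new_measurement("p1", item_id, value, sites = sites,
                       missing_code = missing_code)
  dichotomize(m, norms = norms,
              participants = one_participant(age = age, sex = sex,
                                             archetype = archetype))
}

# a tiny fully-assessed cohort with known outcomes is built from outcome
# vectors directly where tests only exercise the scoring layer
outcomes_tbl <- function(pid, dimension, outcome) {
  tibble::tibble(participant_id = pid, dimension = dimension,
                 outcome = as.integer(outcome))
}
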