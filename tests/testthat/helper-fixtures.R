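# In-code fixture builders: a demographically complete respondent with no
# instrument banks, plus helpers that bolt instrument responses on.

blank_cohort <- function(n = 1, ids = sprintf("P%03d", seq_len(n))) {
  tibble::tibble(
    respondent_id = ids, age = 40L, sex = "female",
    ethnicity = "white_european", education = "medium",
    relationship_duration = 10, household_size = 2L, work_hours = 30,
    providers_visited = 2L, eq5d = 80, mini_depression = FALSE,
    mini_anxiety = FALSE, ctq = 30, lte = 0L, ldi = 1L, loneliness = 0L,
    neuroticism = 25, chronic_diseases = ""
  )
}

with_wpi <- function(cohort, n_locations, duration, hamper) {
  cohort$wpi_n_locations <- n_locations
  cohort$wpi_duration <- duration
  cohort$wpi_hamper <- hamper
  cohort
}

with_rome <- function(cohort, symptom, duration = NA_character_,
                      frequency = NA_character_, days = NA_real_,
                      hamper = NA_character_) {
  cohort[[paste0("rome_", symptom, "_duration")]] <- duration
  cohort[[paste0("rome_", symptom, "_frequency")]] <- frequency
  cohort[[paste0("rome_", symptom, "_days")]] <- days
  cohort[[paste0("rome_", symptom, "_hamper")]] <- hamper
  cohort
}

with_cdc <- function(cohort, symptom, frequency = NA_character_,
                     duration = NA_character_) {
  cohort[[paste0("cdc_", symptom, "_frequency")]] <- frequency
  cohort[[paste0("cdc_", symptom, "_duration")]] <- duration
  cohort
}

with_cis <- function(cohort, score, persistent) {
  cohort$cis_score <- score
  cohort$cis_persistent <- persistent
  cohort
}

with_scl <- function(cohort, symptom, t1, t2 = NULL) {
  cohort[[paste0("scl_", symptom, "_t1")]] <- t1
  if (!is.null(t2)) cohort[[paste0("scl_", symptom, "_t2")]] <- t2
  cohort
}

# a minimal qualifying-symptom record for classifier tests
sym_rec <- function(id, symptom, system) {
  tibble::tibble(respondent_id = id, symptom_id = symptom,
                 organ_system = system, instrument = "TEST",
                 persistent = TRUE, troublesome = TRUE, qualifies = TRUE,
                 provenance = "test")
}

# independent brute-force subgroup oracle: a direct restatement of the
# three rules, kept deliberately separate from classify_fsd()
oracle_subgroup <- function(symptom_ids, systems) {
  ids <- unique(symptom_ids)
  sys <- unique(systems[match(ids, symptom_ids)])
  if (length(ids) == 0) return("non_case")
  if (length(ids) == 1) return("single_symptom")
  if (length(unique(sys)) == 1) return("single_system")
  "multi_system"
}

# independent tie-corrected Kruskal-Wallis oracle from the textbook formula
oracle_kw <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  groups <- factor(groups)
  R <- tapply(r, groups, sum)
  n_i <- tabulate(groups, nlevels(groups))
  H <- 12 / (N * (N + 1)) * sum(R^2 / n_i) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# independent Pearson chi-square oracle from margins
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}
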