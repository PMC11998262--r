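#' Default symptom catalog
#'
#' The candidate symptoms evaluated by the qualification rules, with the
#' instrument each is measured by, its organ system, and (for ROME-III
#' symptoms) which troublesome route applies. The catalog is data, not code:
#' analyses that use a different symptom list or system mapping pass their
#' own catalog, or load one from YAML with [read_symptom_catalog()].
#'
#' ROME troublesome routes (`rome_mode`):
#' * `"frequency"` — often or more, on at least 3 days per month;
#' * `"hamper"` — hampers normal activities quite a bit or more;
#' * `"either"` — either route suffices.
#'
#' Stool-pattern symptoms default to the frequency route, bloating and
#' meal-related symptoms to the hamper route, and abdominal pain accepts
#' either.
#'
#' @return A tibble with columns `symptom_id`, `display_name`, `instrument`,
#'   `organ_system`, `rome_mode` (`NA` outside ROME).
#' @export
default_symptom_catalog <- function() {
  tibble::tribble(
    ~symptom_id,             ~display_name,                      ~instrument, ~organ_system,        ~rome_mode,
    "musculoskeletal_pain",  "Musculoskeletal pain (WPI)",       "WPI",       "musculoskeletal",    NA,
    "loose_bowel_movements", "Frequent loose bowel movements",   "ROME",      "gastrointestinal",   "frequency",
    "abdominal_pain",        "Abdominal pain",                   "ROME",      "gastrointestinal",   "either",
    "bloating",              "Feeling bloated",                  "ROME",      "gastrointestinal",   "hamper",
    "hard_stools",           "Hard stools",                      "ROME",      "gastrointestinal",   "frequency",
    "constipation",          "Constipation",                     "ROME",      "gastrointestinal",   "frequency",
    "burning_upper_stomach", "Burning sensation upper stomach",  "ROME",      "gastrointestinal",   "hamper",
    "post_meal_bloating",    "Unpleasant bloating after meals",  "ROME",      "gastrointestinal",   "hamper",
    "incomplete_meals",      "Inability to complete meals",      "ROME",      "gastrointestinal",   "hamper",
    "muscle_pain",           "Muscle pain",                      "CDC",       "musculoskeletal",    NA,
    "joint_pain",            "Joint pain",                       "CDC",       "musculoskeletal",    NA,
    "unrefreshing_sleep",    "Unrefreshing sleep",               "CDC",       "fatigue_related",    NA,
    "fatigue",               "Fatigue (CIS)",                    "CIS",       "fatigue_related",    NA,
    "difficulty_breathing",  "Difficulty breathing",             "SCL",       "cardiorespiratory",  NA,
    "hot_cold_spells",       "Hot and cold spells",              "SCL",       "neurological_other", NA,
    "nausea",                "Nausea",                           "SCL",       "gastrointestinal",   NA,
    "localised_weakness",    "Localised weakness",               "SCL",       "neurological_other", NA,
    "numbness_tingling",     "Numbness or tingling",             "SCL",       "neurological_other", NA,
    "dizziness",             "Dizziness",                        "SCL",       "neurological_other", NA
  )
}

validate_symptom_catalog <- function(catalog) {
  req <- c("symptom_id", "display_name", "instrument", "organ_system", "rome_mode")
  missing_cols <- setdiff(req, names(catalog))
  if (length(missing_cols)) {
    stop("symptom catalog is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(catalog$symptom_id)) {
    stop("symptom catalog has duplicate symptom_id values: ",
         paste(unique(catalog$symptom_id[duplicated(catalog$symptom_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad_sys <- setdiff(unique(catalog$organ_system), fsd_systems)
  if (length(bad_sys)) {
    stop("unknown organ system(s) in catalog: ",
         paste(bad_sys, collapse = ", "), call. = FALSE)
  }
  bad_inst <- setdiff(unique(catalog$instrument),
                      c("WPI", "ROME", "CDC", "CIS", "SCL"))
  if (length(bad_inst)) {
    stop("unknown instrument(s) in catalog: ",
         paste(bad_inst, collapse = ", "), call. = FALSE)
  }
  rome <- catalog[catalog$instrument == "ROME", ]
  bad_mode <- setdiff(rome$rome_mode, c("frequency", "hamper", "either"))
  if (length(bad_mode)) {
    stop("unknown rome_mode(s): ", paste(bad_mode, collapse = ", "),
         call. = FALSE)
  }
  invisible(catalog)
}

#' Read or write a symptom catalog as YAML
#'
#' @param path File path.
#' @param catalog A catalog tibble as returned by [default_symptom_catalog()].
#' @return `read_symptom_catalog()` returns a validated catalog tibble.
#' @export
read_symptom_catalog <- function(path) {
  raw <- yaml::read_yaml(path)
  catalog <- dplyr::bind_rows(lapply(raw$symptoms, function(s) {
    tibble::tibble(
      symptom_id = s$symptom_id,
      display_name = s$display_name %||% s$symptom_id,
      instrument = s$instrument,
      organ_system = s$organ_system,
      rome_mode = s$rome_mode %||% NA_character_
    )
  }))
  validate_symptom_catalog(catalog)
  catalog
}

#' @rdname read_symptom_catalog
#' @export
write_symptom_catalog <- function(catalog, path) {
  validate_symptom_catalog(catalog)
  symptoms <- lapply(seq_len(nrow(catalog)), function(i) {
    row <- as.list(catalog[i, ])
    if (is.na(row$rome_mode)) row$rome_mode <- NULL
    row
  })
  yaml::write_yaml(list(symptoms = symptoms), path)
  invisible(path)
}
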