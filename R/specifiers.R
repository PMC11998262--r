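#' Default chronic-disease catalog
#'
#' Maps self-reported chronic-disease codes to the organ system used by the
#' symptom clusters. Conditions that are not clearly attributable to one of
#' the four disease-bearing systems (e.g. cancer, diabetes) are marked
#' `unassigned` and ignored by the same-system logic. The catalog is
#' configuration: studies with their own disease inventory supply their own
#' mapping.
#'
#' @return Tibble with columns `code`, `organ_system`.
#' @export
default_disease_catalog <- function() {
  tibble::tribble(
    ~code,                  ~organ_system,
    "asthma",               "cardiorespiratory",
    "copd",                 "cardiorespiratory",
    "hypertension",         "cardiorespiratory",
    "heart_failure",        "cardiorespiratory",
    "arrhythmia",           "cardiorespiratory",
    "coronary_disease",     "cardiorespiratory",
    "crohns_disease",       "gastrointestinal",
    "ulcerative_colitis",   "gastrointestinal",
    "coeliac_disease",      "gastrointestinal",
    "liver_disease",        "gastrointestinal",
    "stomach_ulcer",        "gastrointestinal",
    "rheumatoid_arthritis", "musculoskeletal",
    "osteoarthritis",       "musculoskeletal",
    "osteoporosis",         "musculoskeletal",
    "chronic_back_disorder","musculoskeletal",
    "migraine",             "neurological_other",
    "epilepsy",             "neurological_other",
    "multiple_sclerosis",   "neurological_other",
    "neuropathy",           "neurological_other",
    "thyroid_disorder",     "neurological_other",
    "cancer",               "unassigned",
    "diabetes",             "unassigned"
  )
}

parse_disease_codes <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  trimws(strsplit(x, "[;,]")[[1]])
}

#' Same-system chronic disease specifier
#'
#' Flags, per organ system, whether a respondent both has qualifying
#' symptoms from that system and reports a chronic disease mapped to it.
#' Flags can only be set for systems present among the respondent's
#' qualifying symptoms; unassigned diseases are ignored.
#'
#' @param cohort Cohort tibble with a `chronic_diseases` column
#'   (`;`-separated codes).
#' @param classification Tibble from [classify_fsd()].
#' @param disease_catalog Tibble mapping `code` to `organ_system`.
#' @param strict If `TRUE`, unknown disease codes raise an error; by default
#'   they produce a single warning and are ignored.
#' @return Tibble with `respondent_id`, one logical `ss_<system>` column per
#'   disease-bearing system, and `ss_any`.
#' @export
same_system_disease <- function(cohort, classification,
                                disease_catalog = default_disease_catalog(),
                                strict = FALSE) {
  systems <- setdiff(fsd_systems, "fatigue_related")
  codes <- lapply(cohort$chronic_diseases %||% rep(NA_character_, nrow(cohort)),
                  parse_disease_codes)
  all_codes <- unique(unlist(codes))
  unknown <- setdiff(all_codes, disease_catalog$code)
  if (length(unknown)) {
    msg <- paste0("unknown disease code(s): ", paste(unknown, collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, "; ignored",
                                                      call. = FALSE)
  }
  disease_systems <- lapply(codes, function(cd) {
    unique(disease_catalog$organ_system[match(intersect(cd, disease_catalog$code),
                                              disease_catalog$code)])
  })
  cls <- classification[match(cohort$respondent_id, classification$respondent_id), ]
  symptom_systems <- strsplit(cls$systems, ";", fixed = TRUE)
  out <- tibble::tibble(respondent_id = cohort$respondent_id)
  for (s in systems) {
    out[[paste0("ss_", s)]] <- mapply(function(dsys, ssys) {
      s %in% ssys && s %in% dsys
    }, disease_systems, symptom_systems)
  }
  out$ss_any <- Reduce(`|`, out[paste0("ss_", systems)])
  out
}

#' Default functional-syndrome criteria sets
#'
#' Declarative threshold sets for the three specialty-specific functional
#' syndromes the package evaluates alongside FSD. These are documented
#' approximations of the CDC-1994 chronic fatigue syndrome definition, the
#' ACR-2010 / Fibromyalgia Survey Questionnaire definition, and the ROME-III
#' irritable bowel syndrome definition, expressed over the instrument fields
#' the cohort carries; every threshold is configuration.
#'
#' @return Named list with elements `cfs`, `fibromyalgia`, `ibs`.
#' @export
default_syndrome_criteria <- function() {
  list(
    cfs = list(
      cis_cutoff = 45,            # severe fatigue, above the 35 symptom cut-off
      require_persistent = TRUE,
      accompanying = c("muscle_pain", "joint_pain", "unrefreshing_sleep"),
      min_accompanying = 2
    ),
    fibromyalgia = list(
      min_locations = 7,          # WPI pain-location count
      min_hamper = "quite_a_bit",
      min_duration = "6_months"
    ),
    ibs = list(
      min_frequency = "often",    # abdominal-pain frequency
      min_days = 3,
      min_duration = "6_months",  # strictly longer than 6 months
      association = c("loose_bowel_movements", "hard_stools", "constipation"),
      association_min_frequency = "sometimes",
      min_association = 1
    )
  )
}

#' Evaluate functional-syndrome criteria
#'
#' Computes chronic fatigue syndrome, fibromyalgia and irritable bowel
#' syndrome flags from the instrument banks against a declarative criteria
#' set. When a required bank is absent from the cohort the syndrome is
#' *undetermined* (`NA`), distinct from `FALSE`, so complete-case filters
#' can act on it; a message records which banks were missing.
#'
#' @param cohort Cohort tibble.
#' @param criteria Criteria list, see [default_syndrome_criteria()].
#' @param catalog Symptom catalog (used for the CDC accompanying-symptom
#'   rule).
#' @return Tibble with `respondent_id`, logical `cfs`, `fibromyalgia`,
#'   `ibs` (possibly `NA`), and `n_syndromes` (`NA` when any flag is
#'   undetermined).
#' @export
syndrome_criteria <- function(cohort, criteria = default_syndrome_criteria(),
                              catalog = default_symptom_catalog()) {
  n <- nrow(cohort)
  ids <- cohort$respondent_id

  # chronic fatigue syndrome: severe persistent fatigue + accompanying
  # CDC symptoms at qualifying frequency/duration
  if (!"cis_score" %in% names(cohort)) {
    message("syndrome_criteria: CIS bank absent; CFS undetermined")
    cfs <- rep(NA, n)
  } else {
    cc <- criteria$cfs
    severe <- na_false(cohort$cis_score >= cc$cis_cutoff)
    persistent <- if (cc$require_persistent) {
      if ("cis_persistent" %in% names(cohort)) na_false(cohort$cis_persistent)
      else rep(FALSE, n)
    } else rep(TRUE, n)
    cdc_records <- qualify_cdc(cohort, catalog)
    acc <- cdc_records[cdc_records$symptom_id %in% cc$accompanying &
                         cdc_records$qualifies, , drop = FALSE]
    acc_count <- table(factor(acc$respondent_id, levels = ids))
    has_cdc <- any(startsWith(names(cohort), "cdc_"))
    if (!has_cdc) {
      message("syndrome_criteria: CDC bank absent; CFS undetermined")
      cfs <- rep(NA, n)
    } else {
      cfs <- severe & persistent & (as.integer(acc_count) >= cc$min_accompanying)
    }
  }

  # fibromyalgia: widespread pain locations + impact + duration
  fmcols <- c("wpi_n_locations", "wpi_hamper", "wpi_duration")
  if (!all(fmcols %in% names(cohort))) {
    message("syndrome_criteria: WPI bank absent; fibromyalgia undetermined")
    fm <- rep(NA, n)
  } else {
    fc <- criteria$fibromyalgia
    fm <- na_false(cohort$wpi_n_locations >= fc$min_locations) &
      likert_at_least(cohort$wpi_hamper, fc$min_hamper, fsd_scales$hamper) &
      likert_at_least(cohort$wpi_duration, fc$min_duration, fsd_scales$duration)
  }

  # irritable bowel syndrome: frequent abdominal pain + stool-pattern
  # association
  ic <- criteria$ibs
  pain_cols <- c("rome_abdominal_pain_frequency", "rome_abdominal_pain_days",
                 "rome_abdominal_pain_duration")
  if (!all(pain_cols %in% names(cohort))) {
    message("syndrome_criteria: ROME abdominal-pain bank absent; IBS undetermined")
    ibs <- rep(NA, n)
  } else {
    pain <- likert_at_least(cohort$rome_abdominal_pain_frequency,
                            ic$min_frequency, fsd_scales$frequency_rome) &
      na_false(cohort$rome_abdominal_pain_days >= ic$min_days) &
      likert_at_least(cohort$rome_abdominal_pain_duration, ic$min_duration,
                      fsd_scales$duration, strict = TRUE)
    assoc_cols <- paste0("rome_", ic$association, "_frequency")
    present <- assoc_cols[assoc_cols %in% names(cohort)]
    if (length(present) == 0) {
      message("syndrome_criteria: ROME stool-pattern bank absent; IBS undetermined")
      ibs <- rep(NA, n)
    } else {
      assoc_n <- Reduce(`+`, lapply(present, function(cl) {
        as.integer(likert_at_least(cohort[[cl]], ic$association_min_frequency,
                                   fsd_scales$frequency_rome))
      }))
      ibs <- pain & (assoc_n >= ic$min_association)
    }
  }

  tibble::tibble(
    respondent_id = ids,
    cfs = cfs,
    fibromyalgia = fm,
    ibs = ibs,
    n_syndromes = as.integer(cfs) + as.integer(fm) + as.integer(ibs)
  )
}

#' Tabulate functional-syndrome counts among FSD cases
#'
#' @param classification Tibble from [classify_fsd()].
#' @param profile Tibble from [syndrome_criteria()].
#' @return Tibble with `n_syndromes` (0--3), `n`, `pct` of determinate
#'   cases; counts partition the cases with determinate syndrome flags.
#' @export
syndrome_count_table <- function(classification, profile) {
  merged <- dplyr::inner_join(classification, profile, by = "respondent_id")
  cases <- merged[merged$is_case & !is.na(merged$n_syndromes), , drop = FALSE]
  tab <- tibble::tibble(n_syndromes = 0:3) |>
    dplyr::left_join(dplyr::count(cases, .data$n_syndromes, name = "n"),
                     by = "n_syndromes") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  pct = if (nrow(cases) > 0) round(100 * .data$n / nrow(cases), 1)
                        else 0)
  tab
}
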