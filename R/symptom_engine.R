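#' Symptom qualification rules
#'
#' A symptom contributes to a functional somatic disorder (FSD) diagnosis
#' only if it is *persistent* (present for at least six months) and
#' *troublesome* (moderately to severely impacting daily life). Each source
#' instrument encodes those two ideas differently, so there is one rule per
#' instrument:
#'
#' * [qualify_wpi()] — Widespread Pain Index: pain present, duration
#'   6 months **or longer**, hampering activities `quite_a_bit`+.
#' * [qualify_rome()] — ROME-III gastrointestinal symptoms: duration
#'   **longer than** 6 months, plus either frequency `often`+ on >= 3 days a
#'   month, or hampering `quite_a_bit`+, per symptom (`rome_mode`).
#' * [qualify_cdc()] — CDC Symptom Inventory: frequency
#'   `a_few_times_a_week`+ for longer than 6 months.
#' * [qualify_cis_fatigue()] — Checklist Individual Strength: fatigue
#'   severity score at or above the 35-point cut-off, with a 6-month
#'   persistence flag.
#' * [qualify_scl()] — SCL-90 somatization items: severity `moderately`+ at
#'   both questionnaire waves (the instrument asks no duration, so the
#'   second wave stands in for persistence).
#'
#' Every rule returns one row per evaluated (respondent, symptom) with
#' logical columns `persistent`, `troublesome` and
#' `qualifies = persistent & troublesome`. Missing responses never qualify.
#' [extract_symptoms()] unions the five rules and keeps qualifying records.
#'
#' @name symptom_rules
NULL

symptom_record <- function(respondent_id, symptom_id, organ_system,
                           instrument, persistent, troublesome, provenance) {
  persistent <- na_false(persistent)
  troublesome <- na_false(troublesome)
  tibble::tibble(
    respondent_id = as.character(respondent_id),
    symptom_id = symptom_id,
    organ_system = organ_system,
    instrument = instrument,
    persistent = persistent,
    troublesome = troublesome,
    qualifies = persistent & troublesome,
    provenance = provenance
  )
}

empty_symptom_records <- function() {
  symptom_record(character(), character(), character(), character(),
                 logical(), logical(), character())
}

catalog_row <- function(catalog, instrument) {
  catalog[catalog$instrument == instrument, , drop = FALSE]
}

#' @rdname symptom_rules
#' @param cohort Cohort tibble (see [load_cohort()]).
#' @param catalog Symptom catalog (see [default_symptom_catalog()]).
#' @param per_location If `TRUE`, emit one musculoskeletal pain record per
#'   `wpi_loc_*` column marked `TRUE` (symptom ids `wpi_<location>`); the
#'   default emits a single aggregate record, because the questionnaire asks
#'   duration and impact once for "musculoskeletal pain complaints".
#' @return A tibble of symptom records (possibly with `qualifies = FALSE`).
#' @export
qualify_wpi <- function(cohort, catalog = default_symptom_catalog(),
                        per_location = FALSE) {
  spec <- catalog_row(catalog, "WPI")
  if (nrow(spec) == 0 || !("wpi_duration" %in% names(cohort) ||
                           "wpi_hamper" %in% names(cohort) ||
                           "wpi_n_locations" %in% names(cohort) ||
                           any(startsWith(names(cohort), "wpi_loc_")))) {
    return(empty_symptom_records())
  }
  n <- nrow(cohort)
  loc_cols <- grep("^wpi_loc_", names(cohort), value = TRUE)
  n_loc <- if ("wpi_n_locations" %in% names(cohort)) {
    cohort$wpi_n_locations
  } else if (length(loc_cols)) {
    rowSums(matrix(vapply(loc_cols, function(cl) na_false(cohort[[cl]]),
                          logical(n)), nrow = n))
  } else {
    rep(NA_integer_, n)
  }
  pain_present <- na_false(n_loc >= 1)
  duration <- if ("wpi_duration" %in% names(cohort)) cohort$wpi_duration else rep(NA_character_, n)
  hamper <- if ("wpi_hamper" %in% names(cohort)) cohort$wpi_hamper else rep(NA_character_, n)
  no_duration <- pain_present & is.na(duration)
  if (any(no_duration)) {
    warning(sum(no_duration), " respondent(s) report pain without a ",
            "duration answer; treated as not persistent", call. = FALSE)
  }
  persistent <- likert_at_least(duration, "6_months", fsd_scales$duration)
  troublesome <- likert_at_least(hamper, "quite_a_bit", fsd_scales$hamper)
  if (!per_location || length(loc_cols) == 0) {
    keep <- pain_present
    return(symptom_record(cohort$respondent_id[keep],
                          spec$symptom_id[1], spec$organ_system[1], "WPI",
                          persistent[keep], troublesome[keep],
                          "wpi_aggregate"))
  }
  recs <- lapply(loc_cols, function(cl) {
    keep <- na_false(cohort[[cl]])
    symptom_record(cohort$respondent_id[keep],
                   sub("^wpi_loc_", "wpi_", cl), spec$organ_system[1], "WPI",
                   persistent[keep], troublesome[keep], "wpi_per_location")
  })
  dplyr::bind_rows(recs)
}

#' @rdname symptom_rules
#' @export
qualify_rome <- function(cohort, catalog = default_symptom_catalog()) {
  spec <- catalog_row(catalog, "ROME")
  if (nrow(spec) == 0) return(empty_symptom_records())
  if (any(is.na(spec$rome_mode))) {
    stop("configuration error: ROME symptom(s) without rome_mode: ",
         paste(spec$symptom_id[is.na(spec$rome_mode)], collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(cohort)
  recs <- lapply(seq_len(nrow(spec)), function(i) {
    id <- spec$symptom_id[i]
    cols <- paste0("rome_", id, c("_duration", "_frequency", "_days", "_hamper"))
    if (!any(cols %in% names(cohort))) return(NULL)
    duration <- if (cols[1] %in% names(cohort)) cohort[[cols[1]]] else rep(NA_character_, n)
    frequency <- if (cols[2] %in% names(cohort)) cohort[[cols[2]]] else rep(NA_character_, n)
    days <- if (cols[3] %in% names(cohort)) cohort[[cols[3]]] else rep(NA_real_, n)
    hamper <- if (cols[4] %in% names(cohort)) cohort[[cols[4]]] else rep(NA_character_, n)
    persistent <- likert_at_least(duration, "6_months", fsd_scales$duration,
                                  strict = TRUE)
    freq_route <- likert_at_least(frequency, "often", fsd_scales$frequency_rome) &
      na_false(days >= 3)
    hamper_route <- likert_at_least(hamper, "quite_a_bit", fsd_scales$hamper)
    troublesome <- switch(spec$rome_mode[i],
                          frequency = freq_route,
                          hamper = hamper_route,
                          either = freq_route | hamper_route)
    symptom_record(cohort$respondent_id, id, spec$organ_system[i], "ROME",
                   persistent, troublesome,
                   paste0("rome_", spec$rome_mode[i]))
  })
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0) empty_symptom_records() else out
}

#' @rdname symptom_rules
#' @export
qualify_cdc <- function(cohort, catalog = default_symptom_catalog()) {
  spec <- catalog_row(catalog, "CDC")
  if (nrow(spec) == 0) return(empty_symptom_records())
  n <- nrow(cohort)
  recs <- lapply(seq_len(nrow(spec)), function(i) {
    id <- spec$symptom_id[i]
    cols <- paste0("cdc_", id, c("_frequency", "_duration"))
    if (!any(cols %in% names(cohort))) return(NULL)
    frequency <- if (cols[1] %in% names(cohort)) cohort[[cols[1]]] else rep(NA_character_, n)
    duration <- if (cols[2] %in% names(cohort)) cohort[[cols[2]]] else rep(NA_character_, n)
    persistent <- likert_at_least(duration, "6_months", fsd_scales$duration,
                                  strict = TRUE)
    troublesome <- likert_at_least(frequency, "a_few_times_a_week",
                                   fsd_scales$frequency_cdc)
    symptom_record(cohort$respondent_id, id, spec$organ_system[i], "CDC",
                   persistent, troublesome, "cdc_frequency")
  })
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0) empty_symptom_records() else out
}

#' @rdname symptom_rules
#' @param cis_cutoff Fatigue-severity cut-off on the CIS subscale score
#'   (inclusive); 35 is the instrument's recommended cut-off.
#' @export
qualify_cis_fatigue <- function(cohort, catalog = default_symptom_catalog(),
                                cis_cutoff = 35) {
  spec <- catalog_row(catalog, "CIS")
  if (nrow(spec) == 0 || !"cis_score" %in% names(cohort)) {
    return(empty_symptom_records())
  }
  score <- cohort$cis_score
  out_of_range <- !is.na(score) & (score < 0 | score > 56)
  if (any(out_of_range)) {
    stop("data error: CIS score out of range [0, 56] for respondent(s): ",
         paste(utils::head(cohort$respondent_id[out_of_range], 5),
               collapse = ", "), call. = FALSE)
  }
  persistent <- if ("cis_persistent" %in% names(cohort)) {
    na_false(cohort$cis_persistent)
  } else {
    rep(FALSE, nrow(cohort))
  }
  troublesome <- na_false(score >= cis_cutoff)
  symptom_record(cohort$respondent_id, spec$symptom_id[1],
                 spec$organ_system[1], "CIS", persistent, troublesome,
                 paste0("cis_cutoff_", cis_cutoff))
}

#' @rdname symptom_rules
#' @param scl_gap_window Optional numeric `c(min, max)` in months: when
#'   given, the inter-wave gap (`scl_gap_months`) must fall inside the
#'   window for persistence; by default the gap is reported descriptively
#'   and not filtered on.
#' @export
qualify_scl <- function(cohort, catalog = default_symptom_catalog(),
                        scl_gap_window = NULL) {
  spec <- catalog_row(catalog, "SCL")
  if (nrow(spec) == 0) return(empty_symptom_records())
  n <- nrow(cohort)
  gap_ok <- rep(TRUE, n)
  if (!is.null(scl_gap_window)) {
    gap <- if ("scl_gap_months" %in% names(cohort)) cohort$scl_gap_months else rep(NA_real_, n)
    gap_ok <- na_false(gap >= scl_gap_window[1] & gap <= scl_gap_window[2])
  }
  recs <- lapply(seq_len(nrow(spec)), function(i) {
    id <- spec$symptom_id[i]
    c1 <- paste0("scl_", id, "_t1")
    c2 <- paste0("scl_", id, "_t2")
    if (!c1 %in% names(cohort)) return(NULL)
    t1 <- cohort[[c1]]
    if (c2 %in% names(cohort)) {
      t2 <- cohort[[c2]]
    } else {
      message("qualify_scl: second wave absent for '", id,
              "'; symptom cannot qualify")
      t2 <- rep(NA_character_, n)
    }
    troublesome <- likert_at_least(t1, "moderately", fsd_scales$severity_scl)
    persistent <- likert_at_least(t2, "moderately", fsd_scales$severity_scl) & gap_ok
    symptom_record(cohort$respondent_id, id, spec$organ_system[i], "SCL",
                   persistent, troublesome, "scl_two_wave")
  })
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0) empty_symptom_records() else out
}

#' Extract all qualifying symptoms for a cohort
#'
#' Unions the five instrument rules, keeps records with
#' `qualifies = TRUE`, deduplicates by (respondent, symptom) and returns
#' them in deterministic order (respondent id, then symptom id).
#'
#' @inheritParams qualify_wpi
#' @inheritParams qualify_cis_fatigue
#' @inheritParams qualify_scl
#' @return Tibble of qualifying symptom records.
#' @export
extract_symptoms <- function(cohort, catalog = default_symptom_catalog(),
                             per_location = FALSE, cis_cutoff = 35,
                             scl_gap_window = NULL) {
  validate_symptom_catalog(catalog)
  all <- dplyr::bind_rows(
    qualify_wpi(cohort, catalog, per_location = per_location),
    qualify_rome(cohort, catalog),
    qualify_cdc(cohort, catalog),
    qualify_cis_fatigue(cohort, catalog, cis_cutoff = cis_cutoff),
    qualify_scl(cohort, catalog, scl_gap_window = scl_gap_window)
  )
  out <- all[all$qualifies, , drop = FALSE]
  out <- out[!duplicated(out[, c("respondent_id", "symptom_id")]), , drop = FALSE]
  out[order(out$respondent_id, out$symptom_id), , drop = FALSE]
}
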