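#' FSD diagnostic subgroups
#'
#' Ordered labels for the caseness partition: `non_case` (no qualifying
#' symptom), `single_symptom` (exactly one), `single_system` (two or more
#' symptoms, all from one organ system), `multi_system` (symptoms from two
#' or more organ systems).
#'
#' @format Character vector of the four labels, in comparison order.
#' @export
fsd_subgroups <- c("non_case", "single_symptom", "single_system", "multi_system")

#' Classify respondents into FSD caseness and subgroup
#'
#' A respondent meets the FSD case definition when they have at least one
#' qualifying (persistent and troublesome) symptom. Cases are sub-classified
#' by the number of distinct symptoms and the number of distinct organ
#' systems involved. Distinctness is by symptom id: a symptom qualifying via
#' two instruments counts once.
#'
#' @param symptoms Tibble of qualifying symptom records, as returned by
#'   [extract_symptoms()]; all rows must have `qualifies = TRUE`.
#' @param respondent_ids Optional character vector of all respondent ids in
#'   the cohort; respondents with no qualifying symptom are then included as
#'   `non_case` rows. Defaults to the ids present in `symptoms`.
#' @param fatigue_as_system If `TRUE` (default) fatigue-related symptoms
#'   form a fifth organ system for subgroup purposes; if `FALSE` they are
#'   folded into `neurological_other` before counting systems.
#' @return A tibble with one row per respondent: `respondent_id`, `is_case`,
#'   `subgroup` (factor with levels [fsd_subgroups]), `n_symptoms`,
#'   `n_systems`, `systems` (`;`-separated, alphabetical).
#' @export
classify_fsd <- function(symptoms, respondent_ids = NULL,
                         fatigue_as_system = TRUE) {
  if (nrow(symptoms) > 0 && !all(symptoms$qualifies)) {
    stop("contract violation: classify_fsd() expects qualifying symptom ",
         "records only", call. = FALSE)
  }
  if (is.null(respondent_ids)) respondent_ids <- unique(symptoms$respondent_id)
  respondent_ids <- as.character(respondent_ids)
  system <- symptoms$organ_system
  if (!fatigue_as_system) {
    system[system == "fatigue_related"] <- "neurological_other"
  }
  sym <- tibble::tibble(respondent_id = symptoms$respondent_id,
                        symptom_id = symptoms$symptom_id,
                        organ_system = system)
  sym <- sym[!duplicated(sym[, c("respondent_id", "symptom_id")]), ]
  agg <- sym |>
    dplyr::group_by(.data$respondent_id) |>
    dplyr::summarise(
      n_symptoms = dplyr::n_distinct(.data$symptom_id),
      n_systems = dplyr::n_distinct(.data$organ_system),
      systems = paste(sort(unique(.data$organ_system)), collapse = ";"),
      .groups = "drop"
    )
  out <- tibble::tibble(respondent_id = respondent_ids) |>
    dplyr::left_join(agg, by = "respondent_id") |>
    dplyr::mutate(
      n_symptoms = dplyr::coalesce(.data$n_symptoms, 0L),
      n_systems = dplyr::coalesce(.data$n_systems, 0L),
      systems = dplyr::coalesce(.data$systems, ""),
      is_case = .data$n_symptoms >= 1L,
      subgroup = factor(
        dplyr::case_when(
          .data$n_symptoms == 0L ~ "non_case",
          .data$n_symptoms == 1L ~ "single_symptom",
          .data$n_systems == 1L ~ "single_system",
          TRUE ~ "multi_system"
        ),
        levels = fsd_subgroups
      )
    ) |>
    dplyr::select("respondent_id", "is_case", "subgroup", "n_symptoms",
                  "n_systems", "systems")
  out
}

#' Distribution of organ-system counts among cases
#'
#' @param classification Tibble from [classify_fsd()].
#' @return Tibble with `n_systems`, `n`, `pct` (percentage of cases, one
#'   decimal place). Empty (zero rows) when there are no cases.
#' @export
tabulate_system_counts <- function(classification) {
  cases <- classification[classification$is_case, , drop = FALSE]
  if (nrow(cases) == 0) {
    return(tibble::tibble(n_systems = integer(), n = integer(), pct = numeric()))
  }
  tab <- cases |>
    dplyr::count(.data$n_systems, name = "n") |>
    dplyr::mutate(pct = round(100 * .data$n / nrow(cases), 1))
  tab
}
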