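#' Ordered response scales used by the symptom-qualification rules
#'
#' The five instruments ask about symptom impact, frequency, severity and
#' duration on ordered Likert scales. All threshold rules in the package
#' compare positions on these orderings, never string values, so the scales
#' are defined once here.
#'
#' * `hamper` — "to what extent did the symptom hamper your normal
#'   activities"; troublesome means `quite_a_bit` or higher.
#' * `frequency_rome` — ROME-III symptom frequency; `often` or higher counts
#'   towards the frequency route.
#' * `frequency_cdc` — CDC Symptom Inventory frequency; `a_few_times_a_week`
#'   or higher is troublesome.
#' * `severity_scl` — SCL-90 somatization item severity; `moderately` or
#'   higher at both waves marks a persistent troublesome symptom.
#' * `duration` — symptom duration bands. "6 months or longer" is
#'   `>= six_months`; "longer than 6 months" is `> six_months`
#'   (i.e. `more_than_6_months` only).
#'
#' @format A named list of character vectors, each in increasing order.
#' @export
fsd_scales <- list(
  hamper = c("not_at_all", "a_little", "somewhat",
             "quite_a_bit", "a_lot", "very_much"),
  frequency_rome = c("never", "sometimes", "often",
                     "most_of_the_time", "always"),
  frequency_cdc = c("never", "rarely", "monthly",
                    "a_few_times_a_week", "everyday"),
  severity_scl = c("not_at_all", "a_little", "moderately",
                   "quite_a_bit", "extremely"),
  duration = c("lt_3_months", "3_to_6_months", "6_months",
               "more_than_6_months")
)

#' Compare Likert responses against a threshold level
#'
#' Returns `TRUE` where `x` is at or above `level` in the ordering given by
#' `scale`. Missing responses and values not on the scale never reach a
#' threshold (`FALSE`), matching the complete-case reading of the
#' qualification rules: an unanswered item cannot make a symptom qualify.
#'
#' @param x Character vector of responses.
#' @param level Threshold level (must be on the scale).
#' @param scale Character vector giving the ordering (one of [fsd_scales]).
#' @param strict If `TRUE`, require strictly above `level`.
#' @return Logical vector, `FALSE` for missing/unknown responses.
#' @export
likert_at_least <- function(x, level, scale, strict = FALSE) {
  stopifnot(level %in% scale)
  pos <- match(x, scale)
  thr <- match(level, scale)
  out <- if (strict) pos > thr else pos >= thr
  out & !is.na(pos)
}

# internal: NA -> FALSE for logical vectors
na_false <- function(x) {
  x[is.na(x)] <- FALSE
  x
}

#' Organ systems used for symptom clustering
#'
#' The four disease-bearing organ systems plus the fatigue-related symptom
#' cluster. Fatigue-related symptoms have no matching chronic-disease
#' cluster; whether they count as an organ system for subgroup purposes is
#' controlled in [classify_fsd()].
#'
#' @format Character vector.
#' @export
fsd_systems <- c("cardiorespiratory", "gastrointestinal", "musculoskeletal",
                 "neurological_other", "fatigue_related")
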