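#' Load a tabular cohort file
#'
#' Reads a CSV or TSV file with one row per respondent, optionally renaming
#' source columns to the canonical names used throughout the package via a
#' column-mapping schema. Rows that fail to parse are reported through a
#' warning (with row numbers), never silently dropped: readr keeps them with
#' `NA` in the offending fields so the exclusion step can account for them.
#'
#' The canonical columns are those produced by [generate_cohort()]:
#' demographics (`respondent_id`, `age`, `sex`, `ethnicity`, `education`,
#' `relationship_duration`, `household_size`, `work_hours`), outcomes and
#' covariates (`providers_visited`, `eq5d`, `mini_depression`,
#' `mini_anxiety`, `ctq`, `lte`, `ldi`, `loneliness`, `neuroticism`,
#' `chronic_diseases`), and the instrument banks (`wpi_*`, `rome_*`,
#' `cdc_*`, `cis_*`, `scl_*`).
#'
#' @param path Path to a CSV (`.csv`) or TSV (`.tsv`/`.txt`) file with one
#'   header row, UTF-8.
#' @param schema Optional column-mapping schema: a named character vector or
#'   list mapping canonical name -> source column name, a path to a YAML
#'   file with fields `columns` (that mapping) and optionally `required`
#'   (canonical names that must be present), or `NULL` for identity mapping.
#' @return A tibble of respondent records, one row per respondent.
#' @export
load_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  schema <- resolve_schema(schema)
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  cohort <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                              progress = FALSE)
  probs <- readr::problems(cohort)
  if (nrow(probs) > 0) {
    warning(nrow(probs), " parsing problem(s) in rows ",
            paste(utils::head(unique(probs$row), 10), collapse = ", "),
            "; affected fields read as NA, rows retained", call. = FALSE)
  }
  if (!is.null(schema$columns)) {
    mapping <- unlist(schema$columns)
    absent <- setdiff(unname(mapping), names(cohort))
    if (length(absent)) {
      stop("configuration error: schema maps to column(s) absent from file: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    names(cohort)[match(mapping, names(cohort))] <- names(mapping)
  }
  required <- schema$required %||% c("respondent_id", "age", "sex")
  missing_req <- setdiff(required, names(cohort))
  if (length(missing_req)) {
    stop("configuration error: required column(s) missing: ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  cohort$respondent_id <- as.character(cohort$respondent_id)
  dup <- unique(cohort$respondent_id[duplicated(cohort$respondent_id)])
  if (length(dup)) {
    stop("data error: duplicate respondent_id(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(cohort)
}

resolve_schema <- function(schema) {
  if (is.null(schema)) return(list(columns = NULL, required = NULL))
  if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
    raw <- yaml::read_yaml(schema)
    return(list(columns = raw$columns, required = unlist(raw$required)))
  }
  if (is.list(schema) && (!is.null(schema$columns) || !is.null(schema$required))) {
    return(list(columns = schema$columns, required = unlist(schema$required)))
  }
  list(columns = as.list(schema), required = NULL)
}

#' Write a cohort back to CSV
#'
#' Inverse of [load_cohort()] for canonical cohorts: `load_cohort(write_cohort(x, p))`
#' reproduces the field values.
#'
#' @param cohort Cohort tibble.
#' @param path Output path (CSV).
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}

#' Apply the basic-demographics exclusion rule
#'
#' Respondents who did not provide basic demographic data are excluded from
#' all analyses. Which fields count as "basic" is configurable; the default
#' (`age`, `sex`) is the minimum needed by every downstream table.
#'
#' @param cohort Cohort tibble.
#' @param required Character vector of fields that must be non-missing.
#' @return A list with elements `included` (tibble), `excluded` (tibble with
#'   an added `exclusion_reason` column) and `counts` (named integer vector).
#'   Always `nrow(included) + nrow(excluded) == nrow(cohort)`.
#' @export
apply_exclusions <- function(cohort, required = c("age", "sex")) {
  absent <- setdiff(required, names(cohort))
  if (length(absent)) {
    stop("configuration error: exclusion field(s) not in cohort: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  miss <- vapply(required, function(f) is.na(cohort[[f]]), logical(nrow(cohort)))
  if (nrow(cohort) == 1) miss <- matrix(miss, nrow = 1)
  drop <- rowSums(miss) > 0
  reasons <- apply(miss, 1, function(m) {
    if (!any(m)) NA_character_
    else paste0("basic demographics: missing ", paste(required[m], collapse = ", "))
  })
  excluded <- cohort[drop, , drop = FALSE]
  excluded$exclusion_reason <- reasons[drop]
  out <- list(
    included = cohort[!drop, , drop = FALSE],
    excluded = excluded,
    counts = c(included = sum(!drop), excluded = sum(drop))
  )
  message("apply_exclusions: ", out$counts[["included"]], " included, ",
          out$counts[["excluded"]], " excluded")
  out
}
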