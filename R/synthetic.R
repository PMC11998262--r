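#' Synthetic cohort generator configuration
#'
#' Defines the study conditions the generator emulates: cohort size,
#' demographic marginals, base rates for chronic-disease clusters and
#' psychiatric diagnoses, the planted caseness model (log-odds per
#' covariate, continuous covariates on the standardized scale), the
#' subgroup mixture among cases, the organ-system count distribution for
#' multi-system cases, the inter-wave gap for the two somatization
#' questionnaire waves, and syndrome planting probabilities among eligible
#' cases. Defaults mirror the published population frequencies: 58.6%
#' caseness; 31.3 / 17.7 / 51.9% single-symptom / single-system /
#' multi-system among cases; system counts 2:3:4 in proportion
#' 32.7 : 15.6 : 2.6 among multi-system cases; planted odds ratios from the
#' reported penalized model (musculoskeletal condition 1.78, concurrent
#' anxiety 1.57, gastrointestinal condition 1.40, providers visited 1.25
#' per SD, neurological condition 1.19, long-term difficulties 1.21 per SD,
#' male sex 0.79, loneliness 1.06 per SD); wave gap Normal(16, 10) months
#' truncated at one month.
#'
#' @param n Cohort size.
#' @param prevalence Target caseness prevalence (mean of the planted
#'   case-probability).
#' @param subgroup_probs Mixture over the three case subgroups.
#' @param multi_system_probs Distribution of the number of organ systems
#'   (names `"2"`..`"4"`) for multi-system cases.
#' @param female_fraction,age_mean,age_sd,white_fraction,education_probs
#'   Demographic marginals.
#' @param disease_rates Named base rates for chronic-disease clusters
#'   (including `unassigned`).
#' @param anxiety_rate,depression_rate Concurrent psychiatric diagnosis
#'   rates.
#' @param caseness_log_odds Named planted log-odds. Binary features enter
#'   as 0/1; continuous features (providers_visited, ldi, loneliness) on
#'   the standardized scale.
#' @param scl_gap_mean,scl_gap_sd Inter-wave gap distribution (months).
#' @param syndrome_plant Named probabilities of planting each functional
#'   syndrome among eligible cases.
#' @param extra_symptom_rate Poisson rate of extra symptoms beyond one per
#'   system for multi-system cases.
#' @param catalog Symptom catalog the emissions target.
#' @return A validated list of class `fsd_generator_config`.
#' @export
generator_config <- function(
    n = 5000,
    prevalence = 0.586,
    subgroup_probs = c(single_symptom = 0.313, single_system = 0.177,
                       multi_system = 0.510),
    multi_system_probs = c(`2` = 0.642, `3` = 0.307, `4` = 0.051),
    female_fraction = 0.59,
    age_mean = 50, age_sd = 13,
    white_fraction = 0.90,
    education_probs = c(low = 0.26, medium = 0.31, high = 0.27,
                        missing = 0.16),
    disease_rates = c(cardiorespiratory = 0.37, gastrointestinal = 0.06,
                      musculoskeletal = 0.12, neurological_other = 0.21,
                      unassigned = 0.08),
    anxiety_rate = 0.06, depression_rate = 0.03,
    caseness_log_odds = c(msk_condition = log(1.78), anxiety = log(1.57),
                          gi_condition = log(1.40),
                          providers_visited = log(1.25),
                          neuro_condition = log(1.19), ldi = log(1.21),
                          male = log(0.79), loneliness = log(1.06)),
    scl_gap_mean = 16, scl_gap_sd = 10,
    syndrome_plant = c(cfs = 0.30, fibromyalgia = 0.30, ibs = 0.35),
    extra_symptom_rate = 0.8,
    catalog = default_symptom_catalog()) {
  cfg <- list(n = n, prevalence = prevalence,
              subgroup_probs = subgroup_probs,
              multi_system_probs = multi_system_probs,
              female_fraction = female_fraction,
              age_mean = age_mean, age_sd = age_sd,
              white_fraction = white_fraction,
              education_probs = education_probs,
              disease_rates = disease_rates,
              anxiety_rate = anxiety_rate, depression_rate = depression_rate,
              caseness_log_odds = caseness_log_odds,
              scl_gap_mean = scl_gap_mean, scl_gap_sd = scl_gap_sd,
              syndrome_plant = syndrome_plant,
              extra_symptom_rate = extra_symptom_rate,
              catalog = catalog)
  class(cfg) <- "fsd_generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$n < 0) stop("generator config: n must be >= 0", call. = FALSE)
  if (cfg$prevalence < 0 || cfg$prevalence > 1) {
    stop("generator config: prevalence must lie in [0, 1]", call. = FALSE)
  }
  if (!setequal(names(cfg$subgroup_probs),
                c("single_symptom", "single_system", "multi_system")) ||
      any(cfg$subgroup_probs < 0) || sum(cfg$subgroup_probs) <= 0) {
    stop("generator config: subgroup_probs must be nonnegative weights for ",
         "single_symptom, single_system, multi_system", call. = FALSE)
  }
  ns <- as.integer(names(cfg$multi_system_probs))
  n_systems_avail <- length(unique(cfg$catalog$organ_system))
  if (any(is.na(ns)) || any(ns < 2) || any(ns > n_systems_avail)) {
    stop("generator config: multi_system_probs names must be counts in 2..",
         n_systems_avail, " (infeasible system count requested)",
         call. = FALSE)
  }
  probs <- c(cfg$female_fraction, cfg$white_fraction, cfg$education_probs,
             cfg$disease_rates, cfg$anxiety_rate, cfg$depression_rate,
             cfg$syndrome_plant)
  if (any(probs < 0 | probs > 1)) {
    stop("generator config: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(cfg$caseness_log_odds))) {
    stop("generator config: planted log-odds must be finite", call. = FALSE)
  }
  validate_symptom_catalog(cfg$catalog)
  invisible(cfg)
}

std0 <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Generate a synthetic cohort with ground truth
#'
#' Two-stage generation: a latent stage draws demographics, covariates,
#' caseness from the planted logistic model (intercept calibrated so the
#' mean case probability equals the configured prevalence), the diagnostic
#' subgroup, and the intended set of qualifying symptoms; an emission stage
#' writes questionnaire item responses such that every intended symptom
#' passes its qualification rule and no unintended symptom does. The
#' classification pipeline therefore recovers the intended subgroup exactly
#' (round trip by construction), while unintended responses carry
#' sub-threshold noise so the rules are exercised, not short-circuited.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; generation is fully reproducible.
#' @return List with `cohort` (tibble of respondent records), `truth`
#'   (tibble of intended caseness, subgroup, symptom set, syndrome flags
#'   and true case probability) and `config`.
#' @export
generate_cohort <- function(config = generator_config(), seed = 1) {
  validate_generator_config(config)
  n <- config$n
  catalog <- config$catalog
  if (n == 0) {
    g <- generate_cohort(generator_config(n = 1, catalog = catalog), seed = 1)
    return(list(cohort = g$cohort[0, ], truth = g$truth[0, ],
                config = config))
  }
  set.seed(seed)
  ids <- sprintf("R%06d", seq_len(n))

  sex <- sample(c("female", "male"), n, replace = TRUE,
                prob = c(config$female_fraction, 1 - config$female_fraction))
  age <- pmin(pmax(round(stats::rnorm(n, config$age_mean, config$age_sd)), 18L), 95L)
  ethnicity <- sample(c("white_european", "other"), n, replace = TRUE,
                      prob = c(config$white_fraction, 1 - config$white_fraction))
  education <- sample(names(config$education_probs), n, replace = TRUE,
                      prob = config$education_probs)
  relationship_duration <- pmax(0, round(stats::rnorm(n, 25, 14), 1))
  household_size <- 1L + stats::rpois(n, 1.8)
  work_hours <- pmin(pmax(round(stats::rnorm(n, 31, 12.6), 1), 0), 80)

  dr <- config$disease_rates
  dis <- lapply(dr, function(p) stats::rbinom(n, 1, p) == 1)
  anxiety <- stats::rbinom(n, 1, config$anxiety_rate) == 1
  depression <- stats::rbinom(n, 1, config$depression_rate) == 1
  providers_visited <- stats::rpois(n, 2.5)
  ldi <- stats::rpois(n, 1.9)
  lte <- stats::rpois(n, 0.75)
  loneliness <- stats::rpois(n, 0.85)
  neuroticism <- pmin(pmax(round(stats::rnorm(n, 27, 7.3), 1), 0), 48)
  ctq <- pmin(pmax(round(stats::rnorm(n, 34, 9), 1), 25), 125)
  eq5d <- pmin(pmax(round(stats::rnorm(n, 80, 20)), 0), 100)

  features <- list(
    msk_condition = as.numeric(dis$musculoskeletal),
    gi_condition = as.numeric(dis$gastrointestinal),
    neuro_condition = as.numeric(dis$neurological_other),
    cardio_condition = as.numeric(dis$cardiorespiratory),
    anxiety = as.numeric(anxiety),
    male = as.numeric(sex == "male"),
    providers_visited = std0(providers_visited),
    ldi = std0(ldi),
    loneliness = std0(loneliness)
  )
  lo <- config$caseness_log_odds
  unknown <- setdiff(names(lo), names(features))
  if (length(unknown)) {
    stop("generator config: unknown caseness feature(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  lp <- rep(0, n)
  for (nm in names(lo)) lp <- lp + lo[[nm]] * features[[nm]]
  if (config$prevalence <= 0) {
    p_case <- rep(0, n)
  } else if (config$prevalence >= 1) {
    p_case <- rep(1, n)
  } else {
    intercept <- stats::uniroot(
      function(b) mean(stats::plogis(b + lp)) - config$prevalence,
      interval = c(-30, 30), tol = 1e-10)$root
    p_case <- stats::plogis(intercept + lp)
  }
  is_case <- stats::rbinom(n, 1, p_case) == 1

  sg_probs <- config$subgroup_probs / sum(config$subgroup_probs)
  subgroup <- rep("non_case", n)
  subgroup[is_case] <- sample(names(sg_probs), sum(is_case), replace = TRUE,
                              prob = sg_probs)

  sys_syms <- split(catalog$symptom_id, catalog$organ_system)
  multi_sys_syms <- sys_syms[lengths(sys_syms) >= 2]
  ms_counts <- as.integer(names(config$multi_system_probs))
  ms_probs <- config$multi_system_probs / sum(config$multi_system_probs)

  intended <- vector("list", n)
  for (i in seq_len(n)) {
    intended[[i]] <- switch(
      subgroup[i],
      non_case = character(),
      single_symptom = sample(catalog$symptom_id, 1),
      single_system = {
        sys <- sample(names(multi_sys_syms), 1,
                      prob = lengths(multi_sys_syms))
        m <- min(2L + stats::rbinom(1, 1, 0.4), length(multi_sys_syms[[sys]]))
        sample(multi_sys_syms[[sys]], m)
      },
      multi_system = {
        nsys <- sample(ms_counts, 1, prob = ms_probs)
        systems <- sample(names(sys_syms), nsys)
        base <- vapply(systems, function(s) {
          if (length(sys_syms[[s]]) == 1) sys_syms[[s]] else sample(sys_syms[[s]], 1)
        }, character(1))
        pool <- setdiff(unlist(sys_syms[systems]), base)
        extra <- min(stats::rpois(1, config$extra_symptom_rate), length(pool))
        c(base, if (extra > 0) sample(pool, extra))
      }
    )
  }
  has <- function(id) vapply(intended, function(v) id %in% v, logical(1))

  # syndrome eligibility and planting
  cfs_elig <- has("fatigue") &
    (as.integer(has("muscle_pain")) + as.integer(has("joint_pain")) +
       as.integer(has("unrefreshing_sleep"))) >= 2
  fm_elig <- has("musculoskeletal_pain")
  ibs_elig <- has("abdominal_pain")
  plant <- config$syndrome_plant
  cfs_p <- cfs_elig & stats::rbinom(n, 1, plant[["cfs"]]) == 1
  fm_p <- fm_elig & stats::rbinom(n, 1, plant[["fibromyalgia"]]) == 1
  ibs_p <- ibs_elig & stats::rbinom(n, 1, plant[["ibs"]]) == 1

  dur_all <- fsd_scales$duration
  dur_6p <- c("6_months", "more_than_6_months")
  hamper_hi <- c("quite_a_bit", "a_lot", "very_much")
  hamper_lo <- c("not_at_all", "a_little", "somewhat")
  rfreq_hi <- c("often", "most_of_the_time", "always")
  rfreq_lo <- c("never", "sometimes")
  cfreq_hi <- c("a_few_times_a_week", "everyday")
  cfreq_lo <- c("never", "rarely", "monthly")
  scl_hi <- c("moderately", "quite_a_bit", "extremely")
  scl_lo <- c("not_at_all", "a_little")
  rs <- function(x, size) sample(x, size, replace = TRUE)

  cohort <- tibble::tibble(
    respondent_id = ids, age = age, sex = sex, ethnicity = ethnicity,
    education = education, relationship_duration = relationship_duration,
    household_size = household_size, work_hours = work_hours,
    providers_visited = providers_visited, eq5d = eq5d,
    mini_depression = depression, mini_anxiety = anxiety,
    ctq = ctq, lte = lte, ldi = ldi, loneliness = loneliness,
    neuroticism = neuroticism
  )

  disease_codes <- default_disease_catalog()
  code_pool <- split(disease_codes$code, disease_codes$organ_system)
  cohort$chronic_diseases <- vapply(seq_len(n), function(i) {
    present <- names(dr)[vapply(names(dr), function(s) dis[[s]][i], logical(1))]
    if (!length(present)) return("")
    paste(vapply(present, function(s) rs(code_pool[[s]], 1), character(1)),
          collapse = ";")
  }, character(1))

  # WPI emission
  msk_int <- has("musculoskeletal_pain")
  pain_noise <- !msk_int & stats::rbinom(n, 1, 0.25) == 1
  cohort$wpi_n_locations <- ifelse(msk_int,
                                   ifelse(fm_p, rs(7:15, n), rs(1:6, n)),
                                   ifelse(pain_noise, rs(1:3, n), 0L))
  cohort$wpi_duration <- ifelse(msk_int, rs(dur_6p, n),
                                ifelse(pain_noise, rs(dur_all, n),
                                       NA_character_))
  cohort$wpi_hamper <- ifelse(msk_int, rs(hamper_hi, n),
                              ifelse(pain_noise, rs(hamper_lo, n),
                                     NA_character_))

  # ROME emission
  rome <- catalog[catalog$instrument == "ROME", ]
  for (i in seq_len(nrow(rome))) {
    id <- rome$symptom_id[i]
    int_i <- has(id)
    freq_route <- int_i & (rome$rome_mode[i] == "frequency" |
                             (id == "abdominal_pain" & ibs_p))
    hamper_route <- int_i & !freq_route
    cohort[[paste0("rome_", id, "_duration")]] <-
      ifelse(int_i, "more_than_6_months", rs(dur_all, n))
    cohort[[paste0("rome_", id, "_frequency")]] <-
      ifelse(freq_route, rs(rfreq_hi, n), rs(rfreq_lo, n))
    cohort[[paste0("rome_", id, "_days")]] <-
      ifelse(freq_route, rs(3:20, n), rs(0:2, n))
    cohort[[paste0("rome_", id, "_hamper")]] <-
      ifelse(hamper_route, rs(hamper_hi, n), rs(hamper_lo, n))
  }
  # ensure a stool-pattern association item for planted IBS
  assoc_col <- "rome_loose_bowel_movements_frequency"
  fix <- ibs_p & cohort[[assoc_col]] == "never"
  cohort[[assoc_col]][fix] <- "sometimes"

  # CDC emission
  for (id in catalog$symptom_id[catalog$instrument == "CDC"]) {
    int_i <- has(id)
    cohort[[paste0("cdc_", id, "_frequency")]] <-
      ifelse(int_i, rs(cfreq_hi, n), rs(cfreq_lo, n))
    cohort[[paste0("cdc_", id, "_duration")]] <-
      ifelse(int_i, "more_than_6_months", rs(dur_all, n))
  }

  # CIS emission
  fat_int <- has("fatigue")
  cohort$cis_score <- ifelse(fat_int, ifelse(cfs_p, rs(45:56, n), rs(35:44, n)),
                             rs(0:34, n))
  cohort$cis_persistent <- ifelse(fat_int, TRUE, rs(c(TRUE, FALSE), n))

  # SCL emission (two waves)
  for (id in catalog$symptom_id[catalog$instrument == "SCL"]) {
    int_i <- has(id)
    cohort[[paste0("scl_", id, "_t1")]] <-
      ifelse(int_i, rs(scl_hi, n), rs(fsd_scales$severity_scl, n))
    cohort[[paste0("scl_", id, "_t2")]] <-
      ifelse(int_i, rs(scl_hi, n), rs(scl_lo, n))
  }
  cohort$scl_gap_months <- round(pmax(1, stats::rnorm(n, config$scl_gap_mean,
                                                      config$scl_gap_sd)), 1)

  truth_sys <- vapply(intended, function(v) {
    if (!length(v)) return("")
    s <- catalog$organ_system[match(v, catalog$symptom_id)]
    paste(sort(unique(s)), collapse = ";")
  }, character(1))
  truth <- tibble::tibble(
    respondent_id = ids,
    is_case = is_case,
    subgroup = factor(subgroup, levels = fsd_subgroups),
    n_symptoms = lengths(intended),
    n_systems = vapply(truth_sys, function(s) {
      if (!nzchar(s)) 0L else length(strsplit(s, ";", fixed = TRUE)[[1]])
    }, integer(1), USE.NAMES = FALSE),
    symptoms = vapply(intended, function(v) paste(sort(v), collapse = ";"),
                      character(1)),
    systems = truth_sys,
    p_case = p_case,
    cfs = cfs_p, fibromyalgia = fm_p, ibs = ibs_p,
    cfs_eligible = cfs_elig, fibromyalgia_eligible = fm_elig,
    ibs_eligible = ibs_elig
  )
  attr(truth, "caseness_log_odds") <- lo
  list(cohort = cohort, truth = truth, config = config)
}

#' Inject field-level missingness into a cohort
#'
#' Sets each listed field to `NA` independently at the stated rate,
#' deterministically by seed, to exercise the exclusion and complete-case
#' paths. Rate 0 is the identity; rate 1 blanks the field.
#'
#' @param cohort Cohort tibble.
#' @param rates Named numeric vector/list: field name -> missingness rate.
#' @param seed Integer seed.
#' @return The degraded cohort tibble.
#' @export
corrupt_cohort <- function(cohort, rates, seed = 1) {
  absent <- setdiff(names(rates), names(cohort))
  if (length(absent)) {
    stop("corrupt_cohort: field(s) not in cohort: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (any(unlist(rates) < 0 | unlist(rates) > 1)) {
    stop("corrupt_cohort: rates must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  for (f in names(rates)) {
    hit <- stats::runif(nrow(cohort)) < rates[[f]]
    cohort[[f]][hit] <- NA
  }
  cohort
}
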