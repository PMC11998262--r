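test_that("same-system disease requires matching symptom and disease systems", {
  co <- blank_cohort(2)
  co$chronic_diseases <- c("crohns_disease", "asthma")
  cl <- classify_fsd(rbind(sym_rec("P001", "abdominal_pain", "gastrointestinal"),
                           sym_rec("P002", "nausea", "gastrointestinal")),
                     respondent_ids = co$respondent_id)
  ss <- same_system_disease(co, cl)
  expect_true(ss$ss_gastrointestinal[1])   # GI symptoms + Crohn's
  expect_true(ss$ss_any[1])
  expect_false(any(unlist(ss[2, -1])))     # GI symptoms + asthma: mismatch
})

test_that("same-system flags equal a brute-force set-intersection oracle", {
  set.seed(3)
  catalog <- default_disease_catalog()
  pool <- default_symptom_catalog()
  systems <- setdiff(fsd_systems, "fatigue_related")
  for (rep in 1:10) {
    n <- 20
    co <- blank_cohort(n)
    co$chronic_diseases <- vapply(seq_len(n), function(i) {
      paste(sample(catalog$code, sample(0:3, 1)), collapse = ";")
    }, character(1))
    recs <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      k <- sample(0:3, 1)
      if (k == 0) return(NULL)
      rows <- pool[sample(nrow(pool), k), ]
      sym_rec(rep(co$respondent_id[i], k), rows$symptom_id, rows$organ_system)
    }))
    if (is.null(recs)) recs <- sym_rec(character(), character(), character())
    cl <- classify_fsd(recs, respondent_ids = co$respondent_id)
    ss <- same_system_disease(co, cl, catalog)
    for (i in seq_len(n)) {
      codes <- strsplit(co$chronic_diseases[i], ";")[[1]]
      dsys <- catalog$organ_system[match(codes, catalog$code)]
      ssys <- strsplit(cl$systems[i], ";")[[1]]
      for (s in systems) {
        expect_equal(ss[[paste0("ss_", s)]][i],
                     s %in% intersect(dsys, ssys))
      }
    }
  }
})

test_that("unassigned and unknown disease codes are handled as configured", {
  co <- blank_cohort(1)
  co$chronic_diseases <- "cancer;mystery_disease"
  cl <- classify_fsd(sym_rec("P001", "nausea", "gastrointestinal"))
  expect_warning(ss <- same_system_disease(co, cl), "mystery_disease")
  expect_false(ss$ss_any[1])  # cancer is unassigned, mystery ignored
  expect_error(suppressWarnings(same_system_disease(co, cl, strict = TRUE)),
               "mystery_disease")
})

test_that("a symptom-free respondent meets no syndrome criteria", {
  co <- blank_cohort(1)
  co <- with_wpi(co, 0L, NA_character_, NA_character_)
  co <- with_cis(co, 10, FALSE)
  co <- with_cdc(co, "muscle_pain", "never", "lt_3_months")
  co <- with_cdc(co, "joint_pain", "never", "lt_3_months")
  co <- with_cdc(co, "unrefreshing_sleep", "never", "lt_3_months")
  co <- with_rome(co, "abdominal_pain", "lt_3_months", "never", 0, "not_at_all")
  co <- with_rome(co, "loose_bowel_movements", "lt_3_months", "never", 0,
                  "not_at_all")
  prof <- syndrome_criteria(co)
  expect_false(prof$cfs)
  expect_false(prof$fibromyalgia)
  expect_false(prof$ibs)
  expect_equal(prof$n_syndromes, 0L)
})

test_that("fibromyalgia is met exactly at the configured boundary", {
  crit <- default_syndrome_criteria()
  co <- with_wpi(blank_cohort(2),
                 c(crit$fibromyalgia$min_locations,
                   crit$fibromyalgia$min_locations - 1L),
                 "6_months", "quite_a_bit")
  co <- with_cis(co, 0, FALSE)
  co <- with_cdc(co, "muscle_pain", "never", "lt_3_months")
  co <- with_rome(co, "abdominal_pain", "lt_3_months", "never", 0, "not_at_all")
  co <- with_rome(co, "loose_bowel_movements", "lt_3_months", "never", 0,
                  "not_at_all")
  prof <- syndrome_criteria(co, crit)
  expect_true(prof$fibromyalgia[1])
  expect_false(prof$fibromyalgia[2])
})

test_that("a missing instrument bank leaves the syndrome undetermined, not false", {
  co <- blank_cohort(1)   # no banks at all
  expect_message(prof <- syndrome_criteria(co), "undetermined")
  expect_true(is.na(prof$cfs))
  expect_true(is.na(prof$fibromyalgia))
  expect_true(is.na(prof$ibs))
  expect_true(is.na(prof$n_syndromes))
})

test_that("syndrome flags equal an independent recoding of the same criteria", {
  set.seed(9)
  crit <- default_syndrome_criteria()
  n <- 200
  co <- blank_cohort(n)
  co <- with_wpi(co, sample(0:15, n, TRUE), sample(fsd_scales$duration, n, TRUE),
                 sample(fsd_scales$hamper, n, TRUE))
  co <- with_cis(co, sample(0:56, n, TRUE), sample(c(TRUE, FALSE), n, TRUE))
  for (s in c("muscle_pain", "joint_pain", "unrefreshing_sleep")) {
    co <- with_cdc(co, s, sample(fsd_scales$frequency_cdc, n, TRUE),
                   sample(fsd_scales$duration, n, TRUE))
  }
  for (s in c("abdominal_pain", "loose_bowel_movements", "hard_stools",
              "constipation")) {
    co <- with_rome(co, s, sample(fsd_scales$duration, n, TRUE),
                    sample(fsd_scales$frequency_rome, n, TRUE),
                    sample(0:10, n, TRUE), sample(fsd_scales$hamper, n, TRUE))
  }
  prof <- syndrome_criteria(co, crit)

  # straight-line recoding, written independently of the engine
  dur <- fsd_scales$duration; ham <- fsd_scales$hamper
  rfr <- fsd_scales$frequency_rome; cfr <- fsd_scales$frequency_cdc
  acc_q <- sapply(c("muscle_pain", "joint_pain", "unrefreshing_sleep"),
                  function(s) {
    match(co[[paste0("cdc_", s, "_frequency")]], cfr) >= 4 &
      match(co[[paste0("cdc_", s, "_duration")]], dur) == 4
  })
  cfs_o <- co$cis_score >= 45 & co$cis_persistent & rowSums(acc_q) >= 2
  fm_o <- co$wpi_n_locations >= 7 & match(co$wpi_hamper, ham) >= 4 &
    match(co$wpi_duration, dur) >= 3
  assoc <- sapply(c("loose_bowel_movements", "hard_stools", "constipation"),
                  function(s) {
    match(co[[paste0("rome_", s, "_frequency")]], rfr) >= 2
  })
  ibs_o <- match(co$rome_abdominal_pain_frequency, rfr) >= 3 &
    co$rome_abdominal_pain_days >= 3 &
    match(co$rome_abdominal_pain_duration, dur) == 4 &
    rowSums(assoc) >= 1
  expect_equal(prof$cfs, unname(cfs_o))
  expect_equal(prof$fibromyalgia, unname(fm_o))
  expect_equal(prof$ibs, unname(ibs_o))
})

test_that("syndrome-count table partitions determinate cases", {
  cl <- classify_fsd(
    dplyr::bind_rows(sym_rec("A", "fatigue", "fatigue_related"),
                     sym_rec("B", "nausea", "gastrointestinal"),
                     sym_rec("C", "dizziness", "neurological_other")),
    respondent_ids = c("A", "B", "C"))
  prof <- tibble::tibble(respondent_id = c("A", "B", "C"),
                         cfs = c(TRUE, FALSE, TRUE),
                         fibromyalgia = c(FALSE, FALSE, TRUE),
                         ibs = c(FALSE, FALSE, TRUE))
  prof$n_syndromes <- as.integer(prof$cfs) + as.integer(prof$fibromyalgia) +
    as.integer(prof$ibs)
  tab <- syndrome_count_table(cl, prof)
  expect_equal(tab$n, c(1L, 1L, 0L, 1L))
  expect_equal(sum(tab$n), 3L)

  prof0 <- prof
  prof0[, c("cfs", "fibromyalgia", "ibs")] <- FALSE
  prof0$n_syndromes <- 0L
  tab0 <- syndrome_count_table(cl, prof0)
  expect_equal(tab0$n, c(3L, 0L, 0L, 0L))
})
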