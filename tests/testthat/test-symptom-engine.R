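test_that("WPI rule matches the hand truth table over the full grid", {
  durations <- fsd_scales$duration
  hampers <- fsd_scales$hamper
  grid <- expand.grid(duration = durations, hamper = hampers,
                      stringsAsFactors = FALSE)
  co <- blank_cohort(nrow(grid))
  co <- with_wpi(co, 2L, grid$duration, grid$hamper)
  recs <- qualify_wpi(co)
  # independent enumeration: position >= that of the threshold level
  expected <- (match(grid$duration, durations) >= 3) &
    (match(grid$hamper, hampers) >= 4)
  expect_equal(recs$qualifies[match(co$respondent_id, recs$respondent_id)],
               expected)
})

test_that("WPI per-location mode emits one record per pain site", {
  co <- blank_cohort(1)
  co$wpi_loc_shoulder <- TRUE
  co$wpi_loc_knee <- TRUE
  co$wpi_loc_hip <- FALSE
  co$wpi_duration <- "6_months"
  co$wpi_hamper <- "a_lot"
  recs <- qualify_wpi(co, per_location = TRUE)
  expect_equal(nrow(recs), 2)
  expect_true(all(recs$qualifies))
  # aggregate default: one record
  co$wpi_n_locations <- 2L
  expect_equal(nrow(qualify_wpi(co)), 1)
  # troublesome but not persistent
  co$wpi_duration <- "3_to_6_months"
  co$wpi_hamper <- "very_much"
  expect_false(any(qualify_wpi(co)$qualifies))
})

test_that("WPI pain without a duration answer is flagged, not persistent", {
  co <- with_wpi(blank_cohort(1), 3L, NA_character_, "a_lot")
  expect_warning(recs <- qualify_wpi(co), "duration")
  expect_false(recs$persistent)
  expect_false(recs$qualifies)
})

test_that("ROME frequency-route symptoms match the brute-force truth table", {
  freqs <- fsd_scales$frequency_rome
  grid <- expand.grid(frequency = freqs, days = 0:5,
                      hamper = fsd_scales$hamper, stringsAsFactors = FALSE)
  co <- blank_cohort(nrow(grid))
  co <- with_rome(co, "loose_bowel_movements", "more_than_6_months",
                  grid$frequency, grid$days, grid$hamper)
  recs <- qualify_rome(co)
  expected <- (match(grid$frequency, freqs) >= 3) & (grid$days >= 3)
  expect_equal(recs$qualifies, expected)

  # persistence is strictly longer than six months
  co2 <- blank_cohort(length(fsd_scales$duration))
  co2 <- with_rome(co2, "loose_bowel_movements", fsd_scales$duration,
                   "often", 5, "not_at_all")
  recs2 <- qualify_rome(co2)
  expect_equal(recs2$persistent,
               fsd_scales$duration == "more_than_6_months")
})

test_that("ROME hamper-route and either-route follow their configured disjunct", {
  # bloating (hamper route): frequency is irrelevant
  co <- blank_cohort(2)
  co <- with_rome(co, "bloating", "more_than_6_months",
                  c("always", "sometimes"), c(20, 0),
                  c("a_little", "quite_a_bit"))
  recs <- qualify_rome(co)
  expect_equal(recs$qualifies, c(FALSE, TRUE))

  # abdominal pain (either route): the worked examples
  co2 <- blank_cohort(2)
  co2 <- with_rome(co2, "abdominal_pain",
                   c("more_than_6_months", "more_than_6_months"),
                   c("often", "sometimes"), c(4, 1),
                   c("not_at_all", "a_little"))
  recs2 <- qualify_rome(co2)
  expect_true(recs2$qualifies[1])   # 8 months, often, 4 days/month
  expect_false(recs2$qualifies[2])
})

test_that("CDC rule matches the frequency-by-duration truth table", {
  freqs <- fsd_scales$frequency_cdc
  grid <- expand.grid(frequency = freqs, duration = fsd_scales$duration,
                      stringsAsFactors = FALSE)
  co <- blank_cohort(nrow(grid))
  co <- with_cdc(co, "joint_pain", grid$frequency, grid$duration)
  recs <- qualify_cdc(co)
  expected <- (match(grid$frequency, freqs) >= 4) &
    (grid$duration == "more_than_6_months")
  expect_equal(recs$qualifies, expected)
  # everyday joint pain for two years qualifies; monthly muscle pain does not
  co2 <- with_cdc(with_cdc(blank_cohort(1), "joint_pain", "everyday",
                           "more_than_6_months"),
                  "muscle_pain", "monthly", "more_than_6_months")
  recs2 <- qualify_cdc(co2)
  expect_equal(recs2$qualifies[recs2$symptom_id == "joint_pain"], TRUE)
  expect_equal(recs2$qualifies[recs2$symptom_id == "muscle_pain"], FALSE)
})

test_that("CIS fatigue uses the inclusive 35-point cut-off with persistence", {
  co <- with_cis(blank_cohort(3), c(35, 34, 50), c(TRUE, TRUE, FALSE))
  recs <- qualify_cis_fatigue(co)
  expect_equal(recs$qualifies, c(TRUE, FALSE, FALSE))

  # oracle replay over random score/flag pairs
  set.seed(42)
  score <- sample(0:56, 100, replace = TRUE)
  flag <- sample(c(TRUE, FALSE), 100, replace = TRUE)
  co2 <- with_cis(blank_cohort(100), score, flag)
  recs2 <- qualify_cis_fatigue(co2)
  expect_equal(recs2$qualifies, score >= 35 & flag)

  expect_error(qualify_cis_fatigue(with_cis(blank_cohort(1), 60, TRUE)),
               "data error")
})

test_that("SCL qualification needs moderate severity at both waves", {
  sev <- fsd_scales$severity_scl
  grid <- expand.grid(t1 = sev, t2 = sev, stringsAsFactors = FALSE)
  co <- blank_cohort(nrow(grid))
  co <- with_scl(co, "dizziness", grid$t1, grid$t2)
  recs <- qualify_scl(co)
  expected <- (match(grid$t1, sev) >= 3) & (match(grid$t2, sev) >= 3)
  expect_equal(recs$qualifies, expected)
  expect_equal(sum(expected), 9)  # 3 x 3 of the 25 severity pairs

  # second wave absent: cannot qualify, and this is logged
  co2 <- with_scl(blank_cohort(1), "nausea", "extremely")
  expect_message(recs2 <- qualify_scl(co2), "second wave")
  expect_false(recs2$qualifies)
})

test_that("optional SCL gap window filters persistence", {
  co <- with_scl(blank_cohort(2), "dizziness", "quite_a_bit", "moderately")
  co$scl_gap_months <- c(16, 40)
  recs <- qualify_scl(co, scl_gap_window = c(6, 26))
  expect_equal(recs$qualifies, c(TRUE, FALSE))
  # no window by default
  expect_true(all(qualify_scl(co)$qualifies))
})

test_that("extract_symptoms unions the five rules deterministically", {
  expect_equal(nrow(extract_symptoms(blank_cohort(3))), 0)

  co <- blank_cohort(1)
  co <- with_wpi(co, 1L, "6_months", "quite_a_bit")
  co <- with_rome(co, "abdominal_pain", "more_than_6_months", "often", 5,
                  "not_at_all")
  co <- with_cdc(co, "joint_pain", "everyday", "more_than_6_months")
  co <- with_cis(co, 40, TRUE)
  co <- with_scl(co, "dizziness", "moderately", "extremely")
  recs <- extract_symptoms(co)
  expect_equal(nrow(recs), 5)
  expect_setequal(recs$instrument, c("WPI", "ROME", "CDC", "CIS", "SCL"))
  expect_identical(recs, extract_symptoms(co))  # deterministic
  expect_false(is.unsorted(recs$symptom_id))
})

test_that("perturbing one instrument bank never alters another's records", {
  co <- blank_cohort(4)
  co <- with_cdc(co, "muscle_pain", "a_few_times_a_week", "more_than_6_months")
  co <- with_cis(co, 45, TRUE)
  before <- qualify_cdc(co)
  co2 <- with_cis(co, 5, FALSE)   # wreck the CIS bank
  co2 <- with_rome(co2, "bloating", "lt_3_months", "never", 0, "not_at_all")
  expect_identical(qualify_cdc(co2), before)
})

test_that("raising any severity, frequency or duration never de-qualifies", {
  set.seed(7)
  for (i in 1:40) {
    co <- blank_cohort(1)
    co <- with_wpi(co, sample(0:4, 1), sample(fsd_scales$duration, 1),
                   sample(fsd_scales$hamper, 1))
    co <- with_rome(co, "loose_bowel_movements",
                    sample(fsd_scales$duration, 1),
                    sample(fsd_scales$frequency_rome, 1), sample(0:6, 1),
                    sample(fsd_scales$hamper, 1))
    base <- nrow(extract_symptoms(co))
    # bump each ordered field up one level where possible
    bump <- function(x, scale) {
      i <- match(x, scale); scale[min(i + 1, length(scale))]
    }
    co_up <- co
    co_up$wpi_duration <- bump(co$wpi_duration, fsd_scales$duration)
    co_up$wpi_hamper <- bump(co$wpi_hamper, fsd_scales$hamper)
    co_up$rome_loose_bowel_movements_frequency <-
      bump(co$rome_loose_bowel_movements_frequency, fsd_scales$frequency_rome)
    co_up$rome_loose_bowel_movements_days <-
      co$rome_loose_bowel_movements_days + 1
    co_up$rome_loose_bowel_movements_duration <-
      bump(co$rome_loose_bowel_movements_duration, fsd_scales$duration)
    expect_gte(nrow(extract_symptoms(co_up)), base)
  }
})
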