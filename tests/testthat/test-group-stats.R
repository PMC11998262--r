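test_that("Kruskal-Wallis reproduces hand-computed and degenerate values", {
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4)))
  expect_equal(kw$statistic, 2.4)   # rank sums 3 and 7, by hand
  expect_equal(kw$df, 1)

  expect_equal(kruskal_wallis(list(1:3, 1:3))$statistic, 0)
  expect_equal(kruskal_wallis(list(c(5, 5), c(5, 5, 5)))$statistic, 0)
  expect_error(kruskal_wallis(list(1:3)), "at least 2")
  expect_error(kruskal_wallis(c(1, 2, 3), factor(c("a", "a", "a"),
                                                 levels = c("a", "b"))),
               "empty")
})

test_that("Kruskal-Wallis agrees with the textbook tie-corrected oracle", {
  set.seed(21)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    sizes <- sample(3:8, k, replace = TRUE)
    x <- sample(1:6, sum(sizes), replace = TRUE)  # integers force ties
    g <- rep(seq_len(k), sizes)
    if (length(unique(x)) == 1) next
    expect_lt(abs(kruskal_wallis(x, g)$statistic - oracle_kw(x, g)), 1e-10)
  }
})

test_that("with two groups H equals the squared Dunn z", {
  set.seed(4)
  for (i in 1:10) {
    x <- sample(1:10, 24, replace = TRUE)
    g <- rep(1:2, each = 12)
    H <- kruskal_wallis(x, g)$statistic
    z <- dunn_posthoc(x, g)$z
    expect_equal(H, z^2, tolerance = 1e-10)
  }
})

test_that("epsilon squared follows H/(n-1) and its interpretation ladder", {
  expect_equal(epsilon_squared(0, 10), 0)
  expect_equal(epsilon_squared(2.4, 4), 0.8)
  expect_equal(effect_label(0.118, "epsilon_squared"), "moderate")
  expect_equal(effect_label(c(0.005, 0.0223, 0.0459, 0.2, 0.5),
                            "epsilon_squared"),
               c("negligible", "weak", "moderate", "relatively_strong",
                 "strong"))
  # boundary convention: exactly at the edge falls in the lower bin
  expect_equal(effect_label(0.1, "cramers_v"), "negligible")
  expect_equal(effect_label(c(0.162, 0.218, 0.358, 0.55), "cramers_v"),
               c("small", "small", "medium", "large"))
})

test_that("Dunn post hoc emits all pairs with Bonferroni control", {
  set.seed(8)
  x <- c(rnorm(10), rnorm(10), rnorm(10, 2), rnorm(10, 2))
  g <- rep(1:4, each = 10)
  ph <- dunn_posthoc(x, g)
  expect_equal(nrow(ph), 6)                 # k(k-1)/2 for k = 4
  expect_equal(attr(ph, "threshold"), 0.05 / 6)

  # identical groups give z = 0 for their pair
  x2 <- c(1:5, 1:5, rnorm(5, 10), rnorm(5, -3))
  ph2 <- dunn_posthoc(x2, rep(1:4, each = 5))
  row12 <- ph2[ph2$group1 == "1" & ph2$group2 == "2", ]
  expect_equal(row12$z, 0)
  expect_false(row12$significant)

  # sign of z matches the sign of the mean-rank difference (oracle)
  for (i in 1:10) {
    x3 <- sample(1:8, 28, replace = TRUE)
    g3 <- factor(rep(1:4, each = 7))
    ph3 <- dunn_posthoc(x3, g3)
    mr <- tapply(rank(x3), g3, mean)
    for (r in seq_len(nrow(ph3))) {
      d <- mr[[ph3$group1[r]]] - mr[[ph3$group2[r]]]
      expect_equal(sign(ph3$z[r]), sign(d))
    }
  }

  # Bonferroni-significant pairs are a subset of unadjusted-significant ones
  expect_true(all(ph$p_value[ph$significant] < 0.05))
  expect_error(dunn_posthoc(1:3, factor(c("a", "a", "a"), levels = c("a", "b"))),
               "nonempty")
})

test_that("chi-square matches closed forms and the margins oracle", {
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))   # proportional rows
  expect_equal(chi_square(prop)$statistic, 0)

  cs <- chi_square(rbind(c(10, 20), c(20, 10)))
  expect_equal(cs$statistic, 20 / 3)            # N(ad-bc)^2 / (r1 r2 c1 c2)
  expect_equal(cs$df, 1)

  m <- rbind(a = c(5, 0), b = c(3, 0))
  expect_error(chi_square(m), "column")
  expect_error(chi_square(rbind(c(0, 0), c(3, 2))), "row")

  set.seed(13)
  for (i in 1:50) {
    tab <- matrix(sample(1:30, 8), 2, 4)
    expect_lt(abs(chi_square(tab)$statistic - oracle_chisq(tab)), 1e-10)
    # invariant under row/column permutation
    perm <- tab[sample(2), sample(4)]
    expect_equal(chi_square(perm)$statistic, chi_square(tab)$statistic)
  }
})

test_that("Cramer's V uses the per-table n and stays within [0, 1]", {
  expect_equal(cramers_v(0, 100, 2, 4), 0)
  set.seed(14)
  for (i in 1:20) {
    tab <- matrix(sample(1:50, 8), 2, 4)
    cs <- chi_square(tab)
    V <- cramers_v(cs$statistic, cs$n, 2, 4)
    expect_gte(V, 0); expect_lte(V, 1)
  }
})

test_that("small-cell masking hides counts below threshold and round-trips", {
  tab <- matrix(c(9, 10, 0, 25), 2, 2)
  masked <- mask_small_cells(tab)
  expect_equal(masked[1, 1], "<10")
  expect_equal(masked[2, 1], "10")
  expect_equal(masked[1, 2], "<10")
  expect_identical(unmask_cells(masked), tab)
  allzero <- mask_small_cells(matrix(0, 2, 2))
  expect_true(all(allzero == "<10"))
})

test_that("comparison tables carry per-variable effective n and structure", {
  set.seed(5)
  g <- suppressMessages(generate_cohort(generator_config(n = 600), seed = 5))
  cl <- classify_fsd(extract_symptoms(g$cohort), g$cohort$respondent_id)
  dat <- dplyr::left_join(g$cohort, cl, by = "respondent_id")
  dat$eq5d[1:50] <- NA
  tabs <- compare_subgroups(dat, "subgroup",
                            continuous = c("age", "eq5d", "neuroticism"),
                            categorical = c("sex", "mini_anxiety"))
  expect_equal(tabs$continuous$variable, c("age", "eq5d", "neuroticism"))
  expect_equal(tabs$continuous$n[tabs$continuous$variable == "eq5d"], 550)
  expect_equal(tabs$continuous$n[tabs$continuous$variable == "age"], 600)
  expect_equal(tabs$categorical$variable, c("sex", "mini_anxiety"))
  expect_true(all(vapply(tabs$posthoc, nrow, integer(1)) == 6))
  expect_true(all(tabs$continuous$epsilon_squared >= 0))
  expect_true(all(tabs$categorical$cramers_v >= 0 &
                    tabs$categorical$cramers_v <= 1))
})
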