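#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected Kruskal-Wallis H with an asymptotic chi-square p-value
#' (df = k - 1). This is the omnibus test used for continuous variables in
#' the subgroup comparisons; the sample sizes this package targets make
#' exact tests irrelevant. When every value is identical across all groups
#' the statistic is defined as 0 (the usual tie correction would be 0/0).
#'
#' @param x Numeric vector of values, or a list of numeric vectors (one per
#'   group, `g` then ignored).
#' @param g Group labels, same length as `x`.
#' @return List with `statistic` (H), `df`, `p_value`, `n`, `k`.
#' @export
kruskal_wallis <- function(x, g = NULL) {
  if (is.list(x) && !is.data.frame(x)) {
    g <- rep(seq_along(x), lengths(x))
    x <- unlist(x, use.names = FALSE)
  }
  if (!is.factor(g)) g <- factor(g)
  if (nlevels(g) < 2) stop("kruskal_wallis needs at least 2 groups", call. = FALSE)
  if (any(tabulate(g, nlevels(g)) == 0)) {
    stop("kruskal_wallis: empty group(s): ",
         paste(levels(g)[tabulate(g, nlevels(g)) == 0], collapse = ", "),
         call. = FALSE)
  }
  k <- nlevels(g)
  if (length(unique(x)) == 1) {
    return(list(statistic = 0, df = k - 1,
                p_value = stats::pchisq(0, k - 1, lower.tail = FALSE),
                n = length(x), k = k))
  }
  ht <- stats::kruskal.test(x, g)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, n = length(x), k = k)
}

#' Epsilon-squared effect size for a Kruskal-Wallis test
#'
#' \eqn{\epsilon^2 = H / (n - 1)}, the rank-based analogue of eta-squared.
#'
#' @param H Kruskal-Wallis statistic.
#' @param n Total sample size across groups (>= 2).
#' @return Numeric effect size.
#' @export
epsilon_squared <- function(H, n) {
  stopifnot(n >= 2)
  H / (n - 1)
}

#' Interpretation labels for effect sizes
#'
#' Bins effect sizes into the conventional interpretation ladders, with an
#' exclusive lower boundary (a value exactly at a bin edge falls in the
#' lower bin, matching the "small > 0.1" style of statement):
#'
#' * `epsilon_squared`: negligible (<= 0.01) < weak (<= 0.04) < moderate
#'   (<= 0.16) < relatively_strong (<= 0.36) < strong.
#' * `cramers_v`: negligible (<= 0.1) < small (<= 0.3) < medium (<= 0.5)
#'   < large.
#'
#' @param value Numeric effect size(s), >= 0.
#' @param type `"epsilon_squared"` or `"cramers_v"`.
#' @return Character vector of labels.
#' @export
effect_label <- function(value, type = c("epsilon_squared", "cramers_v")) {
  type <- match.arg(type)
  bins <- switch(type,
    epsilon_squared = list(breaks = c(0.01, 0.04, 0.16, 0.36),
                           labels = c("negligible", "weak", "moderate",
                                      "relatively_strong", "strong")),
    cramers_v = list(breaks = c(0.1, 0.3, 0.5),
                     labels = c("negligible", "small", "medium", "large"))
  )
  idx <- vapply(value, function(v) sum(v > bins$breaks) + 1L, integer(1))
  bins$labels[idx]
}

#' Dunn's pairwise post hoc comparisons with Bonferroni correction
#'
#' After a Kruskal-Wallis omnibus test, compares every pair of groups on
#' the shared midranks:
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum_t (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}}
#' with the tie term summed over tied-value group sizes \eqn{t}. Family-wise
#' error is controlled by Bonferroni over the \eqn{m = k(k-1)/2} pairs:
#' significance requires an unadjusted two-sided p below
#' `alpha_family / m` (0.05/6 = 0.00833 for four groups).
#'
#' @inheritParams kruskal_wallis
#' @param alpha_family Family-wise significance level.
#' @return Tibble with one row per pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted` (Bonferroni, capped at 1), `significant`.
#'   Attributes `threshold` (`alpha_family / m`) and `m`.
#' @export
dunn_posthoc <- function(x, g = NULL, alpha_family = 0.05) {
  if (is.list(x) && !is.data.frame(x)) {
    g <- rep(seq_along(x), lengths(x))
    x <- unlist(x, use.names = FALSE)
  }
  if (!is.factor(g)) g <- factor(g)
  k <- nlevels(g)
  sizes <- tabulate(g, k)
  if (k < 2 || any(sizes == 0)) {
    stop("dunn_posthoc: every group must be nonempty", call. = FALSE)
  }
  N <- length(x)
  r <- rank(x)
  mean_ranks <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_core <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  res <- lapply(seq_len(m), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    se <- sqrt(var_core * (1 / sizes[i] + 1 / sizes[j]))
    z <- if (se == 0) 0 else (mean_ranks[i] - mean_ranks[j]) / se
    tibble::tibble(group1 = levels(g)[i], group2 = levels(g)[j],
                   z = unname(z))
  })
  out <- dplyr::bind_rows(res)
  out$p_value <- 2 * stats::pnorm(-abs(out$z))
  out$p_adjusted <- pmin(1, m * out$p_value)
  out$significant <- out$p_value < alpha_family / m
  attr(out, "threshold") <- alpha_family / m
  attr(out, "m") <- m
  out
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square without continuity correction, with
#' df = (r - 1)(c - 1). Degenerate margins are rejected with an error that
#' names the empty row or column.
#'
#' @param table Matrix of non-negative counts.
#' @return List with `statistic`, `df`, `p_value`, `n`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("chi_square: negative counts", call. = FALSE)
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0)) {
    nm <- rownames(table) %||% as.character(seq_along(rs))
    stop("chi_square: zero margin in row ",
         paste(nm[rs == 0], collapse = ", "), call. = FALSE)
  }
  if (any(cs == 0)) {
    nm <- colnames(table) %||% as.character(seq_along(cs))
    stop("chi_square: zero margin in column ",
         paste(nm[cs == 0], collapse = ", "), call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, n = sum(table))
}

#' Cramer's V effect size
#'
#' \eqn{V = \sqrt{\chi^2 / (n \min(r-1, c-1))}}. `n` is the per-analysis
#' complete-case total (the sum of the table's own cells), not the cohort
#' size.
#'
#' @param chisq Chi-square statistic.
#' @param n Table total.
#' @param r,c Table dimensions.
#' @return Numeric effect size in `[0, 1]`.
#' @export
cramers_v <- function(chisq, n, r, c) {
  stopifnot(n > 0, r >= 2, c >= 2)
  sqrt(chisq / (n * min(r - 1, c - 1)))
}

#' Mask small cells for display
#'
#' Renders counts below `threshold` as `"<threshold>"` for disclosure
#' control in published tables; the numeric table is preserved in the
#' `"unmasked"` attribute so analyses are unaffected. [unmask_cells()]
#' restores the original.
#'
#' @param table Matrix or vector of counts.
#' @param threshold Minimum publishable count (default 10).
#' @return Character object of the same shape, with attribute `"unmasked"`.
#' @export
mask_small_cells <- function(table, threshold = 10) {
  out <- ifelse(table < threshold, paste0("<", threshold),
                format(table, trim = TRUE, scientific = FALSE))
  if (is.matrix(table)) {
    out <- matrix(out, nrow = nrow(table), dimnames = dimnames(table))
  }
  attr(out, "unmasked") <- table
  attr(out, "threshold") <- threshold
  out
}

#' @rdname mask_small_cells
#' @param masked Object returned by [mask_small_cells()].
#' @export
unmask_cells <- function(masked) {
  un <- attr(masked, "unmasked")
  if (is.null(un)) stop("no unmasked values attached", call. = FALSE)
  un
}

#' Build subgroup-comparison tables
#'
#' For each continuous variable: complete-case Kruskal-Wallis across the
#' four subgroups with epsilon-squared, its interpretation label, and the
#' Dunn-Bonferroni pairwise grid. For each categorical variable: a
#' complete-case Pearson chi-square on the subgroup-by-level table with
#' Cramer's V and its label. Effective n is reported per variable, because
#' complete cases differ between variables.
#'
#' @param data Tibble containing the variables and a subgroup column.
#' @param group Name of the subgroup column (factor-like).
#' @param continuous,categorical Character vectors of variable names.
#' @param alpha_family Family-wise level for the post hoc grid.
#' @return List with `continuous` (tibble), `categorical` (tibble) and
#'   `posthoc` (named list of Dunn tibbles).
#' @export
compare_subgroups <- function(data, group, continuous = character(),
                              categorical = character(),
                              alpha_family = 0.05) {
  g_all <- data[[group]]
  cont_rows <- list(); posthoc <- list()
  for (v in continuous) {
    ok <- !is.na(data[[v]]) & !is.na(g_all)
    x <- data[[v]][ok]; g <- droplevels(factor(g_all[ok]))
    kw <- kruskal_wallis(x, g)
    eps <- epsilon_squared(kw$statistic, kw$n)
    posthoc[[v]] <- dunn_posthoc(x, g, alpha_family = alpha_family)
    cont_rows[[v]] <- tibble::tibble(
      variable = v, n = kw$n, statistic = kw$statistic, df = kw$df,
      p_value = kw$p_value, epsilon_squared = eps,
      label = effect_label(eps, "epsilon_squared")
    )
  }
  cat_rows <- list()
  for (v in categorical) {
    ok <- !is.na(data[[v]]) & !is.na(g_all)
    tab <- table(data[[v]][ok], droplevels(factor(g_all[ok])))
    cs <- chi_square(tab)
    V <- cramers_v(cs$statistic, cs$n, nrow(tab), ncol(tab))
    cat_rows[[v]] <- tibble::tibble(
      variable = v, n = cs$n, statistic = cs$statistic, df = cs$df,
      p_value = cs$p_value, cramers_v = V,
      label = effect_label(V, "cramers_v")
    )
  }
  list(continuous = dplyr::bind_rows(cont_rows),
       categorical = dplyr::bind_rows(cat_rows),
       posthoc = posthoc)
}
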