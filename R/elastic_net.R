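#' Reproducible train/test split
#'
#' @param n Number of observations (>= 10).
#' @param fraction_test Fraction held out for testing.
#' @param seed Integer seed; the same seed always yields the same split.
#' @return List with integer index vectors `train` and `test`; disjoint and
#'   exhaustive.
#' @export
split_train_test <- function(n, fraction_test = 0.2, seed = 1) {
  stopifnot(n >= 10, fraction_test > 0, fraction_test < 1)
  set.seed(seed)
  test <- sort(sample.int(n, round(n * fraction_test)))
  list(train = setdiff(seq_len(n), test), test = test)
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Penalized logistic regression by coordinate descent
#'
#' Minimises the elastic-net logistic objective
#' \deqn{-\frac{1}{n}\,\ell(\beta_0, \beta) + \lambda\left[
#'   \frac{1-\alpha}{2}\lVert\beta\rVert_2^2 + \alpha\lVert\beta\rVert_1
#'   \right]}
#' (intercept unpenalized) by cyclic coordinate descent on the iteratively
#' reweighted least-squares quadratic approximation, iterating outer
#' reweighting steps until the Karush-Kuhn-Tucker conditions hold to
#' `grad_tol`. `alpha = 1` is the lasso, `alpha = 0` ridge. At
#' `lambda = 0` the solution is the unpenalized maximum-likelihood fit.
#'
#' Predictors are expected on a common scale (see [fit_fsd_model()], which
#' standardizes continuous columns with training-set statistics); the
#' solver itself does not rescale.
#'
#' @param X Numeric matrix (n x p), no missing values.
#' @param y Binary outcome (0/1 or logical).
#' @param alpha Elastic-net mixing parameter in `[0, 1]`.
#' @param lambda Penalty strength (>= 0).
#' @param beta_init,a0_init Optional warm starts.
#' @param grad_tol Convergence tolerance on the objective gradient / KKT
#'   violation.
#' @param max_iter Maximum outer (reweighting) iterations; exceeded
#'   iterations produce a warning, e.g. under complete separation at
#'   `lambda = 0`.
#' @return Object of class `penalized_logistic`: list with `a0`
#'   (intercept), `beta` (named coefficients), `alpha`, `lambda`,
#'   `iterations`, `converged`, `grad_max`.
#' @export
fit_penalized_logistic <- function(X, y, alpha, lambda,
                                   beta_init = NULL, a0_init = NULL,
                                   grad_tol = 1e-8, max_iter = 250L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) {
    stop("contract violation: y must be binary (0/1)", call. = FALSE)
  }
  stopifnot(alpha >= 0, alpha <= 1, lambda >= 0)
  n <- nrow(X); p <- ncol(X)
  beta <- beta_init %||% numeric(p)
  pbar <- min(max(mean(y), 1e-6), 1 - 1e-6)
  a0 <- a0_init %||% stats::qlogis(pbar)
  fit <- cd_logistic(X, X * X, y, alpha, lambda, beta, a0,
                     grad_tol = grad_tol, max_iter = max_iter)
  if (!fit$converged) {
    warning("fit_penalized_logistic did not reach gradient tolerance ",
            grad_tol, " in ", max_iter, " iterations (possible separation ",
            "at small lambda); returning bounded solution", call. = FALSE)
  }
  names(fit$beta) <- colnames(X) %||% paste0("x", seq_len(p))
  structure(list(a0 = fit$a0, beta = fit$beta, alpha = alpha,
                 lambda = lambda, iterations = fit$iterations,
                 converged = fit$converged, grad_max = fit$grad_max),
            class = "penalized_logistic")
}

# Coordinate-descent core on the IRLS quadratic approximation, with the
# usual active-set strategy: cycle the nonzero coordinates to convergence,
# then one full sweep to let coordinates enter. X2 = X * X is precomputed
# so path fits can share it.
cd_logistic <- function(X, X2, y, alpha, lambda, beta, a0,
                        grad_tol = 1e-8, max_iter = 250L) {
  n <- nrow(X); p <- ncol(X)
  la <- lambda * alpha
  lr <- lambda * (1 - alpha)
  inner_tol <- max(grad_tol / 10, 1e-11)
  gmax <- Inf; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- pmin(pmax(drop(a0 + X %*% beta), -30), 30)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-5)
    z <- eta + (y - mu) / w
    wX <- w * X
    wx2 <- colSums(w * X2) / n
    wsum <- sum(w)
    r <- z - a0 - drop(X %*% beta)
    sweep_cd <- function(idx) {
      dmax <- 0
      for (j in idx) {
        bj <- beta[j]
        gj <- sum(wX[, j] * r) / n + wx2[j] * bj
        az <- abs(gj) - la
        bnew <- if (az > 0) sign(gj) * az / (wx2[j] + lr) else 0
        if (bnew != bj) {
          r <<- r - X[, j] * (bnew - bj)
          d <- abs(bnew - bj)
          if (d > dmax) dmax <- d
          beta[j] <<- bnew
        }
      }
      da <- sum(w * r) / wsum
      if (da != 0) {
        a0 <<- a0 + da
        r <<- r - da
        if (abs(da) > dmax) dmax <- abs(da)
      }
      dmax
    }
    repeat {
      d_full <- sweep_cd(seq_len(p))
      if (d_full < inner_tol) break
      repeat {
        active <- which(beta != 0)
        if (length(active) == 0) break
        if (sweep_cd(active) < inner_tol) break
      }
    }
    eta <- pmin(pmax(drop(a0 + X %*% beta), -30), 30)
    mu <- stats::plogis(eta)
    grad <- -drop(crossprod(X, y - mu)) / n + lr * beta
    kkt <- ifelse(beta != 0, abs(grad + la * sign(beta)),
                  pmax(abs(grad) - la, 0))
    gmax <- max(c(kkt, abs(mean(y - mu))))
    if (gmax < grad_tol) break
  }
  list(beta = beta, a0 = a0, iterations = it,
       converged = gmax < grad_tol, grad_max = gmax)
}

# Warm-started solution path over a decreasing lambda sequence; shares the
# squared design across fits. Returns intercepts and a coefficient matrix
# (p x length(lambdas)).
fit_penalized_path <- function(X, y, alpha, lambdas, grad_tol = 1e-7) {
  X <- as.matrix(X)
  X2 <- X * X
  p <- ncol(X)
  beta <- numeric(p)
  a0 <- stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  betas <- matrix(NA_real_, nrow = p, ncol = length(lambdas))
  a0s <- numeric(length(lambdas))
  for (li in seq_along(lambdas)) {
    fit <- cd_logistic(X, X2, y, alpha, lambdas[li], beta, a0,
                       grad_tol = grad_tol)
    beta <- fit$beta; a0 <- fit$a0
    betas[, li] <- beta
    a0s[li] <- a0
  }
  list(betas = betas, a0s = a0s, lambdas = lambdas)
}

#' @rdname fit_penalized_logistic
#' @param object Fitted `penalized_logistic` model.
#' @param newdata Matrix of predictors on the same scale as the fit.
#' @param ... Unused.
#' @return `predict()` returns fitted probabilities.
#' @export
predict.penalized_logistic <- function(object, newdata, ...) {
  stats::plogis(drop(object$a0 + as.matrix(newdata) %*% object$beta))
}

default_lambda_grid <- function(X, y, alpha, nlambda = 50,
                                lambda_min_ratio = 1e-3) {
  n <- nrow(X)
  lmax <- max(abs(crossprod(X, y - mean(y)))) / n / max(alpha, 1e-3)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

cv_loss <- function(mu, y, loss) {
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  switch(loss,
         deviance = mean(-2 * (y * log(mu) + (1 - y) * log(1 - mu))),
         brier = mean((y - mu)^2))
}

#' Cross-validated selection of the elastic-net penalty
#'
#' Grid search over the mixing parameter `alpha` and the penalty `lambda`
#' by k-fold cross-validation. For every `(alpha, lambda)` the mean and
#' standard error of the held-out loss across folds are recorded; the
#' selected `alpha` is the one achieving the smallest mean loss,
#' `lambda_min` its minimiser, and `lambda_1se` the largest `lambda` whose
#' mean loss is within one standard error of that minimum (the
#' parsimonious "one standard error" rule). Fold assignment is
#' reproducible by `seed`.
#'
#' Both the binomial deviance and the Brier score (mean squared error of
#' the predicted probability) are available as the CV loss; deviance is the
#' default.
#'
#' @inheritParams fit_penalized_logistic
#' @param alpha_grid Candidate mixing parameters.
#' @param lambda_grid Candidate penalties; `NULL` builds a 50-point
#'   geometric grid per alpha from the smallest all-zero penalty downward.
#' @param k Number of folds (default 10); must not exceed `nrow(X)`.
#' @param seed Integer seed for fold assignment.
#' @param loss `"deviance"` or `"brier"`.
#' @return List with `cv_path` (tibble: alpha, lambda, mean_loss,
#'   se_loss), `alpha`, `lambda_min`, `lambda_1se`, `k`, `seed`, `loss`.
#' @export
cross_validate <- function(X, y, alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                           lambda_grid = NULL, k = 10, seed = 1,
                           loss = c("deviance", "brier")) {
  loss <- match.arg(loss)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (k > n) stop("cross_validate: k exceeds the number of observations",
                  call. = FALSE)
  stopifnot(length(alpha_grid) >= 1)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  path <- list()
  for (a in alpha_grid) {
    lams <- sort(lambda_grid %||% default_lambda_grid(X, y, a),
                 decreasing = TRUE)
    fold_loss <- matrix(NA_real_, nrow = k, ncol = length(lams))
    for (f in seq_len(k)) {
      tr <- fold != f
      pf <- fit_penalized_path(X[tr, , drop = FALSE], y[tr], a, lams,
                               grad_tol = 1e-7)
      mu_val <- stats::plogis(
        sweep(X[!tr, , drop = FALSE] %*% pf$betas, 2, pf$a0s, "+"))
      fold_loss[f, ] <- vapply(seq_along(lams), function(li) {
        cv_loss(mu_val[, li], y[!tr], loss)
      }, numeric(1))
    }
    path[[as.character(a)]] <- tibble::tibble(
      alpha = a, lambda = lams,
      mean_loss = colMeans(fold_loss),
      se_loss = apply(fold_loss, 2, stats::sd) / sqrt(k)
    )
  }
  cv_path <- dplyr::bind_rows(path)
  best <- cv_path[which.min(cv_path$mean_loss), ]
  at_alpha <- cv_path[cv_path$alpha == best$alpha, ]
  i_min <- which.min(at_alpha$mean_loss)
  lambda_min <- at_alpha$lambda[i_min]
  bound <- at_alpha$mean_loss[i_min] + at_alpha$se_loss[i_min]
  lambda_1se <- max(at_alpha$lambda[at_alpha$mean_loss <= bound])
  list(cv_path = cv_path, alpha = best$alpha, lambda_min = lambda_min,
       lambda_1se = lambda_1se, k = k, seed = seed, loss = loss)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) form: the probability that a random positive scores
#' above a random negative, counting ties as one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical); both classes must occur.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) {
    stop("evaluate_auc: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Assemble the caseness design matrix
#'
#' Builds the predictor set for the caseness regression: per-system
#' chronic-condition flags, concurrent psychiatric diagnoses, healthcare
#' utilisation, psychosocial scales, demographics and education dummies
#' (low as reference; the `missing` education level becomes `NA` and is
#' removed by the complete-case filter), with `is_case` as outcome.
#'
#' @param cohort Cohort tibble.
#' @param classification Tibble from [classify_fsd()].
#' @param disease_catalog Disease-code mapping.
#' @return Tibble with `respondent_id`, `is_case` and numeric predictors.
#' @export
build_design_matrix <- function(cohort, classification,
                                disease_catalog = default_disease_catalog()) {
  codes <- lapply(cohort$chronic_diseases %||% rep(NA_character_, nrow(cohort)),
                  parse_disease_codes)
  dsys <- lapply(codes, function(cd) {
    unique(disease_catalog$organ_system[match(intersect(cd, disease_catalog$code),
                                              disease_catalog$code)])
  })
  has_sys <- function(s) vapply(dsys, function(d) s %in% d, logical(1))
  cls <- classification[match(cohort$respondent_id, classification$respondent_id), ]
  edu <- cohort$education
  edu[edu == "missing"] <- NA_character_
  tibble::tibble(
    respondent_id = cohort$respondent_id,
    is_case = as.integer(cls$is_case),
    msk_condition = as.numeric(has_sys("musculoskeletal")),
    gi_condition = as.numeric(has_sys("gastrointestinal")),
    cardio_condition = as.numeric(has_sys("cardiorespiratory")),
    neuro_condition = as.numeric(has_sys("neurological_other")),
    anxiety = as.numeric(cohort$mini_anxiety),
    depression = as.numeric(cohort$mini_depression),
    providers_visited = as.numeric(cohort$providers_visited),
    ldi = as.numeric(cohort$ldi),
    lte = as.numeric(cohort$lte),
    loneliness = as.numeric(cohort$loneliness),
    neuroticism = as.numeric(cohort$neuroticism),
    ctq = as.numeric(cohort$ctq),
    work_hours = as.numeric(cohort$work_hours),
    eq5d = as.numeric(cohort$eq5d),
    male = as.numeric(cohort$sex == "male"),
    age = as.numeric(cohort$age),
    white_european = as.numeric(cohort$ethnicity == "white_european"),
    education_medium = as.numeric(edu == "medium"),
    education_high = as.numeric(edu == "high"),
    household_size = as.numeric(cohort$household_size),
    relationship_duration = as.numeric(cohort$relationship_duration)
  )
}

standardize_train_test <- function(Xtr, Xte) {
  cont <- apply(Xtr, 2, function(col) length(unique(col)) > 2)
  center <- ifelse(cont, colMeans(Xtr), 0)
  scale_ <- ifelse(cont, apply(Xtr, 2, stats::sd), 1)
  scale_[scale_ == 0 | is.na(scale_)] <- 1
  list(
    train = sweep(sweep(Xtr, 2, center), 2, scale_, "/"),
    test = if (is.null(Xte)) NULL else sweep(sweep(Xte, 2, center), 2, scale_, "/"),
    center = center, scale = scale_
  )
}

#' Fit the full caseness model
#'
#' End-to-end penalized regression for predictors of FSD caseness:
#' complete-case filtering, a reproducible 80/20 train/test split,
#' standardization of continuous predictors with training-set statistics
#' only, cross-validated selection of `(alpha, lambda)`, a final fit on the
#' training set at the chosen penalty (`lambda_1se` by default), and AUC on
#' the held-out test set.
#'
#' @param design Tibble from [build_design_matrix()].
#' @param fraction_test Held-out fraction.
#' @param alpha_grid,k,loss Passed to [cross_validate()].
#' @param seed Integer seed driving split and fold assignment.
#' @param rule `"lambda_1se"` (default) or `"lambda_min"`.
#' @return Object of class `fsd_penalized_fit`: coefficients on the
#'   standardized scale, odds ratios, selected `(alpha, lambda)`, the CV
#'   path, test AUC and bookkeeping (effective n, split indices, seed).
#' @export
fit_fsd_model <- function(design, fraction_test = 0.2,
                          alpha_grid = c(0, 0.25, 0.5, 0.75, 1), k = 10,
                          seed = 1, rule = c("lambda_1se", "lambda_min"),
                          loss = "deviance") {
  rule <- match.arg(rule)
  cc <- design[stats::complete.cases(design), , drop = FALSE]
  n_effective <- nrow(cc)
  y <- cc$is_case
  X <- as.matrix(cc[, setdiff(names(cc), c("respondent_id", "is_case"))])
  idx <- split_train_test(n_effective, fraction_test, seed)
  std <- standardize_train_test(X[idx$train, , drop = FALSE],
                                X[idx$test, , drop = FALSE])
  cv <- cross_validate(std$train, y[idx$train], alpha_grid = alpha_grid,
                       k = k, seed = seed, loss = loss)
  lambda_use <- if (rule == "lambda_1se") cv$lambda_1se else cv$lambda_min
  fit <- fit_penalized_logistic(std$train, y[idx$train], cv$alpha, lambda_use,
                                grad_tol = 1e-8)
  auc_test <- evaluate_auc(predict(fit, std$test), y[idx$test])
  structure(list(
    coefficients = fit$beta, intercept = fit$a0,
    odds_ratios = exp(fit$beta),
    alpha = cv$alpha, lambda = lambda_use, rule = rule,
    cv_path = cv$cv_path, lambda_min = cv$lambda_min,
    lambda_1se = cv$lambda_1se, auc_test = auc_test,
    n_effective = n_effective, n_train = length(idx$train),
    n_test = length(idx$test), train = idx$train, test = idx$test,
    center = std$center, scale = std$scale, seed = seed, loss = loss
  ), class = "fsd_penalized_fit")
}

#' @export
print.fsd_penalized_fit <- function(x, ...) {
  cat("Penalized logistic caseness model\n")
  cat(sprintf("  alpha = %.2f, lambda = %.4g (%s), CV loss = %s\n",
              x$alpha, x$lambda, x$rule, x$loss))
  cat(sprintf("  n = %d (train %d / test %d), test AUC = %.3f\n",
              x$n_effective, x$n_train, x$n_test, x$auc_test))
  cat(sprintf("  nonzero coefficients: %d of %d\n",
              sum(x$coefficients != 0), length(x$coefficients)))
  invisible(x)
}

#' Model report table
#'
#' Features sorted by absolute coefficient; exactly-zero coefficients —
#' predictors the penalty removed from the model — are displayed as `"."`,
#' odds ratios to two decimals.
#'
#' @param fit Object from [fit_fsd_model()] or a `penalized_logistic` fit.
#' @return Tibble with `feature`, `coefficient`, `odds_ratio`,
#'   `coefficient_display`, `odds_ratio_display`.
#' @export
report_model <- function(fit) {
  beta <- if (inherits(fit, "fsd_penalized_fit")) fit$coefficients else fit$beta
  out <- tibble::tibble(
    feature = names(beta),
    coefficient = unname(beta),
    odds_ratio = exp(unname(beta))
  )
  out <- out[order(-abs(out$coefficient)), ]
  out$coefficient_display <- ifelse(out$coefficient == 0, ".",
                                    sprintf("%.2f", out$coefficient))
  out$odds_ratio_display <- ifelse(out$coefficient == 0, ".",
                                   sprintf("%.2f", out$odds_ratio))
  out
}
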