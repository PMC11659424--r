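#' Nested cross-validation configuration
#'
#' @param k_outer,k_inner outer and inner fold counts (default 10 each).
#' @param alpha_grid elastic-net mixing values searched; 0 = ridge, 1 = lasso.
#' @param lambda_path_length length of the log-spaced lambda path (per alpha,
#'   derived from the training data).
#' @param dose_bins number of dose-quantile bins used for stratification.
#' @param seed RNG seed; the whole nested CV is deterministic given it.
#' @return A `cv_config` list.
#' @export
cv_config <- function(k_outer = 10L, k_inner = 10L,
                      alpha_grid = seq(0, 1, by = 0.1),
                      lambda_path_length = 50L, dose_bins = 3L, seed = 1L) {
  stopifnot(k_outer >= 2, k_inner >= 2, length(alpha_grid) >= 1,
            all(alpha_grid >= 0 & alpha_grid <= 1), dose_bins >= 1)
  structure(list(k_outer = as.integer(k_outer), k_inner = as.integer(k_inner),
                 alpha_grid = alpha_grid,
                 lambda_path_length = as.integer(lambda_path_length),
                 dose_bins = as.integer(dose_bins), seed = as.integer(seed)),
            class = "cv_config")
}

#' Class- and dose-stratified fold assignment
#'
#' Strata are the crossing of the class label with dose-quantile bins, so each
#' fold carries a balanced range of chlorpromazine-equivalent doses as well as
#' a balanced class mix. Subjects within a stratum are shuffled (seeded) and
#' dealt round-robin across folds with a continuing counter, guaranteeing fold
#' sizes differ by at most one. With all doses equal the binning degenerates
#' and the folds are plain class-stratified.
#'
#' @param labels binary vector (logical, 0/1, or 2-level factor).
#' @param dose non-negative numeric vector, same length.
#' @param k number of folds.
#' @param dose_bins number of quantile bins.
#' @param seed RNG seed.
#' @return Integer fold assignment in `1..k`.
#' @export
make_stratified_folds <- function(labels, dose, k, dose_bins = 3L, seed = 1L) {
  n <- length(labels)
  stopifnot(length(dose) == n, all(dose >= 0))
  if (n < k) stop("need at least k subjects")
  labels <- as.integer(as.factor(labels))
  breaks <- unique(quantile(dose, probs = seq(0, 1, length.out = dose_bins + 1)))
  bin <- if (length(breaks) <= 2) rep(1L, n) else
    as.integer(cut(dose, breaks = breaks, include.lowest = TRUE))
  stratum <- interaction(labels, bin, drop = TRUE)
  set.seed(seed)
  fold <- integer(n)
  counter <- 0L
  for (s in levels(stratum)) {
    idx <- which(stratum == s)
    idx <- idx[sample.int(length(idx))]
    for (i in idx) {
      fold[i] <- (counter %% k) + 1L
      counter <- counter + 1L
    }
  }
  if (length(unique(fold)) < k) {
    stop("stratification left ", k - length(unique(fold)),
         " fold(s) empty; use fewer dose bins or folds")
  }
  fold
}

# column standardization with training statistics; zero-variance columns kept
# with unit scale so they contribute nothing after centering
.std_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl < .Machine$double.eps] <- 1
  list(center = ctr, scale = scl)
}
.std_apply <- function(X, std) sweep(sweep(X, 2, std$center), 2, std$scale, "/")

#' Elastic-net logistic regression at fixed hyperparameters
#'
#' Minimizes mean logistic deviance plus
#' `lambda * (alpha * ||beta||_1 + (1 - alpha) * ||beta||_2^2 / 2)` on
#' training-standardized features. Deterministic.
#'
#' @param X numeric feature matrix (subjects x features), unstandardized;
#'   standardization statistics are computed here from `X` alone.
#' @param y binary outcome (logical or 0/1).
#' @param alpha elastic-net mixing in `[0, 1]`.
#' @param lambda regularization strength, `>= 0`.
#' @return An `enet_model`: coefficients on the standardized scale,
#'   intercept, and the standardization statistics; use [predict_enet()] for
#'   probabilities on new data.
#' @export
fit_enet_logistic <- function(X, y, alpha, lambda) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("y must contain both classes")
  std <- .std_fit(X)
  Xs <- .std_apply(X, std)
  # glmnet wants a decreasing path; pad above the target for stable warm starts
  lam_ref <- max(lambda, 1e-3)
  lam_seq <- sort(unique(c(lam_ref * c(16, 8, 4, 2), lambda)), decreasing = TRUE)
  fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = alpha,
                        lambda = lam_seq, standardize = FALSE,
                        maxit = 1e6, thresh = 1e-10)
  cf <- as.numeric(coef(fit, s = lambda, exact = FALSE))
  structure(list(intercept = cf[1],
                 beta = setNames(cf[-1], colnames(X)),
                 alpha = alpha, lambda = lambda, std = std),
            class = "enet_model")
}

#' @rdname fit_enet_logistic
#' @param model an `enet_model`.
#' @param Xnew new feature matrix on the original (unstandardized) scale.
#' @return Predicted probabilities of the positive class.
#' @export
predict_enet <- function(model, Xnew) {
  Xs <- .std_apply(as.matrix(Xnew), model$std)
  eta <- model$intercept + drop(Xs %*% model$beta)
  1 / (1 + exp(-eta))
}

#' Brier score
#'
#' Mean squared difference between predicted probability and binary outcome;
#' 0 is perfect, 0.25 is an uninformative constant 0.5.
#'
#' @param probs predicted probabilities in `[0, 1]`.
#' @param labels binary outcomes.
#' @return Scalar in `[0, 1]`.
#' @export
brier_score <- function(probs, labels) {
  stopifnot(length(probs) == length(labels),
            all(probs >= 0 & probs <= 1))
  mean((probs - as.numeric(labels))^2)
}

#' AUC with DeLong variance and 95 percent confidence interval
#'
#' Mann-Whitney AUC (ties credited 1/2) with the DeLong structural-components
#' variance estimator and a Wald 95 percent CI clipped to `[0, 1]`.
#'
#' @param scores predicted scores or probabilities.
#' @param labels binary outcomes (1 = positive class).
#' @return List: `auc`, `variance`, `ci_low`, `ci_high`.
#' @export
delong_auc_ci <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2) stop("both classes must be present")
  cases <- scores[y == 1]
  controls <- scores[y == 0]
  m <- length(cases)
  n <- length(controls)
  psi <- outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)   # structural components over cases
  v01 <- colMeans(psi)   # over controls
  variance <- var(v10) / m + var(v01) / n
  half <- 1.959964 * sqrt(variance)
  list(auc = auc, variance = variance,
       ci_low = max(0, auc - half), ci_high = min(1, auc + half))
}

# shared hyperparameter search: inner k-fold CV over alpha x lambda path,
# selecting by pooled inner AUC (ties -> larger lambda, then larger alpha)
.search_enet <- function(X, y, dose, k, config, seed) {
  folds <- make_stratified_folds(y, dose, k, config$dose_bins, seed)
  std_all <- .std_fit(X)
  Xs_all <- .std_apply(X, std_all)
  n <- nrow(X)
  best <- list(auc = -Inf, alpha = NA, lambda = NA)
  for (alpha in config$alpha_grid) {
    a_eff <- max(alpha, 1e-3)
    lmax <- max(abs(crossprod(Xs_all, y - mean(y)))) / (n * a_eff)
    lmax <- max(lmax, 1e-4)
    path <- exp(seq(log(lmax), log(0.01 * lmax),
                    length.out = config$lambda_path_length))
    preds <- matrix(NA_real_, n, length(path))
    ok <- TRUE
    for (f in sort(unique(folds))) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) { ok <- FALSE; break }
      std <- .std_fit(X[tr, , drop = FALSE])
      fit <- glmnet::glmnet(.std_apply(X[tr, , drop = FALSE], std), y[tr],
                            family = "binomial", alpha = alpha,
                            lambda = path, standardize = FALSE, maxit = 1e5)
      pr <- predict(fit, newx = .std_apply(X[!tr, , drop = FALSE], std),
                    s = path, type = "response")
      preds[!tr, ] <- as.matrix(pr)
    }
    if (!ok) next
    for (li in seq_along(path)) {
      pv <- preds[, li]
      auc <- delong_auc_ci(pv, y)$auc
      better <- auc > best$auc + 1e-12
      tie <- abs(auc - best$auc) <= 1e-12 &&
        (is.na(best$lambda) || path[li] > best$lambda ||
           (path[li] == best$lambda && alpha > best$alpha))
      if (better || tie) best <- list(auc = auc, alpha = alpha, lambda = path[li])
    }
  }
  if (!is.finite(best$auc)) stop("inner cross-validation failed: a fold had a single class")
  best
}

#' Dose-stratified nested cross-validation of the TRS/nTRS classifier
#'
#' For each outer fold, an inner k-fold search over the elastic-net
#' `(alpha, lambda)` grid — conducted strictly within the outer-training
#' subjects — picks the hyperparameters maximizing pooled inner AUC; the
#' winning model is refit on the full outer-training set and predicts the
#' held-out subjects. Pooled out-of-fold predictions give accuracy (threshold
#' 0.5), AUC with DeLong variance and 95 percent CI, and the Brier score. A final
#' k-fold CV on all subjects fixes the reported hyperparameters, and the
#' absolute final coefficients, normalized to sum 1, give variable
#' importance.
#'
#' @param study a normalized [uptake_study()] containing nTRS and TRS
#'   subjects (TRS is the positive class).
#' @param feature_set `"all"`, `"dmn"` or `"ddp"` — selects region columns by
#'   atlas membership flags.
#' @param config a [cv_config()].
#' @return A `nested_cv_result`.
#' @export
nested_cv <- function(study, feature_set = c("all", "dmn", "ddp"),
                      config = cv_config()) {
  feature_set <- match.arg(feature_set)
  stopifnot(inherits(study, "uptake_study"), inherits(config, "cv_config"))
  if (!study$normalized) stop("study must be normalized")
  sub <- subset_study(study, group = c("nTRS", "TRS"))
  y <- as.integer(sub$subjects$group == "TRS")
  if (length(unique(y)) < 2) stop("study must contain both nTRS and TRS subjects")
  dose <- sub$subjects$cpz_equiv
  regions <- switch(feature_set,
                    all = sub$atlas$region_id,
                    dmn = subnetwork_regions(sub$atlas, "dmn"),
                    ddp = subnetwork_regions(sub$atlas, "ddp"))
  if (length(regions) == 0) stop("feature set '", feature_set, "' selects no regions")
  X <- sub$values[, regions, drop = FALSE]
  n <- nrow(X)

  outer_folds <- make_stratified_folds(y, dose, config$k_outer,
                                       config$dose_bins, config$seed)
  prob <- rep(NA_real_, n)
  fold_summary <- NULL
  for (f in sort(unique(outer_folds))) {
    tr <- outer_folds != f
    if (length(unique(y[tr])) < 2) {
      stop("outer training fold ", f, " has a single class after stratification")
    }
    best <- .search_enet(X[tr, , drop = FALSE], y[tr], dose[tr],
                         config$k_inner, config, seed = config$seed + f)
    model <- fit_enet_logistic(X[tr, , drop = FALSE], y[tr],
                               best$alpha, best$lambda)
    prob[!tr] <- predict_enet(model, X[!tr, , drop = FALSE])
    fold_summary <- rbind(fold_summary,
                          data.frame(fold = f, alpha = best$alpha,
                                     lambda = best$lambda,
                                     inner_auc = best$auc))
  }
  stopifnot(!anyNA(prob))   # every subject predicted exactly once

  acc <- mean((prob > 0.5) == (y == 1))
  auc <- delong_auc_ci(prob, y)
  brier <- brier_score(prob, y)

  final <- .search_enet(X, y, dose, config$k_outer, config,
                        seed = config$seed + 10000L)
  final_model <- fit_enet_logistic(X, y, final$alpha, final$lambda)
  ab <- abs(final_model$beta)
  importance <- if (sum(ab) > 0) ab / sum(ab) else {
    warning("final model has all-zero coefficients; importance set uniform")
    setNames(rep(1 / length(ab), length(ab)), names(ab))
  }

  structure(list(
    outer_predictions = data.frame(subject_id = sub$subjects$subject_id,
                                   group = sub$subjects$group,
                                   label = y, fold = outer_folds, prob = prob,
                                   stringsAsFactors = FALSE),
    accuracy = acc, auc = auc$auc, auc_variance = auc$variance,
    auc_ci = c(auc$ci_low, auc$ci_high), brier = brier,
    fold_summary = fold_summary,
    final_alpha = final$alpha, final_lambda = final$lambda,
    importance = importance, feature_set = feature_set, config = config),
    class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat("<nested_cv_result> features=", x$feature_set,
      " n=", nrow(x$outer_predictions),
      "\n  accuracy=", round(x$accuracy, 3),
      "  AUC=", round(x$auc, 3),
      " (95% CI ", round(x$auc_ci[1], 3), "-", round(x$auc_ci[2], 3), ")",
      "  Brier=", round(x$brier, 3),
      "\n  final alpha=", x$final_alpha,
      ", lambda=", signif(x$final_lambda, 4), "\n", sep = "")
  invisible(x)
}

#' Write nested-CV outputs to plain-text files
#'
#' @param res a `nested_cv_result`.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return Written paths, invisibly.
#' @export
write_cv_results <- function(res, dir, prefix = "cv") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jp <- file.path(dir, paste0(prefix, "_metrics.json"))
  jsonlite::write_json(list(feature_set = res$feature_set,
                            accuracy = res$accuracy, auc = res$auc,
                            auc_variance = res$auc_variance,
                            auc_ci = res$auc_ci, brier = res$brier,
                            final_alpha = res$final_alpha,
                            final_lambda = res$final_lambda,
                            seed = res$config$seed),
                       jp, auto_unbox = TRUE, digits = NA)
  pp <- file.path(dir, paste0(prefix, "_predictions.csv"))
  write.csv(res$outer_predictions, pp, row.names = FALSE)
  ip <- file.path(dir, paste0(prefix, "_importance.csv"))
  write.csv(data.frame(region_id = names(res$importance),
                       importance = unname(res$importance)),
            ip, row.names = FALSE)
  invisible(c(jp, pp, ip))
}
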