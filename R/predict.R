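## Trial-by-trial prediction: choice from theta-sequence counts, and
## correct/incorrect outcome from reactivation strength. The classifier
## contract is a binary nonlinear-margin classifier with a radial basis
## function kernel; here a kernel ridge classifier (RBF kernel, labels in
## {-1, +1}, closed-form leave-one-out residuals) fills that contract.
## Hyperparameters (regularization C and kernel width gamma) are chosen by
## random search under leave-one-out cross-validation.

rbf_kernel <- function(X, gamma, Y = X) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  exp(-gamma * pmax(d2, 0))
}

## Leave-one-out decision values of an RBF kernel ridge classifier.
## For f = K (K + lambda I)^{-1} y, the LOO prediction has the closed form
## f_i^{(-i)} = (f_i - H_ii * y_i) / (1 - H_ii), H = K (K + lambda I)^{-1}.
## With observation weights w (e.g. resampling counts), the smoother is
## H = K (W K + lambda I)^{-1} W and the same identity leaves out the
## *whole* weighted observation — duplicates produced by resampling a
## trial never sit in the training set of their own fold.
krr_loo <- function(X, y, C, gamma, w = NULL) {
  n <- length(y)
  K <- rbf_kernel(X, gamma)
  lambda <- 1 / C
  if (is.null(w)) {
    H <- K %*% solve(K + diag(lambda, n))
  } else {
    H <- K %*% solve(diag(w) %*% K + diag(lambda, n)) %*% diag(w)
  }
  f <- as.numeric(H %*% y)
  h <- pmin(diag(H), 1 - 1e-10)
  (f - h * y) / (1 - h)
}

#' Random-search RBF classifier with leave-one-out accuracy
#'
#' Draws `n_draws` (C, gamma) pairs log-uniformly (C in \[1e-2, 1e3\],
#' gamma in \[1e-3, 1e1\]), evaluates leave-one-out accuracy for each, and
#' reports the best. Features are standardized internally.
#'
#' @param X numeric feature matrix (trials x features).
#' @param y labels, any 2-level vector.
#' @param n_draws random-search draws (default 50).
#' @param seed RNG seed (draws are fixed given the seed, so the same
#'   hyperparameter candidates are reused across permutations).
#' @return list: accuracy (LOO), decision (LOO decision values), C, gamma,
#'   levels (label order; decision > 0 predicts `levels[2]`).
#' @export
fit_rbf_classifier <- function(X, y, n_draws = 50, seed = 1L, w = NULL) {
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2) stop("need exactly two classes")
  yy <- ifelse(as.character(y) == lev[2], 1, -1)
  X <- as.matrix(X)
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  set.seed(seed)
  Cs <- 10^stats::runif(n_draws, -2, 3)
  gs <- 10^stats::runif(n_draws, -3, 1)
  best <- list(accuracy = -Inf)
  for (i in seq_len(n_draws)) {
    dec <- krr_loo(Xs, yy, Cs[i], gs[i], w = w)
    acc <- if (is.null(w)) mean(sign(dec) == yy) else
      stats::weighted.mean(sign(dec) == yy, w)
    if (acc > best$accuracy) {
      best <- list(accuracy = acc, decision = dec, C = Cs[i],
                   gamma = gs[i], levels = lev)
    }
  }
  best
}

#' Predict behavioral choice from theta-sequence counts
#'
#' Features per trial are the numbers of theta sequences representing the
#' actual vs the alternative choice within a segment; labels are the
#' trial's choice (L/R). Reports leave-one-out accuracy of the selected
#' classifier and a permutation null (trial-label shuffles; significant
#' when accuracy exceeds the null's 95th percentile).
#'
#' @param features trials x 2 matrix (n_actual, n_alternative).
#' @param labels choice per trial ("L"/"R" or any 2-level vector).
#' @param n_perm label permutations (default 500).
#' @param n_draws random-search draws (default 50).
#' @param seed RNG seed.
#' @param min_trials minimum usable trials (default 10).
#' @return list of class `choice_prediction`: accuracy, p, null_95,
#'   null_ci (2.5/97.5 percentiles of the null), n_trials, C, gamma.
#' @export
predict_choice <- function(features, labels, n_perm = 500, n_draws = 50,
                           seed = 1L, min_trials = 10) {
  features <- as.matrix(features)
  if (length(unique(as.character(labels))) < 2) stop("single-class labels")
  if (nrow(features) < min_trials) stop("fewer than ", min_trials, " trials")
  fit <- fit_rbf_classifier(features, labels, n_draws, seed)
  # draw all label permutations up front: the classifier seeds the RNG
  # internally, so interleaving sample() with fits would repeat one
  # permutation over and over
  set.seed(seed + 1L)
  perms <- lapply(seq_len(n_perm), function(i) sample(labels))
  null <- vapply(perms, function(yp) {
    fit_rbf_classifier(features, yp, n_draws, seed)$accuracy
  }, numeric(1))
  thr <- stats::quantile(null, 0.95, names = FALSE)
  structure(list(accuracy = fit$accuracy,
                 p = mean(null >= fit$accuracy),
                 null_95 = thr,
                 null_ci = stats::quantile(null, c(0.025, 0.975),
                                           names = FALSE),
                 significant = fit$accuracy > thr,
                 n_trials = nrow(features), C = fit$C, gamma = fit$gamma),
            class = "choice_prediction")
}

#' ROC curve and AUC from decision values
#'
#' @param decision numeric scores (higher = positive class).
#' @param truth logical or 0/1 positives.
#' @return list: auc, fpr, tpr.
#' @export
roc_auc <- function(decision, truth) {
  truth <- as.logical(truth)
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0 || nn == 0) stop("need both classes for ROC")
  # AUC as the Mann-Whitney statistic (ties counted half)
  rk <- rank(decision)
  auc <- (sum(rk[truth]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(decision, decreasing = TRUE)
  tpr <- cumsum(truth[ord]) / np
  fpr <- cumsum(!truth[ord]) / nn
  list(auc = auc, fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Predict trial outcome from reactivation strength
#'
#' Features per trial are the mean reactivation strengths for the actual
#' and the alternative trajectory over pre-trial SWR events. Incorrect
#' trials are resampled with replacement to match the correct-trial count,
#' a classifier is trained as in [predict_choice()], and predictive power
#' is the AUC of the leave-one-out decision values; significance compares
#' the AUC with label-permutation nulls.
#'
#' @param features trials x 2 matrix (R_actual, R_alternative).
#' @param correct logical outcome per trial.
#' @param n_perm label permutations (default 500).
#' @param n_draws random-search draws (default 50).
#' @param seed RNG seed.
#' @param min_incorrect minimum incorrect trials before resampling (5).
#' @return list of class `outcome_prediction`: auc, p, null_95,
#'   significant, n_correct, n_incorrect, roc.
#' @export
predict_outcome <- function(features, correct, n_perm = 500, n_draws = 50,
                            seed = 1L, min_incorrect = 5) {
  features <- as.matrix(features)
  correct <- as.logical(correct)
  if (!any(!correct)) stop("no incorrect trials")
  if (sum(!correct) < min_incorrect) {
    stop("fewer than ", min_incorrect, " incorrect trials")
  }
  # the whole pipeline (resample incorrect trials to balance, fit, ROC)
  # is applied identically to real and label-shuffled trials; shuffling
  # happens at the trial level, before resampling. Resampling is encoded
  # as observation weights so the leave-one-out folds hold out a trial
  # together with all its resampled copies — otherwise duplicates sit in
  # their own training folds and the AUC saturates for real and null
  # alike.
  run_auc <- function(y, rseed) {
    set.seed(rseed)
    res_inc <- sample(which(!y), sum(y), replace = TRUE)
    w <- as.numeric(y)                      # each correct trial once
    tw <- table(res_inc)
    w[as.integer(names(tw))] <- as.numeric(tw)
    keep <- w > 0
    fit <- fit_rbf_classifier(features[keep, , drop = FALSE],
                              ifelse(y[keep], "correct", "incorrect"),
                              n_draws, seed, w = w[keep])
    dec <- fit$decision
    # decision > 0 predicts levels[2]; orient toward "correct" as positive
    if (fit$levels[2] != "correct") dec <- -dec
    roc_auc(dec, y[keep])
  }
  obs <- run_auc(correct, seed)
  set.seed(seed + 1L)
  perms <- lapply(seq_len(n_perm), function(i) sample(correct))
  null <- vapply(seq_len(n_perm), function(i) {
    y <- perms[[i]]
    if (!any(!y) || !any(y)) return(NA_real_)
    run_auc(y, seed + i)$auc
  }, numeric(1))
  null <- null[!is.na(null)]
  thr <- stats::quantile(null, 0.95, names = FALSE)
  structure(list(auc = obs$auc, p = mean(null >= obs$auc), null_95 = thr,
                 significant = obs$auc > thr,
                 n_correct = sum(correct), n_incorrect = sum(!correct),
                 roc = obs[c("fpr", "tpr")]),
            class = "outcome_prediction")
}
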