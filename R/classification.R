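# Cross-validated Gaussian Naive Bayes classification of diagnosis and of
# negative-symptom severity, with the full metric panel.

#' Median split of symptom scores into high/low severity
#'
#' The cutoff is the sample median of the scores supplied (the entire group
#' of psychotic patients; controls must not enter the cutoff computation).
#' `high` means strictly greater than the median, `low` means less than or
#' equal. For an even n the mean-of-middle-values median convention is
#' used.
#'
#' @param scores numeric symptom scores (>= 2).
#' @return object of class `"severity_split"`: list with `labels`
#'   (factor high/low) and `cutoff`.
#' @examples
#' median_split(c(10, 16, 20))
#' @export
median_split <- function(scores) {
  stopifnot(is.numeric(scores))
  if (length(scores) < 2L) stop("need at least 2 scores", call. = FALSE)
  cutoff <- stats::median(scores)
  labels <- factor(ifelse(scores > cutoff, "high", "low"),
                   levels = c("low", "high"))
  if (all(labels == "low")) {
    warning("degenerate split: all scores <= median, everyone labeled low",
            call. = FALSE)
  }
  structure(list(labels = labels, cutoff = cutoff),
            class = "severity_split")
}

#' @export
print.severity_split <- function(x, ...) {
  cat(sprintf("<severity_split> cutoff = %g: %d low, %d high\n", x$cutoff,
              sum(x$labels == "low"), sum(x$labels == "high")))
  invisible(x)
}

# Gaussian class-conditional Naive Bayes. Per-class variances are floored
# at 1e-9 times the overall variance so a zero-variance fold cannot produce
# degenerate densities.
.gnb_fit <- function(X, y) {
  lv <- levels(y)
  floor_var <- 1e-9 * apply(X, 2L, stats::var)
  floor_var[!is.finite(floor_var) | floor_var == 0] <- 1e-12
  stats_by <- lapply(lv, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    mu <- colMeans(Xc)
    v <- apply(Xc, 2L, function(col) {
      if (length(col) < 2L) 0 else stats::var(col)
    })
    list(mu = mu, var = pmax(v, floor_var))
  })
  names(stats_by) <- lv
  prior <- as.vector(table(y)) / length(y)
  names(prior) <- lv
  list(classes = lv, stats = stats_by, prior = prior)
}

# posterior probability of the second (positive) class
.gnb_posterior <- function(fit, X) {
  loglik <- vapply(fit$classes, function(cl) {
    st <- fit$stats[[cl]]
    rowSums(vapply(seq_len(ncol(X)), function(j) {
      stats::dnorm(X[, j], st$mu[j], sqrt(st$var[j]), log = TRUE)
    }, numeric(nrow(X)))) + log(fit$prior[[cl]])
  }, numeric(nrow(X)))
  if (!is.matrix(loglik)) loglik <- matrix(loglik, nrow = 1L)
  m <- apply(loglik, 1L, max)
  p <- exp(loglik - m)
  p[, 2L] / rowSums(p)
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin into folds, so every training set keeps both classes whenever
# each class has at least 2 members.
.stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validated Gaussian Naive Bayes classification
#'
#' Gaussian class-conditional Naive Bayes with empirical class priors,
#' refit on each training fold of a stratified k-fold split. Out-of-fold
#' posterior probabilities are pooled into a single vector and evaluated
#' once (see [evaluate_classification()]): AUC is the Mann-Whitney rank
#' statistic on the pooled posteriors, and the confusion-matrix metrics use
#' a posterior threshold of 0.5.
#'
#' The reported `auc` is the mean of per-fold AUCs: pooling posteriors
#' across folds into one ROC carries a systematic pessimistic bias under
#' the null (fold-specific calibration shifts scramble the cross-fold
#' ranking), while the per-fold average is null-calibrated. Folds whose
#' test set lacks a class contribute no AUC; if no fold is valid the
#' pooled value is used. The single-ROC value is always available as
#' `auc_pooled`.
#'
#' @param features numeric matrix or data.frame (rows = subjects).
#' @param labels binary labels; the second factor level is the positive
#'   class (coerced with the positive class last if not already a factor).
#' @param folds number of folds (default 10).
#' @param seed integer seed for the fold assignment; the report is
#'   bit-reproducible given (data, folds, seed).
#' @param positive optional value of `labels` to treat as positive.
#' @return a `"classification_report"` (see [evaluate_classification()])
#'   with `per_fold` metrics (accuracy and AUC per fold), `auc_pooled`,
#'   `seed` and `folds` recorded.
#' @export
naive_bayes_cv <- function(features, labels, folds = 10L, seed = NULL,
                           positive = NULL) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (!is.factor(labels)) labels <- factor(labels)
  if (!is.null(positive)) {
    labels <- stats::relevel(factor(labels), ref = setdiff(levels(factor(labels)),
                                                           positive)[1L])
  }
  y <- droplevels(labels)
  if (nlevels(y) != 2L) stop("labels must contain exactly 2 classes",
                             call. = FALSE)
  folds <- as.integer(folds)
  if (nrow(X) < folds) stop("fewer observations than folds", call. = FALSE)
  if (min(table(y)) < 2L) stop("each class needs at least 2 members",
                               call. = FALSE)
  fold <- .with_seed(seed, {
    f <- .stratified_folds(y, folds)
    # re-stratify in the unlikely event a training fold lost a class
    for (tries in 1:10) {
      ok <- all(vapply(seq_len(folds), function(k) {
        nlevels(droplevels(y[f != k])) == 2L
      }, logical(1)))
      if (ok) break
      f <- .stratified_folds(y, folds)
    }
    f
  })
  posterior <- numeric(nrow(X))
  per_fold <- data.frame(accuracy = rep(NA_real_, folds),
                         auc = rep(NA_real_, folds))
  rank_auc <- function(p, pos) {
    (sum(rank(p)[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
      (sum(pos) * sum(!pos))
  }
  for (k in seq_len(folds)) {
    test <- fold == k
    if (!any(test)) next
    fit <- .gnb_fit(X[!test, , drop = FALSE], droplevels(y[!test]))
    posterior[test] <- .gnb_posterior(fit, X[test, , drop = FALSE])
    pos_k <- y[test] == levels(y)[2L]
    per_fold$accuracy[k] <- mean((posterior[test] > 0.5) == pos_k)
    if (any(pos_k) && any(!pos_k)) {
      per_fold$auc[k] <- rank_auc(posterior[test], pos_k)
    }
  }
  rep <- evaluate_classification(posterior, y)
  rep$auc_pooled <- rep$auc
  if (any(!is.na(per_fold$auc))) {
    rep$auc <- mean(per_fold$auc, na.rm = TRUE)
  }
  rep$per_fold <- per_fold
  rep$seed <- if (is.null(seed)) NA_integer_ else seed
  rep$folds <- folds
  rep
}

#' Classification metric panel from pooled posteriors
#'
#' Sensitivity (true positive rate; equals recall for the positive class),
#' specificity (true negative rate), precision, recall, F-measure (harmonic
#' mean of precision and recall), AUC (Mann-Whitney rank form, ties counted
#' half) and accuracy as a percentage.
#'
#' @param posterior posterior probabilities of the positive class.
#' @param truth binary truth labels; second factor level = positive class.
#' @param threshold posterior threshold for the confusion matrix (default
#'   0.5).
#' @return object of class `"classification_report"`.
#' @export
evaluate_classification <- function(posterior, truth, threshold = 0.5) {
  if (!is.factor(truth)) truth <- factor(truth)
  truth <- droplevels(truth)
  if (nlevels(truth) != 2L) {
    stop("AUC undefined: truth contains a single class", call. = FALSE)
  }
  stopifnot(length(posterior) == length(truth))
  pos <- truth == levels(truth)[2L]
  pred <- posterior > threshold
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  rec <- sens
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  r <- rank(posterior)
  auc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
    (sum(pos) * sum(!pos))
  structure(list(sensitivity = sens, specificity = spec,
                 precision = prec, recall = rec, f_measure = f1,
                 auc = auc,
                 accuracy_percent = 100 * (tp + tn) / length(truth),
                 confusion = matrix(c(tn, fp, fn, tp), 2L, 2L,
                                    dimnames = list(predicted = c("neg", "pos"),
                                                    truth = c("neg", "pos"))),
                 posterior = posterior, truth = truth,
                 per_fold = NULL, seed = NA_integer_, folds = NA_integer_),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report>\n")
  cat(sprintf("  sensitivity %.2f  specificity %.2f  precision %.2f  recall %.2f\n",
              x$sensitivity, x$specificity, x$precision, x$recall))
  cat(sprintf("  F-measure %.2f  AUC %.2f  accuracy %.2f%%\n",
              x$f_measure, x$auc, x$accuracy_percent))
  if (!is.null(x$auc_pooled) && !identical(x$auc_pooled, x$auc)) {
    cat(sprintf("  (pooled single-ROC AUC %.2f)\n", x$auc_pooled))
  }
  invisible(x)
}
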