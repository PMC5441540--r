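#' Construct a Disorganization Index model
#'
#' A Disorganization Index is an affine combination of connectedness
#' attributes: `score = intercept + sum(coefficients * attributes)`. Higher
#' scores mean more disorganized speech (the index is anti-correlated with
#' connectedness). Coefficient names refer to attributes the pipeline
#' computes (`E`, `LCC`, `LSC`, `LCCz`, `LSCz`), optionally suffixed by
#' report type (e.g. `LSC_negative`, `LCC_dream`).
#'
#' @param intercept numeric scalar.
#' @param coefficients named numeric vector.
#' @param provenance `"fixed"` for published constants, `"fitted"` for a
#'   model estimated by [fit_disorg_index()].
#' @param fit_stats optional list (`r_squared`, `p_value`, `observed_power`,
#'   `n`, `df`).
#' @param source_reports optional character vector of report types the
#'   attributes come from.
#' @return object of class `"disorg_index"`.
#' @export
disorg_index <- function(intercept, coefficients,
                         provenance = c("fixed", "fitted"),
                         fit_stats = NULL, source_reports = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(coefficients), !is.null(names(coefficients)),
            all(nzchar(names(coefficients))))
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients,
                 provenance = provenance,
                 fit_stats = fit_stats,
                 source_reports = source_reports),
            class = "disorg_index")
}

#' Published Disorganization Index equations
#'
#' The four fixed index equations with published coefficients: three from
#' the recent-onset protocol (combined negative-image + dream attributes,
#' negative-image only, dream only) and one from the chronic-sample dream
#' protocol, whose attributes are averages over 30-word windows
#' (see [windowed_attributes()]). These are immutable constants; use
#' [fit_disorg_index()] to re-derive an index on new data.
#'
#' @return named list of `"disorg_index"` objects: `negative_dream`,
#'   `negative`, `dream`, `chronic_dream`.
#' @examples
#' m <- reference_index_models()$dream
#' predict(m, data.frame(LCC = 10, LSC = 5))  # 27.82 - 3.2 - 0.06
#' @export
reference_index_models <- function() {
  list(
    negative_dream = disorg_index(
      30.78,
      c(LSC_negative = 0.015, LSCz_negative = -2.33, LCC_dream = -0.20),
      provenance = "fixed",
      source_reports = c("image_negative", "dream")),
    negative = disorg_index(
      31.43, c(LCC = -0.30, LSC = 0.08, LSCz = -2.12),
      provenance = "fixed", source_reports = "image_negative"),
    dream = disorg_index(
      27.82, c(LCC = -0.32, LSC = -0.012),
      provenance = "fixed", source_reports = "dream"),
    chronic_dream = disorg_index(
      93.91, c(E = -3.08, LSC = 0.21),
      provenance = "fixed", source_reports = "dream")
  )
}

#' Evaluate a Disorganization Index on attribute values
#'
#' @param object a `"disorg_index"` model.
#' @param newdata data.frame (one row per subject) or named list/vector of
#'   attribute values. Every attribute named by the model must be present;
#'   a missing one is an error naming it, so callers can fall back to the
#'   negative-image-only index when a subject failed to recall a dream.
#' @param ... unused.
#' @return numeric vector of index scores.
#' @export
predict.disorg_index <- function(object, newdata, ...) {
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  need <- names(object$coefficients)
  missing <- setdiff(need, names(newdata))
  if (length(missing) > 0L) {
    stop("missing attribute(s) required by the index: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(newdata[, need, drop = FALSE])
  drop(object$intercept + X %*% object$coefficients)
}

#' Alias of [predict.disorg_index()] taking attributes first
#' @param attributes named attribute values.
#' @param model a `"disorg_index"`.
#' @export
apply_index <- function(model, attributes) predict(model, attributes)

#' @export
print.disorg_index <- function(x, digits = 4, ...) {
  terms <- paste(sprintf("%s x (%g)", names(x$coefficients),
                         round(x$coefficients, digits)), collapse = " + ")
  cat(sprintf("Disorganization Index (%s)\n  score = %g + %s\n",
              x$provenance, round(x$intercept, digits), terms))
  if (!is.null(x$fit_stats)) {
    fs <- x$fit_stats
    cat(sprintf("  R^2 = %.3f, p = %.4g, observed power = %.4f, n = %d\n",
                fs$r_squared, fs$p_value, fs$observed_power, fs$n))
  }
  invisible(x)
}

#' @export
coef.disorg_index <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
summary.disorg_index <- function(object, ...) {
  print(object)
  if (!is.null(object$collinearity)) print(object$collinearity)
  invisible(object)
}

#' Serialize / load a Disorganization Index model as JSON
#' @param model a `"disorg_index"`.
#' @param path file path.
#' @export
write_index_model <- function(model, path) {
  stopifnot(inherits(model, "disorg_index"))
  jsonlite::write_json(
    list(intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         provenance = model$provenance,
         fit_stats = model$fit_stats,
         source_reports = model$source_reports),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_index_model
#' @export
read_index_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  disorg_index(x$intercept, unlist(x$coefficients),
               provenance = x$provenance,
               fit_stats = x$fit_stats,
               source_reports = x$source_reports)
}

#' Belsley collinearity diagnosis and sequential pruning
#'
#' Operationalizes condition-index / variance-decomposition collinearity
#' diagnosis: the design (with its intercept column, never droppable) is
#' scaled to unit column length, singular-value decomposed, and the
#' condition index of each component is the largest singular value divided
#' by that component's. While any condition index exceeds `threshold`, the
#' candidate variable with the largest variance-decomposition proportion on
#' an offending component is dropped (ties broken by the larger proportion
#' summed across offending components, then by input order) and the
#' diagnosis repeats.
#'
#' @param design numeric matrix or data.frame of candidate attributes
#'   (without intercept; one is added).
#' @param threshold condition-index threshold (default 10).
#' @param intercept include an intercept column in the scaled design
#'   (default `TRUE`, standard practice).
#' @return list with `kept` (surviving variable names) and `report`
#'   (class `"collinearity_report"`: per-iteration condition indices,
#'   variance-decomposition matrix, dropped variable).
#' @export
collinearity_prune <- function(design, threshold = 10, intercept = TRUE) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) < 2L) stop("need at least 2 candidate variables", call. = FALSE)
  if (nrow(X) < ncol(X) + 2L) {
    stop("need at least (variables + 2) observations", call. = FALSE)
  }
  iterations <- list()
  keep <- colnames(X)
  repeat {
    M <- X[, keep, drop = FALSE]
    if (intercept) M <- cbind(`(Intercept)` = 1, M)
    Ms <- sweep(M, 2L, sqrt(colSums(M^2)), "/")
    sv <- svd(Ms)
    d <- sv$d
    cond_idx <- max(d) / d
    # variance-decomposition proportions: rows = variables, cols = components
    phi <- sweep(sv$v^2, 2L, d^2, "/")
    vdp <- sweep(phi, 1L, rowSums(phi), "/")
    dimnames(vdp) <- list(colnames(M), NULL)
    offending <- which(cond_idx > threshold)
    it <- list(condition_indices = cond_idx,
               variance_decomposition = vdp,
               dropped_variable = NA_character_)
    if (length(offending) == 0L) {
      iterations[[length(iterations) + 1L]] <- it
      break
    }
    droppable <- setdiff(rownames(vdp), "(Intercept)")
    sub <- vdp[droppable, offending, drop = FALSE]
    best <- max(sub)
    # tolerance so that exactly collinear columns (equal up to rounding in
    # the SVD) are treated as tied and resolved by the stated tie rules
    tol <- 1e-9
    cand <- droppable[apply(sub, 1L, max) >= best - tol]
    if (length(cand) > 1L) {
      sums <- rowSums(sub[cand, , drop = FALSE])
      cand <- cand[sums >= max(sums) - tol]
      # remaining ties: input order, keeping the earlier-listed variable
      cand <- cand[length(cand)]
    }
    it$dropped_variable <- cand
    iterations[[length(iterations) + 1L]] <- it
    keep <- setdiff(keep, cand)
    if (length(keep) == 0L) {
      stop("all candidate variables were pruned as collinear; ",
           "consider using the single best-correlated attribute alone",
           call. = FALSE)
    }
  }
  list(kept = keep,
       report = structure(list(iterations = iterations),
                          class = "collinearity_report"))
}

#' @export
print.collinearity_report <- function(x, ...) {
  for (i in seq_along(x$iterations)) {
    it <- x$iterations[[i]]
    cat(sprintf("iteration %d: max condition index %.2f%s\n", i,
                max(it$condition_indices),
                if (is.na(it$dropped_variable)) " (non-collinear, stop)"
                else paste0(" -> dropped ", it$dropped_variable)))
  }
  invisible(x)
}

#' Fit a Disorganization Index by collinearity-pruned regression
#'
#' Re-derives an index on a cohort: candidate connectedness attributes are
#' pruned with [collinearity_prune()], the survivors enter an ordinary
#' least-squares regression of the symptom score (typically the PANSS
#' negative subscale total, patients only), and the fitted coefficients
#' define the index. Rows with missing values in any used column are
#' dropped (complete-case analysis, the per-analysis n is recorded).
#'
#' @param data data.frame with one row per subject.
#' @param candidates names of candidate attribute columns. Callers should
#'   restrict these to attributes showing corrected group differences (see
#'   [kruskal_wallis()] and [bonferroni_alpha()]).
#' @param symptom name of the symptom-score column.
#' @param prune run collinearity pruning first (default `TRUE`).
#' @param threshold condition-index threshold for pruning.
#' @return a `"disorg_index"` (provenance `"fitted"`) with `fit_stats`
#'   (R-squared, overall F-test p, observed power, n) and the
#'   `collinearity` report attached.
#' @export
fit_disorg_index <- function(data, candidates, symptom, prune = TRUE,
                             threshold = 10) {
  stopifnot(is.data.frame(data), all(candidates %in% names(data)),
            symptom %in% names(data))
  use <- stats::complete.cases(data[, c(candidates, symptom)])
  d <- data[use, , drop = FALSE]
  constant <- candidates[vapply(candidates, function(cl) {
    stats::var(d[[cl]]) == 0
  }, logical(1))]
  if (length(constant) > 0L) {
    message("dropping constant candidate attribute(s): ",
            paste(constant, collapse = ", "))
    candidates <- setdiff(candidates, constant)
    if (length(candidates) == 0L) {
      stop("no non-constant candidate attributes left", call. = FALSE)
    }
  }
  if (nrow(d) < length(candidates) + 2L) {
    stop("too few complete cases (", nrow(d), ") for ",
         length(candidates), " candidate attributes", call. = FALSE)
  }
  if (prune && length(candidates) >= 2L) {
    pr <- collinearity_prune(d[, candidates, drop = FALSE],
                             threshold = threshold)
    kept <- pr$kept
    report <- pr$report
  } else {
    kept <- candidates
    report <- NULL
  }
  fml <- stats::reformulate(kept, response = symptom)
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)
  k <- length(kept)
  n <- nrow(d)
  fstat <- sm$fstatistic
  p_overall <- stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  model <- disorg_index(
    stats::coef(fit)[["(Intercept)"]],
    stats::coef(fit)[kept],
    provenance = "fitted",
    fit_stats = list(r_squared = sm$r.squared,
                     p_value = unname(p_overall),
                     observed_power = observed_power(sm$r.squared, n, k),
                     n = n, df = unname(fstat[3L]),
                     std_errors = sm$coefficients[, "Std. Error"]))
  model$collinearity <- report
  model$lm <- fit
  model
}

#' Post-hoc (observed) power of a regression F-test
#'
#' Power of the overall F-test of a fitted multiple regression at level
#' `alpha`, from the Cohen effect size `f2 = R2 / (1 - R2)` and the
#' noncentral F distribution with noncentrality `lambda = f2 * n`
#' (the alternative `lambda = f2 * (n - k - 1)` differs negligibly at these
#' sample sizes).
#'
#' @param R2 coefficient of determination in `[0, 1]`.
#' @param n number of observations (must exceed `k + 1`).
#' @param k number of predictors.
#' @param alpha test level (default 0.05).
#' @return power in `[0, 1]`.
#' @examples
#' observed_power(0.88, 15, 3)
#' @export
observed_power <- function(R2, n, k, alpha = 0.05) {
  stopifnot(R2 >= 0, R2 <= 1, n > k + 1, k >= 1)
  if (R2 == 1) {
    warning("R2 = 1: observed power reported as 1", call. = FALSE)
    return(1)
  }
  f2 <- R2 / (1 - R2)
  lambda <- f2 * n
  crit <- stats::qf(1 - alpha, k, n - k - 1)
  stats::pf(crit, k, n - k - 1, ncp = lambda, lower.tail = FALSE)
}

#' Prevalence-based sample size
#'
#' `N = Z^2 P (1 - P) / d^2`, rounded up, with a minimum of 1. With the
#' population prevalence of schizophrenia (P = 0.0057), a 95% confidence
#' Z of 1.96 and precision d = 0.05 this gives N = 9.
#'
#' @param Z standard-normal quantile for the confidence level.
#' @param P expected proportion (prevalence), strictly inside (0, 1).
#' @param d absolute precision, > 0.
#' @return integer sample size.
#' @examples
#' sample_size_estimate(1.96, 0.0057, 0.05)
#' @export
sample_size_estimate <- function(Z, P, d) {
  stopifnot(P > 0, P < 1, d > 0)
  max(1L, as.integer(ceiling(Z^2 * P * (1 - P) / d^2)))
}
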