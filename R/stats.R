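# The non-parametric statistics battery applied throughout the analysis.
# Thin, uniform wrappers around the standard tests, returning a common
# "speech_test" structure (statistic, p_value, n, method, corrected_alpha).

.speech_test <- function(statistic, p_value, n, method,
                         corrected_alpha = NULL, extra = NULL) {
  structure(c(list(statistic = unname(statistic),
                   p_value = unname(p_value),
                   n = n, method = method,
                   corrected_alpha = corrected_alpha),
              extra),
            class = "speech_test")
}

#' @export
print.speech_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p_value, paste(x$n, collapse = "/")))
  if (!is.null(x$corrected_alpha)) {
    cat(sprintf("  Bonferroni-corrected alpha = %.4g\n", x$corrected_alpha))
  }
  invisible(x)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with the chi-square approximation
#' (df = groups - 1).
#'
#' @param values numeric vector, or a list of group vectors.
#' @param groups group labels (ignored when `values` is a list).
#' @return a `"speech_test"`.
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values)
  }
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tabulate(groups) == 0L)) stop("empty group", call. = FALSE)
  ht <- stats::kruskal.test(values, groups)
  .speech_test(ht$statistic, ht$p.value, as.integer(table(groups)),
               "Kruskal-Wallis")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-value for small samples without ties; otherwise the normal
#' approximation with tie correction.
#'
#' @param a,b numeric samples.
#' @return a `"speech_test"` (statistic is the Mann-Whitney U of `a`).
#' @export
wilcoxon_ranksum <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample", call. = FALSE)
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL))
  .speech_test(ht$statistic, ht$p.value, c(length(a), length(b)),
               "Wilcoxon rank-sum (two-sided)")
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param table 2x2 matrix of nonnegative counts; all marginals must be
#'   positive.
#' @param continuity apply the Yates continuity correction (default
#'   `FALSE`).
#' @return a `"speech_test"` with df = 1.
#' @export
chi_square_2x2 <- function(table, continuity = FALSE) {
  tab <- as.matrix(table)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal in 2x2 table", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = continuity))
  .speech_test(ht$statistic, ht$p.value, sum(tab), "Chi-square (2x2)")
}

#' Spearman rank correlation
#'
#' Rho with tie handling; exact p for n <= 9 without ties, t approximation
#' otherwise. Constant input leaves Rho undefined and is an error.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return a `"speech_test"` whose `statistic` is Rho.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: Spearman correlation undefined", call. = FALSE)
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  .speech_test(ht$estimate, ht$p.value, length(x), "Spearman correlation")
}

#' Partial Spearman correlation controlling for confounders
#'
#' All variables are rank-transformed; the partial correlation is the
#' Pearson correlation of the rank variables after residualizing both on
#' the rank-transformed covariates (one of several non-equivalent
#' definitions of a partial Spearman coefficient; this rank-residualization
#' form is the one implemented). p-value from the t distribution with
#' `n - 2 - q` degrees of freedom for `q` covariates. With no covariates it
#' reduces to [spearman_cor()].
#'
#' @param x,y numeric vectors.
#' @param covariates numeric vector, matrix or data.frame of confounders
#'   (e.g. word rate, medication dose); must be full column rank after rank
#'   transformation.
#' @return a `"speech_test"` whose `statistic` is the partial Rho.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0L) return(spearman_cor(x, y))
  Z <- as.matrix(covariates)
  stopifnot(length(x) == length(y), nrow(Z) == length(x))
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  RZ <- apply(Z, 2L, rank)
  if (qr(cbind(1, RZ))$rank < ncol(RZ) + 1L) {
    stop("rank-deficient covariate matrix", call. = FALSE)
  }
  ex <- stats::lm.fit(cbind(1, RZ), rx)$residuals
  ey <- stats::lm.fit(cbind(1, RZ), ry)$residuals
  # a variable fully explained by the covariates leaves nothing to correlate
  if (stats::sd(ex) < 1e-12 || stats::sd(ey) < 1e-12) {
    rho <- 0
  } else {
    rho <- stats::cor(ex, ey)
  }
  q <- ncol(RZ)
  df <- n - 2L - q
  tval <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  .speech_test(rho, p, n, sprintf("Partial Spearman (%d covariate%s)", q,
                                  if (q == 1L) "" else "s"))
}

#' Bonferroni-corrected significance threshold
#'
#' The family alpha divided by the number of comparisons; raw p-values are
#' compared against this threshold (the threshold is reported, p-values are
#' not inflated).
#'
#' @param alpha family-wise level, in (0, 1].
#' @param m number of comparisons, >= 1.
#' @return corrected alpha.
#' @examples
#' round(bonferroni_alpha(0.05, 8), 4)  # 0.0063
#' @export
bonferroni_alpha <- function(alpha, m) {
  stopifnot(alpha > 0, alpha <= 1, m >= 1)
  alpha / m
}

#' Normality and variance-homogeneity checks
#'
#' Per-group one-sample Kolmogorov-Smirnov test against a normal with the
#' sample mean and standard deviation (approximate, since the parameters
#' are estimated), and a Levene test of variance homogeneity across groups
#' (mean-centered by default; `center = median` gives the Brown-Forsythe
#' variant).
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 groups for Levene).
#' @param center centering function for Levene, `mean` (default) or
#'   `median`.
#' @return list with `normality` (named list of per-group
#'   `"speech_test"`s; groups smaller than 3 are skipped with a warning)
#'   and `variance_homogeneity` (a `"speech_test"`).
#' @export
distribution_checks <- function(values, groups, center = mean) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups for Levene",
                                 call. = FALSE)
  normality <- list()
  for (g in levels(groups)) {
    v <- values[groups == g]
    if (length(v) < 3L) {
      warning("group ", g, " has fewer than 3 observations; ",
              "normality check skipped", call. = FALSE)
      next
    }
    ht <- suppressWarnings(stats::ks.test(v, "pnorm", mean(v),
                                          stats::sd(v)))
    normality[[g]] <- .speech_test(ht$statistic, ht$p.value, length(v),
                                   "Kolmogorov-Smirnov (estimated normal)")
  }
  lv <- car::leveneTest(values, groups, center = center)
  variance <- .speech_test(lv[1L, "F value"], lv[1L, "Pr(>F)"],
                           length(values), "Levene")
  list(normality = normality, variance_homogeneity = variance)
}
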