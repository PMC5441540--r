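test_that("the fixed published index equations evaluate exactly", {
  m <- reference_index_models()
  expect_equal(predict(m$dream, c(LCC = 0, LSC = 0)), 27.82)
  expect_equal(predict(m$dream, c(LCC = 10, LSC = 5)),
               27.82 + 10 * (-0.32) + 5 * (-0.012))
  expect_equal(predict(m$negative, c(LCC = 0, LSC = 0, LSCz = 0)), 31.43)
  expect_equal(predict(m$negative_dream,
                       c(LSC_negative = 0, LSCz_negative = 0, LCC_dream = 0)),
               30.78)
  expect_equal(predict(m$chronic_dream, c(E = 0, LSC = 0)), 93.91)
  expect_equal(predict(m$chronic_dream, c(E = 20, LSC = 30)),
               93.91 + 20 * (-3.08) + 30 * 0.21)
  # coefficients are immutable constants
  expect_identical(m$dream$coefficients, c(LCC = -0.32, LSC = -0.012))
  expect_identical(m$negative$coefficients,
                   c(LCC = -0.30, LSC = 0.08, LSCz = -2.12))
  expect_identical(m$negative_dream$coefficients,
                   c(LSC_negative = 0.015, LSCz_negative = -2.33,
                     LCC_dream = -0.20))
  expect_identical(m$chronic_dream$coefficients, c(E = -3.08, LSC = 0.21))
  expect_true(all(vapply(m, function(x) x$provenance == "fixed", TRUE)))
})

test_that("index evaluation is affine and vectorized, missing attributes are named", {
  m <- reference_index_models()$negative
  set.seed(4)
  a <- c(LCC = 12, LSC = 7, LSCz = -1.4)
  b <- c(LCC = 30, LSC = 2, LSCz = 2.2)
  for (lam in c(0, 0.25, 0.7, 1)) {
    expect_equal(predict(m, as.list(lam * a + (1 - lam) * b)),
                 lam * predict(m, as.list(a)) + (1 - lam) * predict(m, as.list(b)))
  }
  df <- data.frame(LCC = c(0, 10), LSC = c(0, 5), LSCz = c(0, -2))
  expect_equal(predict(m, df), c(31.43, 31.43 - 3 + 0.4 + 4.24))
  expect_error(predict(m, c(LCC = 1, LSC = 1)), "LSCz")
  expect_error(
    predict(reference_index_models()$negative_dream, c(LSC_negative = 1,
                                                       LSCz_negative = 0)),
    "LCC_dream")
})

test_that("index models serialize to JSON and back", {
  m <- reference_index_models()$negative_dream
  f <- tempfile(fileext = ".json")
  write_index_model(m, f)
  m2 <- read_index_model(f)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$provenance, "fixed")
})

test_that("collinearity pruning follows the condition-index rule", {
  set.seed(8)
  # near-orthogonal columns: nothing dropped, single iteration
  X <- cbind(x1 = c(1, -1, 1, -1, 1, -1), x2 = c(1, 1, -1, -1, 1, -1))
  out <- collinearity_prune(X)
  expect_setequal(out$kept, c("x1", "x2"))
  expect_length(out$report$iterations, 1L)
  expect_true(all(out$report$iterations[[1]]$condition_indices <= 10))

  # duplicated column: one copy dropped in the first iteration,
  # keeping the earlier-listed one
  z <- rnorm(20)
  X2 <- cbind(a = z, b = rnorm(20), a_dup = z)
  out2 <- collinearity_prune(X2)
  expect_equal(out2$report$iterations[[1]]$dropped_variable, "a_dup")
  expect_setequal(out2$kept, c("a", "b"))

  # near-duplicate: exactly one of the pair goes, chosen by the stated rule
  x1 <- rnorm(30)
  X3 <- cbind(x1 = x1, x2 = x1 + rnorm(30, 0, 1e-6), x3 = rnorm(30))
  out3 <- collinearity_prune(X3)
  dropped <- vapply(out3$report$iterations, `[[`, "", "dropped_variable")
  expect_equal(sum(dropped %in% c("x1", "x2"), na.rm = TRUE), 1L)
  expect_true("x3" %in% out3$kept)
  # the recorded pick carries a (numerically tied-or-) largest
  # variance-decomposition proportion on the offending components
  it1 <- out3$report$iterations[[1]]
  off <- which(it1$condition_indices > 10)
  vdp <- it1$variance_decomposition
  cand <- setdiff(rownames(vdp), "(Intercept)")
  maxima <- apply(vdp[cand, off, drop = FALSE], 1, max)
  expect_gte(maxima[[dropped[1]]], max(maxima) - 1e-9)

  expect_error(collinearity_prune(X[, 1, drop = FALSE]), "at least 2")
  expect_error(collinearity_prune(X[1:3, ]), "observations")
})

test_that("noiseless fits recover the generating equation after pruning a planted duplicate", {
  set.seed(15)
  n <- 40
  # wide spread keeps the genuine attributes clear of the intercept in the
  # scaled design, so only the planted duplicate is collinear
  d <- data.frame(LCC = rnorm(n, 15, 12), LSC = rnorm(n, 8, 6))
  d$LCC_dup <- d$LCC  # deliberately collinear column
  m <- reference_index_models()$dream
  d$panss_negative <- predict(m, d)
  fit <- suppressWarnings(  # R2 = 1 by construction
    fit_disorg_index(d, c("LCC", "LSC", "LCC_dup"), "panss_negative"))
  expect_equal(fit$provenance, "fitted")
  expect_setequal(names(fit$coefficients), c("LCC", "LSC"))
  expect_lt(abs(fit$intercept - 27.82) / 27.82, 1e-8)
  expect_lt(abs(fit$coefficients[["LCC"]] - (-0.32)) / 0.32, 1e-8)
  expect_lt(abs(fit$coefficients[["LSC"]] - (-0.012)) / 0.012, 1e-8)
  expect_equal(fit$fit_stats$r_squared, 1, tolerance = 1e-12)
  drops <- vapply(fit$collinearity$iterations, `[[`, "", "dropped_variable")
  expect_true("LCC_dup" %in% drops)

  expect_error(fit_disorg_index(d[1:3, ], c("LCC", "LSC"), "panss_negative"),
               "complete cases")
})

test_that("the fitted index tracks symptoms better than any single attribute", {
  set.seed(303)
  cfg <- generator_config(
    n_per_group = c(schizophrenia_like = 11, bipolar_like = 10,
                    control_like = 0),
    n_surrogates = 80)
  res <- replicate(40, {
    co <- generate_cohort(cfg)
    pat <- co$table
    fit <- fit_disorg_index(pat, c("LSC_negative", "LSCz_negative"),
                            "panss_negative", prune = FALSE)
    idx <- predict(fit, pat)
    singles <- c("E_negative", "LSC_negative", "LSCz_negative")
    # OLS identity: in Pearson terms the fitted combination always
    # dominates each of its ingredients
    r_pear_idx <- cor(idx, pat$panss_negative)
    r_pear_max <- max(sapply(singles, function(cl)
      abs(cor(pat[[cl]], pat$panss_negative))))
    rho_idx <- suppressWarnings(
      cor(idx, pat$panss_negative, method = "spearman"))
    rho_max <- max(sapply(singles, function(cl) suppressWarnings(
      abs(cor(pat[[cl]], pat$panss_negative, method = "spearman")))))
    c(pearson_dominates = r_pear_idx >= r_pear_max - 1e-9,
      rho_positive = rho_idx > 0,
      rho_wins = rho_idx >= rho_max - 1e-9)
  })
  expect_true(all(res["pearson_dominates", ]))
  expect_gte(mean(res["rho_positive", ]), 0.9)
  # in rank terms the dominant single attribute occasionally edges out the
  # two-term index at n = 21; the index must still win a clear majority
  expect_gte(mean(res["rho_wins", ]), 0.6)
})

test_that("observed power follows the noncentral-F formulation", {
  expect_equal(observed_power(0, 20, 2), 0.05, tolerance = 1e-10)
  expect_gt(observed_power(0.88, 15, 3), 0.99)
  expect_identical(observed_power(0.5, 30, 3), observed_power(0.5, 30, 3))
  expect_warning(p1 <- observed_power(1, 10, 2), "R2 = 1")
  expect_equal(p1, 1)
  expect_error(observed_power(0.5, 4, 3))
  # monotone in R2 and in n
  expect_true(observed_power(0.3, 30, 3) < observed_power(0.5, 30, 3))
  expect_true(observed_power(0.3, 30, 3) < observed_power(0.3, 60, 3))
})

test_that("the prevalence-based sample-size formula evaluates and rounds up", {
  expect_identical(sample_size_estimate(1.96, 0.0057, 0.05), 9L)
  expect_identical(sample_size_estimate(1.96, 0.5, 0.05), 385L)
  expect_identical(sample_size_estimate(1.96, 0.5, 1e6), 1L)
  expect_error(sample_size_estimate(1.96, 0, 0.05))
  expect_error(sample_size_estimate(1.96, 0.5, 0))
})
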