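test_that("generator config validates its inputs and keeps the recurrence ordering", {
  cfg <- generator_config()
  expect_s3_class(cfg, "generator_config")
  rho <- cfg$recurrence_rho
  expect_true(rho[["control_like"]] >= rho[["bipolar_like"]])
  expect_true(rho[["bipolar_like"]] >= rho[["schizophrenia_like"]])
  expect_equal(cfg$panss_range, c(7, 49))
  expect_error(generator_config(recurrence_rho = c(
    schizophrenia_like = 1.2, bipolar_like = 0.1, control_like = 0.1)))
  expect_error(generator_config(tokens_range = c(50, 40)))
})

test_that("zero recurrence yields loop-free reports at the shuffle null", {
  cfg <- generator_config(recurrence_rho = c(schizophrenia_like = 0,
                                             bipolar_like = 0,
                                             control_like = 0))
  tr <- generate_transcript(cfg, "schizophrenia_like", seed = 4)
  expect_equal(length(unique(tr$tokens)), length(tr$tokens))
  att <- connectedness(tr$tokens)
  expect_equal(att$LSC, 1L)
  d <- make_surrogates(tr$tokens, n = 50, seed = 1)
  z <- z_scores(att, d)
  expect_equal(z$LSCz, 0)
  expect_true(z$random_like)
})

test_that("transcript generation is seed-reproducible with in-range lengths", {
  cfg <- generator_config()
  t1 <- generate_transcript(cfg, "control_like", seed = 9)
  t2 <- generate_transcript(cfg, "control_like", seed = 9)
  expect_identical(t1$tokens, t2$tokens)
  expect_true(length(t1$tokens) >= 40 && length(t1$tokens) <= 120)
  expect_equal(t1$duration_s, 30)
  t3 <- generate_transcript(cfg, "control_like", seed = 10)
  expect_false(identical(t1$tokens, t3$tokens))
})

test_that("high recurrence produces strong components covering most of the vocabulary", {
  cfg <- generator_config(recurrence_rho = c(schizophrenia_like = 0.9,
                                             bipolar_like = 0.9,
                                             control_like = 0.9))
  set.seed(31)
  frac_ok <- replicate(100, {
    toks <- .subset2(generate_transcript(cfg, "control_like"), "tokens")
    att <- connectedness(toks)
    att$LSC >= 0.5 * length(unique(toks))
  })
  expect_gte(mean(frac_ok), 0.95)
})

test_that("group-mean LSC is non-decreasing in the recurrence parameter", {
  set.seed(55)
  mean_lsc <- sapply(c(0, 0.05, 0.12, 0.3), function(rho) {
    cfg <- generator_config(recurrence_rho = c(schizophrenia_like = rho,
                                               bipolar_like = rho,
                                               control_like = rho))
    mean(replicate(200, {
      connectedness(.subset2(generate_transcript(cfg, "control_like"),
                             "tokens"))$LSC
    }))
  })
  expect_true(all(diff(mean_lsc) > 0))
})

test_that("cohorts carry symptoms generated from measured attributes", {
  cfg <- generator_config(
    n_per_group = c(schizophrenia_like = 5, bipolar_like = 5,
                    control_like = 4),
    n_surrogates = 60, seed = 123)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$table), 14L)
  expect_true(all(is.na(co$table$panss_negative[
    co$table$group == "control_like"])))
  pat <- co$table[co$table$group != "control_like", ]
  expect_true(all(pat$panss_negative >= 7 & pat$panss_negative <= 49))
  expect_named(co$ground_truth$symptom_model$coefficients,
               c("LSC_negative", "LSCz_negative", "LCC_negative"))
  # determinism
  co2 <- generate_cohort(cfg)
  expect_identical(co$table, co2$table)
})

test_that("a noiseless identity symptom model is recovered exactly end-to-end", {
  cfg <- generator_config(
    n_per_group = c(schizophrenia_like = 8, bipolar_like = 8,
                    control_like = 0),
    # intercept keeps noiseless scores inside [7, 49], so clipping is inert
    symptom_model = list(intercept = 10, coefficients = c(LSC = 1),
                         noise_sd = 0),
    n_surrogates = 50, seed = 77)
  co <- generate_cohort(cfg)
  fit <- suppressWarnings(  # R2 = 1 by construction
    fit_disorg_index(co$table, "LSC_negative", "panss_negative",
                     prune = FALSE))
  expect_equal(fit$intercept, 10, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["LSC_negative"]), 1,
               tolerance = 1e-10)
  expect_equal(fit$fit_stats$r_squared, 1, tolerance = 1e-12)
})

test_that("exported cohorts round-trip from disk", {
  cfg <- generator_config(
    n_per_group = c(schizophrenia_like = 2, bipolar_like = 2,
                    control_like = 2),
    n_surrogates = 30, seed = 3)
  co <- generate_cohort(cfg)
  dir <- tempfile()
  export_cohort(co, dir)
  expect_true(all(file.exists(file.path(
    dir, c("transcripts.tsv", "metadata.tsv", "ground_truth.json")))))
  trs <- read_transcripts(file.path(dir, "transcripts.tsv"))
  expect_length(trs, 6L)
  expect_identical(trs[[1]]$tokens,
                   co$transcripts[[paste(trs[[1]]$subject_id,
                                         trs[[1]]$report_type,
                                         sep = ".")]]$tokens)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$symptom_model$noise_sd,
               co$ground_truth$symptom_model$noise_sd)
})
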