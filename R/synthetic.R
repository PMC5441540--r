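# Synthetic transcripts and cohorts with controllable word-recurrence
# structure. The generator is this package's own construction (no clinical
# data are imitated beyond connectedness structure): a recurrence process
# in which each step either emits a fresh word from an unbounded vocabulary
# or revisits an already-used word, with the revisit probability rho the
# single interpretable "loop structure" dial.

.group_levels <- c("schizophrenia_like", "bipolar_like", "control_like")

.type_suffix <- function(report_type) {
  switch(report_type,
         image_negative = "negative",
         image_neutral = "neutral",
         image_positive = "positive",
         report_type)
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate 30-second time-limited reports: lengths uniform on
#' 40-120 tokens and group-dependent recurrence. Revisits are
#' recency-weighted by default (weight `decay^s` for a word last used `s`
#' steps ago), so recurrence forms tight loops and drives the report's LSC
#' away from its shuffle null; the per-group revisit probabilities
#' (control 0.12 > bipolar 0.05 > schizophrenia 0.025) were calibrated once
#' so that the default groups reproduce the published random-like
#' prevalence gradient (~5% / ~30% / ~64%). Symptom scores are generated
#' from measured graph attributes - not from group labels - so attributes
#' explain symptom variance by construction, and are clipped to the
#' feasible PANSS negative subscale range [7, 49]. Control-like subjects
#' are not clinical and get no symptom score.
#'
#' @param n_per_group named integer vector over
#'   `schizophrenia_like`, `bipolar_like`, `control_like`.
#' @param tokens_range inclusive integer range of report lengths.
#' @param recurrence_rho named per-group revisit probability in `[0, 1)`.
#' @param revisit_mode `"recency-weighted"` (default) or `"uniform"`
#'   (uniform revisits are near-exchangeable, hence near the shuffle null
#'   at any rho).
#' @param recency_decay geometric decay of revisit weights.
#' @param symptom_model list with `intercept`, named `coefficients` over
#'   graph attributes (default `LSC`, `LSCz`, `LCC`; names may be suffixed
#'   by report type, unsuffixed names resolve to the first requested report
#'   type) and `noise_sd` of the added Gaussian noise.
#' @param report_types report types generated per subject.
#' @param n_surrogates surrogates per report for the z-scores.
#' @param seed integer seed for [generate_cohort()].
#' @return object of class `"generator_config"`.
#' @export
generator_config <- function(n_per_group = c(schizophrenia_like = 11L,
                                             bipolar_like = 10L,
                                             control_like = 21L),
                             tokens_range = c(40L, 120L),
                             recurrence_rho = c(schizophrenia_like = 0.025,
                                                bipolar_like = 0.05,
                                                control_like = 0.12),
                             revisit_mode = c("recency-weighted", "uniform"),
                             recency_decay = 0.8,
                             symptom_model = list(
                               intercept = 30,
                               coefficients = c(LSC = -0.25, LSCz = 1.0,
                                                LCC = 0),
                               noise_sd = 2.5),
                             report_types = "image_negative",
                             n_surrogates = 1000L,
                             seed = NULL) {
  revisit_mode <- match.arg(revisit_mode)
  stopifnot(all(.group_levels %in% names(n_per_group)),
            all(.group_levels %in% names(recurrence_rho)),
            all(recurrence_rho >= 0), all(recurrence_rho < 1),
            length(tokens_range) == 2L, tokens_range[1] >= 2L,
            tokens_range[1] <= tokens_range[2],
            recency_decay > 0, recency_decay <= 1,
            is.list(symptom_model),
            all(c("intercept", "coefficients", "noise_sd") %in%
                  names(symptom_model)),
            symptom_model$noise_sd >= 0,
            all(report_types %in% .report_types))
  structure(list(n_per_group = n_per_group[.group_levels],
                 tokens_range = as.integer(tokens_range),
                 recurrence_rho = recurrence_rho[.group_levels],
                 revisit_mode = revisit_mode,
                 recency_decay = recency_decay,
                 symptom_model = symptom_model,
                 report_types = report_types,
                 n_surrogates = as.integer(n_surrogates),
                 panss_range = c(7, 49),
                 seed = seed),
            class = "generator_config")
}

# Token sequence of the recurrence process, on the current RNG stream.
.gen_tokens <- function(n, rho, mode, decay) {
  toks <- integer(n)
  last <- integer(n)           # last occurrence position per word id
  toks[1L] <- 1L; last[1L] <- 1L; nxt <- 2L
  if (n >= 2L) for (t in 2:n) {
    if (nxt > 2L && stats::runif(1) < rho) {
      cand <- seq_len(nxt - 1L)
      tok <- if (mode == "uniform") {
        cand[sample.int(length(cand), 1L)]
      } else {
        w <- decay^((t - 1L) - last[cand])
        cand[sample.int(length(cand), 1L, prob = w)]
      }
      toks[t] <- tok; last[tok] <- t
    } else {
      toks[t] <- nxt; last[nxt] <- t; nxt <- nxt + 1L
    }
  }
  sprintf("w%03d", toks)
}

#' Generate one synthetic transcript
#'
#' @param config a [generator_config()].
#' @param group one of `"schizophrenia_like"`, `"bipolar_like"`,
#'   `"control_like"`.
#' @param subject_id,report_type metadata for the [transcript()].
#' @param seed optional seed (the caller's RNG state is restored).
#' @return a [transcript()].
#' @export
generate_transcript <- function(config, group, subject_id = "sim1",
                                report_type = config$report_types[1L],
                                seed = NULL) {
  stopifnot(inherits(config, "generator_config"),
            group %in% .group_levels)
  .with_seed(seed, {
    n <- sample(seq.int(config$tokens_range[1L], config$tokens_range[2L]), 1L)
    toks <- .gen_tokens(n, config$recurrence_rho[[group]],
                        config$revisit_mode, config$recency_decay)
    transcript(toks, subject_id = subject_id, report_type = report_type,
               duration_s = 30)
  })
}

# resolve symptom-model coefficient names against cohort table columns
.resolve_coef_names <- function(coefs, columns, first_suffix) {
  nm <- names(coefs)
  resolved <- ifelse(nm %in% columns, nm, paste0(nm, "_", first_suffix))
  bad <- resolved[!resolved %in% columns]
  if (length(bad) > 0L) {
    stop("symptom model names not found in cohort table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stats::setNames(as.numeric(coefs), resolved)
}

#' Generate a synthetic cohort through the real pipeline
#'
#' For every subject, one transcript per requested report type is
#' generated, its full connectedness profile (including surrogate z-scores
#' and the random-like flag) is computed with the same functions used on
#' real data, and - for the clinical groups - a PANSS-negative-like symptom
#' score is produced by the configured linear model on the measured
#' attributes plus Gaussian noise, clipped to [7, 49]. Attribute columns
#' are suffixed by report type (`LSC_negative`, `LCC_dream`, ...) exactly
#' as the published index equations name them.
#'
#' @param config a [generator_config()].
#' @return object of class `"speech_cohort"`: list with `table` (one row
#'   per subject), `transcripts` (named list), and `ground_truth` (per-group
#'   rho, the generating symptom model and seed) for recovery tests.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  .with_seed(config$seed, {
    rows <- list(); transcripts <- list()
    sid <- 0L
    for (grp in .group_levels) {
      for (i in seq_len(config$n_per_group[[grp]])) {
        sid <- sid + 1L
        id <- sprintf("sub%03d", sid)
        row <- list(subject_id = id, group = grp)
        for (rt in config$report_types) {
          tr <- generate_transcript(config, grp, id, rt)
          transcripts[[paste(id, rt, sep = ".")]] <- tr
          att <- connectedness(tr$tokens)
          dist <- make_surrogates(tr$tokens, n = config$n_surrogates)
          z <- suppressWarnings(z_scores(att, dist))
          suf <- .type_suffix(rt)
          row[paste0(c("word_rate", "E", "LCC", "LSC",
                       "E_norm", "LCC_norm", "LSC_norm",
                       "LCCz", "LSCz"), "_", suf)] <-
            list(att$word_rate, att$E, att$LCC, att$LSC,
                 att$E_norm, att$LCC_norm, att$LSC_norm,
                 z$LCCz, z$LSCz)
          row[[paste0("random_like_", suf)]] <- z$random_like
        }
        rows[[sid]] <- row
      }
    }
    tab <- do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
    sm <- config$symptom_model
    first_suf <- .type_suffix(config$report_types[1L])
    coefs <- .resolve_coef_names(sm$coefficients, names(tab), first_suf)
    X <- as.matrix(tab[, names(coefs), drop = FALSE])
    raw <- sm$intercept + drop(X %*% coefs) +
      stats::rnorm(nrow(tab), 0, sm$noise_sd)
    symptom <- pmin(pmax(raw, config$panss_range[1L]),
                    config$panss_range[2L])
    symptom[tab$group == "control_like"] <- NA_real_  # not clinical
    tab$panss_negative <- symptom
    structure(list(table = tab, transcripts = transcripts,
                   ground_truth = list(
                     recurrence_rho = config$recurrence_rho,
                     symptom_model = list(intercept = sm$intercept,
                                          coefficients = coefs,
                                          noise_sd = sm$noise_sd),
                     seed = config$seed)),
              class = "speech_cohort")
  })
}

#' @export
print.speech_cohort <- function(x, ...) {
  cat(sprintf("<speech_cohort> %d subjects (%s)\n", nrow(x$table),
              paste(sprintf("%s: %d", levels(factor(x$table$group)),
                            table(factor(x$table$group))), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes `transcripts.tsv` (subject_id, report_type, text),
#' `metadata.tsv` (subject_id, group, panss_negative) and
#' `ground_truth.json` into `dir`, the on-disk layout [run_pipeline()]
#' consumes.
#'
#' @param cohort a `"speech_cohort"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "speech_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- cohort$transcripts
  ttab <- data.frame(
    subject_id = vapply(tr, function(t) t$subject_id, ""),
    report_type = vapply(tr, function(t) t$report_type, ""),
    text = vapply(tr, function(t) paste(t$tokens, collapse = " "), ""))
  utils::write.table(ttab, file.path(dir, "transcripts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- cohort$table[, c("subject_id", "group", "panss_negative")]
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
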