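# End-to-end orchestration: attributes -> surrogate z-scores -> index ->
# group statistics -> classification, with seeds and configuration recorded
# in a run manifest so any run can be reproduced exactly.

.attr_cols <- c("E", "LCC", "LSC", "LCCz", "LSCz")

# long per-report attribute table -> wide per-subject table with
# report-type-suffixed columns
.widen_attributes <- function(long) {
  subjects <- unique(long$subject_id)
  out <- data.frame(subject_id = subjects, stringsAsFactors = FALSE)
  for (rt in unique(long$report_type)) {
    suf <- .type_suffix(rt)
    sub <- long[long$report_type == rt, ]
    idx <- match(subjects, sub$subject_id)
    for (col in setdiff(names(sub), c("subject_id", "report_type"))) {
      out[[paste0(col, "_", suf)]] <- sub[[col]][idx]
    }
  }
  out
}

#' Run the full speech-graph analysis pipeline
#'
#' Reads transcripts and subject metadata, computes per-report
#' connectedness attributes and surrogate z-scores, scores or fits a
#' Disorganization Index, runs the group-statistics battery, classifies
#' diagnosis and negative-symptom severity, and writes every table plus a
#' reproducibility manifest into `output_dir`. Subjects missing a dream
#' report are scored with the negative-image-only index as a fallback
#' (logged via `message()`).
#'
#' @param transcripts path to a transcript TSV (`subject_id`,
#'   `report_type`, `text`), a directory of `.txt` files, or a list of
#'   [transcript()] objects.
#' @param metadata path to a metadata TSV (or data.frame) with columns
#'   `subject_id`, `group` and, for patients, `panss_negative`.
#' @param output_dir directory for the output bundle (created if needed).
#' @param index_model `"fit"` (default) to re-derive an index on the
#'   patients, a `"disorg_index"` object, or a path to a model JSON.
#' @param candidates candidate attribute columns for fitting; by default
#'   the suffixed attributes showing Kruskal-Wallis group differences at
#'   the Bonferroni-corrected level.
#' @param n_surrogates surrogates per report.
#' @param folds,features classification settings: cross-validation folds
#'   and whether to classify on the `"index"` (default) or on all
#'   `"attributes"`.
#' @param seed integer seed controlling every stochastic stage (surrogates
#'   and fold assignment).
#' @return invisibly, a list with `attributes` (long), `subjects` (wide
#'   table joined with metadata, index scores appended), `index_model`,
#'   `stats`, `classification` and `manifest`.
#' @export
run_pipeline <- function(transcripts, metadata, output_dir,
                         index_model = "fit", candidates = NULL,
                         n_surrogates = 1000L, folds = 10L,
                         features = c("index", "attributes"),
                         seed = NULL) {
  features <- match.arg(features)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  trs <- if (is.character(transcripts)) read_transcripts(transcripts)
         else transcripts
  meta <- if (is.character(metadata)) {
    utils::read.delim(metadata, stringsAsFactors = FALSE)
  } else as.data.frame(metadata)
  if (!all(c("subject_id", "group") %in% names(meta))) {
    stop("metadata needs columns subject_id and group", call. = FALSE)
  }
  bad <- is.na(meta$subject_id) | !nzchar(meta$subject_id) |
    is.na(meta$group) | !nzchar(meta$group)
  if (any(bad)) {
    stop("corrupt metadata row(s): ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }

  # per-report attributes + surrogate z-scores
  long <- do.call(rbind, lapply(seq_along(trs), function(i) {
    tr <- trs[[i]]
    att <- connectedness(tr$tokens)
    dist <- make_surrogates(tr$tokens, n = n_surrogates,
                            seed = if (is.null(seed)) NULL else seed + i)
    z <- suppressWarnings(z_scores(att, dist))
    data.frame(subject_id = tr$subject_id, report_type = tr$report_type,
               word_rate = att$word_rate, E = att$E, LCC = att$LCC,
               LSC = att$LSC, E_norm = att$E_norm,
               LCC_norm = att$LCC_norm, LSC_norm = att$LSC_norm,
               LCCz = z$LCCz, LSCz = z$LSCz, random_like = z$random_like,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, file.path(output_dir, "attributes.csv"),
                   row.names = FALSE)

  wide <- merge(meta, .widen_attributes(long), by = "subject_id",
                all.x = TRUE)
  is_patient <- if ("panss_negative" %in% names(wide)) {
    !is.na(wide$panss_negative)
  } else rep(FALSE, nrow(wide))

  # Disorganization Index: fixed model, model file, or re-fit on patients
  suffixed <- unlist(lapply(unique(long$report_type), function(rt) {
    paste0(.attr_cols, "_", .type_suffix(rt))
  }))
  suffixed <- intersect(suffixed, names(wide))
  model <- NULL
  if (inherits(index_model, "disorg_index")) {
    model <- index_model
  } else if (is.character(index_model) && file.exists(index_model)) {
    model <- read_index_model(index_model)
  } else if (identical(index_model, "fit")) {
    if (!any(is_patient)) {
      stop("index fit requested but no subject has a symptom score",
           call. = FALSE)
    }
    if (is.null(candidates)) {
      m <- length(suffixed)
      alpha_c <- bonferroni_alpha(0.05, m)
      pvals <- vapply(suffixed, function(col) {
        p <- kruskal_wallis(wide[[col]], wide$group)$p_value
        if (!is.finite(p)) 1 else p  # constant column (e.g. degenerate LCCz)
      }, numeric(1))
      candidates <- suffixed[pvals < alpha_c]
      if (length(candidates) < 2L) {
        # too few corrected group differences; fall back to all attributes
        candidates <- suffixed
      }
    }
    model <- fit_disorg_index(wide[is_patient, , drop = FALSE],
                              candidates, "panss_negative")
  } else {
    stop("index_model must be 'fit', a disorg_index, or a model file path",
         call. = FALSE)
  }

  # score everyone; fall back to the negative-image-only reference index
  # for subjects missing an attribute the main model needs (e.g. no dream)
  idx <- rep(NA_real_, nrow(wide))
  need <- names(model$coefficients)
  have <- rowSums(is.na(as.matrix(
    wide[, intersect(need, names(wide)), drop = FALSE]))) == 0 &
    all(need %in% names(wide))
  if (any(have)) {
    idx[have] <- predict(model, wide[have, , drop = FALSE])
  }
  if (any(!have)) {
    fb <- reference_index_models()$negative
    fb_cols <- paste0(names(fb$coefficients), "_negative")
    ok_fb <- !have & fb_cols[1] %in% names(wide) &
      rowSums(is.na(as.matrix(wide[, intersect(fb_cols, names(wide)),
                                   drop = FALSE]))) == 0
    if (any(ok_fb)) {
      message(sum(ok_fb), " subject(s) missing attributes for the main ",
              "index; negative-image-only index used as fallback")
      nd <- wide[ok_fb, fb_cols, drop = FALSE]
      names(nd) <- names(fb$coefficients)
      idx[ok_fb] <- predict(fb, nd)
    }
  }
  wide$disorg_index <- idx
  utils::write.csv(wide, file.path(output_dir, "subjects.csv"),
                   row.names = FALSE)
  if (model$provenance == "fitted") {
    write_index_model(model, file.path(output_dir, "index_model.json"))
  }

  # statistics battery: per-attribute group comparisons + random-like rates
  m <- length(suffixed) + 1L
  alpha_c <- bonferroni_alpha(0.05, m)
  stat_rows <- lapply(c(suffixed, "disorg_index"), function(col) {
    tt <- kruskal_wallis(wide[[col]], wide$group)
    data.frame(comparison = paste0("kruskal_wallis:", col),
               statistic = tt$statistic, p = tt$p_value,
               corrected_alpha = alpha_c,
               significant = tt$p_value < alpha_c)
  })
  stats_tab <- do.call(rbind, stat_rows)
  rl_cols <- grep("^random_like_", names(wide), value = TRUE)
  rates <- NULL
  if (length(rl_cols) > 0L) {
    rates <- random_like_rate(wide[[rl_cols[1L]]], wide$group)
  }
  utils::write.csv(stats_tab, file.path(output_dir, "stats.csv"),
                   row.names = FALSE)

  # classification: schizophrenia-like diagnosis and severity
  X <- if (features == "index") {
    data.frame(disorg_index = wide$disorg_index)
  } else wide[, suffixed, drop = FALSE]
  keep <- stats::complete.cases(X)
  pos <- grepl("schiz", wide$group, ignore.case = TRUE)
  classification <- list()
  if (sum(keep) >= folds && length(unique(pos[keep])) == 2L) {
    classification$diagnosis <- naive_bayes_cv(
      X[keep, , drop = FALSE],
      factor(ifelse(pos[keep], "schizophrenia", "other"),
             levels = c("other", "schizophrenia")),
      folds = min(folds, sum(keep)), seed = seed)
  }
  pk <- is_patient & keep
  if (sum(pk) >= 4L) {
    sev <- median_split(wide$panss_negative[pk])
    if (nlevels(droplevels(sev$labels)) == 2L) {
      classification$severity <- naive_bayes_cv(
        X[pk, , drop = FALSE], sev$labels,
        folds = min(folds, sum(pk)), seed = seed)
      classification$severity_cutoff <- sev$cutoff
    }
  }
  cls_json <- lapply(classification, function(r) {
    if (inherits(r, "classification_report")) {
      r[c("sensitivity", "specificity", "precision", "recall",
          "f_measure", "auc", "auc_pooled", "accuracy_percent",
          "folds", "seed")]
    } else r
  })
  jsonlite::write_json(cls_json, file.path(output_dir,
                                           "classification.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("speechdisorg")),
    seed = if (is.null(seed)) NA else seed,
    n_surrogates = n_surrogates, folds = folds, features = features,
    index_provenance = model$provenance,
    n_subjects = nrow(wide), n_reports = nrow(long))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(attributes = long, subjects = wide, index_model = model,
                 stats = list(group_comparisons = stats_tab,
                              random_like = rates),
                 classification = classification, manifest = manifest))
}
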