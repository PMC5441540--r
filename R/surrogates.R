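# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Shuffled-word surrogate null distribution for one report
#'
#' Builds `n` surrogate graphs by uniformly permuting the report's token
#' sequence and rebuilding the word-trajectory graph, so every surrogate
#' preserves the original node set and number of edges while destroying the
#' temporal word structure. Per-surrogate LCC and LSC are recorded together
#' with their means (`LCCmr`, `LSCmr`) and population standard deviations
#' (`LCCsdr`, `LSCsdr`; divisor `n`, a fixed documented choice that is
#' numerically immaterial at the default `n = 1000`).
#'
#' @param tokens character token vector or [transcript()], length >= 2.
#' @param n number of surrogates (default 1000; must be >= 2 so a standard
#'   deviation is definable).
#' @param seed optional integer; the caller's RNG state is restored after
#'   use, and identical `(tokens, n, seed)` give identical output.
#' @param keep_sequences also return the permuted token sequences
#'   (`sequences`, a list), e.g. to audit that every surrogate preserves
#'   the node set and edge count.
#' @return object of class `"surrogate_dist"` with fields `n_surrogates`,
#'   `lcc_values`, `lsc_values`, `LCCmr`, `LSCmr`, `LCCsdr`, `LSCsdr`,
#'   `rng_seed`, plus the reference `nodes` and `E` used for validation.
#' @examples
#' d <- make_surrogates(c("a", "b", "a", "b", "a"), n = 100, seed = 1)
#' d$LSCmr
#' @export
make_surrogates <- function(tokens, n = 1000L, seed = NULL,
                            keep_sequences = FALSE) {
  if (inherits(tokens, "transcript")) tokens <- tokens$tokens
  if (length(tokens) < 2L) {
    stop("need at least 2 tokens to build surrogates", call. = FALSE)
  }
  n <- as.integer(n)
  if (n < 2L) {
    stop("need at least 2 surrogates for a standard deviation",
         call. = FALSE)
  }
  nodes <- unique(tokens)
  ids <- match(tokens, nodes)
  k <- length(nodes)
  seqs <- if (keep_sequences) vector("list", n) else NULL
  vals <- .with_seed(seed, {
    vapply(seq_len(n), function(i) {
      perm <- sample(ids)
      if (keep_sequences) seqs[[i]] <<- nodes[perm]
      .lcc_lsc(perm, k)
    }, integer(2))
  })
  lcc <- vals[1L, ]; lsc <- vals[2L, ]
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(list(n_surrogates = n,
                 sequences = seqs,
                 lcc_values = lcc, lsc_values = lsc,
                 LCCmr = mean(lcc), LSCmr = mean(lsc),
                 LCCsdr = pop_sd(lcc), LSCsdr = pop_sd(lsc),
                 rng_seed = if (is.null(seed)) NA_integer_ else seed,
                 nodes = nodes, E = length(tokens) - 1L),
            class = "surrogate_dist")
}

#' @export
print.surrogate_dist <- function(x, ...) {
  cat(sprintf(
    "<surrogate_dist> n=%d  LCCmr=%.2f (sd %.2f)  LSCmr=%.2f (sd %.2f)\n",
    x$n_surrogates, x$LCCmr, x$LCCsdr, x$LSCmr, x$LSCsdr))
  invisible(x)
}

#' z-scores of a report against its shuffled surrogates
#'
#' `LCCz = (LCC - LCCmr) / LCCsdr` and `LSCz = (LSC - LSCmr) / LSCsdr`.
#' When a surrogate distribution is degenerate (sd = 0, e.g. a report with
#' all-distinct words whose every shuffle is a loop-free path), the z-score
#' is 0 if the original equals the degenerate value — such loop-free speech
#' is indistinguishable from its own shuffles and is classified random-like
#' — and a signed `Inf` sentinel (with a warning) if it differs.
#'
#' @param original a `"connectedness"` object for the same report.
#' @param dist a [make_surrogates()] distribution built from the same token
#'   multiset; a mismatched node set or edge count is an error.
#' @param attribute,k_sd passed to [classify_random_like()] for the
#'   `random_like` field.
#' @return object of class `"randomness_scores"`: list `LCCz`, `LSCz`,
#'   `random_like`.
#' @export
z_scores <- function(original, dist, attribute = "LSCz", k_sd = 2) {
  stopifnot(inherits(dist, "surrogate_dist"))
  if (inherits(original, "speech_graph") || is.character(original)) {
    original <- connectedness(original)
  }
  if (original$E != dist$E) {
    stop("edge count mismatch: surrogate distribution was built from a ",
         "different token multiset", call. = FALSE)
  }
  one_z <- function(value, m, s, label) {
    if (s == 0) {
      if (value == m) return(0)
      warning("degenerate surrogate distribution for ", label,
              ": sd = 0 but original differs from the mean", call. = FALSE)
      return(sign(value - m) * Inf)
    }
    (value - m) / s
  }
  scores <- structure(
    list(LCCz = one_z(original$LCC, dist$LCCmr, dist$LCCsdr, "LCC"),
         LSCz = one_z(original$LSC, dist$LSCmr, dist$LSCsdr, "LSC")),
    class = "randomness_scores")
  scores$random_like <- classify_random_like(scores, attribute, k_sd)
  scores
}

#' @export
print.randomness_scores <- function(x, ...) {
  cat(sprintf("<randomness_scores> LCCz=%.3f LSCz=%.3f random_like=%s\n",
              x$LCCz, x$LSCz, x$random_like))
  invisible(x)
}

#' Is a report random-like?
#'
#' A report is random-like when its designated z attribute lies within
#' `k_sd` standard deviations of the shuffle-null mean — the closed
#' interval `[-k_sd, k_sd]`, so a z of exactly -2 counts as random-like.
#' Infinite sentinel z-scores are never random-like.
#'
#' @param scores a `"randomness_scores"` object (or list with `LCCz`/`LSCz`).
#' @param attribute `"LSCz"` (default), `"LCCz"`, or `"both"` (both must lie
#'   inside the band).
#' @param k_sd half-width of the band in null standard deviations.
#' @return logical scalar.
#' @export
classify_random_like <- function(scores, attribute = c("LSCz", "LCCz", "both"),
                                 k_sd = 2) {
  attribute <- match.arg(attribute)
  inside <- function(z) is.finite(z) && abs(z) <= k_sd
  switch(attribute,
         LSCz = inside(scores$LSCz),
         LCCz = inside(scores$LCCz),
         both = inside(scores$LSCz) && inside(scores$LCCz))
}

#' Random-like prevalence by group
#'
#' Per-group proportion of random-like reports, with pairwise 2x2
#' chi-square comparisons of the counts (via [chi_square_2x2()]).
#'
#' @param random_like logical vector, one entry per report.
#' @param group group label per report.
#' @return list with `proportions` (named), `counts` (2 x groups table) and
#'   `tests` (named list of pairwise test results; empty with a warning when
#'   only one group is present).
#' @export
random_like_rate <- function(random_like, group) {
  stopifnot(length(random_like) == length(group))
  group <- as.factor(group)
  if (any(table(group) == 0L)) stop("empty group", call. = FALSE)
  prop <- vapply(split(random_like, group), mean, numeric(1))
  counts <- rbind(random_like = vapply(split(random_like, group), sum,
                                       numeric(1)),
                  not_random = vapply(split(!random_like, group), sum,
                                      numeric(1)))
  lv <- levels(group)
  tests <- list()
  if (length(lv) < 2L) {
    warning("only one group: proportions reported, test skipped",
            call. = FALSE)
  } else {
    for (i in seq_len(length(lv) - 1L)) for (j in seq.int(i + 1L, length(lv))) {
      tab <- counts[, c(i, j)]
      nm <- paste(lv[i], "vs", lv[j])
      tests[[nm]] <- tryCatch(chi_square_2x2(t(tab)),
                              error = function(e) e$message)
    }
  }
  list(proportions = prop, counts = counts, tests = tests)
}
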