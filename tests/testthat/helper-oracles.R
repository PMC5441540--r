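# Independent oracles used across the suite. These deliberately avoid the
# package's own graph machinery: reachability is computed by brute-force
# boolean closure on the adjacency matrix.

# LCC/LSC by all-pairs reachability on the word-trajectory graph
oracle_lcc_lsc <- function(tokens) {
  nodes <- unique(tokens)
  k <- length(nodes)
  A <- matrix(FALSE, k, k)
  if (length(tokens) >= 2L) {
    for (i in seq_len(length(tokens) - 1L)) {
      A[match(tokens[i], nodes), match(tokens[i + 1L], nodes)] <- TRUE
    }
  }
  closure <- function(M) {
    R <- diag(TRUE, k) | M
    repeat {
      R2 <- R | ((R %*% R) > 0)
      if (identical(R2, R)) return(R)
      R <- R2
    }
  }
  R <- closure(A)
  mutual <- R & t(R)
  W <- closure(A | t(A))
  list(LCC = max(rowSums(W)), LSC = max(rowSums(mutual)))
}

# all distinct orderings of a small token multiset
oracle_all_permutations <- function(tokens) {
  n <- length(tokens)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  unique(perms(tokens))
}

# exact mean/sd of LSC over all orderings of a multiset
oracle_exact_lsc_null <- function(tokens) {
  vals <- vapply(oracle_all_permutations(tokens),
                 function(p) oracle_lcc_lsc(p)$LSC, numeric(1))
  list(mean = mean(vals), sd = sqrt(mean((vals - mean(vals))^2)),
       values = vals)
}

# random token sequence: length n over a vocabulary of size v
random_tokens <- function(n, v) {
  sample(paste0("t", seq_len(v)), n, replace = TRUE)
}

# tie-corrected Kruskal-Wallis H, straight from the textbook formula
oracle_kw_h <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  groups <- as.factor(groups)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) sum(x)^2 / length(x))) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}
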