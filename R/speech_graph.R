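#' Build a word-trajectory graph from a token sequence
#'
#' Each unique word becomes a node and every consecutive token pair
#' contributes one directed edge, so the edge list is an ordered multiset:
#' repeated transitions are retained and a consecutively repeated word forms
#' a self-loop. A graph built from one contiguous transcript therefore has
#' exactly `length(tokens) - 1` edges and is weakly connected.
#'
#' @param x character vector of tokens, or a [transcript()].
#' @param drop_self_loops drop edges created by a word immediately repeating
#'   itself (default `FALSE`: self-loops count as edges and make their node a
#'   singleton strong component).
#' @return object of class `"speech_graph"`: list with `tokens`, `nodes`
#'   (distinct words), `edges` (two-column character matrix in temporal
#'   order) and `graph` (the underlying [igraph::graph] directed multigraph).
#' @examples
#' g <- speech_graph(c("a", "b", "c", "a", "b"))
#' g
#' @export
speech_graph <- function(x, drop_self_loops = FALSE) {
  toks <- if (inherits(x, "transcript")) x$tokens else as.character(x)
  if (length(toks) == 0L) stop("cannot build a graph from zero tokens",
                               call. = FALSE)
  nodes <- unique(toks)
  if (length(toks) == 1L) {
    edges <- matrix(character(0), ncol = 2,
                    dimnames = list(NULL, c("source", "target")))
  } else {
    edges <- cbind(source = toks[-length(toks)], target = toks[-1L])
  }
  if (drop_self_loops && nrow(edges) > 0L) {
    edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = length(nodes), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(edges) > 0L) {
    idx <- rbind(match(edges[, 1L], nodes), match(edges[, 2L], nodes))
    g <- igraph::add_edges(g, as.vector(idx))
  }
  structure(list(tokens = toks, nodes = nodes, edges = edges, graph = g),
            class = "speech_graph")
}

#' @export
print.speech_graph <- function(x, ...) {
  cat(sprintf("<speech_graph> %d nodes, %d directed edges (multigraph)\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
plot.speech_graph <- function(x, ...) {
  plot(x$graph, edge.arrow.size = 0.4, vertex.size = 16,
       vertex.label.cex = 0.8, ...)
}

#' Export a speech graph as a directed edge list
#'
#' Writes a TSV with columns `source`, `target`, `occurrence_index`
#' (temporal order of the transition), loadable by standard graph tools.
#'
#' @param g a [speech_graph()].
#' @param path output file.
#' @export
write_edgelist <- function(g, path) {
  stopifnot(inherits(g, "speech_graph"))
  df <- data.frame(source = g$edges[, 1L], target = g$edges[, 2L],
                   occurrence_index = seq_len(nrow(g$edges)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Fast path used in hot loops (surrogates, calibration): tokens already
# mapped to integer ids in 1..k. Returns c(LCC, LSC) node counts.
.lcc_lsc <- function(ids, k) {
  if (length(ids) < 2L) return(c(1L, 1L))
  g <- igraph::graph_from_edgelist(
    cbind(ids[-length(ids)], ids[-1L]), directed = TRUE)
  c(as.integer(max(igraph::components(g, mode = "weak")$csize)),
    as.integer(max(igraph::components(g, mode = "strong")$csize)))
}

#' Connectedness attributes of a speech graph
#'
#' Computes the connectedness panel of one report: `E`, the multigraph edge
#' count (every word-to-word transition, a direct verbosity measure); `LCC`,
#' the node count of the largest component whose members are linked by some
#' path ignoring edge direction; `LSC`, the node count of the largest
#' component whose members are all mutually reachable along directed paths
#' (recurrent "loop" structure); plus each attribute divided by the word
#' rate (token count of the time-limited report).
#'
#' @param g a [speech_graph()], [transcript()] or token vector.
#' @param word_rate number of words produced in the report; defaults to the
#'   token count of `g`.
#' @return object of class `"connectedness"`: named list `E`, `LCC`, `LSC`,
#'   `word_rate`, `E_norm`, `LCC_norm`, `LSC_norm`.
#' @examples
#' connectedness(c("a", "b", "c", "a", "b"))
#' @export
connectedness <- function(g, word_rate = NULL) {
  if (!inherits(g, "speech_graph")) g <- speech_graph(g)
  if (is.null(word_rate)) word_rate <- length(g$tokens)
  if (!is.numeric(word_rate) || word_rate <= 0) {
    stop("word_rate must be a positive number", call. = FALSE)
  }
  E <- nrow(g$edges)
  comps_w <- igraph::components(g$graph, mode = "weak")
  comps_s <- igraph::components(g$graph, mode = "strong")
  out <- list(E = as.integer(E),
              LCC = as.integer(max(comps_w$csize)),
              LSC = as.integer(max(comps_s$csize)),
              word_rate = word_rate)
  out$E_norm <- out$E / word_rate
  out$LCC_norm <- out$LCC / word_rate
  out$LSC_norm <- out$LSC / word_rate
  structure(out, class = "connectedness")
}

#' @export
print.connectedness <- function(x, ...) {
  cat(sprintf(
    "<connectedness> E=%g LCC=%g LSC=%g word_rate=%g (E/w=%.3f LCC/w=%.3f LSC/w=%.3f)\n",
    x$E, x$LCC, x$LSC, x$word_rate, x$E_norm, x$LCC_norm, x$LSC_norm))
  invisible(x)
}

#' Average connectedness over sliding 30-word windows
#'
#' For protocols without a time limit, verbosity is controlled by averaging
#' graph attributes over fixed-length windows of consecutive tokens instead
#' of normalizing by word rate. Each window of `window` tokens is built into
#' its own graph; attributes are averaged arithmetically across windows.
#' The default step of 1 gives maximally overlapping windows.
#'
#' @param tokens character vector (or [transcript()]).
#' @param window window length in tokens (default 30, minimum 2).
#' @param step advance between consecutive windows (default 1).
#' @return object of class `"connectedness"` whose `E`, `LCC`, `LSC` are
#'   window means; `word_rate` is the window length and the `_norm` fields
#'   divide by it.
#' @export
windowed_attributes <- function(tokens, window = 30L, step = 1L) {
  if (inherits(tokens, "transcript")) tokens <- tokens$tokens
  window <- as.integer(window); step <- as.integer(step)
  if (window < 2L) stop("window must be at least 2 tokens", call. = FALSE)
  if (step < 1L) stop("step must be at least 1", call. = FALSE)
  n <- length(tokens)
  if (n < window) {
    stop("report has fewer tokens than the window; ",
         "use whole-report attributes instead", call. = FALSE)
  }
  starts <- seq.int(1L, n - window + 1L, by = step)
  ids_all <- match(tokens, unique(tokens))
  acc <- vapply(starts, function(s) {
    ids <- ids_all[s:(s + window - 1L)]
    cl <- .lcc_lsc(match(ids, unique(ids)), length(unique(ids)))
    c(E = window - 1, LCC = cl[1L], LSC = cl[2L])
  }, numeric(3))
  m <- rowMeans(acc)
  structure(list(E = m[["E"]], LCC = m[["LCC"]], LSC = m[["LSC"]],
                 word_rate = window,
                 E_norm = m[["E"]] / window,
                 LCC_norm = m[["LCC"]] / window,
                 LSC_norm = m[["LSC"]] / window),
            class = "connectedness")
}
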