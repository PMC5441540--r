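test_that("tokenizer lowercases, strips boundary punctuation, keeps order", {
  expect_equal(tokenize("A dog. The dog ran"), c("a", "dog", "the", "dog", "ran"))
  expect_equal(tokenize("word"), "word")
  expect_equal(tokenize("  \n "), character(0))
  # intra-word hyphen/apostrophe survive; boundary punctuation does not
  expect_equal(tokenize("it's a well-known (fact)."),
               c("it's", "a", "well-known", "fact"))
  expect_equal(tokenize("Dog", lowercase = FALSE), "Dog")
  expect_error(transcript(""), "empty transcript")
})

test_that("graph construction keeps one edge per transition, repeats and self-loops", {
  g <- speech_graph(c("a", "b", "c", "a", "b"))
  expect_setequal(g$nodes, c("a", "b", "c"))
  expect_equal(nrow(g$edges), 4L)
  expect_equal(unname(g$edges[, 1]), c("a", "b", "c", "a"))
  expect_equal(unname(g$edges[, 2]), c("b", "c", "a", "b"))

  g1 <- speech_graph("w")
  expect_equal(g1$nodes, "w")
  expect_equal(nrow(g1$edges), 0L)

  gs <- speech_graph(c("a", "a"))
  expect_equal(nrow(gs$edges), 1L)
  expect_equal(unname(gs$edges[1, ]), c("a", "a"))
  expect_equal(nrow(speech_graph(c("a", "a"), drop_self_loops = TRUE)$edges), 0L)

  expect_error(speech_graph(character(0)), "zero tokens")
})

test_that("connectedness attributes match definitions and the reachability oracle", {
  a <- connectedness(c("a", "b", "c", "a", "b"))
  expect_equal(a$E, 4L)
  expect_equal(a$LCC, 3L)
  expect_equal(a$LSC, 3L)  # cycle a -> b -> c -> a
  expect_equal(a$word_rate, 5)
  expect_equal(a$E_norm, 4 / 5)

  path <- connectedness(c("a", "b", "c", "d"))
  expect_equal(path$E, 3L)
  expect_equal(path$LCC, 4L)
  expect_equal(path$LSC, 1L)

  loop <- connectedness(c("a", "a"))
  expect_equal(loop$E, 1L)
  expect_equal(loop$LCC, 1L)
  expect_equal(loop$LSC, 1L)  # self-loop: node is its own strong component

  expect_error(connectedness(c("a", "b"), word_rate = 0), "positive")
})

test_that("attribute invariants hold and LCC/LSC equal the brute-force oracle", {
  set.seed(101)
  for (i in 1:300) {
    toks <- random_tokens(sample(2:25, 1), sample(1:10, 1))
    att <- connectedness(toks)
    expect_equal(att$E, length(toks) - 1L)
    expect_true(1 <= att$LSC)
    expect_true(att$LSC <= att$LCC)
    expect_true(att$LCC <= length(unique(toks)))
    expect_true(length(unique(toks)) <= length(toks))
    orc <- oracle_lcc_lsc(toks)
    expect_equal(att$LCC, orc$LCC)
    expect_equal(att$LSC, orc$LSC)
    # permuting tokens never changes E or the node set
    perm <- sample(toks)
    expect_equal(connectedness(perm)$E, att$E)
    expect_setequal(unique(perm), unique(toks))
  }
})

test_that("appending a strong-component member after another member never shrinks the LSC", {
  set.seed(7)
  tried <- 0L
  for (i in 1:200) {
    toks <- random_tokens(sample(6:30, 1), sample(3:8, 1))
    g <- speech_graph(toks)
    comp <- igraph::components(g$graph, mode = "strong")
    big <- which.max(comp$csize)
    members <- g$nodes[comp$membership == big]
    if (comp$csize[big] < 2) next
    tried <- tried + 1L
    lsc0 <- connectedness(toks)$LSC
    ext <- c(toks, sample(members, 1), sample(members, 1))
    expect_gte(connectedness(ext)$LSC, lsc0)
  }
  expect_gt(tried, 50L)
})

test_that("windowed attributes average per-window graphs", {
  toks30 <- random_tokens(30, 8)
  w <- windowed_attributes(toks30, window = 30)
  a <- connectedness(toks30)
  expect_equal(w$E, a$E)
  expect_equal(w$LCC, a$LCC)
  expect_equal(w$LSC, a$LSC)

  alt <- rep(c("a", "b"), length.out = 31)
  w2 <- windowed_attributes(alt, window = 30, step = 1)
  expect_equal(w2$E, 29)
  expect_equal(w2$LCC, 2)
  expect_equal(w2$LSC, 2)

  expect_error(windowed_attributes(random_tokens(10, 5), window = 30),
               "whole-report")
  expect_error(windowed_attributes(random_tokens(40, 5), window = 1))

  # step > 1 drops intermediate windows
  set.seed(1)
  toks <- random_tokens(50, 6)
  w_5 <- windowed_attributes(toks, window = 30, step = 5)
  manual <- sapply(seq(1, 21, by = 5),
                   function(s) connectedness(toks[s:(s + 29)])$LSC)
  expect_equal(w_5$LSC, mean(manual))
})

test_that("transcripts round-trip through TSV and directory readers", {
  tmp <- tempfile(fileext = ".tsv")
  df <- data.frame(subject_id = c("s1", "s2"),
                   report_type = c("dream", "image_negative"),
                   text = c("A dog. The dog ran", "one two three"))
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  trs <- read_transcripts(tmp)
  expect_length(trs, 2L)
  expect_equal(trs[[1]]$tokens, c("a", "dog", "the", "dog", "ran"))
  expect_equal(trs[[2]]$report_type, "image_negative")

  d <- tempfile(); dir.create(d)
  writeLines("hello world hello", file.path(d, "s9_dream.txt"))
  trd <- read_transcripts(d)
  expect_equal(trd[[1]]$subject_id, "s9")
  expect_equal(trd[[1]]$report_type, "dream")
  expect_equal(trd[[1]]$tokens, c("hello", "world", "hello"))

  g <- speech_graph(trd[[1]])
  f <- tempfile(fileext = ".tsv")
  write_edgelist(g, f)
  el <- read.delim(f)
  expect_equal(nrow(el), 2L)
  expect_equal(el$occurrence_index, 1:2)
})
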