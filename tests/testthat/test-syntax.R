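fig_tree <- function() {
  parsed_sentence("fig", c("rs429358", "associated", "risk", "dementia"),
                  c("NN", "JJ", "NN", "NN"), c(2L, NA, 2L, 3L),
                  c("nsubj", "root", "nmod", "nmod"))
}

test_that("shortest_path returns the unique tree path and its LCA", {
  # chain root <- x <- y
  s <- parsed_sentence("ch", c("y", "x", "root"), rep("NN", 3),
                       c(2L, 3L, NA), c("d1", "d2", "root"))
  p <- shortest_path(s, 1L, 3L)
  expect_identical(p$nodes, c(1L, 2L, 3L))
  expect_identical(p$lca, 3L)
  expect_identical(p$edges, c("d1", "d2"))

  # siblings under a root
  s2 <- parsed_sentence("sib", c("a", "r", "b"), rep("NN", 3),
                        c(2L, NA, 2L), c("da", "root", "db"))
  p2 <- shortest_path(s2, 1L, 3L)
  expect_identical(p2$nodes, c(1L, 2L, 3L))
  expect_identical(p2$lca, 2L)
  expect_error(shortest_path(s2, 2L, 2L), "degenerate")
})

test_that("shortest_path equals brute-force BFS on every rooted 5-node tree", {
  n <- 5L
  choices <- lapply(2:n, function(i) setdiff(1:n, i))
  n_trees <- 0L
  for (h2 in choices[[1]]) for (h3 in choices[[2]])
    for (h4 in choices[[3]]) for (h5 in choices[[4]]) {
      head <- c(NA, h2, h3, h4, h5)
      if (!is_tree_oracle(head)) next
      n_trees <- n_trees + 1L
      s <- parsed_sentence("x", sprintf("w%d", 1:n), rep("NN", n),
                           head, rep("dep", n))
      for (a in 1:n) for (b in 1:n) {
        if (a == b) next
        expect_identical(shortest_path(s, a, b)$nodes,
                         as.integer(bfs_path_oracle(head, a, b)))
      }
    }
  # rooted labeled trees on 5 nodes with a fixed root: 5^(5-2) = 125
  expect_identical(n_trees, 125L)
})

test_that("shortest_path equals BFS on random 12-node trees", {
  set.seed(31)
  for (draw in 1:200) {
    head <- random_head_vector(12L)
    s <- parsed_sentence("r", sprintf("w%d", 1:12), rep("NN", 12),
                         head, sprintf("d%d", 1:12))
    ab <- sample.int(12L, 2L)
    expect_identical(shortest_path(s, ab[1], ab[2])$nodes,
                     as.integer(bfs_path_oracle(head, ab[1], ab[2])))
  }
})

test_that("the three pattern dialects reproduce the running example", {
  s <- fig_tree()
  p <- shortest_path(s, 1L, 4L)
  expect_identical(render_pattern(s, p, "POS_DT"), "NN nsubj *JJ* nmod NN nmod NN")
  expect_identical(render_pattern(s, p, "POS"), "NN *JJ* NN NN")
  expect_identical(render_pattern(s, p, "DT"), "nsubj ** nmod nmod")
})

test_that("pattern rendering handles an entity at the LCA and counts symbols", {
  # parent = LCA: *VBZ* dobj NN
  s <- parsed_sentence("p", c("eats", "fish"), c("VBZ", "NN"),
                       c(NA, 1L), c("root", "dobj"))
  p <- shortest_path(s, 1L, 2L)
  expect_identical(render_pattern(s, p, "POS_DT"), "*VBZ* dobj NN")
  expect_identical(render_pattern(s, p, "DT"), "** dobj")

  set.seed(37)
  for (draw in 1:20) {
    sr <- random_sentence(9L)
    ab <- sample.int(9L, 2L)
    pr <- shortest_path(sr, ab[1], ab[2])
    L <- length(pr$nodes)
    n_tok <- function(x) length(strsplit(x, " ", fixed = TRUE)[[1]])
    expect_identical(n_tok(render_pattern(sr, pr, "POS_DT")), 2L * L - 1L)
    expect_identical(n_tok(render_pattern(sr, pr, "POS")), L)
    expect_identical(n_tok(render_pattern(sr, pr, "DT")), L)
  }
})

test_that("pattern distributions normalize over true-relation instances", {
  s <- fig_tree()
  i1 <- relation_instance(s, c(1L, 1L), c(4L, 4L), "pos")
  i2 <- relation_instance(s, c(1L, 1L), c(4L, 4L), "pos")
  co <- re_corpus("d", list(i1, i2), label_set = c("pos", "FALSE"))
  d <- pattern_distribution(co, "POS_DT")
  expect_identical(nrow(d), 1L)
  expect_equal(d$freq, 1)

  # 3 instances, two sharing a pattern
  s2 <- parsed_sentence("v", c("a", "links", "b"), c("NN", "VBZ", "NN"),
                        c(2L, NA, 2L), c("nsubj", "root", "dobj"))
  i3 <- relation_instance(s2, c(1L, 1L), c(3L, 3L), "pos")
  co2 <- re_corpus("d2", list(i1, i2, i3), label_set = c("pos", "FALSE"))
  d2 <- pattern_distribution(co2, "POS_DT")
  expect_equal(sort(d2$freq), c(1 / 3, 2 / 3))
  expect_equal(sum(d2$freq), 1, tolerance = 1e-9)

  # only excluded labels -> empty distribution
  neg <- re_corpus("n", list(relation_instance(s, c(1L, 1L), c(4L, 4L), "FALSE")),
                   label_set = c("pos", "FALSE"))
  expect_identical(nrow(pattern_distribution(neg, "POS_DT",
                                             exclude_labels = "FALSE")), 0L)
})

test_that("mirror canonicalization collapses a pattern with its reverse", {
  s <- parsed_sentence("v", c("a", "links", "b"), c("NN", "VBZ", "NN"),
                       c(2L, NA, 2L), c("nsubj", "root", "dobj"))
  fwd <- relation_instance(s, c(1L, 1L), c(3L, 3L), "pos")     # subject first
  s2 <- parsed_sentence("w", c("b", "links", "a"), c("NN", "VBZ", "NN"),
                        c(2L, NA, 2L), c("dobj", "root", "nsubj"))
  rev <- relation_instance(s2, c(1L, 1L), c(3L, 3L), "pos")    # object first
  co_f <- re_corpus("f", list(fwd)); co_r <- re_corpus("r", list(rev))
  # default: the two readings are distinct patterns
  expect_equal(pattern_cosine(pattern_distribution(co_f, "POS_DT"),
                              pattern_distribution(co_r, "POS_DT")), 0)
  # canonicalized: they collapse onto the same string
  expect_equal(pattern_cosine(
    pattern_distribution(co_f, "POS_DT", canonical_mirror = TRUE),
    pattern_distribution(co_r, "POS_DT", canonical_mirror = TRUE)), 1)
})

test_that("pattern cosine is symmetric, bounded, and exact on the hand example", {
  mk <- function(pats, freqs, dialect = "POS_DT") {
    d <- tibble::tibble(pattern = pats, n = 1L, freq = freqs)
    attr(d, "dialect") <- dialect
    d
  }
  d1 <- mk("A", 1)
  d2 <- mk(c("A", "B"), c(0.5, 0.5))
  expect_equal(pattern_cosine(d1, d2), 0.5 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(pattern_cosine(d1, d1), 1)
  expect_equal(pattern_cosine(mk("A", 1), mk("B", 1)), 0)
  expect_error(pattern_cosine(d1, mk("A", 1, dialect = "DT")), "dialect mismatch")

  set.seed(41)
  for (draw in 1:50) {
    k1 <- sample(1:6, 1); k2 <- sample(1:6, 1)
    f1 <- stats::runif(k1); f2 <- stats::runif(k2)
    a <- mk(sample(LETTERS[1:8], k1), f1 / sum(f1))
    b <- mk(sample(LETTERS[1:8], k2), f2 / sum(f2))
    cab <- pattern_cosine(a, b)
    expect_equal(cab, pattern_cosine(b, a), tolerance = 1e-12)
    expect_gte(cab, 0); expect_lte(cab, 1 + 1e-12)
    # proportional distributions have cosine 1
    expect_equal(pattern_cosine(a, a), 1, tolerance = 1e-12)
  }
})

test_that("dictionary coverage counts target word types found in the source", {
  mk_corpus <- function(words, name) {
    n <- length(words)
    s <- parsed_sentence(name, words, rep("NN", n),
                         c(NA, rep(1L, n - 1L)), rep("dep", n))
    re_corpus(name, list(relation_instance(s, c(1L, 1L), c(2L, 2L), "r")))
  }
  t4 <- mk_corpus(c("a", "b", "c", "d"), "t")
  s3 <- mk_corpus(c("a", "b", "x"), "s")
  expect_equal(dictionary_coverage(t4, s3), 50)
  expect_equal(dictionary_coverage(t4, t4), 100)
  disj <- mk_corpus(c("p", "q"), "u")
  expect_equal(dictionary_coverage(t4, disj), 0)
  empty <- re_corpus("e", list())
  expect_error(dictionary_coverage(empty, s3), "empty vocabulary")
})

test_that("LCA term table lowercases, ranks, and masks entity-internal heads", {
  # every LCA is the verb
  s <- parsed_sentence("l", c("X", "Associated", "Y"), c("NN", "VBZ", "NN"),
                       c(2L, NA, 2L), c("nsubj", "root", "dobj"))
  co <- re_corpus("l", list(relation_instance(s, c(1L, 1L), c(3L, 3L), "r"),
                            relation_instance(s, c(1L, 1L), c(3L, 3L), "r")))
  tab <- lca_term_table(co)
  expect_identical(tab$term, "associated")
  expect_equal(tab$freq, 100)

  # LCA inside an entity span counts as "entity": e1 = [1,2] dominates token 3
  s2 <- parsed_sentence("l2", c("mod", "head", "dep"), c("JJ", "NN", "NN"),
                        c(2L, NA, 2L), c("nmod", "root", "nmod"))
  i_ent <- relation_instance(s2, c(1L, 2L), c(3L, 3L), "r")
  co2 <- re_corpus("l2", list(i_ent))
  expect_identical(lca_term_table(co2)$term, "entity")

  # mixed counts: (x, x, entity, y) -> 50 / 25 / 25
  co3 <- re_corpus("l3", list(
    relation_instance(s, c(1L, 1L), c(3L, 3L), "r"),
    relation_instance(s, c(1L, 1L), c(3L, 3L), "r"),
    i_ent,
    relation_instance(
      parsed_sentence("y", c("A", "Yoked", "B"), c("NN", "VBZ", "NN"),
                      c(2L, NA, 2L), c("nsubj", "root", "dobj")),
      c(1L, 1L), c(3L, 3L), "r")))
  tab3 <- lca_term_table(co3)
  expect_equal(tab3$freq[tab3$term == "associated"], 50)
  expect_equal(tab3$freq[tab3$term == "entity"], 25)
  expect_equal(tab3$freq[tab3$term == "yoked"], 25)
})

test_that("similarity_report bundles cosines, coverage and LCA tables", {
  pair <- generate_transfer_pair(0.5, 40L, 40L, seed = 5L)
  rep <- similarity_report(pair$target, pair$source)
  expect_identical(rep$cosines$dialect, c("POS_DT", "POS", "DT"))
  expect_true(all(rep$cosines$cosine >= 0 & rep$cosines$cosine <= 1))
  expect_equal(rep$coverage, 0)  # vocabularies are disjoint by construction
  td <- tidy(rep)
  expect_identical(nrow(td), 3L)
})
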