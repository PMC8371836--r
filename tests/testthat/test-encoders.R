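test_that("embedding lookup assigns entity roles and the unknown-word row", {
  set.seed(7)
  tb <- embedding_tables(c("alpha", "beta", "gamma", "delta"), d_w = 5L, d_e = 3L)
  s <- parsed_sentence("e", c("Alpha", "beta", "zzz", "delta"), rep("NN", 4),
                       c(2L, NA, 2L, 2L), rep("dep", 4))
  inst <- relation_instance(s, c(1L, 1L), c(4L, 4L), "r")
  X <- embed_instance(inst, tb)
  expect_identical(dim(X), c(8L, 4L))
  # lookup is case-insensitive
  expect_equal(X[1:5, 1], tb$word_table[1, ])
  # out-of-vocabulary form maps to the UNK row (last row)
  expect_equal(X[1:5, 3], tb$word_table[5, ])
  # role sequence: first, other, other, second
  expect_equal(X[6:8, 1], tb$entity_table[1, ])
  expect_equal(X[6:8, 2], tb$entity_table[3, ])
  expect_equal(X[6:8, 3], tb$entity_table[3, ])
  expect_equal(X[6:8, 4], tb$entity_table[2, ])
})

test_that("pre-trained vectors seed matching word rows", {
  pre <- matrix(1:6 / 10, 2, 3, dimnames = list(c("beta", "nomatch"), NULL))
  set.seed(1)
  tb <- embedding_tables(c("alpha", "beta"), d_w = 3L, d_e = 2L, pretrained = pre)
  expect_equal(tb$word_table[2, ], pre["beta", ])
  expect_false(all(tb$word_table[1, ] == pre["nomatch", ]))
})

test_that("childsum_step matches scalar hand computations", {
  p0 <- zero_treelstm(1L, 1L)
  st <- childsum_step(0, list(), p0)
  expect_equal(st$c, 0)
  expect_equal(st$h, 0)

  p1 <- zero_treelstm(1L, 1L)
  p1$W_u[] <- 1
  st1 <- childsum_step(1, list(), p1)
  expect_equal(st1$c, 0.5 * tanh(1), tolerance = 1e-12)
  expect_equal(st1$h, 0.5 * tanh(0.5 * tanh(1)), tolerance = 1e-12)

  # child-state permutation leaves the step unchanged
  set.seed(3)
  p <- treelstm_params(4L, 3L)
  kids <- lapply(1:3, function(i) list(c = rnorm(3), h = rnorm(3)))
  a <- childsum_step(rnorm(4), kids, p)
  # reuse same x
  x <- rnorm(4)
  a <- childsum_step(x, kids, p)
  b <- childsum_step(x, kids[c(3, 1, 2)], p)
  expect_equal(a$h, b$h, tolerance = 1e-12)
  expect_equal(a$c, b$c, tolerance = 1e-12)
})

test_that("treelstm_forward agrees with a recursive application of childsum_step", {
  set.seed(11)
  for (rep in 1:5) {
    s <- random_sentence(7L)
    inst <- relation_instance(s, c(1L, 1L), c(3L, 3L), "r")
    tb <- embedding_tables(tolower(s$form), d_w = 4L, d_e = 2L)
    p <- treelstm_params(6L, 5L)
    r <- treelstm_forward(inst, tb, p)
    # reference: recurse with the R-level step
    X <- embed_instance(inst, tb)
    rec <- function(j) {
      kids <- which(!is.na(s$head) & s$head == j)
      childsum_step(X[, j], lapply(kids, rec), p)
    }
    root <- which(is.na(s$head))
    expect_equal(r, rec(root)$h, tolerance = 1e-12)
  }
})

test_that("all-zero parameters yield a zero sentence representation", {
  s <- random_sentence(6L)
  inst <- relation_instance(s, c(1L, 1L), c(2L, 2L), "r")
  set.seed(2)
  tb <- embedding_tables(tolower(s$form), d_w = 3L, d_e = 2L)
  expect_equal(treelstm_forward(inst, tb, zero_treelstm(5L, 4L)), rep(0, 4))

  mp <- mccnn_params(5L, d_h = 3L, kernel_sizes = c(2L, 3L), channels = 2L)
  for (q in 1:2) {
    for (ch in 1:2) mp$W[[q]][[ch]][] <- 0
    mp$b[[q]][] <- 0
  }
  expect_equal(mccnn_encode(inst, tb, mp), rep(0, 6))
})

test_that("treelstm on chain trees equals a sequential LSTM sweep", {
  set.seed(5)
  for (draw in 1:20) {
    n <- sample(3:7, 1L)
    d_in <- 3L; d_h <- 4L
    p <- treelstm_params(d_in, d_h)
    X <- matrix(rnorm(d_in * n), d_in, n)
    # chain: token 1 is the leaf, token n the root
    head <- c(2:n, NA_integer_)
    state <- list(h = rep(0, d_h), c = rep(0, d_h))
    for (j in seq_len(n)) state <- lstm_cell_oracle(X[, j], state$h, state$c, p)
    parent <- ifelse(is.na(head), 0L, head)
    mask <- matrix(1, d_h, n)
    out <- synre:::cpp_treelstm_forward(X, as.integer(parent), unclass(p), mask, "h")
    expect_equal(drop(out$r), state$h, tolerance = 1e-10)
  }
})

test_that("treelstm output is invariant to sibling order", {
  set.seed(9)
  for (draw in 1:50) {
    n <- sample(4:10, 1L)
    head <- random_head_vector(n)
    d_in <- 3L; d_h <- 4L
    p <- treelstm_params(d_in, d_h)
    X <- matrix(rnorm(d_in * n), d_in, n)
    parent <- as.integer(ifelse(is.na(head), 0L, head))
    mask <- matrix(1, d_h, n)
    r1 <- drop(synre:::cpp_treelstm_forward(X, parent, unclass(p), mask, "h")$r)
    # relabel the nodes with a random permutation (changes traversal order)
    perm <- sample.int(n)
    head2 <- rep(NA_integer_, n)
    for (i in seq_len(n)) if (!is.na(head[i])) head2[perm[i]] <- perm[head[i]]
    X2 <- X[, order(perm), drop = FALSE]
    parent2 <- as.integer(ifelse(is.na(head2), 0L, head2))
    r2 <- drop(synre:::cpp_treelstm_forward(X2, parent2, unclass(p), mask, "h")$r)
    expect_equal(r1, r2, tolerance = 1e-12)
  }
})

test_that("mccnn_forward matches the scalar hand computation and the loop oracle", {
  # single window, d = 1: tanh(1*1 + 1*(-1) + 0.5) = tanh(0.5)
  pars <- mccnn_params(1L, d_h = 1L, kernel_sizes = 2L, channels = 1L)
  pars$W[[1]][[1]] <- matrix(c(1, 1), 1, 2)
  pars$b[[1]] <- 0.5
  expect_equal(mccnn_forward(matrix(c(1, -1), 1, 2), pars), tanh(0.5),
               tolerance = 1e-12)

  set.seed(13)
  for (draw in 1:10) {
    d_in <- 4L; N <- sample(2:8, 1L)
    mp <- mccnn_params(d_in, d_h = 3L, kernel_sizes = c(2L, 3L), channels = 2L)
    Xs <- lapply(1:2, function(i) matrix(rnorm(d_in * N), d_in, N))
    expect_equal(mccnn_forward(Xs, mp),
                 mccnn_oracle(Xs, mp$W, mp$b, mp$kernel_sizes),
                 tolerance = 1e-12)
  }
})

test_that("representation widths follow the stated hyper-parameters", {
  s <- random_sentence(6L)
  inst <- relation_instance(s, c(1L, 1L), c(2L, 2L), "r")
  set.seed(21)
  tb <- embedding_tables(tolower(s$form), d_w = 100L, d_e = 10L)
  expect_identical(nrow(embed_instance(inst, tb)), 110L)
  mp <- mccnn_params(110L, d_h = 100L, kernel_sizes = c(3L, 5L), channels = 2L)
  expect_length(mccnn_encode(inst, tb, mp), 200L)
  tp <- treelstm_params(110L, 200L)
  expect_length(treelstm_forward(inst, tb, tp), 200L)
})

test_that("max-pooling ignores windows dominated by existing maxima", {
  set.seed(17)
  mp <- mccnn_params(3L, d_h = 2L, kernel_sizes = 1L, channels = 1L)
  X <- matrix(rnorm(12), 3, 4)
  r1 <- mccnn_forward(X, mp)
  # duplicating a column adds windows whose pre-activations equal existing ones
  r2 <- mccnn_forward(cbind(X, X[, 2]), mp)
  expect_identical(r1, r2)
})

test_that("short sentences are zero-padded up to the kernel width", {
  set.seed(19)
  mp <- mccnn_params(3L, d_h = 2L, kernel_sizes = 5L, channels = 1L)
  X <- matrix(rnorm(6), 3, 2)
  r <- mccnn_forward(X, mp)
  expect_length(r, 2L)
  expect_true(all(is.finite(r)))
  # padded input equals explicit zero-padding
  Xp <- cbind(matrix(0, 3, 1), X, matrix(0, 3, 2))
  expect_equal(r, mccnn_forward(Xp, mp), tolerance = 1e-12)
})

test_that("encoders are deterministic for fixed inputs", {
  set.seed(23)
  s <- random_sentence(8L)
  inst <- relation_instance(s, c(1L, 1L), c(4L, 4L), "r")
  tb <- embedding_tables(tolower(s$form), d_w = 6L, d_e = 3L)
  tp <- treelstm_params(9L, 5L)
  expect_identical(treelstm_forward(inst, tb, tp), treelstm_forward(inst, tb, tp))
  mp <- mccnn_params(9L, d_h = 4L, kernel_sizes = c(2L, 3L), channels = 2L)
  expect_identical(mccnn_encode(inst, tb, mp), mccnn_encode(inst, tb, mp))
})

test_that("readout switch exposes the root output gate", {
  set.seed(29)
  s <- random_sentence(5L)
  inst <- relation_instance(s, c(1L, 1L), c(2L, 2L), "r")
  tb <- embedding_tables(tolower(s$form), d_w = 4L, d_e = 2L)
  tp <- treelstm_params(6L, 3L)
  h <- treelstm_forward(inst, tb, tp, readout = "h")
  o <- treelstm_forward(inst, tb, tp, readout = "o")
  expect_false(isTRUE(all.equal(h, o)))
  expect_true(all(o > 0 & o < 1))  # a sigmoid gate
})
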