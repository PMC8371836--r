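# Independent oracles used across the suite. These deliberately share no code
# with the package internals they check.

# breadth-first search on the undirected edge set of a head vector;
# returns the node index path from a to b
bfs_path_oracle <- function(head, a, b) {
  n <- length(head)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    h <- head[i]
    if (!is.na(h)) {
      adj[[i]] <- c(adj[[i]], h)
      adj[[h]] <- c(adj[[h]], i)
    }
  }
  prev <- rep(NA_integer_, n)
  seen <- rep(FALSE, n)
  queue <- a
  seen[a] <- TRUE
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    if (u == b) break
    for (v in adj[[u]]) if (!seen[v]) {
      seen[v] <- TRUE; prev[v] <- u; queue <- c(queue, v)
    }
  }
  path <- b
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  path
}

# a head vector is a tree iff the undirected edges connect all nodes
# (n-1 edges are guaranteed by construction, so connectivity <=> acyclicity)
is_tree_oracle <- function(head) {
  n <- length(head)
  if (sum(is.na(head)) != 1L) return(FALSE)
  if (any(head == seq_len(n), na.rm = TRUE)) return(FALSE)
  reached <- rep(FALSE, n)
  start <- which(is.na(head))
  reached[start] <- TRUE
  repeat {
    new <- reached
    for (i in seq_len(n)) if (!is.na(head[i]) && (reached[i] || reached[head[i]])) {
      new[i] <- TRUE; new[head[i]] <- TRUE
    }
    if (identical(new, reached)) break
    reached <- new
  }
  all(reached)
}

# standard LSTM cell: one step of the sequential recurrence
lstm_cell_oracle <- function(x, h_prev, c_prev, p) {
  sg <- function(z) 1 / (1 + exp(-z))
  i <- sg(drop(p$W_i %*% x + p$U_i %*% h_prev) + p$b_i)
  f <- sg(drop(p$W_f %*% x + p$U_f %*% h_prev) + p$b_f)
  o <- sg(drop(p$W_o %*% x + p$U_o %*% h_prev) + p$b_o)
  u <- tanh(drop(p$W_u %*% x + p$U_u %*% h_prev) + p$b_u)
  c_new <- i * u + f * c_prev
  list(h = o * tanh(c_new), c = c_new)
}

# loop-based multichannel CNN forward (sum over channels, tanh, max over time)
mccnn_oracle <- function(Xs, W, b, kernel_sizes) {
  parts <- lapply(seq_along(kernel_sizes), function(q) {
    k <- kernel_sizes[q]
    X1 <- Xs[[1]]
    N <- ncol(X1); d <- nrow(X1)
    if (N < k) {
      left <- (k - N) %/% 2
      Xs <- lapply(Xs, function(X) {
        Xp <- matrix(0, d, k); Xp[, left + seq_len(N)] <- X; Xp
      })
      N <- k
    }
    dh <- length(b[[q]])
    Z <- sapply(seq_len(N - k + 1L), function(i) {
      a <- b[[q]]
      for (ch in seq_along(Xs))
        a <- a + drop(W[[q]][[ch]] %*% as.vector(Xs[[ch]][, i:(i + k - 1L)]))
      tanh(a)
    })
    Z <- matrix(Z, nrow = dh)
    apply(Z, 1L, max)
  })
  unlist(parts)
}

# one-vs-rest precision/recall/F from a base::table confusion matrix
eval_oracle <- function(gold, pred, labels) {
  cm <- table(factor(gold, levels = labels), factor(pred, levels = labels))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  p <- ifelse(tp + fp > 0, 100 * tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, 100 * tp / (tp + fn), 0)
  f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  data.frame(label = labels, precision = as.numeric(p), recall = as.numeric(r),
             f = as.numeric(f))
}

# random rooted tree over n nodes with a uniformly chosen label permutation
random_head_vector <- function(n) {
  stopifnot(n >= 2)
  perm <- sample.int(n)            # perm[k] = label of the k-th attached node
  head <- rep(NA_integer_, n)
  for (k in 2:n) head[perm[k]] <- perm[sample.int(k - 1L, 1L)]
  head
}

random_sentence <- function(n, id = "rnd") {
  parsed_sentence(id, sprintf("w%d", seq_len(n)),
                  sample(c("NN", "JJ", "VBZ", "IN"), n, replace = TRUE),
                  random_head_vector(n),
                  sample(c("nsubj", "nmod", "dobj", "case"), n, replace = TRUE))
}

# fresh zero-initialized treelstm parameter list (for scalar hand checks)
zero_treelstm <- function(d_in, d_h) {
  p <- treelstm_params(d_in, d_h)
  for (nm in grep("^[WUb]_", names(p), value = TRUE)) p[[nm]][] <- 0
  p
}
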