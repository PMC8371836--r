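init_mat <- function(nr, nc) {
  a <- sqrt(1 / nc)
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

#' Initialize multichannel CNN parameters
#'
#' One weight matrix per (kernel, channel) pair of shape `d_h x (k * d_in)`
#' plus one bias per kernel, where `k` is the kernel width and `d_in = d_w +
#' d_e` is the input width. The sentence representation produced by
#' [mccnn_forward()] has length `K * d_h` for `K` kernels. Only the embeddings
#' feeding `trainable_channel` receive gradients during training; the other
#' channels read frozen embedding copies.
#'
#' @param d_in Input width per token (`d_w + d_e`).
#' @param d_h Hidden width per kernel.
#' @param kernel_sizes Integer vector of window widths.
#' @param channels Number of input channels.
#' @param trainable_channel Index of the channel whose embeddings are updated.
#' @return An object of class `mccnn_parameters`.
#' @export
mccnn_params <- function(d_in, d_h = 100L, kernel_sizes = c(3L, 5L),
                         channels = 2L, trainable_channel = 1L) {
  stopifnot(length(kernel_sizes) >= 1, all(kernel_sizes >= 1), d_h > 0,
            channels >= 1, trainable_channel %in% seq_len(channels))
  W <- lapply(kernel_sizes, function(k)
    lapply(seq_len(channels), function(ch) init_mat(d_h, k * d_in)))
  b <- lapply(kernel_sizes, function(k) rep(0, d_h))
  structure(list(W = W, b = b, kernel_sizes = as.integer(kernel_sizes),
                 channels = as.integer(channels), d_h = as.integer(d_h),
                 d_in = as.integer(d_in),
                 trainable_channel = as.integer(trainable_channel),
                 d_s = as.integer(length(kernel_sizes) * d_h)),
            class = "mccnn_parameters")
}

#' Initialize Child-Sum TreeLSTM parameters
#'
#' Gate matrices `W` (`d_h x d_in`), recurrent matrices `U` (`d_h x d_h`) and
#' biases `b` for the four gates (input `i`, forget `f`, output `o`, update
#' `u`). The sentence representation has length `d_h`.
#'
#' @param d_in Input width per token (`d_w + d_e`).
#' @param d_h Hidden width.
#' @return An object of class `treelstm_parameters`.
#' @export
treelstm_params <- function(d_in, d_h = 200L) {
  stopifnot(d_in > 0, d_h > 0)
  p <- list()
  for (gate in c("i", "f", "o", "u")) {
    p[[paste0("W_", gate)]] <- init_mat(d_h, d_in)
    p[[paste0("U_", gate)]] <- init_mat(d_h, d_h)
    p[[paste0("b_", gate)]] <- rep(0, d_h)
  }
  p$d_h <- as.integer(d_h)
  p$d_in <- as.integer(d_in)
  p$d_s <- as.integer(d_h)
  structure(p, class = "treelstm_parameters")
}

#' One Child-Sum TreeLSTM transition
#'
#' Reference implementation of the node update. With `h_tilde` the sum of the
#' children's hidden states (zero for a leaf):
#' \deqn{i_j = \sigma(W^{(i)} x_j + U^{(i)} \tilde h_j + b^{(i)})}
#' \deqn{f_{jk} = \sigma(W^{(f)} x_j + U^{(f)} h_k + b^{(f)})}
#' \deqn{o_j = \sigma(W^{(o)} x_j + U^{(o)} \tilde h_j + b^{(o)})}
#' \deqn{u_j = \tanh(W^{(u)} x_j + U^{(u)} \tilde h_j + b^{(u)})}
#' \deqn{c_j = i_j \odot u_j + \sum_k f_{jk} \odot c_k,\quad
#'       h_j = o_j \odot \tanh(c_j)}
#' The sum over children makes the update invariant to sibling order.
#'
#' @param x_j Input vector of length `d_in`.
#' @param child_states List of child states, each `list(c = , h = )`; empty
#'   for a leaf.
#' @param params A [treelstm_params()] object.
#' @return `list(c = , h = , o = )` for the node.
#' @export
childsum_step <- function(x_j, child_states, params) {
  sigm <- function(z) 1 / (1 + exp(-z))
  d_h <- params$d_h
  h_tilde <- rep(0, d_h)
  for (cs in child_states) h_tilde <- h_tilde + cs$h
  i_j <- sigm(drop(params$W_i %*% x_j + params$U_i %*% h_tilde) + params$b_i)
  o_j <- sigm(drop(params$W_o %*% x_j + params$U_o %*% h_tilde) + params$b_o)
  u_j <- tanh(drop(params$W_u %*% x_j + params$U_u %*% h_tilde) + params$b_u)
  c_j <- i_j * u_j
  for (cs in child_states) {
    f_jk <- sigm(drop(params$W_f %*% x_j + params$U_f %*% cs$h) + params$b_f)
    c_j <- c_j + f_jk * cs$c
  }
  h_j <- o_j * tanh(c_j)
  list(c = c_j, h = h_j, o = o_j)
}

# head vector -> parent vector for the C++ side (0 = root)
parent_vector <- function(head) {
  p <- head
  p[is.na(p)] <- 0L
  as.integer(p)
}

#' Encode a relation instance with the Child-Sum TreeLSTM
#'
#' Applies [childsum_step()] bottom-up (children before parents) over the
#' sentence's dependency tree, with the per-token inputs from
#' [embed_instance()], and reads out the root's hidden state `h_root` (or the
#' root's output gate `o_root` when `readout = "o"`).
#'
#' @param instance A [relation_instance()].
#' @param tables An [embedding_tables()] object.
#' @param params A [treelstm_params()] object.
#' @param readout `"h"` (default) for the root hidden state, `"o"` for the raw
#'   root output gate.
#' @return Numeric sentence representation of length `d_h`.
#' @export
treelstm_forward <- function(instance, tables, params, readout = c("h", "o")) {
  readout <- match.arg(readout)
  X <- embed_instance(instance, tables)
  parent <- parent_vector(instance$sentence$head)
  mask <- matrix(1, params$d_h, ncol(X))
  out <- cpp_treelstm_forward(X, parent, unclass(params), mask, readout)
  drop(out$r)
}

#' Encode token sequences with the multichannel CNN
#'
#' For each kernel of width `k`, every window of `k` consecutive token inputs
#' is scored as `tanh(sum_c W_c [x_i .. x_{i+k-1}]^c + b)` (sum over channels),
#' max-pooled over window positions, and the per-kernel outputs are
#' concatenated into the sentence representation of length `K * d_h`.
#' Sequences shorter than a kernel width are zero-padded to that width.
#'
#' @param inputs A single `d_in x N` matrix (replicated over channels) or a
#'   list of one such matrix per channel.
#' @param params An [mccnn_params()] object.
#' @return Numeric sentence representation of length `K * d_h`.
#' @export
mccnn_forward <- function(inputs, params) {
  if (is.matrix(inputs)) inputs <- rep(list(inputs), params$channels)
  if (length(inputs) != params$channels)
    stop(sprintf("expected %d channels, got %d", params$channels, length(inputs)))
  d <- dim(inputs[[1]])
  for (ch in inputs) if (!all(dim(ch) == d)) stop("channel shape mismatch")
  out <- cpp_mccnn_forward(inputs, params$W, params$b, params$kernel_sizes)
  drop(out$r)
}

#' Encode a relation instance with the multichannel CNN
#'
#' Builds the per-channel input matrices (channel 1 from the trainable
#' embedding tables, remaining channels from frozen word-table copies) and
#' applies [mccnn_forward()].
#'
#' @inheritParams treelstm_forward
#' @param params An [mccnn_params()] object.
#' @param frozen_words Optional list of frozen word tables (one per extra
#'   channel); defaults to reusing the trainable table for every channel.
#' @return Numeric sentence representation of length `K * d_h`.
#' @export
mccnn_encode <- function(instance, tables, params, frozen_words = NULL) {
  ix <- instance_indices(instance, tables)
  ent <- t(tables$entity_table[ix$role, , drop = FALSE])
  chans <- vector("list", params$channels)
  for (ch in seq_len(params$channels)) {
    wt <- if (ch == params$trainable_channel || is.null(frozen_words))
      tables$word_table
    else frozen_words[[if (ch > params$trainable_channel) ch - 1L else ch]]
    chans[[ch]] <- rbind(t(wt[ix$widx, , drop = FALSE]), ent)
  }
  mccnn_forward(chans, params)
}
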