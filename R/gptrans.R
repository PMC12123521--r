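# Graph propagation transformer layer: node-to-node attention with
# edge-derived biases, node-to-edge and edge-to-node propagation, and a
# residual output map. One weight-shared layer is iterated (default three
# times); the graph readout is the super-node row.
#
# Per head h:  A_h = Q_h K_h' / sqrt(d_head) + phi_h,   x' = softmax(A) V
#              x_edge' = (A + softmax(A)) W_expand
#              x''    = FC( sum_j x_edge' * softmax_j(x_edge') )
#              x'''   = (x' + x'') W_O
# The attention runs over all node pairs; graph structure enters through the
# phi biases predicted from the edge latents.

#' Initialise graph propagation transformer parameters
#'
#' Key/query width per head equals `d_k` (which is also the `sqrt(d_head)`
#' scaling constant); the per-head value width is `d_node / n_head` so that
#' the concatenated heads return a `d_node`-wide update.
#'
#' @param d_node node latent width.
#' @param d_edge edge latent width.
#' @param n_head number of attention heads.
#' @param d_k per-head key/query width (= the attention scaling constant).
#' @param seed RNG seed for initialisation.
#' @return list of parameter matrices (class `molfuse_gptrans`).
#' @export
mf_gptrans_params <- function(d_node = 256L, d_edge = 64L, n_head = 4L,
                              d_k = 4L, seed = 1L) {
  stopifnot(d_node %% n_head == 0L)
  set.seed(seed)
  p <- list(
    W_Q = glorot(d_node, n_head * d_k),
    W_K = glorot(d_node, n_head * d_k),
    W_V = glorot(d_node, d_node),
    W_reduce = glorot(d_edge, n_head),
    W_expand = glorot(n_head, d_edge),
    W_en = glorot(d_edge, d_node),
    b_en = numeric(d_node),
    W_O = glorot(d_node, d_node)
  )
  attr(p, "dims") <- list(d_node = d_node, d_edge = d_edge,
                          n_head = n_head, d_k = d_k,
                          d_v = d_node %/% n_head)
  class(p) <- "molfuse_gptrans"
  p
}

.gpt_dims <- function(params) attr(params, "dims")

#' Edge-derived attention biases
#'
#' @param x_edge `N x N x d_edge` edge latent tensor.
#' @param params a [mf_gptrans_params()] list (uses `W_reduce`).
#' @return array `n_head x N x N` of per-head biases.
#' @export
mf_attention_bias <- function(x_edge, params) {
  dm <- .gpt_dims(params)
  N <- dim(x_edge)[1L]
  phi_mat <- matrix(x_edge, N * N, dm$d_edge) %*% params$W_reduce  # (N^2, nh)
  aperm(array(phi_mat, dim = c(N, N, dm$n_head)), c(3L, 1L, 2L))
}

#' Node-to-node attention update
#'
#' @param x_node `N x d_node` node latents.
#' @param phi `n_head x N x N` attention biases.
#' @param params a [mf_gptrans_params()] list.
#' @return list with `x_node_prime` (`N x d_node`) and attention logits `A`
#'   (`n_head x N x N`).
#' @export
mf_node_attention <- function(x_node, phi, params) {
  if (any(!is.finite(x_node))) stop("non-finite node features")
  dm <- .gpt_dims(params)
  N <- nrow(x_node)
  A <- array(0, dim = c(dm$n_head, N, N))
  xp <- matrix(0, N, dm$d_node)
  for (h in seq_len(dm$n_head)) {
    qcols <- (h - 1L) * dm$d_k + seq_len(dm$d_k)
    vcols <- (h - 1L) * dm$d_v + seq_len(dm$d_v)
    Qh <- x_node %*% params$W_Q[, qcols, drop = FALSE]
    Kh <- x_node %*% params$W_K[, qcols, drop = FALSE]
    Vh <- x_node %*% params$W_V[, vcols, drop = FALSE]
    Ah <- tcrossprod(Qh, Kh) / sqrt(dm$d_k) + matrix(phi[h, , ], N, N)
    A[h, , ] <- Ah
    xp[, vcols] <- row_softmax(Ah) %*% Vh
  }
  list(x_node_prime = xp, A = A)
}

#' Node-to-edge update
#'
#' Lifts the per-head attention channels (logits plus their softmax) into the
#' edge feature space.
#'
#' @param A `n_head x N x N` attention logits.
#' @param params a [mf_gptrans_params()] list (uses `W_expand`).
#' @return `N x N x d_edge` updated edge features.
#' @export
mf_node_to_edge <- function(A, params) {
  dm <- .gpt_dims(params)
  N <- dim(A)[2L]
  B <- matrix(0, N * N, dm$n_head)
  for (h in seq_len(dm$n_head)) {
    Ah <- matrix(A[h, , ], N, N)
    B[, h] <- as.vector(Ah + row_softmax(Ah))
  }
  array(B %*% params$W_expand, dim = c(N, N, dm$d_edge))
}

#' Edge-to-node update
#'
#' For each node i the edge features along the second dimension are gated by
#' their neighbour-axis softmax, summed, and mapped back to the node width by
#' a fully connected layer.
#'
#' @param x_edge_prime `N x N x d_edge` updated edge features.
#' @param params a [mf_gptrans_params()] list (uses `W_en`, `b_en`).
#' @return `N x d_node` node update.
#' @export
mf_edge_to_node <- function(x_edge_prime, params) {
  dm <- .gpt_dims(params)
  N <- dim(x_edge_prime)[1L]
  S <- matrix(0, N, dm$d_edge)
  for (i in seq_len(N)) {
    Ti <- matrix(x_edge_prime[i, , ], N, dm$d_edge)
    S[i, ] <- colSums(Ti * col_softmax(Ti))
  }
  sweep(S %*% params$W_en, 2L, params$b_en, "+")
}

#' One full propagation layer
#'
#' @param state list with `x_node` (`N x d_node`) and `x_edge`
#'   (`N x N x d_edge`).
#' @param params a [mf_gptrans_params()] list.
#' @return updated state: `x_node` holds the residual-aggregated node
#'   features, `x_edge` the updated edge features.
#' @export
mf_layer_forward <- function(state, params) {
  phi <- mf_attention_bias(state$x_edge, params)
  att <- mf_node_attention(state$x_node, phi, params)
  x_edge_prime <- mf_node_to_edge(att$A, params)
  x_node_dd <- mf_edge_to_node(x_edge_prime, params)
  x_node_out <- (att$x_node_prime + x_node_dd) %*% params$W_O
  list(x_node = x_node_out, x_edge = x_edge_prime)
}

#' Encode a molecule graph to its graph-level embedding
#'
#' Applies the weight-shared propagation layer `n_iterations` times and
#' returns the super-node row as the molecule representation.
#'
#' @param g a projected graph (see [mf_project_latents()]).
#' @param params a [mf_gptrans_params()] list.
#' @param n_iterations number of propagation iterations.
#' @return numeric vector of length `d_node`.
#' @export
mf_encode_graph <- function(g, params, n_iterations = 3L) {
  if (is.null(g$node_latent)) stop("graph has no latents; run mf_project_latents()")
  state <- list(x_node = g$node_latent, x_edge = g$edge_latent)
  for (it in seq_len(n_iterations)) state <- mf_layer_forward(state, params)
  state$x_node[g$N, ]
}

# --- forward with tape + backward (training path) ---------------------------

.gpt_forward_tape <- function(x_node, x_edge, params, n_iterations) {
  dm <- .gpt_dims(params)
  tape <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    N <- nrow(x_node)
    Q <- x_node %*% params$W_Q
    K <- x_node %*% params$W_K
    V <- x_node %*% params$W_V
    Emat <- matrix(x_edge, N * N, dm$d_edge)
    Phi <- Emat %*% params$W_reduce                      # (N^2, nh)
    Slist <- vector("list", dm$n_head)
    Alist <- vector("list", dm$n_head)
    Bmat <- matrix(0, N * N, dm$n_head)
    xp <- matrix(0, N, dm$d_node)
    for (h in seq_len(dm$n_head)) {
      qcols <- (h - 1L) * dm$d_k + seq_len(dm$d_k)
      vcols <- (h - 1L) * dm$d_v + seq_len(dm$d_v)
      Ah <- tcrossprod(Q[, qcols, drop = FALSE], K[, qcols, drop = FALSE]) /
        sqrt(dm$d_k) + matrix(Phi[, h], N, N)
      Sh <- row_softmax(Ah)
      xp[, vcols] <- Sh %*% V[, vcols, drop = FALSE]
      Alist[[h]] <- Ah
      Slist[[h]] <- Sh
      Bmat[, h] <- as.vector(Ah + Sh)
    }
    EPmat <- Bmat %*% params$W_expand                    # (N^2, d_edge)
    EP <- array(EPmat, dim = c(N, N, dm$d_edge))
    # neighbour-axis gated sum, vectorized over (i, channel) columns:
    # m2 has one column per (i, c) pair, rows indexed by neighbour j
    m2 <- matrix(aperm(EP, c(2L, 1L, 3L)), N, N * dm$d_edge)
    mx <- m2[1L, ]
    if (N > 1L) for (j in 2:N) mx <- pmax(mx, m2[j, ])
    e <- exp(sweep(m2, 2L, mx))
    sm <- sweep(e, 2L, colSums(e), "/")
    s_vec <- colSums(m2 * sm)
    Smat <- matrix(s_vec, N, dm$d_edge)
    x2 <- sweep(Smat %*% params$W_en, 2L, params$b_en, "+")
    x_out <- (xp + x2) %*% params$W_O
    tape[[it]] <- list(x_in = x_node, Emat = Emat, Q = Q, K = K, V = V,
                       A = Alist, S = Slist, Bmat = Bmat, EP = EP,
                       m2 = m2, sm = sm, s_vec = s_vec, Smat = Smat,
                       xp = xp, x2 = x2)
    x_node <- x_out
    x_edge <- EP
  }
  list(x_node = x_node, x_edge = x_edge, tape = tape)
}

# Backward through the iterated shared layer. d_x_out: gradient wrt the final
# x_node (N x d_node). Returns gradients wrt the initial node/edge latents
# plus accumulated parameter gradients.
.gpt_backward <- function(tape, params, d_x_out) {
  dm <- .gpt_dims(params)
  gr <- lapply(params, function(x) array(0, dim = if (is.null(dim(x))) length(x) else dim(x)))
  gr <- lapply(gr, function(x) if (length(dim(x)) == 1L) as.numeric(x) else x)
  d_E_out <- NULL   # gradient wrt the layer's output edge tensor
  for (it in rev(seq_along(tape))) {
    tp <- tape[[it]]
    N <- nrow(tp$x_in)
    # x_out = (xp + x2) W_O
    gr$W_O <- gr$W_O + crossprod(tp$xp + tp$x2, d_x_out)
    d_sum <- d_x_out %*% t(params$W_O)
    d_xp <- d_sum
    d_x2 <- d_sum
    # x2 = Smat W_en + b_en
    gr$W_en <- gr$W_en + crossprod(tp$Smat, d_x2)
    gr$b_en <- gr$b_en + colSums(d_x2)
    d_Smat <- d_x2 %*% t(params$W_en)
    # d s_(i,c) / d T[j,(i,c)] = sm[j] * (1 + T[j] - s); columns are (i, c)
    dm2 <- sweep(tp$sm * sweep(tp$m2, 2L, 1 - tp$s_vec, "+"),
                 2L, as.vector(d_Smat), "*")
    d_EP <- aperm(array(dm2, dim = c(N, N, dm$d_edge)), c(2L, 1L, 3L))
    if (!is.null(d_E_out)) d_EP <- d_EP + d_E_out
    d_EPmat <- matrix(d_EP, N * N, dm$d_edge)
    # EPmat = Bmat W_expand
    gr$W_expand <- gr$W_expand + crossprod(tp$Bmat, d_EPmat)
    d_Bmat <- d_EPmat %*% t(params$W_expand)             # (N^2, nh)
    # per-head attention backward
    d_Q <- matrix(0, N, dm$n_head * dm$d_k)
    d_K <- matrix(0, N, dm$n_head * dm$d_k)
    d_V <- matrix(0, N, dm$d_node)
    d_Phi <- matrix(0, N * N, dm$n_head)
    for (h in seq_len(dm$n_head)) {
      qcols <- (h - 1L) * dm$d_k + seq_len(dm$d_k)
      vcols <- (h - 1L) * dm$d_v + seq_len(dm$d_v)
      Sh <- tp$S[[h]]
      dBh <- matrix(d_Bmat[, h], N, N)
      d_xph <- d_xp[, vcols, drop = FALSE]
      dSh <- d_xph %*% t(tp$V[, vcols, drop = FALSE]) + dBh
      d_V[, vcols] <- crossprod(Sh, d_xph)
      dAh <- dBh + row_softmax_backward(Sh, dSh)
      d_Phi[, h] <- as.vector(dAh)
      d_Q[, qcols] <- dAh %*% tp$K[, qcols, drop = FALSE] / sqrt(dm$d_k)
      d_K[, qcols] <- crossprod(dAh, tp$Q[, qcols, drop = FALSE]) / sqrt(dm$d_k)
    }
    gr$W_Q <- gr$W_Q + crossprod(tp$x_in, d_Q)
    gr$W_K <- gr$W_K + crossprod(tp$x_in, d_K)
    gr$W_V <- gr$W_V + crossprod(tp$x_in, d_V)
    gr$W_reduce <- gr$W_reduce + crossprod(tp$Emat, d_Phi)
    d_x_out <- d_Q %*% t(params$W_Q) + d_K %*% t(params$W_K) +
      d_V %*% t(params$W_V)
    d_E_out <- array(d_Phi %*% t(params$W_reduce), dim = c(N, N, dm$d_edge))
  }
  list(d_x_node = d_x_out, d_x_edge = d_E_out, grads = gr)
}
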