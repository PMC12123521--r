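# Independent straight-line reference implementations used as test oracles.
# These deliberately use explicit loops and no package internals.

oracle_attention_bias <- function(x_edge, W_reduce) {
  N <- dim(x_edge)[1L]
  n_head <- ncol(W_reduce)
  phi <- array(0, dim = c(n_head, N, N))
  for (h in seq_len(n_head)) {
    for (i in seq_len(N)) {
      for (j in seq_len(N)) {
        phi[h, i, j] <- sum(x_edge[i, j, ] * W_reduce[, h])
      }
    }
  }
  phi
}

oracle_softmax_vec <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

oracle_node_attention <- function(x_node, phi, params) {
  dm <- attr(params, "dims")
  N <- nrow(x_node)
  xp <- matrix(0, N, dm$d_node)
  A <- array(0, dim = c(dm$n_head, N, N))
  for (h in seq_len(dm$n_head)) {
    qcols <- (h - 1L) * dm$d_k + seq_len(dm$d_k)
    vcols <- (h - 1L) * dm$d_v + seq_len(dm$d_v)
    Q <- x_node %*% params$W_Q[, qcols, drop = FALSE]
    K <- x_node %*% params$W_K[, qcols, drop = FALSE]
    V <- x_node %*% params$W_V[, vcols, drop = FALSE]
    for (i in seq_len(N)) {
      row <- numeric(N)
      for (j in seq_len(N)) {
        row[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dm$d_k) + phi[h, i, j]
      }
      A[h, i, ] <- row
      s <- oracle_softmax_vec(row)
      for (c in seq_len(dm$d_v)) {
        xp[i, vcols[c]] <- sum(s * V[, c])
      }
    }
  }
  list(x_node_prime = xp, A = A)
}

oracle_node_to_edge <- function(A, params) {
  dm <- attr(params, "dims")
  N <- dim(A)[2L]
  out <- array(0, dim = c(N, N, dm$d_edge))
  for (i in seq_len(N)) {
    for (h in seq_len(dm$n_head)) {
      s <- oracle_softmax_vec(A[h, i, ])
      for (j in seq_len(N)) {
        b <- A[h, i, j] + s[j]
        out[i, j, ] <- out[i, j, ] + b * params$W_expand[h, ]
      }
    }
  }
  out
}

oracle_edge_to_node <- function(x_edge_prime, params) {
  dm <- attr(params, "dims")
  N <- dim(x_edge_prime)[1L]
  out <- matrix(0, N, dm$d_node)
  for (i in seq_len(N)) {
    s_i <- numeric(dm$d_edge)
    for (c in seq_len(dm$d_edge)) {
      col <- x_edge_prime[i, , c]
      sm <- oracle_softmax_vec(col)
      s_i[c] <- sum(col * sm)
    }
    out[i, ] <- as.numeric(s_i %*% params$W_en) + params$b_en
  }
  out
}

oracle_layer_forward <- function(state, params) {
  phi <- oracle_attention_bias(state$x_edge, params$W_reduce)
  att <- oracle_node_attention(state$x_node, phi, params)
  ep <- oracle_node_to_edge(att$A, params)
  x2 <- oracle_edge_to_node(ep, params)
  list(x_node = (att$x_node_prime + x2) %*% params$W_O, x_edge = ep)
}

# 3x3 'same' convolution by explicit window sums (zero padding)
oracle_conv3x3 <- function(x, k, b) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; Cin <- d[3L]
  Cout <- dim(k)[4L]
  out <- array(0, dim = c(H, W, Cout))
  for (co in seq_len(Cout)) {
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        acc <- b[co]
        for (l in -1:1) {
          for (g in -1:1) {
            ii <- i + l; jj <- j + g
            if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
              for (ci in seq_len(Cin)) {
                acc <- acc + k[l + 2L, g + 2L, ci, co] * x[ii, jj, ci]
              }
            }
          }
        }
        out[i, j, co] <- acc
      }
    }
  }
  out
}

oracle_cosine_map <- function(Q, K) {
  d <- dim(Q)
  hw <- d[1L] * d[2L]
  cq <- d[3L]
  Qm <- matrix(Q, hw, cq)
  Km <- matrix(K, hw, cq)
  I <- matrix(0, hw, hw)
  for (p in seq_len(hw)) {
    for (q in seq_len(hw)) {
      nq <- sqrt(sum(Qm[p, ]^2)); nk <- sqrt(sum(Km[q, ]^2))
      I[p, q] <- if (nq == 0 || nk == 0) 0 else sum(Qm[p, ] * Km[q, ]) / (nq * nk)
    }
  }
  I
}

oracle_gauss_matrix <- function(H, W, d, theta, alpha) {
  hw <- H * W
  M <- matrix(0, hw, hw)
  for (p in seq_len(hw)) {
    for (q in seq_len(hw)) {
      ip <- (p - 1L) %% H + 1L; jp <- (p - 1L) %/% H + 1L
      iq <- (q - 1L) %% H + 1L; jq <- (q - 1L) %/% H + 1L
      num <- (ip - iq)^2 * (2^d / H)^2 + (jp - jq)^2 * (2^d / W)^2
      M[p, q] <- exp(-num / (2 * (theta * alpha)^2))
    }
  }
  M
}

oracle_attend_embed <- function(I, M, V, fc_w, fc_b) {
  hw <- nrow(I)
  v <- as.numeric(V)
  ctx <- numeric(hw)
  for (p in seq_len(hw)) {
    acc <- 0
    for (q in seq_len(hw)) acc <- acc + I[p, q] * M[p, q] * v[q]
    ctx[p] <- acc
  }
  out <- numeric(nrow(fc_w))
  for (r in seq_len(nrow(fc_w))) out[r] <- sum(fc_w[r, ] * ctx) + fc_b[r]
  out
}

# exhaustive Mann-Whitney pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (n in neg) {
      tot <- tot + (p > n) + 0.5 * (p == n)
    }
  }
  tot / (length(pos) * length(neg))
}

oracle_masked_bce <- function(yhat, y, mask, eps = 1e-7) {
  vals <- c()
  for (i in seq_along(yhat)) {
    if (!mask[i]) next
    p <- min(max(yhat[i], eps), 1 - eps)
    vals <- c(vals, -(y[i] * log(p) + (1 - y[i]) * log(1 - p)))
  }
  mean(vals)
}

# independent greedy scaffold-fill given group keys (fill train, then valid)
oracle_greedy_split <- function(keys, fractions = c(0.8, 0.1, 0.1)) {
  n <- length(keys)
  groups <- split(seq_len(n), keys)
  groups <- groups[order(-lengths(groups), names(groups))]
  cut1 <- round(fractions[1] * n)
  cut2 <- cut1 + round(fractions[2] * n)
  tr <- va <- te <- integer(0)
  for (g in groups) {
    if (length(tr) + length(g) <= cut1) tr <- c(tr, g)
    else if (length(tr) + length(va) + length(g) <= cut2) va <- c(va, g)
    else te <- c(te, g)
  }
  list(train = sort(tr), valid = sort(va), test = sort(te))
}

# connected components of the heavy-atom graph after removing cut bonds,
# by hand-rolled breadth-first search
oracle_components <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1L]; b <- edges[k, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  out <- split(seq_len(n), comp)
  unname(out[order(vapply(out, min, numeric(1)))])
}
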