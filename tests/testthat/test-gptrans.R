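rand_state <- function(N, dm, seed = 1) {
  set.seed(seed)
  list(x_node = matrix(rnorm(N * dm$d_node), N, dm$d_node),
       x_edge = array(rnorm(N * N * dm$d_edge), dim = c(N, N, dm$d_edge)))
}

small_params <- function(seed = 1) {
  mf_gptrans_params(d_node = 8L, d_edge = 5L, n_head = 2L, d_k = 3L,
                    seed = seed)
}

test_that("attention biases equal the per-slot edge projection", {
  p <- small_params()
  dm <- attr(p, "dims")
  st <- rand_state(4L, dm, seed = 2)
  phi <- mf_attention_bias(st$x_edge, p)
  expect_equal(phi, oracle_attention_bias(st$x_edge, p$W_reduce),
               tolerance = 1e-12)
  # zero edges with any map give zero biases
  z <- array(0, dim = dim(st$x_edge))
  expect_true(all(mf_attention_bias(z, p) == 0))
  # single-edge scalar arithmetic
  e1 <- array(0, dim = c(2, 2, dm$d_edge))
  e1[1, 2, ] <- seq_len(dm$d_edge)
  phi1 <- mf_attention_bias(e1, p)
  expect_equal(phi1[1, 1, 2], sum(seq_len(dm$d_edge) * p$W_reduce[, 1]))
})

test_that("node attention matches the per-head loop oracle", {
  p <- small_params(3)
  dm <- attr(p, "dims")
  for (N in c(2L, 4L, 6L)) {
    st <- rand_state(N, dm, seed = N)
    phi <- mf_attention_bias(st$x_edge, p)
    got <- mf_node_attention(st$x_node, phi, p)
    ref <- oracle_node_attention(st$x_node, phi, p)
    expect_equal(got$x_node_prime, ref$x_node_prime, tolerance = 1e-9)
    expect_equal(got$A, ref$A, tolerance = 1e-9)
  }
  # N = 1: softmax of a scalar is 1, so the update is V itself
  st1 <- rand_state(1L, dm, seed = 9)
  phi1 <- array(rnorm(dm$n_head), dim = c(dm$n_head, 1L, 1L))
  got1 <- mf_node_attention(st1$x_node, phi1, p)
  expect_equal(got1$x_node_prime, st1$x_node %*% p$W_V, tolerance = 1e-12)
  # -Inf off-diagonal biases reduce to self-attention
  stm <- rand_state(3L, dm, seed = 10)
  phim <- array(-Inf, dim = c(dm$n_head, 3L, 3L))
  for (i in 1:3) phim[, i, i] <- 0
  gotm <- mf_node_attention(stm$x_node, phim, p)
  expect_equal(gotm$x_node_prime, stm$x_node %*% p$W_V, tolerance = 1e-9)
  expect_error(mf_node_attention(stm$x_node * NaN, phim, p), "non-finite")
})

test_that("node-to-edge lifting matches the loop oracle", {
  p <- small_params(4)
  dm <- attr(p, "dims")
  set.seed(5)
  A <- array(rnorm(dm$n_head * 16), dim = c(dm$n_head, 4L, 4L))
  expect_equal(mf_node_to_edge(A, p), oracle_node_to_edge(A, p),
               tolerance = 1e-9)
  # A = 0 at N = 2: uniform softmax 1/2, so every slot is 0.5 * row sums
  A0 <- array(0, dim = c(dm$n_head, 2L, 2L))
  out0 <- mf_node_to_edge(A0, p)
  expect_equal(out0[1, 2, ], 0.5 * colSums(p$W_expand), tolerance = 1e-12)
  # zero expansion map kills the output
  pz <- p
  pz$W_expand <- pz$W_expand * 0
  expect_true(all(mf_node_to_edge(A, pz) == 0))
})

test_that("edge-to-node gating matches the loop oracle", {
  p <- small_params(6)
  dm <- attr(p, "dims")
  set.seed(6)
  for (N in c(1L, 3L, 5L)) {
    ep <- array(rnorm(N * N * dm$d_edge), dim = c(N, N, dm$d_edge))
    expect_equal(mf_edge_to_node(ep, p), oracle_edge_to_node(ep, p),
                 tolerance = 1e-9)
  }
  # constant tensor: uniform softmax, identical rows equal to FC(c)
  cst <- array(0.7, dim = c(4L, 4L, dm$d_edge))
  out <- mf_edge_to_node(cst, p)
  expect_equal(out[1, ], out[3, ], tolerance = 1e-12)
  expect_equal(out[1, ],
               as.numeric(rep(0.7, dm$d_edge) %*% p$W_en) + p$b_en,
               tolerance = 1e-12)
})

test_that("a full layer equals the composition of the four oracles", {
  p <- small_params(8)
  dm <- attr(p, "dims")
  for (N in c(2L, 5L)) {
    st <- rand_state(N, dm, seed = 20 + N)
    got <- mf_layer_forward(st, p)
    ref <- oracle_layer_forward(st, p)
    expect_equal(got$x_node, ref$x_node, tolerance = 1e-9)
    expect_equal(got$x_edge, ref$x_edge, tolerance = 1e-9)
  }
  # zeroed network maps everything to zero
  pz <- rapply(unclass(p), function(x) x * 0, how = "replace")
  attributes(pz) <- attributes(p)
  st <- rand_state(3L, dm, seed = 31)
  outz <- mf_layer_forward(st, pz)
  expect_true(all(outz$x_node == 0))
})

test_that("attention rows are normalized and iterated layers stay finite", {
  p <- mf_gptrans_params(seed = 2)
  proj <- mf_projection_params(seed = 2)
  g <- mf_project_latents(mf_build_hier_graph("CC(=O)Oc1ccccc1C(=O)O"), proj)
  phi <- mf_attention_bias(g$edge_latent, p)
  att <- mf_node_attention(g$node_latent, phi, p)
  dm <- attr(p, "dims")
  for (h in seq_len(dm$n_head)) {
    sm <- t(apply(matrix(att$A[h, , ], g$N, g$N), 1L, function(r) {
      e <- exp(r - max(r)); e / sum(e)
    }))
    expect_equal(rowSums(sm), rep(1, g$N), tolerance = 1e-6)
  }
  emb <- mf_encode_graph(g, p, n_iterations = 3L)
  expect_length(emb, 256L)
  expect_true(all(is.finite(emb)))
})

test_that("the graph readout is invariant to atom permutations", {
  p <- mf_gptrans_params(seed = 5)
  proj <- mf_projection_params(seed = 5)
  for (smi in c("CCO", "CC(=O)Oc1ccccc1", "c1ccc(Cl)cc1CC(=O)O")) {
    f <- molfuse:::.mf_mol_features(smi)[[1L]]
    emb0 <- mf_encode_graph(mf_project_latents(mf_build_hier_graph(f), proj), p)
    set.seed(nchar(smi))
    perm <- sample(f$n_atoms)
    fp <- molfuse:::.mf_mol_features(smi, perms = list(perm))[[1L]]
    emb1 <- mf_encode_graph(mf_project_latents(mf_build_hier_graph(fp), proj), p)
    expect_equal(emb0, emb1, tolerance = 1e-5)
  }
})

test_that("the smallest graph encodes deterministically; zero net gives zero", {
  p <- mf_gptrans_params(seed = 3)
  proj <- mf_projection_params(seed = 3)
  g <- mf_project_latents(mf_build_hier_graph("C"), proj)   # 1 atom + motif + super
  expect_equal(g$N, 3L)
  e1 <- mf_encode_graph(g, p)
  expect_true(all(is.finite(e1)))
  expect_identical(e1, mf_encode_graph(g, p))
  pz <- rapply(unclass(p), function(x) x * 0, how = "replace")
  attributes(pz) <- attributes(p)
  expect_true(all(mf_encode_graph(g, pz) == 0))
})

test_that("analytic layer gradients agree with finite differences", {
  cfg <- tiny_cfg()
  m <- mf_model(2L, cfg, seed = 99L)
  graphs <- lapply(c("CCO", "c1ccc(Cl)cc1C(=O)O"), mf_build_hier_graph)
  set.seed(42)
  lat <- matrix(rnorm(2 * 9), 2, 9)
  y <- matrix(c(1, 0, NA, 1), 2, 2)
  mask <- !is.na(y); y[!mask] <- 0
  lg <- molfuse:::.mf_model_loss_grad(m$params, graphs, lat, y, mask, 3L)
  flat <- molfuse:::mf_flatten(m$params)
  gflat <- molfuse:::mf_flatten(lg$grads)
  eps <- 1e-6
  idx <- sort(sample(length(flat), 60))
  for (i in idx) {
    fp <- flat; fp[i] <- fp[i] + eps
    fm <- flat; fm[i] <- fm[i] - eps
    num <- (molfuse:::.mf_model_loss_grad(
              molfuse:::mf_unflatten(fp, m$params), graphs, lat, y, mask, 3L)$loss -
            molfuse:::.mf_model_loss_grad(
              molfuse:::mf_unflatten(fm, m$params), graphs, lat, y, mask, 3L)$loss) /
      (2 * eps)
    expect_equal(gflat[i], num, tolerance = 1e-4)
  }
})
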