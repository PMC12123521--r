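# Convolutional self-attention autoencoder over 2D molecular depictions.
#
# Encoder: three Conv-BN-ReLU blocks with average-pool halvings
# (size -> size/8, channels 3 -> c1 -> c2 -> c3), a Conv-BN-ReLU collapse to a
# single-channel map, then a CNN-style self-attention block with cosine
# similarity reweighted by a learnable Gaussian distance prior, flattened and
# mapped to the latent width. Decoder: linear back to the pooled map, then
# Conv-BN-ReLU + nearest-neighbour upsampling stages back to a 3-channel
# image. Trained by mean-squared-error reconstruction with plain gradient
# descent; the encoder is frozen after pretraining and only used to embed
# depictions.

.bn_eps <- 1e-5
.bn_momentum <- 0.1

.as4d <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

# batch norm (+ fused ReLU) lives in compiled code; see src/convops.cpp
.bn_update_stats <- function(stats, cache) {
  stats$mean <- (1 - .bn_momentum) * stats$mean + .bn_momentum * cache$mu
  stats$var <- (1 - .bn_momentum) * stats$var + .bn_momentum * cache$var
  stats
}

#' Construct the image autoencoder
#'
#' @param size input image side length (must be divisible by 8).
#' @param channels the three encoder channel widths.
#' @param cq number of channels of the attention query/key maps.
#' @param d_latent latent embedding width.
#' @param alpha fixed Gaussian width hyperparameter.
#' @param theta_init initial value of the learnable Gaussian width.
#' @param seed RNG seed for initialisation.
#' @return an object of class `molfuse_autoencoder` (unfrozen).
#' @export
mf_autoencoder <- function(size = 224L, channels = c(64L, 128L, 256L),
                           cq = 4L, d_latent = 768L, alpha = 1.0,
                           theta_init = 1.0, seed = 1L) {
  stopifnot(size %% 8L == 0L, length(channels) == 3L)
  set.seed(seed)
  ha <- size %/% 8L
  hw <- ha * ha
  kinit <- function(ks, cin, cout) {
    array(runif(ks * ks * cin * cout, -1, 1) * sqrt(6 / (ks * ks * cin + cout)),
          dim = c(ks, ks, cin, cout))
  }
  params <- list(
    conv1_w = kinit(3L, 3L, channels[1L]), conv1_b = numeric(channels[1L]),
    bn1_g = rep(1, channels[1L]), bn1_b = numeric(channels[1L]),
    conv2_w = kinit(3L, channels[1L], channels[2L]), conv2_b = numeric(channels[2L]),
    bn2_g = rep(1, channels[2L]), bn2_b = numeric(channels[2L]),
    conv3_w = kinit(3L, channels[2L], channels[3L]), conv3_b = numeric(channels[3L]),
    bn3_g = rep(1, channels[3L]), bn3_b = numeric(channels[3L]),
    conv4_w = kinit(3L, channels[3L], 1L), conv4_b = numeric(1L),
    bn4_g = rep(1, 1L), bn4_b = numeric(1L),
    Eq_w = kinit(3L, 1L, cq), Eq_b = numeric(cq),
    Ek_w = kinit(3L, 1L, cq), Ek_b = numeric(cq),
    Ev_w = kinit(3L, 1L, 1L), Ev_b = numeric(1L),
    theta = theta_init,
    fc_w = glorot(d_latent, hw), fc_b = numeric(d_latent),
    dec_w = glorot(hw, d_latent), dec_b = numeric(hw),
    dconv1_w = kinit(3L, 1L, 3L), dconv1_b = numeric(3L),
    dbn1_g = rep(1, 3L), dbn1_b = numeric(3L),
    dconv2_w = kinit(3L, 3L, 3L), dconv2_b = numeric(3L),
    dbn2_g = rep(1, 3L), dbn2_b = numeric(3L),
    dconv3_w = kinit(1L, 3L, 3L), dconv3_b = numeric(3L),
    dbn3_g = rep(1, 3L), dbn3_b = numeric(3L)
  )
  stats <- list()
  for (nm in c("bn1", "bn2", "bn3", "bn4", "dbn1", "dbn2", "dbn3")) {
    C <- length(params[[paste0(nm, "_g")]])
    stats[[nm]] <- list(mean = numeric(C), var = rep(1, C))
  }
  structure(list(size = size, channels = channels, cq = cq,
                 d_latent = d_latent, alpha = alpha, h_att = ha,
                 n_pool = 3L, params = params, stats = stats,
                 frozen = FALSE),
            class = "molfuse_autoencoder")
}

#' @export
print.molfuse_autoencoder <- function(x, ...) {
  cat("<molfuse_autoencoder>", x$size, "x", x$size, "input,",
      "attention map", x$h_att, "x", x$h_att, ",",
      x$d_latent, "d latent,", if (x$frozen) "frozen" else "trainable", "\n")
  invisible(x)
}

#' Query/key/value maps via 3x3 convolutions
#'
#' @param x feature map array `H x W x C` (or `H x W x C x 1`).
#' @param kernels list with `Eq_w`, `Eq_b`, `Ek_w`, `Ek_b`, `Ev_w`, `Ev_b`.
#' @return list of maps `Q`, `K`, `V` (each `H x W x channels`).
#' @export
mf_conv_qkv <- function(x, kernels) {
  x <- .as4d(x)
  drop1 <- function(a) array(a, dim = dim(a)[1:3])
  list(Q = drop1(.conv2d_fwd(x, kernels$Eq_w, kernels$Eq_b)),
       K = drop1(.conv2d_fwd(x, kernels$Ek_w, kernels$Ek_b)),
       V = drop1(.conv2d_fwd(x, kernels$Ev_w, kernels$Ev_b)))
}

#' Cosine similarity map between query and key pixels
#'
#' Entry `(p, q)` is the cosine of the channel vectors at query pixel `p` and
#' key pixel `q` (column-major pixel order); pixels with zero-norm vectors get
#' similarity 0.
#'
#' @param Q,K maps `H x W x c`.
#' @return matrix `(H*W) x (H*W)` with entries in `[-1, 1]`.
#' @export
mf_similarity_map <- function(Q, K) {
  dq <- dim(Q)
  hw <- dq[1L] * dq[2L]
  cq <- if (length(dq) >= 3L) dq[3L] else 1L
  Qm <- matrix(Q, hw, cq)
  Km <- matrix(K, hw, cq)
  qn <- sqrt(rowSums(Qm^2))
  kn <- sqrt(rowSums(Km^2))
  Qn <- Qm / ifelse(qn > 0, qn, 1)
  Kn <- Km / ifelse(kn > 0, kn, 1)
  I <- tcrossprod(Qn, Kn)
  I[qn == 0, ] <- 0
  I[, kn == 0] <- 0
  I
}

# squared pixel distances rescaled to input coordinates; cached per (H, W, d)
.gauss_D <- function(H, W, d) {
  key <- paste0("gaussD:", H, ":", W, ":", d)
  if (!exists(key, envir = .mf_cache)) {
    i <- rep(seq_len(H), times = W)
    j <- rep(seq_len(W), each = H)
    si <- (2^d / H)^2
    sj <- (2^d / W)^2
    D <- outer(i, i, function(a, b) (a - b)^2) * si +
      outer(j, j, function(a, b) (a - b)^2) * sj
    assign(key, D, envir = .mf_cache)
  }
  get(key, envir = .mf_cache)
}

#' Gaussian distance prior over feature-map pixels
#'
#' `M[p,q] = exp(-((i_p-i_q)^2 (2^d/H)^2 + (j_p-j_q)^2 (2^d/W)^2) /
#' (2 (theta*alpha)^2))` where `d` is the number of pooling layers; symmetric
#' with a unit diagonal.
#'
#' @param H,W feature map height and width.
#' @param d number of pooling halvings before the attention block.
#' @param theta learnable width scalar.
#' @param alpha fixed width hyperparameter.
#' @return matrix `(H*W) x (H*W)` with entries in `(0, 1]`.
#' @export
mf_gaussian_distance_matrix <- function(H = 28L, W = 28L, d = 3L,
                                        theta = 1.0, alpha = 1.0) {
  if (theta * alpha == 0) stop("theta * alpha must be nonzero")
  exp(-.gauss_D(H, W, d) / (2 * (theta * alpha)^2))
}

#' Distance-reweighted attention and latent embedding
#'
#' `A = I * M` elementwise; the context is `A` applied to the flattened value
#' map, then a fully connected layer maps the flattened context to the latent
#' width.
#'
#' @param I similarity map `(H*W) x (H*W)`.
#' @param M Gaussian distance matrix of the same shape.
#' @param V value map (`H x W x 1` or a length `H*W` vector).
#' @param fc_w latent map `d_latent x (H*W)`.
#' @param fc_b latent bias.
#' @return numeric latent vector with the flattened context in attribute
#'   `"context"`.
#' @export
mf_attend_and_embed <- function(I, M, V, fc_w, fc_b) {
  A <- I * M
  ctx <- as.numeric(A %*% as.numeric(V))
  out <- as.numeric(fc_w %*% ctx + fc_b)
  attr(out, "context") <- ctx
  out
}

# --- full forward (with optional tape) --------------------------------------

.ae_forward <- function(ae, x, train = FALSE, tape = FALSE) {
  p <- ae$params
  x <- .as4d(x)
  B <- dim(x)[4L]
  tp <- if (tape) list(x = x) else NULL
  st <- ae$stats

  block <- function(inp, cw, cb, gname, act = TRUE) {
    cc <- .conv2d_fwd(inp, p[[cw]], p[[cb]])
    bn <- .bn_fwd_cpp(cc, p[[paste0(gname, "_g")]], p[[paste0(gname, "_b")]],
                      train, st[[gname]]$mean, st[[gname]]$var, act)
    list(conv = cc, bn = bn, out = bn$y)
  }

  b1 <- block(x, "conv1_w", "conv1_b", "bn1");  p1 <- .avgpool2_fwd(b1$out)
  b2 <- block(p1, "conv2_w", "conv2_b", "bn2"); p2 <- .avgpool2_fwd(b2$out)
  b3 <- block(p2, "conv3_w", "conv3_b", "bn3"); p3 <- .avgpool2_fwd(b3$out)
  b4 <- block(p3, "conv4_w", "conv4_b", "bn4")

  ha <- ae$h_att
  hw <- ha * ha
  M <- mf_gaussian_distance_matrix(ha, ha, ae$n_pool, p$theta, ae$alpha)
  Q <- .conv2d_fwd(b4$out, p$Eq_w, p$Eq_b)
  K <- .conv2d_fwd(b4$out, p$Ek_w, p$Ek_b)
  V <- .conv2d_fwd(b4$out, p$Ev_w, p$Ev_b)
  latents <- matrix(0, ae$d_latent, B)
  att <- vector("list", B)
  for (b in seq_len(B)) {
    Qm <- matrix(Q[, , , b], hw, ae$cq)
    Km <- matrix(K[, , , b], hw, ae$cq)
    vb <- as.numeric(V[, , 1L, b])
    qn <- sqrt(rowSums(Qm^2)); kn <- sqrt(rowSums(Km^2))
    Qn <- Qm / ifelse(qn > 0, qn, 1)
    Kn <- Km / ifelse(kn > 0, kn, 1)
    I <- tcrossprod(Qn, Kn)
    I[qn == 0, ] <- 0; I[, kn == 0] <- 0
    A <- I * M
    ctx <- as.numeric(A %*% vb)
    latents[, b] <- p$fc_w %*% ctx + p$fc_b
    if (tape) att[[b]] <- list(Qm = Qm, Km = Km, Qn = Qn, Kn = Kn,
                               qn = qn, kn = kn, I = I, A = A,
                               v = vb, ctx = ctx)
  }

  # decoder
  d0 <- sweep(p$dec_w %*% latents, 1L, p$dec_b, "+")     # hw x B
  d0m <- array(d0, dim = c(ha, ha, 1L, B))
  e1 <- block(d0m, "dconv1_w", "dconv1_b", "dbn1"); u1 <- .upsample2_fwd(e1$out)
  e2 <- block(u1, "dconv2_w", "dconv2_b", "dbn2");  u2 <- .upsample2_fwd(e2$out)
  e3 <- block(u2, "dconv3_w", "dconv3_b", "dbn3");  recon <- .upsample2_fwd(e3$out)

  if (tape) {
    tp <- c(tp, list(b1 = b1, p1 = p1, b2 = b2, p2 = p2, b3 = b3, p3 = p3,
                     b4 = b4, Q = Q, K = K, V = V, att = att, M = M,
                     latents = latents, d0m = d0m, e1 = e1, u1 = u1,
                     e2 = e2, u2 = u2, e3 = e3))
  }
  list(latents = latents, recon = recon, tape = tp)
}

# loss + full parameter gradient for a minibatch (training-mode BN)
.ae_loss_grad <- function(ae, x) {
  x <- .as4d(x)
  fw <- .ae_forward(ae, x, train = TRUE, tape = TRUE)
  tp <- fw$tape
  p <- ae$params
  B <- dim(x)[4L]
  n_el <- length(x)
  loss <- mean((fw$recon - x)^2)
  g <- lapply(p, function(q) array(0, dim = if (is.null(dim(q))) length(q) else dim(q)))
  g <- lapply(g, function(q) if (length(dim(q)) == 1L) as.numeric(q) else q)

  block_bwd <- function(blk, inp, cw, cb, gname, dy, act = TRUE) {
    bb <- .bn_bwd_cpp(blk$conv, blk$out, p[[paste0(gname, "_g")]],
                      blk$bn$mu, blk$bn$inv, dy, act)
    g[[paste0(gname, "_g")]] <<- g[[paste0(gname, "_g")]] + bb$dgamma
    g[[paste0(gname, "_b")]] <<- g[[paste0(gname, "_b")]] + bb$dbeta
    cb2 <- .conv2d_bwd(inp, p[[cw]], bb$dx)
    g[[cw]] <<- g[[cw]] + cb2$dw
    g[[cb]] <<- g[[cb]] + cb2$db
    cb2$dx
  }

  d_recon <- 2 * (fw$recon - x) / n_el
  d_e3 <- .upsample2_bwd(d_recon)
  d_u2 <- block_bwd(tp$e3, tp$u2, "dconv3_w", "dconv3_b", "dbn3", d_e3)
  d_e2 <- .upsample2_bwd(d_u2)
  d_u1 <- block_bwd(tp$e2, tp$u1, "dconv2_w", "dconv2_b", "dbn2", d_e2)
  d_e1 <- .upsample2_bwd(d_u1)
  d_d0m <- block_bwd(tp$e1, tp$d0m, "dconv1_w", "dconv1_b", "dbn1", d_e1)

  ha <- ae$h_att; hw <- ha * ha
  d_d0 <- matrix(d_d0m, hw, B)
  g$dec_w <- g$dec_w + d_d0 %*% t(tp$latents)
  g$dec_b <- g$dec_b + rowSums(d_d0)
  d_lat <- t(p$dec_w) %*% d_d0                            # d_latent x B

  # attention backward per image
  d_Q <- array(0, dim = dim(tp$Q))
  d_K <- array(0, dim = dim(tp$K))
  d_V <- array(0, dim = dim(tp$V))
  d_theta <- 0
  M <- tp$M
  D <- .gauss_D(ha, ha, ae$n_pool)
  for (b in seq_len(B)) {
    at <- tp$att[[b]]
    dl <- d_lat[, b]
    g$fc_w <- g$fc_w + dl %*% t(at$ctx)
    g$fc_b <- g$fc_b + dl
    d_ctx <- as.numeric(t(p$fc_w) %*% dl)
    d_A <- d_ctx %*% t(at$v)                              # hw x hw
    d_v <- as.numeric(t(at$A) %*% d_ctx)
    d_I <- d_A * M
    d_M <- d_A * at$I
    d_theta <- d_theta + sum(d_M * M * D) / (ae$alpha^2 * p$theta^3)
    d_Qn <- d_I %*% at$Kn
    d_Kn <- t(d_I) %*% at$Qn
    norm_bwd <- function(Xn, n, dXn) {
      proj <- rowSums(dXn * Xn)
      dX <- (dXn - Xn * proj) / ifelse(n > 0, n, 1)
      dX[n == 0, ] <- 0
      dX
    }
    d_Q[, , , b] <- array(norm_bwd(at$Qn, at$qn, d_Qn), dim = c(ha, ha, ae$cq))
    d_K[, , , b] <- array(norm_bwd(at$Kn, at$kn, d_Kn), dim = c(ha, ha, ae$cq))
    d_V[, , 1L, b] <- array(d_v, dim = c(ha, ha))
  }
  g$theta <- g$theta + d_theta

  a4 <- tp$b4$out
  cq1 <- .conv2d_bwd(a4, p$Eq_w, d_Q)
  cq2 <- .conv2d_bwd(a4, p$Ek_w, d_K)
  cq3 <- .conv2d_bwd(a4, p$Ev_w, d_V)
  g$Eq_w <- g$Eq_w + cq1$dw; g$Eq_b <- g$Eq_b + cq1$db
  g$Ek_w <- g$Ek_w + cq2$dw; g$Ek_b <- g$Ek_b + cq2$db
  g$Ev_w <- g$Ev_w + cq3$dw; g$Ev_b <- g$Ev_b + cq3$db
  d_a4 <- cq1$dx + cq2$dx + cq3$dx

  d_p3 <- block_bwd(tp$b4, tp$p3, "conv4_w", "conv4_b", "bn4", d_a4)
  d_b3 <- .avgpool2_bwd(d_p3)
  d_p2 <- block_bwd(tp$b3, tp$p2, "conv3_w", "conv3_b", "bn3", d_b3)
  d_b2 <- .avgpool2_bwd(d_p2)
  d_p1 <- block_bwd(tp$b2, tp$p1, "conv2_w", "conv2_b", "bn2", d_b2)
  d_b1 <- .avgpool2_bwd(d_p1)
  invisible(block_bwd(tp$b1, tp$x, "conv1_w", "conv1_b", "bn1", d_b1))

  # running-stat updates for every BN layer
  stats <- ae$stats
  for (nm in c("bn1", "bn2", "bn3", "bn4")) {
    blk <- tp[[c(bn1 = "b1", bn2 = "b2", bn3 = "b3", bn4 = "b4")[[nm]]]]
    stats[[nm]] <- .bn_update_stats(stats[[nm]], blk$bn)
  }
  for (nm in c("dbn1", "dbn2", "dbn3")) {
    blk <- tp[[c(dbn1 = "e1", dbn2 = "e2", dbn3 = "e3")[[nm]]]]
    stats[[nm]] <- .bn_update_stats(stats[[nm]], blk$bn)
  }
  list(loss = loss, grads = g, stats = stats)
}

#' Pretrain the autoencoder on depictions and freeze the encoder
#'
#' Minimises the mean squared pixel reconstruction error with plain
#' (momentum-free) minibatch gradient descent, then returns the model with a
#' frozen flag; downstream training never touches its parameters.
#'
#' @param images list of `size x size x 3` arrays in `[0, 1]`.
#' @param epochs number of passes over the image set.
#' @param lr learning rate.
#' @param seed RNG seed (initialisation and shuffling).
#' @param batch_size minibatch size.
#' @param ae optionally, a pre-built [mf_autoencoder()] to continue from.
#' @return a frozen `molfuse_autoencoder`; attributes `mse_initial`,
#'   `mse_final` (evaluation-mode MSE over `images` before/after) and
#'   `loss_curve` (per-epoch mean training loss).
#' @export
mf_pretrain_autoencoder <- function(images, epochs = 2L, lr = 0.3,
                                    seed = 1L, batch_size = 8L, ae = NULL) {
  if (length(images) == 0L) stop("empty image set")
  if (length(images) < 16L) stop("autoencoder pretraining needs >= 16 images")
  if (is.null(ae)) {
    sz <- dim(images[[1L]])[1L]
    ae <- mf_autoencoder(size = sz, seed = seed)
  }
  eval_mse <- function(a) {
    tot <- 0
    for (i in seq_along(images)) {
      fw <- .ae_forward(a, images[[i]], train = FALSE)
      tot <- tot + mean((fw$recon - .as4d(images[[i]]))^2)
    }
    tot / length(images)
  }
  mse0 <- eval_mse(ae)
  set.seed(mf_derive_seed(seed, "autoencoder"))
  n <- length(images)
  curve <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- array(0, dim = c(ae$size, ae$size, 3L, length(idx)))
      for (k in seq_along(idx)) xb[, , , k] <- images[[idx[k]]]
      lg <- .ae_loss_grad(ae, xb)
      ae$params <- mf_param_map(function(a, b) a - lr * b, ae$params, lg$grads)
      ae$stats <- lg$stats
      losses <- c(losses, lg$loss)
    }
    curve[ep] <- mean(losses)
  }
  ae$frozen <- TRUE
  # calibrate a fixed per-coordinate standardization of the latent space on
  # the pretraining corpus: the attention context sums H*W pixel terms, so
  # raw latents carry a large common offset that would dominate the
  # downstream alignment layer
  raw <- matrix(0, length(images), ae$d_latent)
  for (i in seq_along(images)) {
    raw[i, ] <- .ae_forward(ae, images[[i]], train = FALSE)$latents[, 1L]
  }
  sds <- apply(raw, 2L, stats::sd)
  ae$latent_scale <- list(mean = colMeans(raw),
                          sd = ifelse(sds > 1e-8, sds, 1))
  attr(ae, "mse_initial") <- mse0
  attr(ae, "mse_final") <- eval_mse(ae)
  attr(ae, "loss_curve") <- curve
  ae
}

#' Embed a depiction with the frozen encoder
#'
#' @param img `size x size x 3` array.
#' @param ae a (frozen) `molfuse_autoencoder`.
#' @return numeric latent vector of length `d_latent`.
#' @export
mf_encode_image <- function(img, ae) {
  img <- .as4d(img)
  if (!all(dim(img)[1:3] == c(ae$size, ae$size, 3L))) {
    stop("image must be ", ae$size, "x", ae$size, "x3")
  }
  fw <- .ae_forward(ae, img, train = FALSE)
  .ae_scale_latents(ae, t(fw$latents))[1L, ]
}

# apply the frozen standardization (rows = images), if calibrated
.ae_scale_latents <- function(ae, lat) {
  if (is.null(ae$latent_scale)) return(lat)
  sweep(sweep(lat, 2L, ae$latent_scale$mean), 2L, ae$latent_scale$sd, "/")
}

#' Embed several depictions at once
#'
#' @param images list of `size x size x 3` arrays.
#' @param ae a (frozen) `molfuse_autoencoder`.
#' @param batch_size images per forward pass.
#' @return matrix `length(images) x d_latent`.
#' @export
mf_encode_images <- function(images, ae, batch_size = 16L) {
  out <- matrix(0, length(images), ae$d_latent)
  for (start in seq(1L, length(images), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(images))
    xb <- array(0, dim = c(ae$size, ae$size, 3L, length(idx)))
    for (k in seq_along(idx)) xb[, , , k] <- images[[idx[k]]]
    fw <- .ae_forward(ae, xb, train = FALSE)
    out[idx, ] <- t(fw$latents)
  }
  .ae_scale_latents(ae, out)
}

#' Decode a latent vector back to an image
#'
#' @param latent numeric vector of length `d_latent`.
#' @param ae a `molfuse_autoencoder`.
#' @return array `size x size x 3`.
#' @export
mf_decode <- function(latent, ae) {
  p <- ae$params
  ha <- ae$h_att
  d0 <- as.numeric(p$dec_w %*% latent + p$dec_b)
  x <- array(d0, dim = c(ha, ha, 1L, 1L))
  st <- ae$stats
  block <- function(inp, cw, cb, gname) {
    cc <- .conv2d_fwd(inp, p[[cw]], p[[cb]])
    .bn_fwd_cpp(cc, p[[paste0(gname, "_g")]], p[[paste0(gname, "_b")]],
                FALSE, st[[gname]]$mean, st[[gname]]$var, TRUE)$y
  }
  x <- .upsample2_fwd(block(x, "dconv1_w", "dconv1_b", "dbn1"))
  x <- .upsample2_fwd(block(x, "dconv2_w", "dconv2_b", "dbn2"))
  x <- .upsample2_fwd(block(x, "dconv3_w", "dconv3_b", "dbn3"))
  array(x, dim = dim(x)[1:3])
}
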