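# Alignment, bottleneck-attention fusion and the prediction head.
#
# The graph embedding (d_node) and image embedding (d_image) are linearly
# aligned, concatenated (d_node + d_image wide), passed through the channel
# branch of a bottleneck attention module in its residual form
# out = in * (1 + gate), and mapped by a two-layer rectified head to a
# 64-d representation, then to per-task probabilities via a sigmoid output
# layer. Training uses masked binary cross-entropy.

#' Initialise fusion and head parameters
#'
#' @param d_node graph embedding width.
#' @param d_image image embedding width.
#' @param bam_reduction channel-attention bottleneck reduction ratio.
#' @param head_widths widths of the two head layers.
#' @param n_tasks number of output tasks `C`.
#' @param seed RNG seed.
#' @return list of parameter arrays (class `molfuse_fusion`).
#' @export
mf_fusion_params <- function(d_node = 256L, d_image = 768L,
                             bam_reduction = 16L, head_widths = c(256L, 64L),
                             n_tasks = 1L, seed = 1L) {
  set.seed(seed)
  d_cat <- d_node + d_image
  d_mid <- max(1L, d_cat %/% bam_reduction)
  p <- list(
    W_g = glorot(d_node, d_node),
    W_i = glorot(d_image, d_image),
    bam_W1 = glorot(d_cat, d_mid), bam_b1 = numeric(d_mid),
    bam_W2 = glorot(d_mid, d_cat), bam_b2 = numeric(d_cat),
    H1 = glorot(d_cat, head_widths[1L]), h1_b = numeric(head_widths[1L]),
    H2 = glorot(head_widths[1L], head_widths[2L]), h2_b = numeric(head_widths[2L]),
    W_o = glorot(head_widths[2L], n_tasks), b_o = numeric(n_tasks)
  )
  attr(p, "dims") <- list(d_node = d_node, d_image = d_image, d_cat = d_cat,
                          d_mid = d_mid, head_widths = head_widths,
                          n_tasks = n_tasks)
  class(p) <- "molfuse_fusion"
  p
}

#' Align graph and image embeddings to a common latent space
#'
#' @param x_super graph-level embedding (length `d_node`).
#' @param latent image embedding (length `d_image`).
#' @param params a [mf_fusion_params()] list.
#' @return list with `x_graph` and `x_image`.
#' @export
mf_align <- function(x_super, latent, params) {
  list(x_graph = as.numeric(x_super %*% params$W_g),
       x_image = as.numeric(latent %*% params$W_i))
}

#' Concatenate and apply bottleneck channel attention
#'
#' The concatenated vector is treated as a 1x1 spatial map with
#' `d_node + d_image` channels, so only the channel branch of the bottleneck
#' attention module is active; the residual form `x * (1 + gate)` is applied.
#'
#' @param x_graph,x_image aligned embeddings.
#' @param params a [mf_fusion_params()] list.
#' @return fused vector of length `d_node + d_image`.
#' @export
mf_fuse <- function(x_graph, x_image, params) {
  x_cat <- c(x_graph, x_image)
  hid <- relu(as.numeric(x_cat %*% params$bam_W1) + params$bam_b1)
  gate <- sigmoid(as.numeric(hid %*% params$bam_W2) + params$bam_b2)
  x_cat * (1 + gate)
}

#' Map a fused vector to task probabilities
#'
#' @param x_fused fused vector.
#' @param params a [mf_fusion_params()] list.
#' @return numeric vector of `n_tasks` probabilities, strictly inside (0, 1).
#' @export
mf_predict_head <- function(x_fused, params) {
  h1 <- relu(as.numeric(x_fused %*% params$H1) + params$h1_b)
  h2 <- relu(as.numeric(h1 %*% params$H2) + params$h2_b)
  sigmoid(as.numeric(h2 %*% params$W_o) + params$b_o)
}

#' Masked binary cross-entropy
#'
#' Mean of `-(y log p + (1-y) log(1-p))` over unmasked entries only, with
#' probabilities clamped away from 0 and 1 for stability.
#'
#' @param yhat predicted probabilities (vector or matrix).
#' @param y labels 0/1, same shape; entries under the mask are ignored.
#' @param mask logical same shape, `TRUE` where the label is observed. By
#'   default, `!is.na(y)`.
#' @param eps probability clamp.
#' @return scalar loss.
#' @export
mf_masked_bce <- function(yhat, y, mask = NULL, eps = 1e-7) {
  if (is.null(mask)) mask <- !is.na(y)
  if (!any(mask)) stop("all labels are masked")
  p <- pmin(pmax(yhat[mask], eps), 1 - eps)
  yy <- y[mask]
  -mean(yy * log(p) + (1 - yy) * log(1 - p))
}
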