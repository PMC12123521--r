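# The assembled trainable model: raw-to-latent projections, the
# weight-shared graph propagation layer, and the fusion + prediction head.
# The frozen image encoder is a separate object and is never counted among
# or updated with the trainable parameters.

#' Assemble the trainable multimodal model
#'
#' @param n_tasks number of output tasks `C`.
#' @param config a [mf_config()].
#' @param seed RNG seed for initialisation (defaults to the config seed).
#' @return an object of class `molfuse_model`.
#' @export
mf_model <- function(n_tasks = 1L, config = mf_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  seed <- mf_derive_seed(seed, "model")
  g <- config$graph
  params <- list(
    proj = mf_projection_params(g$d_node, g$d_edge, seed = seed),
    gpt = mf_gptrans_params(g$d_node, g$d_edge, g$n_head, g$d_k,
                            seed = seed + 1L),
    fus = mf_fusion_params(g$d_node, config$image$d_latent,
                           config$fusion$bam_reduction,
                           config$fusion$head_widths, n_tasks,
                           seed = seed + 2L)
  )
  structure(list(config = config, n_tasks = n_tasks, params = params),
            class = "molfuse_model")
}

#' Count trainable parameters
#'
#' Counts every scalar in the projections, the shared propagation layer and
#' the fusion/head; the frozen image encoder is excluded by construction.
#'
#' @param model a [mf_model()].
#' @return integer count.
#' @export
mf_count_trainable <- function(model) {
  stopifnot(inherits(model, "molfuse_model"))
  length(mf_flatten(model$params))
}

#' @export
print.molfuse_model <- function(x, ...) {
  cat("<molfuse_model>", x$n_tasks, "task(s),",
      format(mf_count_trainable(x), big.mark = ","), "trainable parameters\n")
  invisible(x)
}

#' @export
summary.molfuse_model <- function(object, ...) {
  sizes <- rapply(object$params, length, how = "unlist")
  cat("molfuse model parameter blocks:\n")
  for (nm in names(sizes)) cat(sprintf("  %-16s %8d\n", nm, sizes[nm]))
  cat(sprintf("  %-16s %8d\n", "total", sum(sizes)))
  invisible(sizes)
}

# forward through the trainable path for one molecule; optional tape
.mf_model_forward <- function(params, graph, latent, n_iterations,
                              tape = FALSE) {
  pr <- params$proj
  g <- mf_project_latents(graph, pr)
  fw <- .gpt_forward_tape(g$node_latent, g$edge_latent, params$gpt,
                          n_iterations)
  x_super <- fw$x_node[graph$N, ]
  fs <- params$fus
  x_graph <- as.numeric(x_super %*% fs$W_g)
  x_image <- as.numeric(latent %*% fs$W_i)
  x_cat <- c(x_graph, x_image)
  pre1 <- as.numeric(x_cat %*% fs$bam_W1) + fs$bam_b1
  hid <- relu(pre1)
  gate <- sigmoid(as.numeric(hid %*% fs$bam_W2) + fs$bam_b2)
  x_fused <- x_cat * (1 + gate)
  h1 <- relu(as.numeric(x_fused %*% fs$H1) + fs$h1_b)
  h2 <- relu(as.numeric(h1 %*% fs$H2) + fs$h2_b)
  z <- as.numeric(h2 %*% fs$W_o) + fs$b_o
  out <- list(prob = sigmoid(z), logits = z)
  if (tape) {
    out$tape <- list(gpt = fw$tape, x_super = x_super, latent = latent,
                     x_graph = x_graph, x_image = x_image, x_cat = x_cat,
                     hid = hid, gate = gate, x_fused = x_fused,
                     h1 = h1, h2 = h2, graph = g)
  }
  out
}

# loss + gradients over a batch of molecules.
# graphs: list of molfuse_graph; latents: matrix n x d_image;
# y, mask: n x n_tasks. Returns mean masked BCE and the gradient list.
.mf_model_loss_grad <- function(params, graphs, latents, y, mask,
                                n_iterations) {
  n <- length(graphs)
  n_obs <- sum(mask)
  if (n_obs == 0L) stop("all labels are masked")
  zero_like <- function(x) {
    if (is.list(x)) {
      out <- lapply(x, zero_like)
      attributes(out) <- attributes(x)
      return(out)
    }
    x * 0
  }
  gr <- zero_like(params)
  loss <- 0
  fs <- params$fus
  for (i in seq_len(n)) {
    fw <- .mf_model_forward(params, graphs[[i]], latents[i, ], n_iterations,
                            tape = TRUE)
    tp <- fw$tape
    m <- mask[i, ]
    if (!any(m)) next
    z <- fw$logits
    p <- fw$prob
    yy <- y[i, ]
    # stable BCE from logits, averaged over all unmasked entries in the batch
    li <- ifelse(m, pmax(z, 0) - z * yy + log1p(exp(-abs(z))), 0)
    loss <- loss + sum(li) / n_obs
    dz <- ifelse(m, (p - yy) / n_obs, 0)
    gr$fus$W_o <- gr$fus$W_o + outer(tp$h2, dz)
    gr$fus$b_o <- gr$fus$b_o + dz
    dh2 <- as.numeric(fs$W_o %*% dz) * (tp$h2 > 0)
    gr$fus$H2 <- gr$fus$H2 + outer(tp$h1, dh2)
    gr$fus$h2_b <- gr$fus$h2_b + dh2
    dh1 <- as.numeric(fs$H2 %*% dh2) * (tp$h1 > 0)
    gr$fus$H1 <- gr$fus$H1 + outer(tp$x_fused, dh1)
    gr$fus$h1_b <- gr$fus$h1_b + dh1
    df <- as.numeric(fs$H1 %*% dh1)
    dcat <- df * (1 + tp$gate)
    dgate <- df * tp$x_cat
    dzg <- dgate * tp$gate * (1 - tp$gate)
    gr$fus$bam_W2 <- gr$fus$bam_W2 + outer(tp$hid, dzg)
    gr$fus$bam_b2 <- gr$fus$bam_b2 + dzg
    dhid <- as.numeric(fs$bam_W2 %*% dzg) * (tp$hid > 0)
    gr$fus$bam_W1 <- gr$fus$bam_W1 + outer(tp$x_cat, dhid)
    gr$fus$bam_b1 <- gr$fus$bam_b1 + dhid
    dcat <- dcat + as.numeric(fs$bam_W1 %*% dhid)
    d_node_idx <- seq_along(tp$x_graph)
    dxg <- dcat[d_node_idx]
    dxi <- dcat[-d_node_idx]
    gr$fus$W_g <- gr$fus$W_g + outer(tp$x_super, dxg)
    gr$fus$W_i <- gr$fus$W_i + outer(tp$latent, dxi)
    dx_super <- as.numeric(fs$W_g %*% dxg)
    N <- graphs[[i]]$N
    d_x_out <- matrix(0, N, length(dx_super))
    d_x_out[N, ] <- dx_super
    gb <- .gpt_backward(tp$gpt, params$gpt, d_x_out)
    for (nm in names(gb$grads)) {
      gr$gpt[[nm]] <- gr$gpt[[nm]] + gb$grads[[nm]]
    }
    # projection backward
    g <- tp$graph
    gr$proj$W_node <- gr$proj$W_node + crossprod(g$node_raw, gb$d_x_node)
    gr$proj$b_node <- gr$proj$b_node + colSums(gb$d_x_node)
    d_edge <- dim(gb$d_x_edge)[3L]
    dEmat <- matrix(gb$d_x_edge, N * N, d_edge)
    emat <- matrix(g$edge_raw, N * N, 6L)
    gr$proj$W_edge <- gr$proj$W_edge + crossprod(emat, dEmat)
    gr$proj$b_edge <- gr$proj$b_edge + colSums(dEmat)
    vmask <- as.vector(g$virtual)
    if (any(vmask)) {
      gr$proj$v_edge <- gr$proj$v_edge +
        colSums(dEmat[vmask, , drop = FALSE])
    }
  }
  list(loss = loss, grads = gr)
}

#' Predict property probabilities for molecules
#'
#' Builds the hierarchical graph and the frozen-encoder image embedding for
#' each molecule, runs the fused model, and returns per-task probabilities.
#'
#' @param object a [mf_model()].
#' @param newdata character vector of SMILES or a [mf_dataset()].
#' @param encoder a frozen [mf_autoencoder()].
#' @param ... unused.
#' @return matrix `n x n_tasks` of probabilities.
#' @export
predict.molfuse_model <- function(object, newdata, encoder, ...) {
  smiles <- if (inherits(newdata, "molfuse_dataset")) newdata$smiles
            else as.character(newdata)
  graphs <- lapply(smiles, mf_build_hier_graph)
  imgs <- mf_render_depictions(smiles, size = encoder$size)
  latents <- mf_encode_images(imgs, encoder)
  out <- matrix(0, length(smiles), object$n_tasks)
  for (i in seq_along(smiles)) {
    fw <- .mf_model_forward(object$params, graphs[[i]], latents[i, ],
                            object$config$graph$n_iterations)
    out[i, ] <- fw$prob
  }
  rownames(out) <- smiles
  out
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the resolved configuration.
#'
#' @param model a `molfuse_model` (or any molfuse object).
#' @param path file path.
#' @return `path`, invisibly (for save); the object (for load).
#' @export
mf_save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname mf_save_checkpoint
#' @export
mf_load_checkpoint <- function(path) {
  readRDS(path)
}
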