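# Reptile meta-learning over episodic binary property-prediction tasks.
#
# One task is one binary endpoint of the multitask pool. An episode draws a
# class-balanced support set (shot per class) and a query set five times the
# support size. Inner adaptation copies the meta parameters, takes
# `support_iters` plain gradient steps on the support loss at the inner
# learning rate, then one step on the query loss, giving task parameters
# theta''. The outer update moves the meta parameters toward the mean of the
# per-task theta'': theta <- theta + eps * mean(theta'' - theta).

#' Featurize a dataset into a meta-learning pool
#'
#' Builds the hierarchical graph and the frozen-encoder image embedding for
#' every molecule, and attaches a scaffold split used to separate episode
#' sampling (train) from validation and testing.
#'
#' @param dataset a (typically multitask) [mf_dataset()].
#' @param encoder a frozen [mf_autoencoder()].
#' @param split optional precomputed [mf_scaffold_split()].
#' @param verbose print progress.
#' @return an object of class `molfuse_pool`.
#' @export
mf_featurize_pool <- function(dataset, encoder, split = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "molfuse_dataset"))
  if (is.null(split)) split <- mf_scaffold_split(dataset)
  if (verbose) message("building ", length(dataset$smiles), " graphs")
  graphs <- lapply(dataset$smiles, mf_build_hier_graph)
  if (verbose) message("rendering + encoding depictions")
  imgs <- mf_render_depictions(dataset$smiles, size = encoder$size)
  latents <- mf_encode_images(imgs, encoder)
  structure(list(dataset = dataset, graphs = graphs, latents = latents,
                 split = split, d_latent = encoder$d_latent),
            class = "molfuse_pool")
}

#' @export
print.molfuse_pool <- function(x, ...) {
  cat("<molfuse_pool>", length(x$dataset$smiles), "molecules,",
      length(x$dataset$task_names), "task(s)\n")
  invisible(x)
}

.pool_task_indices <- function(pool, task, subset = "train") {
  idx <- switch(subset,
                train = pool$split$train_idx,
                valid = pool$split$valid_idx,
                test = pool$split$test_idx,
                all = seq_along(pool$dataset$smiles))
  y <- pool$dataset$labels[, task]
  idx[!is.na(y[idx])]
}

#' Sample a few-shot episode for one task
#'
#' The support set holds `shot` molecules per class; the query set is
#' `ratio` times the support size, also class-balanced, drawn from the
#' remaining labelled molecules. Support and query never overlap.
#'
#' @param pool a [mf_featurize_pool()] result.
#' @param task task name (a column of the pool's label matrix).
#' @param way number of classes (2 for binary endpoints).
#' @param shot support molecules per class.
#' @param ratio query:support size ratio.
#' @param seed RNG seed; identical seeds give identical episodes.
#' @param subset which split portion to sample from.
#' @return an object of class `molfuse_episode`.
#' @export
mf_sample_episode <- function(pool, task, way = 2L, shot = 3L, ratio = 5L,
                              seed = 1L, subset = "train") {
  stopifnot(way == 2L)
  idx <- .pool_task_indices(pool, task, subset)
  y <- pool$dataset$labels[idx, task]
  pos <- idx[y == 1]
  neg <- idx[y == 0]
  need <- shot * (1L + ratio)
  if (length(pos) < need || length(neg) < need) {
    stop(structure(class = c("molfuse_insufficient", "error", "condition"),
                   list(message = paste0("task '", task, "' has too few ",
                                         "labelled molecules per class"),
                        call = NULL)))
  }
  set.seed(seed)
  sup_pos <- sample(pos, shot)
  sup_neg <- sample(neg, shot)
  qry_pos <- sample(setdiff(pos, sup_pos), shot * ratio)
  qry_neg <- sample(setdiff(neg, sup_neg), shot * ratio)
  support <- c(sup_pos, sup_neg)
  query <- c(qry_pos, qry_neg)
  structure(list(task = task, support_idx = support, query_idx = query,
                 y_support = pool$dataset$labels[support, task],
                 y_query = pool$dataset$labels[query, task]),
            class = "molfuse_episode")
}

#' @export
print.molfuse_episode <- function(x, ...) {
  cat("<molfuse_episode>", x$task, "- support", length(x$support_idx),
      "/ query", length(x$query_idx), "\n")
  invisible(x)
}

# single gradient-descent step on a set of molecules for one binary task.
# The gradient is clipped to a global norm of `clip`: the image-alignment
# path sees large-magnitude frozen embeddings, and plain SGD diverges
# within a few steps without a norm bound.
.task_step <- function(params, pool, idx, y, lr, n_iterations, clip = 5.0) {
  lg <- .mf_model_loss_grad(params, pool$graphs[idx],
                            pool$latents[idx, , drop = FALSE],
                            matrix(y, ncol = 1L),
                            matrix(TRUE, length(idx), 1L), n_iterations)
  if (!is.finite(lg$loss)) stop("non-finite loss during adaptation")
  gn <- sqrt(sum(mf_flatten(lg$grads)^2))
  s <- if (is.finite(gn) && gn > clip) clip / gn else 1
  list(params = mf_param_map(function(a, b) a - lr * s * b, params, lg$grads),
       loss = lg$loss)
}

#' Inner-loop adaptation on one episode
#'
#' Copies the meta parameters, performs `support_iters` gradient-descent
#' steps on the support loss at `lr_support`, then one step on the query
#' loss at `lr_query`, and returns the adapted parameters theta''. The meta
#' parameters are not modified.
#'
#' @param params the meta model's parameter list (`model$params`).
#' @param episode a [mf_sample_episode()] result.
#' @param pool the featurized pool.
#' @param support_iters number of support gradient steps.
#' @param lr_support,lr_query learning rates for the two phases.
#' @param n_iterations graph propagation iterations.
#' @return adapted parameter list.
#' @export
mf_inner_adapt <- function(params, episode, pool, support_iters = 5L,
                           lr_support = 0.001, lr_query = 0.001,
                           n_iterations = 3L) {
  th <- params
  for (k in seq_len(support_iters)) {
    th <- .task_step(th, pool, episode$support_idx, episode$y_support,
                     lr_support, n_iterations)$params
  }
  if (lr_query > 0) {
    th <- .task_step(th, pool, episode$query_idx, episode$y_query,
                     lr_query, n_iterations)$params
  }
  th
}

#' Reptile outer update
#'
#' `theta <- theta + eps * mean_t(theta''_t - theta)`, elementwise over the
#' flat parameter vector.
#'
#' @param params meta parameter list.
#' @param adapted list of adapted parameter lists (one per task).
#' @param meta_step the interpolation step `eps`.
#' @return updated parameter list.
#' @export
mf_reptile_outer_update <- function(params, adapted, meta_step) {
  stopifnot(length(adapted) >= 1L)
  th <- mf_flatten(params)
  mean_dir <- Reduce(`+`, lapply(adapted, function(a) mf_flatten(a) - th)) /
    length(adapted)
  mf_unflatten(th + meta_step * mean_dir, params)
}

#' ROC-AUC of scores against binary labels
#'
#' The probability that a random positive is scored above a random negative
#' (ties count one half).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return numeric value in `[0, 1]`.
#' @export
mf_roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(unique(labels[!is.na(labels)])) < 2L) {
    stop("ROC-AUC undefined: only one class present")
  }
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

# mean post-adaptation validation AUC across tasks: the meta parameters
# are task-blind (one shared head, no task input), so they are scored the
# way they are used -- adapted on a support episode first, then evaluated
# on the task's validation molecules
.pool_validation_auc <- function(params, pool, tasks, n_iterations,
                                 mc, eval_seed) {
  aucs <- c()
  for (k in seq_along(tasks)) {
    task <- tasks[k]
    idx <- .pool_task_indices(pool, task, "valid")
    y <- pool$dataset$labels[idx, task]
    if (length(unique(y)) < 2L) next
    th <- tryCatch({
      ep <- mf_sample_episode(pool, task, way = mc$way, shot = mc$shot,
                              ratio = mc$ratio, seed = eval_seed + k)
      mf_inner_adapt(params, ep, pool, support_iters = mc$support_iters,
                     lr_support = mc$lr, lr_query = mc$lr,
                     n_iterations = n_iterations)
    }, molfuse_insufficient = function(e) params)
    sc <- vapply(idx, function(i) {
      .mf_model_forward(th, pool$graphs[[i]], pool$latents[i, ],
                        n_iterations)$prob[1L]
    }, numeric(1))
    aucs <- c(aucs, mf_roc_auc(sc, y))
  }
  if (length(aucs)) mean(aucs) else NA_real_
}

#' Meta-train the model with Reptile
#'
#' Loops over `cycles x batches`; each batch samples `tasks_per_batch`
#' episodes, adapts a copy of the meta parameters per task
#' ([mf_inner_adapt()]), and interpolates the meta parameters toward the
#' adapted ones ([mf_reptile_outer_update()]). The checkpoint with the best
#' mean post-adaptation validation ROC-AUC across tasks is returned: at each
#' evaluation the current meta parameters are adapted on one support episode
#' per task and scored on that task's validation molecules. Tasks without enough
#' labelled molecules per class are skipped with a warning.
#'
#' @param pool a [mf_featurize_pool()] result over the multitask dataset.
#' @param config a [mf_config()]; the `meta` block holds every knob.
#' @param tasks task names to train on; default all pool tasks.
#' @param verbose print per-evaluation progress.
#' @return an object of class `molfuse_meta` with elements `model` (best
#'   checkpoint), `final_model`, `history` (per-evaluation metric log) and
#'   `config`.
#' @export
mf_meta_train <- function(pool, config = mf_config(), tasks = NULL,
                          verbose = FALSE) {
  mc <- config$meta
  if (is.null(tasks)) tasks <- pool$dataset$task_names
  if (length(tasks) < mc$tasks_per_batch) {
    stop("pool has fewer tasks than tasks_per_batch")
  }
  model <- mf_model(1L, config)
  n_it <- config$graph$n_iterations
  seed0 <- mf_derive_seed(config$seed, "meta")
  best <- list(auc = -Inf, params = model$params)
  history <- data.frame(cycle = integer(0), batch = integer(0),
                        val_auc = numeric(0))
  step <- 0L
  for (cycle in seq_len(mc$cycles)) {
    for (batch in seq_len(mc$batches)) {
      step <- step + 1L
      set.seed(seed0 + step)
      batch_tasks <- sample(tasks, mc$tasks_per_batch)
      adapted <- list()
      for (k in seq_along(batch_tasks)) {
        ep <- tryCatch(
          mf_sample_episode(pool, batch_tasks[k], way = mc$way,
                            shot = mc$shot, ratio = mc$ratio,
                            seed = seed0 + 7L * step + k),
          molfuse_insufficient = function(e) {
            warning(conditionMessage(e), call. = FALSE)
            NULL
          })
        if (is.null(ep)) next
        adapted[[length(adapted) + 1L]] <-
          mf_inner_adapt(model$params, ep, pool,
                         support_iters = mc$support_iters,
                         lr_support = mc$lr, lr_query = mc$lr,
                         n_iterations = n_it)
      }
      if (!length(adapted)) next
      model$params <- mf_reptile_outer_update(model$params, adapted,
                                              mc$meta_step)
      if (step %% mc$eval_every == 0L || step == mc$cycles * mc$batches) {
        auc <- .pool_validation_auc(model$params, pool, tasks, n_it,
                                    mc, seed0 + 500000L + step)
        history <- rbind(history, data.frame(cycle = cycle, batch = batch,
                                             val_auc = auc))
        if (verbose) message(sprintf("cycle %d batch %d: val AUC %.3f",
                                     cycle, batch, auc))
        if (!is.na(auc) && auc > best$auc) {
          best <- list(auc = auc, params = model$params)
        }
      }
    }
  }
  final_model <- model
  model$params <- best$params
  structure(list(model = model, final_model = final_model,
                 best_val_auc = best$auc, history = history,
                 config = config),
            class = "molfuse_meta")
}

#' @export
print.molfuse_meta <- function(x, ...) {
  cat("<molfuse_meta> best mean validation ROC-AUC:",
      round(x$best_val_auc, 3), "\n")
  invisible(x)
}

#' Fine-tune a model on one task
#'
#' Plain minibatch gradient descent on the task's training molecules with
#' best-checkpoint selection on validation ROC-AUC.
#'
#' @param model a [mf_model()] (typically the meta-trained checkpoint).
#' @param pool the featurized pool holding the task.
#' @param task task name.
#' @param epochs training epochs; 0 returns the model unchanged.
#' @param lr learning rate.
#' @param batch_size minibatch size.
#' @param seed RNG seed for shuffling.
#' @param train_idx optional explicit training molecule indices (defaults to
#'   the task's labelled training-split molecules).
#' @return list with `model` (best checkpoint), `history` (per-epoch
#'   validation AUC) and `best_val_auc`.
#' @export
mf_finetune <- function(model, pool, task, epochs = 20L, lr = 0.001,
                        batch_size = 16L, seed = 1L, train_idx = NULL) {
  if (is.null(train_idx)) train_idx <- .pool_task_indices(pool, task, "train")
  valid_idx <- .pool_task_indices(pool, task, "valid")
  n_it <- model$config$graph$n_iterations
  y_tr <- pool$dataset$labels[train_idx, task]
  eval_auc <- function(params) {
    y <- pool$dataset$labels[valid_idx, task]
    if (length(unique(y)) < 2L) return(NA_real_)
    sc <- vapply(valid_idx, function(i) {
      .mf_model_forward(params, pool$graphs[[i]], pool$latents[i, ],
                        n_it)$prob[1L]
    }, numeric(1))
    mf_roc_auc(sc, y)
  }
  # the untrained initialization is logged but is not a checkpoint
  # candidate: on small validation sets, selecting over it lets a random
  # model win by chance rather than by training
  history <- data.frame(epoch = 0L, val_auc = eval_auc(model$params))
  best <- list(auc = NA_real_, params = model$params)
  if (epochs > 0L) {
    set.seed(mf_derive_seed(seed, "finetune"))
    for (ep in seq_len(epochs)) {
      ord <- sample(seq_along(train_idx))
      for (start in seq(1L, length(ord), by = batch_size)) {
        sel <- ord[start:min(start + batch_size - 1L, length(ord))]
        st <- .task_step(model$params, pool, train_idx[sel], y_tr[sel],
                         lr, n_it)
        model$params <- st$params
      }
      auc <- eval_auc(model$params)
      history <- rbind(history, data.frame(epoch = ep, val_auc = auc))
      if (!is.na(auc) && (is.na(best$auc) || auc >= best$auc)) {
        best <- list(auc = auc, params = model$params)
      }
    }
  } else {
    best$auc <- history$val_auc[1L]
  }
  model$params <- best$params
  list(model = model, history = history, best_val_auc = best$auc)
}

#' Evaluate a model's ROC-AUC on one task
#'
#' @param model a [mf_model()].
#' @param pool the featurized pool.
#' @param task task name.
#' @param subset one of "train", "valid", "test", "all".
#' @return list with `auc` and `n` (molecules scored).
#' @export
mf_evaluate <- function(model, pool, task, subset = "test") {
  idx <- .pool_task_indices(pool, task, subset)
  y <- pool$dataset$labels[idx, task]
  n_it <- model$config$graph$n_iterations
  sc <- vapply(idx, function(i) {
    .mf_model_forward(model$params, pool$graphs[[i]], pool$latents[i, ],
                      n_it)$prob[1L]
  }, numeric(1))
  list(auc = mf_roc_auc(sc, y), n = length(idx))
}
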