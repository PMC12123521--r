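# A tiny featurized pool with fabricated embeddings; label rule: halogen.
tiny_pool <- function(n = 120L, seed = 4L) {
  memo(paste0("tiny_pool_", n, "_", seed), function() {
    smi <- mf_generate_molecules(n, seed = seed)
    spec <- mf_task_spec("[F,Cl,Br,I]", seed = seed)
    ds <- mf_label_by_rule(smi, spec, task_name = "halo")
    ds2 <- mf_label_by_rule(smi, mf_task_spec("[CX3]=O", seed = seed),
                            task_name = "carbonyl")
    merged <- mf_merge_multitask(list(ds, ds2))
    graphs <- lapply(merged$smiles, mf_build_hier_graph)
    set.seed(seed)
    latents <- matrix(rnorm(length(merged$smiles) * 9), ncol = 9)
    structure(list(dataset = merged, graphs = graphs, latents = latents,
                   split = mf_scaffold_split(merged), d_latent = 9L),
              class = "molfuse_pool")
  })
}

test_that("episodes are balanced, ratio-sized and reproducible", {
  pool <- tiny_pool()
  ep <- mf_sample_episode(pool, "halo", shot = 3L, ratio = 5L, seed = 1L,
                          subset = "all")
  expect_length(ep$support_idx, 6L)
  expect_length(ep$query_idx, 30L)
  expect_equal(sum(ep$y_support), 3)
  expect_length(intersect(ep$support_idx, ep$query_idx), 0L)
  ep2 <- mf_sample_episode(pool, "halo", shot = 3L, ratio = 5L, seed = 1L,
                           subset = "all")
  expect_identical(ep$support_idx, ep2$support_idx)
  expect_identical(ep$query_idx, ep2$query_idx)
  # support of size 12 at ratio 1:5 yields a query of size 60
  ep6 <- mf_sample_episode(pool, "halo", shot = 6L, ratio = 5L, seed = 2L,
                           subset = "all")
  expect_length(ep6$support_idx, 12L)
  expect_length(ep6$query_idx, 60L)
  # insufficient data is a typed condition
  expect_error(mf_sample_episode(pool, "halo", shot = 50L, seed = 1L),
               class = "molfuse_insufficient")
})

test_that("support and query never overlap across many sampled episodes", {
  pool <- tiny_pool()
  for (k in 1:1000) {
    ep <- mf_sample_episode(pool, if (k %% 2) "halo" else "carbonyl",
                            seed = k, subset = "all")
    expect_length(intersect(ep$support_idx, ep$query_idx), 0L)
  }
})

test_that("inner adaptation composes plain gradient steps and keeps meta intact", {
  pool <- tiny_pool()
  cfg <- tiny_cfg()
  m <- mf_model(1L, cfg, seed = 2L)
  ep <- mf_sample_episode(pool, "halo", seed = 3L, subset = "all")
  theta0 <- molfuse:::mf_flatten(m$params)

  # no support steps and zero query rate: adaptation is the identity
  same <- mf_inner_adapt(m$params, ep, pool, support_iters = 0L,
                         lr_support = 0.01, lr_query = 0, n_iterations = 3L)
  expect_equal(molfuse:::mf_flatten(same), theta0)

  # three support steps match hand-iterated gradient descent
  adapted <- mf_inner_adapt(m$params, ep, pool, support_iters = 3L,
                            lr_support = 0.01, lr_query = 0,
                            n_iterations = 3L)
  th <- m$params
  for (k in 1:3) {
    lg <- molfuse:::.mf_model_loss_grad(
      th, pool$graphs[ep$support_idx],
      pool$latents[ep$support_idx, , drop = FALSE],
      matrix(ep$y_support, ncol = 1), matrix(TRUE, 6, 1), 3L)
    th <- molfuse:::mf_param_map(function(a, b) a - 0.01 * b, th, lg$grads)
  }
  expect_equal(molfuse:::mf_flatten(adapted), molfuse:::mf_flatten(th),
               tolerance = 1e-12)
  # the meta parameters were never modified
  expect_identical(molfuse:::mf_flatten(m$params), theta0)
  # determinism
  adapted2 <- mf_inner_adapt(m$params, ep, pool, support_iters = 3L,
                             lr_support = 0.01, lr_query = 0,
                             n_iterations = 3L)
  expect_identical(molfuse:::mf_flatten(adapted),
                   molfuse:::mf_flatten(adapted2))
})

test_that("the Reptile outer update interpolates toward adapted parameters", {
  cfg <- tiny_cfg()
  m <- mf_model(1L, cfg, seed = 5L)
  th <- molfuse:::mf_flatten(m$params)

  # fixed point: all adapted copies equal theta
  upd <- mf_reptile_outer_update(m$params, list(m$params, m$params), 0.3)
  expect_identical(molfuse:::mf_flatten(upd), th)

  # eps = 1 with one task lands exactly on theta''
  shift <- molfuse:::mf_unflatten(th + 0.5, m$params)
  upd1 <- mf_reptile_outer_update(m$params, list(shift), 1.0)
  expect_equal(molfuse:::mf_flatten(upd1), th + 0.5)

  # three tasks with known offsets: mean interpolation, by hand arithmetic
  offs <- c(-1, 2, 5)
  adapted <- lapply(offs, function(o) molfuse:::mf_unflatten(th + o, m$params))
  upd3 <- mf_reptile_outer_update(m$params, adapted, 0.25)
  expect_equal(molfuse:::mf_flatten(upd3), th + 0.25 * mean(offs),
               tolerance = 1e-12)

  # interpolation bound: coordinates stay in the hull of {theta, mean theta''}
  for (eps in c(0, 0.4, 1)) {
    u <- molfuse:::mf_flatten(
      mf_reptile_outer_update(m$params, adapted, eps))
    lo <- pmin(th, th + mean(offs)); hi <- pmax(th, th + mean(offs))
    expect_true(all(u >= lo - 1e-12 & u <= hi + 1e-12))
  }
})

test_that("ROC-AUC equals exhaustive pair counting", {
  expect_equal(mf_roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(mf_roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  s <- c(0.1, 0.4, 0.35, 0.8, 0.65, 0.8, 0.2, 0.5)
  y <- c(0, 0, 1, 1, 0, 1, 0, 1)
  expect_equal(mf_roc_auc(s, y), oracle_auc(s, y))
  # ties count one half
  st <- c(0.5, 0.5, 0.2, 0.9)
  yt <- c(1, 0, 0, 1)
  expect_equal(mf_roc_auc(st, yt), oracle_auc(st, yt))
  expect_error(mf_roc_auc(c(0.1, 0.9), c(1, 1)), "one class")
})

test_that("fine-tuning with zero epochs returns the parameters unchanged", {
  pool <- tiny_pool()
  cfg <- tiny_cfg()
  m <- mf_model(1L, cfg, seed = 6L)
  ft <- mf_finetune(m, pool, "halo", epochs = 0L)
  expect_identical(molfuse:::mf_flatten(ft$model$params),
                   molfuse:::mf_flatten(m$params))
  # best-so-far validation tracking is non-decreasing over training epochs
  # (the untrained epoch-0 state is logged but not a checkpoint candidate)
  ft2 <- mf_finetune(m, pool, "halo", epochs = 3L, lr = 0.05, seed = 2L)
  trained <- ft2$history$val_auc[ft2$history$epoch >= 1L]
  expect_true(ft2$best_val_auc >= max(trained, na.rm = TRUE) - 1e-12)
  expect_true(all(diff(cummax(ifelse(is.na(trained), 0, trained))) >= 0))
})

test_that("scaled meta-training runs, logs metrics and is seed-deterministic", {
  pool <- tiny_pool()
  cfg <- mf_config(graph = list(d_node = 12L, d_edge = 6L, n_head = 2L,
                                d_k = 2L, n_iterations = 2L),
                   image = list(d_latent = 9L),
                   fusion = list(bam_reduction = 3L, head_widths = c(7L, 5L)),
                   meta = list(batches = 4L, cycles = 1L, tasks_per_batch = 2L,
                               support_iters = 2L, lr = 0.05,
                               meta_step = 0.5, eval_every = 2L))
  r1 <- mf_meta_train(pool, cfg, tasks = c("halo", "carbonyl"))
  expect_s3_class(r1, "molfuse_meta")
  expect_true(all(is.finite(molfuse:::mf_flatten(r1$final_model$params))))
  expect_gt(nrow(r1$history), 0L)
  expect_true(all(!is.na(r1$history$val_auc)))
  r2 <- mf_meta_train(pool, cfg, tasks = c("halo", "carbonyl"))
  expect_identical(molfuse:::mf_flatten(r1$final_model$params),
                   molfuse:::mf_flatten(r2$final_model$params))
  expect_error(mf_meta_train(pool, cfg, tasks = "halo"), "fewer tasks")
})
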