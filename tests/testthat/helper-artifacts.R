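# Shared test artifacts, built lazily once per test run. The heavier pieces
# (benchmark suite, pretrained encoder, featurized pool, meta-trained model)
# are reused across test files to keep the suite inside a desk-scale budget.

.artifacts <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .artifacts)) {
    assign(name, build(), envir = .artifacts)
  }
  get(name, envir = .artifacts)
}

# a small reduced-width configuration for fast exact tests
tiny_cfg <- function(n_tasks_latent = 9L) {
  mf_config(graph = list(d_node = 12L, d_edge = 6L, n_head = 2L, d_k = 2L,
                         n_iterations = 3L),
            image = list(d_latent = n_tasks_latent),
            fusion = list(bam_reduction = 3L, head_widths = c(7L, 5L)))
}

small_mols <- function() {
  c("CCO", "c1ccccc1", "CC(=O)O", "CC(=O)Oc1ccccc1C(=O)O",
    "Cn1c(=O)c2c(ncn2C)n(C)c1=O", "c1ccc(Cl)cc1", "CCCCBr", "CC(=O)NC")
}

# the synthetic five-task benchmark under the default study conditions
get_suite <- function() {
  memo("suite", function() mf_make_benchmark_suite(seed = 1L))
}

# depictions of the first 50 pool molecules; the autoencoder pretraining set
get_pretrain_images <- function() {
  memo("pretrain_images", function() {
    mf_render_depictions(get_suite()$pool[1:50])
  })
}

# the frozen encoder (seed 1, default pretraining configuration)
get_encoder <- function() {
  memo("encoder", function() {
    mf_pretrain_autoencoder(get_pretrain_images(), seed = 1L)
  })
}

# the featurized multitask pool (graphs + frozen-encoder embeddings)
get_pool <- function() {
  memo("pool", function() {
    suite <- get_suite()
    mf_featurize_pool(suite$merged, get_encoder(),
                      split = suite$merged_split)
  })
}

meta_train_tasks <- function() c("halogen", "carbonyl", "amine", "hydroxy_ether")
heldout_task <- function() "acyl_oxy"

# desk-scale meta-training configuration (20 batches x 1 cycle)
scaled_meta_cfg <- function() {
  mf_config(meta = list(batches = 20L, cycles = 1L, lr = 0.05,
                        meta_step = 1.0, eval_every = 5L))
}

get_meta <- function() {
  memo("meta", function() {
    mf_meta_train(get_pool(), scaled_meta_cfg(), tasks = meta_train_tasks())
  })
}
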