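# One configuration object for every knob; unknown keys are rejected.

.mf_defaults <- function() {
  list(
    seed = 1L,
    image = list(size = 224L, channels = c(64L, 128L, 256L), cq = 4L,
                 d_latent = 768L, alpha = 1.0, theta_init = 1.0,
                 epochs = 2L, lr = 0.3, batch_size = 8L),
    graph = list(d_node = 256L, d_edge = 64L, n_head = 4L, d_k = 4L,
                 n_iterations = 3L),
    fusion = list(bam_reduction = 16L, head_widths = c(256L, 64L),
                  clamp_eps = 1e-7),
    meta = list(way = 2L, shot = 3L, ratio = 5L, batches = 1000L,
                tasks_per_batch = 3L, support_iters = 5L, cycles = 10L,
                lr = 0.001, meta_step = 0.1, eval_every = 25L),
    finetune = list(epochs = 20L, lr = 0.001, batch_size = 16L)
  )
}

.merge_config <- function(base, over, path = "") {
  for (nm in names(over)) {
    if (!nm %in% names(base)) {
      stop("unknown configuration key: ", paste0(path, nm))
    }
    if (is.list(base[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], as.list(over[[nm]]),
                                  paste0(path, nm, "."))
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Build a run configuration
#'
#' Defaults follow the published training settings where stated (1000
#' batches, learning rate 0.001, three tasks per batch, five support
#' iterations, ten cycles, 2-way/3-shot episodes with a 1:5 support:query
#' ratio, three propagation iterations, four attention heads). Overrides are
#' supplied as nested lists; unknown keys are an error.
#'
#' @param ... named overrides, e.g. `meta = list(batches = 20)`.
#' @return nested configuration list of class `molfuse_config`.
#' @export
mf_config <- function(...) {
  over <- list(...)
  cfg <- .merge_config(.mf_defaults(), over)
  class(cfg) <- "molfuse_config"
  cfg
}

#' Read a configuration from a YAML file
#'
#' @param path YAML file whose keys mirror [mf_config()].
#' @return a `molfuse_config`.
#' @export
mf_read_config <- function(path) {
  over <- yaml::read_yaml(path)
  if (is.null(over)) over <- list()
  do.call(mf_config, over)
}

#' @export
print.molfuse_config <- function(x, ...) {
  cat("<molfuse_config>\n")
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}
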