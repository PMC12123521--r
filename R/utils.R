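#' @useDynLib molfuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm predict
#' @importFrom utils read.csv write.csv head str
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# row-wise softmax with max subtraction
row_softmax <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

# column-wise softmax with max subtraction
col_softmax <- function(m) {
  m <- sweep(m, 2L, apply(m, 2L, max))
  e <- exp(m)
  sweep(e, 2L, colSums(e), "/")
}

# backward of row_softmax: given s = row_softmax(a) and ds, return da
row_softmax_backward <- function(s, ds) {
  s * (ds - rowSums(ds * s))
}

# Glorot-style uniform initialisation
glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# --- flat parameter view -----------------------------------------------------
# Trainable parameters live in nested named lists of numeric arrays. The
# Reptile outer update and checkpointing need a flat vector view that can be
# restored exactly (including dim attributes).

mf_flatten <- function(params) {
  unlist(params, use.names = FALSE)
}

mf_unflatten <- function(vec, skeleton) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) {
      out <- lapply(x, walk)
      attributes(out) <- attributes(x)   # keep class/dims metadata
      return(out)
    }
    n <- length(x)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    dim(out) <- dim(x)
    out
  }
  out <- walk(skeleton)
  stopifnot(pos == length(vec))
  out
}

# elementwise arithmetic over nested parameter lists
mf_param_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- if (is.null(b)) lapply(a, mf_param_map, f = f)
           else Map(function(x, y) mf_param_map(f, x, y), a, b)
    attributes(out) <- attributes(a)    # keep class/dims metadata
    return(out)
  }
  if (is.null(b)) f(a) else f(a, b)
}

# deterministic per-stage seed derivation from one root seed (kept < 2^31)
mf_derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(fixtures = 11L, render = 23L, autoencoder = 37L, model = 53L,
               meta = 71L, episode = 89L, finetune = 107L, split = 131L,
               noise = 151L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 2654435L + off * 97L) %% 2147483647L)
}
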