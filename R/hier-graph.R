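# The three-level hierarchical molecular graph: one-hot atom/bond features,
# BRICS motif nodes, a super node, and the hierarchical adjacency.
#
# Atom features (31-d): type 11 | degree 6 | formal charge 5 | chiral tag 4 |
# hybridization 4 | aromatic 1. Bond features (6-d): type 4 | ring 1 |
# conjugated 1. Categories outside a block's vocabulary map to the block's
# final slot.

.atom_types <- c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "B", "other")
.degrees <- c("0", "1", "2", "3", "4", "5+")
.charges <- c("-2", "-1", "0", "+1", "+2+")
.chirals <- c("none", "cw", "ccw", "other")
.hybrids <- c("sp", "sp2", "sp3", "other")
.bond_types <- c("single", "double", "triple", "aromatic")

.onehot <- function(value, vocab) {
  v <- numeric(length(vocab))
  i <- match(value, vocab)
  if (is.na(i)) i <- length(vocab)
  v[i] <- 1
  v
}

#' One-hot featurize an atom
#'
#' @param atom a one-row data frame (or list) with fields `symbol`, `degree`,
#'   `charge`, `chiral`, `hybrid`, `aromatic`, as produced by the chemistry
#'   backend.
#' @return numeric vector of length 31.
#' @export
mf_featurize_atom <- function(atom) {
  deg <- if (atom$degree >= 5) "5+" else as.character(atom$degree)
  chg <- if (atom$charge <= -2) "-2"
         else if (atom$charge >= 2) "+2+"
         else c("-2" = "-2", "-1" = "-1", "0" = "0", "1" = "+1")[
           as.character(atom$charge)]
  c(.onehot(atom$symbol, .atom_types),
    .onehot(deg, .degrees),
    .onehot(chg, .charges),
    .onehot(atom$chiral, .chirals),
    .onehot(atom$hybrid, .hybrids),
    as.numeric(atom$aromatic))
}

#' One-hot featurize a bond
#'
#' @param bond a one-row data frame (or list) with fields `type`, `ring`,
#'   `conj`.
#' @return numeric vector of length 6.
#' @export
mf_featurize_bond <- function(bond) {
  c(.onehot(bond$type, .bond_types),
    as.numeric(bond$ring),
    as.numeric(bond$conj))
}

#' BRICS motif partition of a molecule
#'
#' Cuts every BRICS-cleavable bond and returns the connected components of
#' the remaining heavy-atom graph as a partition of atom indices, ordered by
#' smallest member index. Molecules with no cleavable bond form one motif.
#'
#' @param smiles a single SMILES string, or a parsed feature payload.
#' @return list of integer vectors (1-based atom indices).
#' @export
mf_brics_motifs <- function(smiles) {
  f <- if (is.character(smiles)) .mf_mol_features(smiles)[[1L]] else smiles
  if (is.null(f)) stop("invalid SMILES")
  n <- f$n_atoms
  bonds <- f$bonds
  if (nrow(bonds)) {
    cut_key <- vapply(f$brics, function(p) paste(sort(p), collapse = "-"),
                      character(1))
    bond_key <- paste(pmin(bonds$a, bonds$b), pmax(bonds$a, bonds$b),
                      sep = "-")
    keep <- !(bond_key %in% cut_key)
    el <- cbind(bonds$a[keep], bonds$b[keep])
  } else {
    el <- matrix(integer(0), 0, 2)
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  motifs <- split(seq_len(n), comp)
  motifs <- unname(motifs[order(vapply(motifs, min, numeric(1)))])
  lapply(motifs, as.integer)
}

#' Build the hierarchical molecular graph
#'
#' Nodes are the heavy atoms, one node per BRICS motif, and one super node
#' (always the last index). Atom-atom edges carry the 6-d bond feature;
#' motif-to-member-atom and super-to-motif edges are virtual (all-zero raw
#' feature, flagged in `virtual`); the adjacency is symmetric. Motif rows of
#' `node_raw` are all-ones, the super row all-zeros.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `molfuse_graph`.
#' @export
mf_build_hier_graph <- function(smiles) {
  f <- if (is.character(smiles)) .mf_mol_features(smiles)[[1L]] else smiles
  if (is.null(f)) stop("invalid SMILES: cannot build graph")
  n_atoms <- f$n_atoms
  if (n_atoms < 1L) stop("molecule has no heavy atoms")
  motifs <- mf_brics_motifs(f)
  n_motifs <- length(motifs)
  N <- n_atoms + n_motifs + 1L
  super <- N

  node_raw <- matrix(0, N, 31L)
  for (i in seq_len(n_atoms)) {
    node_raw[i, ] <- mf_featurize_atom(f$atoms[i, ])
  }
  if (n_motifs > 0L) {
    node_raw[n_atoms + seq_len(n_motifs), ] <- 1
  }
  # super row stays all-zeros

  edge_raw <- array(0, dim = c(N, N, 6L))
  adj <- matrix(FALSE, N, N)
  virtual <- matrix(FALSE, N, N)
  if (nrow(f$bonds)) {
    for (k in seq_len(nrow(f$bonds))) {
      a <- f$bonds$a[k]; b <- f$bonds$b[k]
      bv <- mf_featurize_bond(f$bonds[k, ])
      edge_raw[a, b, ] <- bv
      edge_raw[b, a, ] <- bv
      adj[a, b] <- adj[b, a] <- TRUE
    }
  }
  for (m in seq_len(n_motifs)) {
    mi <- n_atoms + m
    for (a in motifs[[m]]) {
      adj[mi, a] <- adj[a, mi] <- TRUE
      virtual[mi, a] <- virtual[a, mi] <- TRUE
    }
    adj[super, mi] <- adj[mi, super] <- TRUE
    virtual[super, mi] <- virtual[mi, super] <- TRUE
  }

  structure(list(
    smiles = if (is.character(smiles)) smiles else f$canonical,
    canonical = f$canonical,
    n_atoms = n_atoms, n_motifs = n_motifs, N = N,
    node_raw = node_raw, edge_raw = edge_raw,
    adj = adj, virtual = virtual,
    level = c(rep("atom", n_atoms), rep("motif", n_motifs), "super"),
    motif_members = motifs
  ), class = "molfuse_graph")
}

#' @export
print.molfuse_graph <- function(x, ...) {
  cat("<molfuse_graph>", x$canonical, "-", x$n_atoms, "atoms,",
      x$n_motifs, "motifs, 1 super node (N =", x$N, ")\n")
  invisible(x)
}

#' Initialise the raw-to-latent projection maps
#'
#' One shared linear layer projects all 31-d node rows (atoms, all-ones
#' motifs, all-zero super) to the node latent space, and one projects the 6-d
#' edge slots to the edge latent space. Virtual hierarchical edges
#' additionally receive a learned embedding vector after projection.
#'
#' @param d_node node latent width.
#' @param d_edge edge latent width.
#' @param seed RNG seed for the Glorot-style initialisation.
#' @return list with `W_node`, `b_node`, `W_edge`, `b_edge`, `v_edge`.
#' @export
mf_projection_params <- function(d_node = 256L, d_edge = 64L, seed = 1L) {
  set.seed(seed)
  list(W_node = glorot(31L, d_node), b_node = numeric(d_node),
       W_edge = glorot(6L, d_edge), b_edge = numeric(d_edge),
       v_edge = as.numeric(glorot(1L, d_edge)))
}

#' Project raw graph features into the latent spaces
#'
#' Every node row and every edge slot (including non-edges, which map to the
#' zero-input image of the edge map) is projected linearly; the learned
#' virtual-edge embedding is added to motif-atom and super-motif slots.
#'
#' @param g a [mf_build_hier_graph()] result.
#' @param proj a [mf_projection_params()] list.
#' @return `g` with `node_latent` (`N x d_node`) and `edge_latent`
#'   (`N x N x d_edge`) filled in.
#' @export
mf_project_latents <- function(g, proj) {
  stopifnot(inherits(g, "molfuse_graph"))
  N <- g$N
  d_edge <- ncol(proj$W_edge)
  g$node_latent <- sweep(g$node_raw %*% proj$W_node, 2L, proj$b_node, "+")
  emat <- matrix(g$edge_raw, N * N, 6L)
  el <- sweep(emat %*% proj$W_edge, 2L, proj$b_edge, "+")
  vmask <- as.vector(g$virtual)
  if (any(vmask)) {
    el[vmask, ] <- sweep(el[vmask, , drop = FALSE], 2L, proj$v_edge, "+")
  }
  g$edge_latent <- array(el, dim = c(N, N, d_edge))
  g
}

#' Serialize a hierarchical graph to JSON
#'
#' Captures node levels, motif membership, adjacency triplets and raw
#' features; latents are recomputed from projections and are not stored.
#'
#' @param g a `molfuse_graph`.
#' @return a JSON string.
#' @export
mf_graph_to_json <- function(g) {
  stopifnot(inherits(g, "molfuse_graph"))
  idx <- which(g$adj & upper.tri(g$adj), arr.ind = TRUE)
  edges <- lapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    list(i = i, j = j, virtual = g$virtual[i, j],
         feature = as.numeric(g$edge_raw[i, j, ]))
  })
  jsonlite::toJSON(list(
    canonical = g$canonical, n_atoms = g$n_atoms, n_motifs = g$n_motifs,
    level = g$level, motif_members = g$motif_members,
    node_raw = g$node_raw, edges = edges
  ), auto_unbox = TRUE, digits = NA)
}

#' Deserialize a hierarchical graph from JSON
#'
#' @param json a string produced by [mf_graph_to_json()].
#' @return a `molfuse_graph` (without latents).
#' @export
mf_graph_from_json <- function(json) {
  d <- jsonlite::fromJSON(json, simplifyVector = TRUE, simplifyMatrix = TRUE)
  N <- d$n_atoms + d$n_motifs + 1L
  edge_raw <- array(0, dim = c(N, N, 6L))
  adj <- matrix(FALSE, N, N)
  virtual <- matrix(FALSE, N, N)
  if (length(d$edges)) {
    for (k in seq_len(nrow(d$edges))) {
      i <- d$edges$i[k]; j <- d$edges$j[k]
      fv <- unlist(d$edges$feature[k])
      edge_raw[i, j, ] <- fv; edge_raw[j, i, ] <- fv
      adj[i, j] <- adj[j, i] <- TRUE
      if (isTRUE(d$edges$virtual[k])) virtual[i, j] <- virtual[j, i] <- TRUE
    }
  }
  structure(list(
    smiles = d$canonical, canonical = d$canonical,
    n_atoms = d$n_atoms, n_motifs = d$n_motifs, N = N,
    node_raw = matrix(d$node_raw, N, 31L), edge_raw = edge_raw,
    adj = adj, virtual = virtual, level = d$level,
    motif_members = lapply(d$motif_members, as.integer)
  ), class = "molfuse_graph")
}
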