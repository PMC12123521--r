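vocab_expect <- function(atom) {
  # independent per-property construction of the expected 31-d one-hot
  blocks <- list(
    type = c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "B", "other"),
    degree = c("0", "1", "2", "3", "4", "5+"),
    charge = c("-2", "-1", "0", "+1", "+2+"),
    chiral = c("none", "cw", "ccw", "other"),
    hybrid = c("sp", "sp2", "sp3", "other")
  )
  pick <- function(value, vocab) {
    v <- numeric(length(vocab))
    i <- match(value, vocab)
    v[if (is.na(i)) length(vocab) else i] <- 1
    v
  }
  deg <- if (atom$degree >= 5) "5+" else as.character(atom$degree)
  chg <- if (atom$charge <= -2) "-2" else if (atom$charge >= 2) "+2+"
         else switch(as.character(atom$charge), "-1" = "-1", "0" = "0",
                     "1" = "+1")
  c(pick(atom$symbol, blocks$type), pick(deg, blocks$degree),
    pick(chg, blocks$charge), pick(atom$chiral, blocks$chiral),
    pick(atom$hybrid, blocks$hybrid), as.numeric(atom$aromatic))
}

block_sums <- function(v) {
  c(sum(v[1:11]), sum(v[12:17]), sum(v[18:22]), sum(v[23:26]), sum(v[27:30]))
}

test_that("atom featurization is a 31-d partitioned one-hot", {
  f <- molfuse:::.mf_mol_features("CCO")[[1L]]
  v <- mf_featurize_atom(f$atoms[1, ])        # sp3 carbon of ethanol
  expect_length(v, 31L)
  expect_equal(v[1], 1)                       # type block selects C
  expect_equal(v[31], 0)                      # not aromatic
  expect_equal(block_sums(v), rep(1, 5))

  fb <- molfuse:::.mf_mol_features("c1ccccc1")[[1L]]
  vb <- mf_featurize_atom(fb$atoms[1, ])      # aromatic carbon of benzene
  expect_equal(vb[31], 1)
  expect_equal(vb[26 + 2], 1)                 # hybridization block: sp2 slot

  # every atom of caffeine, against the independent per-property lookup
  fc <- molfuse:::.mf_mol_features("Cn1c(=O)c2c(ncn2C)n(C)c1=O")[[1L]]
  for (i in seq_len(fc$n_atoms)) {
    v <- mf_featurize_atom(fc$atoms[i, ])
    expect_equal(v, vocab_expect(fc$atoms[i, ]))
    expect_equal(block_sums(v), rep(1, 5))
    expect_true(v[31] %in% c(0, 1))
  }
})

test_that("bond featurization is the 6-d type/ring/conjugation one-hot", {
  fe <- molfuse:::.mf_mol_features("CC")[[1L]]
  expect_equal(mf_featurize_bond(fe$bonds[1, ]), c(1, 0, 0, 0, 0, 0))

  fb <- molfuse:::.mf_mol_features("c1ccccc1")[[1L]]
  for (k in seq_len(nrow(fb$bonds))) {
    expect_equal(mf_featurize_bond(fb$bonds[k, ]), c(0, 0, 0, 1, 1, 1))
  }

  # all bonds of aspirin against an independent per-bond property scan
  fa <- molfuse:::.mf_mol_features("CC(=O)Oc1ccccc1C(=O)O")[[1L]]
  for (k in seq_len(nrow(fa$bonds))) {
    b <- fa$bonds[k, ]
    exp_v <- c(as.numeric(c("single", "double", "triple", "aromatic") == b$type),
               as.numeric(b$ring), as.numeric(b$conj))
    expect_equal(mf_featurize_bond(b), exp_v)
  }
})

test_that("BRICS motifs partition the heavy atoms", {
  # ethanol: no cleavable bond, one motif
  m <- mf_brics_motifs("CCO")
  expect_length(m, 1L)
  expect_equal(m[[1L]], 1:3)

  # a single cleavable bond gives exactly two disjoint covering motifs
  f <- molfuse:::.mf_mol_features("c1ccccc1CC")[[1L]]
  if (length(f$brics) == 1L) {
    m2 <- mf_brics_motifs("c1ccccc1CC")
    expect_length(m2, 2L)
    expect_setequal(unlist(m2), seq_len(f$n_atoms))
    expect_length(intersect(m2[[1L]], m2[[2L]]), 0L)
  }

  # aspirin against an independent cut-and-BFS components oracle
  fa <- molfuse:::.mf_mol_features("CC(=O)Oc1ccccc1C(=O)O")[[1L]]
  cut <- vapply(fa$brics, function(p) paste(sort(p), collapse = "-"),
                character(1))
  keep <- !(paste(pmin(fa$bonds$a, fa$bonds$b),
                  pmax(fa$bonds$a, fa$bonds$b), sep = "-") %in% cut)
  ref <- oracle_components(fa$n_atoms,
                           cbind(fa$bonds$a, fa$bonds$b)[keep, , drop = FALSE])
  expect_equal(mf_brics_motifs("CC(=O)Oc1ccccc1C(=O)O"), ref)
})

test_that("the hierarchical graph obeys its structural invariants", {
  g <- mf_build_hier_graph("CCO")
  expect_equal(g$N, 3L + 1L + 1L)
  expect_equal(g$level[g$N], "super")
  expect_equal(sum(g$adj[g$N, ]), g$n_motifs)          # super touches motifs only
  expect_equal(sum(g$adj[4L, 1:3]), 3L)                # motif touches members

  gb <- mf_build_hier_graph("c1ccccc1")
  expect_equal(gb$n_atoms, 6L)
  expect_equal(gb$n_motifs, 1L)
  expect_equal(sum(gb$adj[1:6, 1:6]) / 2, 6)           # six aromatic ring bonds

  # fixture set: partition conservation, symmetry, level rules
  for (smi in mf_generate_molecules(50, seed = 7)) {
    g <- mf_build_hier_graph(smi)
    expect_equal(sort(unlist(g$motif_members)), seq_len(g$n_atoms))
    expect_equal(g$edge_raw, aperm(g$edge_raw, c(2L, 1L, 3L)))
    expect_true(all(g$adj == t(g$adj)))
    expect_equal(sum(g$level == "super"), 1L)
    expect_true(all(g$node_raw[g$N, ] == 0))
    if (g$n_motifs > 0) {
      expect_true(all(g$node_raw[g$n_atoms + seq_len(g$n_motifs), ] == 1))
    }
    # virtual edges exist exactly for motif-member and super-motif pairs
    expect_true(all(which(g$virtual, arr.ind = TRUE) |>
                      apply(1L, function(ij) {
                        lv <- g$level[ij]
                        ("super" %in% lv && "motif" %in% lv) ||
                          ("motif" %in% lv && "atom" %in% lv)
                      })))
  }
})

test_that("latent projection matches dense algebra and zero-maps zeros", {
  g <- mf_build_hier_graph("CC(=O)O")
  proj <- mf_projection_params(d_node = 16L, d_edge = 8L, seed = 2L)
  gp <- mf_project_latents(g, proj)
  expect_equal(dim(gp$node_latent), c(g$N, 16L))
  expect_equal(dim(gp$edge_latent), c(g$N, g$N, 8L))
  # dense-algebra oracle per node / edge slot
  for (i in seq_len(g$N)) {
    expect_equal(gp$node_latent[i, ],
                 as.numeric(g$node_raw[i, ] %*% proj$W_node) + proj$b_node)
  }
  for (i in seq_len(g$N)) {
    for (j in seq_len(g$N)) {
      exp_e <- as.numeric(g$edge_raw[i, j, ] %*% proj$W_edge) + proj$b_edge
      if (g$virtual[i, j]) exp_e <- exp_e + proj$v_edge
      expect_equal(gp$edge_latent[i, j, ], exp_e)
    }
  }
  # all-zeros super row with zero bias maps to the zero latent
  proj0 <- proj
  proj0$b_node <- proj0$b_node * 0
  gp0 <- mf_project_latents(g, proj0)
  expect_equal(gp0$node_latent[g$N, ], numeric(16L))
})

test_that("graphs are equivariant under atom permutation", {
  smi <- "CC(=O)Oc1ccccc1"
  f <- molfuse:::.mf_mol_features(smi)[[1L]]
  set.seed(3)
  perm <- sample(f$n_atoms)
  fp <- molfuse:::.mf_mol_features(smi, perms = list(perm))[[1L]]
  g0 <- mf_build_hier_graph(f)
  g1 <- mf_build_hier_graph(fp)
  # atom rows permute consistently: new atom i is old atom perm[i]
  expect_equal(g0$n_atoms, g1$n_atoms)
  expect_equal(g1$node_raw[seq_len(g1$n_atoms), ],
               g0$node_raw[perm, ])
  # and atom-atom edge slots permute the same way
  inv <- order(perm)
  for (k in seq_len(nrow(f$bonds))) {
    a <- f$bonds$a[k]; b <- f$bonds$b[k]
    expect_equal(g1$edge_raw[inv[a], inv[b], ], g0$edge_raw[a, b, ])
  }
})

test_that("graphs survive the JSON round trip", {
  g <- mf_build_hier_graph("CC(=O)Oc1ccccc1C(=O)O")
  j <- mf_graph_to_json(g)
  g2 <- mf_graph_from_json(j)
  expect_equal(g2$n_atoms, g$n_atoms)
  expect_equal(g2$n_motifs, g$n_motifs)
  expect_equal(g2$node_raw, g$node_raw)
  expect_equal(g2$edge_raw, g$edge_raw)
  expect_equal(g2$adj, g$adj)
  expect_equal(g2$virtual, g$virtual)
  expect_equal(g2$motif_members, g$motif_members)
})
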