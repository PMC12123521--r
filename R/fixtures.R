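# Fully offline synthetic molecule benchmark. Molecules are assembled from a
# fixed fragment grammar (ring cores and alkyl chains decorated with common
# substituents), so every SMILES parses, renders and builds a hierarchical
# graph. Binary labels are deterministic substructure functions (optionally
# noised), which makes task learnability a designed property.

.mf_subs <- c("C", "CC", "CCC", "C(C)C", "O", "OC", "OCC", "N", "NC",
              "N(C)C", "F", "Cl", "Br", "I", "C(=O)O", "C(=O)OC",
              "C(=O)NC", "C(=O)C", "C#N", "S")

.mf_cores1 <- c(benzene = "c1ccc(%s)cc1", pyridine = "c1ccc(%s)nc1",
                cyclohexane = "C1CCC(%s)CC1", thiophene = "c1cc(%s)cs1",
                furan = "c1cc(%s)co1", naphthalene = "c1ccc2cc(%s)ccc2c1")
.mf_cores2 <- c(benzene2 = "c1cc(%s)ccc1%s", pyridine2 = "c1cc(%s)cnc1%s",
                cyclohexane2 = "C1CC(%s)CCC1%s")
.mf_chains <- c("%sCC%s", "%sCCC%s", "%sCCCC%s", "%sCCCCC%s")

# the full deterministic enumeration of the grammar, canonicalized and
# de-duplicated (first occurrence kept); cached for the session
.mf_grammar_pool <- function() {
  key <- "grammar_pool"
  if (!exists(key, envir = .mf_cache)) {
    raw <- c(
      sub("\\(%s\\)", "", .mf_cores1),   # bare cores
      unlist(lapply(.mf_cores1, function(tpl) sprintf(tpl, .mf_subs))),
      unlist(lapply(.mf_cores2, function(tpl) {
        as.vector(outer(.mf_subs, .mf_subs,
                        function(a, b) sprintf(tpl, a, b)))
      })),
      unlist(lapply(.mf_chains, function(tpl) {
        as.vector(outer(.mf_subs, .mf_subs,
                        function(a, b) sprintf(tpl, a, b)))
      }))
    )
    canon <- mf_canonicalize(raw)
    canon <- canon[!is.na(canon)]
    assign(key, unique(canon), envir = .mf_cache)
  }
  get(key, envir = .mf_cache)
}

#' Generate synthetic molecules
#'
#' Draws `n` distinct molecules (canonical SMILES) from the fixed fragment
#' grammar; identical seeds give identical lists.
#'
#' @param n number of molecules.
#' @param seed RNG seed.
#' @return character vector of `n` unique canonical SMILES.
#' @export
mf_generate_molecules <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  pool <- .mf_grammar_pool()
  if (n > length(pool)) {
    stop("grammar supports at most ", length(pool), " distinct molecules")
  }
  set.seed(mf_derive_seed(seed, "fixtures"))
  sample(pool, n)
}

#' Define a synthetic labelling task
#'
#' @param rule SMARTS pattern defining the positive class.
#' @param n_molecules intended dataset size.
#' @param positive_fraction target positive fraction.
#' @param noise_rate independent label-flip probability in `[0, 0.5)`.
#' @param seed RNG seed.
#' @return list of class `molfuse_task_spec`.
#' @export
mf_task_spec <- function(rule, n_molecules = 400L, positive_fraction = 0.4,
                         noise_rate = 0, seed = 1L) {
  if (noise_rate < 0 || noise_rate >= 0.5) {
    stop("noise_rate must be in [0, 0.5)")
  }
  structure(list(rule = rule, n_molecules = n_molecules,
                 positive_fraction = positive_fraction,
                 noise_rate = noise_rate, seed = seed),
            class = "molfuse_task_spec")
}

#' Label molecules by a substructure rule
#'
#' Label 1 iff the SMARTS rule matches, then each label is flipped
#' independently with probability `noise_rate`.
#'
#' @param smiles character vector of SMILES.
#' @param spec a [mf_task_spec()] (only `rule`, `noise_rate`, `seed` used).
#' @param task_name label column name.
#' @return a single-task [mf_dataset()].
#' @export
mf_label_by_rule <- function(smiles, spec, task_name = "task") {
  hits <- mf_smarts_match(smiles, spec$rule)[, 1L]
  if (anyNA(hits)) stop("unparseable SMILES passed to mf_label_by_rule")
  y <- as.numeric(hits)
  if (spec$noise_rate > 0) {
    set.seed(mf_derive_seed(spec$seed, "noise"))
    flip <- runif(length(y)) < spec$noise_rate
    y[flip] <- 1 - y[flip]
  }
  mf_dataset(smiles, matrix(y, ncol = 1L), task_name, source = "synthetic")
}

# default benchmark rules: substituent-driven so labels cut across scaffolds
.mf_benchmark_rules <- function() {
  c(halogen = "[F,Cl,Br,I]",
    carbonyl = "[CX3]=O",
    amine = "[NX3;!$(NC=O)]",
    hydroxy_ether = "[OX2;!$(OC=O)]",
    acyl_oxy = "C(=O)[OX2]")
}

#' Build the five-task synthetic benchmark suite
#'
#' Five binary tasks with distinct substructure rules, sampled from one
#' shared molecule pool (so multitask merging deduplicates overlapping
#' molecules), each with a stratified size between 300 and 450 at a 0.35
#' target positive fraction, plus per-task scaffold splits and the merged
#' multitask pool with its own split.
#'
#' @param seed RNG seed.
#' @param pool_size number of distinct molecules in the shared pool.
#' @param noise_rate label-flip probability applied to every task.
#' @return list of class `molfuse_suite` with `tasks` (named single-task
#'   datasets), `splits` (per task), `merged`, `merged_split`, and `rules`.
#' @export
mf_make_benchmark_suite <- function(seed = 1L, pool_size = 600L,
                                    noise_rate = 0) {
  rules <- .mf_benchmark_rules()
  pool <- mf_generate_molecules(pool_size, seed)
  hits <- mf_smarts_match(pool, unname(rules))
  set.seed(mf_derive_seed(seed, "fixtures") + 1L)
  tasks <- list()
  splits <- list()
  target <- 0.35
  for (k in seq_along(rules)) {
    task <- names(rules)[k]
    pos <- pool[hits[, k] == 1L]
    neg <- pool[hits[, k] == 0L]
    n_task <- min(450L, floor(length(pos) / target),
                  floor(length(neg) / (1 - target)))
    n_pos <- round(target * n_task)
    smiles <- c(sample(pos, n_pos), sample(neg, n_task - n_pos))
    spec <- mf_task_spec(rules[[k]], n_task, target, noise_rate,
                         seed = seed + k)
    ds <- mf_label_by_rule(smiles, spec, task_name = task)
    tasks[[task]] <- ds
    splits[[task]] <- mf_scaffold_split(ds)
  }
  merged <- mf_merge_multitask(tasks)
  structure(list(tasks = tasks, splits = splits, merged = merged,
                 merged_split = mf_scaffold_split(merged),
                 rules = rules, pool = pool),
            class = "molfuse_suite")
}

#' @export
print.molfuse_suite <- function(x, ...) {
  cat("<molfuse_suite>", length(x$tasks), "tasks over",
      length(x$merged$smiles), "distinct molecules\n")
  for (nm in names(x$tasks)) {
    cat(sprintf("  %-14s n=%d, positives=%d  (rule %s)\n", nm,
                length(x$tasks[[nm]]$smiles),
                sum(x$tasks[[nm]]$labels == 1), x$rules[[nm]]))
  }
  invisible(x)
}
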