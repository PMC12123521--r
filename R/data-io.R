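# Dataset reading/writing, multitask merging, depiction rendering and the
# scaffold-based train/validation/test split (MoleculeNet CSV dialect).

#' Construct a molecule dataset
#'
#' A `molfuse_dataset` holds canonical SMILES, a binary label matrix with
#' `NA` marking missing labels, the task names, and a per-record source tag.
#'
#' @param smiles character vector of canonical SMILES.
#' @param labels numeric matrix (`n x n_tasks`) with entries 0, 1 or `NA`.
#' @param task_names character vector naming the label columns.
#' @param source character scalar or vector tagging record provenance.
#' @return an object of class `molfuse_dataset`.
#' @export
mf_dataset <- function(smiles, labels, task_names, source = "unknown") {
  labels <- as.matrix(labels)
  stopifnot(is.character(smiles), nrow(labels) == length(smiles),
            ncol(labels) == length(task_names))
  bad <- labels[!is.na(labels)]
  if (length(bad) && !all(bad %in% c(0, 1))) {
    stop("non-missing labels must be exactly 0 or 1")
  }
  colnames(labels) <- task_names
  structure(list(smiles = smiles, labels = labels,
                 task_names = task_names,
                 source = rep_len(source, length(smiles))),
            class = "molfuse_dataset")
}

#' @export
print.molfuse_dataset <- function(x, ...) {
  cat("<molfuse_dataset>", length(x$smiles), "molecules,",
      length(x$task_names), "task(s):",
      paste(x$task_names, collapse = ", "), "\n")
  obs <- colSums(!is.na(x$labels))
  pos <- colSums(x$labels == 1, na.rm = TRUE)
  for (j in seq_along(x$task_names)) {
    cat(sprintf("  %-12s %d labelled, %d positive\n",
                x$task_names[j], obs[j], pos[j]))
  }
  invisible(x)
}

#' @export
length.molfuse_dataset <- function(x) length(x$smiles)

# subset a dataset by record index
mf_dataset_subset <- function(ds, idx) {
  mf_dataset(ds$smiles[idx], ds$labels[idx, , drop = FALSE],
             ds$task_names, ds$source[idx])
}

#' Read a MoleculeNet-dialect CSV of molecules
#'
#' One molecule per row; a header row names the SMILES column and one or more
#' binary label columns. Empty label cells become missing (`NA`). Rows whose
#' SMILES does not parse are skipped and counted in the `n_skipped` attribute.
#'
#' @param path path to a delimited text file.
#' @param smiles_column name of the SMILES column.
#' @param label_columns names of the label columns; default: all other columns.
#' @param source provenance tag; default the file name.
#' @return a [mf_dataset()] with attribute `n_skipped`.
#' @export
mf_read_dataset <- function(path, smiles_column = "smiles",
                            label_columns = NULL, source = basename(path)) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!smiles_column %in% names(df)) {
    stop("SMILES column '", smiles_column, "' not present in ", path)
  }
  if (is.null(label_columns)) {
    label_columns <- setdiff(names(df), smiles_column)
  }
  missing_cols <- setdiff(label_columns, names(df))
  if (length(missing_cols)) {
    stop("label column(s) not present: ", paste(missing_cols, collapse = ", "))
  }
  labels <- as.matrix(df[, label_columns, drop = FALSE])
  if (is.character(labels)) {
    labels[labels == ""] <- NA
    storage.mode(labels) <- "numeric"
  }
  canon <- mf_canonicalize(as.character(df[[smiles_column]]))
  keep <- !is.na(canon)
  if (!any(keep)) stop("no parseable SMILES rows in ", path)
  out <- mf_dataset(canon[keep], labels[keep, , drop = FALSE],
                    label_columns, source)
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Write a dataset as a MoleculeNet-dialect CSV
#'
#' @param dataset a [mf_dataset()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
mf_write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "molfuse_dataset"))
  df <- data.frame(smiles = dataset$smiles, check.names = FALSE)
  for (tn in dataset$task_names) df[[tn]] <- dataset$labels[, tn]
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Merge several datasets into one multitask dataset
#'
#' Records are keyed by canonical SMILES and duplicates collapsed into one
#' record carrying the union of task labels. When duplicates disagree on the
#' same task, the first-seen value is kept and the conflict counted in the
#' `n_conflicts` attribute.
#'
#' @param datasets list of [mf_dataset()] objects.
#' @return a merged [mf_dataset()] with attribute `n_conflicts`.
#' @export
mf_merge_multitask <- function(datasets) {
  stopifnot(is.list(datasets))
  datasets <- Filter(function(d) length(d$smiles) > 0L, datasets)
  if (!length(datasets)) {
    return(mf_dataset(character(0), matrix(numeric(0), 0, 0), character(0)))
  }
  tasks <- unique(unlist(lapply(datasets, `[[`, "task_names")))
  all_smiles <- unique(unlist(lapply(datasets, `[[`, "smiles")))
  labels <- matrix(NA_real_, length(all_smiles), length(tasks),
                   dimnames = list(all_smiles, tasks))
  source <- setNames(rep(NA_character_, length(all_smiles)), all_smiles)
  n_conflicts <- 0L
  for (d in datasets) {
    for (i in seq_along(d$smiles)) {
      smi <- d$smiles[i]
      if (is.na(source[smi])) source[smi] <- d$source[i]
      for (tn in d$task_names) {
        val <- d$labels[i, tn]
        if (is.na(val)) next
        cur <- labels[smi, tn]
        if (is.na(cur)) {
          labels[smi, tn] <- val
        } else if (cur != val) {
          n_conflicts <- n_conflicts + 1L
        }
      }
    }
  }
  out <- mf_dataset(all_smiles, labels, tasks, unname(source))
  attr(out, "n_conflicts") <- n_conflicts
  out
}

#' Render a 2D molecular depiction
#'
#' Renders the canonical form of the molecule as a white-background raster
#' with fixed depiction options, so identical molecules give bit-identical
#' pixels within one environment.
#'
#' @param smiles a single SMILES string.
#' @param size image side length in pixels.
#' @param cache memoise by canonical SMILES for the session.
#' @return numeric array `size x size x 3` with values in `[0, 1]`.
#' @export
mf_render_depiction <- function(smiles, size = 224L, cache = TRUE) {
  mf_render_depictions(smiles, size = size, cache = cache)[[1L]]
}

#' Render several depictions at once
#'
#' @inheritParams mf_render_depiction
#' @return list of `size x size x 3` arrays (one per SMILES).
#' @export
mf_render_depictions <- function(smiles, size = 224L, cache = TRUE) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  canon <- mf_canonicalize(smiles)
  if (anyNA(canon)) {
    stop("cannot render invalid SMILES: ",
         paste(smiles[is.na(canon)], collapse = ", "))
  }
  key <- paste0("img", size, ":", canon)
  need <- if (cache) !vapply(key, exists, logical(1), envir = .mf_cache)
          else rep(TRUE, length(smiles))
  if (any(need)) {
    todo <- which(need)
    files <- vapply(todo, function(i) tempfile(fileext = ".png"), character(1))
    ok <- .mf_render_files(canon[todo], files, size)
    if (!all(ok)) stop("depiction rendering failed")
    for (k in seq_along(todo)) {
      px <- png::readPNG(files[k])
      if (dim(px)[3L] == 4L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
      assign(key[todo[k]], px, envir = .mf_cache)
      unlink(files[k])
    }
  }
  lapply(key, get, envir = .mf_cache)
}

#' Export depictions of a dataset as PNG files
#'
#' @param dataset a [mf_dataset()].
#' @param dir output directory (created if needed).
#' @param size image side length in pixels.
#' @return character vector of written file paths.
#' @export
mf_export_depictions <- function(dataset, dir, size = 224L) {
  stopifnot(inherits(dataset, "molfuse_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, sprintf("mol_%05d.png", seq_along(dataset$smiles)))
  ok <- .mf_render_files(dataset$smiles, files, size)
  if (!all(ok)) stop("depiction rendering failed for ", sum(!ok), " molecules")
  files
}

#' Bemis-Murcko scaffold strings for a dataset
#'
#' Molecules without rings have an empty framework; each such molecule forms
#' its own group, keyed by canonical SMILES.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of scaffold group keys.
#' @export
mf_scaffold_keys <- function(smiles) {
  feats <- .mf_mol_features(smiles)
  vapply(seq_along(smiles), function(i) {
    f <- feats[[i]]
    if (is.null(f)) stop("invalid SMILES: ", smiles[i])
    if (nzchar(f$scaffold)) f$scaffold else paste0("mol:", f$canonical)
  }, character(1))
}

#' Scaffold-based train/validation/test split
#'
#' Groups molecules by Bemis-Murcko scaffold, orders groups by descending
#' size (ties broken lexicographically by scaffold string) and greedily fills
#' the training set, then the validation set, with the remainder going to the
#' test set. The ordering makes the split deterministic, and places common
#' scaffolds in training.
#'
#' @param dataset a [mf_dataset()] (or character vector of SMILES).
#' @param fractions train/valid/test fractions summing to 1.
#' @param seed accepted for interface symmetry; the split is deterministic.
#' @return an object of class `molfuse_split` with `train_idx`, `valid_idx`,
#'   `test_idx` and `scaffold_of`.
#' @export
mf_scaffold_split <- function(dataset, fractions = c(0.8, 0.1, 0.1),
                              seed = 1L) {
  smiles <- if (inherits(dataset, "molfuse_dataset")) dataset$smiles
            else as.character(dataset)
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L) {
    stop("fractions must be three numbers summing to 1")
  }
  n <- length(smiles)
  if (n < 10L) stop("scaffold split needs at least 10 molecules")
  scaffold_of <- mf_scaffold_keys(smiles)
  groups <- split(seq_len(n), scaffold_of)
  sizes <- lengths(groups)
  ord <- order(-sizes, names(groups))
  groups <- groups[ord]
  cut_train <- round(fractions[1L] * n)
  cut_valid <- cut_train + round(fractions[2L] * n)
  train_idx <- valid_idx <- test_idx <- integer(0)
  for (g in groups) {
    if (length(train_idx) + length(g) <= cut_train) {
      train_idx <- c(train_idx, g)
    } else if (length(train_idx) + length(valid_idx) + length(g) <= cut_valid) {
      valid_idx <- c(valid_idx, g)
    } else {
      test_idx <- c(test_idx, g)
    }
  }
  structure(list(train_idx = sort(train_idx), valid_idx = sort(valid_idx),
                 test_idx = sort(test_idx), scaffold_of = scaffold_of),
            class = "molfuse_split")
}

#' @export
print.molfuse_split <- function(x, ...) {
  cat("<molfuse_split> train/valid/test:",
      length(x$train_idx), "/", length(x$valid_idx), "/",
      length(x$test_idx), "molecules;",
      length(unique(x$scaffold_of)), "scaffold groups\n")
  invisible(x)
}

#' Write a split as three CSV files
#'
#' @param dataset the [mf_dataset()] the split was computed on.
#' @param split a [mf_scaffold_split()] result.
#' @param dir output directory.
#' @return character vector of the three file paths.
#' @export
mf_write_split <- function(dataset, split, dir) {
  stopifnot(inherits(split, "molfuse_split"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("train.csv", "valid.csv", "test.csv"))
  idx <- list(split$train_idx, split$valid_idx, split$test_idx)
  for (k in 1:3) mf_write_dataset(mf_dataset_subset(dataset, idx[[k]]), paths[k])
  paths
}
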