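# Bridge to the bundled RDKit helper (inst/python/chem_backend.py).
#
# All calls are batched: one python process per request, JSON over
# stdin/stdout. Per-SMILES results are memoised for the session so repeated
# graph builds and renders do not re-spawn the helper.

.mf_cache <- new.env(parent = emptyenv())

.mf_python <- function() {
  getOption("molfuse.python", Sys.which("python"))
}

.mf_backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "molfuse")
  if (!nzchar(path)) stop("chem_backend.py not found; is molfuse installed?")
  path
}

# names on list elements would serialize as JSON objects, not arrays
.json_array <- function(x) as.list(unname(x))

.mf_chem_call <- function(op, payload) {
  input <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
                            digits = NA)
  out <- suppressWarnings(system2(.mf_python(),
                                  args = c(shQuote(.mf_backend_script()), op),
                                  input = input, stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("chemistry backend failed (op=", op, ", status=", status, ")")
  }
  res <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
  if (!is.null(res$error)) stop("chemistry backend error: ", res$error)
  res
}

#' Canonicalize SMILES strings
#'
#' Parses each SMILES with RDKit and returns its canonical form, or `NA`
#' for strings that do not parse to a molecule with at least one heavy atom.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES; `NA` where unparseable.
#' @export
mf_canonicalize <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  key <- paste0("canon:", smiles)
  hit <- vapply(key, exists, logical(1), envir = .mf_cache)
  if (any(!hit)) {
    res <- .mf_chem_call("canon", list(smiles = .json_array(smiles[!hit])))
    vals <- vapply(res$canonical,
                   function(x) if (is.null(x)) NA_character_ else x,
                   character(1))
    for (i in seq_along(vals)) assign(key[!hit][i], vals[i], envir = .mf_cache)
  }
  vapply(key, get, character(1), envir = .mf_cache, USE.NAMES = FALSE)
}

# Raw chemical facts for one or more molecules: atom/bond property tables,
# BRICS cleavable bonds (1-based index pairs), Bemis-Murcko scaffold string
# and the canonical SMILES. Returns NULL for unparseable input.
.mf_mol_features <- function(smiles, perms = NULL) {
  stopifnot(is.character(smiles))
  use_cache <- is.null(perms)
  key <- paste0("feat:", smiles)
  need <- if (use_cache) {
    !vapply(key, exists, logical(1), envir = .mf_cache)
  } else rep(TRUE, length(smiles))
  if (any(need)) {
    payload <- list(smiles = .json_array(smiles[need]))
    if (!is.null(perms)) {
      payload$perms <- lapply(perms[need], function(p) {
        if (is.null(p)) NULL else .json_array(as.integer(p - 1L))
      })
    }
    res <- .mf_chem_call("features", payload)
    mols <- lapply(res$mols, .mf_parse_mol_payload)
    if (use_cache) {
      for (i in seq_along(mols)) {
        assign(key[need][i], mols[i], envir = .mf_cache)
      }
    } else {
      out <- vector("list", length(smiles))
      out[need] <- mols
      return(out)
    }
  }
  out <- lapply(key, function(k) get(k, envir = .mf_cache)[[1L]])
  out
}

.mf_parse_mol_payload <- function(m) {
  if (is.null(m)) return(NULL)
  atoms <- data.frame(
    symbol = vapply(m$atoms, `[[`, character(1), "symbol"),
    degree = vapply(m$atoms, `[[`, numeric(1), "degree"),
    charge = vapply(m$atoms, `[[`, numeric(1), "charge"),
    chiral = vapply(m$atoms, `[[`, character(1), "chiral"),
    hybrid = vapply(m$atoms, `[[`, character(1), "hybrid"),
    aromatic = vapply(m$atoms, `[[`, logical(1), "aromatic"),
    stringsAsFactors = FALSE
  )
  bonds <- if (length(m$bonds)) data.frame(
    a = vapply(m$bonds, `[[`, numeric(1), "a") + 1L,
    b = vapply(m$bonds, `[[`, numeric(1), "b") + 1L,
    type = vapply(m$bonds, `[[`, character(1), "type"),
    ring = vapply(m$bonds, `[[`, logical(1), "ring"),
    conj = vapply(m$bonds, `[[`, logical(1), "conj"),
    stringsAsFactors = FALSE
  ) else data.frame(a = integer(0), b = integer(0), type = character(0),
                    ring = logical(0), conj = logical(0))
  brics <- lapply(m$brics, function(p) c(p[[1L]] + 1L, p[[2L]] + 1L))
  list(canonical = m$canonical, n_atoms = m$n_atoms, atoms = atoms,
       bonds = bonds, brics = brics, scaffold = m$scaffold)
}

#' Test molecules for substructure patterns
#'
#' @param smiles character vector of SMILES.
#' @param smarts character vector of SMARTS patterns.
#' @return integer matrix `length(smiles) x length(smarts)` of 0/1 hits;
#'   `NA` rows for unparseable SMILES.
#' @export
mf_smarts_match <- function(smiles, smarts) {
  stopifnot(is.character(smiles), is.character(smarts), length(smarts) >= 1L)
  res <- .mf_chem_call("match", list(smiles = .json_array(smiles),
                                     smarts = .json_array(smarts)))
  hits <- vapply(res$hits, function(r) {
    vapply(r, function(x) if (is.null(x)) NA_integer_ else as.integer(x),
           integer(1))
  }, integer(length(smarts)))
  hits <- matrix(hits, nrow = length(smiles), ncol = length(smarts),
                 byrow = TRUE, dimnames = list(smiles, smarts))
  hits
}

# Render depictions to PNG files (one per molecule); returns logical vector.
.mf_render_files <- function(smiles, files, size = 224L) {
  res <- .mf_chem_call("render", list(smiles = .json_array(smiles),
                                      files = .json_array(files),
                                      size = as.integer(size)))
  vapply(res$ok, isTRUE, logical(1))
}

#' Clear the in-memory chemistry cache
#' @return invisibly, the number of entries removed.
#' @export
mf_clear_cache <- function() {
  n <- length(ls(.mf_cache))
  rm(list = ls(.mf_cache), envir = .mf_cache)
  invisible(n)
}
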