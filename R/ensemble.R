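#' Structure models and ensembles
#'
#' A *model* is a plain data.frame of atom records with columns `chain`,
#' `resno`, `resname`, `atom`, `x`, `y`, `z`. Residue numbering is plain
#' integer and may be zero or negative (histone tail conventions such as
#' Met0 or Gly(-3) are legal). An *ensemble* (`nmr_ensemble`) holds one
#' shared atom table plus a coordinate array, so every model is guaranteed
#' to contain the same atoms in the same order.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`, `atom`.
#' @param coords numeric array of dimension `c(n_atoms, 3, n_models)`.
#' @param model_ids character vector of model labels (default `"1"`, `"2"`, ...).
#' @return An object of class `nmr_ensemble`.
#' @export
nmr_ensemble <- function(atoms, coords, model_ids = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "resno", "resname", "atom") %in% names(atoms)))
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != nrow(atoms))
    stop("coords has ", dim(coords)[1], " atoms but atom table has ", nrow(atoms))
  if (dim(coords)[3] < 1L) stop("an ensemble needs at least one model")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  if (any(!nzchar(atoms$atom))) stop("empty atom names")
  if (is.null(model_ids)) model_ids <- as.character(seq_len(dim(coords)[3]))
  stopifnot(length(model_ids) == dim(coords)[3])
  atoms <- atoms[, c("chain", "resno", "resname", "atom")]
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, coords = coords,
                 model_ids = as.character(model_ids)),
            class = "nmr_ensemble")
}

#' Assemble an ensemble from a list of per-model atom tables
#'
#' Validates that every model carries the identical (chain, residue, atom)
#' set in the identical order; the first discrepancy found is reported.
#'
#' @param models list of model data.frames (see [nmr_ensemble()]).
#' @param model_ids optional labels.
#' @export
as_ensemble <- function(models, model_ids = NULL) {
  stopifnot(is.list(models), length(models) >= 1L)
  key <- function(m) paste(m$chain, m$resno, m$atom, sep = "|")
  ref <- key(models[[1L]])
  for (k in seq_along(models)[-1L]) {
    kk <- key(models[[k]])
    if (length(kk) != length(ref) || any(kk != ref)) {
      n <- min(length(kk), length(ref))
      bad <- if (length(kk) != length(ref)) n + 1L else which(kk != ref)[1L]
      stop("model ", k, " atom set differs from model 1 at position ", bad,
           " (expected '", ref[min(bad, length(ref))], "', got '",
           if (bad <= length(kk)) kk[bad] else "<missing>", "')")
    }
  }
  coords <- array(NA_real_, c(length(ref), 3L, length(models)))
  for (k in seq_along(models))
    coords[, , k] <- as.matrix(models[[k]][, c("x", "y", "z")])
  nmr_ensemble(models[[1L]][, c("chain", "resno", "resname", "atom")],
               coords, model_ids)
}

#' Extract one model of an ensemble as an atom-record data.frame
#' @param ens an `nmr_ensemble`.
#' @param i model index or model id.
#' @export
ens_model <- function(ens, i = 1L) {
  stopifnot(inherits(ens, "nmr_ensemble"))
  if (is.character(i)) i <- match(i, ens$model_ids)
  stopifnot(!is.na(i), i >= 1L, i <= n_models(ens))
  m <- ens$atoms
  m$x <- ens$coords[, 1L, i]
  m$y <- ens$coords[, 2L, i]
  m$z <- ens$coords[, 3L, i]
  m
}

#' @rdname ens_model
#' @export
n_models <- function(ens) dim(ens$coords)[3]

#' @export
print.nmr_ensemble <- function(x, ...) {
  cat("NMR structure ensemble:", n_models(x), "model(s),",
      nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues, chains:",
      paste(unique(x$atoms$chain), collapse = " "), "\n")
  invisible(x)
}

## matrix of Ca coordinates for one model restricted to a residue selection
ca_coords <- function(model, chains = NULL, resnos = NULL) {
  sel <- model$atom == "CA"
  if (!is.null(chains)) sel <- sel & model$chain %in% chains
  if (!is.null(resnos)) sel <- sel & model$resno %in% resnos
  m <- model[sel, , drop = FALSE]
  structure(as.matrix(m[, c("x", "y", "z")]),
            dimnames = list(paste(m$chain, m$resno, sep = ":"), NULL))
}

#' Residue-range selections
#'
#' A selection is a named list mapping chain ids to integer residue vectors,
#' e.g. `sel("A", 27:96)` or the parsed form of `"A:27-96,B:38-125"`.
#'
#' @param spec character, e.g. `"A:27-96,B:38-125"`.
#' @return named list of integer vectors.
#' @export
parse_selection <- function(spec) {
  parts <- strsplit(spec, ",", fixed = TRUE)[[1L]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(trimws(p), ":", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("bad selection term: '", p, "'")
    rng <- strsplit(kv[2L], "-(?=[0-9])", perl = TRUE)[[1L]]
    rng <- as.integer(rng)
    out[[kv[1L]]] <- c(out[[kv[1L]]], if (length(rng) == 2L) rng[1L]:rng[2L] else rng)
  }
  out
}

## flatten a selection against a model -> logical over Ca atoms present
select_ca <- function(model, selection) {
  ca <- model[model$atom == "CA", , drop = FALSE]
  if (is.null(selection)) return(ca)
  keep <- rep(FALSE, nrow(ca))
  for (ch in names(selection))
    keep <- keep | (ca$chain == ch & ca$resno %in% selection[[ch]])
  ca[keep, , drop = FALSE]
}
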