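#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of the selected Ca atoms of `mobile` onto `reference`.
#' The returned transform maps mobile coordinates as
#' `x' = x %*% t(rotation) + translation` and is always a proper rotation
#' (det = +1).
#'
#' @param mobile,reference atom-record data.frames (models).
#' @param selection optional residue selection (named list chain -> resnos,
#'   see [parse_selection()]); default uses all Ca atoms common to both.
#' @return object of class `superposition`: `rotation` (3x3),
#'   `translation` (length 3), `rmsd` (A, over the selection), `n` atoms.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  mm <- select_ca(mobile, selection)
  rr <- select_ca(reference, selection)
  keym <- paste(mm$chain, mm$resno); keyr <- paste(rr$chain, rr$resno)
  common <- intersect(keym, keyr)
  if (length(common) < 3L) stop("need at least 3 common Ca atoms, got ",
                                length(common))
  X <- as.matrix(mm[match(common, keym), c("x", "y", "z")])
  Y <- as.matrix(rr[match(common, keyr), c("x", "y", "z")])
  fit <- kabsch(X, Y)
  if (is.null(fit)) stop("degenerate (collinear) selection")
  structure(c(fit, list(n = length(common))), class = "superposition")
}

## Kabsch algorithm on paired coordinate matrices (rows = atoms)
kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2L, cx); Y0 <- sweep(Y, 2L, cy)
  if (max(svd(X0)$d) < 1e-8) return(NULL)
  s <- svd(crossprod(Y0, X0))
  d <- sign(det(s$u %*% t(s$v)))
  if (s$d[2] < 1e-8) return(NULL)      # collinear selection: rotation undetermined
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  Xr <- X0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((Xr - Y0)^2)))
  list(rotation = R, translation = as.numeric(cy - R %*% cx), rmsd = rmsd)
}

#' @export
print.superposition <- function(x, ...) {
  cat("Rigid-body superposition over", x$n, "Ca atoms; rmsd =",
      format(x$rmsd, digits = 4), "A\n")
  invisible(x)
}

#' Apply a superposition to a model or coordinate matrix
#' @param model atom-record data.frame.
#' @param sp a `superposition`.
#' @export
apply_superposition <- function(model, sp) {
  co <- as.matrix(model[, c("x", "y", "z")])
  co <- co %*% t(sp$rotation) + rep(1, nrow(co)) %o% sp$translation
  model$x <- co[, 1L]; model$y <- co[, 2L]; model$z <- co[, 3L]
  model
}

#' Per-residue Ca root-mean-square fluctuation of an ensemble
#'
#' Models are superposed over `align_selection` before fluctuations are
#' measured; the default reference is the ensemble mean structure after two
#' rounds of iterative superposition (order-invariant). `ref = "model1"`
#' reproduces the convention of aligning everything onto the first model.
#' `rmsf(i) = sqrt(mean_k |Ca_i^k - <Ca_i>|^2)`.
#'
#' @param ens an [nmr_ensemble()].
#' @param align_selection residue selection used for the fit (default: all).
#' @param ref `"mean"` (iterative, default) or `"model1"`.
#' @return data.frame `chain`, `resno`, `resname`, `rmsf` (A).
#' @export
ca_rmsf <- function(ens, align_selection = NULL, ref = c("mean", "model1")) {
  ref <- match.arg(ref)
  stopifnot(inherits(ens, "nmr_ensemble"))
  nm <- n_models(ens)
  models <- lapply(seq_len(nm), function(k) ens_model(ens, k))
  if (nm == 1L) warning("single-model ensemble: rmsf is identically zero")
  if (nm > 1L) {
    if (ref == "model1") {
      for (k in 2:nm) {
        sp <- superpose(models[[k]], models[[1L]], align_selection)
        models[[k]] <- apply_superposition(models[[k]], sp)
      }
    } else {
      for (round in 1:2) {
        mean_model <- models[[1L]]
        co <- Reduce(`+`, lapply(models, function(m) as.matrix(m[, c("x", "y", "z")]))) / nm
        mean_model$x <- co[, 1L]; mean_model$y <- co[, 2L]; mean_model$z <- co[, 3L]
        for (k in seq_len(nm)) {
          sp <- superpose(models[[k]], mean_model, align_selection)
          models[[k]] <- apply_superposition(models[[k]], sp)
        }
      }
    }
  }
  ca <- lapply(models, ca_coords)
  mean_ca <- Reduce(`+`, ca) / nm
  dev2 <- Reduce(`+`, lapply(ca, function(m) rowSums((m - mean_ca)^2))) / nm
  info <- models[[1L]][models[[1L]]$atom == "CA", c("chain", "resno", "resname")]
  out <- data.frame(info, rmsf = sqrt(dev2), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Ca window distance d(Ca[i-h], Ca[i+h])
#'
#' The distance between the Ca atoms `h` residues before and after residue
#' i: ~11-12 A inside an alpha-helix, ~28 A in an extended strand, and low
#' values in disordered tails indicate bends. For an ensemble the
#' per-residue mean over models is reported alongside the per-model range.
#'
#' @param x a model data.frame or an [nmr_ensemble()].
#' @param half_window residues on each side (default 4, i.e. i-4 to i+4).
#' @return data.frame `chain`, `resno`, `resname`, `d` (A; ensemble mean),
#'   plus `d_min`/`d_max` over models for ensembles. Residues whose i-h or
#'   i+h neighbour is absent are omitted.
#' @export
ca_window_distance <- function(x, half_window = 4L) {
  stopifnot(half_window >= 1L)
  if (inherits(x, "nmr_ensemble")) {
    per <- lapply(seq_len(n_models(x)), function(k)
      ca_window_distance(ens_model(x, k), half_window))
    d <- sapply(per, `[[`, "d")
    if (is.null(dim(d))) d <- matrix(d, nrow = 1L)
    out <- per[[1L]]
    out$d <- rowMeans(d)
    out$d_min <- apply(d, 1L, min)
    out$d_max <- apply(d, 1L, max)
    return(out)
  }
  ca <- x[x$atom == "CA", , drop = FALSE]
  ca <- ca[order(ca$chain, ca$resno), , drop = FALSE]
  out <- NULL
  for (ch in unique(ca$chain)) {
    cc <- ca[ca$chain == ch, , drop = FALSE]
    co <- as.matrix(cc[, c("x", "y", "z")])
    im <- match(cc$resno - half_window, cc$resno)
    ip <- match(cc$resno + half_window, cc$resno)
    keep <- !is.na(im) & !is.na(ip)
    if (!any(keep)) next
    d <- sqrt(rowSums((co[ip[keep], , drop = FALSE] -
                         co[im[keep], , drop = FALSE])^2))
    out <- rbind(out, data.frame(cc[keep, c("chain", "resno", "resname")],
                                 d = d, stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(chain = character(), resno = integer(),
                      resname = character(), d = numeric())
  rownames(out) <- NULL
  out
}

## deterministic quasi-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

vdw_radii <- c(N = 1.55, C = 1.70, O = 1.52, S = 1.80, H = 1.20)

#' Backbone accessible surface area (Shrake-Rupley)
#'
#' Sphere-sampling solvent-accessible surface area of the backbone atoms
#' (N, CA, C, O; amide hydrogens excluded) of every residue, with a probe
#' of 1.4 A by default. All atoms of the model occlude, but only backbone
#' atoms are summed per residue. Relative exposure divides by a
#' per-residue-type reference maximum computed from an extended
#' Gly-X-Gly-style tripeptide built with ideal geometry.
#'
#' @param model atom-record data.frame.
#' @param probe_radius probe radius in A (default 1.4).
#' @param n_points sphere sample points per atom (default 960).
#' @param relative also compute exposure relative to the reference maximum.
#' @return data.frame `chain`, `resno`, `resname`, `asa` (A^2) and,
#'   if `relative`, `rel_exposure`.
#' @export
backbone_asa <- function(model, probe_radius = 1.4, n_points = 960L,
                         relative = TRUE) {
  backbone <- c("N", "CA", "C", "O")
  at <- model[model$atom != "H", , drop = FALSE]
  asa <- atom_asa(at, probe_radius, n_points)
  bb <- at$atom %in% backbone
  keys <- unique(at[, c("chain", "resno", "resname")])
  tot <- tapply(asa[bb], paste(at$chain[bb], at$resno[bb]), sum)
  out <- data.frame(keys,
                    asa = as.numeric(tot[paste(keys$chain, keys$resno)]),
                    stringsAsFactors = FALSE)
  out$asa[is.na(out$asa)] <- 0
  if (relative) {
    refs <- vapply(out$resname, gxg_reference_asa, 0,
                   probe_radius = probe_radius, n_points = n_points)
    out$rel_exposure <- out$asa / refs
  }
  rownames(out) <- NULL
  out
}

## Shrake-Rupley per atom, all atoms occlude
atom_asa <- function(at, probe_radius, n_points) {
  co <- as.matrix(at[, c("x", "y", "z")])
  elem <- toupper(substring(sub("^[0-9]*", "", at$atom), 1L, 1L))
  rad <- vdw_radii[elem]
  rad[is.na(rad)] <- 1.70
  rad <- rad + probe_radius
  pts <- sphere_points(n_points)
  n <- nrow(co)
  asa <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * rad[i], 2L, co[i, ], `+`)
    free <- rep(TRUE, n_points)
    d2 <- rowSums(sweep(co, 2L, co[i, ])^2)
    nb <- which(d2 < (rad + rad[i])^2 & seq_len(n) != i)
    for (j in nb) {
      if (!any(free)) break
      dj <- rowSums(sweep(p[free, , drop = FALSE], 2L, co[j, ])^2)
      free[free] <- dj >= rad[j]^2
    }
    asa[i] <- 4 * pi * rad[i]^2 * sum(free) / n_points
  }
  asa
}

## reference maximum backbone ASA for residue type X in an extended G-X-G
.gxg_cache <- new.env(parent = emptyenv())
gxg_reference_asa <- function(resname, probe_radius = 1.4, n_points = 960L) {
  key <- paste(resname, probe_radius, n_points)
  if (!is.null(.gxg_cache[[key]])) return(.gxg_cache[[key]])
  map <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  code1 <- names(map)[match(resname, map)]
  if (is.na(code1)) code1 <- "A"
  spec <- peptide_spec(paste0("G", code1, "G"), "EEE", seed = 1L)
  tri <- build_ideal_peptide(spec)
  a <- backbone_asa(tri, probe_radius, n_points, relative = FALSE)
  val <- a$asa[a$resno == 2L]
  .gxg_cache[[key]] <- val
  val
}
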