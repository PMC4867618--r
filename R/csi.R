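#' Secondary chemical shifts from Ca/Cb resonances
#'
#' The secondary shift of an atom is the observed shift minus the
#' random-coil reference for the same residue type,
#' `dd = d_obs - d_rc`. Positive `dd(CA)` and negative `dd(CB)` mark
#' helical propensity; the reverse marks extended/strand propensity.
#'
#' @param shifts a [shift_table()] (only CA/CB rows are used).
#' @param rc random-coil reference, default [random_coil_table()].
#' @return data.frame with one row per residue: `chain`, `resno`,
#'   `resname`, `dCA`, `dCB` (ppm; `NA` where the shift is missing).
#' @export
secondary_shifts <- function(shifts, rc = random_coil_table()) {
  sh <- shifts[shifts$atom %in% c("CA", "CB"), , drop = FALSE]
  if (nrow(sh) == 0L) stop("no CA or CB rows in shift table")
  known <- sh$resname %in% rc$resname
  if (any(!known)) {
    warning("skipping residues with no random-coil reference: ",
            paste(unique(sh$resname[!known]), collapse = ", "))
    sh <- sh[known, , drop = FALSE]
  }
  gly_cb <- sh$resname == "GLY" & sh$atom == "CB"
  if (any(gly_cb)) {
    warning("skipping ", sum(gly_cb), " Cb row(s) for glycine")
    sh <- sh[!gly_cb, , drop = FALSE]
  }
  ridx <- match(sh$resname, rc$resname)
  ref <- ifelse(sh$atom == "CA", rc$CA[ridx], rc$CB[ridx])
  sh$dd <- sh$shift - ref
  keys <- unique(sh[, c("chain", "resno", "resname")])
  keys <- keys[order(keys$chain, keys$resno), , drop = FALSE]
  pick <- function(at) {
    i <- match(paste(keys$chain, keys$resno, at),
               paste(sh$chain, sh$resno, sh$atom))
    sh$dd[i]
  }
  out <- data.frame(keys, dCA = pick("CA"), dCB = pick("CB"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Chemical shift index profile
#'
#' Combines the Ca and Cb secondary shifts into the composite statistic
#' `dCA - dCB` and thresholds it into a per-residue index: `+1`
#' (helix-like) where the composite exceeds `+threshold`, `-1`
#' (strand-like) below `-threshold`, else `0`. Residues where both
#' secondary shifts are missing get `NA`. A missing Ca or Cb term (e.g.
#' glycine Cb) contributes 0 to the composite.
#'
#' @inheritParams secondary_shifts
#' @param threshold composite threshold in ppm (default 0.7).
#' @return data.frame of class `csi_profile`: `chain`, `resno`, `resname`,
#'   `dCA`, `dCB`, `composite`, `index`.
#' @export
csi_profile <- function(shifts, rc = random_coil_table(), threshold = 0.7) {
  stopifnot(threshold > 0)
  ss <- secondary_shifts(shifts, rc)
  comp <- ifelse(is.na(ss$dCA), 0, ss$dCA) - ifelse(is.na(ss$dCB), 0, ss$dCB)
  comp[is.na(ss$dCA) & is.na(ss$dCB)] <- NA_real_
  idx <- ifelse(comp > threshold, 1L, ifelse(comp < -threshold, -1L, 0L))
  out <- data.frame(ss, composite = comp, index = idx)
  class(out) <- c("csi_profile", "data.frame")
  out
}
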