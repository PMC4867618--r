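#' Kabsch-Sander secondary-structure assignment
#'
#' Assigns one of seven classes per residue from backbone geometry,
#' following the classic DSSP recipe. Backbone hydrogen-bond energies are
#' computed with the electrostatic model
#' `E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)` kcal/mol and a bond
#' is called when `E < -0.5`. Classes: `H` (alpha-helix, two consecutive
#' i->i+4 turns), `G` (3-10 helix, i->i+3), `E` (extended strand in a
#' ladder), `B` (isolated beta-bridge), `T` (3/4/5-turn), `S` (bend, Ca
#' angle > 70 degrees), `C` (coil). Overlaps are resolved with priority
#' H > G > E > B > T > S > C. Amide hydrogens are built geometrically when
#' absent (1.0 A from N, opposite the preceding carbonyl); prolines do not
#' donate. Residues missing backbone atoms are assigned `C` with a warning.
#'
#' @param model an atom-record data.frame (see [nmr_ensemble()]) with
#'   N, CA, C, O atoms for consecutive residues.
#' @return data.frame `chain`, `resno`, `resname`, `ss`.
#' @export
assign_ss <- function(model) {
  res <- residue_frame(model)
  n <- length(res$chain)
  ss <- rep("C", n)
  ok <- res$complete
  if (any(!ok)) warning(sum(!ok), " residue(s) missing backbone atoms; assigned C")

  hb <- hbond_matrix(res)             # hb[a, d]: CO of a accepts from NH of d

  same_seg <- function(i, j) {
    # i..j consecutive within one chain with no break
    if (i < 1L || j > n) return(FALSE)
    all(res$chain[i:j] == res$chain[i]) && all(!res$brk[i:(j - 1L)])
  }
  turn <- function(nn) {
    t <- rep(FALSE, n)
    for (i in seq_len(max(0L, n - nn)))
      if (same_seg(i, i + nn) && hb[i, i + nn]) t[i] <- TRUE
    t
  }
  t3 <- turn(3L); t4 <- turn(4L); t5 <- turn(5L)

  # bends (S)
  bend <- rep(FALSE, n)
  if (n >= 5L) for (i in 3:(n - 2L)) {
    if (!same_seg(i - 2L, i + 2L)) next
    if (!all(res$complete[c(i - 2L, i, i + 2L)])) next
    u <- res$ca[i, ] - res$ca[i - 2L, ]
    v <- res$ca[i + 2L, ] - res$ca[i, ]
    cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    if (acos(max(-1, min(1, cosang))) > 70 * pi / 180) bend[i] <- TRUE
  }

  # turns (T): interior residues of any n-turn
  tt <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (t3[i]) tt[(i + 1L):(i + 2L)] <- TRUE
    if (t4[i]) tt[(i + 1L):(i + 3L)] <- TRUE
    if (t5[i]) tt[(i + 1L):(i + 4L)] <- TRUE
  }
  tt <- tt[seq_len(n)]

  # bridges
  bridge <- matrix(FALSE, n, n)
  hbx <- function(a, d) a >= 1L && a <= n && d >= 1L && d <= n && hb[a, d]
  if (n >= 4L) for (i in 2:(n - 1L)) {
    for (j in 2:(n - 1L)) {
      near <- res$chain[i] == res$chain[j] && abs(i - j) < 3L
      if (near) next
      if (!same_seg(i - 1L, i + 1L) || !same_seg(j - 1L, j + 1L)) next
      par <- (hbx(i - 1L, j) && hbx(j, i + 1L)) || (hbx(j - 1L, i) && hbx(i, j + 1L))
      anti <- (hbx(i, j) && hbx(j, i)) || (hbx(i - 1L, j + 1L) && hbx(j - 1L, i + 1L))
      if (par || anti) bridge[i, j] <- TRUE
    }
  }
  has_bridge <- apply(bridge, 1L, any)
  in_ladder <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!has_bridge[i]) next
    js <- which(bridge[i, ])
    for (j in js) {
      neigh <- FALSE
      for (di in c(-1L, 1L)) for (dj in c(-1L, 1L)) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1L && ii <= n && jj >= 1L && jj <= n && bridge[ii, jj]) neigh <- TRUE
      }
      if (neigh) in_ladder[i] <- TRUE
    }
  }

  # helices from consecutive turns
  isH <- rep(FALSE, n); isG <- rep(FALSE, n)
  if (n >= 2L) for (i in 2:n) {
    if (i + 3L <= n && t4[i - 1L] && t4[i]) isH[i:(i + 3L)] <- TRUE
    if (i + 2L <= n && t3[i - 1L] && t3[i]) isG[i:(i + 2L)] <- TRUE
  }

  ss[bend] <- "S"
  ss[tt] <- "T"
  ss[has_bridge & !in_ladder] <- "B"
  ss[in_ladder] <- "E"
  ss[isG] <- "G"
  ss[isH] <- "H"
  ss[!ok] <- "C"
  data.frame(chain = res$chain, resno = res$resno, resname = res$resname,
             ss = ss, stringsAsFactors = FALSE)
}

## per-residue backbone coordinate frame, with geometric amide H where absent
residue_frame <- function(model) {
  ord <- order(model$chain, model$resno)
  model <- model[ord, , drop = FALSE]
  ukey <- unique(paste(model$chain, model$resno))
  n <- length(ukey)
  get <- function(atom) {
    m <- matrix(NA_real_, n, 3L)
    sel <- model$atom == atom
    i <- match(paste(model$chain[sel], model$resno[sel]), ukey)
    m[i, ] <- as.matrix(model[sel, c("x", "y", "z")])
    m
  }
  Nc <- get("N"); ca <- get("CA"); Cc <- get("C"); O <- get("O"); H <- get("H")
  first <- match(ukey, paste(model$chain, model$resno))
  chain <- model$chain[first]
  resno <- model$resno[first]
  resname <- model$resname[first]
  complete <- stats::complete.cases(Nc) & stats::complete.cases(ca) &
    stats::complete.cases(Cc) & stats::complete.cases(O)
  brk <- rep(TRUE, n)                  # brk[i]: break between i and i+1
  for (i in seq_len(n - 1L)) {
    if (chain[i] != chain[i + 1L] || resno[i + 1L] != resno[i] + 1L) next
    if (!complete[i] || !complete[i + 1L]) next
    brk[i] <- sqrt(sum((Nc[i + 1L, ] - Cc[i, ])^2)) > 2.5
  }
  if (n >= 2L) for (i in 2:n) {
    if (!is.na(H[i, 1L])) next
    if (brk[i - 1L] || !complete[i] || !complete[i - 1L]) next
    v <- Cc[i - 1L, ] - O[i - 1L, ]
    H[i, ] <- Nc[i, ] + v / sqrt(sum(v^2))
  }
  list(chain = chain, resno = resno, resname = resname, complete = complete,
       brk = brk, ca = ca, nN = Nc, cC = Cc, oO = O, hH = H)
}

## Kabsch-Sander H-bond matrix: hb[a, d] TRUE when CO of residue a accepts
## a hydrogen bond from the NH of residue d (E < -0.5 kcal/mol)
hbond_matrix <- function(res) {
  n <- length(res$chain)
  hb <- matrix(FALSE, n, n)
  q <- 0.084 * 332
  for (d in seq_len(n)) {
    if (!res$complete[d] || res$resname[d] == "PRO") next
    if (is.na(res$hH[d, 1L])) next
    for (a in seq_len(n)) {
      if (a == d || !res$complete[a]) next
      if (res$chain[a] == res$chain[d] && abs(res$resno[a] - res$resno[d]) < 2L) next
      if (sum((res$ca[a, ] - res$ca[d, ])^2) > 81) next  # 9 A Ca cutoff
      rON <- sqrt(sum((res$oO[a, ] - res$nN[d, ])^2))
      rCH <- sqrt(sum((res$cC[a, ] - res$hH[d, ])^2))
      rOH <- sqrt(sum((res$oO[a, ] - res$hH[d, ])^2))
      rCN <- sqrt(sum((res$cC[a, ] - res$nN[d, ])^2))
      if (min(rON, rCH, rOH, rCN) < 0.5) next     # atom clash guard
      e <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      if (e < -0.5) hb[a, d] <- TRUE
    }
  }
  hb
}

#' Ensemble secondary-structure propensities
#'
#' Runs [assign_ss()] on every model and reports, per residue, the
#' frequency of each class across models. Frequencies sum to 1 at every
#' residue assigned in all models.
#'
#' @param ens an [nmr_ensemble()].
#' @return data.frame of class `ss_propensity`: `chain`, `resno`,
#'   `resname`, then one frequency column per class `H,G,E,B,T,S,C`.
#' @export
ensemble_propensity <- function(ens) {
  stopifnot(inherits(ens, "nmr_ensemble"))
  classes <- c("H", "G", "E", "B", "T", "S", "C")
  nm <- n_models(ens)
  tab <- NULL
  for (k in seq_len(nm)) {
    a <- assign_ss(ens_model(ens, k))
    if (is.null(tab)) {
      tab <- a[, c("chain", "resno", "resname")]
      counts <- matrix(0, nrow(tab), length(classes),
                       dimnames = list(NULL, classes))
    }
    counts[cbind(seq_len(nrow(a)), match(a$ss, classes))] <-
      counts[cbind(seq_len(nrow(a)), match(a$ss, classes))] + 1
  }
  out <- data.frame(tab, counts / nm)
  class(out) <- c("ss_propensity", "data.frame")
  out
}

#' Define helix/strand elements from ensemble propensities
#'
#' Elements are maximal runs of consecutive residues whose summed
#' propensity over the class group *strictly exceeds* the threshold
#' (helix: H, optionally plus G; strand: E plus B). Runs shorter than the
#' class minimum (3 residues for helix, 2 for strand) are dropped.
#'
#' @param profile an `ss_propensity` data.frame from [ensemble_propensity()].
#' @param threshold strict propensity cutoff in (0, 1], default 0.8.
#' @param helix_classes classes grouped as helix (default `c("H","G")`).
#' @param strand_classes classes grouped as strand (default `c("E","B")`).
#' @return data.frame `type`, `chain`, `start`, `end`.
#' @export
define_elements <- function(profile, threshold = 0.8,
                            helix_classes = c("H", "G"),
                            strand_classes = c("E", "B")) {
  stopifnot(threshold > 0, threshold <= 1)
  group_sum <- function(cls) rowSums(profile[, cls, drop = FALSE])
  runs_of <- function(above, min_len, type) {
    out <- NULL
    for (ch in unique(profile$chain)) {
      sel <- which(profile$chain == ch)
      sel <- sel[order(profile$resno[sel])]
      flag <- above[sel]
      start <- NULL
      i <- 1L
      while (i <= length(sel)) {
        if (!flag[i]) { i <- i + 1L; next }
        j <- i
        while (j + 1L <= length(sel) && flag[j + 1L] &&
               profile$resno[sel[j + 1L]] == profile$resno[sel[j]] + 1L) j <- j + 1L
        if (j - i + 1L >= min_len)
          out <- rbind(out, data.frame(type = type, chain = ch,
                                       start = profile$resno[sel[i]],
                                       end = profile$resno[sel[j]],
                                       stringsAsFactors = FALSE))
        i <- j + 1L
      }
    }
    out
  }
  helix <- runs_of(group_sum(helix_classes) > threshold, 3L, "helix")
  strand <- runs_of(group_sum(strand_classes) > threshold, 2L, "strand")
  out <- rbind(helix, strand)
  if (is.null(out))
    out <- data.frame(type = character(), chain = character(),
                      start = integer(), end = integer())
  rownames(out) <- NULL
  out[order(out$chain, out$start), , drop = FALSE]
}
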