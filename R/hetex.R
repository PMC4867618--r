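#' Saturation-transfer forward model for fast amide-water exchange
#'
#' Single point of truth for the water-exchange experiment: the same
#' function generates synthetic data and drives the fit. The amide proton
#' magnetization starts at zero after the readout and recovers during the
#' relaxation delay `d` under longitudinal relaxation (rate `r1`, toward
#' the equilibrium intensity `i_eq`) while exchanging with water protons at
#' rate `kex`. Water magnetization is held at zero under saturation; in the
#' unsaturated experiment it recovers as `w(t) = 1 - a*exp(-r1w*t)`
#' (normalized to its equilibrium), which is what the measured water
#' intensities trace. Solving the two-site Bloch-McConnell equation with
#' these boundary conditions gives
#'
#' saturated:   `I(d) = i_eq * r1/(r1+kex) * (1 - exp(-(r1+kex) d))`
#'
#' unsaturated: `I(d) = i_eq * (1 - exp(-(r1+kex) d)
#'                - a*kex * (exp(-r1w d) - exp(-(r1+kex) d)) / (r1+kex-r1w))`
#'
#' With `kex = 0` the two conditions coincide; with fully saturated water
#' the unsaturated curve reduces to the saturated one, and with instantly
#' recovered water (`r1w -> Inf`) exchange costs nothing.
#'
#' @param delay relaxation delay(s), seconds.
#' @param kex exchange rate, 1/s (>= 0).
#' @param r1 amide longitudinal relaxation rate, 1/s (> 0).
#' @param i_eq equilibrium signal intensity.
#' @param saturated logical: water-saturated condition?
#' @param water list with `r1w` (water recovery rate, 1/s) and `a` (initial
#'   saturated fraction of water). The defaults (`a = 0.3`, `r1w = 1`)
#'   describe a band-selective (BEST-type) readout that leaves water mostly
#'   at equilibrium; the measured water intensities correct the residual
#'   dip.
#' @return intensities, same length as `delay`.
#' @export
hetex_forward <- function(delay, kex, r1, i_eq, saturated,
                          water = list(r1w = 1, a = 0.3)) {
  stopifnot(kex >= 0, r1 > 0, all(delay >= 0))
  lam <- r1 + kex
  if (saturated)
    return(i_eq * (r1 / lam) * (1 - exp(-lam * delay)))
  r1w <- water$r1w
  a <- if (is.null(water$a)) 0.3 else water$a
  if (is.infinite(r1w)) return(i_eq * (1 - exp(-lam * delay)))
  if (abs(lam - r1w) < 1e-9)
    xfer <- a * kex * delay * exp(-lam * delay)
  else
    xfer <- a * kex * (exp(-r1w * delay) - exp(-lam * delay)) / (lam - r1w)
  i_eq * (1 - exp(-lam * delay) - xfer)
}

#' Estimate the water recovery curve from measured water intensities
#'
#' Fits `W(d) = W_eq * (1 - a*exp(-r1w*d))` to the water intensities of the
#' unsaturated condition; `a` is freed when at least three distinct delays
#' are available, otherwise held at the BEST-typical 0.3.
#'
#' @param tab an `intensity_table` with a `water_intensity` column.
#' @return list `r1w`, `a` usable as the `water` argument of
#'   [hetex_forward()]; falls back to `r1w = 1, a = 0.3` with a warning
#'   when no water intensities are present.
#' @export
estimate_water_recovery <- function(tab) {
  w <- unique(tab[tab$condition == "unsaturated" & !is.na(tab$water_intensity),
                  c("delay", "water_intensity")])
  if (nrow(w) < 2L) {
    warning("no usable water intensities; assuming r1w = 1 1/s, a = 0.3")
    return(list(r1w = 1, a = 0.3))
  }
  free_a <- nrow(w) >= 3L
  resid <- function(p) {
    a <- if (free_a) p[3L] else 0.3
    w$water_intensity - p[1L] * (1 - a * exp(-p[2L] * w$delay))
  }
  p0 <- c(max(w$water_intensity) * 1.1, 1, if (free_a) 0.3)
  lo <- c(1e-9, 1e-4, if (free_a) 0)
  hi <- c(Inf, Inf, if (free_a) 1)
  fit <- minpack.lm::nls.lm(par = p0, fn = resid, lower = lo, upper = hi,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  list(r1w = fit$par[2L], a = if (free_a) fit$par[3L] else 0.3)
}

#' Fit the amide-water exchange rate for one residue
#'
#' Bounded nonlinear least squares of the [hetex_forward()] model in
#' `(kex, r1, i_eq)` against the saturated and unsaturated intensities of a
#' single residue, with several kex starts spanning the sensitive window to
#' dodge local minima. Residuals are relative (weight 1/intensity) by default, the
#' maximum-likelihood choice when intensity noise is multiplicative;
#' `weighting = "absolute"` gives plain least squares. The experiment is
#' sensitive in the window 0.1 < kex < 10 1/s;
#' fits outside it are flagged by `in_window = FALSE`. Non-convergence
#' yields a flagged record, not an error.
#'
#' @param data `intensity_table` rows of one residue (>= 2 distinct delays,
#'   both conditions).
#' @param water water recovery parameters (see [hetex_forward()]); by
#'   default estimated from the table via [estimate_water_recovery()].
#' @param starts numeric vector of kex starting values.
#' @param weighting `"relative"` (default) or `"absolute"` residuals.
#' @return object of class `hetex_fit` with components `kex`, `r1`, `i_eq`,
#'   `residual_ss`, `in_window`, `converged`, `water`, `data`.
#' @export
fit_kex <- function(data, water = NULL, starts = c(0.05, 0.2, 1, 5, 9),
                    weighting = c("relative", "absolute")) {
  weighting <- match.arg(weighting)
  key <- unique(paste(data$chain, data$resno))
  if (length(key) != 1L) stop("fit_kex expects data for exactly one residue")
  if (length(unique(data$delay)) < 2L)
    stop("need at least 2 distinct relaxation delays")
  if (!all(c("saturated", "unsaturated") %in% data$condition))
    stop("need both saturated and unsaturated conditions")
  if (is.null(water)) water <- suppressWarnings(estimate_water_recovery(data))
  sat <- data$condition == "saturated"
  scale_floor <- 1e-6 * max(abs(data$intensity), 1e-12)
  resid <- function(p) {
    mu <- c(hetex_forward(data$delay[sat], p[1L], p[2L], p[3L], TRUE, water),
            hetex_forward(data$delay[!sat], p[1L], p[2L], p[3L], FALSE, water))
    obs <- c(data$intensity[sat], data$intensity[!sat])
    if (weighting == "relative") (mu - obs) / pmax(abs(mu), scale_floor)
    else mu - obs
  }
  i0 <- max(data$intensity) * 1.1 + 1e-9
  best <- NULL
  for (k0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(k0, 1, i0), fn = resid,
                         lower = c(0, 1e-6, 1e-9),
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(fit$fvec^2)
    if (is.null(best) || ss < best$ss)
      best <- list(par = fit$par, ss = ss, info = fit$info)
  }
  if (is.null(best)) {
    out <- list(kex = NA_real_, r1 = NA_real_, i_eq = NA_real_,
                residual_ss = NA_real_, in_window = FALSE, converged = FALSE,
                water = water, data = data)
    class(out) <- "hetex_fit"
    return(out)
  }
  kex <- best$par[1L]
  out <- list(kex = kex, r1 = best$par[2L], i_eq = best$par[3L],
              residual_ss = best$ss,
              in_window = kex > 0.1 && kex < 10,
              converged = best$info %in% 1:4,
              water = water, data = data)
  class(out) <- "hetex_fit"
  out
}

#' @export
print.hetex_fit <- function(x, ...) {
  cat("Amide-water exchange fit:",
      if (!x$converged) "(did not converge)" else "", "\n")
  cat(sprintf("  kex  = %.4g 1/s %s\n", x$kex,
              if (isTRUE(x$in_window)) "(within sensitive window 0.1-10 1/s)"
              else "(outside sensitive window)"))
  cat(sprintf("  R1   = %.4g 1/s\n  I_eq = %.4g\n  residual SS = %.4g\n",
              x$r1, x$i_eq, x$residual_ss))
  invisible(x)
}

#' @export
coef.hetex_fit <- function(object, ...)
  c(kex = object$kex, r1 = object$r1, i_eq = object$i_eq)

#' @export
fitted.hetex_fit <- function(object, ...) {
  d <- object$data
  ifelse(d$condition == "saturated",
         hetex_forward(d$delay, object$kex, object$r1, object$i_eq, TRUE,
                       object$water),
         hetex_forward(d$delay, object$kex, object$r1, object$i_eq, FALSE,
                       object$water))
}

#' @export
residuals.hetex_fit <- function(object, ...)
  object$data$intensity - stats::fitted(object)

#' Fit exchange rates for every residue of an intensity table
#'
#' @param tab an `intensity_table`.
#' @inheritParams fit_kex
#' @return data.frame `chain`, `resno`, `kex`, `r1`, `i_eq`,
#'   `residual_ss`, `in_window`, `converged`.
#' @export
fit_kex_table <- function(tab, water = NULL, starts = c(0.05, 0.2, 1, 5, 9),
                          weighting = c("relative", "absolute")) {
  weighting <- match.arg(weighting)
  if (is.null(water)) water <- suppressWarnings(estimate_water_recovery(tab))
  keys <- unique(tab[, c("chain", "resno")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    d <- tab[tab$chain == keys$chain[i] & tab$resno == keys$resno[i], ]
    f <- fit_kex(d, water, starts, weighting)
    data.frame(chain = keys$chain[i], resno = keys$resno[i],
               kex = f$kex, r1 = f$r1, i_eq = f$i_eq,
               residual_ss = f$residual_ss, in_window = f$in_window,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' H/D-exchange protection classes
#'
#' Residues are classified by the latest D2O timepoint at which their amide
#' signal is still identifiable; residues absent already at the first
#' timepoint exchange fast. Observation sets should be prefix-closed in
#' time (a signal seen late was seen early); violations are flagged with a
#' warning and the residue is classified by its latest observation.
#'
#' @param obs data.frame with columns `chain`, `resno`, `timepoint`
#'   (minutes), one row per (residue, timepoint at which it is seen).
#' @param timepoints the full timepoint grid (minutes); defaults to the
#'   sorted unique observed timepoints.
#' @param residues optional data.frame `chain`, `resno` enumerating all
#'   measured residues (so never-seen residues get classified too).
#' @return data.frame `chain`, `resno`, `last_seen` (minutes, `NA` when
#'   exchanged before the first timepoint) and `class` (e.g. `">=431min"`
#'   or `"fast(<11min)"`).
#' @export
hd_protection <- function(obs, timepoints = NULL, residues = NULL) {
  if (is.null(timepoints)) timepoints <- sort(unique(obs$timepoint))
  if (!all(obs$timepoint %in% timepoints))
    stop("observation at a timepoint not on the grid")
  if (is.null(residues)) residues <- unique(obs[, c("chain", "resno")])
  out <- NULL
  for (i in seq_len(nrow(residues))) {
    sel <- obs$chain == residues$chain[i] & obs$resno == residues$resno[i]
    seen <- sort(unique(obs$timepoint[sel]))
    if (length(seen)) {
      expect <- timepoints[timepoints <= max(seen)]
      if (!all(expect %in% seen))
        warning("residue ", residues$chain[i], ":", residues$resno[i],
                " observations not prefix-closed in time; using latest")
      last <- max(seen)
      cls <- paste0(">=", last, "min")
    } else {
      last <- NA_real_
      cls <- paste0("fast(<", min(timepoints), "min)")
    }
    out <- rbind(out, data.frame(chain = residues$chain[i],
                                 resno = residues$resno[i],
                                 last_seen = last, class = cls,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Heteronuclear NOE values and rigidity classes
#'
#' `noe = I_irradiated / I_unirradiated`. Classes follow the usual reading
#' of backbone {1H}-15N NOE profiles: `flexible` below 0 (ps-ns dynamic),
#' `rigid` strictly above 0.5, `intermediate` between. A zero unirradiated
#' intensity yields an `NA` record flagged in `undefined`.
#'
#' @param i_irr,i_unirr numeric vectors of irradiated / unirradiated
#'   intensities.
#' @param chain,resno optional residue labels carried through.
#' @param thresholds length-2 numeric, default `c(0, 0.5)`.
#' @return data.frame with `noe`, `class`, `undefined` (plus labels).
#' @export
het_noe <- function(i_irr, i_unirr, chain = NULL, resno = NULL,
                    thresholds = c(0, 0.5)) {
  stopifnot(length(i_irr) == length(i_unirr), length(thresholds) == 2L)
  undef <- i_unirr == 0
  noe <- ifelse(undef, NA_real_, i_irr / i_unirr)
  cls <- ifelse(is.na(noe), NA_character_,
                ifelse(noe < thresholds[1L], "flexible",
                       ifelse(noe > thresholds[2L], "rigid", "intermediate")))
  out <- data.frame(noe = noe, class = cls, undefined = undef,
                    stringsAsFactors = FALSE)
  if (!is.null(chain)) out <- data.frame(chain = chain, resno = resno, out,
                                         stringsAsFactors = FALSE)
  out
}

#' Maximal same-class residue runs
#'
#' Collapses a per-residue classification into maximal runs of consecutive
#' residues (within a chain, consecutive numbering) sharing a class, and
#' drops runs shorter than `min_run`.
#'
#' @param chain,resno,class parallel vectors.
#' @param min_run minimum run length reported (default 1).
#' @return data.frame `chain`, `start`, `end`, `class`, `length`.
#' @export
classify_regions <- function(chain, resno, class, min_run = 1L) {
  chain <- rep_len(chain, length(resno))
  stopifnot(length(resno) == length(class))
  out <- NULL
  for (ch in unique(chain)) {
    sel <- which(chain == ch)
    sel <- sel[order(resno[sel])]
    i <- 1L
    while (i <= length(sel)) {
      if (is.na(class[sel[i]])) { i <- i + 1L; next }
      j <- i
      while (j + 1L <= length(sel) &&
             !is.na(class[sel[j + 1L]]) &&
             class[sel[j + 1L]] == class[sel[i]] &&
             resno[sel[j + 1L]] == resno[sel[j]] + 1L) j <- j + 1L
      if (j - i + 1L >= min_run)
        out <- rbind(out, data.frame(chain = ch, start = resno[sel[i]],
                                     end = resno[sel[j]],
                                     class = class[sel[i]],
                                     length = j - i + 1L,
                                     stringsAsFactors = FALSE))
      i <- j + 1L
    }
  }
  if (is.null(out))
    out <- data.frame(chain = character(), start = integer(), end = integer(),
                      class = character(), length = integer())
  rownames(out) <- NULL
  out
}

#' Flag residues whose neighbour is a serine or threonine
#'
#' In water-exchange experiments the hydroxyl of an adjacent Ser/Thr can
#' relay NOE onto the amide proton and inflate the apparent exchange rate;
#' this flag (i +/- 1 within a chain) lets users exclude such residues.
#'
#' @param chain,resno,resname parallel vectors describing the sequence.
#' @return logical vector.
#' @export
flag_st_neighbors <- function(chain, resno, resname) {
  st <- toupper(resname) %in% c("SER", "THR")
  key <- paste(chain, resno)
  up <- match(paste(chain, resno + 1L), key)
  dn <- match(paste(chain, resno - 1L), key)
  has <- function(idx) !is.na(idx) & st[ifelse(is.na(idx), 1L, idx)]
  has(up) | has(dn)
}
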