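#' Specification for a synthetic peptide / ensemble
#'
#' Bundles everything the generators need: sequence, per-residue secondary
#' structure (`H` helix, `E` strand, `C` coil), the rigid core range, the
#' coordinate noise levels of core and tail, the ensemble size and the
#' seed. Generators are pure functions of (spec, seed): identical inputs
#' give identical outputs.
#'
#' @param sequence one-letter amino-acid string.
#' @param ss_string per-residue class string over `H`, `E`, `C`; same
#'   length as `sequence`.
#' @param core_range integer residue interval treated as rigid core (e.g.
#'   `5:16`); default all residues.
#' @param noise_core,noise_tail isotropic coordinate noise sd, A.
#' @param n_models ensemble size (>= 1).
#' @param seed integer seed.
#' @export
peptide_spec <- function(sequence, ss_string, core_range = NULL,
                         noise_core = 0, noise_tail = 0, n_models = 1L,
                         seed = 1L) {
  ss <- strsplit(ss_string, "")[[1L]]
  if (nchar(sequence) != length(ss))
    stop("sequence and ss_string lengths differ")
  if (!all(ss %in% c("H", "E", "C")))
    stop("unknown secondary-structure class in ss_string (use H/E/C)")
  stopifnot(noise_core >= 0, noise_tail >= 0, n_models >= 1L)
  structure(list(sequence = toupper(sequence), ss = ss,
                 core_range = if (is.null(core_range))
                   seq_len(length(ss)) else as.integer(core_range),
                 noise_core = noise_core, noise_tail = noise_tail,
                 n_models = as.integer(n_models), seed = as.integer(seed)),
            class = "peptide_spec")
}

## run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

## natural-extension reference frame: place atom d bonded to c, with
## angle(b,c,d) and torsion(a,b,c,d)
nerf <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  nn <- pracma_cross(b - a, bc); nn <- nn / sqrt(sum(nn^2))
  m <- pracma_cross(nn, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * nn
}
pracma_cross <- function(u, v)
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])

## Engh-Huber-style ideal backbone geometry
.bb <- list(b_NCa = 1.458, b_CaC = 1.525, b_CN = 1.329, b_CO = 1.231,
            b_CaCb = 1.521,
            a_NCaC = 111.2, a_CaCN = 116.2, a_CNCa = 121.7,
            a_CaCO = 120.8, a_NCaCb = 110.4, omega = 180)

#' Build an ideal-geometry peptide from a synthetic spec
#'
#' Backbone (N, CA, C, O) plus CB (except glycine) built residue by
#' residue with ideal bond lengths/angles and per-class dihedrals:
#' helix `H` (phi, psi) = (-57, -47), strand `E` = (-135, +135), coil `C`
#' sampled (seeded) from the broad beta/PPII basin phi in (-180, -60),
#' psi in (60, 180) with a 2.5 A minimum-distance rejection between
#' non-neighbouring Ca atoms.
#'
#' @param spec a [peptide_spec()].
#' @param chain chain id (default `"A"`).
#' @param start_resno first residue number (may be <= 0).
#' @return an atom-record model data.frame.
#' @export
build_ideal_peptide <- function(spec, chain = "A", start_resno = 1L) {
  stopifnot(inherits(spec, "peptide_spec"))
  with_seed(spec$seed, function() {
    n <- length(spec$ss)
    for (attempt in 1:60) {
      phi <- numeric(n); psi <- numeric(n)
      for (i in seq_len(n)) {
        if (spec$ss[i] == "H") { phi[i] <- -57; psi[i] <- -47 }
        else if (spec$ss[i] == "E") { phi[i] <- -135; psi[i] <- 135 }
        else { phi[i] <- stats::runif(1, -180, -60); psi[i] <- stats::runif(1, 60, 180) }
      }
      m <- build_backbone(spec, phi, psi, chain, start_resno)
      ca <- as.matrix(m[m$atom == "CA", c("x", "y", "z")])
      if (nrow(ca) < 3L) return(m)
      dd <- as.matrix(stats::dist(ca))
      dd[abs(row(dd) - col(dd)) <= 1L] <- Inf
      if (min(dd) >= 2.5) return(m)
    }
    stop("failed to build a self-avoiding coil in 60 attempts")
  })
}

#' Build a peptide from explicit backbone dihedrals
#'
#' Lower-level companion of [build_ideal_peptide()] for designed fixtures
#' (e.g. beta-hairpins with specific turn dihedrals): same ideal bond
#' geometry, but `phi`/`psi` given per residue.
#'
#' @param sequence one-letter amino-acid string.
#' @param phi,psi numeric vectors of backbone dihedrals, degrees.
#' @param chain chain id; `start_resno` first residue number.
#' @param start_resno first residue number.
#' @return an atom-record model data.frame.
#' @export
build_peptide_dihedrals <- function(sequence, phi, psi, chain = "A",
                                    start_resno = 1L) {
  n <- nchar(sequence)
  stopifnot(length(phi) == n, length(psi) == n)
  spec <- list(ss = rep("C", n), sequence = toupper(sequence))
  build_backbone(spec, phi, psi, chain, start_resno)
}

build_backbone <- function(spec, phi, psi, chain, start_resno) {
  n <- length(spec$ss)
  resnames <- aa1to3(spec$sequence)
  g <- .bb
  N <- matrix(NA_real_, n, 3L); CA <- N; C <- N; O <- N; CB <- N
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g$b_NCa, 0, 0)
  C[1L, ] <- nerf(c(0, -1, 0), N[1L, ], CA[1L, ], g$b_CaC, g$a_NCaC, 60)
  for (i in seq_len(n)) {
    if (i > 1L) {
      N[i, ] <- nerf(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                     g$b_CN, g$a_CaCN, psi[i - 1L])
      CA[i, ] <- nerf(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                      g$b_NCa, g$a_CNCa, g$omega)
      C[i, ] <- nerf(C[i - 1L, ], N[i, ], CA[i, ], g$b_CaC, g$a_NCaC, phi[i])
    }
    # carbonyl O in the peptide plane, trans to the next N
    O[i, ] <- nerf(N[i, ], CA[i, ], C[i, ], g$b_CO, g$a_CaCO, psi[i] + 180)
    if (resnames[i] != "GLY")
      CB[i, ] <- nerf(C[i, ], N[i, ], CA[i, ], g$b_CaCb, g$a_NCaCb, -122.6)
  }
  rows <- list()
  for (i in seq_len(n)) {
    atoms <- rbind(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O[i, ],
                   CB = CB[i, ])
    atoms <- atoms[!is.na(atoms[, 1L]), , drop = FALSE]
    rows[[i]] <- data.frame(chain = chain, resno = start_resno + i - 1L,
                            resname = resnames[i], atom = rownames(atoms),
                            x = atoms[, 1L], y = atoms[, 2L], z = atoms[, 3L],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Perturb a model into an ensemble with rigid core and mobile tails
#'
#' Makes `n_models` copies of `model` with isotropic Gaussian coordinate
#' noise: sd `noise_core` for residues inside `core_range`, `noise_tail`
#' outside. Emulates an NMR ensemble whose core superimposes tightly while
#' the tails fan out.
#'
#' @param model an atom-record data.frame.
#' @param spec a [peptide_spec()] supplying `core_range`, noise levels,
#'   `n_models` and `seed`.
#' @return an [nmr_ensemble()].
#' @export
perturb_ensemble <- function(model, spec) {
  stopifnot(inherits(spec, "peptide_spec"))
  with_seed(spec$seed + 1L, function() {
    sd_atom <- ifelse(model$resno %in% spec$core_range,
                      spec$noise_core, spec$noise_tail)
    models <- lapply(seq_len(spec$n_models), function(k) {
      m <- model
      m$x <- m$x + stats::rnorm(nrow(m), 0, sd_atom)
      m$y <- m$y + stats::rnorm(nrow(m), 0, sd_atom)
      m$z <- m$z + stats::rnorm(nrow(m), 0, sd_atom)
      m
    })
    as_ensemble(models)
  })
}

#' Default secondary-shift offsets used by the shift simulator
#' @export
default_ss_offsets <- function()
  list(H = c(CA = 2.8, CB = -0.5), E = c(CA = -1.5, CB = 2.2),
       C = c(CA = 0, CB = 0))

#' Simulate a Ca/Cb chemical-shift table with known secondary structure
#'
#' Shifts are random-coil reference values plus a per-class secondary
#' shift offset plus Gaussian noise:
#' `d = d_rc + offset(class) + N(0, noise_ppm)`. With zero noise,
#' [csi_profile()] recovers the generating class string exactly under the
#' default offsets and threshold.
#'
#' @param spec a [peptide_spec()].
#' @param rc random-coil table (default [random_coil_table()]).
#' @param offsets list mapping class to `c(CA=, CB=)` offsets in ppm.
#' @param noise_ppm Gaussian noise sd in ppm.
#' @param chain,start_resno residue addressing of the output.
#' @return a [shift_table()].
#' @export
simulate_shifts <- function(spec, rc = random_coil_table(),
                            offsets = default_ss_offsets(), noise_ppm = 0,
                            chain = "A", start_resno = 1L) {
  stopifnot(inherits(spec, "peptide_spec"))
  with_seed(spec$seed + 2L, function() {
    resnames <- aa1to3(spec$sequence)
    rows <- list()
    for (i in seq_along(resnames)) {
      ri <- match(resnames[i], rc$resname)
      off <- offsets[[spec$ss[i]]]
      for (at in c("CA", "CB")) {
        ref <- rc[[at]][ri]
        if (is.na(ref)) next
        rows[[length(rows) + 1L]] <- data.frame(
          chain = chain, resno = start_resno + i - 1L,
          resname = resnames[i], atom = at,
          shift = ref + off[[at]] + stats::rnorm(1, 0, noise_ppm),
          sd = if (noise_ppm > 0) noise_ppm else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    shift_table(do.call(rbind, rows))
  })
}

#' Simulate saturation-transfer intensity data with known exchange rates
#'
#' Evaluates the [hetex_forward()] model (the same function the fitter
#' uses) at the given delays for both conditions and applies multiplicative
#' Gaussian noise. `kex` may be a vector: one residue per element,
#' numbered consecutively.
#'
#' @param kex exchange rate(s), 1/s.
#' @param r1 amide longitudinal relaxation rate(s), 1/s.
#' @param i_eq equilibrium intensity(ies).
#' @param delays relaxation delays in seconds (default the 566, 878 and
#'   1659 ms grid).
#' @param water water recovery parameters (see [hetex_forward()]).
#' @param noise_frac multiplicative noise sd (e.g. 0.02 for 2%).
#' @param seed integer seed.
#' @param chain chain id, `start_resno` first residue number.
#' @param start_resno first residue number.
#' @return an `intensity_table` with water intensities filled in
#'   (arbitrary water equilibrium intensity 100).
#' @export
simulate_hetex <- function(kex, r1 = 1.5, i_eq = 100,
                           delays = c(0.566, 0.878, 1.659),
                           water = list(r1w = 1, a = 0.3),
                           noise_frac = 0, seed = 1L,
                           chain = "A", start_resno = 1L) {
  nres <- length(kex)
  r1 <- rep_len(r1, nres); i_eq <- rep_len(i_eq, nres)
  with_seed(seed, function() {
    rows <- list()
    for (i in seq_len(nres)) {
      for (cond in c("saturated", "unsaturated")) {
        mu <- hetex_forward(delays, kex[i], r1[i], i_eq[i],
                            cond == "saturated", water)
        obs <- mu * (1 + stats::rnorm(length(delays), 0, noise_frac))
        wint <- if (cond == "saturated") 0 else
          100 * (1 - water$a * exp(-water$r1w * delays))
        rows[[length(rows) + 1L]] <- data.frame(
          chain = chain, resno = start_resno + i - 1L, condition = cond,
          delay = delays, intensity = obs, water_intensity = wint,
          stringsAsFactors = FALSE)
      }
    }
    intensity_table(do.call(rbind, rows))
  })
}

#' Simulate a scored model pool for the selection stage
#'
#' Draws per-model energies and shift-agreement statistics, builds matching
#' perturbed coordinates (so Ca-RMSDs are computable), and keeps the
#' generating parameters as ground truth for oracle tests.
#'
#' @param n pool size (>= 20).
#' @param seed integer seed.
#' @param c weighting factor for the rescoring.
#' @param energy_law function `n -> data.frame(e_rosetta, chi2)`; the
#'   default draws `e_rosetta ~ N(-100, 10)` and `chi2 ~ Gamma(shape 4,
#'   scale 10)`.
#' @param rmsd_law function `n -> per-model coordinate noise sd (A)`; the
#'   default draws `sd ~ U(0.05, 3)`.
#' @return list `table` (a [score_table()]), `ensemble`
#'   (an [nmr_ensemble()] of `n` models plus the unperturbed base model
#'   as reference coordinates), and `truth` (per-model noise sd).
#' @export
simulate_score_table <- function(n, seed = 1L, c = 0.25,
                                 energy_law = NULL, rmsd_law = NULL) {
  if (n < 20L) stop("need n >= 20 models")
  if (is.null(energy_law))
    energy_law <- function(n) data.frame(
      e_rosetta = stats::rnorm(n, -100, 10),
      chi2 = stats::rgamma(n, shape = 4, scale = 10))
  if (is.null(rmsd_law))
    rmsd_law <- function(n) stats::runif(n, 0.05, 3)
  base_spec <- peptide_spec(paste(rep("A", 20L), collapse = ""),
                            paste(rep("H", 20L), collapse = ""), seed = seed)
  base <- build_ideal_peptide(base_spec)
  with_seed(seed + 10L, function() {
    laws <- energy_law(n)
    sds <- rmsd_law(n)
    ids <- sprintf("m%04d", seq_len(n))
    models <- lapply(seq_len(n), function(k) {
      m <- base
      m$x <- m$x + stats::rnorm(nrow(m), 0, sds[k])
      m$y <- m$y + stats::rnorm(nrow(m), 0, sds[k])
      m$z <- m$z + stats::rnorm(nrow(m), 0, sds[k])
      m
    })
    ens <- as_ensemble(models, ids)
    list(table = score_table(ids, laws$e_rosetta, laws$chi2, c),
         ensemble = ens, truth = data.frame(model_id = ids, noise_sd = sds))
  })
}
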