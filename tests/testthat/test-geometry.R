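test_that("superposition recovers identity and pure translations", {
  m <- build_ideal_peptide(peptide_spec(strrep("A", 10), strrep("H", 10)))
  sp <- superpose(m, m)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)

  shifted <- m; shifted$x <- shifted$x + 5
  sp2 <- superpose(shifted, m)
  expect_equal(sp2$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp2$translation, c(-5, 0, 0), tolerance = 1e-8)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-10)

  # too few atoms and collinear selections are rejected
  expect_error(superpose(m[m$resno <= 2, ], m[m$resno <= 2, ]), "3 common")
  lin <- data.frame(chain = "A", resno = 1:5, resname = "ALA", atom = "CA",
                    x = 1:5 * 3.8, y = 0, z = 0)
  expect_error(superpose(lin, lin), "collinear")
})

test_that("superposition matches the quaternion oracle and beats random rotations", {
  set.seed(12)
  for (rep in 1:20) {
    X <- matrix(stats::rnorm(12), 4, 3)
    Y <- matrix(stats::rnorm(12), 4, 3)
    mX <- data.frame(chain = "A", resno = 1:4, resname = "ALA", atom = "CA",
                     x = X[, 1], y = X[, 2], z = X[, 3])
    mY <- transform(mX, x = Y[, 1], y = Y[, 2], z = Y[, 3])
    got <- superpose(mX, mY)$rmsd
    expect_equal(got, quaternion_fit_rmsd(X, Y), tolerance = 1e-8)
    # optimality: no random rigid transform does better
    X0 <- sweep(X, 2, colMeans(X)); Y0 <- sweep(Y, 2, colMeans(Y))
    best_random <- min(replicate(200, {
      R <- random_rotation()
      sqrt(mean(rowSums((X0 %*% t(R) - Y0)^2)))
    }))
    expect_lte(got, best_random + 1e-12)
  }
})

test_that("rmsf is zero for identical models, large in noisy tails, rigid-motion invariant", {
  core <- 5:16
  spec <- peptide_spec(strrep("A", 20), strrep("H", 20), core_range = core,
                       noise_core = 0.2, noise_tail = 3, n_models = 10L,
                       seed = 5L)
  base <- build_ideal_peptide(spec)

  same <- as_ensemble(rep(list(base), 3L))
  expect_equal(max(ca_rmsf(same)$rmsf), 0, tolerance = 1e-10)

  expect_warning(r1 <- ca_rmsf(as_ensemble(list(base))), "single")
  expect_equal(max(r1$rmsf), 0)

  ens <- perturb_ensemble(base, spec)
  sel <- list(A = core)
  r <- ca_rmsf(ens, align_selection = sel)
  expect_gt(mean(r$rmsf[!r$resno %in% core]) / mean(r$rmsf[r$resno %in% core]), 5)

  # applying one global rigid transform to every model changes nothing
  set.seed(8)
  R <- random_rotation(); tvec <- c(10, -4, 2)
  moved <- as_ensemble(lapply(seq_len(n_models(ens)), function(k)
    apply_rigid(ens_model(ens, k), R, tvec)))
  r2 <- ca_rmsf(moved, align_selection = sel)
  expect_equal(r2$rmsf, r$rmsf, tolerance = 1e-7)
  # and both alignment references behave the same way under rigid motion
  expect_equal(ca_rmsf(moved, sel, ref = "model1")$rmsf,
               ca_rmsf(ens, sel, ref = "model1")$rmsf, tolerance = 1e-7)
})

test_that("window distance: exact on a straight trace, calibrated on ideal elements, rigid/mirror invariant", {
  # collinear Ca trace at 3.8 A spacing: d(i-4, i+4) = 8 * 3.8 = 30.4 exactly
  lin <- data.frame(chain = "A", resno = 1:12, resname = "ALA", atom = "CA",
                    x = (1:12) * 3.8, y = 0, z = 0)
  expect_equal(ca_window_distance(lin)$d, rep(30.4, 4), tolerance = 1e-12)

  helix <- build_ideal_peptide(peptide_spec(strrep("A", 20), strrep("H", 20)))
  strand <- build_ideal_peptide(peptide_spec(strrep("A", 20), strrep("E", 20)))
  dh <- ca_window_distance(helix)$d
  de <- ca_window_distance(strand)$d
  # helix is tightly wound, extended strand nearly straight, and the two
  # are widely separated (helix ~12-13 A, strand ~27-28 A)
  expect_lt(max(dh), 14); expect_gt(min(de), 26); expect_lt(max(de), 30.4)
  expect_lt(stats::sd(dh), 0.01)

  # rigid motion and mirror invariance
  set.seed(3)
  R <- random_rotation()
  moved <- apply_rigid(helix, R, c(3, 1, -7))
  expect_equal(ca_window_distance(moved)$d, dh, tolerance = 1e-9)
  mirror <- helix; mirror$z <- -mirror$z
  expect_equal(ca_window_distance(mirror)$d, dh, tolerance = 1e-9)

  # ensemble version averages across models
  ens <- as_ensemble(list(helix, helix))
  expect_equal(ca_window_distance(ens)$d, dh, tolerance = 1e-12)
  # short chain -> empty profile
  expect_equal(nrow(ca_window_distance(lin[1:5, ])), 0L)
})

test_that("backbone ASA matches the analytic two-sphere oracle, converges, and flags burial/exposure", {
  cap_area <- function(r1, r2, d) {
    if (d >= r1 + r2) return(0)
    h <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
    2 * pi * r1 * h
  }
  two <- data.frame(chain = "A", resno = c(1L, 1L), resname = "ALA",
                    atom = c("N", "C"), x = c(0, 2), y = 0, z = 0)
  got <- nmrens:::atom_asa(two, 1.4, 4000L)
  r1 <- 1.55 + 1.4; r2 <- 1.70 + 1.4
  exact <- c(4 * pi * r1^2 - cap_area(r1, r2, 2), 4 * pi * r2^2 - cap_area(r2, r1, 2))
  expect_equal(got, exact, tolerance = 0.005)

  # an atom enclosed by a dense shell of blockers has zero area
  set.seed(4)
  shell <- nmrens:::sphere_points(40L) * 2.0
  buried <- data.frame(chain = "A", resno = 1L, resname = "ALA",
                       atom = c("N", rep("C", 40L)),
                       x = c(0, shell[, 1]), y = c(0, shell[, 2]),
                       z = c(0, shell[, 3]))
  expect_equal(nmrens:::atom_asa(buried, 1.4, 960L)[1L], 0)

  # convergence of the sampling: 960 vs 4000 points
  m <- build_ideal_peptide(peptide_spec(strrep("A", 10), strrep("H", 10)))
  a1 <- backbone_asa(m, n_points = 960L, relative = FALSE)$asa
  a2 <- backbone_asa(m, n_points = 4000L, relative = FALSE)$asa
  expect_lt(abs(sum(a1) - sum(a2)) / sum(a2), 0.02)
  expect_lt(mean(abs(a1 - a2) / a2), 0.02)

  # nothing occludes an isolated residue: at or above the in-chain reference
  iso <- build_ideal_peptide(peptide_spec("A", "C", seed = 1L))
  expect_gte(backbone_asa(iso)$rel_exposure, 1)

  # chain interior is less exposed than the termini
  rel <- backbone_asa(m)$rel_exposure
  expect_lt(mean(rel[4:7]), rel[1L])
})
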