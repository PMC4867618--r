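test_that("forward model limits behave physically", {
  d <- c(0.566, 0.878, 1.659)
  w <- list(r1w = 1, a = 0.3)
  # no exchange: saturation transfer has no effect
  expect_equal(hetex_forward(d, 0, 1.5, 100, TRUE, w),
               hetex_forward(d, 0, 1.5, 100, FALSE, w))
  # water held saturated throughout (a=1, no recovery): conditions coincide
  expect_equal(hetex_forward(d, 2, 1.5, 100, FALSE, list(r1w = 1e-12, a = 1)),
               hetex_forward(d, 2, 1.5, 100, TRUE, w), tolerance = 1e-9)
  # instantly recovered water: exchange costs nothing relative to R1+kex recovery
  expect_equal(hetex_forward(d, 2, 1.5, 100, FALSE, list(r1w = Inf, a = 1)),
               100 * (1 - exp(-(1.5 + 2) * d)))
  # removable singularity at r1w == r1 + kex
  eps_side <- hetex_forward(d, 0.5, 0.5 + 1e-7, 100, FALSE, list(r1w = 1, a = 0.3))
  at_sing <- hetex_forward(d, 0.5, 0.5, 100, FALSE, list(r1w = 1, a = 0.3))
  expect_equal(at_sing, eps_side, tolerance = 1e-4)
  # intensities grow with delay and stay below equilibrium
  expect_true(all(diff(hetex_forward(d, 1, 1.5, 100, FALSE, w)) > 0))
  expect_true(all(hetex_forward(d, 1, 1.5, 100, FALSE, w) < 100))
})

test_that("noise-free generation round-trips through the fitter exactly", {
  tab <- simulate_hetex(kex = 1.0, r1 = 1.5, i_eq = 100, noise_frac = 0, seed = 2L)
  f <- fit_kex(tab)
  expect_lt(abs(f$kex - 1.0) / 1.0, 0.01)
  expect_equal(f$r1, 1.5, tolerance = 1e-3)
  expect_equal(f$i_eq, 100, tolerance = 1e-2)
  expect_lt(f$residual_ss, 1e-10)
  expect_true(f$in_window)
  expect_equal(unname(stats::residuals(f)), rep(0, 6L), tolerance = 1e-6)

  # no exchange: fitted kex ~ 0, and the two conditions coincide in the data
  tab0 <- simulate_hetex(kex = 0, r1 = 1.2, i_eq = 50, noise_frac = 0, seed = 3L)
  wide <- merge(tab0[tab0$condition == "saturated", c("delay", "intensity")],
                tab0[tab0$condition == "unsaturated", c("delay", "intensity")],
                by = "delay")
  expect_equal(wide$intensity.x, wide$intensity.y)
  f0 <- fit_kex(tab0)
  expect_lt(f0$kex, 0.01)
  expect_false(f0$in_window)

  # far above the window: flagged as outside 0.1-10 1/s
  tab50 <- simulate_hetex(kex = 50, r1 = 1.5, i_eq = 100, noise_frac = 0, seed = 4L)
  expect_false(fit_kex(tab50)$in_window)
})

test_that("median kex recovery error is below 10% at 2% noise across the sensitive window", {
  set.seed(42)
  kex_true <- exp(stats::runif(100, log(0.1), log(10)))
  tab <- simulate_hetex(kex_true, r1 = 1.5, i_eq = 100, noise_frac = 0.02,
                        seed = 43L)
  fits <- fit_kex_table(tab)
  rel_err <- abs(fits$kex - kex_true) / kex_true
  expect_lt(stats::median(rel_err), 0.10)
  expect_true(all(fits$converged))
})

test_that("water recovery estimation reproduces the generating curve", {
  w <- list(r1w = 1.4, a = 0.45)
  tab <- simulate_hetex(kex = 1, r1 = 1.5, i_eq = 80, water = w, seed = 6L)
  est <- estimate_water_recovery(tab)
  expect_equal(est$r1w, w$r1w, tolerance = 1e-4)
  expect_equal(est$a, w$a, tolerance = 1e-4)
  # absent water intensities: documented fallback with warning
  tab$water_intensity <- NA_real_
  expect_warning(fb <- estimate_water_recovery(tab), "assuming")
  expect_equal(fb, list(r1w = 1, a = 0.3))
})

test_that("H/D protection classes map observation sets to latest timepoints", {
  grid <- c(11, 39, 67, 431)
  protected <- c(34, 51, 52, 55, 58, 62, 114)   # seen at every timepoint
  mid <- c(5, 20)                                # seen only at 11 min
  fast <- c(1, 2, 3)                             # never seen
  obs <- rbind(
    expand.grid(chain = "A", resno = protected, timepoint = grid),
    expand.grid(chain = "A", resno = mid, timepoint = 11))
  residues <- data.frame(chain = "A", resno = c(protected, mid, fast))
  cls <- hd_protection(obs, timepoints = grid, residues = residues)
  expect_equal(cls$class[match(protected, cls$resno)],
               rep(">=431min", length(protected)))
  expect_equal(cls$class[match(mid, cls$resno)], rep(">=11min", 2L))
  expect_equal(cls$class[match(fast, cls$resno)], rep("fast(<11min)", 3L))
  # round trip: the set protected at 11 min equals the generating list
  seen11 <- cls$resno[!is.na(cls$last_seen)]
  expect_setequal(seen11, c(protected, mid))

  # non-prefix-closed set: warned, classified by latest
  holey <- data.frame(chain = "A", resno = 7L, timepoint = c(11, 431))
  expect_warning(h <- hd_protection(holey, timepoints = grid), "prefix")
  expect_equal(h$class, ">=431min")
})

test_that("hetNOE ratios classify rigidity with strict thresholds and scale invariance", {
  r <- het_noe(c(1, -0.2, 0.5, 0.8, 0), c(1, 1, 1, 1, 1))
  expect_equal(r$noe, c(1, -0.2, 0.5, 0.8, 0))
  expect_equal(r$class, c("rigid", "flexible", "intermediate", "rigid",
                          "intermediate"))
  # scaling both intensities changes nothing
  r2 <- het_noe(7 * c(1, -0.2, 0.5, 0.8, 0), 7 * rep(1, 5))
  expect_equal(r2$class, r$class)
  # undefined ratio flagged
  u <- het_noe(1, 0)
  expect_true(u$undefined)
  expect_true(is.na(u$noe))
})

test_that("region classification collapses runs and recovers a rigid core", {
  # alternating classes never reach min_run 3
  alt <- classify_regions("A", 1:10, rep(c("a", "b"), 5L), min_run = 3L)
  expect_equal(nrow(alt), 0L)
  # a 16-residue run is one region
  one <- classify_regions("A", 1:16, rep("slightly_positive", 16L), min_run = 3L)
  expect_equal(nrow(one), 1L)
  expect_equal(one$length, 16L)

  # synthetic hetNOE profile: rigid core 27-95, flexible tails
  resno <- 1:120
  noe <- ifelse(resno >= 27 & resno <= 95, 0.8, -0.3)
  cls <- het_noe(noe, rep(1, 120L), chain = "A", resno = resno)
  reg <- classify_regions(cls$chain, cls$resno, cls$class, min_run = 5L)
  rigid <- reg[reg$class == "rigid", ]
  expect_equal(c(rigid$start, rigid$end), c(27L, 95L))
})

test_that("Ser/Thr neighbour flag marks amides at risk of relayed-NOE artifacts", {
  resname <- c("ALA", "SER", "LEU", "GLY", "THR", "LYS")
  flag <- flag_st_neighbors("A", 1:6, resname)
  expect_equal(flag, c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  # chain boundaries are respected
  flag2 <- flag_st_neighbors(c("A", "B"), c(1, 2), c("SER", "ALA"))
  expect_equal(flag2, c(FALSE, FALSE))
})
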