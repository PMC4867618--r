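test_that("chi2 shift agreement matches hand arithmetic and a brute-force sum", {
  obs <- shift_table(data.frame(chain = "A", resno = 1L, resname = "ALA",
                                atom = "CA", shift = 52.5, sd = NA_real_))
  pred_same <- shift_table(data.frame(chain = "A", resno = 1L, resname = "ALA",
                                      atom = "CA", shift = 52.5, sd = 0.4))
  expect_equal(chi2_shift_agreement(pred_same, obs)$chi2, 0)

  # one matched value off by two sigma -> chi2 = 4
  pred2 <- pred_same; pred2$shift <- 52.5 + 2 * 0.4
  expect_equal(chi2_shift_agreement(pred2, obs)$chi2, 4)

  # 50-key random tables vs an explicit loop
  set.seed(21)
  n <- 50L
  keys <- data.frame(chain = "A", resno = rep(1:25, each = 2L),
                     resname = "ALA", atom = rep(c("CA", "CB"), 25L))
  obs_big <- shift_table(transform(keys, shift = stats::rnorm(n, 50, 5),
                                   sd = NA_real_))
  pred_big <- shift_table(transform(keys, shift = stats::rnorm(n, 50, 5),
                                    sd = stats::runif(n, 0.1, 1)))
  got <- chi2_shift_agreement(pred_big, obs_big)
  manual <- 0
  for (i in seq_len(n)) {
    j <- which(obs_big$resno == pred_big$resno[i] & obs_big$atom == pred_big$atom[i])
    manual <- manual + ((pred_big$shift[i] - obs_big$shift[j]) / pred_big$sd[i])^2
  }
  expect_equal(got$chi2, manual)
  expect_equal(got$n_matched, n)

  # disjoint keys -> error; missing sigma -> error
  obs_b <- obs; obs_b$resno <- 99L
  expect_error(chi2_shift_agreement(pred_same, obs_b), "no shared")
  bad <- pred_same; bad$sd <- NA_real_
  expect_error(chi2_shift_agreement(bad, obs), "uncertainty")
})

test_that("rescoring is the weighted sum of energy and chi2", {
  expect_equal(rescore(-100, 40, 0.25), -90)
  expect_equal(rescore(-100, 40, 0), -100)
  expect_equal(rescore(-100, 0, 0.25), -100)
  expect_equal(rescore(c(-10, -20), c(4, 8)), c(-9, -18))
  expect_error(rescore(-10, 4, c = -1))
})

test_that("two-stage selection matches the enumerate-and-sort oracle on random pools", {
  for (seed in 1:100) {
    st <- simulate_score_table(30L, seed = seed)
    got <- select_core_models(st$table, st$ensemble)
    expect_identical(got$selected, selection_oracle(st$table, st$ensemble))
  }
})

test_that("selection invariants: row order, consistent rankings, monotonicity, ties", {
  st <- simulate_score_table(40L, seed = 11L)
  base <- select_core_models(st$table, st$ensemble)

  # invariant to input row order
  perm <- st$table[sample(nrow(st$table)), ]
  expect_identical(select_core_models(perm, st$ensemble)$selected, base$selected)

  # when energy ranking equals rmsd ranking, result is the 10 lowest e_cs
  # (noise levels spaced by x1.5 so realized rmsd ordering matches the law)
  st2 <- simulate_score_table(
    30L, seed = 3L,
    energy_law = function(n) data.frame(e_rosetta = seq_len(n), chi2 = 0),
    rmsd_law = function(n) 0.05 * 1.5^seq_len(n))
  got2 <- select_core_models(st2$table, st2$ensemble)
  expect_true(all(diff(got2$table$rmsd_to_ref[order(got2$table$e_cs)]) >= 0))
  low10 <- st2$table$model_id[order(st2$table$e_cs)][1:10]
  expect_setequal(got2$selected, low10)

  # decreasing a selected model's e_cs never drops it from the selection
  pick <- base$selected[5L]
  tweaked <- st$table
  tweaked$e_cs[tweaked$model_id == pick] <- min(tweaked$e_cs) - 10
  expect_true(pick %in% select_core_models(tweaked, st$ensemble)$selected)

  # all-equal energies: tie-break by model id, deterministic
  st3 <- simulate_score_table(
    25L, seed = 8L,
    energy_law = function(n) data.frame(e_rosetta = rep(-50, n), chi2 = 0))
  got3a <- select_core_models(st3$table, st3$ensemble)
  got3b <- select_core_models(st3$table[rev(seq_len(25L)), ], st3$ensemble)
  expect_identical(got3a$selected, got3b$selected)
  expect_equal(got3a$reference, sort(st3$table$model_id)[1L])

  # guard rails
  expect_error(select_core_models(st$table[1:10, ], st$ensemble), "at least")
  expect_error(select_core_models(st$table, st$ensemble, n_energy = 20L,
                                  n_final = 25L), "n_final")
})

test_that("tail-model choice is the chi2 argmin with lexicographic ties", {
  expect_equal(select_tail_model(c(m1 = 400, m2 = 350, m3 = 520)), "m2")
  expect_equal(select_tail_model(c(only = 12)), "only")
  expect_equal(select_tail_model(c(m2 = 100, m1 = 100)), "m1")
  expect_error(select_tail_model(numeric()), "no candidates")
})

test_that("the lookup predictor plugs into the chi2 stage", {
  obs <- shift_table(data.frame(chain = "A", resno = 1:5, resname = "ALA",
                                atom = "CA", shift = 52.5, sd = NA_real_))
  t1 <- obs; t1$sd <- 0.3                      # perfect agreement
  t2 <- obs; t2$sd <- 0.3; t2$shift <- t2$shift + 0.6  # 2 sigma off each
  pred <- lookup_predictor(list(a = t1, b = t2))
  chi <- vapply(c(a = "a", b = "b"),
                function(id) chi2_shift_agreement(pred(id), obs)$chi2, 0)
  expect_equal(unname(chi), c(0, 5 * 4))
  expect_equal(select_tail_model(chi), "a")
  expect_error(pred("missing"), "no predicted shifts")
})
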