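# Independent oracles used across the suite.

# Reference DSSP via mdtraj (python), full (non-simplified) codes;
# blanks mapped to C to match assign_ss()'s coil label.
dssp_oracle <- function(model) {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  write_ensemble(as_ensemble(list(model)), tf)
  out <- system2("python", c("-c", shQuote(sprintf(
    "import mdtraj as md; t = md.load(%s); print(''.join(md.compute_dssp(t, simplified=False)[0]))",
    dQuote(tf, q = FALSE)))), stdout = TRUE, stderr = FALSE)
  gsub(" ", "C", out[length(out)])
}

# Horn's quaternion method for optimal rigid superposition (independent of
# the svd-based Kabsch implementation under test).
quaternion_fit_rmsd <- function(X, Y) {
  X0 <- sweep(X, 2, colMeans(X)); Y0 <- sweep(Y, 2, colMeans(Y))
  S <- crossprod(X0, Y0)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  sqrt(mean(rowSums((X0 %*% t(R) - Y0)^2)))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Brute-force enumerate-and-sort selection oracle: full sort by (e_cs, id),
# reference = first; Ca-RMSD of every model to it; filter to the n_energy
# lowest-energy, then sort by (rmsd, e_cs, id) and take n_final.
selection_oracle <- function(table, ensemble, n_energy = 20L, n_final = 10L) {
  ord <- order(table$e_cs, table$model_id)
  ref <- ens_model(ensemble, table$model_id[ord[1]])
  rmsd <- sapply(table$model_id, function(id) {
    if (id == table$model_id[ord[1]]) 0
    else superpose(ens_model(ensemble, id), ref)$rmsd
  })
  pool <- ord[seq_len(n_energy)]
  pool <- pool[order(rmsd[pool], table$e_cs[pool], table$model_id[pool])]
  table$model_id[pool[seq_len(n_final)]]
}

# beta-hairpin fixture: two strands joined by a type I' turn
hairpin_model <- function(n_strand = 7) {
  phi <- c(rep(-120, n_strand), 60, 90, rep(-120, n_strand))
  psi <- c(rep(140, n_strand), 30, 0, rep(140, n_strand))
  build_peptide_dihedrals(strrep("A", 2 * n_strand + 2), phi, psi)
}

apply_rigid <- function(model, R, t) {
  co <- as.matrix(model[, c("x", "y", "z")]) %*% t(R)
  model$x <- co[, 1] + t[1]; model$y <- co[, 2] + t[2]; model$z <- co[, 3] + t[3]
  model
}
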