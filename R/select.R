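#' Chi-squared agreement between predicted and observed chemical shifts
#'
#' `chi2 = sum over matched (chain, residue, atom) keys of
#' ((d_pred - d_obs) / sigma)^2`, where `sigma` is the per-value
#' uncertainty of the prediction. Keys present in only one table are
#' ignored; the matched count is reported.
#'
#' @param pred predicted shifts: a [shift_table()] whose `sd` column holds
#'   the prediction uncertainty (must be > 0 for every row).
#' @param obs observed shifts: a [shift_table()].
#' @return list with `chi2` and `n_matched`.
#' @export
chi2_shift_agreement <- function(pred, obs) {
  if (any(is.na(pred$sd)) || any(pred$sd <= 0))
    stop("every predicted shift needs an uncertainty > 0")
  kp <- paste(pred$chain, pred$resno, pred$atom)
  ko <- paste(obs$chain, obs$resno, obs$atom)
  common <- intersect(kp, ko)
  if (length(common) == 0L) stop("no shared (chain, residue, atom) keys")
  ip <- match(common, kp); io <- match(common, ko)
  z <- (pred$shift[ip] - obs$shift[io]) / pred$sd[ip]
  list(chi2 = sum(z^2), n_matched = length(common))
}

#' Rescore a model energy with the chemical-shift penalty
#'
#' `e_cs = e_rosetta + c * chi2`, the shift-augmented energy used to rank
#' candidate models; the weighting factor defaults to 0.25.
#'
#' @param e_rosetta all-atom model energy (vectorized).
#' @param chi2 shift-agreement statistic (vectorized).
#' @param c weighting factor, >= 0 (default 0.25).
#' @export
rescore <- function(e_rosetta, chi2, c = 0.25) {
  stopifnot(c >= 0, all(chi2 >= 0 | is.na(chi2)))
  e_rosetta + c * chi2
}

#' Build a score table for a model pool
#'
#' @param model_id character vector.
#' @param e_rosetta,chi2 numeric vectors.
#' @param c weighting factor passed to [rescore()].
#' @return data.frame of class `score_table` with `model_id`, `e_rosetta`,
#'   `chi2`, `e_cs` and an empty `rmsd_to_ref` column.
#' @export
score_table <- function(model_id, e_rosetta, chi2, c = 0.25) {
  stopifnot(length(model_id) == length(e_rosetta),
            length(chi2) == length(e_rosetta))
  if (anyDuplicated(model_id)) stop("duplicate model ids")
  out <- data.frame(model_id = as.character(model_id),
                    e_rosetta = e_rosetta, chi2 = chi2,
                    e_cs = rescore(e_rosetta, chi2, c),
                    rmsd_to_ref = NA_real_, stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Two-stage model selection by energy then RMSD
#'
#' Implements the rescored-energy selection: (a) find the single model with
#' the lowest shift-rescored energy `e_cs`; (b) compute the Ca-RMSD of
#' every model to it (after Kabsch superposition, optionally restricted to
#' a core selection); (c) keep the `n_energy` models with lowest `e_cs`;
#' (d) of those, return the `n_final` with lowest RMSD. Ties are broken by
#' `e_cs` then `model_id` (lexicographic), so the result is deterministic
#' and invariant to input row order.
#'
#' @param table a [score_table()].
#' @param ensemble an [nmr_ensemble()] whose `model_ids` cover the table.
#' @param selection optional core residue selection for the RMSD.
#' @param n_energy size of the low-energy pool (default 20).
#' @param n_final number of models returned (default 10).
#' @return list with `selected` (ordered model ids), `reference` (the
#'   lowest-`e_cs` model id) and `table` (the score table with
#'   `rmsd_to_ref` filled in).
#' @export
select_core_models <- function(table, ensemble, selection = NULL,
                               n_energy = 20L, n_final = 10L) {
  if (n_final > n_energy) stop("n_final must be <= n_energy")
  if (nrow(table) < n_energy)
    stop("need at least ", n_energy, " models, got ", nrow(table))
  miss <- setdiff(table$model_id, ensemble$model_ids)
  if (length(miss)) stop("models missing from ensemble: ",
                         paste(utils::head(miss, 3L), collapse = ", "))
  ord <- order(table$e_cs, table$model_id)
  ref_id <- table$model_id[ord[1L]]
  ref_model <- ens_model(ensemble, ref_id)
  rmsd <- vapply(table$model_id, function(id) {
    if (id == ref_id) return(0)
    superpose(ens_model(ensemble, id), ref_model, selection)$rmsd
  }, 0)
  table$rmsd_to_ref <- as.numeric(rmsd)
  pool <- table[ord[seq_len(n_energy)], , drop = FALSE]
  pick <- pool[order(pool$rmsd_to_ref, pool$e_cs, pool$model_id), , drop = FALSE]
  list(selected = pick$model_id[seq_len(n_final)],
       reference = ref_id, table = table)
}

#' Pick the tail model with the best shift agreement
#'
#' Argmin of chi2 over candidate models; ties go to the lexicographically
#' lowest model id.
#'
#' @param chi2_by_candidate named numeric vector (names = model ids).
#' @return the winning model id.
#' @export
select_tail_model <- function(chi2_by_candidate) {
  if (length(chi2_by_candidate) == 0L) stop("no candidates")
  if (is.null(names(chi2_by_candidate)) || any(!nzchar(names(chi2_by_candidate))))
    stop("candidates must be named by model id")
  ids <- names(chi2_by_candidate)
  ord <- order(chi2_by_candidate, ids)
  ids[ord[1L]]
}

#' Table-lookup shift predictor
#'
#' A trivial pluggable predictor: returns the same pre-computed shift table
#' (with uncertainties) for any model, optionally perturbed by a per-model
#' offset column. Real applications plug in any function
#' `model -> shift_table`; this one exists so the selection stage can be
#' exercised without an external shift-prediction program.
#'
#' @param tables either one [shift_table()] used for every model, or a
#'   named list of tables keyed by model id.
#' @return function `(model_id) -> shift_table`.
#' @export
lookup_predictor <- function(tables) {
  function(model_id) {
    if (is.data.frame(tables)) return(tables)
    t <- tables[[model_id]]
    if (is.null(t)) stop("no predicted shifts for model ", model_id)
    t
  }
}
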