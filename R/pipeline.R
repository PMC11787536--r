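#' End-to-end real-versus-shuffled task-independence comparison
#'
#' Convenience wrapper over the full detection pipeline for one session:
#' build the image + omission aligned tensor, fit an ensemble of CP models
#' to the real tensor, fit one CP model to each of `n_iterations`
#' independently within-condition-shuffled tensors, and compare the
#' omission-specific neuronal weight magnitudes between the two ensembles
#' with [compare_real_vs_shuffled_weights()].
#'
#' @param session A `neural_session`.
#' @param n_iterations Ensemble size for both the real and shuffled fits
#'   (the full-scale convention is 100; reduced ensembles of ~20 retain the
#'   qualitative behavior at a fraction of the cost).
#' @param rank CP rank (default 5).
#' @param seed Master seed for fits and shuffles.
#' @param window Alignment window in seconds (default `c(-0.3, 0.6)`).
#' @param specificity Condition whose components are compared.
#' @param max_iter,tol Per-fit ALS settings. Ensembles default to a
#'   reduced-cost configuration (200 sweeps, `tol = 1e-5`): the ensemble
#'   already averages over initializations, and the moderate tolerance's
#'   early stopping also limits how far individual fits chase incoherent
#'   trial-to-trial variance.
#' @param ... Further arguments passed to [fit_cp_als()].
#' @return The [compare_real_vs_shuffled_weights()] result, with the
#'   aligned tensor and ensembles attached (`$tensor`, `$real_models`,
#'   `$shuffled_models`).
#' @export
run_shuffle_comparison <- function(session, n_iterations = 20L, rank = 5L,
                                   seed = 1L, window = c(-0.3, 0.6),
                                   specificity = "omission",
                                   max_iter = 200L, tol = 1e-5, ...) {
  tens <- align_to_events(session, c("image", "omission"), window,
                          trace = "rate")
  real <- run_tca_ensemble(tens, n_iterations = n_iterations, rank = rank,
                           seed = derive_seed(seed, 7L),
                           max_iter = max_iter, tol = tol, ...)
  shuf <- lapply(seq_len(n_iterations), function(j) {
    st <- shuffle_within_condition(tens, seed = derive_seed(seed, 500L + j))
    fit_cp_als(st, rank = rank, n_restarts = 1L,
               seed = derive_seed(seed, 900L + j),
               max_iter = max_iter, tol = tol, ...)
  })
  out <- compare_real_vs_shuffled_weights(real, shuf, tens$trial_labels,
                                          tens$neurons,
                                          specificity = specificity)
  out$tensor <- tens
  out$real_models <- real
  out$shuffled_models <- shuf
  out
}

#' Did the comparison detect task-independent structure?
#'
#' The detection rule used in validation studies: the pooled rank-sum test
#' is significant at `alpha` *and* the real ensemble's mean weight exceeds
#' the shuffled ensemble's (a drop after shuffling is the signature of
#' shared task-independent structure; see the methods vignette for why the
#' direction matters at small scale).
#'
#' @param comparison Result of [run_shuffle_comparison()] or
#'   [compare_real_vs_shuffled_weights()].
#' @param alpha Significance level (default 0.01).
#' @return Logical.
#' @export
shuffle_comparison_detects <- function(comparison, alpha = 0.01) {
  o <- comparison$overall
  isTRUE(o$p_pooled < alpha && o$direction > 0)
}
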