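#' Remove the stimulus-locked signal from an aligned tensor
#'
#' For each neuron, frame and stimulus category, subtracts the across-trial
#' mean response of that category from each of its trials. Categories are the
#' image identities (8 per session under the default task configuration);
#' omission trials form their own category. What remains is the trial-to-trial
#' "noise" used for noise-correlation analysis. Categories with a single
#' trial get an exactly-zero residual and are counted in
#' `attr(, "n_single_trial_categories")`.
#'
#' @param tensor An `aligned_tensor` whose labels carry `image_identity`.
#' @return An `aligned_tensor` of residuals.
#' @export
remove_stimulus_signal <- function(tensor) {
  stopifnot(inherits(tensor, "aligned_tensor"))
  lab <- tensor$trial_labels
  category <- ifelse(lab$condition == "omission", "omission",
                     paste0("img", lab$image_identity))
  out <- tensor
  n_single <- 0L
  for (cat_ in unique(category)) {
    idx <- which(category == cat_)
    if (length(idx) == 1L) n_single <- n_single + 1L
    m <- apply(tensor$data[, , idx, drop = FALSE], c(1L, 2L), mean)
    out$data[, , idx] <- tensor$data[, , idx, drop = FALSE] -
      as.vector(m)  # recycles over the trial slab
  }
  attr(out, "n_single_trial_categories") <- n_single
  out
}

# Expand a pair specification into a 2-column index matrix.
resolve_pairs <- function(pairs, n_neurons) {
  if (is.null(pairs)) {
    pairs <- t(utils::combn(n_neurons, 2L))
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L || any(pairs < 1L) || any(pairs > n_neurons)) {
    stop("`pairs` must be a 2-column matrix of valid neuron indices",
         call. = FALSE)
  }
  storage.mode(pairs) <- "integer"
  pairs
}

#' Frame-wise Spearman correlations across trials for neuron pairs
#'
#' At every frame offset, computes the Spearman rank correlation between the
#' two neurons' values across trials (average ranks for ties). A pair-frame
#' where either neuron is constant across trials has no defined rank
#' correlation; it is returned as `NA` and counted in
#' `attr(, "n_degenerate")`.
#'
#' @param residuals An `aligned_tensor`, normally the output of
#'   [remove_stimulus_signal()].
#' @param pairs 2-column matrix of neuron index pairs, or `NULL` for all
#'   pairs.
#' @param min_trials Minimum number of trials required (default 5).
#' @return Matrix pairs x offsets of correlation coefficients, with
#'   attributes `offsets` and `pairs`.
#' @export
framewise_pair_correlation <- function(residuals, pairs = NULL,
                                       min_trials = 5L) {
  stopifnot(inherits(residuals, "aligned_tensor"))
  d <- dim(residuals$data)
  if (d[3L] < min_trials) {
    stop(sprintf("need at least %d trials, got %d", min_trials, d[3L]),
         call. = FALSE)
  }
  pairs <- resolve_pairs(pairs, d[1L])
  cc <- matrix(NA_real_, nrow(pairs), d[2L])
  n_degenerate <- 0L
  for (f in seq_len(d[2L])) {
    slab <- residuals$data[, f, , drop = TRUE]   # neurons x trials
    if (d[1L] == 1L) slab <- matrix(slab, nrow = 1L)
    rk <- t(apply(slab, 1L, rank))               # average ranks
    const <- apply(slab, 1L, function(v) max(v) - min(v) == 0)
    cmat <- suppressWarnings(stats::cor(t(rk)))
    vals <- cmat[pairs]
    bad <- const[pairs[, 1L]] | const[pairs[, 2L]]
    vals[bad] <- NA_real_
    n_degenerate <- n_degenerate + sum(bad)
    cc[, f] <- vals
  }
  attr(cc, "offsets") <- residuals$offsets
  attr(cc, "pairs") <- pairs
  attr(cc, "n_degenerate") <- n_degenerate
  cc
}

#' Trial-shuffle null distribution for pairwise correlations
#'
#' Each neuron's trial order is permuted independently, destroying any
#' across-neuron trial-to-trial covariation while preserving every neuron's
#' marginal distribution; the frame-wise Spearman correlations are then
#' recomputed. Repeating this (50 times by default, per the shuffle-control
#' convention) yields a null distribution per pair and frame that controls
#' for activity-level effects on correlations.
#'
#' @param residuals An `aligned_tensor` of signal-removed traces.
#' @param pairs 2-column matrix of neuron index pairs, or `NULL` for all.
#' @param n_shuffles Number of shuffle repetitions (default 50).
#' @param seed Integer seed.
#' @param min_trials Minimum trials, as in [framewise_pair_correlation()].
#' @return Array pairs x offsets x shuffles with attribute `offsets`.
#' @export
correlation_shuffle_null <- function(residuals, pairs = NULL,
                                     n_shuffles = 50L, seed = 1L,
                                     min_trials = 5L) {
  stopifnot(inherits(residuals, "aligned_tensor"))
  d <- dim(residuals$data)
  pairs <- resolve_pairs(pairs, d[1L])
  out <- array(NA_real_, c(nrow(pairs), d[2L], n_shuffles))
  shuf <- residuals
  for (s in seq_len(n_shuffles)) {
    perm <- with_seed(derive_seed(seed, s), {
      replicate(d[1L], sample.int(d[3L]))   # trials x neurons
    })
    for (i in seq_len(d[1L])) {
      shuf$data[i, , ] <- residuals$data[i, , perm[, i]]
    }
    out[, , s] <- framewise_pair_correlation(shuf, pairs,
                                             min_trials = min_trials)
  }
  attr(out, "offsets") <- residuals$offsets
  attr(out, "pairs") <- pairs
  out
}

# Windows on the omission-aligned [-1, 2] s frame grid used for the cc
# quantification. Image onsets sit at multiples of the stimulus period
# around the omission at 0.
cc_quant_windows <- function(cell_class, offsets, period = 0.75) {
  image_onsets <- setdiff(
    seq(ceiling(min(offsets) / period) * period, max(offsets), by = period),
    0
  )
  img_win <- if (cell_class == "VIP") c(-0.25, 0.25) else c(0, 0.5)
  list(image_onsets = image_onsets, img_win = img_win,
       vip_baseline = cell_class == "VIP", omission_win = c(0, 0.75))
}

#' Quantify correlation changes around images and omissions
#'
#' From a pairs x offsets matrix of omission-aligned frame-wise correlations,
#' computes three scalars per pair: `image_cc` (mean over 500 ms after each
#' surrounding image flash for excitatory/SST, or -250..+250 ms around image
#' onsets for VIP), `omission_cc` (mean over 750 ms after the omission) and
#' `baseline_cc` (mean over the frame immediately preceding each image flash
#' for excitatory/SST, or the frame 250 ms before it for VIP), plus the
#' deltas `image_cc - baseline_cc` and `omission_cc - baseline_cc`.
#'
#' @param ccframes Pairs x offsets matrix from
#'   [framewise_pair_correlation()] (must carry the `offsets` attribute, or
#'   pass `offsets`).
#' @param cell_class `"excitatory"`, `"SST"` or `"VIP"`.
#' @param offsets Frame offsets (s); default taken from `ccframes`.
#' @param period Stimulus period in seconds (default 0.75).
#' @return data.frame, one row per pair: `baseline_cc`, `image_cc`,
#'   `omission_cc`, `delta_image`, `delta_omission`.
#' @export
quantify_cc_change <- function(ccframes, cell_class,
                               offsets = attr(ccframes, "offsets"),
                               period = 0.75) {
  if (is.null(offsets)) stop("`offsets` required", call. = FALSE)
  if (length(offsets) != ncol(ccframes)) {
    stop("`offsets` length must match ncol(ccframes)", call. = FALSE)
  }
  w <- cc_quant_windows(cell_class, offsets, period)
  eps <- 1e-9
  in_any_img <- rep(FALSE, length(offsets))
  base_sel <- rep(FALSE, length(offsets))
  for (on in w$image_onsets) {
    in_any_img <- in_any_img |
      (offsets >= on + w$img_win[1L] - eps & offsets < on + w$img_win[2L] - eps)
    # baseline: the frame immediately preceding the flash (excitatory/SST),
    # or the latest frame at/before 250 ms earlier than the flash (VIP)
    cand <- if (w$vip_baseline) {
      which(offsets <= on - 0.25 + eps)
    } else {
      which(offsets < on - eps)
    }
    if (length(cand) > 0) base_sel[max(cand)] <- TRUE
  }
  om_sel <- offsets >= w$omission_win[1L] - eps &
    offsets < w$omission_win[2L] - eps
  if (!any(in_any_img) || !any(base_sel) || !any(om_sel)) {
    stop("ccframes do not cover the quantification windows", call. = FALSE)
  }
  rm_ <- function(m, sel) rowMeans(m[, sel, drop = FALSE], na.rm = TRUE)
  out <- data.frame(
    baseline_cc = rm_(ccframes, base_sel),
    image_cc = rm_(ccframes, in_any_img),
    omission_cc = rm_(ccframes, om_sel)
  )
  out$delta_image <- out$image_cc - out$baseline_cc
  out$delta_omission <- out$omission_cc - out$baseline_cc
  out
}

#' Aggregate pair-level correlation scalars into plane-pair summaries
#'
#' Groups neuron pairs by their plane pair (area x depth against area x
#' depth), reports mean and SEM of each quantified scalar, and two p-value
#' flavors for the omission delta: the median across pairs of the asymptotic
#' Spearman test p (recomputed from each pair's `omission_cc` and the trial
#' count), and a two-sided one-sample t-test of the shuffle-null
#' distribution of plane-level mean `omission_cc` against the real value.
#'
#' @param cc_scalars data.frame from [quantify_cc_change()].
#' @param pairs 2-column neuron-pair index matrix matching `cc_scalars` rows.
#' @param neurons Neuron metadata with `plane_id`, `area`, `depth`.
#' @param null_cc Optional pairs x offsets x shuffles array from
#'   [correlation_shuffle_null()]; when given, the shuffle-based t-test p is
#'   computed per plane pair from the same quantification windows.
#' @param cell_class Cell class for the shuffle-null quantification windows.
#' @param n_trials Trial count behind each correlation (for the asymptotic
#'   Spearman p).
#' @return data.frame, one row per plane pair, with means, SEMs, pair
#'   counts and p-values (`NA` where a flavor is unavailable).
#' @export
aggregate_plane_pairs <- function(cc_scalars, pairs, neurons,
                                  null_cc = NULL, cell_class = "VIP",
                                  n_trials = NULL) {
  stopifnot(nrow(cc_scalars) == nrow(pairs))
  p1 <- neurons$plane_id[pairs[, 1L]]
  p2 <- neurons$plane_id[pairs[, 2L]]
  key <- paste(pmin(p1, p2), pmax(p1, p2), sep = "-")
  plane_desc <- function(pid) {
    i <- match(pid, neurons$plane_id)
    sprintf("%s-%.0f", neurons$area[i], neurons$depth[i])
  }
  rows <- lapply(unique(key), function(k) {
    idx <- which(key == k)
    pid <- as.integer(strsplit(k, "-")[[1L]])
    r <- data.frame(
      plane_a = plane_desc(pid[1L]), plane_b = plane_desc(pid[2L]),
      n_pairs = length(idx)
    )
    for (col in names(cc_scalars)) {
      v <- cc_scalars[[col]][idx]
      r[[paste0(col, "_mean")]] <- mean(v, na.rm = TRUE)
      r[[paste0(col, "_sem")]] <- sem(v)
    }
    # flavor 1: asymptotic Spearman p per pair (t approximation), median
    r$p_spearman <- if (!is.null(n_trials) && n_trials > 3) {
      ps <- vapply(cc_scalars$omission_cc[idx], function(rho) {
        if (!is.finite(rho) || abs(rho) >= 1) return(NA_real_)
        tstat <- rho * sqrt((n_trials - 2) / (1 - rho^2))
        2 * stats::pt(-abs(tstat), df = n_trials - 2)
      }, numeric(1))
      stats::median(ps, na.rm = TRUE)
    } else NA_real_
    # flavor 2: plane-level shuffle-null t-test on omission_cc
    r$p_shuffle_t <- if (!is.null(null_cc)) {
      offs <- attr(null_cc, "offsets")
      nulls <- vapply(seq_len(dim(null_cc)[3L]), function(s) {
        ms <- null_cc[, , s, drop = FALSE]
        dim(ms) <- dim(null_cc)[1:2]
        q <- quantify_cc_change(ms[idx, , drop = FALSE],
                                cell_class, offsets = offs)
        mean(q$omission_cc, na.rm = TRUE)
      }, numeric(1))
      one_sample_t_vs_null(mean(cc_scalars$omission_cc[idx], na.rm = TRUE),
                           nulls)$p.value
    } else NA_real_
    r
  })
  do.call(rbind, rows)
}
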