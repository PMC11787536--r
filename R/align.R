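#' Construct an event-aligned neurons x time x trials tensor
#'
#' Offset 0 is the first imaging frame with timestamp at or after the event
#' onset; the window is half-open `[start, end)` in seconds and is realized
#' as the frame offsets `j / frame_rate` with `start <= j/frame_rate < end`.
#' Events whose window would run past either recording edge are dropped (the
#' count is recorded in `attr(, "n_truncated")`). Because the stimulus is
#' strictly periodic, omission-aligned windows are simultaneously aligned on
#' the surrounding image flashes.
#'
#' @param session A `neural_session`.
#' @param event_kind Character vector of event kinds to align on: any of
#'   `"image"`, `"omission"`, `"change"`. Use `c("image", "omission")` to
#'   build the concatenated image + omission trial tensor used for the CP
#'   decomposition.
#' @param window Length-2 numeric `(start, end)` in seconds relative to
#'   onset; default `c(-0.3, 0.6)`.
#' @param trace Which trace variant to align: `"rate"` (event-rate traces,
#'   used for the tensor decomposition) or `"dff"` (slow filtered variant,
#'   used for correlation and population-average analyses).
#' @param include_changes If `FALSE` (default) change flashes are excluded
#'   from the `"image"` pool; the repeated-familiar-image analyses never use
#'   them.
#' @return An `aligned_tensor`: list with `data` (neurons x offsets x
#'   trials), `offsets` (s), `trial_labels` (data.frame: `condition`,
#'   `image_identity`, `onset_time`, `wheel`, `pupil`) and `neurons` (the
#'   session neuron table).
#' @export
align_to_events <- function(session, event_kind = "omission",
                            window = c(-0.3, 0.6),
                            trace = c("rate", "dff"),
                            include_changes = FALSE) {
  stopifnot(inherits(session, "neural_session"))
  trace <- match.arg(trace)
  if (length(window) != 2L || window[1L] >= window[2L]) {
    stop("`window` must be (start, end) with start < end", call. = FALSE)
  }
  kinds <- match.arg(event_kind, c("image", "omission", "change"),
                     several.ok = TRUE)
  sched <- session$schedule
  sel <- sched$event_kind %in% kinds
  if (!include_changes) sel <- sel & sched$event_kind != "change"
  if (!any(sel)) {
    stop(sprintf("no events of kind %s in schedule",
                 paste(kinds, collapse = "/")), call. = FALSE)
  }
  dt <- 1 / session$provenance$config$frame_rate
  eps <- 1e-9
  j_lo <- ceiling(window[1L] / dt - eps)
  j_hi <- ceiling(window[2L] / dt - eps) - 1L
  offs <- seq.int(j_lo, j_hi)
  n_frames <- length(session$frame_times)
  onset_frame <- findInterval(sched$onset_time[sel] - eps,
                              session$frame_times) + 1L
  ok <- onset_frame + j_lo >= 1L & onset_frame + j_hi <= n_frames
  n_truncated <- sum(!ok)
  if (!any(ok)) stop("no usable events: all windows truncated by recording edges",
                     call. = FALSE)
  ev <- which(sel)[ok]
  onset_frame <- onset_frame[ok]
  mat <- if (trace == "rate") session$traces else session$traces_dff
  n_neurons <- nrow(mat)
  data <- array(NA_real_, c(n_neurons, length(offs), length(ev)))
  for (k in seq_along(ev)) {
    data[, , k] <- mat[, onset_frame[k] + offs, drop = FALSE]
  }
  cond <- ifelse(sched$event_kind[ev] == "omission", "omission", "image")
  labels <- data.frame(
    condition = cond,
    image_identity = sched$image_identity[ev],
    onset_time = sched$onset_time[ev],
    wheel = session$trial_behavior$wheel[ev],
    pupil = session$trial_behavior$pupil[ev]
  )
  out <- structure(
    list(data = data, offsets = offs * dt, trial_labels = labels,
         neurons = session$neurons),
    class = "aligned_tensor"
  )
  attr(out, "n_truncated") <- n_truncated
  out
}

#' Low-level aligned-tensor constructor
#'
#' Builds an `aligned_tensor` directly from an array and labels, for
#' simulation studies or tests that do not start from a full session.
#'
#' @param data neurons x offsets x trials numeric array.
#' @param offsets Numeric vector of time offsets (s), uniformly spaced.
#' @param trial_labels data.frame with at least a `condition` column
#'   (`"image"`/`"omission"`), one row per trial.
#' @param neurons Optional neuron metadata data.frame (default: bare ids).
#' @return An `aligned_tensor`.
#' @export
aligned_tensor <- function(data, offsets, trial_labels,
                           neurons = data.frame(id = seq_len(dim(data)[1L]))) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (length(offsets) != dim(data)[2L]) {
    stop("`offsets` length must match dim(data)[2]", call. = FALSE)
  }
  if (nrow(trial_labels) != dim(data)[3L]) {
    stop("`trial_labels` rows must match dim(data)[3]", call. = FALSE)
  }
  if (anyNA(data)) stop("aligned tensor must not contain NA", call. = FALSE)
  structure(
    list(data = data, offsets = offsets,
         trial_labels = as.data.frame(trial_labels), neurons = neurons),
    class = "aligned_tensor"
  )
}

#' @export
print.aligned_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<aligned_tensor> %d neurons x %d offsets [%.3g, %.3g] s x %d trials (%s)\n",
    d[1L], d[2L], min(x$offsets), max(x$offsets), d[3L],
    paste(sprintf("%d %s", table(x$trial_labels$condition),
                  names(table(x$trial_labels$condition))), collapse = ", ")
  ))
  invisible(x)
}

#' Normalize each neuron's aligned traces by its baseline standard deviation
#'
#' The baseline SD is taken across all frames in `baseline_window` and all
#' trials, separately per neuron; the neuron's whole aligned trace is divided
#' by it. Neurons with zero baseline SD are dropped and counted in
#' `attr(, "n_excluded")`.
#'
#' @param tensor An `aligned_tensor`.
#' @param baseline_window Length-2 numeric `(start, end)` s, half-open,
#'   within the tensor's offsets.
#' @return A normalized `aligned_tensor`.
#' @export
normalize_to_baseline_sd <- function(tensor, baseline_window = c(-0.3, 0)) {
  stopifnot(inherits(tensor, "aligned_tensor"))
  sel <- tensor$offsets >= baseline_window[1L] - 1e-9 &
    tensor$offsets < baseline_window[2L] - 1e-9
  if (!any(sel)) stop("baseline window contains no frames", call. = FALSE)
  n <- dim(tensor$data)[1L]
  sds <- vapply(seq_len(n),
                function(i) stats::sd(as.vector(tensor$data[i, sel, ])),
                numeric(1))
  keep <- is.finite(sds) & sds > 0
  out <- tensor
  out$data <- tensor$data[keep, , , drop = FALSE] / sds[keep]
  out$neurons <- tensor$neurons[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Two-stage population trace summary
#'
#' Stage 1 takes the median across trials for each neuron and offset (robust
#' to outlier trials); stage 2 averages across neurons, reporting mean and
#' standard error per offset.
#'
#' @param tensor An `aligned_tensor` with at least 2 trials.
#' @return data.frame with columns `offset`, `mean`, `sem` (`sem` is `NA`
#'   for a single neuron).
#' @export
population_trace_summary <- function(tensor) {
  stopifnot(inherits(tensor, "aligned_tensor"))
  if (dim(tensor$data)[3L] < 2L) stop("need >= 2 trials", call. = FALSE)
  med <- apply(tensor$data, c(1L, 2L), stats::median)  # neurons x offsets
  data.frame(
    offset = tensor$offsets,
    mean = colMeans(med),
    sem = apply(med, 2L, sem)
  )
}

# Class/event-specific quantification windows (seconds, half-open).
# Images: 350 ms post-onset for excitatory/SST; [-250, 100) ms for VIP to
# capture the anticipatory ramp. Omissions: 500 ms post-onset for all classes.
evoked_window_rule <- function(cell_class, event_kind) {
  if (event_kind == "omission") return(c(0, 0.5))
  if (cell_class == "VIP") c(-0.25, 0.1) else c(0, 0.35)
}

#' Quantify evoked responses with class/event-specific windows
#'
#' Each neuron's response is the mean, over the rule-table window, of its
#' across-trial mean trace (the trial mean, not the median, is used for
#' scalar quantification). Windows: 350 ms after onset for excitatory and
#' SST images, -250 to +100 ms for VIP images (anticipatory ramp), and
#' 500 ms after onset for omissions in all classes.
#'
#' @param tensor An `aligned_tensor`.
#' @param cell_class `"excitatory"`, `"SST"` or `"VIP"`.
#' @param event_kind `"image"` or `"omission"`.
#' @return List with `per_neuron` (numeric vector), `session` (mean over
#'   neurons), `window` and `n_trials`.
#' @export
quantify_evoked_response <- function(tensor,
                                     cell_class = tensor$neurons$cell_class[1L],
                                     event_kind = c("image", "omission")) {
  stopifnot(inherits(tensor, "aligned_tensor"))
  event_kind <- match.arg(event_kind)
  win <- evoked_window_rule(cell_class, event_kind)
  eps <- 1e-9
  dt <- stats::median(diff(tensor$offsets))
  sel <- tensor$offsets >= win[1L] - eps & tensor$offsets < win[2L] - eps
  covered <- tensor$offsets[1L] <= win[1L] + eps &&
    tensor$offsets[length(tensor$offsets)] >= win[2L] - dt - eps
  if (!any(sel) || !covered) {
    stop(sprintf("tensor window does not cover required window [%g, %g) s",
                 win[1L], win[2L]), call. = FALSE)
  }
  trials <- tensor$trial_labels$condition == event_kind
  if (!any(trials)) {
    stop(sprintf("no %s trials in tensor", event_kind), call. = FALSE)
  }
  mean_trace <- apply(tensor$data[, , trials, drop = FALSE], c(1L, 2L), mean)
  per_neuron <- rowMeans(mean_trace[, sel, drop = FALSE])
  list(per_neuron = per_neuron, session = mean(per_neuron),
       window = win, n_trials = sum(trials))
}
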