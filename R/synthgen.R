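#' Generate a periodic image/omission stimulus schedule
#'
#' Flash onsets are laid out on a strict grid with period
#' `image_duration + gray_duration` (0.75 s by default). Each flash is an
#' image-identity change with probability `change_prob`; each *non-change*
#' flash is independently replaced by a gray screen (an omission) with
#' probability `omission_prob`. Image identity is constant between changes.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A `stimulus_schedule`: data.frame with columns `onset_time` (s),
#'   `event_kind` (`"image"`, `"omission"`, `"change"`), `image_identity`
#'   (`NA` for omissions) and `flash_index`.
#' @export
generate_schedule <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  period <- config$image_duration + config$gray_duration
  onsets <- seq(period, config$session_duration - period, by = period)
  n <- length(onsets)
  if (n < 1L) stop("session too short for one flash", call. = FALSE)
  with_seed(seed, {
    kind <- character(n)
    identity <- integer(n)
    cur <- sample.int(config$n_image_identities, 1L)
    is_change <- stats::runif(n) < config$change_prob
    is_change[1L] <- FALSE
    u_omit <- stats::runif(n)
    for (i in seq_len(n)) {
      if (is_change[i]) {
        kind[i] <- "change"
        if (config$n_image_identities > 1L) {
          cur <- sample(setdiff(seq_len(config$n_image_identities), cur), 1L)
        }
        identity[i] <- cur
      } else if (u_omit[i] < config$omission_prob) {
        kind[i] <- "omission"
        identity[i] <- NA_integer_
      } else {
        kind[i] <- "image"
        identity[i] <- cur
      }
    }
    structure(
      data.frame(
        onset_time = onsets,
        event_kind = kind,
        image_identity = identity,
        flash_index = seq_len(n)
      ),
      class = c("stimulus_schedule", "data.frame")
    )
  })
}

#' Generate autocorrelated behavior traces
#'
#' Running speed and pupil area are simulated as independent stationary AR(1)
#' processes (lag-1 coefficient `ar`, stationary standard deviation `sd`,
#' mean `mean`), rectified at zero. With `sd = 0` the trace is constant at
#' the process mean.
#'
#' @param config A [generator_config()].
#' @param schedule The session's [generate_schedule()] output (part of the
#'   operation contract; the processes themselves are stimulus-independent).
#' @param seed Integer seed.
#' @return List with numeric vectors `running_speed` (cm/s) and `pupil_area`
#'   (a.u.), one value per imaging frame.
#' @export
generate_behavior <- function(config, schedule, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  n_frames <- n_session_frames(config)
  with_seed(seed, {
    list(
      running_speed = ar1_trace(n_frames, config$behavior$wheel),
      pupil_area = ar1_trace(n_frames, config$behavior$pupil)
    )
  })
}

# Stationary AR(1) with given mean, stationary sd and lag-1 coefficient,
# rectified at zero.
ar1_trace <- function(n, p) {
  if (p$sd == 0) return(rep(p$mean, n))
  innov_sd <- p$sd * sqrt(max(0, 1 - p$ar^2))
  x <- numeric(n)
  x[1L] <- stats::rnorm(1L, 0, p$sd)
  eps <- stats::rnorm(n, 0, innov_sd)
  for (t in seq_len(n)[-1L]) x[t] <- p$ar * x[t - 1L] + eps[t]
  pmax(0, p$mean + x)
}

n_session_frames <- function(config) {
  as.integer(floor(config$session_duration * config$frame_rate))
}

# Evaluate the event kernel for one cell class and event kind on the frame
# grid. Returns list(offsets = integer frame offsets relative to the first
# frame at/after onset, values = kernel values).
event_kernel <- function(cell_class, event_kind, dt, kp) {
  if (cell_class %in% c("excitatory", "SST")) {
    if (event_kind %in% c("image", "change")) {
      t <- seq(0, 0.6, by = dt)
      v <- exp(-t / kp$decay_tau) - exp(-t / kp$rise_tau)
      if (max(v) > 0) v <- v / max(v)
      return(list(offsets = seq_along(t) - 1L, values = kp$image_amp * v))
    }
    # omission: sustained box (slightly negative for SST, ~0 for excitatory)
    t <- seq(0, kp$omission_dur - dt / 2, by = dt)
    return(list(offsets = seq_along(t) - 1L,
                values = rep(kp$omission_amp, length(t))))
  }
  # VIP: anticipatory linear ramp before every flash ...
  n_pre <- max(1L, round(kp$ramp_dur / dt))
  ramp_off <- seq.int(-n_pre, -1L)
  ramp_val <- kp$ramp_amp * seq_len(n_pre) / n_pre
  if (event_kind %in% c("image", "change")) {
    # ... suppressed by the image
    n_post <- max(1L, round(kp$image_supp_dur / dt))
    post_off <- seq.int(0L, n_post - 1L)
    post_val <- kp$image_amp * exp(-(post_off * dt) / 0.15)
  } else {
    # ... further activated when the image is omitted
    n_post <- max(1L, round(kp$omission_dur / dt))
    post_off <- seq.int(0L, n_post - 1L)
    tt <- post_off * dt
    post_val <- kp$omission_amp * pmin(1, tt / 0.15) * exp(-pmax(0, tt - 0.3) / 0.3)
  }
  list(offsets = c(ramp_off, post_off), values = c(ramp_val, post_val))
}

#' Generate a full synthetic session
#'
#' Builds the stimulus schedule and behavior traces, then synthesizes
#' per-neuron event-rate traces as
#' `baseline + sum over events of kernel(class, kind) * trial gain + noise`,
#' rectified at zero. The trial gain is
#' `1 + latent_strength * l(trial) * loading(neuron)` where `l(trial)` is a
#' standard-normal shared latent, linearly coupled to the z-scored per-trial
#' mean running speed and pupil area through `latent_behavior_coupling`, and
#' neuron loadings are drawn once per session from a half-normal. A slow
#' dF/F-like variant of each trace is produced by causal exponential
#' filtering (time constant `dff_tau`).
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (defaults to `config$seed`). Identical
#'   config + seed reproduces the session bit-for-bit.
#' @return A `neural_session`: list with elements `traces`
#'   (neurons x frames event-rate matrix), `traces_dff` (filtered variant),
#'   `frame_times` (s), `neurons` (data.frame: `id`, `cell_class`, `area`,
#'   `depth`, `plane_id`), `schedule`, `behavior`, `latent` (list with the
#'   per-trial latent and per-neuron loadings, for diagnostics), and
#'   `provenance` (config + seed).
#' @export
#' @examples
#' cfg <- generator_config(n_neurons_per_plane = 4, session_duration = 40,
#'                         seed = 7)
#' s <- generate_session(cfg)
#' dim(s$traces)
generate_session <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  schedule <- generate_schedule(config, seed = derive_seed(seed, 1L))
  behavior <- generate_behavior(config, schedule,
                                seed = derive_seed(seed, 2L))
  dt <- 1 / config$frame_rate
  n_frames <- n_session_frames(config)
  frame_times <- (seq_len(n_frames) - 1L) * dt
  n_planes <- nrow(config$planes)
  n_neurons <- config$n_neurons_per_plane * n_planes
  neurons <- data.frame(
    id = seq_len(n_neurons),
    cell_class = config$cell_class,
    area = rep(config$planes$area, each = config$n_neurons_per_plane),
    depth = rep(config$planes$depth, each = config$n_neurons_per_plane),
    plane_id = rep(seq_len(n_planes), each = config$n_neurons_per_plane)
  )

  # per-trial behavior summaries (mean over one stimulus period from onset)
  period <- config$image_duration + config$gray_duration
  n_events <- nrow(schedule)
  wheel_tr <- trial_behavior_summary(behavior$running_speed, frame_times,
                                     schedule$onset_time, period)
  pupil_tr <- trial_behavior_summary(behavior$pupil_area, frame_times,
                                     schedule$onset_time, period)

  out <- with_seed(derive_seed(seed, 3L), {
    loadings <- abs(stats::rnorm(n_neurons))
    lat <- stats::rnorm(n_events) +
      config$latent_behavior_coupling[["wheel"]] * zscore(wheel_tr) +
      config$latent_behavior_coupling[["pupil"]] * zscore(pupil_tr)
    gains <- 1 + config$latent_strength * outer(loadings, lat)  # N x events

    traces <- matrix(config$baseline_rate, n_neurons, n_frames)
    kinds <- unique(schedule$event_kind)
    kernels <- lapply(stats::setNames(kinds, kinds), function(k) {
      event_kernel(config$cell_class, k, dt, config$response_kernel_params)
    })
    onset_frame <- findInterval(schedule$onset_time - 1e-9, frame_times) + 1L
    for (e in seq_len(n_events)) {
      ker <- kernels[[schedule$event_kind[e]]]
      idx <- onset_frame[e] + ker$offsets
      keep <- idx >= 1L & idx <= n_frames
      if (!any(keep)) next
      traces[, idx[keep]] <- traces[, idx[keep]] +
        gains[, e] %o% ker$values[keep]
    }
    if (config$noise_sd > 0) {
      traces <- traces + matrix(stats::rnorm(length(traces), 0,
                                             config$noise_sd),
                                n_neurons, n_frames)
    }
    traces <- pmax(traces, 0)
    list(traces = traces, loadings = loadings, latent = lat)
  })

  dff <- t(apply(out$traces, 1L, function(x) {
    as.numeric(stats::filter(x * dt, exp(-dt / config$dff_tau),
                             method = "recursive"))
  }))

  structure(
    list(
      traces = out$traces,
      traces_dff = dff,
      frame_times = frame_times,
      neurons = neurons,
      schedule = schedule,
      behavior = behavior,
      trial_behavior = data.frame(wheel = wheel_tr, pupil = pupil_tr),
      latent = list(values = out$latent, loadings = out$loadings),
      provenance = list(config = config, seed = as.integer(seed))
    ),
    class = "neural_session"
  )
}

# Mean of a per-frame trace over [onset, onset + width) for each onset.
trial_behavior_summary <- function(trace, frame_times, onsets, width) {
  vapply(onsets, function(o) {
    sel <- frame_times >= o - 1e-9 & frame_times < o + width - 1e-9
    if (!any(sel)) return(NA_real_)
    mean(trace[sel])
  }, numeric(1))
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' @export
print.neural_session <- function(x, ...) {
  cat(sprintf(
    "<neural_session> %d neurons (%s) x %d frames @ %g Hz, %d flashes (%d omissions)\n",
    nrow(x$traces), x$neurons$cell_class[1L], ncol(x$traces),
    x$provenance$config$frame_rate, nrow(x$schedule),
    sum(x$schedule$event_kind == "omission")
  ))
  invisible(x)
}
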