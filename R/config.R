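#' Build a synthetic-session generator configuration
#'
#' Bundles and validates every parameter of the synthetic session generator:
#' the stimulus schedule (a periodic stream of 250 ms natural-image flashes
#' separated by 500 ms gray screens, with a pseudo-random fraction of
#' non-change flashes omitted), the imaged population (cell class, areas,
#' depths), per-class temporal response kernels, the shared trial-varying
#' task-independent latent and its optional coupling to running speed and
#' pupil area, and the noise model.
#'
#' @param n_neurons_per_plane Neurons simulated in each imaging plane.
#' @param cell_class One of `"excitatory"`, `"SST"`, `"VIP"`. Determines the
#'   default response kernels: excitatory and SST neurons are image-evoked
#'   (difference-of-exponentials), VIP neurons show an anticipatory ramp
#'   starting 250 ms before each flash that grows into a sustained activation
#'   when the image is omitted and is suppressed when it is shown.
#' @param planes `data.frame` with columns `area` (`"V1"` or `"LM"`) and
#'   `depth` (micrometres; the study design uses approximately 100, 200, 300
#'   and 375). One row per simultaneously imaged plane.
#' @param frame_rate Imaging frame rate in Hz.
#' @param session_duration Total recording duration in seconds.
#' @param image_duration,gray_duration Flash and inter-flash gray durations in
#'   seconds; their sum is the stimulus period (default 0.75 s).
#' @param omission_prob Probability that a non-change flash is replaced by a
#'   gray screen (an "omission"); default 0.05.
#' @param n_image_identities Number of distinct familiar images (default 8).
#' @param change_prob Probability that a flash switches image identity (a
#'   "change" flash; excluded from the repeated-image trial pool downstream).
#' @param response_kernel_params Named list of kernel amplitudes and time
#'   constants; missing entries are filled from
#'   [default_kernel_params()] for `cell_class`.
#' @param latent_strength Standard-deviation-scale gain of the shared
#'   trial-varying task-independent latent; `0` disables it.
#' @param latent_behavior_coupling Named numeric vector
#'   `c(wheel = ..., pupil = ...)`: linear coefficients coupling the latent to
#'   the z-scored per-trial mean running speed and pupil area.
#' @param noise_sd Standard deviation of the independent per-frame, per-neuron
#'   Gaussian noise (trace units).
#' @param baseline_rate Constant baseline event rate added to every trace.
#' @param dff_tau Time constant (s) of the causal exponential filter used to
#'   derive the slow, dF/F-like trace variant from the event-rate trace.
#' @param behavior Nested list of AR(1) parameters for the two behavior
#'   traces: `wheel = list(mean, sd, ar)` (cm/s) and
#'   `pupil = list(mean, sd, ar)` (a.u.). `sd` is the stationary standard
#'   deviation and `ar` the lag-1 coefficient.
#' @param seed Integer seed; identical config + seed yields a bit-identical
#'   session.
#'
#' @return An object of class `generator_config` (a validated named list).
#' @seealso [generate_session()], [fixture_config()]
#' @export
#' @examples
#' cfg <- generator_config(n_neurons_per_plane = 5, session_duration = 30)
#' cfg$omission_prob
generator_config <- function(n_neurons_per_plane = 25,
                             cell_class = c("VIP", "excitatory", "SST"),
                             planes = data.frame(
                               area = c("V1", "V1"),
                               depth = c(100, 300)
                             ),
                             frame_rate = 10,
                             session_duration = 330,
                             image_duration = 0.25,
                             gray_duration = 0.50,
                             omission_prob = 0.05,
                             n_image_identities = 8,
                             change_prob = 0.03,
                             response_kernel_params = list(),
                             latent_strength = 0,
                             latent_behavior_coupling = c(wheel = 0, pupil = 0),
                             noise_sd = 0.1,
                             baseline_rate = 0.1,
                             dff_tau = 0.4,
                             behavior = list(
                               wheel = list(mean = 5, sd = 3, ar = 0.97),
                               pupil = list(mean = 300, sd = 40, ar = 0.98)
                             ),
                             seed = 1L) {
  cell_class <- match.arg(cell_class)
  check_pos(frame_rate, "frame_rate")
  check_pos(session_duration, "session_duration")
  check_pos(image_duration, "image_duration")
  check_pos(gray_duration, "gray_duration")
  check_prob(omission_prob, "omission_prob")
  check_prob(change_prob, "change_prob")
  if (!is.numeric(n_neurons_per_plane) || n_neurons_per_plane < 1) {
    stop("`n_neurons_per_plane` must be >= 1", call. = FALSE)
  }
  if (!is.data.frame(planes) || !all(c("area", "depth") %in% names(planes)) ||
      nrow(planes) < 1) {
    stop("`planes` must be a data.frame with columns `area` and `depth`",
         call. = FALSE)
  }
  if (!all(planes$area %in% c("V1", "LM"))) {
    stop("plane `area` must be \"V1\" or \"LM\"", call. = FALSE)
  }
  if (n_image_identities < 1) stop("`n_image_identities` must be >= 1",
                                   call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!all(c("wheel", "pupil") %in% names(latent_behavior_coupling))) {
    stop("`latent_behavior_coupling` needs named entries `wheel` and `pupil`",
         call. = FALSE)
  }
  period <- image_duration + gray_duration
  if (session_duration < 2 * period) {
    stop("`session_duration` too short for a single flash cycle",
         call. = FALSE)
  }
  kp <- utils::modifyList(default_kernel_params(cell_class),
                          response_kernel_params)
  cfg <- list(
    n_neurons_per_plane = as.integer(n_neurons_per_plane),
    cell_class = cell_class,
    planes = planes,
    frame_rate = frame_rate,
    session_duration = session_duration,
    image_duration = image_duration,
    gray_duration = gray_duration,
    omission_prob = omission_prob,
    n_image_identities = as.integer(n_image_identities),
    change_prob = change_prob,
    response_kernel_params = kp,
    latent_strength = latent_strength,
    latent_behavior_coupling = latent_behavior_coupling,
    noise_sd = noise_sd,
    baseline_rate = baseline_rate,
    dff_tau = dff_tau,
    behavior = behavior,
    seed = as.integer(seed)
  )
  structure(cfg, class = "generator_config")
}

#' Default response-kernel parameters per cell class
#'
#' Amplitudes are in event-rate trace units, time constants in seconds.
#' Excitatory and SST kernels are difference-of-exponentials image responses;
#' SST carries a small sustained negative omission response. VIP kernels
#' combine a linear anticipatory ramp over the 250 ms before every flash with
#' post-onset suppression on images and a larger sustained activation on
#' omissions.
#'
#' @param cell_class `"excitatory"`, `"SST"` or `"VIP"`.
#' @return Named list of kernel parameters.
#' @export
default_kernel_params <- function(cell_class) {
  switch(cell_class,
    excitatory = list(
      image_amp = 0.5, rise_tau = 0.04, decay_tau = 0.12,
      omission_amp = 0.0, omission_dur = 0.4
    ),
    SST = list(
      image_amp = 0.7, rise_tau = 0.05, decay_tau = 0.15,
      omission_amp = -0.05, omission_dur = 0.4
    ),
    VIP = list(
      ramp_amp = 0.15, ramp_dur = 0.25,
      image_amp = -0.08, image_supp_dur = 0.3,
      omission_amp = 0.5, omission_dur = 0.5
    ),
    stop(sprintf("unknown cell_class \"%s\"", cell_class), call. = FALSE)
  )
}

#' Read a generator configuration from a YAML or JSON file
#'
#' Scalars found in the file override [generator_config()] defaults; the
#' result is validated by `generator_config()` itself.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$planes)) raw$planes <- as.data.frame(raw$planes)
  if (!is.null(raw$latent_behavior_coupling)) {
    raw$latent_behavior_coupling <- unlist(raw$latent_behavior_coupling)
  }
  do.call(generator_config, raw)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> %d %s neurons/plane in %d plane(s), %.0f s @ %g Hz\n",
    x$n_neurons_per_plane, x$cell_class, nrow(x$planes),
    x$session_duration, x$frame_rate
  ))
  cat(sprintf(
    "  omission_prob %.3g, change_prob %.3g, latent_strength %.3g, seed %d\n",
    x$omission_prob, x$change_prob, x$latent_strength, x$seed
  ))
  invisible(x)
}
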