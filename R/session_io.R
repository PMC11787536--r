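SESSION_FORMAT_VERSION <- "1.0"

#' Write a session to an HDF5 container
#'
#' Layout: datasets `/traces`, `/traces_dff`, `/frame_times`, groups
#' `/neurons`, `/schedule`, `/behavior`, `/trial_behavior`, `/latent` holding
#' parallel arrays, and root attributes `format_version`, `seed` and
#' `config_json` (the full generator configuration serialized as JSON) for
#' provenance.
#'
#' @param session A `neural_session`.
#' @param path Destination file path.
#' @param overwrite Overwrite an existing file? Default `FALSE` (refuse).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, overwrite = FALSE) {
  stopifnot(inherits(session, "neural_session"))
  rep_ <- validate_session(session)
  if (length(rep_) > 0) {
    stop("refusing to write invalid session: ",
         paste(rep_, collapse = "; "), call. = FALSE)
  }
  if (file.exists(path) && !overwrite) {
    stop(sprintf("file already exists (use overwrite = TRUE): %s", path),
         call. = FALSE)
  }
  if (!dir.exists(dirname(path))) {
    stop(sprintf("parent directory does not exist: %s", dirname(path)),
         call. = FALSE)
  }
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(session$traces, path, "traces")
  rhdf5::h5write(session$traces_dff, path, "traces_dff")
  rhdf5::h5write(session$frame_times, path, "frame_times")
  rhdf5::h5createGroup(path, "neurons")
  for (col in names(session$neurons)) {
    rhdf5::h5write(session$neurons[[col]], path, paste0("neurons/", col))
  }
  rhdf5::h5createGroup(path, "schedule")
  sched <- session$schedule
  rhdf5::h5write(sched$onset_time, path, "schedule/onset_time")
  rhdf5::h5write(sched$event_kind, path, "schedule/event_kind")
  # NA identities (omissions) encoded as -1
  ident <- sched$image_identity
  ident[is.na(ident)] <- -1L
  rhdf5::h5write(as.integer(ident), path, "schedule/image_identity")
  rhdf5::h5write(sched$flash_index, path, "schedule/flash_index")
  rhdf5::h5createGroup(path, "behavior")
  rhdf5::h5write(session$behavior$running_speed, path,
                 "behavior/running_speed")
  rhdf5::h5write(session$behavior$pupil_area, path, "behavior/pupil_area")
  rhdf5::h5createGroup(path, "trial_behavior")
  rhdf5::h5write(session$trial_behavior$wheel, path, "trial_behavior/wheel")
  rhdf5::h5write(session$trial_behavior$pupil, path, "trial_behavior/pupil")
  rhdf5::h5createGroup(path, "latent")
  rhdf5::h5write(session$latent$values, path, "latent/values")
  rhdf5::h5write(session$latent$loadings, path, "latent/loadings")

  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(SESSION_FORMAT_VERSION, fid, "format_version")
  rhdf5::h5writeAttribute(as.integer(session$provenance$seed), fid, "seed")
  rhdf5::h5writeAttribute(
    as.character(jsonlite::toJSON(unclass(session$provenance$config),
                                  auto_unbox = TRUE, digits = NA)),
    fid, "config_json"
  )
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a session from an HDF5 container
#'
#' Validates the file layout and format version and rebuilds the
#' `neural_session`, including provenance (config + seed).
#'
#' @param path Path written by [write_session()].
#' @return A `neural_session`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("session file not found: %s", path), call. = FALSE)
  }
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  attrs <- rhdf5::h5readAttributes(path, "/")
  ver <- attrs$format_version
  if (is.null(ver)) stop("missing format_version attribute", call. = FALSE)
  if (package_version(ver)$major >
      package_version(SESSION_FORMAT_VERSION)$major) {
    stop(sprintf("unsupported session format version %s (reader supports %s)",
                 ver, SESSION_FORMAT_VERSION), call. = FALSE)
  }
  contents <- rhdf5::h5ls(path)
  need <- c("traces", "traces_dff", "frame_times", "neurons", "schedule",
            "behavior")
  missing <- setdiff(need, contents$name[contents$group == "/"])
  if (length(missing) > 0) {
    stop(sprintf("corrupted session file: missing group(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  rd <- function(name) rhdf5::h5read(path, name)
  ident <- as.integer(rd("schedule/image_identity"))
  ident[ident < 0L] <- NA_integer_
  schedule <- structure(
    data.frame(
      onset_time = as.numeric(rd("schedule/onset_time")),
      event_kind = as.character(rd("schedule/event_kind")),
      image_identity = ident,
      flash_index = as.integer(rd("schedule/flash_index"))
    ),
    class = c("stimulus_schedule", "data.frame")
  )
  cfg_raw <- jsonlite::fromJSON(attrs$config_json)
  cfg_raw$planes <- as.data.frame(cfg_raw$planes)
  lb <- unlist(cfg_raw$latent_behavior_coupling)
  if (is.null(names(lb))) names(lb) <- c("wheel", "pupil")
  cfg_raw$latent_behavior_coupling <- lb
  cfg_raw$seed <- as.integer(cfg_raw$seed)
  config <- do.call(generator_config, cfg_raw[setdiff(
    names(cfg_raw), character(0))])
  session <- structure(
    list(
      traces = as.matrix(rd("traces")),
      traces_dff = as.matrix(rd("traces_dff")),
      frame_times = as.numeric(rd("frame_times")),
      neurons = data.frame(
        id = as.integer(rd("neurons/id")),
        cell_class = as.character(rd("neurons/cell_class")),
        area = as.character(rd("neurons/area")),
        depth = as.numeric(rd("neurons/depth")),
        plane_id = as.integer(rd("neurons/plane_id"))
      ),
      schedule = schedule,
      behavior = list(
        running_speed = as.numeric(rd("behavior/running_speed")),
        pupil_area = as.numeric(rd("behavior/pupil_area"))
      ),
      trial_behavior = data.frame(
        wheel = as.numeric(rd("trial_behavior/wheel")),
        pupil = as.numeric(rd("trial_behavior/pupil"))
      ),
      latent = list(
        values = as.numeric(rd("latent/values")),
        loadings = as.numeric(rd("latent/loadings"))
      ),
      provenance = list(config = config, seed = as.integer(attrs$seed))
    ),
    class = "neural_session"
  )
  rep_ <- validate_session(session)
  if (length(rep_) > 0) {
    stop("invalid session file: ", paste(rep_, collapse = "; "),
         call. = FALSE)
  }
  session
}

#' Validate a session's internal consistency
#'
#' Checks finiteness of traces, shape agreement between traces, frame times,
#' neuron table and behavior traces, uniform frame spacing, and schedule
#' ordering/periodicity.
#'
#' @param session A `neural_session` (or a structurally similar list).
#' @return Character vector of violated invariants; empty if valid.
#' @export
validate_session <- function(session) {
  out <- character(0)
  flag <- function(msg) out <<- c(out, msg)
  if (!is.matrix(session$traces) || !all(is.finite(session$traces))) {
    flag("traces contain non-finite values or are not a matrix")
  }
  if (ncol(session$traces) != length(session$frame_times)) {
    flag("trace frame count does not match frame_times length")
  }
  if (nrow(session$traces) != nrow(session$neurons)) {
    flag("trace neuron count does not match neuron table")
  }
  if (anyDuplicated(session$neurons$id)) flag("neuron ids are not unique")
  ft <- session$frame_times
  if (length(ft) >= 3L) {
    d <- diff(ft)
    if (max(d) - min(d) > 1e-9 * mean(d)) {
      flag("frame_times are not uniformly spaced")
    }
  }
  if (length(session$behavior$running_speed) != length(ft) ||
      length(session$behavior$pupil_area) != length(ft)) {
    flag("behavior traces do not match frame count")
  }
  on_t <- session$schedule$onset_time
  if (is.unsorted(on_t, strictly = TRUE)) {
    flag("schedule onset times are not strictly increasing")
  }
  if (length(on_t) >= 3L) {
    iv <- diff(on_t)
    if (max(iv) - min(iv) > 1e-9) {
      flag("schedule inter-onset intervals are not constant")
    }
  }
  ek <- session$schedule$event_kind
  if (!all(ek %in% c("image", "omission", "change"))) {
    flag("unknown event kinds in schedule")
  }
  if (any(ek %in% c("image", "change") &
          is.na(session$schedule$image_identity))) {
    flag("image/change events missing image identity")
  }
  out
}
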