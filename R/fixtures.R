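# Named, seeded study-condition fixtures used throughout the test suite and
# the reproduction script. Parameter choices are fixed properties of the
# simulated study conditions, documented in the methods vignette.

#' Configuration for a named fixture session
#'
#' Three canonical fixtures, all 50 VIP neurons in two V1 planes (100 and
#' 300 um, one superficial and one deep):
#' \describe{
#'   \item{`"null"`}{no task-independent latent (`latent_strength = 0`);
#'     trials differ only by independent noise.}
#'   \item{`"latent"`}{a strong shared latent (`latent_strength = 0.5`),
#'     uncoupled to behavior.}
#'   \item{`"behavior-coupled"`}{the same latent coupled to behavior with a
#'     wheel-dominant weighting (`wheel = 1.0`, `pupil = 0.35`), a longer
#'     session to accumulate omission trials.}
#' }
#'
#' @param name Fixture name.
#' @param seed Integer seed stored in the config.
#' @return A [generator_config()].
#' @export
fixture_config <- function(name = c("null", "latent", "behavior-coupled"),
                           seed = 20L) {
  name <- match.arg(name)
  base <- list(
    n_neurons_per_plane = 25,
    cell_class = "VIP",
    planes = data.frame(area = c("V1", "V1"), depth = c(100, 300)),
    session_duration = 330,
    seed = seed
  )
  extra <- switch(name,
    "null" = list(latent_strength = 0),
    "latent" = list(latent_strength = 0.5),
    "behavior-coupled" = list(
      latent_strength = 0.5,
      latent_behavior_coupling = c(wheel = 1.0, pupil = 0.35),
      session_duration = 570
    )
  )
  do.call(generator_config, utils::modifyList(base, extra))
}

#' Write the canonical fixture suite to disk
#'
#' Generates the `"null"`, `"latent"` and `"behavior-coupled"` fixture
#' sessions from their recorded seeds and writes them as HDF5 session files
#' (`null.h5`, `latent.h5`, `behavior-coupled.h5`). Regeneration is
#' bit-identical.
#'
#' @param out_dir Writable directory (created if missing).
#' @param seed Base seed for the suite.
#' @return Named character vector of file paths.
#' @export
make_fixture_suite <- function(out_dir, seed = 20L) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop(sprintf("cannot create fixture directory: %s", out_dir),
           call. = FALSE)
    }
  }
  names_ <- c("null", "latent", "behavior-coupled")
  paths <- vapply(names_, function(nm) {
    cfg <- fixture_config(nm, seed = seed)
    s <- generate_session(cfg)
    p <- file.path(out_dir, paste0(nm, ".h5"))
    tryCatch(write_session(s, p, overwrite = TRUE),
             error = function(e) {
               stop(sprintf("failed writing fixture %s to %s: %s", nm, p,
                            conditionMessage(e)), call. = FALSE)
             })
    p
  }, character(1))
  stats::setNames(paths, names_)
}
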