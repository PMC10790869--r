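# End-to-end single-subject simulation: behavior -> triggers -> fNIRS ->
# preprocessing -> decision-phase epochs.

#' Simulate one subject end-to-end
#'
#' Runs the full synthetic pipeline for a single participant: a driving
#' experiment ([generate_experiment()]), a two-wavelength fNIRS recording
#' locked to the accelerator-press triggers ([simulate_fnirs_recording()]),
#' canonical preprocessing ([preprocess_recording()]), and decision-phase
#' epoching ([extract_epochs()]).
#'
#' Intersections whose driver never accepts a gap produce no trigger and
#' contribute no epoch, exactly as in the real task.
#'
#' @param blocks,intersections_per_block Protocol (default 10 x 10).
#' @param profile A [driver_profile()].
#' @param traffic A [traffic_config()].
#' @param fnirs An [fnirs_sim_config()].
#' @param window Decision-phase window in seconds (default `c(-2, 2)`).
#' @param seed Optional integer seed.
#' @param ... Passed to [preprocess_recording()].
#' @return A list: `events`, `triggers`, `recording`, `hb`, `quality`,
#'   `epochs`.
#' @export
simulate_subject <- function(blocks = 10L, intersections_per_block = 10L,
                             profile = driver_profile(),
                             traffic = traffic_config(),
                             fnirs = fnirs_sim_config(),
                             window = c(-2, 2), seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  beh <- generate_experiment(
    blocks, intersections_per_block,
    profile = profile, cfg = traffic
  )
  rec <- simulate_fnirs_recording(beh$triggers, fnirs)
  pre <- preprocess_recording(rec, ...)
  epochs <- extract_epochs(pre$hb, window = window)
  list(
    events = beh$events, triggers = beh$triggers, recording = rec,
    hb = pre$hb, quality = pre$quality, epochs = epochs
  )
}
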