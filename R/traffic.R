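# Synthetic oncoming-traffic streams and Bernoulli gap-acceptance drivers.
# An intersection presents a stream of 8-10 oncoming cars; each car closes a
# gap (seconds since the previous car passed). The first 4-6 gaps are small
# (1-3 s); exactly one large gap (3.5-6 s) is placed at position 5-10; 15% of
# cars are autonomous vehicles (AV), the rest human-driven (HV).

#' Traffic-stream configuration
#'
#' Defaults reproduce the study design: 8-10 oncoming cars per intersection,
#' an initial run of 4-6 small gaps drawn uniformly from 1-3 s, a single large
#' gap of 3.5-6 s placed at a position drawn from 5-10, AVs making up 15% of
#' cars, and oncoming traffic at 14 m/s (50.4 km/h).
#'
#' @param n_cars_range Integer pair: total cars per stream.
#' @param small_gap_range Seconds: range of the initial small gaps.
#' @param large_gap_range Seconds: range of the single large gap.
#' @param n_small_cars_range Integer pair: length of the small-gap run.
#' @param large_gap_position_range Integer pair: admissible 1-based position of
#'   the large gap (intersected with positions after the small run and within
#'   the stream).
#' @param av_fraction Probability a car is labelled AV (independent Bernoulli;
#'   a fixed seed gives the reproducible fixed-sequence variant).
#' @param oncoming_speed Oncoming vehicle speed in m/s.
#' @param gap_cap Upper cap on any generated gap, seconds.
#' @param gap_distribution `"uniform"` (ranges as stated) or `"lognormal"`
#'   (field-like lognormal, truncated to the same ranges).
#' @return A list of class `traffic_config`.
#' @export
traffic_config <- function(n_cars_range = c(8L, 10L),
                           small_gap_range = c(1, 3),
                           large_gap_range = c(3.5, 6),
                           n_small_cars_range = c(4L, 6L),
                           large_gap_position_range = c(5L, 10L),
                           av_fraction = 0.15,
                           oncoming_speed = 14,
                           gap_cap = 6,
                           gap_distribution = c("uniform", "lognormal")) {
  gap_distribution <- match.arg(gap_distribution)
  cfg <- list(
    n_cars_range = as.integer(n_cars_range),
    small_gap_range = small_gap_range,
    large_gap_range = large_gap_range,
    n_small_cars_range = as.integer(n_small_cars_range),
    large_gap_position_range = as.integer(large_gap_position_range),
    av_fraction = av_fraction,
    oncoming_speed = oncoming_speed,
    gap_cap = gap_cap,
    gap_distribution = gap_distribution
  )
  for (nm in c(
    "n_cars_range", "small_gap_range", "large_gap_range",
    "n_small_cars_range", "large_gap_position_range"
  )) {
    r <- cfg[[nm]]
    if (length(r) != 2L || r[1] > r[2]) {
      stop(sprintf("`%s` must be an ordered pair", nm), call. = FALSE)
    }
  }
  if (av_fraction < 0 || av_fraction > 1) {
    stop("`av_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (min(small_gap_range) <= 0 || min(large_gap_range) <= 0) {
    stop("gaps must be strictly positive", call. = FALSE)
  }
  structure(cfg, class = "traffic_config")
}

#' Driver gap-acceptance profile
#'
#' Ground-truth psychometric parameters per agent condition for the simulated
#' Bernoulli driver. Defaults use the threshold/width values observed in the
#' study cohort: near-identical thresholds (~3.1 s) but a much narrower
#' acceptance width for AVs (0.65 s) than HVs (4.17 s).
#'
#' @param m_av,w_av,m_hv,w_hv Threshold and width (seconds) per condition.
#' @return A list of class `driver_profile`.
#' @export
driver_profile <- function(m_av = 3.09, w_av = 0.65, m_hv = 3.08, w_hv = 4.17) {
  stopifnot(m_av > 0, w_av > 0, m_hv > 0, w_hv > 0)
  structure(
    list(m_av = m_av, w_av = w_av, m_hv = m_hv, w_hv = w_hv),
    class = "driver_profile"
  )
}

.draw_gap <- function(n, range, cfg) {
  g <- if (cfg$gap_distribution == "lognormal") {
    # field gap-size distributions are lognormal with mode ~2 s; truncate by
    # rejection to the configured range
    out <- numeric(0)
    while (length(out) < n) {
      cand <- rlnorm(n * 4 + 8, meanlog = log(2), sdlog = 0.6)
      out <- c(out, cand[cand >= range[1] & cand <= range[2]])
    }
    out[seq_len(n)]
  } else {
    runif(n, range[1], range[2])
  }
  pmin(g, cfg$gap_cap)
}

#' Generate one oncoming traffic stream
#'
#' Draws the gap-size/agent template for a single intersection: an initial run
#' of small gaps, one large gap at a drawn position, remaining gaps small, and
#' an independent Bernoulli AV label per car.
#'
#' @param cfg A [traffic_config()].
#' @return A tibble with one row per car: `position`, `gap_size` (s),
#'   `agent` (`"AV"`/`"HV"`), `is_large_gap`.
#' @export
generate_traffic_stream <- function(cfg = traffic_config()) {
  stopifnot(inherits(cfg, "traffic_config"))
  n_cars <- sample(seq(cfg$n_cars_range[1], cfg$n_cars_range[2]), 1L)
  n_small <- sample(seq(cfg$n_small_cars_range[1], cfg$n_small_cars_range[2]), 1L)
  n_small <- min(n_small, n_cars - 1L)
  pos_lo <- max(cfg$large_gap_position_range[1], n_small + 1L)
  pos_hi <- min(cfg$large_gap_position_range[2], n_cars)
  if (pos_lo > pos_hi) {
    stop("large-gap position range incompatible with car count", call. = FALSE)
  }
  large_pos <- sample(seq(pos_lo, pos_hi), 1L)
  gaps <- .draw_gap(n_cars, cfg$small_gap_range, cfg)
  gaps[large_pos] <- .draw_gap(1L, cfg$large_gap_range, cfg)
  tibble::tibble(
    position = seq_len(n_cars),
    gap_size = gaps,
    agent = ifelse(runif(n_cars) < cfg$av_fraction, "AV", "HV"),
    is_large_gap = .data$position == large_pos
  )
}

#' Simulate a driver's decisions at one intersection
#'
#' Walks the gaps of a stream in order; each gap is accepted with the
#' psychometric probability of the matching condition ([gap_acceptance_prob()]
#' with the profile's AV or HV parameters). The walk stops at the first
#' accepted gap; if no gap is accepted the driver turns after the last car
#' (all gaps rejected, `turned_after_last` attribute set).
#'
#' @param stream A tibble from [generate_traffic_stream()].
#' @param profile A [driver_profile()].
#' @return `stream` with an added logical `accepted` column (at most one
#'   `TRUE`, and every position before it rejected) and rows truncated is not
#'   performed — all presented gaps up to and including the accepted one are
#'   returned; gaps after an acceptance were never presented and are dropped.
#'   Attribute `turned_after_last` flags the no-acceptance case.
#' @export
simulate_intersection <- function(stream, profile = driver_profile()) {
  stopifnot(nrow(stream) > 0, inherits(profile, "driver_profile"))
  p <- ifelse(
    stream$agent == "AV",
    gap_acceptance_prob(stream$gap_size, profile$m_av, profile$w_av),
    gap_acceptance_prob(stream$gap_size, profile$m_hv, profile$w_hv)
  )
  draws <- runif(nrow(stream)) < p
  first <- which(draws)[1]
  if (is.na(first)) {
    out <- dplyr::mutate(stream, accepted = FALSE)
    attr(out, "turned_after_last") <- TRUE
  } else {
    out <- stream[seq_len(first), , drop = FALSE]
    out$accepted <- c(rep(FALSE, first - 1L), TRUE)
    attr(out, "turned_after_last") <- FALSE
  }
  out
}

#' Simulate a full driving experiment
#'
#' Runs `blocks * intersections_per_block` intersections (default 10 x 10 =
#' 100, the study protocol) through [generate_traffic_stream()] and
#' [simulate_intersection()], laying intersections out in time and emitting
#' one accelerator-press trigger per accepted turn.
#'
#' Within an intersection the gap clock starts when the first car approaches;
#' a car's passage time is the cumulative sum of gaps. The accelerator press
#' for an accepted gap is placed at the moment the leading car of that gap
#' passes the intersection.
#'
#' @param blocks,intersections_per_block Protocol dimensions.
#' @param profile A [driver_profile()].
#' @param cfg A [traffic_config()].
#' @param inter_onset_interval Seconds between successive intersection starts
#'   (default 30 s, matching the study's ~5:30 min blocks of 10 intersections).
#' @return A list with `events` (tibble: `block`, `intersection_id`,
#'   `position`, `gap_size`, `agent`, `accepted`, `t_trigger`, NA when not the
#'   accepted gap) and `triggers` (tibble: `time`, `label`, `block`,
#'   `intersection_id`).
#' @export
generate_experiment <- function(blocks = 10L, intersections_per_block = 10L,
                                profile = driver_profile(),
                                cfg = traffic_config(),
                                inter_onset_interval = 30) {
  stopifnot(blocks >= 1, intersections_per_block >= 1)
  n_int <- blocks * intersections_per_block
  events <- purrr::map(seq_len(n_int), function(i) {
    res <- simulate_intersection(generate_traffic_stream(cfg), profile)
    t0 <- (i - 1) * inter_onset_interval
    res |>
      dplyr::mutate(
        block = ((i - 1L) %/% intersections_per_block) + 1L,
        intersection_id = i,
        # time the leading car of this gap passes (gap k opens at the passage
        # of car k-1; car 0 is the stream onset)
        t_gap_open = t0 + cumsum(.data$gap_size) - .data$gap_size,
        t_trigger = ifelse(.data$accepted, .data$t_gap_open, NA_real_)
      )
  }) |>
    purrr::list_rbind() |>
    dplyr::select(
      "block", "intersection_id", "position", "gap_size", "agent",
      "accepted", "t_trigger"
    )
  triggers <- events |>
    dplyr::filter(.data$accepted) |>
    dplyr::transmute(
      time = .data$t_trigger, label = .data$agent,
      block = .data$block, intersection_id = .data$intersection_id
    )
  list(events = events, triggers = triggers)
}

#' Write / read gap-acceptance event tables
#'
#' Plain-CSV serialisation of the event table produced by
#' [generate_experiment()] (or recorded equivalently from a simulator).
#'
#' @param events Event tibble.
#' @param path CSV path.
#' @return `read_gap_events()` returns the event tibble.
#' @export
write_gap_events <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname write_gap_events
#' @export
read_gap_events <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
    col_types = readr::cols(agent = readr::col_character())
  )
}
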