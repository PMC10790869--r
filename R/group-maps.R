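# Channel-wise characterisation of the AV-HV difference: per-subject paired
# t-maps over block-wise condition means, accuracy-weighted averaging across
# subjects, and conversion of the weighted t to a Cohen's d effect-size map.

#' Single-subject channel-wise paired t-map
#'
#' Per channel, a paired t-test of AV vs HV decision-phase amplitude. The
#' epoch amplitude is the mean HbR over the 4 s window; the pairing unit is
#' the driving block (per block: mean AV amplitude vs mean HV amplitude),
#' which pairs conditions recorded close in time and guards against slow
#' drifts. Blocks missing either condition are dropped with a warning. A
#' trial-level two-sample (Welch) variant is available via
#' `pairing = "trial"`.
#'
#' @param epochs An `fnirs_epochs` with a `block` column in `trials`.
#' @param pairing `"block"` (paired over blocks, default) or `"trial"`
#'   (two-sample over trials).
#' @param accuracy_weight Optional decoding accuracy (percent) of this
#'   subject, stored for [weighted_t_average()].
#' @param subject_id Optional identifier.
#' @return An object of class `subject_tmap`: tibble `map` (`channel`,
#'   `t`, plus montage labels), `df`, `n_pairs`, `accuracy_weight`,
#'   `subject_id`.
#' @export
subject_tmap <- function(epochs, pairing = c("block", "trial"),
                         accuracy_weight = NA_real_, subject_id = NA) {
  stopifnot(inherits(epochs, "fnirs_epochs"))
  pairing <- match.arg(pairing)
  amp <- apply(epochs$samples, c(1, 2), mean) # trial x channel
  lab <- epochs$trials$label
  if (length(unique(lab)) < 2) stop("both conditions required", call. = FALSE)
  if (pairing == "block") {
    blk <- epochs$trials$block
    if (all(is.na(blk))) stop("block pairing needs a `block` column", call. = FALSE)
    complete <- intersect(unique(blk[lab == "AV"]), unique(blk[lab == "HV"]))
    dropped <- setdiff(unique(blk), complete)
    if (length(dropped) > 0) {
      warning(sprintf("%d block(s) missing one condition dropped", length(dropped)))
    }
    if (length(complete) < 2) {
      stop("fewer than 2 complete AV/HV block pairs", call. = FALSE)
    }
    av <- t(sapply(complete, function(b) colMeans(amp[lab == "AV" & blk == b, , drop = FALSE])))
    hv <- t(sapply(complete, function(b) colMeans(amp[lab == "HV" & blk == b, , drop = FALSE])))
    d <- av - hv # pairs x channel
    n <- nrow(d)
    tval <- apply(d, 2, function(x) {
      s <- sd(x)
      if (s == 0) {
        # degenerate pair table: identical conditions give t = 0,
        # identical nonzero differences give an infinite t
        return(if (mean(x) == 0) 0 else sign(mean(x)) * Inf)
      }
      mean(x) / (s / sqrt(length(x)))
    })
    df <- n - 1L
    n_pairs <- n
  } else {
    tval <- apply(amp, 2, function(x) {
      t.test(x[lab == "AV"], x[lab == "HV"])$statistic
    })
    df <- min(sum(lab == "AV"), sum(lab == "HV")) - 1L
    n_pairs <- min(sum(lab == "AV"), sum(lab == "HV"))
  }
  structure(
    list(
      map = dplyr::mutate(
        epochs$channels[, c("channel", "label_1020")],
        t = unname(tval)
      ),
      df = df, n_pairs = n_pairs,
      accuracy_weight = accuracy_weight, subject_id = subject_id,
      pairing = pairing
    ),
    class = "subject_tmap"
  )
}

#' Accuracy-weighted average t-map across subjects
#'
#' Combines subject t-maps into a group map where each subject's contribution
#' is weighted by their mean decoding accuracy:
#' `t_avg(i) = sum_n t_n(i) w_n / sum_n w_n`, a convex combination per
#' channel. Channels absent from a subject (rejected by that subject's QC)
#' are excluded from that subject's contribution with renormalized weights.
#' Weights are scale-invariant (percent or proportion give the same map).
#'
#' @param tmaps List of [subject_tmap()] objects.
#' @param weights Optional numeric vector overriding the stored
#'   `accuracy_weight`s.
#' @return Tibble: `channel`, `label_1020`, `t_avg`, `n_subjects` (subjects
#'   contributing to the channel).
#' @export
weighted_t_average <- function(tmaps, weights = NULL) {
  stopifnot(length(tmaps) >= 1, all(purrr::map_lgl(tmaps, inherits, "subject_tmap")))
  w <- weights %||% purrr::map_dbl(tmaps, "accuracy_weight")
  if (anyNA(w)) stop("missing accuracy weights", call. = FALSE)
  if (all(w == 0)) stop("all-zero weights", call. = FALSE)
  long <- purrr::imap(tmaps, function(tm, i) {
    dplyr::mutate(tm$map, .w = w[i])
  }) |> purrr::list_rbind()
  long |>
    dplyr::filter(is.finite(.data$t)) |>
    dplyr::group_by(.data$channel, .data$label_1020) |>
    dplyr::summarise(
      t_avg = sum(.data$t * .data$.w) / sum(.data$.w),
      n_subjects = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$channel)
}

#' Cohen's d from the weighted group t-statistic
#'
#' Converts the per-channel weighted average t to an effect size,
#' `|d| = |t_avg| / sqrt(df)`, signed by `t_avg`. The squared variant
#' (`t_avg^2 / df`) is available via `form = "squared"`.
#'
#' @param t_avg Numeric vector of weighted t values (or the tibble returned
#'   by [weighted_t_average()]).
#' @param df Degrees of freedom (>= 1); conventionally `n_subjects - 1`.
#' @param form `"sqrt"` (default) or `"squared"`.
#' @return Numeric vector of d values (or the input tibble with a `cohens_d`
#'   column added).
#' @export
cohens_d_map <- function(t_avg, df, form = c("sqrt", "squared")) {
  form <- match.arg(form)
  if (df < 1) stop("`df` must be >= 1", call. = FALSE)
  if (is.data.frame(t_avg)) {
    t_avg$cohens_d <- cohens_d_map(t_avg$t_avg, df, form)
    attr(t_avg, "df") <- df
    return(t_avg)
  }
  if (form == "sqrt") sign(t_avg) * sqrt(t_avg^2 / df) else t_avg^2 / df
}

#' Build a group effect-size map from subject epochs and decoding results
#'
#' Convenience wrapper chaining [subject_tmap()], [weighted_t_average()] and
#' [cohens_d_map()] for a cohort.
#'
#' @param tmaps List of `subject_tmap`s (with accuracy weights set).
#' @param df Degrees of freedom for the d conversion (default
#'   `length(tmaps) - 1`).
#' @param form Passed to [cohens_d_map()].
#' @return An object of class `group_map`: tibble with `channel`,
#'   `label_1020`, `t_avg`, `n_subjects`, `cohens_d`; attributes `df`,
#'   `n_subjects_total`.
#' @export
group_effect_map <- function(tmaps, df = length(tmaps) - 1, form = "sqrt") {
  map <- weighted_t_average(tmaps) |> cohens_d_map(df, form)
  structure(map,
    class = c("group_map", class(map)),
    df = df, n_subjects_total = length(tmaps)
  )
}

#' Ranked channel report of group effect sizes
#'
#' Lists channels whose absolute Cohen's d meets `threshold_d` (default 0.8,
#' the lower edge of the moderate-to-high band), with their 10-20
#' emitter-detector labels, sorted by |d| descending.
#'
#' @param map A `group_map` (or tibble with `channel`, `label_1020`,
#'   `t_avg`, `cohens_d`).
#' @param threshold_d Minimum |d| to report (default 0.8; 0 lists every
#'   channel).
#' @return Tibble sorted by decreasing |d|.
#' @export
channel_report <- function(map, threshold_d = 0.8) {
  tibble::as_tibble(map) |>
    dplyr::filter(abs(.data$cohens_d) >= threshold_d) |>
    dplyr::arrange(dplyr::desc(abs(.data$cohens_d)))
}

#' @describeIn group_effect_map Channel-space effect-size plot: per-channel
#'   Cohen's d with the moderate-effect band marked.
#' @param object A `group_map`.
#' @param threshold_d Reference |d| line (default 0.8).
#' @param ... Unused.
#' @export
autoplot.group_map <- function(object, threshold_d = 0.8, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(.data$channel, .data$cohens_d)
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_hline(
      yintercept = c(-threshold_d, threshold_d),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$channel, yend = 0),
      colour = "grey75"
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "fNIRS channel", y = "Cohen's d (AV - HV)",
      title = "Group effect-size map"
    )
}

#' Write a group map to CSV
#'
#' @param map A `group_map`.
#' @param path CSV path.
#' @export
write_group_map <- function(map, path) {
  readr::write_csv(tibble::as_tibble(map), path)
  invisible(path)
}
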