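# Two-parameter logistic gap-acceptance model:
#   P(X; m, w) = 1 / (1 + exp(-2 ln(1/0.05 - 1) (X - m) / w))
# m is the 50% acceptance threshold (s); w is the distance between the 5% and
# 95% points of the curve (s). The slope constant 2 ln(19) ties w to that span.

.pf_slope_const <- 2 * log(1 / 0.05 - 1) # 2 ln(19)

#' Logistic gap-acceptance probability
#'
#' Probability that a driver accepts a gap of `gap` seconds, under the
#' two-parameter logistic psychometric model with threshold `m` (gap size at
#' 50% acceptance) and width `w` (distance in seconds between the 5% and 95%
#' points of the curve).
#'
#' @param gap Gap size(s) in seconds (vectorised).
#' @param m Threshold in seconds: the gap size accepted with probability 0.5.
#' @param w Width in seconds: the 5%-to-95% span of the curve; must be > 0.
#' @return Acceptance probabilities in (0, 1), same length as `gap`.
#' @examples
#' gap_acceptance_prob(3.09, m = 3.09, w = 0.65) # 0.5 at threshold
#' gap_acceptance_prob(3.5, m = 3.0, w = 1.0)    # 0.95 at m + w/2
#' @export
gap_acceptance_prob <- function(gap, m, w) {
  if (any(w <= 0)) stop("width `w` must be strictly positive", call. = FALSE)
  stats::plogis(.pf_slope_const * (gap - m) / w)
}

#' Bin gap-acceptance events for reporting
#'
#' Groups presented gaps into fixed-width bins (default 0.35 s) per agent
#' condition and tabulates presented/accepted counts and the empirical
#' acceptance proportion. Bins are half-open `[lo, lo + width)` with the left
#' edge of the first bin at `floor(min(gap)/width) * width`.
#'
#' @param events A data frame of gap events with at least columns `gap_size`
#'   (seconds), `agent` (`"AV"`/`"HV"`) and `accepted` (logical).
#' @param bin_width Bin width in seconds (default 0.35).
#' @return A tibble with columns `agent`, `bin_center`, `bin_width`,
#'   `n_presented`, `n_accepted`, `p_hat`.
#' @export
bin_acceptance <- function(events, bin_width = 0.35) {
  stopifnot(is.data.frame(events), nrow(events) > 0)
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  origin <- floor(min(events$gap_size) / bin_width) * bin_width
  events |>
    dplyr::mutate(.bin = floor((.data$gap_size - origin) / bin_width)) |>
    dplyr::group_by(.data$agent, .data$.bin) |>
    dplyr::summarise(
      n_presented = dplyr::n(),
      n_accepted = sum(.data$accepted),
      .groups = "drop"
    ) |>
    dplyr::transmute(
      agent = .data$agent,
      bin_center = origin + (.data$.bin + 0.5) * bin_width,
      bin_width = bin_width,
      n_presented = .data$n_presented,
      n_accepted = .data$n_accepted,
      p_hat = .data$n_accepted / .data$n_presented
    ) |>
    dplyr::arrange(.data$agent, .data$bin_center)
}

# (m, w) <-> glm(binomial) coefficients. The psychometric model is a logistic
# regression in gap size with slope b = 2 ln(19)/w and intercept a = -b m, so
# glm is the exact maximum-likelihood fit of (m, w).
.coefs_to_mw <- function(a, b) c(m = unname(-a / b), w = unname(.pf_slope_const / b))

.fit_mw_glm <- function(gap, accepted) {
  fit <- suppressWarnings(glm(accepted ~ gap, family = binomial()))
  separated <- !fit$converged || any(abs(coef(fit)) > 1e3)
  list(mw = .coefs_to_mw(coef(fit)[1], coef(fit)[2]), separated = separated)
}

#' Fit the logistic gap-acceptance model to raw accept/reject events
#'
#' Maximum-likelihood fit of the two-parameter psychometric model (threshold
#' `m`, width `w`) to per-event Bernoulli outcomes, with nonparametric
#' bootstrap confidence intervals obtained by resampling events. The fit is
#' performed on the raw events, not on binned proportions; binning
#' ([bin_acceptance()]) is for display. Guess and lapse rates are fixed at 0.
#'
#' Complete separation (all accepted gaps strictly above all rejected gaps)
#' leaves the likelihood unbounded in the slope; the fit is then flagged
#' (`separated = TRUE`) and its intervals should be read as unstable.
#'
#' @param events Data frame with columns `gap_size` and `accepted`; all rows
#'   are fitted, so filter to one condition first (or use `condition` to label
#'   the output).
#' @param condition Optional condition label stored in the result (defaults to
#'   the unique value of `events$agent` when present).
#' @param n_boot Number of bootstrap resamples for the percentile CIs
#'   (default 1000; set to 0 to skip).
#' @param conf_level Confidence level (default 0.95, i.e. 2.5-97.5 percentiles).
#' @param seed Optional integer seed for the bootstrap resampling.
#' @return An object of class `psychometric_fit`: list with `m`, `w`, `ci_m`,
#'   `ci_w`, `condition`, `n_events`, `separated`, `boot` (tibble of bootstrap
#'   replicates). Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' ev <- tibble::tibble(
#'   gap_size = runif(400, 1, 6),
#'   accepted = runif(400) < gap_acceptance_prob(gap_size, 3, 1),
#'   agent = "HV"
#' )
#' fit <- fit_psychometric(ev, n_boot = 100)
#' tidy(fit)
#' @export
fit_psychometric <- function(events, condition = NULL, n_boot = 1000,
                             conf_level = 0.95, seed = NULL) {
  stopifnot(is.data.frame(events), nrow(events) > 0)
  acc <- as.logical(events$accepted)
  if (all(acc) || !any(acc)) {
    stop("events must contain both accepted and rejected outcomes", call. = FALSE)
  }
  if (is.null(condition) && "agent" %in% names(events) &&
    length(unique(events$agent)) == 1L) {
    condition <- as.character(unique(events$agent))
  }
  point <- .fit_mw_glm(events$gap_size, acc)
  boot <- NULL
  ci_m <- ci_w <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(events)
    reps <- purrr::map(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      .fit_mw_glm(events$gap_size[idx], acc[idx])$mw
    })
    boot <- tibble::tibble(
      m = purrr::map_dbl(reps, "m"),
      w = purrr::map_dbl(reps, "w")
    )
    alpha <- (1 - conf_level) / 2
    ci_m <- unname(quantile(boot$m, c(alpha, 1 - alpha), na.rm = TRUE))
    ci_w <- unname(quantile(boot$w, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  structure(
    list(
      m = point$mw[["m"]], w = point$mw[["w"]],
      ci_m = ci_m, ci_w = ci_w,
      conf_level = conf_level,
      condition = condition %||% NA_character_,
      n_events = nrow(events),
      separated = point$separated,
      boot = boot
    ),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Logistic gap-acceptance fit",
    if (!is.na(x$condition)) paste0("[", x$condition, "]"), "\n"
  )
  cat(sprintf(
    "  m (50%% threshold) = %.3f s  [%.3f, %.3f]\n",
    x$m, x$ci_m[1], x$ci_m[2]
  ))
  cat(sprintf(
    "  w (5-95%% width)   = %.3f s  [%.3f, %.3f]\n",
    x$w, x$ci_w[1], x$ci_w[2]
  ))
  cat(sprintf("  n = %d events", x$n_events))
  if (isTRUE(x$separated)) cat("  (complete separation: CI unstable)")
  cat("\n")
  invisible(x)
}

#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    term = c("m", "w"),
    estimate = c(x$m, x$w),
    conf.low = c(x$ci_m[1], x$ci_w[1]),
    conf.high = c(x$ci_m[2], x$ci_w[2]),
    condition = x$condition
  )
}

#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    condition = x$condition, m = x$m, w = x$w,
    n_events = x$n_events, separated = x$separated,
    conf.level = x$conf_level
  )
}

#' Compare two psychometric fits (e.g. AV vs HV)
#'
#' Reports the threshold and width differences between two fitted conditions
#' and whether each parameter's bootstrap confidence intervals overlap. No
#' p-value is computed; CI overlap is the reported evidence.
#'
#' @param fit_a,fit_b Objects from [fit_psychometric()].
#' @return A tibble with one row per parameter: `term`, `estimate_a`,
#'   `estimate_b`, `delta` (a - b), `ci_overlap`.
#' @export
compare_psychometric <- function(fit_a, fit_b) {
  stopifnot(
    inherits(fit_a, "psychometric_fit"),
    inherits(fit_b, "psychometric_fit")
  )
  overlap <- function(ci1, ci2) !(ci1[2] < ci2[1] || ci2[2] < ci1[1])
  tibble::tibble(
    term = c("m", "w"),
    condition_a = fit_a$condition, condition_b = fit_b$condition,
    estimate_a = c(fit_a$m, fit_a$w),
    estimate_b = c(fit_b$m, fit_b$w),
    delta = .data$estimate_a - .data$estimate_b,
    ci_overlap = c(overlap(fit_a$ci_m, fit_b$ci_m), overlap(fit_a$ci_w, fit_b$ci_w))
  )
}

#' @describeIn fit_psychometric Plot the fitted curve over binned acceptance
#'   proportions (marker area = events per bin).
#' @param object A `psychometric_fit`.
#' @param events Optional events to bin and overlay.
#' @param bin_width Bin width for the overlaid proportions.
#' @param ... Unused.
#' @export
autoplot.psychometric_fit <- function(object, events = NULL, bin_width = 0.35, ...) {
  rng <- c(object$m - object$w, object$m + object$w)
  curve <- tibble::tibble(
    gap_size = seq(rng[1], rng[2], length.out = 200),
    p = gap_acceptance_prob(.data$gap_size, object$m, object$w)
  )
  p <- ggplot2::ggplot(curve, ggplot2::aes(.data$gap_size, .data$p)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "gap size (s)", y = "P(accept)",
      title = sprintf(
        "m = %.2f s, w = %.2f s%s", object$m, object$w,
        if (!is.na(object$condition)) paste0("  [", object$condition, "]") else ""
      )
    ) +
    ggplot2::ylim(0, 1)
  if (!is.null(events)) {
    bins <- bin_acceptance(events, bin_width)
    p <- p + ggplot2::geom_point(
      data = bins,
      ggplot2::aes(.data$bin_center, .data$p_hat, size = .data$n_presented),
      alpha = 0.6
    ) + ggplot2::scale_size_area(max_size = 6, name = "events")
  }
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
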