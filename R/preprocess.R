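# Raw intensity -> HbR decision-phase epochs. Fixed pipeline order:
# CV screening -> band-pass -> spike screening -> Beer-Lambert -> epoching ->
# normalization. Each step is exported so the stages can be tested and
# rearranged deliberately; preprocess_recording() applies the canonical order.

#' Channel quality by coefficient of variation
#'
#' Computes the coefficient of variation (100 * sd / mean) per channel and
#' wavelength on the unfiltered raw intensities — a signal-to-noise screen —
#' and flags channels whose worst wavelength exceeds `cv_max` percent for
#' exclusion (strictly greater: a channel at exactly the threshold is kept).
#' Channels with zero mean have undefined CV and are rejected with a warning.
#'
#' @param rec An `fnirs_recording`.
#' @param cv_max Rejection threshold in percent (default 20).
#' @return Tibble: `channel`, `cv_760`, `cv_850`, `kept_cv`.
#' @export
channel_cv <- function(rec, cv_max = 20) {
  stopifnot(inherits(rec, "fnirs_recording"))
  cv_one <- function(wl) {
    mu <- apply(rec$intensities[, , wl, drop = FALSE], 1, mean)
    s <- apply(rec$intensities[, , wl, drop = FALSE], 1, sd)
    ifelse(mu == 0, NA_real_, 100 * s / abs(mu))
  }
  cv1 <- cv_one(1L)
  cv2 <- cv_one(2L)
  if (anyNA(c(cv1, cv2))) {
    warning("zero-mean channel(s): CV undefined, channel rejected")
  }
  worst <- pmax(cv1, cv2)
  tibble::tibble(
    channel = rec$montage$channel,
    cv_760 = cv1, cv_850 = cv2,
    kept_cv = !is.na(worst) & worst <= cv_max
  )
}

#' Automated spike-based channel screening
#'
#' Replacement for visual channel inspection: per channel and wavelength,
#' the robust z-score (against the median, scaled by MAD) of the
#' sample-to-sample increments is computed; increments with `|z| > z_thresh`
#' are counted as spike samples. Working on the first difference makes the
#' screen sensitive to fast artifact discontinuities while ignoring the slow
#' hemodynamic responses and physiological oscillations. Channels with more
#' than `max_spikes` flagged samples on either wavelength are excluded.
#' `z_thresh = Inf` disables the rule.
#'
#' @param rec An `fnirs_recording`.
#' @param quality Optional tibble from [channel_cv()] to extend; otherwise a
#'   fresh table is built.
#' @param z_thresh Robust z threshold (default 5).
#' @param max_spikes Maximum tolerated spike samples (default 5).
#' @return `quality` with added `spike_count` and combined `kept` columns.
#' @export
flag_spiky_channels <- function(rec, quality = NULL, z_thresh = 5, max_spikes = 5) {
  stopifnot(inherits(rec, "fnirs_recording"))
  if (is.null(quality)) quality <- channel_cv(rec)
  count_one <- function(wl) {
    apply(rec$intensities[, , wl, drop = FALSE], 1, function(x) {
      dx <- diff(x)
      s <- mad(dx)
      if (s == 0) return(0L)
      sum(abs(dx - median(dx)) / s > z_thresh)
    })
  }
  spikes <- pmax(count_one(1L), count_one(2L))
  quality |>
    dplyr::mutate(
      spike_count = as.integer(spikes),
      kept = .data$kept_cv & .data$spike_count <= max_spikes
    )
}

#' Zero-phase Butterworth band-pass filter
#'
#' 3rd-order Butterworth applied forward-backward (`signal::filtfilt`), so the
#' filter is zero-phase and epoch timing is preserved. The filter acts on the
#' fluctuation about each row's temporal mean and the mean is re-added, so a
#' band-passed intensity signal stays positive and usable by [beer_lambert()].
#'
#' @param x Numeric matrix (channels x time) or vector.
#' @param fs Sampling frequency, Hz.
#' @param low,high Band edges in Hz (defaults 0.01 and 0.1: pass the slow
#'   hemodynamic band, attenuate drift below and cardiac/respiratory/Mayer
#'   components above).
#' @param order Butterworth order (default 3).
#' @return Filtered data, same shape as `x`.
#' @export
bandpass_filter <- function(x, fs, low = 0.01, high = 0.1, order = 3) {
  if (!(low > 0 && high > low && high < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  filt_row <- function(v) {
    mu <- mean(v)
    mu + signal::filtfilt(bf, v - mu)
  }
  if (is.matrix(x)) t(apply(x, 1, filt_row)) else filt_row(x)
}

#' @describeIn bandpass_filter Band-pass every channel and wavelength of a
#'   recording, returning a new `fnirs_recording`. The filter is applied to
#'   the log-intensity (optical-density) fluctuation and exponentiated back,
#'   which coincides with filtering the raw signal for the small fluctuations
#'   typical of fNIRS but keeps intensities strictly positive even around
#'   large spike artifacts.
#' @param rec An `fnirs_recording`.
#' @export
bandpass_recording <- function(rec, low = 0.01, high = 0.1, order = 3) {
  stopifnot(inherits(rec, "fnirs_recording"))
  if (any(rec$intensities <= 0)) {
    stop("non-positive intensities", call. = FALSE)
  }
  for (wl in seq_along(rec$wavelengths)) {
    rec$intensities[, , wl] <- exp(bandpass_filter(
      log(rec$intensities[, , wl]), rec$fs, low, high, order
    ))
  }
  rec
}

#' Modified Beer-Lambert conversion to hemoglobin concentrations
#'
#' Converts two-wavelength raw intensities to relative HbO/HbR concentration
#' change. Per channel and wavelength the optical-density change is
#' `dOD = -log10(I / I_ref)`; the 2x2 system
#' `dOD(lambda) = eps(lambda, HbX) * dC * d * DPF` is then inverted with the
#' tabulated extinction coefficients ([extinction_coefficients()]), the
#' source-detector distance from the montage and the configured differential
#' pathlength factor.
#'
#' @param rec An `fnirs_recording` (both wavelengths required, intensities
#'   strictly positive).
#' @param dpf Differential pathlength factor (default: the recording's
#'   forward-model value if present, else 6).
#' @param reference `"mean"` (default): `I_ref` is the channel temporal mean,
#'   so recovered concentrations are relative to their own temporal mean;
#'   `"baseline"`: `I_ref` is the sample at `baseline_index`, giving exact
#'   recovery of a forward model whose concentrations start at zero.
#' @param baseline_index Sample index used when `reference = "baseline"`.
#' @return An object of class `hb_series`: `hbo`/`hbr` matrices (channel x
#'   time, umol/L), `fs`, `time`, `montage`, `triggers`.
#' @export
beer_lambert <- function(rec, dpf = NULL,
                         reference = c("mean", "baseline"),
                         baseline_index = 1L) {
  stopifnot(inherits(rec, "fnirs_recording"))
  reference <- match.arg(reference)
  if (length(rec$wavelengths) != 2L) {
    stop("two wavelengths required", call. = FALSE)
  }
  if (any(rec$intensities <= 0)) {
    stop("non-positive intensities: cannot take optical density", call. = FALSE)
  }
  dpf <- dpf %||% rec$dpf %||% 6
  eps <- extinction_coefficients(rec$wavelengths)
  if (abs(det(eps)) < 1e-12) stop("degenerate wavelength pair", call. = FALSE)
  inv_eps <- solve(eps)
  nc <- dim(rec$intensities)[1]
  nt <- dim(rec$intensities)[2]
  hbo <- matrix(NA_real_, nc, nt)
  hbr <- matrix(NA_real_, nc, nt)
  for (ch in seq_len(nc)) {
    dod <- sapply(1:2, function(wl) {
      v <- rec$intensities[ch, , wl]
      iref <- if (reference == "mean") mean(v) else v[baseline_index]
      -log10(v / iref)
    }) # nt x 2
    dc <- dod %*% t(inv_eps) / (rec$montage$distance_cm[ch] * dpf) # mol/L
    hbo[ch, ] <- dc[, 1] * 1e6
    hbr[ch, ] <- dc[, 2] * 1e6
  }
  structure(
    list(
      hbo = hbo, hbr = hbr, fs = rec$fs, time = rec$time,
      montage = rec$montage, triggers = rec$triggers
    ),
    class = "hb_series"
  )
}

#' @export
print.hb_series <- function(x, ...) {
  cat(sprintf(
    "Hb concentration series: %d channels x %d samples @ %.3f Hz (umol/L)\n",
    nrow(x$hbr), ncol(x$hbr), x$fs
  ))
  invisible(x)
}

#' Extract decision-phase HbR epochs
#'
#' Cuts the HbR series into per-trial epochs around each accelerator-press
#' trigger. The default window is -2 s to +2 s (the 4 s decision phase:
#' from 2 s before the press to 2 s into the turn). Alignment is
#' nearest-sample with a closed window: the epoch starts at the sample
#' nearest `t + win[1]` and contains `floor(diff(window) * fs) + 1` samples
#' (8 at the instrument defaults), so every epoch has the same length.
#' Epochs overlapping the recording edges are dropped with a warning.
#'
#' @param hb An `hb_series` from [beer_lambert()].
#' @param triggers Trigger tibble (`time`, `label`, optionally `block`);
#'   defaults to the triggers carried by `hb`.
#' @param window Length-2 numeric, seconds relative to the trigger.
#' @param normalize `"run"` (default): z-score each channel of the HbR series
#'   over the whole run before epoching (constant channels map to 0);
#'   `"none"`: raw concentrations. Whole-run normalization happens before any
#'   train/test split downstream; use the decoder's fold-wise scaling for a
#'   leakage-safe alternative.
#' @return An object of class `fnirs_epochs`: `samples` (trial x channel x
#'   timepoint array), `trials` (tibble: `trial`, `label`, `block`, `time`),
#'   `channels` (montage rows), `window`, `fs`.
#' @export
extract_epochs <- function(hb, triggers = NULL, window = c(-2, 2),
                           normalize = c("run", "none")) {
  stopifnot(inherits(hb, "hb_series"), length(window) == 2, window[1] < window[2])
  normalize <- match.arg(normalize)
  triggers <- triggers %||% hb$triggers
  if (is.null(triggers) || nrow(triggers) == 0) {
    stop("no triggers to epoch", call. = FALSE)
  }
  x <- hb$hbr
  if (normalize == "run") {
    x <- t(apply(x, 1, function(v) {
      s <- sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }))
  }
  n_samp <- floor(diff(window) * hb$fs) + 1L
  nt <- ncol(x)
  starts <- round((triggers$time + window[1]) * hb$fs) + 1L
  ok <- starts >= 1L & (starts + n_samp - 1L) <= nt
  if (!any(ok)) stop("no valid triggers within the recording", call. = FALSE)
  if (any(!ok)) {
    warning(sprintf("%d epoch(s) overlapping recording edges dropped", sum(!ok)))
  }
  kept <- which(ok)
  samples <- array(NA_real_, dim = c(length(kept), nrow(x), n_samp))
  for (i in seq_along(kept)) {
    idx <- starts[kept[i]] + seq_len(n_samp) - 1L
    samples[i, , ] <- x[, idx]
  }
  trials <- tibble::tibble(
    trial = seq_along(kept),
    label = triggers$label[kept],
    block = if ("block" %in% names(triggers)) triggers$block[kept] else NA_integer_,
    time = triggers$time[kept]
  )
  structure(
    list(
      samples = samples, trials = trials, channels = hb$montage,
      window = window, fs = hb$fs
    ),
    class = "fnirs_epochs"
  )
}

#' @export
print.fnirs_epochs <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf(
    "HbR epochs: %d trials x %d channels x %d timepoints, window [%g, %g] s\n",
    d[1], d[2], d[3], x$window[1], x$window[2]
  ))
  cat(sprintf(
    "  labels: %s\n",
    paste(names(table(x$trials$label)), table(x$trials$label),
      sep = "=", collapse = ", "
    )
  ))
  invisible(x)
}

#' Canonical preprocessing pipeline
#'
#' Applies the fixed stage order — CV screening, zero-phase band-pass on raw
#' intensities, spike screening, modified Beer-Lambert conversion, and channel
#' exclusion — and returns the HbR/HbO series restricted to surviving
#' channels together with the QC report. Epoching is a separate step
#' ([extract_epochs()]) because it needs a window choice.
#'
#' @param rec An `fnirs_recording`.
#' @param cv_max CV rejection threshold, percent.
#' @param band Band edges in Hz for [bandpass_filter()].
#' @param z_thresh,max_spikes Spike-screen parameters, see
#'   [flag_spiky_channels()].
#' @param filter_domain `"intensity"` (default): filter raw intensities before
#'   conversion; `"concentration"`: convert first, filter the Hb series.
#' @param dpf Differential pathlength factor for [beer_lambert()].
#' @return A list: `hb` (`hb_series`, surviving channels only), `quality`
#'   (QC tibble: channel, cv per wavelength, spike count, kept).
#' @export
preprocess_recording <- function(rec, cv_max = 20, band = c(0.01, 0.1),
                                 z_thresh = 5, max_spikes = 5,
                                 filter_domain = c("intensity", "concentration"),
                                 dpf = NULL) {
  stopifnot(inherits(rec, "fnirs_recording"))
  filter_domain <- match.arg(filter_domain)
  quality <- channel_cv(rec, cv_max = cv_max)
  quality <- flag_spiky_channels(rec, quality,
    z_thresh = z_thresh, max_spikes = max_spikes
  )
  if (filter_domain == "intensity") {
    hb <- beer_lambert(bandpass_recording(rec, band[1], band[2]), dpf = dpf)
  } else {
    hb <- beer_lambert(rec, dpf = dpf)
    hb$hbo <- bandpass_filter(hb$hbo, hb$fs, band[1], band[2])
    hb$hbr <- bandpass_filter(hb$hbr, hb$fs, band[1], band[2])
  }
  keep <- quality$kept
  if (!any(keep)) stop("all channels rejected by QC", call. = FALSE)
  hb$hbo <- hb$hbo[keep, , drop = FALSE]
  hb$hbr <- hb$hbr[keep, , drop = FALSE]
  hb$montage <- hb$montage[keep, , drop = FALSE]
  list(hb = hb, quality = quality)
}

#' Write a channel QC report
#'
#' @param quality QC tibble from [preprocess_recording()] or
#'   [flag_spiky_channels()].
#' @param path CSV path.
#' @export
write_qc_report <- function(quality, path) {
  readr::write_csv(quality, path)
  invisible(path)
}
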