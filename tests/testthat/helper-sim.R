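# Fixture builders shared across test files. Everything is generated in code;
# seeds are fixed by the calling test.

# Bernoulli gap-acceptance events from known psychometric ground truth
make_events <- function(n, m, w, gap_range = c(0.5, 6.5), agent = "HV") {
  gap <- runif(n, gap_range[1], gap_range[2])
  tibble::tibble(
    gap_size = gap,
    accepted = runif(n) < gap_acceptance_prob(gap, m, w),
    agent = agent
  )
}

# noise-free simulation config for round-trip tests
quiet_sim_config <- function(n_channels = 4, ...) {
  fnirs_sim_config(
    n_channels = n_channels,
    noise_amplitudes = c(
      cardiac = 0, respiratory = 0, mayer = 0,
      drift = 0, white = 0, spike = 0
    ),
    spike_rate = 0, ...
  )
}

# hand-built recording from an intensity array (bypasses the simulator)
make_recording <- function(intensities, fs = 1.955,
                           triggers = tibble::tibble(time = numeric(0), label = character(0))) {
  nc <- dim(intensities)[1]
  structure(
    list(
      intensities = intensities, wavelengths = c(760, 850),
      fs = fs, time = (seq_len(dim(intensities)[2]) - 1) / fs,
      montage = default_montage(nc), triggers = triggers, dpf = 6
    ),
    class = "fnirs_recording"
  )
}

# epoch set with a planted class difference on `effect_channels`:
# trial x channel x time array of N(0, noise_sd) with +/- delta/2 offsets.
# A shared global component (systemic physiology common to all channels,
# sd `global_sd`) mimics the dominant non-neural direction of real
# recordings that the decoder's first-PC removal is meant to absorb.
make_epochs <- function(n_per_class = 20, n_channels = 12, n_time = 8,
                        effect_channels = integer(0), delta = 1,
                        noise_sd = 1, global_sd = 2, n_blocks = 5) {
  n <- 2 * n_per_class
  labels <- rep(c("AV", "HV"), each = n_per_class)
  samples <- array(rnorm(n * n_channels * n_time, sd = noise_sd),
    dim = c(n, n_channels, n_time)
  )
  glob <- array(rnorm(n * n_time, sd = global_sd), dim = c(n, n_time))
  for (ch in seq_len(n_channels)) {
    samples[, ch, ] <- samples[, ch, ] + glob
  }
  for (ch in effect_channels) {
    samples[labels == "AV", ch, ] <- samples[labels == "AV", ch, ] - delta / 2
    samples[labels == "HV", ch, ] <- samples[labels == "HV", ch, ] + delta / 2
  }
  ord <- sample(n)
  block <- rep(rep_len(seq_len(n_blocks), n_per_class), 2) # both classes per block
  structure(
    list(
      samples = samples[ord, , , drop = FALSE],
      trials = tibble::tibble(
        trial = seq_len(n),
        label = labels[ord],
        block = block[ord],
        time = seq_len(n) * 30
      ),
      channels = default_montage(n_channels),
      window = c(-2, 2), fs = 1.955
    ),
    class = "fnirs_epochs"
  )
}

# independent per-sample tally of accuracy/F1, used as the oracle against
# the confusion-count formulas
oracle_metrics <- function(truth, predicted) {
  correct <- sum(truth == predicted)
  prec <- function(cl) {
    called <- predicted == cl
    if (!any(called)) return(NA_real_)
    sum(truth == cl & called) / sum(called)
  }
  rec <- function(cl) sum(truth == cl & predicted == cl) / sum(truth == cl)
  f1 <- function(cl) {
    p <- prec(cl); r <- rec(cl)
    if (is.na(p) || p + r == 0) return(0)
    2 * p * r / (p + r)
  }
  list(
    accuracy = 100 * correct / length(truth),
    f1_av = f1("AV"), f1_hv = f1("HV")
  )
}
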