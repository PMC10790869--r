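test_that("subject t-maps are zero for identical conditions and match a textbook paired t", {
  set.seed(61)
  ep <- make_epochs(n_per_class = 20, n_channels = 5, n_blocks = 5)
  # force AV and HV samples identical within each block
  for (b in unique(ep$trials$block)) {
    av <- which(ep$trials$label == "AV" & ep$trials$block == b)
    hv <- which(ep$trials$label == "HV" & ep$trials$block == b)
    n <- min(length(av), length(hv))
    ep$samples[hv[seq_len(n)], , ] <- ep$samples[av[seq_len(n)], , ]
    drop <- c(av[-seq_len(n)], hv[-seq_len(n)])
    if (length(drop)) {
      ep$samples <- ep$samples[-drop, , , drop = FALSE]
      ep$trials <- ep$trials[-drop, ]
    }
  }
  tm0 <- subject_tmap(ep)
  expect_true(all(abs(tm0$map$t) < 1e-8))

  # oracle: t.test(paired = TRUE) on the same block-level pair table
  set.seed(62)
  ep2 <- make_epochs(n_per_class = 20, n_channels = 4,
    effect_channels = 2, delta = 1, n_blocks = 5)
  tm <- subject_tmap(ep2)
  amp <- apply(ep2$samples, c(1, 2), mean)
  for (ch in 1:4) {
    av <- tapply(
      amp[ep2$trials$label == "AV", ch],
      ep2$trials$block[ep2$trials$label == "AV"], mean
    )
    hv <- tapply(
      amp[ep2$trials$label == "HV", ch],
      ep2$trials$block[ep2$trials$label == "HV"], mean
    )
    tt <- t.test(av, hv, paired = TRUE)
    expect_equal(tm$map$t[ch], unname(tt$statistic), tolerance = 1e-10)
  }
  expect_equal(tm$df, 4)
})

test_that("planted-effect channels carry the largest |t|", {
  set.seed(63)
  ep <- make_epochs(
    n_per_class = 100, n_channels = 10, effect_channels = c(5, 9),
    delta = 1, noise_sd = 1, n_blocks = 10
  )
  tm <- subject_tmap(ep)
  ranked <- order(abs(tm$map$t), decreasing = TRUE)
  expect_setequal(ranked[1:2], c(5, 9))
  expect_true(all(tm$map$t[c(5, 9)] < 0)) # AV - HV negative by construction
})

test_that("blocks missing a condition are dropped; too few pairs error", {
  set.seed(64)
  ep <- make_epochs(n_per_class = 12, n_channels = 3, n_blocks = 4)
  ep$trials$block[ep$trials$label == "AV" & ep$trials$block == 4] <- 1L
  expect_warning(tm <- subject_tmap(ep), "missing one condition")
  expect_equal(tm$n_pairs, 3)

  ep1 <- make_epochs(n_per_class = 6, n_channels = 3, n_blocks = 1)
  expect_error(suppressWarnings(subject_tmap(ep1)), "fewer than 2")
})

test_that("accuracy weighting is the stated convex combination", {
  mk <- function(tvals, w) {
    structure(
      list(
        map = tibble::tibble(
          channel = seq_along(tvals),
          label_1020 = paste0("ch", seq_along(tvals)), t = tvals
        ),
        df = 9, n_pairs = 10, accuracy_weight = w, subject_id = NA,
        pairing = "block"
      ),
      class = "subject_tmap"
    )
  }
  # hand evaluation: weights (70, 30), t = (1, 2) -> 1.3
  got <- weighted_t_average(list(mk(c(1, 1), 70), mk(c(2, 2), 30)))
  expect_equal(got$t_avg, c(1.3, 1.3))
  # single subject -> identity
  expect_equal(weighted_t_average(list(mk(c(0.5, -2), 65)))$t_avg, c(0.5, -2))
  # equal weights -> plain mean
  expect_equal(
    weighted_t_average(list(mk(c(1, 4), 50), mk(c(3, 0), 50)))$t_avg,
    c(2, 2)
  )
  # weight scale invariance (percent vs proportion)
  a <- weighted_t_average(list(mk(c(1, 4), 70), mk(c(3, 0), 30)))
  b <- weighted_t_average(list(mk(c(1, 4), 0.7), mk(c(3, 0), 0.3)))
  expect_equal(a$t_avg, b$t_avg)
  expect_error(
    weighted_t_average(list(mk(c(1, 1), 0), mk(c(2, 2), 0))),
    "all-zero"
  )
  # convexity: t_avg between min and max subject t per channel
  set.seed(65)
  tms <- purrr::map(1:5, ~ mk(rnorm(6), runif(1, 40, 90)))
  avg <- weighted_t_average(tms)
  tmat <- sapply(tms, function(x) x$map$t)
  expect_true(all(avg$t_avg >= apply(tmat, 1, min) - 1e-12))
  expect_true(all(avg$t_avg <= apply(tmat, 1, max) + 1e-12))
})

test_that("Cohen's d conversion follows |d| = |t|/sqrt(df) with t's sign", {
  expect_equal(cohens_d_map(0, df = 11), 0)
  expect_equal(abs(cohens_d_map(3.3, df = 11)), 3.3 / sqrt(11), tolerance = 1e-12)
  expect_equal(abs(cohens_d_map(3.3, df = 11)), 0.995, tolerance = 1e-3)
  expect_equal(cohens_d_map(-3.3, df = 11), -3.3 / sqrt(11))
  # scaling df by 4 halves |d|
  expect_equal(cohens_d_map(2, df = 44), cohens_d_map(2, df = 11) / 2)
  expect_error(cohens_d_map(1, df = 0), "df")
  expect_equal(cohens_d_map(3, df = 12, form = "squared"), 9 / 12)
})

test_that("channel report thresholds and conserves channels", {
  mkmap <- function(d) {
    structure(
      tibble::tibble(
        channel = seq_along(d), label_1020 = paste0("c", seq_along(d)),
        t_avg = d, n_subjects = 5, cohens_d = d
      ),
      class = c("group_map", "tbl_df", "tbl", "data.frame"), df = 4
    )
  }
  expect_equal(nrow(channel_report(mkmap(rep(0, 6)))), 0)
  expect_equal(nrow(channel_report(mkmap(c(0.5, -0.9, 1.2)), threshold_d = 0)), 3)
  rep08 <- channel_report(mkmap(c(0.5, -0.9, 1.2)))
  expect_equal(rep08$channel, c(3, 2))
  expect_true(all(diff(abs(rep08$cohens_d)) <= 0))
})

test_that("a planted cohort yields group |d| above null channels, and nulls calibrate", {
  set.seed(66)
  effect_ch <- c(3, 7)
  cohort <- purrr::map(1:12, function(s) {
    ep <- make_epochs(
      n_per_class = 30, n_channels = 10, effect_channels = effect_ch,
      delta = 1.1, noise_sd = 1, n_blocks = 10
    )
    subject_tmap(ep, accuracy_weight = runif(1, 55, 75), subject_id = s)
  })
  gm <- group_effect_map(cohort)
  expect_equal(attr(gm, "df"), 11)
  d <- gm$cohens_d
  expect_true(all(abs(d[effect_ch]) >= 0.8))
  expect_gt(min(abs(d[effect_ch])), quantile(abs(d[-effect_ch]), 0.95))
  rep <- channel_report(gm)
  expect_true(all(effect_ch %in% rep$channel))

  # null calibration: with no effect, few channels pass |d| >= 0.8
  set.seed(67)
  n_cohorts <- 60
  frac <- purrr::map_dbl(seq_len(n_cohorts), function(i) {
    tms <- purrr::map(1:12, function(s) {
      ep <- make_epochs(n_per_class = 10, n_channels = 8, n_blocks = 5)
      subject_tmap(ep, accuracy_weight = runif(1, 50, 70), subject_id = s)
    })
    mean(abs(group_effect_map(tms)$cohens_d) >= 0.8)
  })
  expect_lte(mean(frac), 0.05)
})

test_that("the full synthetic pipeline recovers planted channels at the group level", {
  set.seed(68)
  effect_ch <- c(2, 6)
  cfg <- fnirs_sim_config(
    n_channels = 8, effect_channels = effect_ch, effect_amplitude = 0.5,
    noise_amplitudes = c(
      cardiac = 0.05, respiratory = 0.04, mayer = 0.03,
      drift = 0.12, white = 0.03, spike = 0.2
    ),
    spike_rate = 0
  )
  # early-trial epochs clipped by the recording edge and occasional blocks
  # missing a condition are expected at this small protocol size
  tms <- purrr::map(1:6, function(s) {
    sub <- suppressWarnings(simulate_subject(
      blocks = 4, intersections_per_block = 8,
      traffic = traffic_config(av_fraction = 0.5),
      fnirs = cfg, seed = 680 + s
    ))
    suppressWarnings(subject_tmap(sub$epochs, accuracy_weight = 65, subject_id = s))
  })
  gm <- group_effect_map(tms)
  expect_true(all(abs(gm$cohens_d[gm$channel %in% effect_ch]) >
    max(abs(gm$cohens_d[!gm$channel %in% effect_ch]))))
  expect_equal(sign(gm$cohens_d[gm$channel %in% effect_ch]), c(-1, -1))
})
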