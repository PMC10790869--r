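test_that("class balancing equalises trial counts without touching AV trials", {
  set.seed(51)
  ep <- make_epochs(n_per_class = 10)
  # drop 20 of the HV side? build unbalanced: 30 HV / 10 AV
  ep_unbal <- make_epochs(n_per_class = 30)
  keep <- c(
    which(ep_unbal$trials$label == "AV")[1:10],
    which(ep_unbal$trials$label == "HV")
  )
  ep_unbal$samples <- ep_unbal$samples[keep, , , drop = FALSE]
  ep_unbal$trials <- ep_unbal$trials[keep, ]
  ep_unbal$trials$trial <- seq_along(keep)
  av_before <- ep_unbal$samples[ep_unbal$trials$label == "AV", , ]

  bal <- balance_classes(ep_unbal, seed = 1)
  expect_equal(sum(bal$trials$label == "AV"), 10)
  expect_equal(sum(bal$trials$label == "HV"), 10)
  expect_equal(bal$samples[bal$trials$label == "AV", , ], av_before)

  # already balanced -> identity
  bal2 <- balance_classes(ep, seed = 1)
  expect_equal(bal2$samples, ep$samples)

  ep_noav <- ep
  ep_noav$trials$label <- "HV"
  expect_error(balance_classes(ep_noav), "AV")
})

test_that("accuracy and F1 match their confusion-count definitions and an oracle tally", {
  counts <- list(tp_av = 60, tp_hv = 60, fp_av = 30, fp_hv = 30)
  expect_equal(accuracy_from_counts(counts), 200 / 3, tolerance = 1e-9)
  f1 <- f1_from_counts(counts)
  expect_equal(unname(f1["f1_av"]), 2 * 60 / (2 * 60 + 60), tolerance = 1e-9)
  expect_equal(unname(f1["f1_hv"]), 2 * 60 / (2 * 60 + 60), tolerance = 1e-9)

  set.seed(52)
  for (i in 1:20) {
    truth <- sample(c("AV", "HV"), 200, replace = TRUE)
    pred <- ifelse(runif(200) < 0.7, truth, sample(c("AV", "HV"), 200, replace = TRUE))
    cc <- gapnirs:::.confusion(truth, pred)
    orc <- oracle_metrics(truth, pred)
    expect_equal(accuracy_from_counts(cc), orc$accuracy, tolerance = 1e-12)
    f <- f1_from_counts(cc)
    expect_equal(unname(f["f1_av"]), orc$f1_av, tolerance = 1e-12)
    expect_equal(unname(f["f1_hv"]), orc$f1_hv, tolerance = 1e-12)
  }
})

test_that("PCA reduction drops the first PC and applies the eigenvalue rule", {
  set.seed(53)
  # dominant artifact direction: one direction with huge variance
  n <- 120; p <- 10
  artifact <- rnorm(n, sd = 20)
  X <- matrix(rnorm(n * p), n, p)
  X <- X + outer(artifact, rep(1 / sqrt(p), p))
  red <- pca_reduce(X, X)
  expect_false(1L %in% red$retained)
  # the retained space is orthogonal to the artifact direction: projecting
  # the artifact regressor onto retained scores explains little variance
  cors <- abs(cor(artifact, red$train))
  expect_lt(max(cors), 0.3)
  # test = train gives identical representations
  expect_equal(red$train, red$test)

  # white-noise eigenvalue rule matches an independent eigen decomposition
  Z <- matrix(rnorm(400 * 20), 400, 20)
  red2 <- pca_reduce(Z, Z, drop_first_pc = FALSE, eig_min = 0.7)
  ev <- eigen(cov(scale(Z, scale = FALSE)), symmetric = TRUE)$values
  expect_equal(length(red2$retained), sum(ev >= 0.7))
  expect_equal(sort(red2$eigenvalues, decreasing = TRUE), sort(ev, decreasing = TRUE),
    tolerance = 1e-8
  )

  # degenerate: everything below the cut degrades to 2 PCs with a warning
  small <- matrix(rnorm(40 * 6, sd = 0.01), 40, 6)
  expect_warning(red3 <- pca_reduce(small, small), "keeping 2")
  expect_equal(ncol(red3$train), 2)
})

test_that("planted-signal epochs decode far above chance, shuffled labels at chance", {
  set.seed(54)
  ep <- make_epochs(
    n_per_class = 16, n_channels = 12, effect_channels = c(2, 5, 9),
    delta = 2.5, noise_sd = 0.6
  )
  cfg <- decoder_config(seed = 7, n_permutations = 30)
  res <- nested_cv_decode(ep, cfg)
  expect_gte(res$accuracy_pct, 95)
  expect_true(all(res$per_fold$n_pc >= 2))

  shuf <- ep
  set.seed(99)
  shuf$trials$label <- sample(shuf$trials$label)
  res_s <- nested_cv_decode(shuf, cfg)
  ci <- empirical_chance_ci(shuf, cfg)
  # shuffled decode must not exceed the chance interval (one draw from the
  # null); the interval straddles theoretical chance
  expect_lte(res_s$accuracy_pct, ci$ci[[2]] + 1e-9)
  expect_lt(ci$ci[[1]], 50)
  expect_gt(ci$ci[[2]], 50)
})

test_that("decoding is invariant to channel order and deterministic under a seed", {
  set.seed(55)
  ep <- make_epochs(
    n_per_class = 12, n_channels = 8, effect_channels = c(1, 4),
    delta = 1.5, noise_sd = 0.8
  )
  cfg <- decoder_config(seed = 11, n_permutations = 20)
  r1 <- nested_cv_decode(ep, cfg)
  r2 <- nested_cv_decode(ep, cfg)
  expect_identical(r1$per_fold, r2$per_fold)

  perm <- sample(8)
  ep_p <- ep
  ep_p$samples <- ep$samples[, perm, , drop = FALSE]
  ep_p$channels <- ep$channels[perm, ]
  r3 <- nested_cv_decode(ep_p, cfg)
  expect_equal(r3$accuracy_pct, r1$accuracy_pct, tolerance = 1e-6)
})

test_that("nested folds never split a trial across train and test", {
  set.seed(56)
  ep <- make_epochs(n_per_class = 10, n_channels = 6)
  # leakage probe: timepoints of one trial are near-duplicates; sample-level
  # folding would classify them from their twins, trial-grouped must not
  cfg <- decoder_config(seed = 3)
  dat <- gapnirs:::.epochs_to_samples(ep)
  units <- dat$trial
  u_lab <- dat$y[match(unique(units), units)]
  set.seed(3)
  fold <- gapnirs:::.make_folds(u_lab, 5)[match(units, unique(units))]
  tab <- table(dat$trial, fold)
  expect_true(all(rowSums(tab > 0) == 1))
  # stratification: every fold holds both classes at the trial level
  trial_fold <- fold[!duplicated(dat$trial)]
  trial_lab <- dat$y[!duplicated(dat$trial)]
  expect_true(all(table(trial_lab, trial_fold) > 0))
})

test_that("no leakage: a model trained on signal scores fresh null test data at chance", {
  set.seed(57)
  ep <- make_epochs(
    n_per_class = 40, n_channels = 8, effect_channels = 1:4,
    delta = 3, noise_sd = 0.5
  )
  dat <- gapnirs:::.epochs_to_samples(ep)
  red <- suppressWarnings(pca_reduce(dat$X, matrix(rnorm(400 * 8), 400, 8)))
  fit <- gapnirs:::.fit_ridge(red$train, dat$y, 10^seq(-2, 2, length.out = 20))
  p <- predict(fit, red$test, s = 1, type = "response")[, 1]
  pred <- ifelse(p >= 0.5, "AV", "HV")
  truth <- sample(c("AV", "HV"), 400, replace = TRUE)
  acc <- 100 * mean(pred == truth)
  expect_lt(acc, 60)
  expect_gt(acc, 40)

  # and an end-to-end null: pure-noise epochs decode at chance
  ep_null <- make_epochs(n_per_class = 12, n_channels = 8)
  res <- nested_cv_decode(ep_null, decoder_config(seed = 5))
  expect_lt(res$accuracy_pct, 70)
  expect_gt(res$accuracy_pct, 30)
})

test_that("single-trial classes and tiny designs are rejected", {
  set.seed(58)
  ep <- make_epochs(n_per_class = 2)
  expect_error(nested_cv_decode(ep), "trials per class")
})

test_that("tidy and glance summarise the decoding result", {
  set.seed(59)
  ep <- make_epochs(n_per_class = 8, n_channels = 6, effect_channels = 1:2, delta = 2)
  res <- nested_cv_decode(ep, decoder_config(seed = 1))
  td <- tidy(res)
  expect_equal(nrow(td), 5)
  expect_equal(mean(td$accuracy), res$accuracy_pct)
  gl <- glance(res)
  expect_equal(gl$n_trials, 16)
  expect_true(gl$accuracy_pct >= 0 && gl$accuracy_pct <= 100)
})
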