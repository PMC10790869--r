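# Multivariate decoding of the interaction partner (AV vs HV) from HbR
# decision-phase epochs: class balancing, train-only PCA reduction (drop the
# first PC, Kaiser/Jolliffe eigenvalue cut at 0.7), and logistic ridge
# regression inside a nested cross-validation whose inner loop tunes the
# regularization strength and the number of retained principal components.
# Every timepoint of an epoch is one sample; folding is grouped by trial so
# that the timepoints of one epoch never straddle a train/test split.

#' Decoder configuration
#'
#' @param outer_folds,inner_folds Fold counts of the nested cross-validation
#'   (defaults 5/5).
#' @param lambda_grid Ridge penalty grid (default 50 log-spaced values,
#'   1e-4 to 1e4).
#' @param drop_first_pc Remove the first principal component (motion-linked)
#'   before classification (default TRUE).
#' @param eig_min Minimum eigenvalue for a PC to be retained (default 0.7,
#'   Jolliffe's relaxation of the Kaiser rule; features are z-scored so the
#'   covariance scale is approximately a correlation scale).
#' @param decision_threshold Class-probability threshold: samples with
#'   P(AV) >= threshold are called AV (default 0.5; the tie goes to AV).
#' @param n_permutations Label permutations for the empirical chance interval
#'   (default 100).
#' @param group_by_trial Keep all timepoints of a trial in one fold (default
#'   TRUE; FALSE folds on raw samples, which risks within-trial leakage from
#'   temporal autocorrelation).
#' @param seed Integer seed making folds, tuning and permutations
#'   reproducible.
#' @return A list of class `decoder_config`.
#' @export
decoder_config <- function(outer_folds = 5L, inner_folds = 5L,
                           lambda_grid = 10^seq(-4, 4, length.out = 50),
                           drop_first_pc = TRUE, eig_min = 0.7,
                           decision_threshold = 0.5,
                           n_permutations = 100L,
                           group_by_trial = TRUE, seed = NULL) {
  stopifnot(
    outer_folds >= 2, inner_folds >= 2, all(lambda_grid > 0),
    decision_threshold > 0, decision_threshold < 1
  )
  structure(
    list(
      outer_folds = as.integer(outer_folds),
      inner_folds = as.integer(inner_folds),
      lambda_grid = sort(lambda_grid, decreasing = TRUE),
      drop_first_pc = drop_first_pc, eig_min = eig_min,
      decision_threshold = decision_threshold,
      n_permutations = as.integer(n_permutations),
      group_by_trial = group_by_trial, seed = seed
    ),
    class = "decoder_config"
  )
}

#' Balance trial counts across conditions
#'
#' Randomly subsamples HV trials to match the (always rarer) AV trial count;
#' AV trials are untouched. Balancing precedes fold assignment.
#'
#' @param epochs An `fnirs_epochs` object.
#' @param seed Optional integer seed for the subsample.
#' @return A balanced `fnirs_epochs` (trial ids renumbered, original ids in
#'   `trials$source_trial`).
#' @export
balance_classes <- function(epochs, seed = NULL) {
  stopifnot(inherits(epochs, "fnirs_epochs"))
  n_av <- sum(epochs$trials$label == "AV")
  n_hv <- sum(epochs$trials$label == "HV")
  if (n_av == 0) stop("no AV trials to balance against", call. = FALSE)
  if (n_hv == n_av) {
    epochs$trials$source_trial <- epochs$trials$trial
    return(epochs)
  }
  if (n_hv < n_av) stop("fewer HV than AV trials: unexpected design", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  keep_hv <- sort(sample(which(epochs$trials$label == "HV"), n_av))
  keep <- sort(c(which(epochs$trials$label == "AV"), keep_hv))
  epochs$samples <- epochs$samples[keep, , , drop = FALSE]
  epochs$trials <- epochs$trials[keep, ]
  epochs$trials$source_trial <- epochs$trials$trial
  epochs$trials$trial <- seq_len(nrow(epochs$trials))
  epochs
}

#' Train-fold PCA reduction with first-PC removal and eigenvalue cut
#'
#' Fits PCA on the training samples only (centred on the train mean), removes
#' the first PC (linked to motion artifacts), removes PCs with eigenvalue
#' below `eig_min`, and projects the test samples with the training
#' eigenvectors and mean. If fewer than two PCs survive the cuts, the first
#' two post-removal PCs are kept with a warning.
#'
#' @param train,test Numeric matrices, samples x features.
#' @param drop_first_pc,eig_min See [decoder_config()].
#' @return List: `train`, `test` (reduced matrices), `eigenvalues` (all PCs),
#'   `retained` (column indices into the original PC order).
#' @export
pca_reduce <- function(train, test, drop_first_pc = TRUE, eig_min = 0.7) {
  stopifnot(nrow(train) >= 2)
  pc <- prcomp(train, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  idx <- seq_along(eig)
  if (drop_first_pc) idx <- idx[-1]
  idx <- idx[eig[idx] >= eig_min]
  if (length(idx) < 2) {
    warning("fewer than 2 PCs retained by the eigenvalue rule; keeping 2")
    idx <- head(setdiff(seq_along(eig), if (drop_first_pc) 1L else integer(0)), 2)
  }
  ctr <- function(m) sweep(m, 2, pc$center)
  list(
    train = ctr(train) %*% pc$rotation[, idx, drop = FALSE],
    test = ctr(test) %*% pc$rotation[, idx, drop = FALSE],
    eigenvalues = eig, retained = idx
  )
}

#' Classification accuracy and F1 from confusion counts
#'
#' `tp_av`/`tp_hv` are correctly classified AV/HV samples; `fp_av` are HV
#' samples called AV and `fp_hv` AV samples called HV. Accuracy is the percent
#' of correctly classified samples; the F1 score of a class is the harmonic
#' mean of its precision and recall,
#' `F1_AV = 2 TP_AV / (2 TP_AV + FP_AV + FP_HV)` (and symmetrically for HV).
#'
#' @param counts Named list or vector with `tp_av`, `tp_hv`, `fp_av`, `fp_hv`.
#' @return `accuracy_from_counts()`: percent in [0, 100];
#'   `f1_from_counts()`: named vector `f1_av`, `f1_hv`.
#' @export
accuracy_from_counts <- function(counts) {
  counts <- as.list(counts)
  tot <- counts$tp_av + counts$tp_hv + counts$fp_av + counts$fp_hv
  if (tot == 0) stop("empty confusion counts", call. = FALSE)
  100 * (counts$tp_av + counts$tp_hv) / tot
}

#' @rdname accuracy_from_counts
#' @export
f1_from_counts <- function(counts) {
  counts <- as.list(counts)
  c(
    f1_av = 2 * counts$tp_av / (2 * counts$tp_av + counts$fp_av + counts$fp_hv),
    f1_hv = 2 * counts$tp_hv / (2 * counts$tp_hv + counts$fp_av + counts$fp_hv)
  )
}

.confusion <- function(truth, predicted) {
  list(
    tp_av = sum(truth == "AV" & predicted == "AV"),
    tp_hv = sum(truth == "HV" & predicted == "HV"),
    fp_av = sum(truth == "HV" & predicted == "AV"),
    fp_hv = sum(truth == "AV" & predicted == "HV")
  )
}

# stratified fold assignment over trials (or samples)
.make_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# flatten epochs into a per-timepoint design: X (samples x channels),
# y, and the trial id of every sample
.epochs_to_samples <- function(epochs) {
  d <- dim(epochs$samples)
  X <- matrix(aperm(epochs$samples, c(3, 1, 2)), nrow = d[1] * d[3], ncol = d[2])
  list(
    X = X,
    y = rep(epochs$trials$label, each = d[3]),
    trial = rep(epochs$trials$trial, each = d[3])
  )
}

.fit_ridge <- function(x, y, lambda_grid) {
  glmnet::glmnet(x, factor(y, levels = c("HV", "AV")),
    family = "binomial", alpha = 0,
    lambda = lambda_grid, standardize = FALSE
  )
}

# inner-loop grid search over (number of PCs, lambda); returns the pair
# maximizing mean inner-validation accuracy (ties: fewer PCs, larger lambda)
.inner_search <- function(X, y, trial, cfg) {
  units <- if (cfg$group_by_trial) trial else seq_along(y)
  u_ids <- unique(units)
  u_lab <- y[match(u_ids, units)]
  fold_of <- .make_folds(u_lab, cfg$inner_folds)[match(units, u_ids)]
  acc <- NULL
  pc_counts <- NULL
  for (f in seq_len(cfg$inner_folds)) {
    tr <- fold_of != f
    red <- suppressWarnings(
      pca_reduce(X[tr, , drop = FALSE], X[!tr, , drop = FALSE],
        cfg$drop_first_pc, cfg$eig_min
      )
    )
    ks <- seq(2L, ncol(red$train))
    if (is.null(acc)) {
      pc_counts <- ks
      acc <- matrix(0, length(ks), length(cfg$lambda_grid))
    } else if (length(ks) != length(pc_counts)) {
      # retained-PC count varies slightly across folds; align on prefix
      n <- min(length(ks), length(pc_counts))
      pc_counts <- pc_counts[seq_len(n)]
      acc <- acc[seq_len(n), , drop = FALSE]
      ks <- ks[seq_len(n)]
    }
    for (i in seq_along(ks)) {
      fit <- .fit_ridge(
        red$train[, seq_len(ks[i]), drop = FALSE], y[tr], cfg$lambda_grid
      )
      p <- predict(fit, red$test[, seq_len(ks[i]), drop = FALSE],
        s = cfg$lambda_grid, type = "response"
      )
      pred <- ifelse(p >= cfg$decision_threshold, "AV", "HV")
      acc[i, ] <- acc[i, ] + colMeans(pred == y[!tr])[seq_len(ncol(acc))]
    }
  }
  best <- arrayInd(which.max(acc), dim(acc))
  list(n_pc = pc_counts[best[1]], lambda = cfg$lambda_grid[best[2]])
}

#' Nested cross-validated decoding of the interaction partner
#'
#' Predicts AV vs HV per timepoint from multichannel HbR epochs with logistic
#' ridge regression. The outer loop (default 5-fold, stratified, grouped by
#' trial) estimates generalization; for each outer training set the inner
#' loop (default 5-fold) selects the ridge penalty and the number of retained
#' principal components by validation accuracy. PCA is always fit on training
#' data only; the first PC is removed and PCs with eigenvalue < 0.7 are
#' discarded before the retained-count search (over prefixes 2..K). Samples
#' with model output P(AV) >= 0.5 are assigned to class AV.
#'
#' @param epochs A balanced `fnirs_epochs` (see [balance_classes()]).
#' @param cfg A [decoder_config()].
#' @return An object of class `decoding_result`: `accuracy_pct` (mean across
#'   outer folds), `accuracy_sd`, `f1_av`, `f1_hv`, `f1_mean`, `per_fold`
#'   tibble (fold, accuracy, F1s, chosen lambda and PC count, confusion
#'   counts), pooled `counts`, and `n_samples`/`n_trials`. Supports [tidy()]
#'   and [glance()].
#' @export
nested_cv_decode <- function(epochs, cfg = decoder_config()) {
  stopifnot(inherits(epochs, "fnirs_epochs"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  dat <- .epochs_to_samples(epochs)
  tab <- table(epochs$trials$label)
  if (length(tab) < 2) stop("both classes required", call. = FALSE)
  if (min(tab) < cfg$outer_folds) {
    stop("need at least `outer_folds` trials per class", call. = FALSE)
  }
  units <- if (cfg$group_by_trial) dat$trial else seq_along(dat$y)
  u_ids <- unique(units)
  u_lab <- dat$y[match(u_ids, units)]
  fold_of <- .make_folds(u_lab, cfg$outer_folds)[match(units, u_ids)]

  per_fold <- purrr::map(seq_len(cfg$outer_folds), function(f) {
    tr <- fold_of != f
    tuned <- .inner_search(
      dat$X[tr, , drop = FALSE], dat$y[tr], dat$trial[tr], cfg
    )
    red <- suppressWarnings(pca_reduce(
      dat$X[tr, , drop = FALSE], dat$X[!tr, , drop = FALSE],
      cfg$drop_first_pc, cfg$eig_min
    ))
    k <- min(tuned$n_pc, ncol(red$train))
    fit <- .fit_ridge(red$train[, seq_len(k), drop = FALSE], dat$y[tr], cfg$lambda_grid)
    p <- predict(fit, red$test[, seq_len(k), drop = FALSE],
      s = tuned$lambda, type = "response"
    )[, 1]
    pred <- ifelse(p >= cfg$decision_threshold, "AV", "HV")
    cc <- .confusion(dat$y[!tr], pred)
    f1 <- f1_from_counts(cc)
    tibble::tibble(
      fold = f, accuracy = accuracy_from_counts(cc),
      f1_av = f1[["f1_av"]], f1_hv = f1[["f1_hv"]],
      lambda = tuned$lambda, n_pc = k,
      tp_av = cc$tp_av, tp_hv = cc$tp_hv, fp_av = cc$fp_av, fp_hv = cc$fp_hv
    )
  }) |> purrr::list_rbind()

  counts <- list(
    tp_av = sum(per_fold$tp_av), tp_hv = sum(per_fold$tp_hv),
    fp_av = sum(per_fold$fp_av), fp_hv = sum(per_fold$fp_hv)
  )
  f1 <- f1_from_counts(counts)
  structure(
    list(
      accuracy_pct = mean(per_fold$accuracy),
      accuracy_sd = sd(per_fold$accuracy),
      f1_av = f1[["f1_av"]], f1_hv = f1[["f1_hv"]],
      f1_mean = mean(f1),
      per_fold = per_fold, counts = counts,
      n_samples = length(dat$y), n_trials = nrow(epochs$trials),
      chance_ci = NULL, config = cfg
    ),
    class = "decoding_result"
  )
}

#' Empirical chance interval by trial-label permutation
#'
#' Repeats the full nested decode on data whose trial labels have been
#' permuted (class sizes preserved) and returns the 5th-95th percentile of
#' the permuted accuracies — the accuracy range compatible with guessing.
#'
#' @param epochs A balanced `fnirs_epochs`.
#' @param cfg A [decoder_config()]; `n_permutations` and `seed` are honoured.
#' @return A list: `ci` (named numeric, percent, 5% and 95% bounds),
#'   `accuracies` (all permuted accuracies), `n_permutations`.
#' @export
empirical_chance_ci <- function(epochs, cfg = decoder_config()) {
  stopifnot(inherits(epochs, "fnirs_epochs"))
  if (cfg$n_permutations < 20) {
    warning("fewer than 20 permutations: chance interval unstable")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cfg_inner <- cfg
  cfg_inner$seed <- NULL
  accs <- purrr::map_dbl(seq_len(cfg$n_permutations), function(i) {
    perm <- epochs
    perm$trials$label <- sample(perm$trials$label)
    nested_cv_decode(perm, cfg_inner)$accuracy_pct
  })
  list(
    ci = c(quantile(accs, 0.05), quantile(accs, 0.95)),
    accuracies = accs,
    n_permutations = cfg$n_permutations
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "Nested-CV decoding (AV vs HV): accuracy %.1f%% (SD %.1f%% across folds)\n",
    x$accuracy_pct, x$accuracy_sd
  ))
  cat(sprintf(
    "  F1: AV %.2f, HV %.2f (mean %.2f); %d trials, %d samples\n",
    x$f1_av, x$f1_hv, x$f1_mean, x$n_trials, x$n_samples
  ))
  if (!is.null(x$chance_ci)) {
    cat(sprintf(
      "  empirical chance 5-95%%: %.1f-%.1f%%\n",
      x$chance_ci[1], x$chance_ci[2]
    ))
  }
  invisible(x)
}

#' @export
tidy.decoding_result <- function(x, ...) x$per_fold

#' @export
glance.decoding_result <- function(x, ...) {
  tibble::tibble(
    accuracy_pct = x$accuracy_pct, accuracy_sd = x$accuracy_sd,
    f1_av = x$f1_av, f1_hv = x$f1_hv, f1_mean = x$f1_mean,
    n_trials = x$n_trials, n_samples = x$n_samples,
    chance_lo = if (is.null(x$chance_ci)) NA_real_ else x$chance_ci[[1]],
    chance_hi = if (is.null(x$chance_ci)) NA_real_ else x$chance_ci[[2]]
  )
}
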