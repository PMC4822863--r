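# Pitch-ranking experiment: a two-output single-layer perceptron (softmax
# + delta rule, i.e. back-propagation collapsed to one layer) decides
# which member of a pair of pooled ISIHs has the higher pitch.

#' Build an ISIH pool for ranking
#'
#' One smoothed pooled ISIH per (stimulus type, pitch) combination,
#' computed from the trained model; histograms are reused across pairs, as
#' implied by the fixed stimulus set.
#'
#' @param model A [pitch_snn] fit.
#' @param types Stimulus types in the pool (same-type pairs only are ever
#'   formed).
#' @param seed Integer seed.
#' @param reps Presentations pooled per histogram.
#' @return A list with `features` (named list `type:pitch_index` of
#'   smoothed 50-bin vectors), `types`, `pitches`.
#' @export
isih_pool <- function(model, types = c("vowel_a", "vowel_i"), seed = 1,
                      reps = NULL) {
  stopifnot(inherits(model, "pitch_snn"))
  feats <- list()
  for (ty in types) {
    st <- stacked_isih(model, stim_type = ty, seed = seed, reps = reps)
    for (k in seq_along(st))
      feats[[paste(ty, k, sep = ":")]] <- st[[k]]$smoothed
  }
  list(features = feats, types = types, pitches = model$pitches)
}

# All eligible ordered same-type pairs with semitone separation in range.
.eligible_pairs <- function(types, n_pitch, interval_range = c(1, 12)) {
  out <- NULL
  for (ty in types) {
    ij <- expand.grid(i = seq_len(n_pitch), j = seq_len(n_pitch))
    d <- abs(ij$i - ij$j)
    keep <- d >= interval_range[1] & d <= interval_range[2]
    out <- rbind(out, data.frame(type = ty, a = ij$i[keep], b = ij$j[keep],
                                 interval = d[keep]))
  }
  out
}

#' Sample ranking pairs
#'
#' Uniform random draws (with replacement) from the eligible set of
#' same-type pairs whose pitches differ by 1--12 semitones; presentation
#' order is part of the draw, and the label records which member has the
#' higher pitch.
#'
#' @param pool An [isih_pool()].
#' @param n Number of pairs.
#' @param interval_range Allowed semitone separations, inclusive.
#' @param seed Integer seed.
#' @param eligible Optional pre-filtered eligible-pair data.frame (used by
#'   the experiment driver to keep train and test pools disjoint).
#' @return A data.frame: `type`, `a`, `b` (pitch indices in presentation
#'   order), `interval` (semitones), `label` (1 if the first member is
#'   higher-pitched, 2 otherwise).
#' @export
make_ranking_pairs <- function(pool, n, interval_range = c(1, 12),
                               seed = 1, eligible = NULL) {
  if (is.null(eligible))
    eligible <- .eligible_pairs(pool$types, length(pool$pitches),
                                interval_range)
  if (!nrow(eligible)) stop("no eligible stimulus pairs")
  if (n == 0) return(eligible[0, c("type", "a", "b", "interval")])
  idx <- .with_seed(seed, sample.int(nrow(eligible), n, replace = TRUE))
  out <- eligible[idx, c("type", "a", "b", "interval")]
  out$label <- ifelse(out$a > out$b, 1L, 2L)
  rownames(out) <- NULL
  out
}

# pairs -> feature matrix (concatenated smoothed ISIHs) and labels
.pair_features <- function(pool, pairs) {
  X <- t(vapply(seq_len(nrow(pairs)), function(r) {
    ka <- paste(pairs$type[r], pairs$a[r], sep = ":")
    kb <- paste(pairs$type[r], pairs$b[r], sep = ":")
    c(pool$features[[ka]], pool$features[[kb]])
  }, numeric(2 * length(pool$features[[1]]))))
  list(X = X, y = pairs$label)
}

#' Train the ranking perceptron
#'
#' Two linear output units with softmax on the concatenated pair vector,
#' fitted by full-batch gradient descent on the cross-entropy (the delta
#' rule -- back-propagation through a single layer). A validation split is
#' held out for early stopping.
#'
#' @param X Feature matrix (pairs x features).
#' @param y Labels (1 or 2: which member is higher-pitched).
#' @param learning_rate Gradient step size.
#' @param max_epochs Epoch cap.
#' @param val_frac Validation fraction for early stopping.
#' @param patience Epochs without validation improvement before stopping.
#' @param seed Integer seed (initial weights, validation split).
#' @return A list of class `rank_perceptron` with the weight matrix `W`
#'   (2 x (features + 1), bias last) and the epochs run.
#' @export
perceptron_train <- function(X, y, learning_rate = 0.1, max_epochs = 500,
                             val_frac = 0.1, patience = 25, seed = 1) {
  stopifnot(nrow(X) == length(y), nrow(X) > 0)
  n <- nrow(X)
  Xb <- cbind(X, 1)
  Y <- cbind(y == 1L, y == 2L) * 1
  .with_seed(seed, {
    val <- sample.int(n, max(1L, round(val_frac * n)))
    W <- matrix(stats::rnorm(2 * ncol(Xb), sd = 0.01), 2, ncol(Xb))
  })
  tr <- setdiff(seq_len(n), val)
  if (!length(tr)) tr <- seq_len(n)
  best <- list(W = W, loss = Inf, since = 0L)
  softmax <- function(Z) {
    Z <- Z - apply(Z, 1, max)
    E <- exp(Z)
    E / rowSums(E)
  }
  xent <- function(P, Y) -mean(log(rowSums(P * Y) + 1e-12))
  epoch <- 0L
  for (epoch in seq_len(max_epochs)) {
    P <- softmax(Xb[tr, , drop = FALSE] %*% t(W))
    G <- t(P - Y[tr, , drop = FALSE]) %*% Xb[tr, , drop = FALSE] / length(tr)
    W <- W - learning_rate * G
    vloss <- xent(softmax(Xb[val, , drop = FALSE] %*% t(W)),
                  Y[val, , drop = FALSE])
    if (vloss < best$loss - 1e-6) {
      best <- list(W = W, loss = vloss, since = 0L)
    } else {
      best$since <- best$since + 1L
      if (best$since >= patience) break
    }
  }
  structure(list(W = best$W, epochs = epoch, val_loss = best$loss),
            class = "rank_perceptron")
}

#' @export
predict.rank_perceptron <- function(object, X, ...) {
  Z <- cbind(X, 1) %*% t(object$W)
  ifelse(Z[, 1] >= Z[, 2], 1L, 2L)
}

#' Run the pitch-ranking experiment
#'
#' For each trial, the eligible same-type pair set is split into disjoint
#' train- and test-eligible subsets; 1500 training pairs (10% reserved for
#' validation) and 500 unseen test pairs are drawn, the perceptron is
#' fitted, and per-semitone-interval accuracy is recorded. Scores are
#' averaged over trials with their standard errors. Chance level is 50%.
#'
#' @param pool An [isih_pool()].
#' @param n_train,n_test Pairs per trial.
#' @param n_trials Trials.
#' @param test_frac Fraction of the eligible pair set reserved for
#'   testing.
#' @param seed Integer master seed.
#' @param ... Passed to [perceptron_train()].
#' @return A data.frame: `interval` (semitones), `mean_score`, `sem`,
#'   `n_pairs` (test pairs contributing across trials); attribute
#'   `overall` holds the per-trial overall accuracies.
#' @export
pitch_ranking_experiment <- function(pool, n_train = 1500, n_test = 500,
                                     n_trials = 20, test_frac = 0.25,
                                     seed = 1, ...) {
  eligible <- .eligible_pairs(pool$types, length(pool$pitches))
  seeds <- .sub_seeds(seed, 3L * n_trials)
  per_int <- list()
  overall <- numeric(n_trials)
  for (tr in seq_len(n_trials)) {
    te_idx <- .with_seed(seeds[3 * tr - 2],
                         sample.int(nrow(eligible),
                                    round(test_frac * nrow(eligible))))
    train_pairs <- make_ranking_pairs(pool, n_train,
                                      seed = seeds[3 * tr - 1],
                                      eligible = eligible[-te_idx, ])
    test_pairs <- make_ranking_pairs(pool, n_test, seed = seeds[3 * tr],
                                     eligible = eligible[te_idx, ])
    trf <- .pair_features(pool, train_pairs)
    tef <- .pair_features(pool, test_pairs)
    fit <- perceptron_train(trf$X, trf$y, seed = seeds[3 * tr], ...)
    ok <- predict(fit, tef$X) == tef$y
    overall[tr] <- mean(ok)
    per_int[[tr]] <- tapply(ok, test_pairs$interval, mean)
  }
  ints <- sort(unique(unlist(lapply(per_int, names))))
  res <- do.call(rbind, lapply(ints, function(iv) {
    sc <- vapply(per_int, function(p) p[iv] %||% NA_real_, numeric(1))
    sc <- sc[!is.na(sc)]
    data.frame(interval = as.integer(iv), mean_score = mean(sc),
               sem = stats::sd(sc) / sqrt(length(sc)),
               n_trials = length(sc))
  }))
  attr(res, "overall") <- overall
  res
}
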