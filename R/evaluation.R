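## Goodness-of-fit suite: train/test splitting, moment statistics, nRMSE,
## reconstruction likelihood, GLM baseline, compositional-phase
## diagnostics, bimodality / time constants, hidden-unit sorting.

#' Chronological train/test split selection
#'
#' Divides the recording into `n_segments` chronological segments of equal
#' length and enumerates every choice of `n_test` test segments. Each
#' candidate split is scored by the RMSE between train and test over the
#' concatenated \eqn{[\langle v_i\rangle;\ \langle v_i v_j\rangle -
#' \langle v_i\rangle\langle v_j\rangle]} statistics; candidates are
#' ranked ascending and the split at the requested percentile rank is
#' returned (rank `floor(percentile/100 * n_candidates)`, 0-based, so
#' percentile 0 gives the most similar split).
#'
#' @param data a [crbm_data] or N x T binary matrix.
#' @param n_segments number of chronological segments (default 10).
#' @param n_test number of test segments (default 3).
#' @param percentile percentile of the ascending RMSE ranking to select
#'   (default 10).
#' @return object of class `crbm_split`: list with `segments` (frame
#'   index list), `test_segments` (chosen segment triple), `train_idx`,
#'   `test_idx` (frame indices), `rank` (1-based rank of the chosen
#'   split), `rmse` (its score) and `candidates` (data.frame of all
#'   splits with scores).
#' @export
split_train_test <- function(data, n_segments = 10, n_test = 3, percentile = 10) {
  v <- if (inherits(data, "crbm_data")) data$v else as.matrix(data)
  Tn <- ncol(v)
  if (Tn < n_segments)
    stop_dims("need at least n_segments = %d frames, got %d", n_segments, Tn)
  bounds <- floor(Tn * (0:n_segments) / n_segments)
  segments <- lapply(seq_len(n_segments), function(k) (bounds[k] + 1):bounds[k + 1])

  seg_stats <- lapply(segments, function(idx) {
    x <- v[, idx, drop = FALSE]
    n <- length(idx)
    list(n = n, s1 = rowSums(x), s2 = tcrossprod(x))
  })

  stat_vec <- function(segs) {
    n <- sum(vapply(segs, `[[`, numeric(1), "n"))
    s1 <- Reduce(`+`, lapply(segs, `[[`, "s1"))
    s2 <- Reduce(`+`, lapply(segs, `[[`, "s2"))
    mv <- s1 / n
    vv <- s2 / n - tcrossprod(mv)
    c(mv, vv[upper.tri(vv)])
  }

  combos <- utils::combn(n_segments, n_test)
  scores <- apply(combos, 2, function(test_set) {
    rmse(stat_vec(seg_stats[test_set]), stat_vec(seg_stats[-test_set]))
  })
  ord <- order(scores)
  pick <- ord[min(floor(percentile / 100 * ncol(combos)), ncol(combos) - 1) + 1]
  test_set <- combos[, pick]

  structure(list(
    segments = segments,
    test_segments = test_set,
    train_idx = sort(unlist(segments[-test_set])),
    test_idx = sort(unlist(segments[test_set])),
    rank = which(ord == pick),
    rmse = scores[pick],
    candidates = data.frame(t(combos), rmse = scores)
  ), class = "crbm_split")
}

#' Moment statistics of a data source
#'
#' Computes the five moment sets used for goodness-of-fit assessment:
#' \eqn{\langle v_i\rangle}, \eqn{\langle h_\mu\rangle},
#' \eqn{\langle v_i h_\mu\rangle}, and the centered pairwise statistics
#' \eqn{\langle v_i v_j\rangle - \langle v_i\rangle\langle v_j\rangle},
#' \eqn{\langle h_\mu h_\nu\rangle - \langle h_\mu\rangle\langle
#' h_\nu\rangle}. Hidden values are taken as conditional means
#' \eqn{\Gamma'_\mu(I_\mu(v_t))} when derived from `params`, or from an
#' explicit hidden sample matrix `h` (e.g. model-generated samples).
#'
#' @param v N x T binary matrix (or [crbm_data]).
#' @param params a [crbm_params], used to infer hidden activity, or `NULL`
#'   if `h` is given.
#' @param h optional explicit T x M hidden matrix.
#' @param source tag, e.g. `"train"`, `"test"`, `"model"`.
#' @return object of class `crbm_statistics` with fields `mean_v`,
#'   `mean_h`, `vh`, `vv_centered`, `hh_centered`, `source`.
#' @export
compute_statistics <- function(v, params = NULL, h = NULL, source = "data") {
  v <- if (inherits(v, "crbm_data")) v$v else as.matrix(v)
  check_binary(v)
  Tn <- ncol(v)
  if (is.null(h)) {
    if (is.null(params)) stop_dims("either params or h must be supplied")
    h <- hidden_mean_given_v(t(v), params)
  } else {
    h <- as.matrix(h)
    if (nrow(h) != Tn) stop_dims("h has %d rows, expected T = %d frames", nrow(h), Tn)
  }
  mean_v <- rowMeans(v)
  mean_h <- colMeans(h)
  vv <- tcrossprod(v) / Tn - tcrossprod(mean_v)
  hh <- crossprod(h) / Tn - tcrossprod(mean_h)
  structure(list(mean_v = mean_v, mean_h = mean_h,
                 vh = v %*% h / Tn,
                 vv_centered = vv, hh_centered = hh,
                 source = source), class = "crbm_statistics")
}

#' Upper-triangle vector of a symmetric statistic matrix
#'
#' @param m symmetric matrix.
#' @param diag include the diagonal (default `FALSE`).
#' @return numeric vector of the (strict) upper triangle, column-major.
#' @export
upper_tri_vec <- function(m, diag = FALSE) m[upper.tri(m, diag = diag)]

#' Sparsity correction of the model <v h> statistic
#'
#' The training objective includes an L1 penalty, so at the optimum the
#' model-generated \eqn{\langle v_i h_\mu\rangle} differs from the data
#' statistic by the subgradient; the comparison statistic is corrected by
#' adding \eqn{\lambda\,\mathrm{sign}(w_{i\mu})}. Entries whose weight is
#' exactly zero are masked (`NA`) and excluded from downstream nRMSE.
#'
#' @param model_vh N x M matrix of model-generated \eqn{\langle v_i
#'   h_\mu\rangle}.
#' @param params a [crbm_params].
#' @param lambda the sparsity coefficient used in training.
#' @return corrected matrix with `NA` at zero-weight entries.
#' @export
sparsity_corrected_vh <- function(model_vh, params, lambda) {
  model_vh <- as.matrix(model_vh)
  if (!all(dim(model_vh) == dim(params$weights)))
    stop_dims("model_vh and weights have different shapes")
  out <- model_vh + lambda * sign(params$weights)
  out[params$weights == 0] <- NA
  out
}

#' The nRMSE normalization formula
#'
#' \eqn{\mathrm{nRMSE} = 1 - (\mathrm{RMSE}_{ordinary} -
#' \mathrm{RMSE}_{shuffled}) / (\mathrm{RMSE}_{optimal} -
#' \mathrm{RMSE}_{shuffled})}: shuffled statistics map to 1 and the
#' train-vs-test RMSE maps to 0; values below 0 mean the model statistics
#' are closer to the test statistics than the training statistics are.
#'
#' @param ordinary RMSE between model and test statistics.
#' @param shuffled RMSE between the shuffled statistics.
#' @param optimal RMSE between train and test statistics.
#' @return the normalized value.
#' @export
nrmse_value <- function(ordinary, shuffled, optimal) {
  if (isTRUE(all.equal(optimal, shuffled)))
    stop_dims("degenerate nRMSE normalization: RMSE_optimal == RMSE_shuffled")
  1 - (ordinary - shuffled) / (optimal - shuffled)
}

#' Normalized RMSE between model and test statistics
#'
#' Computes \eqn{\mathrm{RMSE}_{ordinary}} between model and test
#' statistic vectors, the shuffled reference (both model and test vectors
#' independently permuted with a seeded permutation), the optimal
#' reference (train vs test) and applies [nrmse_value()]. Entries that are
#' `NA` in any vector (e.g. masked by [sparsity_corrected_vh()]) are
#' dropped jointly.
#'
#' @param model,test,train equal-length statistic vectors.
#' @param shuffle_seed seed of the fixed permutations used for the
#'   shuffled reference.
#' @param details return all components instead of just the value.
#' @return the nRMSE value, or (with `details = TRUE`) a list with the
#'   value, the three RMSE components and the shuffled vectors.
#' @export
nrmse <- function(model, test, train, shuffle_seed = 1, details = FALSE) {
  stopifnot(length(model) == length(test), length(train) == length(test))
  keep <- stats::complete.cases(cbind(model, test, train))
  model <- model[keep]; test <- test[keep]; train <- train[keep]
  n <- length(model)
  if (n < 2) stop_dims("need at least 2 statistic entries, got %d", n)
  rng <- crbm_rng(shuffle_seed)
  perm <- with_rng(rng, list(m = sample.int(n), t = sample.int(n)))
  model_shuffled <- model[perm$m]
  test_shuffled <- test[perm$t]
  ordinary <- rmse(model, test)
  shuffled <- rmse(model_shuffled, test_shuffled)
  optimal <- rmse(train, test)
  val <- nrmse_value(ordinary, shuffled, optimal)
  if (!details) return(val)
  list(value = val, rmse_ordinary = ordinary, rmse_shuffled = shuffled,
       rmse_optimal = optimal, model_shuffled = model_shuffled,
       test_shuffled = test_shuffled, n_used = n)
}

#' Bernoulli log-likelihood of a binary trace under a probability trace
#'
#' \eqn{\mathrm{LLH} = \frac{1}{T}\sum_t \log(p(t) v(t) + (1 - p(t))(1 -
#' v(t)))}. Probabilities are floored at `eps` only where they would
#' produce `log(0)`, so a perfect reconstruction scores exactly 0.
#'
#' @param v binary vector (one neuron's trace).
#' @param p probability vector of the same length.
#' @param eps clipping floor.
#' @return list with `llh` and `n_clipped`.
#' @export
bernoulli_llh <- function(v, p, eps = 1e-7) {
  stopifnot(length(v) == length(p))
  check_binary(v)
  lik <- ifelse(v == 1, p, 1 - p)
  n_clipped <- sum(lik < eps)
  list(llh = mean(log(pmax(lik, eps))), n_clipped = n_clipped)
}

#' Reconstruction log-likelihood of test data
#'
#' Round-trip reconstruction: data frames are mapped to hidden conditional
#' means \eqn{h = \Gamma'(I(v))}, then back to visible probabilities
#' \eqn{E(v_{recon}) = \sigma(g + W h)}; each neuron's Bernoulli
#' log-likelihood is normalized so that 0 corresponds to the independent
#' model (constant prediction at the neuron's empirical mean) and 1 to a
#' perfect reconstruction: \eqn{\mathrm{nLLH} = (\mathrm{LLH} -
#' \mathrm{LLH}_{indep}) / (-\mathrm{LLH}_{indep})}. Constant neurons
#' (degenerate independent likelihood) get nLLH 0 and are flagged.
#'
#' @param v N x T binary matrix (or [crbm_data]).
#' @param params a [crbm_params].
#' @return list with `per_neuron` (data.frame: `llh`, `llh_indep`,
#'   `nllh`, `flagged`), `median_nllh` and `n_clipped`.
#' @export
reconstruction_llh <- function(v, params) {
  v <- if (inherits(v, "crbm_data")) v$v else as.matrix(v)
  check_binary(v)
  h <- hidden_mean_given_v(t(v), params)
  p <- t(visible_mean_given_h(h, params))  # N x T
  reconstruction_llh_from_probs(v, p)
}

#' Normalized reconstruction log-likelihood from explicit probabilities
#'
#' Core of [reconstruction_llh()] and [glm_baseline()]: given the binary
#' data and an arbitrary matrix of per-frame reconstruction
#' probabilities, computes each neuron's Bernoulli log-likelihood and its
#' normalization against the independent (constant mean-rate) model.
#'
#' @param v N x T binary matrix.
#' @param p N x T matrix of reconstruction probabilities.
#' @param eps probability floor applied only where the likelihood would
#'   vanish.
#' @return list with `per_neuron` (data.frame: `llh`, `llh_indep`,
#'   `nllh`, `flagged`), `median_nllh`, `n_clipped`.
#' @export
reconstruction_llh_from_probs <- function(v, p, eps = 1e-7) {
  N <- nrow(v)
  out <- data.frame(llh = numeric(N), llh_indep = numeric(N),
                    nllh = numeric(N), flagged = logical(N))
  n_clipped <- 0
  for (i in seq_len(N)) {
    b <- bernoulli_llh(v[i, ], p[i, ], eps)
    ind <- bernoulli_llh(v[i, ], rep(mean(v[i, ]), ncol(v)), eps)
    out$llh[i] <- b$llh
    out$llh_indep[i] <- ind$llh
    n_clipped <- n_clipped + b$n_clipped
    if (ind$llh == 0) {  # constant neuron: independent model is already perfect
      out$nllh[i] <- 0
      out$flagged[i] <- TRUE
    } else {
      out$nllh[i] <- (b$llh - ind$llh) / (-ind$llh)
    }
  }
  list(per_neuron = out, median_nllh = stats::median(out$nllh),
       n_clipped = n_clipped)
}

#' Logistic-regression reconstruction baseline
#'
#' For each target neuron, fits an L2-penalized logistic regression
#' predicting its activity from all other neurons in the same frame
#' (fitted on training frames), then evaluates the normalized
#' reconstruction log-likelihood on test frames. `l2_strength` is the
#' total ridge coefficient of the summed-log-loss objective
#' \eqn{-\sum_t \log P(v_i(t)) + \frac{\lambda_{GLM}}{2}\|w\|^2} (the
#' inverse-C convention); it is passed to glmnet as
#' `lambda = l2_strength / T_train`.
#'
#' @param train,test N x T binary matrices with the same neuron set.
#' @param l2_strength ridge penalty (default 1000).
#' @param neurons optional indices of target neurons (default all).
#' @return as [reconstruction_llh()], restricted to `neurons`.
#' @export
glm_baseline <- function(train, test, l2_strength = 1000, neurons = NULL) {
  train <- if (inherits(train, "crbm_data")) train$v else as.matrix(train)
  test <- if (inherits(test, "crbm_data")) test$v else as.matrix(test)
  if (nrow(train) != nrow(test)) stop_dims("train and test must share the neuron set")
  check_binary(train); check_binary(test)
  neurons <- neurons %||% seq_len(nrow(train))
  xt <- t(train); xs <- t(test)
  p <- matrix(0, length(neurons), ncol(test))
  flagged_const <- logical(length(neurons))
  for (k in seq_along(neurons)) {
    i <- neurons[k]
    y <- xt[, i]
    if (length(unique(y)) < 2) {  # constant target: fall back to its mean
      p[k, ] <- mean(y)
      flagged_const[k] <- TRUE
      next
    }
    fit <- glmnet::glmnet(xt[, -i, drop = FALSE], y, family = "binomial",
                          alpha = 0, lambda = l2_strength / nrow(xt),
                          standardize = FALSE)
    eta <- stats::predict(fit, xs[, -i, drop = FALSE], type = "link")
    p[k, ] <- sigmoid(as.vector(eta))
  }
  res <- reconstruction_llh_from_probs(test[neurons, , drop = FALSE], p)
  res$per_neuron$flagged <- res$per_neuron$flagged | flagged_const
  res$per_neuron$neuron <- neurons
  res
}

#' Participation ratio
#'
#' \eqn{\mathrm{PR}(x) = (\sum_i x_i^2)^2 / \sum_i x_i^4}, an effective
#' count of the nonzero components of a vector: 1 for a one-hot vector, n
#' when all entries are equal. `normalized = TRUE` divides by `n` so the
#' result lies in (0, 1].
#'
#' @param x numeric vector, not all zero.
#' @param normalized divide by `length(x)`.
#' @return the participation ratio.
#' @export
participation_ratio <- function(x, normalized = FALSE) {
  if (all(x == 0)) stop_dims("participation ratio of the all-zero vector is undefined")
  pr <- sum(x^2)^2 / sum(x^4)
  if (normalized) pr / length(x) else pr
}

#' Compositional-phase statistic m(t)
#'
#' Effective number of active hidden units per frame. Each unit's inactive
#' peak is subtracted from its trace and the result rectified at zero
#' (inactive units must sit near zero for the participation ratio to count
#' active ones); \eqn{m(t)} is the participation ratio of the rectified
#' frame vector, which lies in \eqn{[1, M]} whenever at least one unit is
#' active, and is 0 by convention for frames with no active unit. A model
#' operates in the compositional phase when \eqn{1 \ll \mathrm{median}(m)
#' \ll M}.
#'
#' @param h_traj T x M matrix of hidden activity traces.
#' @param inactive_peaks length-M vector of per-unit inactive peaks (e.g.
#'   from [bimodality_points()]).
#' @return list with `m` (length-T vector), `median_m` and
#'   `median_fraction` (= median(m)/M).
#' @export
compositional_m <- function(h_traj, inactive_peaks) {
  h_traj <- as.matrix(h_traj)
  M <- ncol(h_traj)
  stopifnot(length(inactive_peaks) == M)
  hp <- pmax(sweep(h_traj, 2, inactive_peaks), 0)
  s2 <- rowSums(hp^2)
  s4 <- rowSums(hp^4)
  m <- ifelse(s2 > 0, s2^2 / s4, 0)
  list(m = m, median_m = stats::median(m), median_fraction = stats::median(m) / M)
}

#' Bimodality transition points of hidden-unit traces
#'
#' Fits a two-component univariate Gaussian mixture to each unit's
#' activity trace; the transition point is the midpoint of the two
#' component means and the inactive peak is the component with the lower
#' mean. Units whose mixture degenerates (constant trace or merged
#' components) are flagged unimodal, with the transition point at the
#' single mean.
#'
#' @param h_traj T x M matrix of hidden activity traces (T >= 100
#'   recommended for a stable fit).
#' @return data.frame with one row per unit: `transition`,
#'   `inactive_peak`, `active_peak`, `unimodal`.
#' @importFrom mclust mclustBIC
#' @export
bimodality_points <- function(h_traj) {
  h_traj <- as.matrix(h_traj)
  M <- ncol(h_traj)
  out <- data.frame(transition = numeric(M), inactive_peak = numeric(M),
                    active_peak = numeric(M), unimodal = logical(M))
  for (mu in seq_len(M)) {
    x <- h_traj[, mu]
    if (stats::sd(x) < 1e-12) {
      out$transition[mu] <- out$inactive_peak[mu] <- out$active_peak[mu] <- mean(x)
      out$unimodal[mu] <- TRUE
      next
    }
    fit <- try(suppressWarnings(
      mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)), silent = TRUE)
    if (inherits(fit, "try-error") || is.null(fit)) {
      out$transition[mu] <- out$inactive_peak[mu] <- out$active_peak[mu] <- mean(x)
      out$unimodal[mu] <- TRUE
      next
    }
    mus <- sort(fit$parameters$mean)
    if (diff(mus) < 1e-6 * max(stats::sd(x), 1e-12)) {
      out$transition[mu] <- out$inactive_peak[mu] <- out$active_peak[mu] <- mean(mus)
      out$unimodal[mu] <- TRUE
    } else {
      out$transition[mu] <- mean(mus)
      out$inactive_peak[mu] <- mus[1]
      out$active_peak[mu] <- mus[2]
    }
  }
  out
}

#' Oscillation time constants of activity traces
#'
#' Segments each trace into maximal sign runs (hidden units, traces
#' already transition-point subtracted) or no-spike / spike runs (binary
#' neurons) and defines one oscillation as a consecutive
#' (negative, positive) — respectively (no-spike, spike) — run pair; its
#' period is the summed length of the pair times the frame interval. The
#' per-unit median period is reported; units with no complete oscillation
#' get `NA`.
#'
#' @param traces T x K matrix (real-valued for `kind = "hidden"`, binary
#'   for `kind = "neuron"`).
#' @param frame_rate frames per second.
#' @param kind `"hidden"` or `"neuron"`.
#' @return length-K vector of median periods in seconds.
#' @export
time_constants <- function(traces, frame_rate, kind = c("hidden", "neuron")) {
  kind <- match.arg(kind)
  traces <- as.matrix(traces)
  apply(traces, 2, function(x) {
    state <- if (kind == "hidden") x > 0 else { check_binary(x); x == 1 }
    r <- rle(as.vector(state))
    ## drop a leading "active" run so pairs are (inactive, active)
    if (length(r$values) && r$values[1]) {
      r$values <- r$values[-1]; r$lengths <- r$lengths[-1]
    }
    n_pairs <- length(r$values) %/% 2
    if (n_pairs < 1) return(NA_real_)
    lens <- r$lengths[seq_len(2 * n_pairs)]
    periods <- lens[seq(1, 2 * n_pairs, by = 2)] + lens[seq(2, 2 * n_pairs, by = 2)]
    stats::median(periods) / frame_rate
  })
}

#' Sort hidden units by activity similarity
#'
#' Hierarchical clustering (Ward variance minimization) of the units'
#' Pearson correlation matrix, using distance \eqn{1 - r}; returns the
#' leaf order, which groups correlated units. Constant traces get zero
#' correlation with every other unit and are flagged.
#'
#' @param h_traj T x M matrix of hidden activity traces (M >= 2).
#' @return list with `order` (permutation of units), `hclust` (the
#'   clustering tree), `flagged` (constant-trace units).
#' @export
sort_hus <- function(h_traj) {
  h_traj <- as.matrix(h_traj)
  M <- ncol(h_traj)
  if (M < 2) stop_dims("need at least 2 hidden units to sort")
  sds <- apply(h_traj, 2, stats::sd)
  flagged <- which(sds < 1e-12)
  r <- suppressWarnings(stats::cor(h_traj))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  hc <- stats::hclust(stats::as.dist(1 - r), method = "ward.D2")
  list(order = hc$order, hclust = hc, flagged = flagged)
}

#' Full goodness-of-fit evaluation of a fitted model
#'
#' Convenience driver: computes train/test/model statistic bundles (model
#' statistics via [generate_model_statistics_dataset()]), nRMSE for each
#' of the five moment statistics (with the sparsity correction and
#' zero-weight masking applied to \eqn{\langle v_i h_\mu\rangle}), and the
#' median reconstruction nLLH on test data.
#'
#' @param params a [crbm_params].
#' @param train,test N x T binary matrices (or [crbm_data]).
#' @param rng a [crbm_rng] or integer seed (for the sampling protocol and
#'   the shuffles).
#' @param lambda sparsity coefficient used in training (for the
#'   \eqn{\langle v h\rangle} correction).
#' @param protocol named list overriding the model-statistics sampling
#'   protocol (`n_chains`, `n_saved`, `thin`, `burn_in`).
#' @param shuffle_seed seed for the nRMSE shuffled references.
#' @return list with `nrmse` (named vector over the five statistics),
#'   `reconstruction` (from [reconstruction_llh()]) and `statistics`
#'   (the three bundles).
#' @export
evaluate_model <- function(params, train, test, rng, lambda = 0,
                           protocol = list(), shuffle_seed = 1) {
  rng <- as_rng(rng)
  train_v <- if (inherits(train, "crbm_data")) train$v else as.matrix(train)
  test_v <- if (inherits(test, "crbm_data")) test$v else as.matrix(test)

  proto <- utils::modifyList(
    list(n_chains = 300, n_saved = 50, thin = 20, burn_in = 100), protocol)
  samp <- generate_model_statistics_dataset(
    params, train_v, rng, n_chains = proto$n_chains, n_saved = proto$n_saved,
    thin = proto$thin, burn_in = proto$burn_in)

  st_train <- compute_statistics(train_v, params, source = "train")
  st_test <- compute_statistics(test_v, params, source = "test")
  st_model <- compute_statistics(t(samp$v), h = samp$h, source = "model")

  vh_model <- sparsity_corrected_vh(st_model$vh, params, lambda)
  nr <- c(
    mean_v = nrmse(st_model$mean_v, st_test$mean_v, st_train$mean_v, shuffle_seed),
    mean_h = nrmse(st_model$mean_h, st_test$mean_h, st_train$mean_h, shuffle_seed),
    vh = nrmse(as.vector(vh_model), as.vector(st_test$vh),
               as.vector(st_train$vh), shuffle_seed),
    vv = nrmse(upper_tri_vec(st_model$vv_centered),
               upper_tri_vec(st_test$vv_centered),
               upper_tri_vec(st_train$vv_centered), shuffle_seed),
    hh = nrmse(upper_tri_vec(st_model$hh_centered),
               upper_tri_vec(st_test$hh_centered),
               upper_tri_vec(st_train$hh_centered), shuffle_seed))

  list(nrmse = nr,
       reconstruction = reconstruction_llh(test_v, params),
       statistics = list(train = st_train, test = st_test, model = st_model))
}
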