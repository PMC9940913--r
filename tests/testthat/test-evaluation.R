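test_that("split selection enumerates all candidates and honors the percentile rank", {
  set.seed(1)
  v <- matrix(rbinom(5 * 300, 1, 0.3), 5, 300)
  sp <- split_train_test(v)
  expect_equal(nrow(sp$candidates), choose(10, 3))
  expect_equal(length(sp$test_segments), 3)
  expect_equal(sort(c(sp$train_idx, sp$test_idx)), 1:300)
  expect_equal(sp$rank, floor(0.10 * 120) + 1)
  # percentile 0 returns the global minimum
  sp0 <- split_train_test(v, percentile = 0)
  expect_equal(sp0$rmse, min(sp0$candidates$rmse))
  expect_error(split_train_test(v[, 1:5]), "n_segments")
})

test_that("split selection agrees with a brute-force re-ranking", {
  set.seed(2)
  v <- matrix(rbinom(5 * 100, 1, 0.25), 5, 100)
  sp <- split_train_test(v, percentile = 10)
  ## independent implementation: recompute each candidate from raw frames
  combos <- combn(10, 3)
  seg <- lapply(1:10, function(k) ((k - 1) * 10 + 1):(k * 10))
  stat <- function(idx) {
    x <- v[, idx, drop = FALSE]
    mv <- rowMeans(x)
    vv <- tcrossprod(x) / length(idx) - tcrossprod(mv)
    c(mv, vv[upper.tri(vv)])
  }
  scores <- apply(combos, 2, function(ts) {
    te <- unlist(seg[ts]); tr <- setdiff(1:100, te)
    sqrt(mean((stat(te) - stat(tr))^2))
  })
  expect_equal(sp$candidates$rmse, scores, tolerance = 1e-12)
  pick <- order(scores)[floor(0.1 * 120) + 1]
  expect_equal(sp$test_segments, combos[, pick])
})

test_that("statistic bundles match a hand-computed instance", {
  v <- matrix(c(1, 0, 0,
                1, 1, 0,
                0, 1, 0,
                1, 0, 0), nrow = 3)  # 3 neurons x 4 frames
  h <- matrix(c(1, 2, 0, 1,
                0, 1, 1, 0), nrow = 4)
  st <- compute_statistics(v, h = h)
  expect_equal(st$mean_v, c(3 / 4, 2 / 4, 0))
  expect_equal(st$mean_h, c(1, 0.5))
  expect_equal(st$vh[1, 1], (1 * 1 + 1 * 2 + 0 * 0 + 1 * 1) / 4)
  expect_equal(st$vh[2, 2], (0 * 0 + 1 * 1 + 1 * 1 + 0 * 0) / 4)
  expect_equal(st$vv_centered[1, 2], 1 / 4 - (3 / 4) * (2 / 4))
  expect_equal(st$hh_centered[1, 2], (0 + 2 + 0 + 0) / 4 - 1 * 0.5)
  # degenerate cases
  z <- compute_statistics(matrix(0, 2, 5), h = matrix(0, 5, 1))
  expect_equal(z$mean_v, c(0, 0))
  expect_true(all(z$vv_centered == 0))
})

test_that("independent high-rate data has vanishing centered correlations", {
  set.seed(3)
  v <- matrix(rbinom(4 * 20000, 1, 0.5), 4, 20000)
  st <- compute_statistics(v, h = matrix(0, 20000, 1))
  expect_true(all(abs(upper_tri_vec(st$vv_centered)) < 4 / sqrt(20000)))
})

test_that("sparsity correction adds the subgradient and masks zero weights", {
  p <- random_params(4, 2, seed = 4)
  p$weights[2, 1] <- 0
  vh <- matrix(1, 4, 2)
  out <- sparsity_corrected_vh(vh, p, lambda = 0.02)
  expect_true(is.na(out[2, 1]))
  expect_equal(out[1, 1], 1 + 0.02 * sign(p$weights[1, 1]))
  expect_equal(sparsity_corrected_vh(vh, p, 0)[1, 2], 1)
})

test_that("nRMSE anchors are exact: shuffled maps to 1, train-as-model to 0", {
  set.seed(5)
  train <- rnorm(100); test <- train + rnorm(100, sd = 0.1); model <- test + rnorm(100, sd = 0.3)
  d <- nrmse(model, test, train, shuffle_seed = 7, details = TRUE)
  # formula evaluated at its anchors
  expect_equal(nrmse_value(d$rmse_shuffled, d$rmse_shuffled, d$rmse_optimal), 1)
  expect_equal(nrmse(train, test, train, shuffle_seed = 7), 0)
  # direct one-liner re-computation of the formula
  expect_equal(d$value, 1 - (rmse(model, test) - d$rmse_shuffled) /
                 (rmse(train, test) - d$rmse_shuffled))
  # hand vectors
  dh <- nrmse(c(0.5, 0.5), c(1, 1), c(0, 0), shuffle_seed = 1, details = TRUE)
  expect_equal(dh$rmse_ordinary, 0.5)
  expect_equal(dh$rmse_optimal, 1)
  expect_equal(dh$value, 1 - (0.5 - dh$rmse_shuffled) / (1 - dh$rmse_shuffled))
  expect_error(nrmse(c(1, 2), c(1, 2), c(1, 2)), "degenerate")
})

test_that("reconstruction likelihood anchors are exact", {
  set.seed(6)
  v <- rbinom(1000, 1, 0.2)
  # perfect reconstruction: LLH exactly 0
  expect_identical(bernoulli_llh(v, v)$llh, 0)
  # constant one-half prediction
  expect_equal(bernoulli_llh(v, rep(0.5, 1000))$llh, -log(2))
  # independent model normalizes to exactly 0, perfect to 1
  V <- matrix(v, 1)
  res <- crbm:::reconstruction_llh_from_probs(V, matrix(mean(v), 1, 1000))
  expect_equal(res$per_neuron$nllh, 0)
  resp <- crbm:::reconstruction_llh_from_probs(V, V)
  expect_equal(resp$per_neuron$nllh, 1)
})

test_that("model-based reconstruction beats the independent baseline on structured data", {
  pm <- planted_model(n_neurons = 40, n_assemblies = 3, assembly_size = 12,
                      overlap = 0, rng = 7)
  sim <- simulate_recording(pm$params, 2000, rng = crbm_rng(8), n_chains = 4)
  rec <- reconstruction_llh(sim$data, pm$params)
  expect_gt(rec$median_nllh, 0.02)
  expect_true(all(rec$per_neuron$llh <= 0))
})

test_that("GLM baseline hits its limiting cases", {
  set.seed(9)
  # target duplicates another neuron: near-perfect prediction at tiny penalty
  x <- rbinom(400, 1, 0.4)
  v <- rbind(x, x, rbinom(400, 1, 0.3))
  res <- glm_baseline(v[, 1:200], v[, 201:400], l2_strength = 1e-4, neurons = 1)
  expect_gt(res$per_neuron$nllh[1], 0.95)
  # independent target: held-out nLLH near 0
  v2 <- rbind(rbinom(2000, 1, 0.3), matrix(rbinom(3 * 2000, 1, 0.4), 3))
  res2 <- glm_baseline(v2[, 1:1000], v2[, 1001:2000], l2_strength = 1000, neurons = 1)
  expect_lt(abs(res2$per_neuron$nllh[1]), 0.05)
  # constant target is flagged with nLLH 0
  v3 <- rbind(rep(0, 200), matrix(rbinom(2 * 200, 1, 0.5), 2))
  res3 <- glm_baseline(v3[, 1:100], v3[, 101:200], neurons = 1)
  expect_true(res3$per_neuron$flagged[1])
  expect_equal(res3$per_neuron$nllh[1], 0)
})

test_that("participation ratio follows the formula and its edge values", {
  expect_equal(participation_ratio(c(1, 1, 0, 0)), 2)
  expect_equal(participation_ratio(rep(3, 7)), 7)
  expect_equal(participation_ratio(c(5, 0, 0)), 1)
  expect_equal(participation_ratio(rep(2, 8), normalized = TRUE), 1)
  set.seed(10)
  x <- rnorm(50)
  expect_equal(participation_ratio(x), sum(x^2)^2 / sum(x^4), tolerance = 1e-12)
  expect_error(participation_ratio(c(0, 0)), "all-zero")
})

test_that("compositional m counts equally active units and respects its bounds", {
  peaks <- rep(0, 6)
  h <- rbind(c(2, 2, 2, 0, 0, 0),   # 3 equally active units
             rep(1.5, 6),          # all units active
             rep(0, 6),            # nothing active
             c(4, 0, 0, 0, 0, 0))  # one unit
  cm <- compositional_m(h, peaks)
  expect_equal(cm$m, c(3, 6, 0, 1))
  # nonzero frames always land in [1, M]
  set.seed(11)
  hr <- matrix(rexp(200 * 6), 200, 6)
  mr <- compositional_m(hr, rep(0, 6))$m
  expect_true(all(mr >= 1 & mr <= 6))
  # planted counts: k units above the inactive peak, rest at it
  pk <- rnorm(6)
  for (k in 1:5) {
    hv <- matrix(pk, 1, 6, byrow = TRUE)
    hv[1, seq_len(k)] <- hv[1, seq_len(k)] + 2
    expect_equal(compositional_m(hv, pk)$m, k)
  }
})

test_that("bimodality transition points recover a planted two-peak mixture", {
  set.seed(12)
  x <- c(rnorm(500, -1, 0.1), rnorm(500, 1, 0.1))[sample(1000)]
  y <- c(rnorm(700, 0, 0.15), rnorm(300, 3, 0.2))[sample(1000)]
  bp <- bimodality_points(cbind(x, y))
  expect_lt(abs(bp$transition[1] - 0), 0.05)
  expect_lt(abs(bp$inactive_peak[1] - (-1)), 0.1)
  expect_lt(abs(bp$transition[2] - 1.5), 0.1)
  expect_false(any(bp$unimodal))
  # constant trace flagged unimodal
  bpc <- bimodality_points(cbind(rep(2, 200), x[1:200]))
  expect_true(bpc$unimodal[1])
  expect_equal(bpc$transition[1], 2)
})

test_that("time constants match square waves and spike trains exactly", {
  sq <- rep(c(rep(-1, 5), rep(1, 5)), 20)
  expect_equal(unname(time_constants(matrix(sq), frame_rate = 1, kind = "hidden")), 10)
  spikes <- rep(c(0, 0, 0, 1), 50)
  expect_equal(unname(time_constants(matrix(spikes), frame_rate = 2, kind = "neuron")), 2)
  # fewer than one oscillation: missing value
  expect_true(is.na(time_constants(matrix(rep(1, 10)), 1, "hidden")))
})

test_that("telegraph-process periods match the analytic median of the run-pair law", {
  set.seed(13)
  p01 <- 0.2; p10 <- 0.25; Tn <- 200000
  s <- integer(Tn); s[1] <- 0
  flips <- runif(Tn)
  for (t in 2:Tn) s[t] <- if (s[t - 1] == 0) as.integer(flips[t] < p01) else
    as.integer(flips[t] >= p10)
  emp <- time_constants(matrix(2 * s - 1), frame_rate = 1, kind = "hidden")
  ## analytic median of (geometric(p01) + geometric(p10)) by convolution
  kmax <- 500
  pmf0 <- dgeom(0:kmax, p01); pmf1 <- dgeom(0:kmax, p10)
  conv <- convolve(pmf0, rev(pmf1), type = "open")[seq_len(kmax + 1)]
  total <- 2 + 0:kmax   # two runs of length >= 1
  med <- total[which(cumsum(conv) >= 0.5)[1]]
  expect_lt(abs(emp - med) / med, 0.1)
})

test_that("hidden-unit sorting groups duplicated traces and ignores permutation", {
  set.seed(14)
  base <- matrix(rnorm(300 * 3), 300, 3)
  h <- cbind(base[, 1], base[, 2], base[, 1] + rnorm(300, sd = 0.01),
             base[, 3], base[, 2] + rnorm(300, sd = 0.01))
  srt <- sort_hus(h)
  pos <- match(c(1, 3), srt$order)
  expect_equal(abs(diff(pos)), 1)      # duplicates adjacent
  pos2 <- match(c(2, 5), srt$order)
  expect_equal(abs(diff(pos2)), 1)
  # permuting the units recovers the same clusters up to relabeling
  perm <- c(4, 2, 5, 1, 3)
  srt_p <- sort_hus(h[, perm])
  cl <- cutree(srt$hclust, k = 3)
  cl_p <- cutree(srt_p$hclust, k = 3)[order(perm)]
  expect_equal(length(unique(paste(cl, cl_p))), 3)
  # merge heights equal an independent Lance-Williams implementation
  r <- cor(h)
  expect_equal(sort(srt$hclust$height),
               sort(naive_ward_heights(as.dist(1 - r))), tolerance = 1e-10)
  # constant trace flagged
  srt_c <- sort_hus(cbind(h[, 1:2], rep(1, 300)))
  expect_equal(srt_c$flagged, 3L)
})
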