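## Exact data-side moments of a model under an arbitrary visible
## distribution, shaped like the internal batch moments.
exact_side_moments <- function(params, prob = NULL) {
  m <- exact_moments(params, prob)
  list(v = m$mean_v, vh = m$vh, hp = m$hp, hm = m$hm,
       hp_sq = m$hp_sq, hm_sq = m$hm_sq)
}

test_that("gradients vanish at the moment-matching fixed point", {
  p <- random_params(6, 2, seed = 2)
  m <- exact_side_moments(p)
  gr <- crbm_gradient(m, m, p$weights, lambda = 0)
  expect_true(all(abs(unlist(gr)) < 1e-12))
})

test_that("analytic gradients match finite differences of the exact log-likelihood", {
  set.seed(7)
  data_p <- random_params(6, 2, seed = 71)
  model_p <- random_params(6, 2, seed = 72)
  pdat <- exact_visible_distribution(data_p)$prob
  V <- enumerate_configs(6)
  loglik <- function(pm)
    sum(pdat * (marginal_log_unnormalized(V, pm) - exact_log_partition(pm)))

  gr <- crbm_gradient(exact_side_moments(model_p, prob = pdat),
                      exact_side_moments(model_p), model_p$weights, lambda = 0)
  eps <- 1e-5
  fd <- function(block, idx) {
    p1 <- model_p; p2 <- model_p
    p1[[block]][idx] <- p1[[block]][idx] + eps
    p2[[block]][idx] <- p2[[block]][idx] - eps
    (loglik(p1) - loglik(p2)) / (2 * eps)
  }
  blocks <- list(g = "g", w = "weights", theta_plus = "theta_plus",
                 theta_minus = "theta_minus", gamma_plus = "gamma_plus",
                 gamma_minus = "gamma_minus")
  for (gname in names(blocks)) {
    analytic <- gr[[gname]]
    for (idx in seq_along(analytic)) {
      num <- fd(blocks[[gname]], idx)
      expect_lt(abs(num - analytic[idx]) / max(abs(num), 1e-4), 1e-5)
    }
  }
})

test_that("the L1 penalty shifts the weight gradient by exactly its subgradient", {
  p <- random_params(5, 2, seed = 5)
  dm <- exact_side_moments(p, prob = exact_visible_distribution(random_params(5, 2, 6))$prob)
  mm <- exact_side_moments(p)
  g0 <- crbm_gradient(dm, mm, p$weights, lambda = 0)
  g1 <- crbm_gradient(dm, mm, p$weights, lambda = 0.07)
  expect_equal(g1$w, g0$w - 0.07 * sign(p$weights), tolerance = 1e-14)
  expect_equal(g1$g, g0$g)
})

test_that("convergence check accepts only weight scales inside the band", {
  p <- random_params(50, 4, seed = 1, w_sd = 0.05)
  expect_true(convergence_check(p)$pass)
  expect_false(convergence_check(crbm_params(matrix(0, 10, 2), rep(0, 10)))$pass)
  p_big <- random_params(50, 4, seed = 1, w_sd = 0.5)
  expect_false(convergence_check(p_big)$pass)
  expect_equal(convergence_check(p_big)$weight_std, sd(p_big$weights))
})

test_that("hidden-unit normalization reaches unit trace variance and fixes nothing twice", {
  set.seed(31)
  batch <- matrix(rbinom(400 * 30, 1, 0.3), 400, 30)
  p <- random_params(30, 3, seed = 32, w_sd = 1.2)
  nm <- hu_normalization(p, batch, damping = 1, center_rate = 0)
  tr <- hidden_mean_given_v(batch, nm$params)
  expect_true(all(abs(apply(tr, 2, sd) - 1) < 0.1))
  # a unit already normalized is a fixed point
  nm2 <- hu_normalization(nm$params, batch, damping = 1, center_rate = 0)
  expect_true(all(abs(nm2$scale - 1) < 1e-8))
  expect_equal(nm2$params$weights, nm$params$weights, tolerance = 1e-6)
  # degenerate unit (zero weights -> constant trace) is left untouched
  pz <- p; pz$weights[, 2] <- 0
  nmz <- hu_normalization(pz, batch, damping = 1)
  expect_true(nmz$degenerate[2])
  expect_equal(nmz$params$weights[, 2], pz$weights[, 2])
})

test_that("variance normalization is an exact reparameterization of P(v)", {
  p <- random_params(8, 2, seed = 44, w_sd = 1)
  set.seed(45)
  batch <- matrix(rbinom(200 * 8, 1, 0.4), 200, 8)
  nm <- hu_normalization(p, batch, damping = 1, center_rate = 0)
  expect_lt(max(abs(exact_visible_distribution(p)$prob -
                    exact_visible_distribution(nm$params)$prob)), 1e-10)
})

test_that("training is bit-reproducible given the seed", {
  set.seed(50)
  v <- matrix(rbinom(30 * 400, 1, 0.2), 30, 400)
  cfg <- training_config(n_hidden = 2, n_updates = 60, batch_size = 50,
                         n_chains = 20, checkpoint_every = 20, seed = 99)
  f1 <- fit_crbm(v, cfg)
  f2 <- fit_crbm(v, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
})

test_that("strong L1 on independent data recovers the independent model", {
  set.seed(61)
  pvec <- runif(40, 0.05, 0.4)
  v <- matrix(rbinom(40 * 6000, 1, pvec), 40, 6000)
  cfg <- training_config(n_hidden = 3, lambda = 0.3, n_updates = 1200,
                         batch_size = 100, n_chains = 50, seed = 62,
                         checkpoint_every = 400)
  fit <- fit_crbm(v, cfg)
  expect_lt(mean(abs(fit$params$weights)), 0.05)
  expect_true(all(abs(sigmoid(fit$params$g) - pvec) < 0.04))
})

test_that("exact train log-likelihood increases over training on an enumerable system", {
  pm <- planted_model(n_neurons = 8, n_assemblies = 2, assembly_size = 4,
                      overlap = 0, weight_scale = 1.2, calibrate = FALSE, rng = 70)
  gains <- vapply(1:3, function(s) {
    sim <- simulate_recording(pm$params, n_frames = 1200, rng = crbm_rng(70 + s),
                              n_chains = 4, thin = 5, burn_in = 50)
    v <- sim$data$v
    V <- enumerate_configs(8)
    ll <- function(pp) mean(marginal_log_unnormalized(t(v), pp)) - exact_log_partition(pp)
    cfg <- training_config(n_hidden = 2, lambda = 0, n_updates = 600,
                           batch_size = 100, n_chains = 50, lr_initial = 2e-3,
                           seed = 80 + s, checkpoint_every = 200, hu_norm = FALSE)
    fit <- fit_crbm(v, cfg)
    start <- ll(crbm:::init_params(v, 2, crbm_rng(80 + s)))
    ll(fit$params) - start
  }, numeric(1))
  expect_gt(median(gains), 0.05)
})

test_that("weight sparsity is non-decreasing in the L1 strength", {
  pm <- planted_model(n_neurons = 40, n_assemblies = 3, assembly_size = 10,
                      overlap = 0, rng = 91)
  sim <- simulate_recording(pm$params, n_frames = 3000, rng = crbm_rng(92),
                            n_chains = 5, thin = 5, burn_in = 50)
  frac_small <- vapply(c(0, 0.01, 0.02, 0.1), function(lam) {
    cfg <- training_config(n_hidden = 3, lambda = lam, n_updates = 600,
                           batch_size = 100, n_chains = 50, seed = 93,
                           checkpoint_every = 300)
    fit <- fit_crbm(sim$data, cfg)
    mean(abs(fit$params$weights) < 1e-3)
  }, numeric(1))
  expect_true(all(diff(frac_small) >= -1e-9))
  expect_gt(frac_small[4], frac_small[1])
})
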