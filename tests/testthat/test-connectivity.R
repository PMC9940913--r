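test_that("local couplings vanish for independent models and equal Ising couplings", {
  # w = 0: no coupling whatever the context configuration
  p0 <- crbm_params(matrix(0, 6, 2), g = rnorm(6))
  set.seed(1)
  for (r in 1:5) {
    v <- rbinom(6, 1, 0.5)
    expect_lt(abs(local_coupling(v, 1, 4, p0)), 1e-10)
  }
  # quadratic model: J_ij(v) constant in v and equal to the Hopfield coupling
  p <- quadratic_params(6, 2, seed = 2)
  Jh <- p$weights %*% (t(p$weights) / p$gamma_plus)
  vals <- sapply(1:6, function(r) {
    set.seed(r); v <- rbinom(6, 1, 0.5)
    local_coupling(v, 2, 5, p)
  })
  expect_lt(max(abs(vals - Jh[2, 5])), 1e-9)
  expect_error(local_coupling(rep(0, 6), 3, 3, p), "i != j")
})

test_that("local couplings equal brute-force conditional log-odds by enumeration", {
  p <- random_params(8, 3, seed = 3, w_sd = 0.4)
  set.seed(4)
  for (r in 1:6) {
    v <- rbinom(8, 1, 0.4)
    i <- sample(8, 1); j <- sample(setdiff(1:8, i), 1)
    expect_equal(local_coupling(v, i, j, p),
                 brute_local_coupling(v, i, j, p), tolerance = 1e-9)
    # symmetry
    expect_equal(local_coupling(v, i, j, p), local_coupling(v, j, i, p),
                 tolerance = 1e-12)
  }
})

test_that("exact coupling matrix averages the local couplings over frames", {
  p <- random_params(6, 2, seed = 5, w_sd = 0.4)
  set.seed(6)
  v <- matrix(rbinom(6 * 40, 1, 0.3), 6, 40)
  J <- coupling_matrix_exact(v, p)
  # frame-by-frame brute force
  ref <- matrix(0, 6, 6)
  for (t in 1:40) for (i in 1:5) for (j in (i + 1):6)
    ref[i, j] <- ref[i, j] + local_coupling(v[, t], i, j, p) / 40
  ref <- ref + t(ref)
  expect_equal(J$values, ref, tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(diag(J$values) == 0))
  expect_error(coupling_matrix_exact(matrix(0, 300, 1000), random_params(300, 20, 1)),
               "budget")
})

test_that("fast estimator is exact for quadratic potentials and tracks the exact one", {
  # hand instance: M = 1, quadratic gamma = 2 -> Gamma'' = 1/2 everywhere
  p1 <- crbm_params(matrix(c(1, 2), 2, 1), g = c(0, 0),
                    gamma_plus = 2, gamma_minus = 2)
  v <- matrix(rbinom(2 * 20, 1, 0.5), 2, 20)
  J1 <- coupling_matrix_fast(v, p1)
  expect_equal(J1$values[1, 2], 1 * 2 * 0.5, tolerance = 1e-12)
  # quadratic: fast == exact to 1e-8
  pq <- quadratic_params(10, 3, seed = 7, w_sd = 0.3)
  set.seed(8)
  vq <- matrix(rbinom(10 * 100, 1, 0.3), 10, 100)
  Jf <- coupling_matrix_fast(vq, pq)
  Je <- coupling_matrix_exact(vq, pq)
  expect_lt(max(abs(Jf$values - Je$values)), 1e-8)
  # generic dReLU: strong correlation with the exact estimator
  pg <- random_params(10, 3, seed = 9, w_sd = 0.4)
  Jf2 <- coupling_matrix_fast(vq, pg)
  Je2 <- coupling_matrix_exact(vq, pg)
  expect_gt(cor(upper_tri_vec(Jf2$values), upper_tri_vec(Je2$values)), 0.95)
  # zero model: everything zero
  expect_true(all(coupling_matrix_fast(vq, crbm_params(matrix(0, 10, 2),
                                                       rnorm(10)))$values == 0))
})

test_that("region aggregation is the mean absolute coupling over block pairs", {
  set.seed(10)
  J <- matrix(rnorm(64), 8, 8); J <- (J + t(J)) / 2; diag(J) <- 0
  cm <- connectivity_matrix(J, "neuron")
  labels <- c("A", "A", "A", "A", "A", "B", "B", "B")
  agg <- region_aggregate(cm, labels, min_neurons = 3)
  # loop oracle
  a <- 1:5; b <- 6:8
  expect_equal(agg$values["A", "B"], mean(abs(J[a, b])))
  expect_equal(agg$values["A", "A"],
               sum(abs(J[a, a])) / (length(a)^2 - length(a)))
  # single region containing everything
  agg1 <- region_aggregate(cm, rep("all", 8), min_neurons = 5)
  expect_equal(agg1$values[1, 1], sum(abs(J)) / (64 - 8))
  # regions below the neuron threshold are dropped
  agg2 <- region_aggregate(cm, c(rep("A", 6), "C", "C"), min_neurons = 5)
  expect_equal(agg2$labels, "A")
})

test_that("specimen averaging reduces to identity and hand-computed weighted means", {
  m1 <- connectivity_matrix(matrix(c(0, 1, 1, 0), 2), "region", c("A", "B"))
  expect_equal(specimen_average(list(m1), 100, list(c(A = 5, B = 5)))$values,
               m1$values)
  # two recordings, equal lengths and counts: plain mean
  m2 <- connectivity_matrix(matrix(c(0, 3, 3, 0), 2), "region", c("A", "B"))
  avg <- specimen_average(list(m1, m2), c(50, 50),
                          list(c(A = 4, B = 4), c(A = 4, B = 4)))
  expect_equal(avg$values[1, 2], 2)
  # hand weights: w1 = 100*(10+20)/2 = 1500, w2 = 200*(5+5)/2 = 1000
  avg2 <- specimen_average(list(m1, m2), c(100, 200),
                           list(c(A = 10, B = 20), c(A = 5, B = 5)))
  expect_equal(avg2$values[1, 2], (1 * 1500 + 3 * 1000) / 2500)
  # masked pair in one fish: the other defines the value; both masked -> NA
  m3 <- connectivity_matrix(matrix(c(0, NA, NA, 0), 2), "region", c("A", "B"))
  avg3 <- specimen_average(list(m1, m3), c(10, 10),
                           list(c(A = 2, B = 2), c(A = 2, B = 2)))
  expect_equal(avg3$values[1, 2], 1)
  avg4 <- specimen_average(list(m3, m3), c(10, 10),
                           list(c(A = 2, B = 2), c(A = 2, B = 2)))
  expect_true(is.na(avg4$values[1, 2]))
})

test_that("baseline covariance/correlation match direct computation", {
  set.seed(11)
  x <- rbinom(500, 1, 0.4)
  v <- rbind(x, x, rbinom(500, 1, 0.3))
  bl <- baseline_matrices(v)
  expect_equal(bl$correlation$values[1, 2], 1)
  expect_equal(bl$covariance$values[1, 3], cov(x, v[3, ]), tolerance = 1e-12)
  # independent neurons: small off-diagonals
  set.seed(12)
  vi <- matrix(rbinom(4 * 20000, 1, 0.3), 4, 20000)
  bli <- baseline_matrices(vi)
  expect_lt(max(abs(upper_tri_vec(bli$correlation$values))), 4 / sqrt(20000))
  # zero-variance neuron flagged, correlation zeroed
  vz <- rbind(rep(0, 100), rbinom(100, 1, 0.5))
  blz <- baseline_matrices(vz)
  expect_equal(blz$flagged, 1L)
  expect_equal(blz$correlation$values[1, 2], 0)
})

test_that("structural estimator matches the two-region hand computation and scaling laws", {
  # neuron 1: soma A, 2 length units in B; neuron 2: soma B, 4 in A; V = 1
  lengths <- matrix(c(0, 4, 2, 0), 2, 2, dimnames = list(NULL, c("A", "B")))
  m <- morphology_set(c("A", "B"), lengths, c(1, 1))
  est <- structural_estimator(m, "direct")
  expect_equal(est$values["A", "B"], (2 + 4) / 2)
  # volume doubling halves every entry; length scaling is linear
  m2 <- morphology_set(c("A", "B"), lengths, c(2, 2))
  expect_equal(structural_estimator(m2, "direct")$values,
               est$values / 2)
  m3 <- morphology_set(c("A", "B"), lengths * 3, c(1, 1))
  expect_equal(structural_estimator(m3, "direct")$values, est$values * 3)
  # no neurites anywhere: zero matrix
  m0 <- morphology_set(c("A", "B"), matrix(0, 2, 2,
                                           dimnames = list(NULL, c("A", "B"))),
                       c(1, 1))
  expect_true(all(structural_estimator(m0, "direct")$values == 0))
  expect_true(all(structural_estimator(m0, "legacy")$values == 0))
})

test_that("direct variant assigns no indirect connection where the legacy one does", {
  ## pass-through neuron: soma in A, neurites in B and C. The legacy
  ## formula credits a B-C connection; the soma-anchored one does not.
  regions <- c("A", "B", "C")
  lengths <- matrix(0, 3, 3, dimnames = list(NULL, regions))
  lengths[1, "B"] <- 5; lengths[1, "C"] <- 5   # the pass-through neuron
  lengths[2, "A"] <- 1                          # one soma per region so all
  lengths[3, "A"] <- 1                          # directed rows are defined
  m <- morphology_set(c("A", "B", "C"), lengths, c(1, 1, 1))
  direct <- structural_estimator(m, "direct")
  legacy <- structural_estimator(m, "legacy")
  expect_equal(direct$values["B", "C"], 0)
  expect_gt(legacy$values["B", "C"], 0)
})

test_that("regional occupancy counts effective regions per assembly", {
  # assembly 1 inside one region; assembly 2 spread equally over 3 regions
  W <- matrix(0, 9, 2)
  W[1:3, 1] <- 0.5
  W[c(1, 4, 7), 2] <- 0.5
  p <- crbm_params(W, rep(0, 9))
  ann <- region_annotation(rep(c("R1", "R2", "R3"), each = 3))
  occ <- regional_occupancy(p, ann)
  expect_equal(occ$per_hu$effective_regions[1], 1, tolerance = 1e-12)
  expect_equal(occ$per_hu$effective_regions[2], 3, tolerance = 1e-12)
  expect_equal(occ$per_hu$regions_above_threshold, c(1L, 3L))
  # disconnected unit flagged
  p0 <- crbm_params(cbind(W[, 1], 0), rep(0, 9))
  occ0 <- regional_occupancy(p0, ann)
  expect_true(occ0$per_hu$disconnected[2])
})

test_that("matrix comparison reproduces textbook correlations and masking rules", {
  A <- connectivity_matrix(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3), "region",
                           c("A", "B", "C"))
  expect_equal(compare_matrices(A, A)$correlation, 1)
  # monotone transform: Spearman 1, Pearson below 1
  set.seed(13)
  x <- matrix(runif(36), 6, 6); x <- x + t(x); diag(x) <- 0
  X <- connectivity_matrix(x, "region")
  Y <- connectivity_matrix(x^3, "region")
  expect_equal(compare_matrices(X, Y, "spearman")$correlation, 1)
  expect_lt(compare_matrices(X, Y, "pearson")$correlation, 1)
  # textbook check on a small instance
  a <- upper_tri_vec(X$values); b <- upper_tri_vec(Y$values)
  expect_equal(compare_matrices(X, Y, "pearson")$correlation, cor(a, b))
  expect_equal(compare_matrices(X, Y, "spearman")$correlation,
               cor(rank(a), rank(b)))
  # zero-entry exclusion for structural comparisons
  z <- x; z[1, 2] <- z[2, 1] <- 0
  Z <- connectivity_matrix(z, "region")
  res <- compare_matrices(X, Z, "spearman", exclude_zero_b = TRUE)
  expect_equal(res$n_pairs, length(a) - 1)
  expect_error(compare_matrices(
    connectivity_matrix(matrix(0, 2, 2), "region"),
    connectivity_matrix(matrix(0, 2, 2), "region")), "fewer than 3")
})
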