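## Independent oracles used across the suite. Each one deliberately
## re-derives its quantity from the definitions, without calling the code
## path under test.

## Random small model with generic dReLU parameters.
random_params <- function(N, M, seed = 1, w_sd = 0.5) {
  set.seed(seed)
  crbm_params(matrix(rnorm(N * M, sd = w_sd), N, M),
              g = rnorm(N, sd = 0.5),
              gamma_plus = runif(M, 0.4, 2), gamma_minus = runif(M, 0.4, 2),
              theta_plus = rnorm(M, sd = 0.8), theta_minus = rnorm(M, sd = 0.8))
}

## Quadratic-potential model (gamma_+ = gamma_-, theta_+ = theta_-).
quadratic_params <- function(N, M, seed = 1, w_sd = 0.5) {
  set.seed(seed)
  gam <- runif(M, 0.5, 2); th <- rnorm(M, sd = 0.5)
  crbm_params(matrix(rnorm(N * M, sd = w_sd), N, M), rnorm(N, sd = 0.5),
              gamma_plus = gam, gamma_minus = gam,
              theta_plus = th, theta_minus = th)
}

## Term-by-term energy evaluation straight from the definition.
naive_energy <- function(v, h, p) {
  U <- 0
  for (mu in seq_len(p$n_hidden)) {
    hp <- max(h[mu], 0); hm <- min(h[mu], 0)
    U <- U + 0.5 * p$gamma_plus[mu] * hp^2 + 0.5 * p$gamma_minus[mu] * hm^2 +
      p$theta_plus[mu] * hp + p$theta_minus[mu] * hm
  }
  inter <- 0
  for (i in seq_len(p$n_visible)) for (mu in seq_len(p$n_hidden))
    inter <- inter + p$weights[i, mu] * v[i] * h[mu]
  -sum(p$g * v) + U - inter
}

## Adaptive-quadrature evaluation of Gamma and its first two derivatives.
quadrature_cumulant <- function(I, gp, gm, tp, tm) {
  U <- function(h) 0.5 * gp * pmax(h, 0)^2 + 0.5 * gm * pmin(h, 0)^2 +
    tp * pmax(h, 0) + tm * pmin(h, 0)
  C <- max(vapply(seq(-50, 50, length.out = 4001),
                  function(h) -U(h) + h * I, numeric(1)))
  f <- function(h, k) h^k * exp(-U(h) + h * I - C)
  z <- integrate(f, -Inf, Inf, k = 0, rel.tol = 1e-12, abs.tol = 0)$value
  m1 <- integrate(f, -Inf, Inf, k = 1, rel.tol = 1e-12, abs.tol = 0)$value
  m2 <- integrate(f, -Inf, Inf, k = 2, rel.tol = 1e-12, abs.tol = 0)$value
  c(value = log(z) + C, mean = m1 / z, var = m2 / z - (m1 / z)^2)
}

## Exact Hopfield (pairwise) log-probabilities implied by a quadratic
## model: log P(v) = const + sum_i g'_i v_i + sum_{i<j} J_ij v_i v_j.
hopfield_log_prob <- function(params) {
  stopifnot(all(params$gamma_plus == params$gamma_minus),
            all(params$theta_plus == params$theta_minus))
  W <- params$weights; gam <- params$gamma_plus; th <- params$theta_plus
  J <- W %*% (t(W) / gam)
  geff <- params$g + diag(J) / 2 - as.vector(W %*% (th / gam))
  V <- enumerate_configs(params$n_visible)
  lp <- V %*% geff + (rowSums((V %*% J) * V) - V %*% diag(J)) / 2
  as.vector(lp) - logsumexp_oracle(as.vector(lp))
}

logsumexp_oracle <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

## Brute-force local coupling from the four conditional probabilities,
## each obtained by explicit enumeration of the joint distribution.
brute_local_coupling <- function(v, i, j, params) {
  d <- exact_visible_distribution(params)
  V <- d$configs
  others <- setdiff(seq_len(params$n_visible), c(i, j))
  match_rest <- colSums(abs(t(V[, others, drop = FALSE]) - v[others])) == 0
  cond_p_vi1 <- function(vj) {
    rows <- match_rest & V[, j] == vj
    num <- sum(d$prob[rows & V[, i] == 1])
    num / sum(d$prob[rows])
  }
  p11 <- cond_p_vi1(1); p10 <- cond_p_vi1(0)
  log(p11 / p10) - log((1 - p11) / (1 - p10))
}

## All permutations (for brute-force assignment checking, n <= 6).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub)))
  }))
}

brute_best_assignment <- function(S) {  # maximize total similarity, square S
  perms <- all_permutations(nrow(S))
  scores <- apply(perms, 1, function(p) sum(S[cbind(seq_len(nrow(S)), p)]))
  perms[which.max(scores), ]
}

## Naive Ward (ward.D2-style) agglomeration via the Lance-Williams update
## on squared distances; returns merge heights in order.
naive_ward_heights <- function(d) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  active <- seq_len(n)
  sizes <- rep(1, n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(active)) for (b in seq_along(active)) if (a < b) {
      if (d2[active[a], active[b]] < best[1])
        best <- c(d2[active[a], active[b]], a, b)
    }
    i <- active[best[2]]; j <- active[best[3]]
    heights <- c(heights, sqrt(best[1]))
    ni <- sizes[i]; nj <- sizes[j]
    new <- numeric(nrow(d2))
    for (k in active) if (k != i && k != j) {
      nk <- sizes[k]
      new[k] <- ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
    }
    d2[i, ] <- new; d2[, i] <- new
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

## z-score of an empirical mean against an exact value, using the
## empirical standard error.
zscore <- function(emp_mean, exact, se) abs(emp_mean - exact) / max(se, 1e-12)
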