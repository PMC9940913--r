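## Core probability model: energy, conditionals, marginal, enumeration.
##
## Configuration convention: visible/hidden configurations are stored as
## rows, i.e. a batch of B visible configurations is a B x N binary matrix
## and the matching hidden batch is B x M. Single configurations may be
## passed as plain vectors.

as_config_matrix <- function(x, width, what) {
  if (is.null(dim(x))) {
    if (length(x) != width)
      stop_dims("%s has length %d, expected %d", what, length(x), width)
    matrix(x, nrow = 1)
  } else {
    if (ncol(x) != width)
      stop_dims("%s has %d columns, expected %d", what, ncol(x), width)
    as.matrix(x)
  }
}

#' Hidden-unit inputs
#'
#' Computes \eqn{I_\mu(v) = \sum_i w_{i\mu} v_i} for each configuration.
#'
#' @param v binary configuration vector (length N) or B x N matrix.
#' @param params a [crbm_params] object.
#' @return B x M matrix of inputs.
#' @export
hidden_input <- function(v, params) {
  v <- as_config_matrix(v, params$n_visible, "v")
  v %*% params$weights
}

#' cRBM energy
#'
#' Joint energy of a visible/hidden configuration pair:
#' \eqn{E(v,h) = -\sum_i g_i v_i + \sum_\mu U_\mu(h_\mu) -
#' \sum_{i\mu} w_{i\mu} v_i h_\mu}, with `U` the dReLU potential.
#'
#' @param v binary vector (length N) or B x N matrix.
#' @param h numeric vector (length M) or B x M matrix.
#' @param params a [crbm_params] object.
#' @return numeric vector of energies, one per configuration row.
#' @export
crbm_energy <- function(v, h, params) {
  validate_params(params)
  v <- as_config_matrix(v, params$n_visible, "v")
  h <- as_config_matrix(h, params$n_hidden, "h")
  if (nrow(v) != nrow(h)) stop_dims("v and h have different numbers of rows")
  check_binary(v)
  U <- drelu_potential(h,
                       rep(params$gamma_plus, each = nrow(h)),
                       rep(params$gamma_minus, each = nrow(h)),
                       rep(params$theta_plus, each = nrow(h)),
                       rep(params$theta_minus, each = nrow(h)))
  dim(U) <- dim(h)
  as.vector(-v %*% params$g + rowSums(U) - rowSums((v %*% params$weights) * h))
}

#' Sample hidden units given the visible layer
#'
#' The conditional factorizes over units; each unit is drawn from its
#' two-branch truncated-Gaussian conditional at input \eqn{I_\mu(v)}.
#'
#' @inheritParams crbm_energy
#' @param rng a [crbm_rng] or integer seed.
#' @return B x M matrix of hidden samples.
#' @export
sample_h_given_v <- function(v, params, rng) {
  I <- hidden_input(v, params)
  drelu_sample(I, params$gamma_plus, params$gamma_minus,
               params$theta_plus, params$theta_minus, rng)
}

#' Conditional mean of hidden units given the visible layer
#'
#' \eqn{\langle h_\mu | v\rangle = \Gamma'_\mu(I_\mu(v))}; this is the
#' convention used throughout for computing hidden-unit activity traces
#' from data.
#'
#' @inheritParams crbm_energy
#' @return B x M matrix.
#' @export
hidden_mean_given_v <- function(v, params) {
  I <- hidden_input(v, params)
  drelu_cumulant(I, params$gamma_plus, params$gamma_minus,
                 params$theta_plus, params$theta_minus)$mean
}

#' Sample the visible layer given hidden units
#'
#' Each neuron is an independent Bernoulli draw with success probability
#' \eqn{\sigma(g_i + w_i^T h)}.
#'
#' @inheritParams crbm_energy
#' @param rng a [crbm_rng] or integer seed.
#' @return B x N binary matrix.
#' @export
sample_v_given_h <- function(h, params, rng) {
  rng <- as_rng(rng)
  h <- as_config_matrix(h, params$n_hidden, "h")
  p <- sigmoid(sweep(h %*% t(params$weights), 2, params$g, "+"))
  with_rng(rng, {
    r <- stats::runif(length(p))
    m <- (r < p) * 1
    dim(m) <- dim(p)
    m
  })
}

#' Mean of the visible layer given hidden units
#'
#' @inheritParams crbm_energy
#' @return B x N matrix of \eqn{\sigma(g_i + w_i^T h)}.
#' @export
visible_mean_given_h <- function(h, params) {
  h <- as_config_matrix(h, params$n_hidden, "h")
  sigmoid(sweep(h %*% t(params$weights), 2, params$g, "+"))
}

#' Unnormalized log marginal of the visible layer
#'
#' \eqn{\log \tilde P(v) = \sum_i g_i v_i + \sum_\mu \Gamma_\mu(I_\mu(v))};
#' subtracting [exact_log_partition()] gives the exact log probability on
#' enumerable systems.
#'
#' @inheritParams crbm_energy
#' @return numeric vector, one value per configuration row.
#' @export
marginal_log_unnormalized <- function(v, params) {
  validate_params(params)
  v <- as_config_matrix(v, params$n_visible, "v")
  check_binary(v)
  G <- drelu_cumulant(v %*% params$weights,
                      params$gamma_plus, params$gamma_minus,
                      params$theta_plus, params$theta_minus)$value
  as.vector(v %*% params$g) +
    (if (params$n_hidden > 0) rowSums(G) else 0)
}

#' Enumerate all binary visible configurations
#'
#' @param n_visible number of neurons; guarded at 20 (about 1e6 states).
#' @return 2^N x N binary matrix, row k encoding integer k-1 (bit i in
#'   column i).
#' @export
enumerate_configs <- function(n_visible) {
  if (n_visible > 20)
    stop_dims("exact enumeration is limited to n_visible <= 20 (got %d)", n_visible)
  k <- 0:(2^n_visible - 1)
  m <- matrix(as.integer(intToBits(k)), nrow = 32)[seq_len(n_visible), , drop = FALSE]
  t(m) * 1
}

#' Exact log partition function by enumeration
#'
#' Sums the unnormalized marginal over all \eqn{2^N} visible
#' configurations. Intended as the ground-truth oracle on small systems;
#' refuses `n_visible > 20`.
#'
#' @param params a [crbm_params] object.
#' @return `log Z` as a scalar.
#' @export
exact_log_partition <- function(params) {
  validate_params(params)
  N <- params$n_visible
  if (N > 20)
    stop_dims("exact_log_partition is limited to n_visible <= 20 (got %d)", N)
  V <- enumerate_configs(N)
  chunk <- 65536L
  parts <- vapply(split(seq_len(nrow(V)), ceiling(seq_len(nrow(V)) / chunk)),
                  function(idx) logsumexp(marginal_log_unnormalized(V[idx, , drop = FALSE], params)),
                  numeric(1))
  logsumexp(parts)
}

#' Exact visible distribution on an enumerable system
#'
#' @param params a [crbm_params] object with `n_visible <= 20`.
#' @return list with `configs` (2^N x N) and `prob` (normalized
#'   probabilities summing to 1).
#' @export
exact_visible_distribution <- function(params) {
  V <- enumerate_configs(params$n_visible)
  lp <- marginal_log_unnormalized(V, params)
  lz <- logsumexp(lp)
  list(configs = V, prob = exp(lp - lz), log_prob = lp - lz)
}

#' Exact model moments on an enumerable system
#'
#' Enumerates the visible distribution and integrates the hidden layer
#' analytically via the cumulant derivatives. Returns every moment that
#' enters the likelihood gradient: \eqn{\langle v_i\rangle},
#' \eqn{\langle v_i h_\mu\rangle}, \eqn{\langle h_{\mu\pm}\rangle},
#' \eqn{\langle h_{\mu\pm}^2\rangle}, plus \eqn{\langle h_\mu\rangle} and
#' the uncentered \eqn{\langle v_i v_j\rangle}.
#'
#' @param params a [crbm_params] with `n_visible <= 20`.
#' @param prob optional probability vector over the enumerated
#'   configurations (in [enumerate_configs()] order) to use as the
#'   visible distribution instead of the model's own; the hidden layer is
#'   still integrated under `params`. This gives exact data-side moments
#'   for a known data distribution.
#' @return named list of exact moments.
#' @export
exact_moments <- function(params, prob = NULL) {
  if (is.null(prob)) {
    d <- exact_visible_distribution(params)
    V <- d$configs; p <- d$prob
  } else {
    V <- enumerate_configs(params$n_visible)
    stopifnot(length(prob) == nrow(V))
    p <- prob / sum(prob)
  }
  cm <- drelu_cumulant(V %*% params$weights,
                       params$gamma_plus, params$gamma_minus,
                       params$theta_plus, params$theta_minus)
  list(
    mean_v = as.vector(crossprod(V, p)),
    mean_h = as.vector(crossprod(cm$mean, p)),
    vh = crossprod(V * p, cm$mean),
    hp = as.vector(crossprod(cm$hp_mean, p)),
    hm = as.vector(crossprod(cm$hm_mean, p)),
    hp_sq = as.vector(crossprod(cm$hp_sq, p)),
    hm_sq = as.vector(crossprod(cm$hm_sq, p)),
    vv = crossprod(V * p, V)
  )
}
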