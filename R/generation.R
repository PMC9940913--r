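## Generating synthetic activity from a fitted model by block Gibbs
## sampling, including the fixed protocol used to produce "model
## statistics" datasets for goodness-of-fit evaluation.

## Alternating Gibbs sweeps for a batch of chains (h ~ P(h|v) then
## v ~ P(v|h), n_steps times) through the compiled kernel. Returns both
## layers after the last sweep.
gibbs_update <- function(v, params, rng, n_steps = 1L) {
  if (params$n_hidden == 0) {
    return(list(v = sample_v_given_h(matrix(0, nrow(v), 0), params, rng),
                h = matrix(0, nrow(v), 0)))
  }
  with_rng(rng, cpp_gibbs_sweeps(v, params$weights, params$g,
                                 params$gamma_plus, params$gamma_minus,
                                 params$theta_plus, params$theta_minus,
                                 as.integer(n_steps)))
}

#' Alternating Gibbs chain
#'
#' Starting from a visible configuration, alternates sampling
#' \eqn{h \sim P(h|v)} and \eqn{v \sim P(v|h)} for `n_steps` sweeps and
#' returns the whole trajectory.
#'
#' @param params a [crbm_params] object.
#' @param v0 binary start configuration (length N vector).
#' @param n_steps number of Gibbs sweeps.
#' @param rng a [crbm_rng] or integer seed.
#' @return list with `v` (`n_steps` x N binary matrix) and `h`
#'   (`n_steps` x M), one row per sweep.
#' @export
gibbs_chain <- function(params, v0, n_steps, rng) {
  validate_params(params)
  rng <- as_rng(rng)
  v <- as_config_matrix(v0, params$n_visible, "v0")
  check_binary(v, "v0")
  V <- matrix(0, n_steps, params$n_visible)
  H <- matrix(0, n_steps, params$n_hidden)
  for (s in seq_len(n_steps)) {
    st <- gibbs_update(v, params, rng)
    v <- st$v
    V[s, ] <- v
    if (params$n_hidden > 0) H[s, ] <- st$h
  }
  list(v = V, h = H)
}

## Run many chains in parallel (vectorized over rows) with thinning.
## init: B x N matrix of start configurations. Returns saved (v, h) stacks.
run_chains <- function(params, init, n_saved, thin, burn_in_steps, rng) {
  rng <- as_rng(rng)
  v <- as_config_matrix(init, params$n_visible, "init")
  B <- nrow(v)
  h <- NULL
  if (burn_in_steps > 0) v <- gibbs_update(v, params, rng, n_steps = burn_in_steps)$v
  Vs <- vector("list", n_saved)
  Hs <- vector("list", n_saved)
  for (k in seq_len(n_saved)) {
    st <- gibbs_update(v, params, rng, n_steps = thin)
    v <- st$v; h <- st$h
    Vs[[k]] <- v
    Hs[[k]] <- h
  }
  list(v = do.call(rbind, Vs), h = do.call(rbind, Hs),
       n_chains = B, n_saved = n_saved)
}

#' Generate a model-statistics sample set
#'
#' Fixed sampling protocol for estimating model-side statistics after
#' training: a set of Monte Carlo chains is initialized on randomly chosen
#' training frames, burned in, and then sampled with thinning. Defaults
#' follow the protocol used for all goodness-of-fit evaluations: 300
#' chains, 50 saved configurations per chain, 20 Gibbs sweeps between
#' saves, and a burn-in of 100 effective configurations (i.e. 100 save
#' intervals = 2000 raw sweeps; set `burn_in_unit = "steps"` to read the
#' burn-in as raw sweeps instead).
#'
#' @param params a [crbm_params] object.
#' @param train_data a [crbm_data] object (or plain N x T binary matrix)
#'   supplying the chain initializations.
#' @param rng a [crbm_rng] or integer seed.
#' @param n_chains,n_saved,thin,burn_in protocol counts (see above).
#' @param burn_in_unit `"saves"` (burn-in counted in save intervals,
#'   default) or `"steps"` (raw Gibbs sweeps).
#' @return list with `v` ((n_chains*n_saved) x N binary matrix), `h`
#'   (same rows x M hidden samples), and the protocol settings.
#' @export
generate_model_statistics_dataset <- function(params, train_data, rng,
                                              n_chains = 300, n_saved = 50,
                                              thin = 20, burn_in = 100,
                                              burn_in_unit = c("saves", "steps")) {
  validate_params(params)
  rng <- as_rng(rng)
  burn_in_unit <- match.arg(burn_in_unit)
  v <- if (inherits(train_data, "crbm_data")) train_data$v else train_data
  if (nrow(v) != params$n_visible)
    stop_dims("train_data has %d neurons, model expects %d", nrow(v), params$n_visible)
  if (ncol(v) < 1) stop_dims("train_data is empty")
  idx <- with_rng(rng, sample.int(ncol(v), n_chains, replace = ncol(v) < n_chains))
  init <- t(v[, idx, drop = FALSE])
  burn_steps <- if (burn_in_unit == "saves") burn_in * thin else burn_in
  out <- run_chains(params, init, n_saved, thin, burn_steps, rng)
  out$protocol <- list(n_chains = n_chains, n_saved = n_saved, thin = thin,
                       burn_in = burn_in, burn_in_unit = burn_in_unit)
  out
}
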