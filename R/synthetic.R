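## Planted-assembly ground-truth models, synthetic recordings, synthetic
## anatomy/morphology, and the assembly-recovery score used to validate
## training.

#' Build a planted-assembly cRBM
#'
#' Constructs a ground-truth model whose weight matrix carries M sparse,
#' index-contiguous (optionally overlapping) assemblies over N neurons,
#' with small background weights, and calibrates the visible fields so
#' that the model's sampled mean activity lies inside a target band. The
#' defaults define the desk-scale benchmark used throughout the package
#' tests: N = 200 neurons, M = 10 assemblies of 20 neurons with 10%
#' overlap and mean activity ~ 0.05.
#'
#' @param n_neurons,n_assemblies N and M.
#' @param assembly_size mean assembly size (neurons per assembly).
#' @param size_jitter integer jitter applied to each assembly size.
#' @param overlap fraction of an assembly shared with its neighbor, in
#'   \[0, 1).
#' @param weight_scale within-assembly coupling scale.
#' @param background_scale sd of i.i.d. background noise weights (0 for
#'   exactly sparse support).
#' @param target_activity desired mean firing probability per frame.
#' @param activity_band acceptable band for the calibrated mean activity.
#' @param gamma_plus,gamma_minus,theta_plus,theta_minus dReLU parameters
#'   given to every unit. The defaults shape a double-well potential:
#'   the active well sits at \eqn{-\theta_+/\gamma_+} (so a negative
#'   `theta_plus` puts it at positive activity) and the inactive well at
#'   \eqn{-\theta_-/\gamma_-} below zero; their relative depths set how
#'   often an assembly turns on, and the coupling scale modulates member
#'   neurons without locking the population into runaway feedback.
#' @param permute scramble neuron order (destroys index contiguity so no
#'   consumer can exploit it).
#' @param calibrate run the short-Gibbs calibration of the fields
#'   (default TRUE).
#' @param max_calibration calibration iterations before giving up.
#' @param rng a [crbm_rng] or integer seed.
#' @return list with `params` ([crbm_params]), `assemblies` (list of
#'   member index vectors), and `calibration` (data.frame of the
#'   calibration trajectory).
#' @export
planted_model <- function(n_neurons = 200, n_assemblies = 10,
                          assembly_size = 20, size_jitter = 0,
                          overlap = 0.1,
                          weight_scale = 0.4, background_scale = 0.01,
                          target_activity = 0.05,
                          activity_band = c(0.03, 0.07),
                          gamma_plus = 1, gamma_minus = 1,
                          theta_plus = -1.5, theta_minus = 3,
                          permute = FALSE, calibrate = TRUE,
                          max_calibration = 15, rng = 1) {
  stopifnot(n_neurons >= 1, n_assemblies >= 1, overlap >= 0, overlap < 1,
            weight_scale >= 0, background_scale >= 0)
  rng <- as_rng(rng)
  N <- n_neurons; M <- n_assemblies

  sizes <- pmax(2, rep_len(assembly_size, M) +
    if (size_jitter > 0) with_rng(rng, sample(-size_jitter:size_jitter, M, replace = TRUE)) else 0)
  stride <- pmax(1, round(sizes * (1 - overlap)))
  starts <- cumsum(c(1, utils::head(stride, -1)))
  if (starts[M] + sizes[M] - 1 > N)
    stop_dims("assemblies do not fit: need %d neurons, have %d",
              starts[M] + sizes[M] - 1, N)
  assemblies <- lapply(seq_len(M), function(k) starts[k]:(starts[k] + sizes[k] - 1))

  W <- with_rng(rng, {
    W <- if (background_scale > 0)
      matrix(stats::rnorm(N * M, sd = background_scale), N, M)
    else matrix(0, N, M)
    for (k in seq_len(M))
      W[assemblies[[k]], k] <- weight_scale * stats::runif(sizes[k], 0.8, 1.2)
    W
  })

  if (permute) {
    ord <- with_rng(rng, sample.int(N))
    W <- W[ord, , drop = FALSE]
    inv <- order(ord)
    assemblies <- lapply(assemblies, function(a) sort(inv[a]))
  }

  g0 <- stats::qlogis(target_activity)
  params <- crbm_params(W, rep(g0, N),
                        gamma_plus = rep(gamma_plus, M),
                        gamma_minus = rep(gamma_minus, M),
                        theta_plus = rep(theta_plus, M),
                        theta_minus = rep(theta_minus, M))

  cal <- data.frame(iter = integer(), offset = numeric(), activity = numeric())
  if (calibrate) {
    offset <- 0
    for (it in seq_len(max_calibration)) {
      sim <- simulate_recording(params, n_frames = 2000, rng = rng,
                                n_chains = 10, thin = 5, burn_in = 100)
      act <- mean(sim$data$v)
      cal <- rbind(cal, data.frame(iter = it, offset = offset, activity = act))
      if (act >= activity_band[1] && act <= activity_band[2]) break
      ## damped log-scale correction; damping grows as iterations pass to
      ## settle oscillations around a steep activity response
      step <- 0.7^ceiling(it / 3) * max(min(log(target_activity / max(act, 1e-5)), 1.5), -1.5)
      offset <- offset + step
      params$g <- params$g + step
    }
    act <- utils::tail(cal$activity, 1)
    if (act < activity_band[1] || act > activity_band[2])
      stop_dims("field calibration failed: mean activity %.4f outside [%g, %g] after %d attempts",
                act, activity_band[1], activity_band[2], max_calibration)
  }

  list(params = params, assemblies = assemblies, calibration = cal)
}

#' Simulate a synthetic recording from a model
#'
#' Draws binary frames as thinned Gibbs samples. Frames are collected
#' from several independent chains (initialized as independent Bernoulli
#' draws at each neuron's marginal field probability) so that slow
#' assembly switching cannot trap the whole recording in one state;
#' chains are concatenated chronologically.
#'
#' @param params a [crbm_params].
#' @param n_frames number of frames T to return.
#' @param frame_rate frames per second recorded in the output.
#' @param rng a [crbm_rng] or integer seed.
#' @param n_chains number of independent chains.
#' @param thin Gibbs sweeps between saved frames.
#' @param burn_in Gibbs sweeps discarded per chain before saving.
#' @return list with `data` ([crbm_data] of exactly `n_frames` frames)
#'   and `h` (T x M matrix of the hidden samples behind each saved
#'   frame).
#' @export
simulate_recording <- function(params, n_frames, frame_rate = 1, rng = 1,
                               n_chains = 10, thin = 10, burn_in = 100) {
  validate_params(params)
  rng <- as_rng(rng)
  per_chain <- ceiling(n_frames / n_chains)
  p0 <- sigmoid(params$g)
  init <- with_rng(rng, {
    m <- matrix(stats::runif(n_chains * params$n_visible), n_chains)
    (m < matrix(p0, n_chains, params$n_visible, byrow = TRUE)) * 1
  })
  out <- run_chains(params, init, per_chain, thin, burn_in, rng)
  ## run_chains stacks save-index-major; reorder chain-major so each
  ## chain's frames stay chronologically contiguous
  ord <- as.vector(t(matrix(seq_len(n_chains * per_chain), n_chains, per_chain)))
  keep <- ord[seq_len(n_frames)]
  list(data = crbm_data(t(out$v[keep, , drop = FALSE]), frame_rate = frame_rate),
       h = out$h[keep, , drop = FALSE])
}

#' Synthetic anatomy aligned with planted assemblies
#'
#' Generates a region annotation, a morphology set and the implied
#' ground-truth structural matrix for a planted model. With
#' `alignment = 1` each assembly maps into one region (region k hosts
#' assembly k, cycling when there are fewer regions than assemblies) and
#' every neuron sends neurites into the regions of the other assemblies
#' it belongs to — so regions whose assemblies share neurons are also
#' structurally connected, planting a structure-function correspondence.
#' With `alignment = 0` regions are assigned at random and no
#' correspondence exists.
#'
#' @param n_neurons N.
#' @param n_regions number of regions (>= 2).
#' @param assemblies list of member index vectors (from
#'   [planted_model()]).
#' @param rng a [crbm_rng] or integer seed.
#' @param alignment probability that a neuron is placed in its assembly's
#'   region rather than a random one.
#' @param neurite_length_unit length assigned per projection.
#' @param self_length neurite length inside the soma's own region.
#' @param volumes region volumes (default all 1).
#' @return list with `annotation` ([region_annotation]), `morphology`
#'   ([morphology_set]), `structural_truth` (region matrix computed from
#'   the construction), `region_of_neuron`.
#' @export
synthetic_anatomy <- function(n_neurons, n_regions, assemblies, rng = 1,
                              alignment = 1, neurite_length_unit = 10,
                              self_length = 5, volumes = NULL) {
  if (n_regions < 2) stop_dims("need at least 2 regions")
  rng <- as_rng(rng)
  M <- length(assemblies)
  region_names <- sprintf("R%02d", seq_len(n_regions))
  home_region <- rep(NA_integer_, n_neurons)
  for (k in seq_len(M))   # first assembly listing a neuron defines its home
    home_region[assemblies[[k]]][is.na(home_region[assemblies[[k]]])] <-
      ((k - 1) %% n_regions) + 1
  free <- which(is.na(home_region))
  home_region[free] <- with_rng(rng, sample.int(n_regions, length(free), replace = TRUE))

  region <- with_rng(rng, {
    r <- home_region
    reroll <- stats::runif(n_neurons) >= alignment
    r[reroll] <- sample.int(n_regions, sum(reroll), replace = TRUE)
    r
  })

  L <- matrix(0L, n_regions, n_neurons, dimnames = list(region_names, NULL))
  L[cbind(region, seq_len(n_neurons))] <- 1L

  lengths <- matrix(0, n_neurons, n_regions, dimnames = list(NULL, region_names))
  lengths[cbind(seq_len(n_neurons), region)] <- self_length
  for (k in seq_len(M)) {
    target <- ((k - 1) %% n_regions) + 1
    for (n in assemblies[[k]])
      if (region[n] != target)
        lengths[n, target] <- lengths[n, target] + neurite_length_unit
  }

  volumes <- volumes %||% rep(1, n_regions)
  morph <- morphology_set(region_names[region], lengths, volumes, region_names)

  ## ground-truth structural matrix straight from the construction
  D <- matrix(NA_real_, n_regions, n_regions)
  for (r in seq_len(n_regions)) {
    idx <- which(region == r)
    if (length(idx))
      D[r, ] <- colSums(lengths[idx, , drop = FALSE]) / (volumes * length(idx))
  }
  truth <- (D + t(D)) / 2
  one_sided <- is.na(D) != is.na(t(D))
  truth[one_sided] <- pmax(D, t(D), na.rm = TRUE)[one_sided]

  list(annotation = region_annotation(L, region_names),
       morphology = morph,
       structural_truth = connectivity_matrix(truth, "region",
                                              labels = region_names,
                                              provenance = "structural"),
       region_of_neuron = region_names[region])
}

## Hungarian algorithm (shortest augmenting paths with potentials) for the
## rectangular assignment problem; minimizes total cost, n rows <= m cols.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  transposed <- FALSE
  if (n > m) { cost <- t(cost); tmp <- n; n <- nrow(cost); m <- ncol(cost); transposed <- TRUE }
  u <- numeric(n); v <- numeric(m + 1)
  p <- integer(m + 1)       # row assigned to each column (0 = none); m+1 virtual
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[m + 1] <- i
    j0 <- m + 1
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0
      for (j in seq_len(m)) if (!used[j]) {
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1
      if (j0 == m + 1) break
    }
  }
  match <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0) match[p[j]] <- j
  if (transposed) {
    out <- rep(NA_integer_, m)
    out[match] <- seq_len(n)
    out
  } else match
}

#' Assembly recovery score
#'
#' Matches learned weight columns to ground-truth columns by
#' sign-invariant cosine similarity (|cos| between columns) under an
#' optimal one-to-one assignment (Hungarian algorithm; rectangular
#' allowed), and reports the matched similarity per true assembly.
#'
#' @param true_weights N x M_true ground-truth weight matrix.
#' @param learned_weights N x M_learned learned weight matrix.
#' @param threshold similarity above which an assembly counts as
#'   recovered (default 0.8).
#' @return list with `table` (data.frame: `true_assembly`,
#'   `matched_unit`, `similarity`) and `n_recovered`.
#' @export
assembly_recovery_score <- function(true_weights, learned_weights,
                                    threshold = 0.8) {
  true_weights <- as.matrix(true_weights)
  learned_weights <- as.matrix(learned_weights)
  if (nrow(true_weights) != nrow(learned_weights))
    stop_dims("weight matrices must share the neuron dimension")
  norm_t <- sqrt(colSums(true_weights^2))
  norm_l <- sqrt(colSums(learned_weights^2))
  S <- abs(crossprod(true_weights, learned_weights)) /
    outer(pmax(norm_t, 1e-12), pmax(norm_l, 1e-12))
  match <- solve_assignment(-S)   # maximize similarity
  rows <- which(!is.na(match) & match > 0)
  tab <- data.frame(true_assembly = rows,
                    matched_unit = match[rows],
                    similarity = S[cbind(rows, match[rows])])
  list(table = tab, n_recovered = sum(tab$similarity >= threshold),
       similarity_matrix = S)
}
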