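## Functional connectivity by in-silico perturbation, region aggregation,
## specimen averaging, structural-connectivity estimation, regional
## occupancy and matrix comparison.

#' Connectivity matrix container
#'
#' @param values symmetric numeric matrix (`NA` entries are masked).
#' @param level `"neuron"` or `"region"`.
#' @param labels entity names (defaults to rownames or indices).
#' @param provenance estimator tag: one of `"crbm_fast"`, `"crbm_exact"`,
#'   `"covariance"`, `"correlation"`, `"structural"`.
#' @return object of class `crbm_connectivity`.
#' @export
connectivity_matrix <- function(values, level = c("neuron", "region"),
                                labels = NULL, provenance = "crbm_fast") {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop_dims("connectivity matrix must be square")
  asym <- max(abs(values - t(values)), na.rm = TRUE)
  if (is.finite(asym) && asym > 1e-10)
    stop_dims("connectivity matrix must be symmetric (max asymmetry %.3g)", asym)
  labels <- labels %||% rownames(values) %||% as.character(seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, level = level, labels = labels,
                 provenance = provenance), class = "crbm_connectivity")
}

#' @export
print.crbm_connectivity <- function(x, ...) {
  cat(sprintf("%s-level connectivity (%s): %d x %d, %d masked entries\n",
              x$level, x$provenance, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' Region annotation
#'
#' Binary membership of neurons in anatomical regions. A neuron may
#' belong to zero or several regions.
#'
#' @param membership R x N binary matrix (`membership[r, i] = 1` when
#'   neuron i lies in region r), or a length-N vector of region labels
#'   (one region per neuron).
#' @param region_names optional region names (rownames used otherwise).
#' @return object of class `crbm_regions` with fields `membership`,
#'   `region_names`, `n_neurons`.
#' @export
region_annotation <- function(membership, region_names = NULL) {
  if (is.null(dim(membership))) {
    labels <- as.character(membership)
    region_names <- region_names %||% sort(unique(labels))
    L <- t(sapply(region_names, function(r) as.integer(labels == r)))
  } else {
    L <- as.matrix(membership)
    check_binary(L, "membership")
    region_names <- region_names %||% rownames(L) %||% as.character(seq_len(nrow(L)))
  }
  rownames(L) <- region_names
  structure(list(membership = L, region_names = region_names,
                 n_neurons = ncol(L)), class = "crbm_regions")
}

#' Local effective coupling between two neurons
#'
#' In-silico perturbation: given the model's marginal \eqn{P(v)}, the
#' local coupling is the change in the log-odds of neuron i's activity
#' caused by flipping neuron j, with all other neurons fixed at the data
#' configuration:
#' \deqn{J_{ij}(v) = \log\frac{P(v_i=1|\ldots,v_j=1)}{P(v_i=1|\ldots,v_j=0)}
#'  - \log\frac{P(v_i=0|\ldots,v_j=1)}{P(v_i=0|\ldots,v_j=0)}.}
#' It is symmetric in (i, j), zero for an independent model, and for a
#' pairwise (Ising) model equals the coupling constant independently of v.
#'
#' @param v binary configuration (length N).
#' @param i,j distinct neuron indices.
#' @param params a [crbm_params].
#' @return scalar \eqn{J_{ij}(v)}.
#' @export
local_coupling <- function(v, i, j, params) {
  if (i == j) stop_dims("local coupling requires i != j")
  v <- as.vector(v)
  f <- function(vi, vj) {
    w <- v; w[i] <- vi; w[j] <- vj
    marginal_log_unnormalized(w, params)
  }
  (f(1, 1) - f(0, 1)) - (f(1, 0) - f(0, 0))
}

#' Exact data-averaged coupling matrix
#'
#' Averages [local_coupling()] over all data frames:
#' \eqn{J_{ij} = \langle J_{ij}(v)\rangle_{data}}. Cost grows as
#' \eqn{O(N^2 M T)}, so a budget guard refuses large systems; use
#' [coupling_matrix_fast()] there.
#'
#' @param data N x T binary matrix (or [crbm_data]).
#' @param params a [crbm_params].
#' @param budget maximum allowed `N * N * M * T` (default 2e8).
#' @return neuron-level [connectivity_matrix()] (provenance
#'   `"crbm_exact"`), diagonal 0.
#' @export
coupling_matrix_exact <- function(data, params, budget = 2e8) {
  v <- if (inherits(data, "crbm_data")) data$v else as.matrix(data)
  check_binary(v)
  N <- params$n_visible; Tn <- ncol(v); M <- max(params$n_hidden, 1)
  if (N^2 * M * Tn > budget)
    stop_dims("exact coupling matrix too costly (N^2*M*T = %.3g > budget %.3g)",
              N^2 * M * Tn, budget)
  W <- params$weights
  gamma_fun <- function(I) {
    rowSums(drelu_cumulant(I, params$gamma_plus, params$gamma_minus,
                           params$theta_plus, params$theta_minus)$value)
  }
  pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  J <- matrix(0, N, N)
  for (t in seq_len(Tn)) {
    vt <- v[, t]
    I <- as.vector(vt %*% W)
    ## base input with neurons i and j forced to 0, per pair
    I00 <- matrix(I, nrow(pairs), ncol(W), byrow = TRUE) -
      vt[pairs[, 1]] * W[pairs[, 1], , drop = FALSE] -
      vt[pairs[, 2]] * W[pairs[, 2], , drop = FALSE]
    g00 <- gamma_fun(I00)
    g10 <- gamma_fun(I00 + W[pairs[, 1], , drop = FALSE])
    g01 <- gamma_fun(I00 + W[pairs[, 2], , drop = FALSE])
    g11 <- gamma_fun(I00 + W[pairs[, 1], , drop = FALSE] + W[pairs[, 2], , drop = FALSE])
    J[pairs] <- J[pairs] + (g11 - g01 - g10 + g00)
  }
  J <- J / Tn
  J <- J + t(J)
  connectivity_matrix(J, "neuron", provenance = "crbm_exact")
}

#' Fast coupling matrix (second-order approximation)
#'
#' \eqn{J_{ij} = \sum_\mu w_{i\mu} w_{j\mu} \langle
#' \Gamma''_\mu(I_\mu(v))\rangle_{data}}: the weighted outer-product sum
#' with the data-averaged conditional hidden variance. Exact for
#' quadratic potentials; an accurate approximation of
#' [coupling_matrix_exact()] in general.
#'
#' @inheritParams coupling_matrix_exact
#' @return neuron-level [connectivity_matrix()] (provenance
#'   `"crbm_fast"`), diagonal 0.
#' @export
coupling_matrix_fast <- function(data, params) {
  v <- if (inherits(data, "crbm_data")) data$v else as.matrix(data)
  check_binary(v)
  cm <- drelu_cumulant(t(v) %*% params$weights,
                       params$gamma_plus, params$gamma_minus,
                       params$theta_plus, params$theta_minus)
  gbar <- colMeans(cm$var)
  J <- params$weights %*% (gbar * t(params$weights))
  J <- (J + t(J)) / 2
  diag(J) <- 0
  connectivity_matrix(J, "neuron", provenance = "crbm_fast")
}

#' Aggregate neuron-level couplings to region level
#'
#' Normalized L1 aggregation: \eqn{J^{\mathcal R}_{km} = \sum_{i \in R_k,
#' j \in R_m} |J_{ij}| / (N_{R_k} N_{R_m})}; within-region blocks exclude
#' the i = j diagonal from both numerator and count. Regions with fewer
#' than `min_neurons` member neurons are dropped.
#'
#' @param J neuron-level [connectivity_matrix()].
#' @param ann a [region_annotation()] (or label vector).
#' @param min_neurons minimum neurons for a region to be kept (default 5).
#' @return region-level [connectivity_matrix()], nonnegative.
#' @export
region_aggregate <- function(J, ann, min_neurons = 5) {
  if (!inherits(ann, "crbm_regions")) ann <- region_annotation(ann)
  Jv <- abs(J$values)
  if (ann$n_neurons != nrow(Jv))
    stop_dims("annotation covers %d neurons, J has %d", ann$n_neurons, nrow(Jv))
  counts <- rowSums(ann$membership)
  keep <- which(counts >= min_neurons)
  if (length(keep) == 0) stop_dims("no region has >= %d neurons", min_neurons)
  R <- length(keep)
  out <- matrix(0, R, R)
  members <- lapply(keep, function(r) which(ann$membership[r, ] == 1))
  for (a in seq_len(R)) for (b in a:R) {
    block <- Jv[members[[a]], members[[b]], drop = FALSE]
    n_pairs <- length(block) - if (a == b) nrow(block) else 0
    out[a, b] <- out[b, a] <- sum(block, na.rm = TRUE) / n_pairs
  }
  connectivity_matrix(out, "region", labels = ann$region_names[keep],
                      provenance = J$provenance)
}

#' Weighted specimen average of region connectivity matrices
#'
#' Averages region-level matrices from several recordings with
#' region-pair-specific weights \eqn{w^F_{rr'} = T_F (N^F_{R_r} +
#' N^F_{R_{r'}}) / 2} (recording length times mean regional neuron
#' count), so well-sampled regions dominate. Matrices may cover different
#' region subsets; pairs with no valid recording are masked `NA`.
#'
#' @param matrices list of region-level [connectivity_matrix()] objects.
#' @param recording_lengths numeric vector \eqn{T_F}, one per matrix.
#' @param region_counts list of named vectors: neurons per region for
#'   each recording.
#' @return region-level [connectivity_matrix()] over the union of
#'   regions.
#' @export
specimen_average <- function(matrices, recording_lengths, region_counts) {
  stopifnot(length(matrices) == length(recording_lengths),
            length(matrices) == length(region_counts))
  regions <- sort(unique(unlist(lapply(matrices, function(m) m$labels))))
  R <- length(regions)
  num <- matrix(0, R, R); den <- matrix(0, R, R)
  for (f in seq_along(matrices)) {
    m <- matrices[[f]]
    idx <- match(m$labels, regions)
    counts <- region_counts[[f]][m$labels]
    w <- recording_lengths[f] * outer(counts, counts, `+`) / 2
    vals <- m$values
    ok <- !is.na(vals)
    num[idx, idx] <- num[idx, idx] + ifelse(ok, vals * w, 0)
    den[idx, idx] <- den[idx, idx] + ifelse(ok, w, 0)
  }
  out <- ifelse(den > 0, num / den, NA)
  connectivity_matrix(out, "region", labels = regions,
                      provenance = matrices[[1]]$provenance)
}

#' Covariance and correlation baseline connectivity
#'
#' Standard across-time covariance and Pearson correlation matrices of
#' the neurons, as model-free baselines. Diagonals are set to 0
#' (self-coupling is not defined for the functional estimators they are
#' compared against); zero-variance neurons get correlation 0 and are
#' flagged.
#'
#' @param v N x T binary matrix (or [crbm_data]).
#' @return list with `covariance` and `correlation` (neuron-level
#'   [connectivity_matrix()]) and `flagged` (zero-variance neurons).
#' @export
baseline_matrices <- function(v) {
  v <- if (inherits(v, "crbm_data")) v$v else as.matrix(v)
  if (ncol(v) < 2) stop_dims("need at least 2 frames")
  cv <- stats::cov(t(v))
  cr <- suppressWarnings(stats::cor(t(v)))
  flagged <- which(apply(v, 1, stats::sd) < 1e-12)
  cr[!is.finite(cr)] <- 0
  diag(cv) <- 0
  diag(cr) <- 0
  list(covariance = connectivity_matrix(cv, "neuron", provenance = "covariance"),
       correlation = connectivity_matrix(cr, "neuron", provenance = "correlation"),
       flagged = flagged)
}

#' Morphology set
#'
#' Per-neuron soma region and neurite length per region, plus region
#' volumes — the inputs of the structural-connectivity estimator.
#'
#' @param soma_region length-N vector of region names/indices (soma
#'   location of each neuron).
#' @param neurite_length N x R matrix: cumulative neurite length of
#'   neuron n inside region r (columns named by region).
#' @param volumes positive length-R vector of region volumes.
#' @param region_names optional region names.
#' @return object of class `crbm_morphology`.
#' @export
morphology_set <- function(soma_region, neurite_length, volumes,
                           region_names = NULL) {
  neurite_length <- as.matrix(neurite_length)
  region_names <- region_names %||% colnames(neurite_length) %||%
    as.character(seq_len(ncol(neurite_length)))
  if (any(neurite_length < 0)) stop_dims("neurite lengths must be >= 0")
  if (any(volumes <= 0)) stop_dims("region volumes must be > 0")
  if (length(volumes) != ncol(neurite_length))
    stop_dims("volumes length %d != number of regions %d",
              length(volumes), ncol(neurite_length))
  soma_region <- as.character(soma_region)
  if (!all(soma_region %in% region_names))
    stop_dims("soma_region contains labels outside region_names")
  colnames(neurite_length) <- region_names
  structure(list(soma_region = soma_region, neurite_length = neurite_length,
                 volumes = stats::setNames(as.numeric(volumes), region_names),
                 region_names = region_names), class = "crbm_morphology")
}

#' Structural connectivity from single-neuron morphology
#'
#' `variant = "direct"`: the average projection density of neurons with
#' somata in region r into region r',
#' \deqn{c_{rr'} = \mathrm{Sym}\left\{\frac{\sum_n \delta_{r(n),r}\,
#' \ell_n(r') / V_{r'}}{\sum_n \delta_{r(n),r}}\right\},}
#' symmetrized as the arithmetic mean of the two directed values (the
#' defined direction is used alone when a region has no somata; pairs
#' undefined in both directions are masked). The diagonal (within-region
#' connectivity) is well-defined. `variant = "legacy"` is the earlier
#' soma-agnostic formula \eqn{c_{rr'} = \sum_n (\ell_n(r) + \ell_n(r')) /
#' (N (V_r + V_{r'}))}, which also credits indirect pass-through
#' neurites.
#'
#' @param m a [morphology_set()].
#' @param variant `"direct"` or `"legacy"`.
#' @return region-level [connectivity_matrix()] (provenance
#'   `"structural"`), nonnegative.
#' @export
structural_estimator <- function(m, variant = c("direct", "legacy")) {
  variant <- match.arg(variant)
  stopifnot(inherits(m, "crbm_morphology"))
  R <- length(m$region_names)
  if (variant == "legacy") {
    tot <- colSums(m$neurite_length)   # sum_n l_n(r)
    N <- nrow(m$neurite_length)
    C <- (outer(tot, rep(1, R)) + outer(rep(1, R), tot)) /
      (N * (outer(m$volumes, rep(1, R)) + outer(rep(1, R), m$volumes)))
  } else {
    D <- matrix(NA_real_, R, R)  # directed: soma region (row) -> target (col)
    for (r in seq_len(R)) {
      idx <- which(m$soma_region == m$region_names[r])
      if (length(idx) == 0) next
      D[r, ] <- colSums(m$neurite_length[idx, , drop = FALSE]) /
        (m$volumes * length(idx))
    }
    C <- matrix(NA_real_, R, R)
    both <- !is.na(D) & !is.na(t(D))
    C[both] <- ((D + t(D)) / 2)[both]
    only_fwd <- !is.na(D) & is.na(t(D))
    C[only_fwd] <- D[only_fwd]
    C[t(only_fwd)] <- t(D)[t(only_fwd)]
  }
  connectivity_matrix(C, "region", labels = m$region_names,
                      provenance = "structural")
}

#' Regional occupancy of neural assemblies
#'
#' For each hidden unit, the weighted region label vector \eqn{L |w_\mu|}
#' (absolute weights) measures how much of the assembly lies in each
#' region; its participation ratio is the effective number of occupied
#' regions (in \eqn{[1, R]}). Also reports the count of regions
#' containing at least one assembly neuron at the membership threshold
#' \eqn{|w_{i\mu}| \ge} `threshold`.
#'
#' @param params a [crbm_params].
#' @param ann a [region_annotation()] covering the model's neurons.
#' @param threshold assembly-membership weight threshold (default 0.15).
#' @return list with `region_vectors` (R x M matrix), and `per_hu`
#'   data.frame: `effective_regions`, `regions_above_threshold`,
#'   `disconnected`.
#' @export
regional_occupancy <- function(params, ann, threshold = 0.15) {
  if (!inherits(ann, "crbm_regions")) ann <- region_annotation(ann)
  if (ann$n_neurons != params$n_visible)
    stop_dims("annotation covers %d neurons, model has %d",
              ann$n_neurons, params$n_visible)
  W <- abs(params$weights)
  rv <- ann$membership %*% W   # R x M
  M <- params$n_hidden
  eff <- numeric(M); nthr <- integer(M); disc <- logical(M)
  for (mu in seq_len(M)) {
    if (all(W[, mu] == 0)) {
      disc[mu] <- TRUE
      eff[mu] <- NA
      nthr[mu] <- 0L
    } else {
      eff[mu] <- participation_ratio(rv[, mu])
      nthr[mu] <- sum(ann$membership %*% (W[, mu] >= threshold) > 0)
    }
  }
  list(region_vectors = rv,
       per_hu = data.frame(effective_regions = eff,
                           regions_above_threshold = nthr,
                           disconnected = disc))
}

#' Correlate two connectivity matrices
#'
#' Vectorizes the strictly-upper-triangle entries of both matrices over
#' their shared region universe, drops pairs masked (`NA`) in either,
#' optionally drops pairs where `B` is exactly 0 (structural comparisons:
#' absent connections carry no strength information), optionally
#' log10-transforms both (functional-vs-functional comparisons; requires
#' positive entries), and returns the Pearson or Spearman correlation
#' with its p-value.
#'
#' @param A,B [connectivity_matrix()] objects on the same labels.
#' @param method `"pearson"` or `"spearman"`.
#' @param log10_transform log10 both matrices before a Pearson
#'   comparison.
#' @param exclude_zero_b drop pairs where `B` is exactly zero.
#' @return list with `correlation`, `p_value`, `n_pairs`, `method`.
#' @export
compare_matrices <- function(A, B, method = c("pearson", "spearman"),
                             log10_transform = FALSE, exclude_zero_b = FALSE) {
  method <- match.arg(method)
  if (!identical(A$labels, B$labels))
    stop_dims("matrices must share the same labels (region universe)")
  ut <- upper.tri(A$values)
  a <- A$values[ut]; b <- B$values[ut]
  keep <- !is.na(a) & !is.na(b)
  if (exclude_zero_b) keep <- keep & b != 0
  a <- a[keep]; b <- b[keep]
  if (log10_transform) {
    pos <- a > 0 & b > 0
    if (!all(pos)) warning(sprintf("dropping %d non-positive pairs before log10", sum(!pos)))
    a <- log10(a[pos]); b <- log10(b[pos])
  }
  if (length(a) < 3) stop_dims("fewer than 3 valid entry pairs to correlate")
  ct <- suppressWarnings(stats::cor.test(a, b, method = method, exact = FALSE))
  list(correlation = unname(ct$estimate), p_value = ct$p.value,
       n_pairs = length(a), method = method)
}
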