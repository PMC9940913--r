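## Model parameter container.

#' Construct cRBM parameters
#'
#' Bundles the full parameter set of a compositional RBM with `N` binary
#' visible units (neurons) and `M` real-valued dReLU hidden units: the
#' coupling matrix `weights` (N x M), the visible fields `g` and the four
#' per-unit dReLU parameter vectors.
#'
#' @param weights numeric N x M matrix of neuron-to-hidden couplings.
#' @param g numeric length-N visible fields.
#' @param gamma_plus,gamma_minus positive length-M branch curvatures.
#' @param theta_plus,theta_minus length-M branch offsets.
#' @return object of class `crbm_params` with fields as above plus
#'   `n_visible`, `n_hidden`.
#' @export
crbm_params <- function(weights, g,
                        gamma_plus = rep(1, ncol(weights)),
                        gamma_minus = rep(1, ncol(weights)),
                        theta_plus = rep(0, ncol(weights)),
                        theta_minus = rep(0, ncol(weights))) {
  weights <- as.matrix(weights)
  p <- structure(list(
    weights = weights,
    g = as.numeric(g),
    gamma_plus = as.numeric(gamma_plus),
    gamma_minus = as.numeric(gamma_minus),
    theta_plus = as.numeric(theta_plus),
    theta_minus = as.numeric(theta_minus),
    n_visible = nrow(weights),
    n_hidden = ncol(weights)
  ), class = "crbm_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  N <- p$n_visible; M <- p$n_hidden
  if (length(p$g) != N)
    stop_dims("g has length %d, expected n_visible = %d", length(p$g), N)
  for (f in c("gamma_plus", "gamma_minus", "theta_plus", "theta_minus"))
    if (length(p[[f]]) != M)
      stop_dims("%s has length %d, expected n_hidden = %d", f, length(p[[f]]), M)
  vals <- c(p$weights, p$g, p$gamma_plus, p$gamma_minus, p$theta_plus, p$theta_minus)
  if (any(!is.finite(vals))) stop_dims("all cRBM parameters must be finite")
  check_drelu(p$gamma_plus, p$gamma_minus)
  invisible(p)
}

#' @export
print.crbm_params <- function(x, ...) {
  cat(sprintf("cRBM parameters: %d neurons, %d hidden units\n",
              x$n_visible, x$n_hidden))
  cat(sprintf("  weight sd: %.4g, |w| > 0.15: %d entries\n",
              stats::sd(x$weights), sum(abs(x$weights) > 0.15)))
  invisible(x)
}

#' Sign-swap transformation of hidden units
#'
#' For each selected unit, swaps the two dReLU branches
#' (\eqn{\gamma_+,\theta_+ \leftrightarrow \gamma_-,\theta_-}) and negates
#' its weight column. The marginal distribution over the visible layer is
#' invariant under this transformation (the hidden unit is relabeled
#' \eqn{h \to -h}). By convention it is applied after training to every
#' unit with predominantly negative weights (\eqn{\sum_i w_{i\mu} < 0}) so
#' that units activate positively with their assemblies.
#'
#' @param params a [crbm_params] object.
#' @param units integer indices of units to swap, or `NULL` (default) to
#'   swap all units with negative weight-column sums.
#' @return transformed [crbm_params].
#' @export
sign_swap <- function(params, units = NULL) {
  validate_params(params)
  if (is.null(units)) units <- which(colSums(params$weights) < 0)
  if (length(units) == 0) return(params)
  p <- params
  p$weights[, units] <- -p$weights[, units]
  ## reflecting the potential, U'(h) = U(-h), swaps the curvatures and
  ## swaps-and-negates the offsets: theta_+' = -theta_-, theta_-' = -theta_+
  tp <- p$theta_plus[units]; gp <- p$gamma_plus[units]
  p$theta_plus[units] <- -p$theta_minus[units]
  p$theta_minus[units] <- -tp
  p$gamma_plus[units] <- p$gamma_minus[units]
  p$gamma_minus[units] <- gp
  p
}

#' Write / read cRBM parameters (JSON)
#'
#' Parameters are serialized to a single JSON file with keys `weights`,
#' `g`, `gamma_plus`, `gamma_minus`, `theta_plus`, `theta_minus`,
#' `n_visible`, `n_hidden` and `format_version`.
#'
#' @param params a [crbm_params] object.
#' @param path file path.
#' @return `read_crbm_params` returns a [crbm_params]; `write_crbm_params`
#'   returns `path` invisibly.
#' @export
write_crbm_params <- function(params, path) {
  validate_params(params)
  obj <- list(
    format_version = 1L,
    n_visible = params$n_visible,
    n_hidden = params$n_hidden,
    weights = params$weights,
    g = params$g,
    gamma_plus = params$gamma_plus,
    gamma_minus = params$gamma_minus,
    theta_plus = params$theta_plus,
    theta_minus = params$theta_minus
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_crbm_params
#' @export
read_crbm_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- matrix(as.numeric(obj$weights), nrow = obj$n_visible, ncol = obj$n_hidden)
  crbm_params(w, obj$g, obj$gamma_plus, obj$gamma_minus,
              obj$theta_plus, obj$theta_minus)
}
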