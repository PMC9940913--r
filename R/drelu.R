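## Double-rectified linear unit (dReLU) potentials and their cumulant
## generating function.
##
## A hidden unit carries the potential
##   U(h) = 1/2 gamma_plus h_+^2 + 1/2 gamma_minus h_-^2
##          + theta_plus h_+ + theta_minus h_-,
## with h_+ = max(h, 0), h_- = min(h, 0). Given an input I the conditional
## density of the unit is proportional to exp(-U(h) + h I): a two-branch
## truncated Gaussian. Everything downstream (sampling, training moments,
## marginal likelihood) rests on evaluating
##   Gamma(I) = log \int exp(-U(h) + h I) dh
## and its derivatives in closed form. Each branch integral is a Gaussian
## mass: for the positive branch, with b = I - theta_plus,
##   Z_+ = exp(b^2 / (2 g)) sqrt(2 pi / g) Phi(b / sqrt(g)),
## and symmetrically for the negative branch. All evaluations are carried
## out in log space through pnorm(log.p = TRUE) so extreme inputs never
## overflow.

## Stable evaluation of phi(a)/Phi(-a) - a (the gap between the Gaussian
## hazard at a and a itself). For a -> +Inf this decays like 1/a; the direct
## log-space difference is accurate up to a ~ 30, beyond which an asymptotic
## series takes over. Used for truncated-Gaussian moments where the naive
## formulas cancel catastrophically.
mills_gap <- function(a) {
  d <- numeric(length(a))
  s <- a <= 30
  if (any(s)) {
    d[s] <- exp(stats::dnorm(a[s], log = TRUE) -
                  stats::pnorm(a[s], lower.tail = FALSE, log.p = TRUE)) - a[s]
  }
  if (any(!s)) {
    ai <- a[!s]
    x <- 1 / (ai * ai)
    d[!s] <- (1 - 2 * x + 10 * x^2 - 74 * x^3 + 706 * x^4) / ai
  }
  d
}

check_drelu <- function(gamma_plus, gamma_minus) {
  if (any(!is.finite(gamma_plus)) || any(!is.finite(gamma_minus)) ||
      any(gamma_plus <= 0) || any(gamma_minus <= 0))
    stop_dims("gamma_plus and gamma_minus must be finite and > 0")
  invisible(TRUE)
}

#' dReLU potential
#'
#' Evaluates the double-rectified linear unit potential
#' \eqn{U(h) = \frac{1}{2}\gamma_+ h_+^2 + \frac{1}{2}\gamma_- h_-^2 +
#' \theta_+ h_+ + \theta_- h_-}. With \eqn{\gamma_+=\gamma_-} and
#' \eqn{\theta_+=\theta_-} it reduces to the quadratic potential
#' \eqn{\frac{1}{2}\gamma h^2 + \theta h}.
#'
#' @param h numeric vector of hidden-unit values.
#' @param gamma_plus,gamma_minus positive curvatures of each branch.
#' @param theta_plus,theta_minus branch offsets.
#' @return `U(h)`, vectorized over all arguments.
#' @export
drelu_potential <- function(h, gamma_plus, gamma_minus, theta_plus, theta_minus) {
  check_drelu(gamma_plus, gamma_minus)
  hp <- pmax(h, 0)
  hm <- pmin(h, 0)
  0.5 * gamma_plus * hp^2 + 0.5 * gamma_minus * hm^2 +
    theta_plus * hp + theta_minus * hm
}

## Moments of the positive-side branch: density prop. to
## exp(-g u^2 / 2 + b u) on u > 0. Returns log mass, mean, second moment and
## variance of u under the truncated Gaussian.
branch_moments <- function(b, g) {
  sig <- 1 / sqrt(g)
  alpha <- -b * sig            # standardized truncation bound
  logz <- b^2 / (2 * g) + 0.5 * log(2 * pi / g) +
    stats::pnorm(b * sig, log.p = TRUE)
  d <- mills_gap(alpha)
  mean <- sig * d
  sq <- sig^2 * (1 - alpha * d)
  var <- sig^2 * (1 - d * (alpha + d))
  list(logz = logz, mean = mean, sq = sq, var = var)
}

#' Cumulant generating function of the dReLU potential
#'
#' Closed-form evaluation of \eqn{\Gamma(I) = \log \int e^{-U(h) + hI} dh}
#' together with its first two derivatives, which are the conditional mean
#' and variance of the unit given its input, and the per-branch moments
#' needed for training gradients. All quantities are computed from the two
#' truncated-Gaussian branch masses in log space; extreme inputs are safe.
#'
#' @param I numeric vector or matrix of unit inputs. If a matrix (frames x
#'   units), parameter vectors of length `ncol(I)` are expanded per column.
#' @param gamma_plus,gamma_minus,theta_plus,theta_minus dReLU parameters
#'   (scalars or vectors, recycled against `I`).
#' @return A list with elements `value` (\eqn{\Gamma}), `mean`
#'   (\eqn{\Gamma' = \langle h|I\rangle}), `var`
#'   (\eqn{\Gamma'' = \mathrm{Var}(h|I)}), `p_plus` (probability of the
#'   positive branch), `hp_mean`, `hm_mean`, `hp_sq`, `hm_sq`
#'   (\eqn{\langle h_\pm|I\rangle}, \eqn{\langle h_\pm^2|I\rangle}). Each
#'   has the shape of `I`.
#' @export
drelu_cumulant <- function(I, gamma_plus, gamma_minus, theta_plus, theta_minus) {
  check_drelu(gamma_plus, gamma_minus)
  if (any(!is.finite(I))) stop_dims("inputs I must be finite")
  shp <- dim(I)
  if (!is.null(shp) && length(gamma_plus) == ncol(I)) {
    n <- nrow(I)
    gamma_plus <- rep(gamma_plus, each = n)
    gamma_minus <- rep(gamma_minus, each = n)
    theta_plus <- rep(theta_plus, each = n)
    theta_minus <- rep(theta_minus, each = n)
  }
  I <- as.vector(I)

  pos <- branch_moments(I - theta_plus, gamma_plus)
  neg <- branch_moments(-(I - theta_minus), gamma_minus)  # mirrored variable u = -h

  value <- logaddexp(pos$logz, neg$logz)
  p_plus <- 1 / (1 + exp(neg$logz - pos$logz))
  p_minus <- 1 - p_plus

  hp_mean <- p_plus * pos$mean
  hm_mean <- -p_minus * neg$mean
  hp_sq <- p_plus * pos$sq
  hm_sq <- p_minus * neg$sq
  mean <- hp_mean + hm_mean
  ## mixture variance: within-branch variances plus between-branch spread;
  ## avoids the cancellation of <h^2> - <h>^2 across branches
  var <- p_plus * pos$var + p_minus * neg$var +
    p_plus * p_minus * (pos$mean + neg$mean)^2

  out <- list(value = value, mean = mean, var = var, p_plus = p_plus,
              hp_mean = hp_mean, hm_mean = hm_mean,
              hp_sq = hp_sq, hm_sq = hm_sq)
  if (!is.null(shp)) out <- lapply(out, function(x) { dim(x) <- shp; x })
  out
}

## Sample standardized Gaussian conditioned on Z > alpha via inverse CDF in
## log space (stable arbitrarily far into the tail).
rtail_norm <- function(alpha, u) {
  stats::qnorm(log(pmax(u, 1e-300)) +
                 stats::pnorm(alpha, lower.tail = FALSE, log.p = TRUE),
               lower.tail = FALSE, log.p = TRUE)
}

#' Sample dReLU units given their inputs
#'
#' Draws from the exact conditional \eqn{P(h|I) \propto e^{-U(h)+hI}}:
#' the branch is chosen with probability proportional to its truncated
#' Gaussian mass, then the value is drawn by inverse-CDF truncated-Gaussian
#' sampling with tail-stable quantile evaluation.
#'
#' @inheritParams drelu_cumulant
#' @param rng a [crbm_rng] object or integer seed.
#' @return numeric vector/matrix of samples, same shape as `I`.
#' @export
drelu_sample <- function(I, gamma_plus, gamma_minus, theta_plus, theta_minus, rng) {
  check_drelu(gamma_plus, gamma_minus)
  rng <- as_rng(rng)
  shp <- dim(I)
  if (!is.null(shp) && length(gamma_plus) == ncol(I)) {
    n <- nrow(I)
    gamma_plus <- rep(gamma_plus, each = n)
    gamma_minus <- rep(gamma_minus, each = n)
    theta_plus <- rep(theta_plus, each = n)
    theta_minus <- rep(theta_minus, each = n)
  } else if (is.null(shp)) {
    k <- length(I)
    gamma_plus <- rep_len(gamma_plus, k); gamma_minus <- rep_len(gamma_minus, k)
    theta_plus <- rep_len(theta_plus, k); theta_minus <- rep_len(theta_minus, k)
  }
  I <- as.vector(I)
  k <- length(I)

  bp <- I - theta_plus
  bm <- -(I - theta_minus)
  logzp <- bp^2 / (2 * gamma_plus) + 0.5 * log(2 * pi / gamma_plus) +
    stats::pnorm(bp / sqrt(gamma_plus), log.p = TRUE)
  logzm <- bm^2 / (2 * gamma_minus) + 0.5 * log(2 * pi / gamma_minus) +
    stats::pnorm(bm / sqrt(gamma_minus), log.p = TRUE)
  p_plus <- 1 / (1 + exp(logzm - logzp))

  h <- with_rng(rng, {
    take_pos <- stats::runif(k) < p_plus
    u <- stats::runif(k)
    out <- numeric(k)
    if (any(take_pos)) {
      g <- gamma_plus[take_pos]; b <- bp[take_pos]
      z <- rtail_norm(-b / sqrt(g), u[take_pos])
      out[take_pos] <- b / g + z / sqrt(g)
    }
    if (any(!take_pos)) {
      g <- gamma_minus[!take_pos]; b <- bm[!take_pos]
      z <- rtail_norm(-b / sqrt(g), u[!take_pos])
      out[!take_pos] <- -(b / g + z / sqrt(g))
    }
    out
  })
  if (!is.null(shp)) dim(h) <- shp
  h
}
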