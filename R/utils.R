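#' @keywords internal
#' @useDynLib crbm, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' Logistic function
#'
#' @param x numeric vector or matrix.
#' @return `1 / (1 + exp(-x))`, same shape as `x`.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

## log(exp(a) + exp(b)) without overflow; a, b same length
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  # when both are -Inf the result is -Inf, guard 0*Inf
  r <- m + log1p(exp(pmin(a, b) - m))
  r[is.infinite(m) & m < 0] <- -Inf
  r
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Root mean square error between two equal-length vectors
#'
#' @param x,y numeric vectors of equal length.
#' @return `sqrt(mean((x - y)^2))`.
#' @export
rmse <- function(x, y) {
  stopifnot(length(x) == length(y))
  sqrt(mean((x - y)^2))
}

stop_dims <- function(...) stop(sprintf(...), call. = FALSE)

check_binary <- function(v, what = "v") {
  if (!all(v %in% c(0, 1)))
    stop_dims("%s must be binary (0/1); found values outside {0,1}", what)
  invisible(TRUE)
}

## ---- explicit random generator objects -------------------------------------
## All stochastic operations funnel through a crbm_rng object so that no
## function touches the global RNG stream of the caller.

#' Create a seeded random generator object
#'
#' All sampling functions in the package take either a `crbm_rng` object or a
#' plain integer seed. Using an explicit generator keeps the caller's global
#' RNG stream untouched and makes every pipeline reproducible.
#'
#' @param seed integer seed.
#' @return an object of class `crbm_rng`.
#' @export
crbm_rng <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "crbm_rng"
  e
}

as_rng <- function(x) {
  if (inherits(x, "crbm_rng")) return(x)
  if (is.numeric(x) && length(x) == 1) return(crbm_rng(x))
  stop_dims("expected a crbm_rng object or an integer seed")
}

## Evaluate expr with the generator's state installed, then stash it back.
with_rng <- function(rng, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
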