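# Small shared helpers: classed errors, angle wrapping, seeded evaluation.

#' Signal a classed imusac error
#'
#' @param message Error message.
#' @param class Short error class, e.g. "shape", "validation", "contract".
#' @noRd
abort_imusac <- function(message, class) {
  stop(structure(
    class = c(paste0("imusac_", class), "imusac_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Wrap angles to (-pi, pi]
#'
#' Maps any real angle onto the half-open interval (-pi, pi].  Used before
#' differencing orientation angles so that residuals never jump by 2*pi
#' across the +/-pi seam.
#'
#' @param x Numeric vector of angles in radians.
#' @return Numeric vector of the same length, each element in (-pi, pi].
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi / 2))
#' @export
wrap_angle <- function(x) {
  m <- x %% (2 * pi)
  ifelse(m > pi, m - 2 * pi, m)
}

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded sub-draws do not
#' perturb an enclosing random stream.  With `seed = NULL` the expression is
#' evaluated against the current stream.
#'
#' @param seed Integer seed or NULL.
#' @param code Expression to evaluate.
#' @noRd
with_local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive k child seeds from one master seed
#'
#' One master seed fans out to independent streams (policy init, critic
#' init, sampler, environment).  Children stay below 2^31.
#' @noRd
fanout_seeds <- function(seed, k) {
  with_local_seed(seed, sample.int(.Machine$integer.max, k))
}

#' Euclidean norm
#' @noRd
vnorm <- function(x) sqrt(sum(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check all values finite
#' @noRd
assert_finite <- function(x, what, class = "validation") {
  if (!all(is.finite(x))) {
    abort_imusac(sprintf("non-finite values in %s", what), class)
  }
  invisible(x)
}
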