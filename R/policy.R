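# Factorized-Gaussian stochastic policy with squashing to the muscle
# excitation box [0, 1]^A.

LOG_STD_MIN <- -5
LOG_STD_MAX <- 2

#' Construct a squashed-Gaussian policy
#'
#' A dense network maps an observation to the mean and (log) diagonal
#' standard deviation of a factorized Gaussian over pre-squash actions.
#' Sampled actions are pushed through `a = (tanh(u) + 1) / 2` into the
#' excitation box \[0, 1\]^A, with the log-density corrected by the squash
#' Jacobian.  The log-std head is soft-clamped to \[-5, 2\] via a tanh
#' rescaling so its gradient never vanishes exactly.
#'
#' @param obs_dim Observation dimensionality.
#' @param act_dim Action (muscle excitation) dimensionality.
#' @param hidden Integer vector of hidden widths (ELU activations).
#' @param seed Optional init seed.
#' @return Object of class `gaussian_policy`.
#' @export
gaussian_policy <- function(obs_dim, act_dim, hidden = c(256, 256, 256, 256),
                            seed = NULL) {
  structure(
    list(net = nn_init(c(obs_dim, hidden, 2 * act_dim), "elu", seed),
         obs_dim = obs_dim, act_dim = act_dim, hidden = hidden),
    class = "gaussian_policy"
  )
}

#' @export
print.gaussian_policy <- function(x, ...) {
  cat(sprintf("<gaussian_policy> obs %d -> hidden [%s] -> act %d (squashed to [0,1])\n",
              x$obs_dim, paste(x$hidden, collapse = ", "), x$act_dim))
  invisible(x)
}

# Soft clamp of the raw log-std head to [LOG_STD_MIN, LOG_STD_MAX].
soft_clamp <- function(x, lo = LOG_STD_MIN, hi = LOG_STD_MAX) {
  lo + 0.5 * (hi - lo) * (tanh(x) + 1)
}
soft_clamp_grad <- function(x, lo = LOG_STD_MIN, hi = LOG_STD_MAX) {
  0.5 * (hi - lo) * (1 - tanh(x)^2)
}

#' Distribution parameters at a batch of observations
#'
#' @param policy A [gaussian_policy()].
#' @param obs Matrix (batch x obs_dim) or vector.
#' @return List `mu`, `log_sigma` (batch x act_dim), `raw_log_sigma`,
#'   and the forward `cache` for backprop.
#' @export
policy_dist <- function(policy, obs) {
  fw <- nn_forward(policy$net, obs)
  A <- policy$act_dim
  mu <- fw$out[, seq_len(A), drop = FALSE]
  raw <- fw$out[, A + seq_len(A), drop = FALSE]
  list(mu = mu, log_sigma = soft_clamp(raw), raw_log_sigma = raw,
       cache = fw$cache)
}

# Squash helpers: a = (tanh(u)+1)/2, da/du = (1 - tanh(u)^2)/2.
squash <- function(u) 0.5 * (tanh(u) + 1)

# Log density of the squashed action given pre-squash draw u and
# distribution parameters; one row per batch element.
squashed_log_prob <- function(u, mu, log_sigma) {
  sigma <- exp(log_sigma)
  base <- -0.5 * ((u - mu) / sigma)^2 - log_sigma - 0.5 * log(2 * pi)
  jac <- log(0.5 * (1 - tanh(u)^2) + 1e-9)
  rowSums(base - jac)
}

#' Sample actions from the policy
#'
#' Reparametrized draw `u = mu + sigma * eps`, squashed into the action
#' box, with the squash-corrected log density.  Reproducible under a
#' fixed seed; with `deterministic = TRUE` the squashed mean is returned.
#'
#' @param policy A [gaussian_policy()].
#' @param obs Observation vector or batch matrix.
#' @param seed Optional seed for the draw.
#' @param deterministic Return the squashed mean instead of a sample.
#' @return List `action` (batch x act_dim, in \[0,1\]), `log_prob`
#'   (length batch), and internals `u`, `eps`, `mu`, `log_sigma`.
#' @export
sample_action <- function(policy, obs, seed = NULL, deterministic = FALSE) {
  if (is.null(dim(obs))) obs <- matrix(obs, nrow = 1)
  if (ncol(obs) != policy$obs_dim) {
    abort_imusac(sprintf("policy expects %d-dim observations, got %d",
                         policy$obs_dim, ncol(obs)), "shape")
  }
  d <- policy_dist(policy, obs)
  n <- nrow(obs)
  eps <- if (deterministic) {
    matrix(0, n, policy$act_dim)
  } else {
    with_local_seed(seed, matrix(stats::rnorm(n * policy$act_dim),
                                 n, policy$act_dim))
  }
  u <- d$mu + exp(d$log_sigma) * eps
  list(action = squash(u),
       log_prob = squashed_log_prob(u, d$mu, d$log_sigma),
       u = u, eps = eps, mu = d$mu, log_sigma = d$log_sigma)
}
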