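# Soft Actor-Critic with per-component Q heads: losses, hand-derived
# gradients, n-step targets with invertible value rescaling, and the
# learned entropy temperature.

#' Invertible value rescaling
#'
#' `h(x) = sign(x) (sqrt(|x| + 1) - 1) + eps * x` with `eps = 1e-3`,
#' applied to bootstrapped values to compress their scale;
#' [value_rescale_inv()] is its closed-form inverse (round-trip accurate
#' to well below 1e-9).
#'
#' @param x Numeric vector.
#' @param eps Linear-tail coefficient.
#' @return Rescaled values.
#' @export
value_rescale <- function(x, eps = 1e-3) {
  sign(x) * (sqrt(abs(x) + 1) - 1) + eps * x
}

#' @rdname value_rescale
#' @param y Rescaled values to invert.
#' @export
value_rescale_inv <- function(y, eps = 1e-3) {
  sign(y) * ((((sqrt(1 + 4 * eps * (abs(y) + 1 + eps)) - 1) / (2 * eps))^2) - 1)
}

#' n-step bootstrapped target per reward component
#'
#' \deqn{y_i = h\left(\sum_{k=0}^{n-1} \gamma^k r_{i,t+k}
#'   + \gamma^n h^{-1}(\text{bootstrap}_i)\right)}
#' Episode termination inside the horizon truncates the bootstrap term.
#'
#' @param rewards Matrix (steps x heads) of reward vectors from time `t`
#'   onwards (a plain vector is treated as single-head).
#' @param bootstrap Per-head bootstrapped value at `t + n` (compressed
#'   scale, i.e. as produced by the target critic trained on `h` targets).
#' @param gamma Discount factor in (0, 1].
#' @param n Number of reward steps to unroll (1 <= n <= nrow(rewards)).
#' @param terminated Does the episode terminate within the n steps?
#' @param h,h_inv Rescaling pair; defaults [value_rescale()] /
#'   [value_rescale_inv()].  Pass `identity` twice for plain targets.
#' @return Per-head target vector (compressed scale).
#' @export
n_step_target <- function(rewards, bootstrap, gamma, n,
                          terminated = FALSE,
                          h = value_rescale, h_inv = value_rescale_inv) {
  if (is.null(dim(rewards))) rewards <- matrix(rewards, ncol = 1)
  if (gamma <= 0 || gamma > 1) {
    abort_imusac("gamma must lie in (0, 1]", "validation")
  }
  if (n < 1 || (n > nrow(rewards) && !terminated)) {
    abort_imusac(sprintf(
      "n = %d exceeds the %d-step horizon without termination",
      n, nrow(rewards)), "contract")
  }
  n_use <- min(n, nrow(rewards))
  disc <- gamma^(seq_len(n_use) - 1)
  acc <- as.numeric(disc %*% rewards[seq_len(n_use), , drop = FALSE])
  if (!terminated) {
    acc <- acc + gamma^n * h_inv(bootstrap)
  }
  h(acc)
}

#' Entropy-temperature state
#'
#' The learned SAC temperature `alpha` (stored as `log_alpha` so it stays
#' positive) with its entropy target `H_bar`; by convention
#' `H_bar = -dim(action)`.
#'
#' @param alpha Initial temperature (> 0).
#' @param target_entropy Entropy target `H_bar`.
#' @return Object of class `temperature_state`.
#' @export
temperature_state <- function(alpha = 0.2, target_entropy) {
  if (alpha < 0) abort_imusac("alpha must be non-negative", "validation")
  structure(list(log_alpha = log(max(alpha, 1e-12)),
                 target_entropy = target_entropy),
            class = "temperature_state")
}

temp_alpha <- function(temp) exp(temp$log_alpha)

# Compute per-head critic targets for a train batch:
# y = h( R_n + gamma_n * (1 - done) * h_inv(min-twin target Q(s', a')) ),
# a' ~ policy(next_obs).  R_n (batch$reward_n) is already the discounted
# within-segment reward sum and gamma_n the matching discount product.
critic_targets <- function(batch, policy, critic, seed = NULL,
                           rescale = TRUE) {
  h <- if (rescale) value_rescale else identity
  h_inv <- if (rescale) value_rescale_inv else identity
  nxt <- sample_action(policy, batch$next_obs, seed = seed)
  qt <- critic_q(critic, batch$next_obs, nxt$action, which = "target")
  boot <- h_inv(qt$qmin) * (1 - batch$done)        # rows: batch, cols: heads
  h(batch$reward_n + batch$gamma_n * boot)
}

#' SAC objective values on a frozen batch
#'
#' Evaluates the three learning objectives without updating anything:
#' the actor objective
#' `J_pi = E[alpha * log pi(a|s) - Q(s, a)]` under reparametrized
#' actions (twin-minimum, scalarized with the component weights), the
#' per-head critic objective `J_Q[i] = E[(Q_i(s,a) - y_i)^2] / 2`
#' (importance-weighted, averaged over the twin pair), and the
#' temperature objective `J_alpha = E[-alpha log pi(a|s) - alpha H_bar]`.
#'
#' @param batch A train batch from [make_train_batch()].
#' @param policy A [gaussian_policy()].
#' @param critic A [multihead_critic()].
#' @param temp A [temperature_state()].
#' @param weights Optional per-head scalarization weights (default: the
#'   critic's own).
#' @param seed Seed for the fresh action draws (bootstrap and actor).
#' @param rescale Apply invertible value rescaling to targets?
#' @return List `J_pi`, `J_Q` (named per head), `J_alpha`, `td_abs`
#'   (batch x heads |TD error| matrix for replay priorities).
#' @export
sac_losses <- function(batch, policy, critic, temp, weights = NULL,
                       seed = NULL, rescale = TRUE) {
  w <- as.numeric(weights %||% critic$weights)
  seeds <- if (is.null(seed)) c(NULL, NULL) else fanout_seeds(seed, 2)
  y <- critic_targets(batch, policy, critic, seed = seeds[1],
                      rescale = rescale)
  qq <- critic_q(critic, batch$obs, batch$act, which = "online")
  wis <- batch$w_is
  per_head_sq <- function(Q) colMeans(wis * (Q - y)^2) / 2
  J_Q <- per_head_sq(qq$q1)
  if (critic$twin) J_Q <- (J_Q + per_head_sq(qq$q2)) / 2
  names(J_Q) <- critic$head_names
  td_abs <- abs(qq$q1 - y)

  smp <- sample_action(policy, batch$obs, seed = seeds[2])
  q_pi <- critic_q(critic, batch$obs, smp$action, which = "online")$qmin
  alpha <- temp_alpha(temp)
  J_pi <- mean(alpha * smp$log_prob - as.numeric(q_pi %*% w))
  J_alpha <- mean(-alpha * smp$log_prob - alpha * temp$target_entropy)
  out <- list(J_pi = J_pi, J_Q = J_Q, J_alpha = J_alpha, td_abs = td_abs)
  if (!all(is.finite(unlist(out[c("J_pi", "J_Q", "J_alpha")])))) {
    abort_imusac(sprintf(
      "non-finite SAC loss (J_pi = %g, max J_Q = %g, J_alpha = %g)",
      out$J_pi, max(out$J_Q), out$J_alpha), "numerical")
  }
  out
}

#' Bundle policy, critic and temperature into a trainable agent
#'
#' @param policy A [gaussian_policy()].
#' @param critic A [multihead_critic()].
#' @param temp A [temperature_state()]; defaults to `H_bar = -act_dim`.
#' @param lr_policy,lr_critic,lr_alpha Adam learning rates.
#' @param tau Polyak coefficient for the target critic.
#' @param gamma Discount factor.
#' @param rescale Use invertible value rescaling in targets?
#' @param clip_norm Global gradient-norm clip for actor/critic steps
#'   (Inf disables).
#' @return Object of class `sac_agent`.
#' @export
sac_agent <- function(policy, critic, temp = NULL,
                      lr_policy = 3e-5, lr_critic = 1e-4, lr_alpha = 3e-4,
                      tau = 0.005, gamma = 0.99, rescale = TRUE,
                      clip_norm = 10) {
  temp <- temp %||% temperature_state(0.2, target_entropy = -policy$act_dim)
  structure(
    list(policy = policy, critic = critic, temp = temp,
         opt_pi = adam_init(policy$net),
         opt_q1 = adam_init(critic$q1),
         opt_q2 = if (critic$twin) adam_init(critic$q2) else NULL,
         alpha_m = 0, alpha_v = 0, alpha_t = 0L,
         lr_policy = lr_policy, lr_critic = lr_critic, lr_alpha = lr_alpha,
         tau = tau, gamma = gamma, rescale = rescale, clip_norm = clip_norm,
         updates = 0L),
    class = "sac_agent"
  )
}

#' @export
print.sac_agent <- function(x, ...) {
  cat(sprintf("<sac_agent> alpha = %.4g, gamma = %.3g, tau = %.3g, %d updates\n",
              temp_alpha(x$temp), x$gamma, x$tau, x$updates))
  print(x$policy)
  print(x$critic)
  invisible(x)
}

# Actor gradient w.r.t. the policy network output, derived for the
# squashed reparametrized sample a = squash(mu + sigma * eps):
#   d log pi / du    = 2 tanh(u)                 (squash-Jacobian term)
#   d log pi / d ls  = -1 + ... via u            (direct -log sigma term)
#   dQ/d phi         = dQ/da * da/du * du/dphi,  da/du = (1 - tanh(u)^2)/2
actor_grads <- function(policy, critic, temp, batch, weights, seed) {
  d <- policy_dist(policy, batch$obs)
  n <- nrow(batch$obs)
  A <- policy$act_dim
  eps <- with_local_seed(seed, matrix(stats::rnorm(n * A), n, A))
  sigma <- exp(d$log_sigma)
  u <- d$mu + sigma * eps
  a <- squash(u)
  th <- tanh(u)

  # dQ_scalar/da via critic input gradients, routing each head's weight
  # to the twin attaining the element-wise minimum.
  X <- critic_input(critic, batch$obs, a)
  fw1 <- nn_forward(critic$q1, X)
  w <- as.numeric(weights)
  if (critic$twin) {
    fw2 <- nn_forward(critic$q2, X)
    sel1 <- (fw1$out <= fw2$out) * 1
    dout1 <- sweep(sel1, 2, w, `*`)
    dout2 <- sweep(1 - sel1, 2, w, `*`)
    dX <- nn_backward(critic$q1, fw1$cache, dout1)$dX +
      nn_backward(critic$q2, fw2$cache, dout2)$dX
    q_pi <- pmin(fw1$out, fw2$out)
  } else {
    dout1 <- matrix(w, n, length(w), byrow = TRUE)
    dX <- nn_backward(critic$q1, fw1$cache, dout1)$dX
    q_pi <- fw1$out
  }
  dQ_da <- dX[, critic$obs_dim + seq_len(A), drop = FALSE]

  alpha <- temp_alpha(temp)
  da_du <- 0.5 * (1 - th^2)
  g_u <- (alpha * 2 * th - dQ_da * da_du) / n
  g_mu <- g_u
  g_ls <- (-alpha / n) + g_u * eps * sigma        # d/d log sigma
  g_raw <- g_ls * soft_clamp_grad(d$raw_log_sigma)
  dout <- cbind(g_mu, g_raw)
  grads <- nn_backward(policy$net, d$cache, dout)
  log_prob <- squashed_log_prob(u, d$mu, d$log_sigma)
  list(grads = grads,
       J_pi = mean(alpha * log_prob - as.numeric(q_pi %*% w)),
       log_prob = log_prob)
}

#' One SAC training step on a batch
#'
#' Performs, in order: an Adam step on each (twin) critic toward the
#' rescaled n-step targets, an Adam step on the actor against the
#' scalarized twin-minimum Q, a temperature step, and a Polyak update of
#' the target critic.  All stochastic draws derive from `seed`.
#'
#' @param agent A [sac_agent()].
#' @param batch A train batch from [make_train_batch()].
#' @param weights Optional scalarization weights (default: critic's own).
#' @param seed Seed for this update's draws.
#' @return List `agent` (updated), `losses` (J_pi, J_Q, J_alpha),
#'   `td` (batch x heads signed TD errors) for priority updates.
#' @export
sac_update <- function(agent, batch, weights = NULL, seed = NULL) {
  critic <- agent$critic
  policy <- agent$policy
  w <- as.numeric(weights %||% critic$weights)
  seeds <- if (is.null(seed)) list(NULL, NULL) else
    as.list(fanout_seeds(seed, 2))

  # --- critic step ---
  y <- critic_targets(batch, policy, critic, seed = seeds[[1]],
                      rescale = agent$rescale)
  n <- nrow(batch$obs)
  X <- critic_input(critic, batch$obs, batch$act)
  upd_critic <- function(net, opt) {
    fw <- nn_forward(net, X)
    dout <- batch$w_is * (fw$out - y) / n
    g <- clip_grads(nn_backward(net, fw$cache, dout), agent$clip_norm)
    st <- adam_step(net, g, opt, agent$lr_critic)
    list(net = st$net, opt = st$state, td = fw$out - y)
  }
  u1 <- upd_critic(critic$q1, agent$opt_q1)
  critic$q1 <- u1$net
  agent$opt_q1 <- u1$opt
  td <- u1$td
  if (critic$twin) {
    u2 <- upd_critic(critic$q2, agent$opt_q2)
    critic$q2 <- u2$net
    agent$opt_q2 <- u2$opt
  }

  # --- actor step (against the updated critic) ---
  ag <- actor_grads(policy, critic, agent$temp, batch, w, seeds[[2]])
  ag$grads <- clip_grads(ag$grads, agent$clip_norm)
  st <- adam_step(policy$net, ag$grads, agent$opt_pi, agent$lr_policy)
  policy$net <- st$net
  agent$opt_pi <- st$state

  # --- temperature step (Adam on log alpha) ---
  alpha <- temp_alpha(agent$temp)
  g_la <- alpha * mean(-ag$log_prob - agent$temp$target_entropy)
  agent$alpha_t <- agent$alpha_t + 1L
  agent$alpha_m <- 0.9 * agent$alpha_m + 0.1 * g_la
  agent$alpha_v <- 0.999 * agent$alpha_v + 0.001 * g_la^2
  mhat <- agent$alpha_m / (1 - 0.9^agent$alpha_t)
  vhat <- agent$alpha_v / (1 - 0.999^agent$alpha_t)
  agent$temp$log_alpha <- agent$temp$log_alpha -
    agent$lr_alpha * mhat / (sqrt(vhat) + 1e-8)
  J_alpha <- mean(-alpha * ag$log_prob - alpha * agent$temp$target_entropy)

  # --- target update ---
  critic <- polyak_update(critic, agent$tau)
  agent$critic <- critic
  agent$policy <- policy
  agent$updates <- agent$updates + 1L

  J_Q <- stats::setNames(colMeans(batch$w_is * td^2) / 2,
                         critic$head_names)
  list(agent = agent,
       losses = list(J_pi = ag$J_pi, J_Q = J_Q, J_alpha = J_alpha),
       td = td)
}
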