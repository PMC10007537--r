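# SAC core: policy sampling, scalarized Q, value rescaling, n-step
# targets, losses, head surgery, target updates.

test_that("sampled actions are squashed, reproducible, and tend to the mean", {
  policy <- gaussian_policy(4, 3, hidden = c(16, 16), seed = 3)
  obs <- matrix(rnorm(400 * 4), 400)

  s1 <- sample_action(policy, obs, seed = 42)
  s2 <- sample_action(policy, obs, seed = 42)
  expect_identical(s1$action, s2$action)
  expect_identical(s1$log_prob, s2$log_prob)

  # 10,000 draws all inside the excitation box
  big <- sample_action(policy, obs[rep(1:400, length.out = 10000), ],
                       seed = 1)
  expect_true(all(big$action >= 0 & big$action <= 1))

  # deterministic mode returns the squashed mean exactly
  d <- sample_action(policy, obs, deterministic = TRUE)
  pd <- policy_dist(policy, obs)
  expect_equal(d$action, 0.5 * (tanh(pd$mu) + 1))

  expect_error(sample_action(policy, rnorm(5)), class = "imusac_shape")
})

test_that("squashed log-density matches a numerical-integration oracle", {
  # the density of a = squash(mu + sigma*eps) must integrate to ~1
  policy <- gaussian_policy(2, 1, hidden = c(8), seed = 5)
  obs <- c(0.3, -0.2)
  pd <- policy_dist(policy, matrix(obs, 1))
  mu <- pd$mu[1, 1]; sig <- exp(pd$log_sigma[1, 1])
  a_grid <- seq(1e-4, 1 - 1e-4, length.out = 4001)
  u_grid <- atanh(2 * a_grid - 1)
  logp <- -0.5 * ((u_grid - mu) / sig)^2 - log(sig) - 0.5 * log(2 * pi) -
    log(0.5 * (1 - tanh(u_grid)^2) + 1e-9)
  mass <- sum(exp(logp)) * diff(a_grid)[1]
  expect_equal(mass, 1, tolerance = 1e-3)
  # and the package computes the same value at sampled points
  s <- sample_action(policy, matrix(obs, 1), seed = 9)
  u <- s$u[1, 1]
  manual <- -0.5 * ((u - mu) / sig)^2 - log(sig) - 0.5 * log(2 * pi) -
    log(0.5 * (1 - tanh(u)^2) + 1e-9)
  expect_equal(s$log_prob, manual, tolerance = 1e-10)
})

test_that("scalar Q is the weighted head sum", {
  critic <- multihead_critic(3, 2, head_names = c("a", "b"),
                             hidden = c(8), twin = FALSE, seed = 2)
  obs <- rnorm(3); act <- runif(2)
  q <- critic_q(critic, obs, act)$q1
  expect_equal(q_scalar(critic, obs, act, weights = c(1, 1)), sum(q))
  expect_equal(q_scalar(critic, obs, act, weights = c(0, 0)), 0)
  # dot-product oracle on random inputs and weights
  set.seed(13)
  for (i in 1:50) {
    o <- rnorm(3); a <- runif(2); w <- rnorm(2)
    qh <- critic_q(critic, o, a)$q1
    expect_equal(q_scalar(critic, o, a, weights = w),
                 w[1] * qh[1] + w[2] * qh[2], tolerance = 1e-12)
  }
  expect_error(q_scalar(critic, obs, act, weights = c(1, 1, 1)),
               class = "imusac_shape")
})

test_that("value rescaling is odd, anchored at zero, and invertible", {
  expect_equal(value_rescale(0), 0)
  set.seed(4)
  x <- c(rnorm(5000, sd = 1), rnorm(5000, sd = 100))
  expect_equal(value_rescale(-x), -value_rescale(x))
  expect_true(max(abs(value_rescale_inv(value_rescale(x)) - x)) < 1e-9)
})

test_that("n-step targets match a brute-force unrolled oracle", {
  # identity-rescale one-step case: r + bootstrap
  expect_equal(n_step_target(matrix(2.5, 1), 1.5, gamma = 1, n = 1,
                             h = identity, h_inv = identity), 4)
  # terminated episode with zero rewards hits h(0) = 0
  expect_equal(n_step_target(matrix(0, 3, 2), c(5, 5), gamma = 0.9, n = 3,
                             terminated = TRUE), c(0, 0))
  set.seed(6)
  for (trial in 1:40) {
    n <- sample(1:5, 1)
    steps <- n + sample(0:3, 1)
    heads <- sample(1:3, 1)
    rew <- matrix(rnorm(steps * heads), steps)
    boot <- rnorm(heads)
    gamma <- runif(1, 0.5, 1)
    oracle <- numeric(heads)
    for (i in seq_len(heads)) {
      acc <- 0
      for (k in 0:(n - 1)) acc <- acc + gamma^k * rew[k + 1, i]
      acc <- acc + gamma^n * value_rescale_inv(boot[i])
      oracle[i] <- value_rescale(acc)
    }
    expect_equal(n_step_target(rew, boot, gamma, n), oracle,
                 tolerance = 1e-10)
  }
  expect_error(n_step_target(matrix(1, 2, 1), 0, gamma = 0.9, n = 5),
               class = "imusac_contract")
})

test_that("SAC losses behave at their analytic anchor points", {
  agent <- tiny_agent()
  batch <- tiny_batch()

  # matched entropy: setting the target to the measured entropy zeroes
  # the temperature objective
  smp <- sample_action(agent$policy, batch$obs,
                       seed = fanout_seeds_test(99)[2])
  agent2 <- agent
  agent2$temp$target_entropy <- mean(-smp$log_prob)
  l <- sac_losses(batch, agent2$policy, agent2$critic, agent2$temp,
                  seed = 99, rescale = FALSE)
  expect_equal(l$J_alpha, 0, tolerance = 1e-10)
  expect_true(all(is.finite(c(l$J_pi, l$J_Q, l$J_alpha))))

  # critic loss is exactly invariant to within-batch ordering when no
  # bootstrap draw is involved (terminated batch)
  batch_t <- batch
  batch_t$done <- rep(1, nrow(batch$obs))
  perm <- sample(seq_len(nrow(batch$obs)))
  batchp <- batch_t
  for (f in c("obs", "act", "reward_n", "next_obs")) {
    batchp[[f]] <- batch_t[[f]][perm, , drop = FALSE]
  }
  for (f in c("gamma_n", "done", "w_is")) batchp[[f]] <- batch_t[[f]][perm]
  lp <- sac_losses(batchp, agent$policy, agent$critic, agent$temp,
                   seed = 99, rescale = FALSE)
  l0 <- sac_losses(batch_t, agent$policy, agent$critic, agent$temp,
                   seed = 99, rescale = FALSE)
  expect_equal(lp$J_Q, l0$J_Q, tolerance = 1e-12)

  # the actor/temperature objectives are order-invariant given the same
  # per-sample draws: permuting batch and noise together changes nothing
  d <- policy_dist(agent$policy, batch$obs)
  set.seed(31)
  eps <- matrix(rnorm(length(d$mu)), nrow(d$mu))
  j_pi_manual <- function(ord) {
    mu <- d$mu[ord, ]; ls <- d$log_sigma[ord, ]
    u <- mu + exp(ls) * eps[ord, ]
    a <- 0.5 * (tanh(u) + 1)
    q <- critic_q(agent$critic, batch$obs[ord, ], a)$qmin
    alpha <- imusac:::temp_alpha(agent$temp)
    lp <- imusac:::squashed_log_prob(u, mu, ls)
    mean(alpha * lp - as.numeric(q %*% as.numeric(agent$critic$weights)))
  }
  expect_equal(j_pi_manual(seq_len(nrow(batch$obs))), j_pi_manual(perm),
               tolerance = 1e-12)
})

test_that("critic heads equal to their targets give zero critic loss", {
  # single-head, non-twin critic whose output layer is zeroed: all Q = 0.
  # With zero rewards, zero bootstrap (target critic also outputs 0) the
  # targets are 0 and J_Q vanishes exactly.
  policy <- gaussian_policy(4, 3, hidden = c(16, 16), seed = 1)
  critic <- multihead_critic(4, 3, head_names = "only", hidden = c(16, 16),
                             twin = FALSE, seed = 2)
  L <- length(critic$q1$W)
  critic$q1$W[[L]][] <- 0
  critic$q1$b[[L]][] <- 0
  critic$target1 <- critic$q1
  batch <- tiny_batch(n_heads = 1)
  batch$reward_n <- matrix(0, nrow(batch$obs), 1)
  temp <- temperature_state(0.1, -3)
  l <- sac_losses(batch, policy, critic, temp, seed = 3, rescale = FALSE)
  expect_equal(unname(l$J_Q), 0)
})

test_that("with alpha = 0 and one head, the actor objective is -E[Q]", {
  policy <- gaussian_policy(4, 3, hidden = c(16, 16), seed = 8)
  critic <- multihead_critic(4, 3, head_names = "only", hidden = c(16, 16),
                             twin = FALSE, seed = 9)
  temp <- temperature_state(0, -3)
  batch <- tiny_batch(n_heads = 1)
  seeds <- fanout_seeds_test(77)
  l <- sac_losses(batch, policy, critic, temp, seed = 77, rescale = FALSE)
  smp <- sample_action(policy, batch$obs, seed = seeds[2])
  q <- critic_q(critic, batch$obs, smp$action)$q1
  expect_equal(l$J_pi, -mean(q), tolerance = 1e-8)
})

test_that("one small actor step on a frozen batch decreases J_pi", {
  agent <- tiny_agent(alpha = 0.05)
  agent$lr_policy <- 1e-4
  batch <- tiny_batch(n = 32)
  before <- sac_losses(batch, agent$policy, agent$critic, agent$temp,
                       seed = 5, rescale = FALSE)
  # actor-only step: keep the critic fixed so the surface does not move
  ag <- imusac:::actor_grads(agent$policy, agent$critic, agent$temp, batch,
                             as.numeric(agent$critic$weights), seed = 5)
  st <- imusac:::adam_step(agent$policy$net, ag$grads, agent$opt_pi, 1e-4)
  agent$policy$net <- st$net
  after <- sac_losses(batch, agent$policy, agent$critic, agent$temp,
                      seed = 5, rescale = FALSE)
  expect_lt(after$J_pi, before$J_pi)
})

test_that("zero-weight reward components do not interfere with the actor", {
  # actor objective with head 2 weighted 0 equals the single-head
  # objective computed without that head
  policy <- gaussian_policy(4, 3, hidden = c(16, 16), seed = 10)
  critic2 <- multihead_critic(4, 3, head_names = c("a", "b"),
                              hidden = c(16, 16), twin = FALSE, seed = 11)
  batch <- tiny_batch(n_heads = 2)
  temp <- temperature_state(0.1, -3)
  seeds <- fanout_seeds_test(55)
  l2 <- sac_losses(batch, policy, critic2, temp, weights = c(1, 0),
                   seed = 55, rescale = FALSE)
  smp <- sample_action(policy, batch$obs, seed = seeds[2])
  q <- critic_q(critic2, batch$obs, smp$action)$q1
  alpha <- 0.1
  expect_equal(l2$J_pi, mean(alpha * smp$log_prob - q[, 1]),
               tolerance = 1e-10)
})

test_that("Polyak update with coefficient 1 copies the online critic", {
  agent <- tiny_agent()
  # perturb online weights away from the target copy
  agent$critic$q1$W[[1]] <- agent$critic$q1$W[[1]] + 0.5
  up <- polyak_update(agent$critic, tau = 1)
  expect_identical(up$target1, up$q1)
  if (up$twin) expect_identical(up$target2, up$q2)
})

test_that("head surgery adds and removes heads without touching others", {
  critic <- multihead_critic(3, 2, head_names = c("a", "b", "c"),
                             hidden = c(12, 12), twin = TRUE, seed = 20)
  set.seed(30)
  obs <- matrix(rnorm(100 * 3), 100)
  act <- matrix(runif(100 * 2), 100)
  q_before <- critic_q(critic, obs, act)$q1

  # remove: scalar Q equals the original with that weight zeroed
  removed <- head_surgery(critic, "remove", index = 2)
  expect_equal(q_scalar(removed, obs, act),
               q_scalar(critic, obs, act, weights = c(1, 0, 1)))

  # add: pre-existing head outputs unchanged on 100 random inputs
  added <- head_surgery(critic, "add", seed = 40)
  q_after <- critic_q(added, obs, act)$q1
  expect_identical(q_after[, 1:3], q_before)
  expect_equal(added$n_heads, 4L)

  # add then remove the new head restores the original scalar Q
  back <- head_surgery(added, "remove", index = 4)
  expect_equal(q_scalar(back, obs, act), q_scalar(critic, obs, act))

  expect_error(head_surgery(critic, "remove", index = 7),
               class = "imusac_contract")
})

test_that("a full SAC update step runs, stays finite, and is seeded", {
  agent <- tiny_agent()
  batch <- tiny_batch(n = 24)
  up1 <- sac_update(agent, batch, seed = 123)
  up2 <- sac_update(agent, batch, seed = 123)
  expect_identical(up1$losses, up2$losses)
  expect_identical(up1$agent$policy$net$W, up2$agent$policy$net$W)
  expect_true(all(is.finite(unlist(up1$losses))))
  expect_equal(dim(up1$td), c(24, 2))
})
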