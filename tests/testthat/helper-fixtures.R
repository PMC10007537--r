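# Shared fixture builders: everything is generated in code at test time.

# A minimal body_kinematics with overridable fields.
kin_fixture <- function(...) {
  args <- list(...)
  base <- list(v_body = c(1, 0), v_tgt = c(1.25, 0),
               activations = rep(0.5, 6), in_step = TRUE, dt = 0.01)
  do.call(body_kinematics, utils::modifyList(base, args))
}

# A synthetic episode of n transitions with deterministic contents.
episode_fixture <- function(n, episode_id = 1, obs_dim = 3, act_dim = 2,
                            n_heads = 10) {
  lapply(seq_len(n), function(t) {
    transition(obs = seq_len(obs_dim) + t / 100,
               action = rep(0.5, act_dim),
               reward = seq_len(n_heads) * 0.01 + t / 1000,
               next_obs = seq_len(obs_dim) + (t + 1) / 100,
               done = (t == n), episode_id = episode_id, t = t)
  })
}

# Tiny policy/critic pair on small dimensions for learner tests.
tiny_agent <- function(obs_dim = 4, act_dim = 3, n_heads = 2,
                       twin = TRUE, seed = 1, alpha = 0.1) {
  policy <- gaussian_policy(obs_dim, act_dim, hidden = c(16, 16),
                            seed = seed)
  critic <- multihead_critic(obs_dim, act_dim,
                             head_names = paste0("h", seq_len(n_heads)),
                             hidden = c(16, 16), twin = twin,
                             seed = seed + 1)
  sac_agent(policy, critic, temperature_state(alpha, -act_dim),
            lr_policy = 1e-3, lr_critic = 1e-3, tau = 0.01, gamma = 0.95,
            rescale = FALSE)
}

# A random but reproducible train batch for the tiny agent.
tiny_batch <- function(n = 16, obs_dim = 4, act_dim = 3, n_heads = 2,
                       seed = 7) {
  withr::with_seed(seed, {
    structure(list(
      obs = matrix(rnorm(n * obs_dim), n),
      act = matrix(runif(n * act_dim), n),
      reward_n = matrix(rnorm(n * n_heads), n),
      next_obs = matrix(rnorm(n * obs_dim), n),
      gamma_n = rep(0.95, n),
      done = rep(0, n),
      w_is = rep(1, n)
    ), class = "train_batch")
  })
}

# The smallest meaningful training configuration (smoke tests only; the
# directional study uses default_config("reduced") unchanged).
smoke_config <- function() {
  cfg <- default_config("reduced")
  cfg$env$max_time <- 1.5
  cfg$train$epochs <- 2
  cfg$train$episodes_per_epoch <- 2
  cfg$train$updates_per_epoch <- 5
  cfg$train$warmup_episodes <- 1
  cfg$sac$hidden_policy <- c(8, 8)
  cfg$sac$hidden_critic <- c(8, 8)
  cfg$sac$batch_size <- 30
  cfg$reference$duration <- 1.5
  cfg$eval$duration <- 1.5
  cfg$eval$smooth_window <- 2
  cfg$distill$steps <- 5
  cfg$distill$hidden <- c(8, 8)
  cfg
}

vnorm_test <- function(x) sqrt(sum(x^2))

# replicate the package's seed fan-out for cross-checking seeded draws
fanout_seeds_test <- function(seed, k = 2) {
  withr::with_seed(seed, sample.int(.Machine$integer.max, k))
}
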