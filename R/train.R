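# Stage-one training loop: rollout collection on the synthetic walker
# with the multivariate reward, segment replay insertion, and SAC
# learner updates.

#' Collect one episode on the synthetic walker
#'
#' Runs the policy (or uniform random excitations during warmup) for one
#' episode, computing the full ten-component reward vector at every
#' timestep: the per-step trajectory-optimization composite, the five
#' shaping terms, the entropy bonus at the current temperature, and the
#' IMU deviations against the reference trace aligned at episode start.
#'
#' @param policy A [gaussian_policy()] (ignored when `random = TRUE`).
#' @param env_config A [walker_config()].
#' @param reference An [imu_trace()] reference (recycled periodically
#'   past its end).
#' @param weights A [reward_weights()] object.
#' @param alpha Entropy temperature for the reward's entropy component
#'   (0 disables it).
#' @param episode_id Integer id stamped on the transitions.
#' @param seed Seed for the action draws.
#' @param random Use uniform random excitations (warmup)?
#' @param deterministic Use the squashed policy mean (evaluation)?
#' @return List `transitions`, `rewards` (timesteps x 10 matrix),
#'   `scalar_return`, `component_sums` (length 10), `steps`, `reached`,
#'   `fallen`, `imu_obs` (an [imu_trace()] of the observed orientation),
#'   `path` (timesteps x 2 positions).
#' @export
collect_episode <- function(policy, env_config = walker_config(),
                            reference = generate_reference_imu(),
                            weights = reward_weights(), alpha = 0,
                            episode_id = 1, seed = NULL, random = FALSE,
                            deterministic = FALSE) {
  rs <- walker_reset(env_config)
  state <- rs$state
  obs <- rs$obs
  n_max <- ceiling(env_config$max_time / env_config$dt)
  seeds <- if (is.null(seed)) rep(list(NULL), n_max) else
    as.list(fanout_seeds(seed, n_max))
  transitions <- vector("list", n_max)
  rewards <- matrix(0, n_max, 10)
  roll <- pitch <- yaw <- numeric(n_max)
  path <- matrix(0, n_max, 2)
  i <- 0
  done <- FALSE
  while (!done && i < n_max) {
    i <- i + 1
    if (random) {
      a <- with_local_seed(seeds[[i]], stats::runif(env_config$n_muscles))
      lp <- 0
    } else {
      smp <- sample_action(policy, obs, seed = seeds[[i]],
                           deterministic = deterministic)
      a <- as.numeric(smp$action)
      lp <- smp$log_prob
    }
    stp <- walker_step(state, a, env_config)
    imu_obs <- observe_imu(stp$state, env_config)
    rvec <- step_reward_vector(
      stp$kin, a, weights, log_prob = lp, alpha = alpha,
      imu_ref = trace_triplet(reference, i),
      imu_obs = imu_triplet(imu_obs[["roll"]], imu_obs[["pitch"]],
                            imu_obs[["yaw"]])
    )
    transitions[[i]] <- transition(obs, a, rvec, stp$obs, stp$done,
                                   episode_id, i)
    rewards[i, ] <- rvec
    roll[i] <- imu_obs[["roll"]]
    pitch[i] <- imu_obs[["pitch"]]
    yaw[i] <- imu_obs[["yaw"]]
    path[i, ] <- c(stp$state$x, stp$state$y)
    state <- stp$state
    obs <- stp$obs
    done <- stp$done
  }
  rewards <- rewards[seq_len(i), , drop = FALSE]
  colnames(rewards) <- reward_component_names()
  list(
    transitions = transitions[seq_len(i)],
    rewards = rewards,
    scalar_return = sum(as.numeric(rewards %*% as.numeric(weights))),
    component_sums = colSums(rewards),
    steps = i, reached = state$reached, fallen = state$fallen,
    imu_obs = imu_trace(env_config$dt, roll[seq_len(i)], pitch[seq_len(i)],
                        yaw[seq_len(i)]),
    path = path[seq_len(i), , drop = FALSE]
  )
}

#' Train a stage-one SAC agent on the synthetic walker
#'
#' Per epoch: collect episodes with the current policy (uniform random
#' during warmup), insert them as half-overlapping segments into the
#' prioritized store, then run learner updates on prioritized batches
#' with n-step rescaled targets, refreshing segment priorities from the
#' new TD errors.  One master seed fans out to every stream (inits,
#' episode draws, batch draws), so single-worker runs are fully
#' reproducible.
#'
#' @param config An `imusac_config` (see [default_config()]).
#' @param seed Master seed.
#' @param reference Reference [imu_trace()]; generated from the config
#'   when NULL.
#' @param weights Reward weights; from the config when NULL (pass
#'   [baseline_weights()] weights for the zero-IMU ablation).
#' @param progress Print per-epoch progress lines?
#' @return List `agent`, `log` (per-epoch data frame with return
#'   statistics and per-component mean episode sums), `store`,
#'   `reference`, `weights`, `config`, `seed`, and `best` (the policy
#'   snapshot with the highest smoothed return, with its epoch).
#' @export
train_sac <- function(config = default_config("reduced"), seed = 1,
                      reference = NULL, weights = NULL, progress = FALSE) {
  validate_config(config)
  seeds <- fanout_seeds(seed, 5)
  weights <- weights %||% config_weights(config)
  env_cfg <- walker_config(dt = config$env$dt,
                           max_time = config$env$max_time,
                           target = config$env$target)
  reference <- reference %||% with(config$reference, generate_reference_imu(
    gait_period = gait_period, amplitudes = amplitudes, phases = phases,
    harmonics = harmonics, drift = drift, noise = noise,
    duration = duration, dt = config$env$dt, seed = seeds[1]))

  lc <- layout_selfcheck()$walker
  policy <- gaussian_policy(lc$obs, lc$act,
                            hidden = config$sac$hidden_policy,
                            seed = seeds[2])
  critic <- multihead_critic(lc$obs, lc$act,
                             hidden = config$sac$hidden_critic,
                             twin = config$sac$twin, seed = seeds[3])
  critic$weights[] <- as.numeric(weights)
  temp <- temperature_state(config$sac$alpha_init,
                            config$sac$target_entropy %||% -lc$act)
  agent <- sac_agent(policy, critic, temp,
                     lr_policy = config$sac$lr_policy,
                     lr_critic = config$sac$lr_critic,
                     lr_alpha = config$sac$lr_alpha,
                     tau = config$sac$tau, gamma = config$sac$gamma,
                     rescale = config$sac$rescale,
                     clip_norm = config$sac$clip_norm)

  store <- segment_store(config$replay$capacity, config$replay$L,
                         config$replay$eta)
  sched <- priority_schedule(config$replay$exp_start, config$replay$exp_end,
                             config$replay$ramp_steps)
  ep_seeds <- fanout_seeds(seeds[4],
                           config$train$epochs * config$train$episodes_per_epoch)
  up_seeds <- fanout_seeds(seeds[5],
                           config$train$epochs * config$train$updates_per_epoch)
  seg_per_batch <- max(2, ceiling(config$sac$batch_size / config$replay$L))

  log <- vector("list", config$train$epochs)
  ep_count <- 0
  step <- 0
  best <- list(policy = agent$policy, epoch = 0L, smooth = -Inf)
  ret_series <- numeric(0)
  for (epoch in seq_len(config$train$epochs)) {
    returns <- numeric(config$train$episodes_per_epoch)
    comp <- matrix(0, config$train$episodes_per_epoch, 10)
    for (e in seq_len(config$train$episodes_per_epoch)) {
      ep_count <- ep_count + 1
      ep <- collect_episode(agent$policy, env_cfg, reference, weights,
                            alpha = if (config$rewards$entropy_in_reward)
                              temp_alpha(agent$temp) else 0,
                            episode_id = ep_count,
                            seed = ep_seeds[ep_count],
                            random = ep_count <= config$train$warmup_episodes)
      store_insert_episode(store, ep$transitions)
      returns[e] <- ep$scalar_return
      comp[e, ] <- ep$component_sums
    }
    for (u in seq_len(config$train$updates_per_epoch)) {
      step <- step + 1
      us <- up_seeds[step]
      smp <- store_sample(store, seg_per_batch, sched, step = step,
                          seed = us)
      batch <- make_train_batch(smp$segments, smp$w_is,
                                n = config$sac$n_step,
                                gamma = config$sac$gamma)
      up <- sac_update(agent, batch, seed = us)
      agent <- up$agent
      deltas <- segment_deltas(batch, up$td, weights = agent$critic$weights)
      ids <- smp$ids[as.integer(names(deltas))]
      store_update_priorities(store, ids, unname(deltas))
    }
    comp_mean <- colMeans(comp)
    row <- data.frame(epoch = epoch, return_mean = mean(returns),
                      return_min = min(returns), return_max = max(returns),
                      alpha = temp_alpha(agent$temp), steps = step)
    for (k in seq_len(10)) {
      row[[reward_component_names()[k]]] <- comp_mean[k]
    }
    log[[epoch]] <- row
    # Track the best policy by smoothed return (the headline comparison
    # in this line of work is the maximum reward obtained).
    ret_series <- c(ret_series, mean(returns))
    w_sm <- min(config$eval$smooth_window, length(ret_series))
    smooth_now <- mean(utils::tail(ret_series, w_sm))
    if (smooth_now > best$smooth) {
      best <- list(policy = agent$policy, epoch = epoch,
                   smooth = smooth_now)
    }
    if (progress) {
      message(sprintf("epoch %3d | return %8.3f | alpha %.4f",
                      epoch, mean(returns), temp_alpha(agent$temp)))
    }
  }
  list(agent = agent, log = do.call(rbind, log), store = store,
       reference = reference, weights = weights, config = config,
       seed = seed, best = best)
}

#' Rescalarize logged returns under different component weights
#'
#' Training logs store the mean per-episode sum of every reward
#' component, so the learning curve under any weighting — for example
#' the six shared task components only, for comparing an IMU-constrained
#' run against the zero-IMU baseline on a common scale — can be
#' recomputed without re-running.
#'
#' @param log A training log from [train_sac()].
#' @param weights Numeric length 10 (or a [reward_weights()]).
#' @return Numeric vector: per-epoch rescalarized mean return.
#' @export
rescalarize_log <- function(log, weights) {
  w <- as.numeric(weights)
  comp <- as.matrix(log[, reward_component_names()])
  as.numeric(comp %*% w)
}

#' Weights selecting the six shared task components
#'
#' Takes a full weight vector and zeroes the entropy and IMU components,
#' leaving the six task components (`r_env ... r_tab`) at their
#' calibrated weights: the common scale on which differently-composed
#' reward configurations are compared.
#'
#' @param weights Base weights (default: the calibrated defaults of
#'   [default_config()]).
#' @return A numeric length-10 weight vector.
#' @export
task_component_weights <- function(weights = NULL) {
  w <- as.numeric(weights %||% default_config("reduced")$rewards$weights)
  names(w) <- reward_component_names()
  w[c("r_entropy", "r_imu_roll", "r_imu_pitch", "r_imu_yaw")] <- 0
  w
}
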