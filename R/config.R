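# Run configuration: defaults, YAML/JSON loading, validation.

#' Default run configuration
#'
#' Nested list of every tunable: environment (synthetic walker),
#' reference-trace generation, reward weights and toggles, SAC
#' hyperparameters (discount 0.99, policy/critic learning rates
#' 3e-5/1e-4, batch 256, four hidden layers, critic width 256, twin
#' critics, n-step 5), replay (capacity 250,000, segment length 10,
#' eta 0.9, exponent ramp 0.1 to 0.9 over 3000 steps), training loop
#' sizes, distillation (hidden width 1024, learning rate 1e-4, batch
#' 128, conditioning-noise variance 0.1) and evaluation (5 s window,
#' smoothing window 10 epochs).
#'
#' @param scale "full" for the published hyperparameters or "reduced"
#'   for the small desk-scale study configuration used by the examples
#'   and the shipped experiments.
#' @return Nested configuration list of class `imusac_config`.
#' @export
default_config <- function(scale = c("full", "reduced")) {
  scale <- match.arg(scale)
  cfg <- list(
    scale = scale,
    env = list(dt = 0.01, max_time = 10, target = c(5, 0),
               difficulty = 1),
    reference = list(gait_period = 1.28,
                     amplitudes = c(0.08, 0.05, 0.06),
                     phases = c(pi / 2, pi, pi / 2),
                     harmonics = c(1, 2, 1),
                     drift = c(0, 0, 0), noise = 0.01, duration = 5),
    # Component weights: IMU terms fixed at 1; the pelvis-velocity bonus
    # and dense effort penalty are scaled (0.3 / 0.1) so that steady
    # walking at the cruise speed is net-positive per step -- with unit
    # weights the effort penalty dominates and the optimum is to creep
    # or fall, which is not the behavior the reward is meant to induce.
    rewards = list(weights = c(1, 1, 1, 0.3, 0.1, 1, 1, 1, 1, 1),
                   w_step = 1, w_vel = 1, w_eff = 1,
                   entropy_in_reward = TRUE, entropy_in_actor = TRUE),
    sac = list(hidden_policy = c(256, 256, 256, 256),
               hidden_critic = c(256, 256, 256, 256),
               gamma = 0.99, lr_policy = 3e-5, lr_critic = 1e-4,
               lr_alpha = 3e-4, batch_size = 256, n_step = 5,
               twin = TRUE, tau = 0.005, alpha_init = 0.2,
               target_entropy = NULL, rescale = TRUE, clip_norm = 10),
    replay = list(capacity = 250000, L = 10, eta = 0.9,
                  exp_start = 0.1, exp_end = 0.9, ramp_steps = 3000,
                  workers = 1),
    train = list(epochs = 100, episodes_per_epoch = 10,
                 updates_per_epoch = 200, warmup_episodes = 10),
    distill = list(enabled = FALSE, hidden = c(1024, 1024, 1024, 1024),
                   lr = 1e-4, batch_size = 128, v_noise_var = 0.1,
                   steps = 1000),
    eval = list(duration = 5, smooth_window = 10)
  )
  if (scale == "reduced") {
    cfg$env$max_time <- 5
    cfg$sac$hidden_policy <- c(32, 32)
    cfg$sac$hidden_critic <- c(32, 32)
    cfg$sac$lr_policy <- 5e-4
    cfg$sac$lr_critic <- 1e-3
    cfg$sac$batch_size <- 120      # transitions (12 segments of 10)
    cfg$sac$n_step <- 5
    cfg$sac$gamma <- 0.95
    cfg$sac$rescale <- FALSE
    cfg$sac$tau <- 0.01
    cfg$sac$lr_alpha <- 1e-3
    cfg$sac$alpha_init <- 0.1
    cfg$replay$capacity <- 20000
    cfg$replay$ramp_steps <- 600
    cfg$train$epochs <- 30
    cfg$train$episodes_per_epoch <- 3
    cfg$train$updates_per_epoch <- 120
    cfg$train$warmup_episodes <- 3
    cfg$distill$hidden <- c(64, 64)
    cfg$distill$batch_size <- 32
    cfg$distill$steps <- 100
    cfg$eval$smooth_window <- 5
  }
  class(cfg) <- c("imusac_config", "list")
  cfg
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a run configuration file
#'
#' Reads a YAML (or JSON) configuration and merges it over the defaults;
#' only keys present in the file are overridden.  The merged
#' configuration is validated.
#'
#' @param path YAML/JSON configuration path; NULL for pure defaults.
#' @param scale Base defaults to merge over (see [default_config()]).
#' @return A validated `imusac_config`.
#' @export
load_config <- function(path = NULL, scale = "full") {
  cfg <- default_config(scale)
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort_imusac(sprintf("no such config file: %s", path), "config")
    }
    override <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, override)
    class(cfg) <- c("imusac_config", "list")
  }
  validate_config(cfg)
}

#' Validate a configuration
#'
#' @param cfg An `imusac_config`.
#' @return `cfg`, invisibly usable (returned on success).
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort_imusac(msg, "config")
  chk(cfg$env$dt > 0, "env.dt must be positive")
  chk(length(cfg$rewards$weights) == 10,
      "rewards.weights must have 10 components")
  chk(all(cfg$rewards$weights >= 0), "reward weights must be non-negative")
  chk(cfg$sac$gamma > 0 && cfg$sac$gamma <= 1, "sac.gamma must be in (0,1]")
  chk(cfg$sac$n_step >= 1 && cfg$sac$n_step <= 10,
      "sac.n_step must be in 1..10")
  chk(cfg$replay$L >= 2 && cfg$replay$L %% 2 == 0,
      "replay.L must be an even integer >= 2")
  chk(cfg$replay$eta >= 0 && cfg$replay$eta <= 1,
      "replay.eta must be in [0,1]")
  chk(cfg$train$epochs >= 1, "train.epochs must be >= 1")
  cfg
}

#' Reward weights object from a configuration
#'
#' @param cfg An `imusac_config`.
#' @param imu_off Zero out the three IMU weights (baseline ablation)?
#' @return A [reward_weights()] object.
#' @export
config_weights <- function(cfg, imu_off = FALSE) {
  w <- cfg$rewards$weights
  nm <- reward_component_names()
  args <- stats::setNames(as.list(w), nm)
  if (imu_off) {
    args$r_imu_roll <- 0
    args$r_imu_pitch <- 0
    args$r_imu_yaw <- 0
  }
  do.call(reward_weights, c(args, list(w_step = cfg$rewards$w_step,
                                       w_vel = cfg$rewards$w_vel,
                                       w_eff = cfg$rewards$w_eff)))
}

#' Save a configuration as YAML
#'
#' @param cfg An `imusac_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
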