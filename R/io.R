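# File I/O: IMU tables, reward traces, learning curves, checkpoints.

#' Write an IMU trace as CSV
#'
#' Columns `time_s, roll_rad, pitch_rad, yaw_rad` at full double
#' precision, re-loadable by [load_imu_table()].
#'
#' @param trace An [imu_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_imu_table <- function(trace, path) {
  df <- data.frame(time_s = trace$time, roll_rad = trace$roll,
                   pitch_rad = trace$pitch, yaw_rad = trace$yaw)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load an IMU table from CSV
#'
#' Expects a header with a time column and three axis columns
#' (`time_s, roll_rad, pitch_rad, yaw_rad`; the plain names
#' `time, roll, pitch, yaw` are also accepted).  Timestamps must be
#' strictly increasing.  Non-uniformly sampled tables are resampled to
#' `dt` (or to their median spacing) by linear interpolation preserving
#' endpoints; a table already on the `dt` grid is returned unchanged.
#'
#' @param path CSV path.
#' @param dt Optional target sampling period (s).
#' @return An [imu_trace()].
#' @export
load_imu_table <- function(path, dt = NULL) {
  if (!file.exists(path)) {
    abort_imusac(sprintf("no such file: %s", path), "format")
  }
  df <- utils::read.csv(path, check.names = FALSE)
  pick <- function(cands) {
    hit <- intersect(cands, names(df))
    if (length(hit) == 0) {
      abort_imusac(sprintf("missing column (tried: %s); found: %s",
                           paste(cands, collapse = ", "),
                           paste(names(df), collapse = ", ")), "format")
    }
    as.numeric(df[[hit[1]]])
  }
  tm <- pick(c("time_s", "time", "timestamp"))
  roll <- pick(c("roll_rad", "roll"))
  pitch <- pick(c("pitch_rad", "pitch"))
  yaw <- pick(c("yaw_rad", "yaw"))
  if (length(tm) < 2) {
    abort_imusac(sprintf("need >= 2 rows, got %d", length(tm)), "format")
  }
  dtv <- diff(tm)
  if (any(dtv <= 0)) {
    bad <- which(dtv <= 0)[1]
    abort_imusac(sprintf(
      "timestamps not strictly increasing at row %d (%g -> %g)",
      bad + 1, tm[bad], tm[bad + 1]), "format")
  }
  target_dt <- dt %||% stats::median(dtv)
  uniform <- isTRUE(all.equal(dtv, rep(target_dt, length(dtv)),
                              tolerance = 1e-9))
  if (uniform) {
    return(imu_trace(target_dt, roll, pitch, yaw,
                     meta = list(source = path)))
  }
  t_new <- seq(tm[1], tm[length(tm)], by = target_dt)
  interp <- function(y) stats::approx(tm, y, xout = t_new, rule = 2)$y
  imu_trace(target_dt, interp(roll), interp(pitch), interp(yaw),
            meta = list(source = path, resampled = TRUE))
}

#' Write a per-timestep reward-vector trace as CSV
#'
#' One named column per reward component plus the timestep index and the
#' scalarized reward.
#'
#' @param rewards Matrix (timesteps x 10) of reward vectors.
#' @param weights The [reward_weights()] used for the scalar column.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reward_trace <- function(rewards, weights, path) {
  df <- as.data.frame(rewards)
  names(df) <- reward_component_names()
  df <- cbind(timestep = seq_len(nrow(df)), df,
              r_scalar = as.numeric(rewards %*% as.numeric(weights)))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a learning-curve log as CSV
#'
#' @param log Data frame of per-epoch statistics.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_learning_curve <- function(log, path) {
  utils::write.csv(format(log, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- checkpoints -----------------------------------------------------------

net_to_list <- function(net) {
  list(sizes = net$sizes, hidden_act = net$hidden_act,
       W = lapply(net$W, function(w) list(dim = dim(w), data = as.numeric(w))),
       b = net$b)
}

net_from_list <- function(x) {
  list(W = lapply(x$W, function(w) {
    d <- as.integer(unlist(w$dim))
    matrix(as.numeric(unlist(w$data)), d[1], d[2])
  }),
       b = lapply(x$b, function(b) as.numeric(unlist(b))),
       sizes = as.integer(unlist(x$sizes)),
       hidden_act = unlist(x$hidden_act))
}

#' Save an agent checkpoint (JSON)
#'
#' Serializes policy, online and target critics, temperature, step
#' counters and the reward-component name list into a portable JSON
#' container.
#'
#' @param agent A [sac_agent()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
checkpoint_save <- function(agent, path) {
  ck <- list(
    format = "imusac-checkpoint-v1",
    head_names = agent$critic$head_names,
    weights = as.numeric(agent$critic$weights),
    obs_dim = agent$policy$obs_dim, act_dim = agent$policy$act_dim,
    hidden_policy = agent$policy$hidden, hidden_critic = agent$critic$hidden,
    twin = agent$critic$twin,
    log_alpha = agent$temp$log_alpha,
    target_entropy = agent$temp$target_entropy,
    updates = agent$updates,
    lr = list(policy = agent$lr_policy, critic = agent$lr_critic,
              alpha = agent$lr_alpha),
    tau = agent$tau, gamma = agent$gamma, rescale = agent$rescale,
    policy_net = net_to_list(agent$policy$net),
    q1 = net_to_list(agent$critic$q1),
    q2 = if (agent$critic$twin) net_to_list(agent$critic$q2),
    target1 = net_to_list(agent$critic$target1),
    target2 = if (agent$critic$twin) net_to_list(agent$critic$target2)
  )
  jsonlite::write_json(ck, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load an agent checkpoint
#'
#' @param path Checkpoint path from [checkpoint_save()].
#' @return A [sac_agent()] with restored parameters (fresh optimizer
#'   state).
#' @export
checkpoint_load <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(ck$format, "imusac-checkpoint-v1")) {
    abort_imusac("unrecognized checkpoint format", "format")
  }
  head_names <- as.character(unlist(ck$head_names))
  ck$twin <- isTRUE(unlist(ck$twin))
  policy <- gaussian_policy(ck$obs_dim, ck$act_dim,
                            hidden = as.numeric(unlist(ck$hidden_policy)))
  policy$net <- net_from_list(ck$policy_net)
  critic <- multihead_critic(ck$obs_dim, ck$act_dim,
                             head_names = head_names,
                             hidden = as.numeric(unlist(ck$hidden_critic)),
                             twin = ck$twin)
  critic$q1 <- net_from_list(ck$q1)
  critic$target1 <- net_from_list(ck$target1)
  if (ck$twin) {
    critic$q2 <- net_from_list(ck$q2)
    critic$target2 <- net_from_list(ck$target2)
  }
  critic$weights <- stats::setNames(as.numeric(unlist(ck$weights)),
                                    head_names)
  temp <- temperature_state(exp(ck$log_alpha), ck$target_entropy)
  agent <- sac_agent(policy, critic, temp,
                     lr_policy = ck$lr$policy, lr_critic = ck$lr$critic,
                     lr_alpha = ck$lr$alpha, tau = ck$tau, gamma = ck$gamma,
                     rescale = ck$rescale)
  agent$updates <- ck$updates
  agent
}
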