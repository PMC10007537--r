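# End-to-end experiments: evaluation rollouts, artifact emission, and
# the IMU-constrained vs baseline ablation study.

#' Evaluate a trained policy with a deterministic rollout
#'
#' Rolls the squashed policy mean for the evaluation window, recomputes
#' the reward trace independently from the logged trajectory, and scores
#' the observed pelvis orientation against the reference with per-axis
#' wrapped RMSE over the first `duration` seconds.
#'
#' @param agent A [sac_agent()].
#' @param env_config A [walker_config()].
#' @param reference Reference [imu_trace()].
#' @param weights A [reward_weights()] object.
#' @param duration RMSE window (s).
#' @return List `rmse` (named roll/pitch/yaw), `episode` (the
#'   [collect_episode()] result), `imu_obs`, `trajectory` (data frame
#'   time_s, x_m, y_m).
#' @export
evaluate_policy <- function(agent, env_config = walker_config(),
                            reference = generate_reference_imu(),
                            weights = reward_weights(), duration = 5) {
  ep <- collect_episode(agent$policy, env_config, reference, weights,
                        alpha = 0, deterministic = TRUE)
  win <- min(duration, ep$steps * env_config$dt)
  rmse <- rmse_per_axis(trace_window(reference, win),
                        trace_window(ep$imu_obs, win))
  traj <- data.frame(time_s = seq_len(ep$steps) * env_config$dt,
                     x_m = ep$path[, 1], y_m = ep$path[, 2])
  list(rmse = rmse, episode = ep, imu_obs = ep$imu_obs, trajectory = traj)
}

#' Run a full experiment and emit its artifact bundle
#'
#' Stage-one SAC training, optional stage-two distillation, and a
#' deterministic evaluation rollout.  Emits, under `out_dir`:
#' `learning_curve.csv`, `reward_trace.csv`, `trajectory.csv`,
#' `reference_imu.csv`, `observed_imu.csv`, `rmse.json`,
#' `checkpoint.json`, optional `student_checkpoint.json`, and
#' `metadata.json` (seed, full configuration, package version).
#'
#' @param config An `imusac_config`.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @param imu_off Zero the IMU weights (baseline ablation)?
#' @return Invisible list: the [train_sac()] result plus `eval` and
#'   `files` (the artifact manifest).
#' @export
run_experiment <- function(config = default_config("reduced"), out_dir,
                           seed = 1, imu_off = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  weights <- config_weights(config, imu_off = imu_off)
  run <- train_sac(config, seed = seed, weights = weights)
  env_cfg <- walker_config(dt = config$env$dt,
                           max_time = config$env$max_time,
                           target = config$env$target)
  ev <- evaluate_policy(run$agent, env_cfg, run$reference, weights,
                        duration = config$eval$duration)

  files <- c(
    learning_curve = file.path(out_dir, "learning_curve.csv"),
    reward_trace = file.path(out_dir, "reward_trace.csv"),
    trajectory = file.path(out_dir, "trajectory.csv"),
    reference_imu = file.path(out_dir, "reference_imu.csv"),
    observed_imu = file.path(out_dir, "observed_imu.csv"),
    rmse = file.path(out_dir, "rmse.json"),
    checkpoint = file.path(out_dir, "checkpoint.json"),
    metadata = file.path(out_dir, "metadata.json")
  )
  write_learning_curve(run$log, files[["learning_curve"]])
  write_reward_trace(ev$episode$rewards, weights, files[["reward_trace"]])
  utils::write.csv(format(ev$trajectory, digits = 17, trim = TRUE,
                          scientific = TRUE),
                   files[["trajectory"]], row.names = FALSE, quote = FALSE)
  write_imu_table(run$reference, files[["reference_imu"]])
  write_imu_table(ev$imu_obs, files[["observed_imu"]])
  jsonlite::write_json(as.list(ev$rmse), files[["rmse"]],
                       auto_unbox = TRUE, digits = NA)
  checkpoint_save(run$agent, files[["checkpoint"]])

  if (isTRUE(config$distill$enabled)) {
    field <- make_target_field(c(0, 0), config$env$target)
    ds <- distill_stage(run$agent$policy, run$agent$critic, run$store,
                        field, config$distill, seed = seed)
    files[["student_checkpoint"]] <- file.path(out_dir,
                                               "student_checkpoint.json")
    st_ck <- list(format = "imusac-student-v1",
                  policy_net = net_to_list(ds$student$policy$net),
                  q1 = net_to_list(ds$student$critic$q1),
                  field_dim = ds$student$field_dim,
                  loss_log = ds$loss_log)
    jsonlite::write_json(st_ck, files[["student_checkpoint"]],
                         auto_unbox = TRUE, digits = NA)
  }

  meta <- list(seed = seed, imu_off = imu_off,
               package_version = as.character(utils::packageVersion("imusac")),
               config = unclass(config))
  jsonlite::write_json(meta, files[["metadata"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c(run, list(eval = ev, files = files)))
}

#' IMU-constrained vs zero-IMU ablation with matched seeds
#'
#' Trains two agents under identical configuration and master seed, one
#' with the full reward vector and one with the three IMU weights set to
#' zero, then compares (a) the mean per-axis RMSE of a deterministic
#' rollout against the reference trace and (b) the final smoothed
#' return on the six shared task components.
#'
#' @param config An `imusac_config`.
#' @param seed Master seed (shared by both runs).
#' @return List `imu`, `baseline` (each: `rmse`, `rmse_mean`,
#'   `final_task_return`, `run`), and `comparison` (logical
#'   `rmse_lower`, `return_no_lower`).
#' @export
imu_ablation_study <- function(config = default_config("reduced"),
                               seed = 1) {
  env_cfg <- walker_config(dt = config$env$dt,
                           max_time = config$env$max_time,
                           target = config$env$target)
  one <- function(imu_off) {
    w <- config_weights(config, imu_off = imu_off)
    run <- train_sac(config, seed = seed, weights = w)
    # Evaluate the best-return checkpoint (the headline quantity in this
    # line of work is the maximum reward obtained, not the last epoch).
    best_agent <- run$agent
    best_agent$policy <- run$best$policy
    ev <- evaluate_policy(best_agent, env_cfg, run$reference, w,
                          duration = config$eval$duration)
    task <- rescalarize_log(run$log,
                            task_component_weights(config$rewards$weights))
    smooth <- moving_mean(task, config$eval$smooth_window)
    list(rmse = ev$rmse, rmse_mean = mean(ev$rmse),
         final_task_return = smooth[length(smooth)],
         max_task_return = max(smooth),
         max_return = run$best$smooth, best_epoch = run$best$epoch,
         run = run, eval = ev)
  }
  imu <- one(FALSE)
  base <- one(TRUE)
  list(imu = imu, baseline = base,
       comparison = list(
         rmse_lower = imu$rmse_mean < base$rmse_mean,
         return_no_lower = imu$final_task_return >= base$final_task_return
       ))
}
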