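# Synthetic reference-IMU generator and the imu_trace container.

#' Time-aligned roll/pitch/yaw trace
#'
#' A uniformly sampled orientation time series at the simulation
#' timestep, used both for the reference (collected) trace and for
#' rollout (observed) traces.  Angles are stored raw (drifting traces
#' may leave (-pi, pi]); wrapping happens when traces are differenced.
#'
#' @param dt Sampling period (s).
#' @param roll,pitch,yaw Numeric vectors of equal length (radians).
#' @param meta Optional named list of generation metadata.
#' @return Object of class `imu_trace` with fields `dt`, `time`,
#'   `roll`, `pitch`, `yaw`, `meta`.
#' @export
imu_trace <- function(dt, roll, pitch, yaw, meta = list()) {
  n <- length(roll)
  if (length(pitch) != n || length(yaw) != n || n < 1) {
    abort_imusac("roll/pitch/yaw must be equal-length, non-empty",
                 "validation")
  }
  if (!is.finite(dt) || dt <= 0) {
    abort_imusac("dt must be positive", "validation")
  }
  structure(list(dt = dt, time = (seq_len(n) - 1) * dt,
                 roll = as.numeric(roll), pitch = as.numeric(pitch),
                 yaw = as.numeric(yaw), meta = meta),
            class = "imu_trace")
}

#' @export
print.imu_trace <- function(x, ...) {
  cat(sprintf("<imu_trace> %d samples at dt = %g s (%.2f s)\n",
              length(x$roll), x$dt, length(x$roll) * x$dt))
  if (length(x$meta)) {
    cat(" meta:", paste(names(x$meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.imu_trace <- function(x) length(x$roll)

#' Generate a synthetic reference IMU trace
#'
#' Emulates a pelvis-mounted IMU recording of a straight comfortable
#' walk: per-axis sinusoid at the gait period (pitch at twice the stride
#' frequency by default, reflecting the double-peaked pelvic tilt of one
#' stride), plus linear drift and seeded additive Gaussian noise.
#' Defaults describe a steady comfortable-speed straight walk in the
#' synthetic walker's own gait: the default stride period (1.28 s) is
#' the walker's stride period at the target-field cruise speed, and the
#' phase offsets match its double-support start, so the reference is the
#' motion a well-trained agent performing the task would itself produce.
#'
#' @param gait_period Stride period (s), > 0.
#' @param amplitudes Per-axis amplitudes (rad), named or ordered
#'   roll/pitch/yaw.
#' @param phases Per-axis phase offsets (rad).
#' @param harmonics Per-axis cycles per stride (pitch default 2).
#' @param drift Per-axis linear drift (rad/s).
#' @param noise Additive Gaussian noise standard deviation (rad).
#' @param duration Trace duration (s).
#' @param dt Sampling period (s); 5 s at 0.01 s gives 500 samples.
#' @param seed Optional seed for the noise.
#' @return An [imu_trace()] with generation metadata.
#' @export
generate_reference_imu <- function(gait_period = 1.28,
                                   amplitudes = c(roll = 0.08, pitch = 0.05,
                                                  yaw = 0.06),
                                   phases = c(roll = pi / 2, pitch = pi,
                                              yaw = pi / 2),
                                   harmonics = c(roll = 1, pitch = 2,
                                                 yaw = 1),
                                   drift = c(roll = 0, pitch = 0, yaw = 0),
                                   noise = 0.01, duration = 5, dt = 0.01,
                                   seed = NULL) {
  if (!is.finite(gait_period) || gait_period <= 0) {
    abort_imusac("gait_period must be positive", "validation")
  }
  if (dt <= 0 || duration < dt) {
    abort_imusac("need dt > 0 and duration >= dt", "validation")
  }
  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  axes <- with_local_seed(seed, {
    lapply(1:3, function(i) {
      amplitudes[i] * sin(2 * pi * harmonics[i] * t / gait_period +
                            phases[i]) +
        drift[i] * t + stats::rnorm(n, 0, noise)
    })
  })
  imu_trace(dt, axes[[1]], axes[[2]], axes[[3]],
            meta = list(gait_period = gait_period,
                        amplitudes = unname(amplitudes),
                        phases = unname(phases),
                        harmonics = unname(harmonics),
                        drift = unname(drift), noise = noise,
                        duration = duration, seed = seed,
                        synthetic = TRUE))
}

#' Reference triplet at a simulation timestep
#'
#' Index the reference trace at step `i` (1-based), recycling
#' periodically when the episode outlasts the trace (the reference is a
#' steady-state gait).
#'
#' @param trace An [imu_trace()].
#' @param i Timestep index (1-based).
#' @return An [imu_triplet()] (untimestamped).
#' @export
trace_triplet <- function(trace, i) {
  n <- length(trace$roll)
  j <- ((i - 1) %% n) + 1
  imu_triplet(trace$roll[j], trace$pitch[j], trace$yaw[j])
}

#' Truncate a trace to its first `duration` seconds
#'
#' @param trace An [imu_trace()].
#' @param duration Window length (s).
#' @return An [imu_trace()] of `round(duration / dt)` samples.
#' @export
trace_window <- function(trace, duration) {
  n <- min(length(trace$roll), round(duration / trace$dt))
  if (n < 1) abort_imusac("window shorter than one sample", "validation")
  imu_trace(trace$dt, trace$roll[seq_len(n)], trace$pitch[seq_len(n)],
            trace$yaw[seq_len(n)], meta = trace$meta)
}
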