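# Evaluation: per-axis RMSE against the reference trace and
# learning-curve aggregation.

#' Per-axis RMSE between two IMU traces
#'
#' Root mean squared wrapped angular difference per axis.  Traces on
#' different sampling periods are first resampled (linear interpolation)
#' onto the reference period; after alignment the sample counts must
#' match exactly.  Residuals are wrapped to (-pi, pi] before squaring so
#' yaw differences never inflate across the +/-pi seam.
#'
#' @param reference,observed [imu_trace()] objects aligned at t = 0.
#' @return Named numeric `c(roll, pitch, yaw)`.
#' @export
rmse_per_axis <- function(reference, observed) {
  if (!inherits(reference, "imu_trace") || !inherits(observed, "imu_trace")) {
    abort_imusac("both arguments must be imu_trace objects", "input")
  }
  if (!isTRUE(all.equal(reference$dt, observed$dt))) {
    observed <- resample_trace(observed, reference$dt)
  }
  n <- length(reference$roll)
  if (length(observed$roll) != n) {
    abort_imusac(sprintf(
      "traces misaligned after resampling: %d vs %d samples",
      n, length(observed$roll)), "alignment")
  }
  one <- function(a, b) sqrt(mean(wrap_angle(a - b)^2))
  c(roll = one(reference$roll, observed$roll),
    pitch = one(reference$pitch, observed$pitch),
    yaw = one(reference$yaw, observed$yaw))
}

#' Resample a trace onto a new sampling period
#'
#' Linear interpolation preserving endpoints; a trace already on the
#' target grid is returned with identical samples.
#'
#' @param trace An [imu_trace()].
#' @param dt Target sampling period (s).
#' @return An [imu_trace()] at period `dt`.
#' @export
resample_trace <- function(trace, dt) {
  if (isTRUE(all.equal(trace$dt, dt))) return(trace)
  t_old <- trace$time
  t_new <- seq(0, t_old[length(t_old)], by = dt)
  interp <- function(y) stats::approx(t_old, y, xout = t_new, rule = 2)$y
  imu_trace(dt, interp(trace$roll), interp(trace$pitch), interp(trace$yaw),
            meta = trace$meta)
}

#' Trailing moving mean with partial windows
#'
#' Window `w = 1` is the identity; earlier points average over the
#' samples available so far.
#' @noRd
moving_mean <- function(x, w) {
  vapply(seq_along(x), function(i) mean(x[max(1, i - w + 1):i]), numeric(1))
}

#' Aggregate run logs into smoothed learning curves
#'
#' Groups per-epoch training logs by configuration name, averages
#' repeated runs on their common epoch axis, and applies a trailing
#' moving-average smoother to the mean return (min/max envelopes are
#' kept unsmoothed).
#'
#' @param logs Named list of per-run data frames with columns `epoch`,
#'   `return_mean`, `return_min`, `return_max` (names identify the
#'   configuration; repeated names are averaged).
#' @param window Smoothing window in epochs (>= 1; 1 = no smoothing).
#' @return Named list of `learning_curve` data frames with columns
#'   `epoch`, `return_mean`, `return_smooth`, `return_min`, `return_max`.
#' @export
aggregate_learning_curves <- function(logs, window = 10) {
  if (length(logs) == 0) abort_imusac("no run logs", "contract")
  if (window < 1) abort_imusac("window must be >= 1", "validation")
  nms <- names(logs) %||% rep("run", length(logs))
  out <- list()
  for (nm in unique(nms)) {
    runs <- logs[nms == nm]
    for (r in runs) {
      need <- c("epoch", "return_mean", "return_min", "return_max")
      if (nrow(r) == 0 || !all(need %in% names(r))) {
        abort_imusac("each run log needs >= 1 epoch and the return columns",
                     "contract")
      }
    }
    epochs <- sort(Reduce(intersect, lapply(runs, function(r) r$epoch)))
    if (length(epochs) == 0) {
      abort_imusac("runs share no common epochs", "contract")
    }
    pick <- function(r, col) r[[col]][match(epochs, r$epoch)]
    mean_ret <- Reduce(`+`, lapply(runs, pick, col = "return_mean")) /
      length(runs)
    min_ret <- do.call(pmin, lapply(runs, pick, col = "return_min"))
    max_ret <- do.call(pmax, lapply(runs, pick, col = "return_max"))
    curve <- data.frame(
      epoch = epochs, return_mean = mean_ret,
      return_smooth = moving_mean(mean_ret, window),
      return_min = min_ret, return_max = max_ret
    )
    class(curve) <- c("learning_curve", "data.frame")
    out[[nm]] <- curve
  }
  out
}
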