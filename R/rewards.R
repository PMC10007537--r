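# Multivariate reward: trajectory-optimization terms, shaping terms,
# IMU-deviation terms, entropy bonus, and linear scalarization.

#' Names of the ten reward-vector components, in their fixed order
#'
#' The order is part of the contract between the reward assembly, the
#' per-component critic heads, and the exported reward traces:
#' `r_env, r_clp, r_vdp, r_pvb, r_dep, r_tab, r_entropy, r_imu_roll,
#' r_imu_pitch, r_imu_yaw`.
#'
#' @return Character vector of length 10.
#' @export
reward_component_names <- function() {
  c("r_env", "r_clp", "r_vdp", "r_pvb", "r_dep", "r_tab",
    "r_entropy", "r_imu_roll", "r_imu_pitch", "r_imu_yaw")
}

#' Per-component reward weights
#'
#' Non-negative weights used wherever the reward vector (or its per-head
#' Q values) is collapsed to a scalar.  The trajectory-optimization
#' composite `r_env` additionally carries three internal weights
#' `w_step`, `w_vel`, `w_eff` for its stepping / velocity-cost /
#' effort-cost terms.  The three IMU deviation weights default to 1; the
#' zero-IMU baseline configuration is obtained by setting them to 0.
#'
#' @param ... Named overrides for individual components, e.g.
#'   `r_imu_roll = 0`.
#' @param default Default weight for components not named (1).
#' @param w_step,w_vel,w_eff Internal weights of the `r_env` composite.
#' @return Object of class `reward_weights`: a named numeric vector of
#'   length 10 with attributes `w_step`, `w_vel`, `w_eff`.
#' @examples
#' reward_weights()                       # full configuration
#' reward_weights(r_imu_roll = 0, r_imu_pitch = 0, r_imu_yaw = 0)  # baseline
#' @export
reward_weights <- function(..., default = 1, w_step = 1, w_vel = 1, w_eff = 1) {
  nm <- reward_component_names()
  w <- stats::setNames(rep(default, length(nm)), nm)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), nm)
    if (length(bad)) {
      abort_imusac(sprintf("unknown reward component(s): %s",
                           paste(bad, collapse = ", ")), "shape")
    }
    w[names(dots)] <- as.numeric(unlist(dots))
  }
  if (any(w < 0) || w_step < 0 || w_vel < 0 || w_eff < 0) {
    abort_imusac("reward weights must be non-negative", "validation")
  }
  structure(w, w_step = w_step, w_vel = w_vel, w_eff = w_eff,
            class = "reward_weights")
}

#' Zero-IMU baseline weights
#'
#' Convenience constructor: identical to [reward_weights()] but with the
#' three IMU deviation weights set to 0.
#' @param ... Passed to [reward_weights()].
#' @return A `reward_weights` object.
#' @export
baseline_weights <- function(...) {
  reward_weights(r_imu_roll = 0, r_imu_pitch = 0, r_imu_yaw = 0, ...)
}

#' Body kinematics for one simulation timestep
#'
#' The per-timestep quantities the reward terms consume, decoupled from
#' any particular simulator: pelvis velocities, the local target velocity,
#' landmark positions used by the crossing-legs score, muscle activations,
#' the in-step indicator and the fall flag.
#'
#' @param v_body Pelvis planar velocity (length-2, m/s).
#' @param v_vel Pelvis velocity entering the velocity cost (length-2, m/s);
#'   defaults to `v_body`.
#' @param v_tgt Local target velocity at the pelvis cell (length-2, m/s).
#' @param r_head,r_pelvis,r_left,r_right Landmark position vectors
#'   (length-3, m): head, pelvis, left foot, right foot.
#' @param activations Per-muscle activations in \[0, 1\].
#' @param in_step Logical: does this timestep belong to a step interval
#'   (exactly one foot in contact)?
#' @param dt Simulation timestep in seconds (default 0.01).
#' @param fallen Logical fall flag.
#' @return Object of class `body_kinematics` (a validated list).
#' @export
body_kinematics <- function(v_body, v_vel = v_body, v_tgt,
                            r_head = c(0, 0, 1.5), r_pelvis = c(0, 0, 0.9),
                            r_left = c(0, 0.1, 0), r_right = c(0, -0.1, 0),
                            activations = numeric(0),
                            in_step = FALSE, dt = 0.01, fallen = FALSE) {
  kin <- list(v_body = as.numeric(v_body), v_vel = as.numeric(v_vel),
              v_tgt = as.numeric(v_tgt),
              r_head = as.numeric(r_head), r_pelvis = as.numeric(r_pelvis),
              r_left = as.numeric(r_left), r_right = as.numeric(r_right),
              activations = as.numeric(activations),
              in_step = isTRUE(in_step), dt = dt, fallen = isTRUE(fallen))
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    abort_imusac("dt must be a single positive number", "validation")
  }
  vecs <- c(kin$v_body, kin$v_vel, kin$v_tgt, kin$r_head, kin$r_pelvis,
            kin$r_left, kin$r_right)
  if (!all(is.finite(vecs))) {
    abort_imusac("non-finite kinematic vectors", "validation")
  }
  if (length(kin$activations) &&
      (!all(is.finite(kin$activations)) ||
       any(kin$activations < 0) || any(kin$activations > 1))) {
    abort_imusac("activations must lie in [0, 1]", "validation")
  }
  class(kin) <- "body_kinematics"
  kin
}

#' Trajectory-optimization reward terms over a window
#'
#' Aggregates the alive bonus, stepping reward, velocity cost and effort
#' cost over a trajectory window and combines them into the composite
#' environment reward:
#' \deqn{r_{env} = R_{alive} + w_{step} r_{step} - w_{vel} c_{vel}
#'       - w_{eff} c_{eff}}
#' with \eqn{r_{alive} = 0.1} per non-fallen timestep,
#' \eqn{r_{step} = \sum_i in\_step_i \Delta t_i},
#' \eqn{c_{vel} = \lVert \sum_i in\_step_i (v_{vel} - v_{tgt}) \Delta t_i \rVert}
#' (note: norm of the vector sum, not sum of norms) and
#' \eqn{c_{eff} = \sum_i in\_step_i \sum_m A_m^2 \Delta t_i}.
#'
#' @param traj List of [body_kinematics()] objects sharing one `dt`.
#' @param weights A [reward_weights()] object (its `w_step`, `w_vel`,
#'   `w_eff` attributes are used).
#' @return Named list with `r_alive`, `r_step`, `c_vel`, `c_eff`, `r_env`.
#' @export
tor_reward_terms <- function(traj, weights = reward_weights()) {
  if (length(traj) == 0) {
    abort_imusac("empty trajectory", "input")
  }
  dts <- vapply(traj, function(k) k$dt, numeric(1))
  if (length(unique(dts)) != 1) {
    abort_imusac("all timesteps must share one dt", "validation")
  }
  dt <- dts[[1]]
  r_alive <- 0
  r_step <- 0
  vel_sum <- c(0, 0)
  c_eff <- 0
  for (kin in traj) {
    if (!inherits(kin, "body_kinematics")) {
      abort_imusac("trajectory elements must be body_kinematics", "input")
    }
    if (!kin$fallen) r_alive <- r_alive + 0.1
    if (kin$in_step) {
      r_step <- r_step + dt
      vel_sum <- vel_sum + (kin$v_vel - kin$v_tgt) * dt
      c_eff <- c_eff + sum(kin$activations^2) * dt
    }
  }
  c_vel <- vnorm(vel_sum)
  r_env <- r_alive + attr(weights, "w_step") * r_step -
    attr(weights, "w_vel") * c_vel - attr(weights, "w_eff") * c_eff
  list(r_alive = r_alive, r_step = r_step, c_vel = c_vel, c_eff = c_eff,
       r_env = r_env)
}

#' Crossing-legs geometry score
#'
#' Signed scalar triple product
#' \eqn{s = ((r_{left}-r_{pelvis}) \times (r_{right}-r_{pelvis}))
#'          \cdot (r_{head}-r_{pelvis})},
#' negative when the legs cross for an upright posture with the standard
#' landmark layout.  The penalty is `min(0, s)`.
#' @noRd
crossing_legs_score <- function(r_head, r_pelvis, r_left, r_right) {
  u <- r_left - r_pelvis
  v <- r_right - r_pelvis
  hvec <- r_head - r_pelvis
  if (vnorm(hvec) == 0 || vnorm(u) == 0 || vnorm(v) == 0) {
    abort_imusac("zero-length landmark vector: direction undefined",
                 "validation")
  }
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  sum(cr * hvec)
}

#' Per-timestep shaping reward terms
#'
#' Computes the five dense shaping terms:
#' * `r_clp` crossing-legs penalty, `min(0, s)` with `s` the signed triple
#'   product of the leg/head landmark geometry (always <= 0);
#' * `r_pvb` pelvis velocity bonus, `||v_body||`;
#' * `r_vdp` velocity deviation penalty, `-||v_body - v_tgt||` while in a
#'   step interval (0 otherwise);
#' * `r_dep` dense effort penalty, `-||action||`;
#' * `r_tab` target achievement bonus, piecewise in `||v_tgt||`:
#'   0 above 0.7, 0.1 on (0.5, 0.7], and `1 - 3.5 ||v_tgt||^2` at or
#'   below 0.5.
#'
#' @param kin A [body_kinematics()] object.
#' @param action Per-muscle excitation vector, each coordinate in \[0, 1\].
#' @return Named list `r_clp`, `r_pvb`, `r_vdp`, `r_dep`, `r_tab`.
#' @export
shaping_terms <- function(kin, action) {
  if (!inherits(kin, "body_kinematics")) {
    abort_imusac("kin must be a body_kinematics object", "input")
  }
  action <- as.numeric(action)
  if (length(action) && (any(!is.finite(action)) ||
                         any(action < 0) || any(action > 1))) {
    abort_imusac("action coordinates must lie in [0, 1]", "validation")
  }
  s <- crossing_legs_score(kin$r_head, kin$r_pelvis, kin$r_left, kin$r_right)
  vt <- vnorm(kin$v_tgt)
  r_tab <- if (vt > 0.7) {
    0
  } else if (vt > 0.5) {
    0.1
  } else {
    1 - 3.5 * vt^2
  }
  list(
    r_clp = min(0, s),
    r_pvb = vnorm(kin$v_body),
    r_vdp = if (kin$in_step) -vnorm(kin$v_body - kin$v_tgt) else 0,
    r_dep = -vnorm(action),
    r_tab = r_tab
  )
}

#' Orientation triplet (roll, pitch, yaw)
#'
#' Pelvis orientation Euler angles in radians (ZXY convention), wrapped to
#' (-pi, pi].  An optional timestamp supports the alignment check in
#' [imu_terms()].
#'
#' @param roll,pitch,yaw Angles in radians.
#' @param t Optional timestamp in seconds.
#' @return Object of class `imu_triplet`: named numeric length 3.
#' @export
imu_triplet <- function(roll, pitch, yaw, t = NULL) {
  x <- c(roll = roll, pitch = pitch, yaw = yaw)
  assert_finite(x, "imu_triplet angles")
  x <- wrap_angle(x)
  names(x) <- c("roll", "pitch", "yaw")
  structure(x, t = t, class = "imu_triplet")
}

#' IMU deviation reward terms
#'
#' Per-axis negative absolute deviation between the collected (reference)
#' and observed pelvis orientation at one simulation timestep:
#' \eqn{r_{IMU,axis} = -\lvert col_{axis} - obs_{axis} \rvert},
#' with the difference wrapped to (-pi, pi] before the absolute value.
#'
#' @param collected Reference orientation, an [imu_triplet()].
#' @param observed Simulated orientation, an [imu_triplet()].
#' @return Named list `r_imu_roll`, `r_imu_pitch`, `r_imu_yaw`, all <= 0.
#' @export
imu_terms <- function(collected, observed) {
  if (!inherits(collected, "imu_triplet") || !inherits(observed, "imu_triplet")) {
    abort_imusac("both arguments must be imu_triplet objects", "input")
  }
  tc <- attr(collected, "t")
  to <- attr(observed, "t")
  if (!is.null(tc) && !is.null(to) && !isTRUE(all.equal(tc, to))) {
    abort_imusac(sprintf(
      "misaligned timestamps: collected at %g s, observed at %g s", tc, to),
      "alignment")
  }
  d <- abs(wrap_angle(unclass(collected) - unclass(observed)))
  list(r_imu_roll = -d[["roll"]], r_imu_pitch = -d[["pitch"]],
       r_imu_yaw = -d[["yaw"]])
}

#' Entropy bonus term
#'
#' The policy-entropy reward component: `alpha * H`, where `H` is the
#' single-sample entropy estimate `-log pi(a|s)` at the sampled action.
#'
#' @param alpha Non-negative temperature.
#' @param log_prob Log density of the sampled action under the policy.
#' @return `alpha * (-log_prob)`.
#' @export
entropy_term <- function(alpha, log_prob) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha < 0) {
    abort_imusac("alpha must be a single non-negative number", "validation")
  }
  alpha * (-log_prob)
}

#' Assemble a reward vector
#'
#' Packs the ten components into the fixed component order and validates
#' finiteness.
#'
#' @param r_env,r_clp,r_vdp,r_pvb,r_dep,r_tab,r_entropy Task components.
#' @param r_imu_roll,r_imu_pitch,r_imu_yaw IMU deviation components.
#' @return Named numeric vector of length 10, class `reward_vector`.
#' @export
assemble_reward_vector <- function(r_env = 0, r_clp = 0, r_vdp = 0, r_pvb = 0,
                                   r_dep = 0, r_tab = 0, r_entropy = 0,
                                   r_imu_roll = 0, r_imu_pitch = 0,
                                   r_imu_yaw = 0) {
  v <- c(r_env, r_clp, r_vdp, r_pvb, r_dep, r_tab, r_entropy,
         r_imu_roll, r_imu_pitch, r_imu_yaw)
  names(v) <- reward_component_names()
  assert_finite(v, "reward vector")
  class(v) <- "reward_vector"
  v
}

#' Scalarize a reward vector
#'
#' The weighted sum \eqn{r_t = \sum_i w_i r_{i,t}} over the fixed
#' component order.
#'
#' @param rvec Numeric length-10 reward vector (named in the component
#'   order, e.g. from [assemble_reward_vector()]).
#' @param weights A [reward_weights()] object (or numeric length 10).
#' @return Scalar reward.
#' @export
assemble_and_scalarize <- function(rvec, weights = reward_weights()) {
  r <- as.numeric(rvec)
  w <- as.numeric(weights)
  if (length(r) != length(w)) {
    abort_imusac(sprintf("reward vector has %d components but %d weights",
                         length(r), length(w)), "shape")
  }
  sum(w * r)
}

#' Per-timestep reward vector for one transition
#'
#' Instantaneous decomposition used during rollout collection: the
#' composite `r_env` contribution of a single timestep
#' (`0.1 * !fallen + w_step * in_step * dt - w_vel * ||v_vel - v_tgt|| *
#' in_step * dt - w_eff * sum(A^2) * in_step * dt`), the five shaping
#' terms, the entropy bonus, and the three IMU deviations.  Note the
#' window-aggregated velocity cost of [tor_reward_terms()] takes the norm
#' of the summed deviation; the per-step decomposition necessarily uses
#' the per-step norm.
#'
#' @param kin A [body_kinematics()] object for the timestep.
#' @param action Excitation vector applied at the timestep.
#' @param weights A [reward_weights()] object.
#' @param log_prob Log density of the sampled action (for the entropy
#'   component); ignored when `alpha = 0`.
#' @param alpha Entropy temperature (0 disables the entropy component).
#' @param imu_ref,imu_obs Optional [imu_triplet()]s; when either is NULL
#'   the three IMU components are 0.
#' @return A `reward_vector`.
#' @export
step_reward_vector <- function(kin, action, weights = reward_weights(),
                               log_prob = 0, alpha = 0,
                               imu_ref = NULL, imu_obs = NULL) {
  sh <- shaping_terms(kin, action)
  alive <- if (kin$fallen) 0 else 0.1
  step_i <- as.numeric(kin$in_step)
  r_env <- alive +
    attr(weights, "w_step") * step_i * kin$dt -
    attr(weights, "w_vel") * step_i * vnorm(kin$v_vel - kin$v_tgt) * kin$dt -
    attr(weights, "w_eff") * step_i * sum(kin$activations^2) * kin$dt
  imu <- if (is.null(imu_ref) || is.null(imu_obs)) {
    list(r_imu_roll = 0, r_imu_pitch = 0, r_imu_yaw = 0)
  } else {
    imu_terms(imu_ref, imu_obs)
  }
  assemble_reward_vector(
    r_env = r_env, r_clp = sh$r_clp, r_vdp = sh$r_vdp, r_pvb = sh$r_pvb,
    r_dep = sh$r_dep, r_tab = sh$r_tab,
    r_entropy = if (alpha > 0) entropy_term(alpha, log_prob) else 0,
    r_imu_roll = imu$r_imu_roll, r_imu_pitch = imu$r_imu_pitch,
    r_imu_yaw = imu$r_imu_yaw
  )
}
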