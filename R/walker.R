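# Synthetic planar walker: a deliberately simple, fully deterministic
# stand-in environment with first-order muscle activation dynamics,
# planar pelvis dynamics, a periodic foot-contact model, and pelvis
# orientation (ZXY Euler) that oscillates with the gait cycle.

#' Fixed layout contract
#'
#' Dimensional constants of the observation/action layouts.  The
#' full-model layout is the published musculoskeletal interface: 97
#' observable state values, 22 muscle excitations, and a 2 x 11 x 11
#' local target-velocity field, giving conditioned input sizes
#' 97 + 2*11*11 = 339 (policy) and 339 + 22 = 361 (critic).  The
#' synthetic walker uses its own smaller documented layout (the state
#' composition of the full model is not published per-component; the
#' walker layout below is this package's own allocation).
#'
#' @return Nested list with `full` and `walker` layouts, each holding
#'   `obs`, `act`, `field_dim`, `policy_in`, `critic_in`.
#' @export
layout_contract <- function() {
  field_dim <- c(2, 11, 11)
  nfield <- prod(field_dim)
  full <- list(obs = 97L, act = 22L, field_dim = field_dim,
               policy_in = 97L + nfield, critic_in = 97L + nfield + 22L)
  wobs <- 20L
  wact <- 6L
  walker <- list(obs = wobs, act = wact, field_dim = field_dim,
                 policy_in = wobs + nfield, critic_in = wobs + nfield + wact)
  list(full = full, walker = walker)
}

#' Verify the layout arithmetic
#'
#' Recomputes every conditioned input size from its parts and checks the
#' published full-model constants (97-dim state, 22-dim action, 339/361
#' conditioned sizes).  Called at load-relevant entry points; returns the
#' contract invisibly or raises a contract error.
#' @return The [layout_contract()], invisibly.
#' @export
layout_selfcheck <- function() {
  lc <- layout_contract()
  for (nm in names(lc)) {
    l <- lc[[nm]]
    ok <- l$policy_in == l$obs + prod(l$field_dim) &&
      l$critic_in == l$policy_in + l$act
    if (!ok) abort_imusac(sprintf("layout '%s' fails arithmetic", nm),
                          "contract")
  }
  stopifnot(lc$full$obs == 97L, lc$full$act == 22L,
            lc$full$policy_in == 339L, lc$full$critic_in == 361L)
  invisible(lc)
}

#' Synthetic walker parameters
#'
#' Defaults are tuned once so that a hand-set open-loop excitation
#' pattern walks the 5 m course in under 10 s, the unexcited walker
#' falls after roughly 2 s, and the pelvis orientation oscillates with
#' amplitudes in the range reported for human pelvic gait kinematics.
#'
#' @param dt Simulation timestep (s).
#' @param n_muscles Muscle count (3 per leg: hip, knee, ankle groups).
#' @param tau_act First-order activation time constant (s).
#' @param gait_period Stride period at full drive (s).
#' @param v_max Pelvis speed at full drive (m/s).
#' @param tau_v Pelvis velocity time constant (s).
#' @param k_turn Heading rate per unit left/right activation imbalance
#'   (rad/s).
#' @param k_h Posture gain (1/s) for the pelvis-height proxy.
#' @param h0 Initial pelvis-height proxy (dimensionless, 1 = standing).
#' @param h_fall Fall threshold on the height proxy.
#' @param phase0 Initial gait phase in \[0, 1) (0.25 = double support).
#' @param roll_amp,pitch_amp,yaw_amp Orientation oscillation amplitudes
#'   (rad); pitch oscillates twice per stride.
#' @param k_roll_imb Roll offset per unit activation imbalance (rad).
#' @param k_lean Forward-pitch offset per unit posture deficit (rad).
#' @param k_pitch_mix Pelvis-tilt offset per unit ankle-vs-hip
#'   excitation mix (rad): a posture coordinate the locomotion reward is
#'   indifferent to, so only the orientation-reference terms anchor it.
#' @param lean_back Head landmark offset behind the pelvis (m).
#' @param foot_half_width Lateral foot offset (m).
#' @param stride_gain Fore-aft foot excursion amplitude (m).
#' @param target Global target coordinates (m).
#' @param stop_radius Target-velocity stopping radius (m).
#' @param cruise_speed Target-field cruise speed (m/s).
#' @param reach_radius Distance at which the target counts as reached (m).
#' @param max_time Episode horizon (s).
#' @return A `walker_config` list.
#' @export
walker_config <- function(dt = 0.01, n_muscles = 6, tau_act = 0.05,
                          gait_period = 1.0, v_max = 1.6, tau_v = 0.15,
                          k_turn = 2.0, k_h = 0.4, h0 = 0.9, h_fall = 0.5,
                          phase0 = 0.25, roll_amp = 0.08, pitch_amp = 0.05,
                          yaw_amp = 0.06, k_roll_imb = 0.3, k_lean = 0.4,
                          k_pitch_mix = 0.6,
                          lean_back = -0.1, foot_half_width = 0.12,
                          stride_gain = 0.3, target = c(5, 0),
                          stop_radius = 0.25, cruise_speed = 1.25,
                          reach_radius = 0.3, max_time = 10) {
  structure(as.list(environment()), class = "walker_config")
}

#' Local target velocity at a point
#'
#' Direction from `pos` toward `target`; magnitude is the cruise speed,
#' tapering linearly to zero inside one cell width (0.5 m) of the target
#' and exactly zero inside the stopping radius.
#'
#' @param pos Length-2 position (m).
#' @param target Length-2 target (m).
#' @param cruise Cruise speed (m/s).
#' @param stop_radius Stopping radius (m).
#' @return Length-2 target velocity (m/s).
#' @export
target_velocity_at <- function(pos, target = c(5, 0), cruise = 1.25,
                               stop_radius = 0.25) {
  d <- target - pos
  dist <- vnorm(d)
  if (dist < stop_radius) return(c(0, 0))
  mag <- cruise * min(1, dist / 0.5)
  d / dist * mag
}

#' Local target-velocity field on the 11 x 11 grid
#'
#' A 2 x 11 x 11 array of target velocities on a lattice of 0.5 m square
#' cells centered on the agent: each cell's vector points from the cell
#' center toward the target with the magnitude profile of
#' [target_velocity_at()].  Flattening with `as.vector()` (column-major:
#' component, then grid x, then grid y) defines the fixed 242-value
#' conditioning order.
#'
#' @param agent_pose Length-2 agent position (m); a longer pose vector
#'   may be given, only the first two coordinates are used.
#' @param target Length-2 target position (m).
#' @param cruise Cruise speed (m/s).
#' @param stop_radius Stopping radius (m).
#' @param cell Cell width (m).
#' @param n Grid side length (cells).
#' @return Numeric array with dim `c(2, n, n)`.
#' @export
make_target_field <- function(agent_pose = c(0, 0), target = c(5, 0),
                              cruise = 1.25, stop_radius = 0.25,
                              cell = 0.5, n = 11) {
  if (!all(is.finite(target))) abort_imusac("non-finite target", "validation")
  center <- agent_pose[1:2]
  half <- (n - 1) / 2
  field <- array(0, dim = c(2, n, n))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      cpos <- center + c((i - 1 - half) * cell, (j - 1 - half) * cell)
      field[, i, j] <- target_velocity_at(cpos, target, cruise, stop_radius)
    }
  }
  field
}

# Foot contact flags from the gait phase (fraction of stride).
# Double support occupies the band |cos| <= 0.25 around the crossings.
contact_flags <- function(phase) {
  cp <- cos(2 * pi * phase)
  c(left = cp >= -0.25, right = cp <= 0.25)
}

walker_orientation <- function(cfg, phase, imb, h, psi, mix = 0) {
  c(roll = cfg$roll_amp * sin(2 * pi * phase) + cfg$k_roll_imb * imb,
    pitch = cfg$pitch_amp * sin(4 * pi * phase) + cfg$k_lean * (cfg$h0 - h) +
      cfg$k_pitch_mix * mix,
    yaw = psi + cfg$yaw_amp * sin(2 * pi * phase))
}

# Ankle-vs-hip excitation mix: a posture coordinate the locomotion
# terms are indifferent to (the mean drive is unchanged), but which
# tilts the pelvis.  activations are ordered (hip, knee, ankle) per leg.
activation_mix <- function(act) {
  mean(act[c(3, 6)]) - mean(act[c(1, 4)])
}

#' Reset the synthetic walker
#'
#' Deterministic initial state at the origin facing the target, standing
#' in double support with zero activations.  The seed argument is part
#' of the environment interface contract (`reset(seed)`); the shipped
#' walker is deterministic and records it in the state for provenance.
#'
#' @param config A [walker_config()].
#' @param seed Optional integer seed (recorded, not consumed).
#' @return List `state` (a `walker_state`) and `obs` (numeric, length
#'   per the walker layout contract).
#' @export
walker_reset <- function(config = walker_config(), seed = NULL) {
  st <- structure(list(
    x = 0, y = 0, v = 0, psi = 0, h = config$h0, phase = config$phase0,
    act = rep(0, config$n_muscles), t = 0, fallen = FALSE, reached = FALSE,
    seed = seed
  ), class = "walker_state")
  list(state = st, obs = walker_observe(st, config))
}

#' Observation vector of the walker layout
#'
#' Fixed 20-value layout: speed, heading (sin, cos), height proxy, gait
#' phase (sin, cos), roll, pitch, yaw, six activations, two contact
#' flags, target bearing in the body frame (2), clamped normalized
#' distance.
#'
#' @param state A `walker_state`.
#' @param config A [walker_config()].
#' @return Numeric vector of length 20.
#' @export
walker_observe <- function(state, config) {
  imb <- mean(state$act[1:3]) - mean(state$act[4:6])
  ang <- walker_orientation(config, state$phase, imb, state$h, state$psi,
                            activation_mix(state$act))
  cf <- contact_flags(state$phase)
  d <- config$target - c(state$x, state$y)
  dist <- vnorm(d)
  bearing <- atan2(d[2], d[1]) - state$psi
  c(state$v, sin(state$psi), cos(state$psi), state$h,
    sin(2 * pi * state$phase), cos(2 * pi * state$phase),
    wrap_angle(ang[["roll"]]), wrap_angle(ang[["pitch"]]),
    wrap_angle(ang[["yaw"]]),
    state$act,
    as.numeric(cf[["left"]]), as.numeric(cf[["right"]]),
    cos(bearing), sin(bearing), min(dist, 5) / 5)
}

#' Advance the walker one timestep
#'
#' First-order activation dynamics drive the gait phase, pelvis speed,
#' heading (via left/right imbalance) and posture; orientation and foot
#' contacts follow the phase.  Fully deterministic given
#' `(state, action, seed)`.  The episode ends when the pelvis-height
#' proxy falls below the fall threshold, the target is reached, or the
#' horizon elapses.
#'
#' @param state A `walker_state`.
#' @param action Excitation vector in \[0, 1\] per muscle.
#' @param config A [walker_config()].
#' @param seed Optional seed (interface contract; unused by the
#'   deterministic dynamics).
#' @return List `state`, `obs`, `kin` (a [body_kinematics()]), `done`.
#' @export
walker_step <- function(state, action, config = walker_config(),
                        seed = NULL) {
  action <- as.numeric(action)
  if (length(action) != config$n_muscles || any(is.na(action))) {
    abort_imusac("action must be a finite excitation vector", "validation")
  }
  if (any(!is.finite(action))) {
    abort_imusac("non-finite action", "validation")
  }
  u <- pmin(pmax(action, 0), 1)
  dt <- config$dt

  act <- state$act + dt * (u - state$act) / config$tau_act
  drive <- mean(act)
  imb <- mean(act[1:3]) - mean(act[4:6])

  phase <- (state$phase + dt * drive / config$gait_period) %% 1
  support <- min(1, drive / 0.3)
  h <- min(1, max(0, state$h + dt * config$k_h * (support - 0.55)))
  v <- state$v + dt * (config$v_max * drive - state$v) / config$tau_v
  psi <- state$psi + dt * config$k_turn * imb
  x <- state$x + dt * v * cos(psi)
  y <- state$y + dt * v * sin(psi)
  t <- state$t + dt

  fallen <- h < config$h_fall
  dist <- vnorm(config$target - c(x, y))
  reached <- dist < config$reach_radius
  done <- fallen || reached || t >= config$max_time - 1e-9

  new_state <- structure(list(
    x = x, y = y, v = v, psi = psi, h = h, phase = phase, act = act,
    t = t, fallen = fallen, reached = reached, seed = state$seed
  ), class = "walker_state")

  ang <- walker_orientation(config, phase, imb, h, psi,
                            activation_mix(act))
  cf <- contact_flags(phase)
  in_step <- xor(cf[["left"]], cf[["right"]])
  v_body <- c(v * cos(psi), v * sin(psi))
  v_tgt <- target_velocity_at(c(x, y), config$target, config$cruise_speed,
                              config$stop_radius)
  hp <- 0.95 * h
  pelvis <- c(x, y, hp)
  head <- c(x + config$lean_back * cos(psi), y + config$lean_back * sin(psi),
            hp + 0.6)
  sx <- config$stride_gain * sin(2 * pi * phase)
  rot <- function(b) c(x + b[1] * cos(psi) - b[2] * sin(psi),
                       y + b[1] * sin(psi) + b[2] * cos(psi), 0)
  foot_l <- rot(c(sx, config$foot_half_width))
  foot_r <- rot(c(-sx, -config$foot_half_width))

  kin <- body_kinematics(
    v_body = v_body, v_vel = v_body, v_tgt = v_tgt,
    r_head = head, r_pelvis = pelvis, r_left = foot_l, r_right = foot_r,
    activations = act, in_step = in_step, dt = dt, fallen = fallen
  )
  list(state = new_state, obs = walker_observe(new_state, config),
       kin = kin, done = done)
}

#' Pelvis orientation as an IMU triplet
#'
#' ZXY Euler angles (roll about x, pitch about y, yaw about z) of the
#' pelvis, wrapped to (-pi, pi], timestamped with the state clock.
#'
#' @param state A `walker_state`.
#' @param config A [walker_config()].
#' @return An [imu_triplet()].
#' @export
observe_imu <- function(state, config = walker_config()) {
  imb <- mean(state$act[1:3]) - mean(state$act[4:6])
  ang <- walker_orientation(config, state$phase, imb, state$h, state$psi,
                            activation_mix(state$act))
  imu_triplet(ang[["roll"]], ang[["pitch"]], ang[["yaw"]], t = state$t)
}

#' Walker energy proxy
#'
#' `h + v^2/2 + sum(activations)`: strictly non-increasing under zero
#' excitation (all three terms decay passively).
#'
#' @param state A `walker_state`.
#' @return Scalar energy proxy.
#' @export
walker_energy <- function(state) {
  state$h + 0.5 * state$v^2 + sum(state$act)
}

#' Hand-set open-loop excitation pattern
#'
#' A fixed balanced excitation with a small stride-phase modulation that
#' walks the default course (>= 5 m) in well under 10 s.  The modulation
#' is common to both legs (left/right balanced), so the pattern holds a
#' straight heading.  Used as a fixture when exercising the environment
#' and the reward pipeline without a trained policy.
#'
#' @param t Time (s), vectorized.
#' @param n_muscles Muscle count.
#' @param level Base excitation level.
#' @param gait_period Stride period for the modulation (s).
#' @return Excitation matrix (length(t) x n_muscles) in \[0, 1\].
#' @export
walk_excitation_pattern <- function(t, n_muscles = 6, level = 0.8,
                                    gait_period = 1.0) {
  t <- as.numeric(t)
  mod <- 0.1 * sin(2 * pi * t / gait_period)
  exc <- matrix(level, length(t), n_muscles) + mod
  pmin(pmax(exc, 0), 1)
}

# ---- ZXY Euler rotation utilities -----------------------------------------

#' Rotation matrix from ZXY Euler angles
#'
#' `R = Rz(yaw) Rx(roll) Ry(pitch)` (intrinsic Z-X-Y order, the
#' torso/pelvis convention: axial rotation, then lateral bending, then
#' flexion/extension).
#'
#' @param roll,pitch,yaw Angles in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_from_euler_zxy <- function(roll, pitch, yaw) {
  ca <- cos(yaw); sa <- sin(yaw)
  cb <- cos(roll); sb <- sin(roll)
  cg <- cos(pitch); sg <- sin(pitch)
  matrix(c(
    ca * cg - sa * sb * sg, -sa * cb, ca * sg + sa * sb * cg,
    sa * cg + ca * sb * sg,  ca * cb, sa * sg - ca * sb * cg,
    -cb * sg,                sb,      cb * cg
  ), 3, 3, byrow = TRUE)
}

#' ZXY Euler angles from a rotation matrix
#'
#' Inverse of [rotation_from_euler_zxy()].  At the gimbal degeneracy
#' (|roll| = pi/2) the split between yaw and pitch is not unique; the
#' documented convention returns pitch = 0 and folds the remaining
#' rotation into yaw.
#'
#' @param R 3x3 rotation matrix.
#' @return Named vector `roll`, `pitch`, `yaw` in (-pi, pi].
#' @export
euler_zxy_from_rotation <- function(R) {
  sb <- max(-1, min(1, R[3, 2]))
  if (abs(sb) > 1 - 1e-9) {
    roll <- asin(sb)
    pitch <- 0
    yaw <- atan2(R[2, 1], R[1, 1])
  } else {
    roll <- asin(sb)
    yaw <- atan2(-R[1, 2], R[2, 2])
    pitch <- atan2(-R[3, 1], R[3, 3])
  }
  c(roll = wrap_angle(roll), pitch = wrap_angle(pitch),
    yaw = wrap_angle(yaw))
}
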