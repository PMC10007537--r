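# Reward terms: trajectory-optimization composite, shaping terms, IMU
# deviations, entropy bonus, and linear scalarization.

test_that("trajectory-optimization terms aggregate as defined", {
  # single non-fallen timestep contributes the 0.1 alive bonus
  one <- tor_reward_terms(list(kin_fixture(in_step = FALSE)))
  expect_equal(one$r_alive, 0.1)
  expect_equal(one$r_step, 0)

  # 30 consecutive in-step samples at dt = 0.01 give r_step = 0.30
  traj <- replicate(30, kin_fixture(), simplify = FALSE)
  agg <- tor_reward_terms(traj)
  expect_equal(agg$r_step, 0.30)

  # zero activations kill the effort cost; matched velocities kill the
  # velocity cost
  traj0 <- replicate(5, kin_fixture(activations = rep(0, 6),
                                    v_body = c(1.25, 0)), simplify = FALSE)
  agg0 <- tor_reward_terms(traj0)
  expect_equal(agg0$c_eff, 0)
  expect_equal(agg0$c_vel, 0)
  expect_equal(agg0$r_env, agg0$r_alive + agg0$r_step)

  # c_vel is the norm of the summed deviation: opposite deviations cancel
  traj_pm <- list(kin_fixture(v_body = c(1.45, 0), v_vel = c(1.45, 0)),
                  kin_fixture(v_body = c(1.05, 0), v_vel = c(1.05, 0)))
  expect_equal(tor_reward_terms(traj_pm)$c_vel, 0)

  expect_error(tor_reward_terms(list()), class = "imusac_input")
  expect_error(kin_fixture(v_body = c(NaN, 0)), class = "imusac_validation")
})

test_that("target achievement bonus follows its piecewise thresholds", {
  tab_at <- function(vt) {
    shaping_terms(kin_fixture(v_tgt = c(vt, 0)), rep(0, 6))$r_tab
  }
  expect_equal(tab_at(0.8), 0)
  expect_equal(tab_at(0.6), 0.1)
  expect_equal(tab_at(0), 1)
  expect_equal(tab_at(0.5), 1 - 3.5 * 0.25)
  # piecewise values stay in [0, 1] on the quadratic branch and are
  # non-increasing across branch representatives
  for (vt in seq(0, 0.5, by = 0.05)) {
    expect_gte(tab_at(vt), 0)
    expect_lte(tab_at(vt), 1)
  }
  expect_true(tab_at(0) > tab_at(0.6) && tab_at(0.6) > tab_at(0.8))
})

test_that("shaping terms have the documented signs and magnitudes", {
  sh <- shaping_terms(kin_fixture(v_body = c(0.3, 0.4)), rep(0, 6))
  expect_equal(sh$r_pvb, 0.5)     # 3-4-5 triangle
  expect_equal(sh$r_dep, 0)       # zero action

  sh2 <- shaping_terms(kin_fixture(), rep(0.5, 6))
  expect_equal(sh2$r_dep, -sqrt(6 * 0.25))
  expect_lte(sh2$r_clp, 0)
  expect_lte(sh2$r_vdp, 0)

  # crossed legs (left/right swapped) are penalised, uncrossed are not
  un <- shaping_terms(kin_fixture(r_left = c(0.1, 0.12, 0),
                                  r_right = c(-0.1, -0.12, 0),
                                  r_head = c(-0.1, 0, 1.5)), rep(0, 6))
  cr <- shaping_terms(kin_fixture(r_left = c(0.1, -0.12, 0),
                                  r_right = c(-0.1, 0.12, 0),
                                  r_head = c(-0.1, 0, 1.5)), rep(0, 6))
  expect_equal(un$r_clp, 0)
  expect_lt(cr$r_clp, 0)

  expect_error(
    shaping_terms(kin_fixture(r_head = c(0, 0, 0.9),
                              r_pelvis = c(0, 0, 0.9)), rep(0, 6)),
    class = "imusac_validation"
  )
  expect_error(shaping_terms(kin_fixture(), rep(1.5, 6)),
               class = "imusac_validation")
})

test_that("IMU deviation terms are wrapped negative absolute differences", {
  a <- imu_triplet(0.2, 0.1, -0.3)
  b <- imu_triplet(0.5, 0.1, -0.3)
  r <- imu_terms(a, b)
  expect_equal(r$r_imu_roll, -0.3)
  expect_equal(r$r_imu_pitch, 0)
  expect_equal(r$r_imu_yaw, 0)
  # symmetry: swapping collected and observed changes nothing
  expect_equal(imu_terms(b, a), r)
  # identical triplets give exact zeros
  expect_equal(unlist(imu_terms(a, a)), c(r_imu_roll = 0, r_imu_pitch = 0,
                                          r_imu_yaw = 0))
  # differences wrap across the +/-pi seam instead of jumping by 2*pi
  near_pi <- imu_terms(imu_triplet(3.1, 0, 0), imu_triplet(-3.1, 0, 0))
  expect_equal(near_pi$r_imu_roll, -(2 * pi - 6.2), tolerance = 1e-12)
  # all terms are <= 0 on random pairs
  for (i in 1:25) {
    set.seed(i)
    r <- imu_terms(imu_triplet(runif(1, -4, 4), runif(1, -4, 4),
                               runif(1, -4, 4)),
                   imu_triplet(runif(1, -4, 4), runif(1, -4, 4),
                               runif(1, -4, 4)))
    expect_true(all(unlist(r) <= 0))
  }
  # timestamp misalignment is an error
  expect_error(imu_terms(imu_triplet(0, 0, 0, t = 0.1),
                         imu_triplet(0, 0, 0, t = 0.2)),
               class = "imusac_alignment")
})

test_that("entropy bonus is alpha times the sampled-entropy estimate", {
  expect_equal(entropy_term(0, -123), 0)
  expect_equal(entropy_term(1, -2), 2)
  expect_equal(entropy_term(0.5, -3), 1.5)
  expect_error(entropy_term(-0.1, 0), class = "imusac_validation")
})

test_that("sampled entropy of a unit Gaussian matches the closed form", {
  # for a d-dimensional unit-variance Gaussian, H = (d/2) log(2*pi*e);
  # the Monte-Carlo mean of -log density must agree within MC error
  d <- 4
  set.seed(11)
  z <- matrix(rnorm(20000 * d), ncol = d)
  neg_logp <- 0.5 * rowSums(z^2) + 0.5 * d * log(2 * pi)
  expect_equal(mean(neg_logp), d / 2 * log(2 * pi * exp(1)),
               tolerance = 0.02)
})

test_that("scalarization is the weighted component sum, in fixed order", {
  expect_equal(reward_component_names()[c(1, 7, 10)],
               c("r_env", "r_entropy", "r_imu_yaw"))
  rv <- assemble_reward_vector(r_env = 1, r_clp = 0.5, r_vdp = 0.7,
                               r_pvb = 0.8, r_dep = 0.7)
  expect_equal(assemble_and_scalarize(rv, reward_weights()), 3.7)

  # zero-weight components cannot affect the output
  w0 <- reward_weights(r_clp = 0)
  rv2 <- rv
  rv2["r_clp"] <- 99
  expect_equal(assemble_and_scalarize(rv, w0),
               assemble_and_scalarize(rv2, w0))

  # dot-product oracle on 1,000 random vectors
  set.seed(5)
  for (i in 1:1000) {
    r <- rnorm(10)
    w <- runif(10)
    oracle <- 0
    for (k in 1:10) oracle <- oracle + w[k] * r[k]
    expect_equal(assemble_and_scalarize(r, w), oracle)
  }
  expect_error(assemble_and_scalarize(rnorm(9), reward_weights()),
               class = "imusac_shape")
})

test_that("scalarization is linear in the reward vector", {
  set.seed(9)
  w <- reward_weights()
  for (i in 1:50) {
    r1 <- rnorm(10); r2 <- rnorm(10)
    a <- rnorm(1); b <- rnorm(1)
    expect_equal(assemble_and_scalarize(a * r1 + b * r2, w),
                 a * assemble_and_scalarize(r1, w) +
                   b * assemble_and_scalarize(r2, w),
                 tolerance = 1e-12)
  }
})

test_that("zero IMU weights reproduce the no-IMU scalar reward bitwise", {
  set.seed(21)
  w_full <- baseline_weights()      # IMU weights zero
  for (i in 1:20) {
    kin <- kin_fixture(v_body = runif(2), activations = runif(6))
    act <- runif(6)
    ref <- imu_triplet(runif(1), runif(1), runif(1))
    obs <- imu_triplet(runif(1), runif(1), runif(1))
    with_imu <- step_reward_vector(kin, act, w_full, imu_ref = ref,
                                   imu_obs = obs)
    without <- step_reward_vector(kin, act, w_full)
    expect_identical(assemble_and_scalarize(with_imu, w_full),
                     assemble_and_scalarize(without, w_full))
  }
})

test_that("per-step reward vector decomposes the composite consistently", {
  kin <- kin_fixture(fallen = FALSE)
  rv <- step_reward_vector(kin, rep(0.5, 6))
  expect_length(rv, 10)
  expect_named(unclass(rv), reward_component_names())
  # alive part present, in-step stepping bonus present
  expect_equal(unname(rv["r_env"]),
               0.1 + 0.01 - vnorm_test(c(1, 0) - c(1.25, 0)) * 0.01 -
                 sum(rep(0.25, 6)) * 0.01,
               tolerance = 1e-12)
  rv_fallen <- step_reward_vector(kin_fixture(fallen = TRUE, in_step = FALSE),
                                  rep(0.5, 6))
  expect_equal(unname(rv_fallen["r_env"]), 0)
})

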