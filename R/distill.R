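# Stage-two policy distillation: transfer the stage-one policy/critic
# into target-velocity-conditioned networks by minimizing KL (policy)
# and squared error (critic) on replayed data.

#' Concatenate a state with a flattened target-velocity field
#'
#' Fixed conditioning order: `[state || as.vector(field)]`, where the
#' field flattens column-major over (component, grid x, grid y); a
#' 2 x 11 x 11 field contributes 242 values.
#'
#' @param state Observation vector.
#' @param field Target-velocity array with dim `c(2, n, n)` (or an
#'   already-flattened numeric vector of matching length).
#' @param field_dim Expected field dimensions.
#' @return Numeric vector `length(state) + prod(field_dim)`.
#' @export
condition_inputs <- function(state, field, field_dim = c(2, 11, 11)) {
  if (is.array(field)) {
    if (!identical(dim(field), as.integer(field_dim))) {
      abort_imusac(sprintf("field has dim [%s], expected [%s]",
                           paste(dim(field), collapse = ","),
                           paste(field_dim, collapse = ",")), "shape")
    }
    field <- as.vector(field)
  } else if (length(field) != prod(field_dim)) {
    abort_imusac(sprintf("flattened field has length %d, expected %d",
                         length(field), prod(field_dim)), "shape")
  }
  c(as.numeric(state), as.numeric(field))
}

#' Construct target-velocity-conditioned student networks
#'
#' Student policy `pi_s(a | s, v)` and critic `Q_s(s, v, a)` with the
#' conditioning field appended to the state input.  With
#' `from_teacher = TRUE` the student copies the teacher's parameters and
#' zeroes the first-layer rows of the `v` inputs, so it initially
#' ignores the field and reproduces the teacher exactly (requires
#' matching hidden sizes).
#'
#' @param teacher_policy A [gaussian_policy()] (stage one).
#' @param teacher_critic A [multihead_critic()] (stage one).
#' @param field_dim Conditioning field dimensions.
#' @param hidden Hidden widths of the student networks (1024-wide by
#'   default in the full configuration).
#' @param from_teacher Initialize as an exact teacher copy (see above)?
#' @param seed Init seed for fresh students.
#' @return List of class `conditioned_networks` with `policy`, `critic`,
#'   `field_dim`, `v_dim`.
#' @export
conditioned_networks <- function(teacher_policy, teacher_critic,
                                 field_dim = c(2, 11, 11),
                                 hidden = c(1024, 1024, 1024, 1024),
                                 from_teacher = FALSE, seed = NULL) {
  v_dim <- prod(field_dim)
  s_dim <- teacher_policy$obs_dim
  a_dim <- teacher_policy$act_dim
  if (from_teacher) hidden <- teacher_policy$hidden
  seeds <- if (is.null(seed)) c(NA, NA) else fanout_seeds(seed, 2)
  policy <- gaussian_policy(s_dim + v_dim, a_dim, hidden = hidden,
                            seed = if (is.na(seeds[1])) NULL else seeds[1])
  critic <- multihead_critic(s_dim + v_dim, a_dim,
                             head_names = teacher_critic$head_names,
                             hidden = if (from_teacher) teacher_critic$hidden
                                      else hidden,
                             twin = teacher_critic$twin,
                             seed = if (is.na(seeds[2])) NULL else seeds[2])
  if (from_teacher) {
    graft <- function(student_net, teacher_net, n_state, n_extra,
                      n_after = 0) {
      # Input layout: [state (n_state), v (n_extra), after (n_after)].
      W1 <- student_net$W[[1]] * 0
      W1[seq_len(n_state), ] <- teacher_net$W[[1]][seq_len(n_state), ]
      if (n_after > 0) {
        W1[n_state + n_extra + seq_len(n_after), ] <-
          teacher_net$W[[1]][n_state + seq_len(n_after), ]
      }
      student_net$W[[1]] <- W1
      student_net$b[[1]] <- teacher_net$b[[1]]
      for (l in seq_along(teacher_net$W)[-1]) {
        student_net$W[[l]] <- teacher_net$W[[l]]
        student_net$b[[l]] <- teacher_net$b[[l]]
      }
      student_net
    }
    policy$net <- graft(policy$net, teacher_policy$net, s_dim, v_dim)
    for (f in c("q1", "q2", "target1", "target2")) {
      if (!is.null(critic[[f]])) {
        critic[[f]] <- graft(critic[[f]], teacher_critic[[f]], s_dim, v_dim,
                             n_after = a_dim)
      }
    }
    critic$weights <- teacher_critic$weights
  }
  structure(list(policy = policy, critic = critic, field_dim = field_dim,
                 v_dim = v_dim, s_dim = s_dim, a_dim = a_dim),
            class = "conditioned_networks")
}

#' @export
print.conditioned_networks <- function(x, ...) {
  cat(sprintf("<conditioned_networks> state %d + field %d -> policy in %d, critic in %d\n",
              x$s_dim, x$v_dim, x$s_dim + x$v_dim,
              x$s_dim + x$v_dim + x$a_dim))
  invisible(x)
}

# KL divergence between factorized Gaussians KL(N_s || N_t), summed over
# dimensions, one value per batch row.
gaussian_kl <- function(mu_s, log_sig_s, mu_t, log_sig_t) {
  v_s <- exp(2 * log_sig_s)
  v_t <- exp(2 * log_sig_t)
  rowSums(log_sig_t - log_sig_s + (v_s + (mu_s - mu_t)^2) / (2 * v_t) - 0.5)
}

# Build the conditioned input batch: per-element field + Gaussian
# perturbation with per-entry variance v_noise_var.
condition_batch <- function(obs, field, v_dim, v_noise_var, seed) {
  n <- nrow(obs)
  base <- matrix(as.vector(field), n, v_dim, byrow = TRUE)
  noise <- with_local_seed(seed, matrix(
    stats::rnorm(n * v_dim, 0, sqrt(v_noise_var)), n, v_dim))
  cbind(obs, base + noise)
}

#' Distillation losses on a replayed batch
#'
#' Policy loss: `E[KL(pi_s(.|s,v) || pi_t(.|s))]` over the batch states,
#' with the conditioning input `v` perturbed per element by zero-mean
#' Gaussian noise of per-entry variance `v_noise_var`.  Critic loss:
#' `E[sum_i (Q_s,i(s,v,a_s) - Q_t,i(s,a_t))^2]` with actions drawn from
#' student and teacher under a shared reparametrization draw (so an
#' exact-copy student incurs zero loss).  Teacher parameters are never
#' modified.
#'
#' @param teacher_policy,teacher_critic Stage-one networks.
#' @param student A [conditioned_networks()].
#' @param batch Train batch (only `obs` is used) from the saved
#'   stage-one replay.
#' @param field The target-velocity field being conditioned on.
#' @param v_noise_var Variance of the conditioning perturbation.
#' @param v_noise_seed Seed for the perturbation and action draws.
#' @return List `J_pi_s`, `J_Q_s` (both >= 0), plus internals for the
#'   update step.
#' @export
distill_losses <- function(teacher_policy, teacher_critic, student, batch,
                           field = make_target_field(),
                           v_noise_var = 0.1, v_noise_seed = NULL) {
  if (student$a_dim != teacher_policy$act_dim) {
    abort_imusac("teacher/student action dimensions differ", "shape")
  }
  seeds <- if (is.null(v_noise_seed)) list(NULL, NULL) else
    as.list(fanout_seeds(v_noise_seed, 2))
  obs <- batch$obs
  n <- nrow(obs)
  sv <- condition_batch(obs, field, student$v_dim, v_noise_var, seeds[[1]])

  dt_t <- policy_dist(teacher_policy, obs)
  dt_s <- policy_dist(student$policy, sv)
  kl <- gaussian_kl(dt_s$mu, dt_s$log_sigma, dt_t$mu, dt_t$log_sigma)
  J_pi_s <- mean(kl)

  eps <- with_local_seed(seeds[[2]],
                         matrix(stats::rnorm(n * student$a_dim), n,
                                student$a_dim))
  a_t <- squash(dt_t$mu + exp(dt_t$log_sigma) * eps)
  a_s <- squash(dt_s$mu + exp(dt_s$log_sigma) * eps)
  q_t <- critic_q(teacher_critic, obs, a_t)$q1
  q_s <- critic_q(student$critic, sv, a_s)$q1
  J_Q_s <- mean(rowSums((q_s - q_t)^2))
  if (!is.finite(J_pi_s) || !is.finite(J_Q_s)) {
    abort_imusac("non-finite distillation loss", "numerical")
  }
  list(J_pi_s = J_pi_s, J_Q_s = J_Q_s,
       internals = list(sv = sv, dt_t = dt_t, dt_s = dt_s, q_t = q_t,
                        a_s = a_s, eps = eps))
}

#' One distillation gradient step
#'
#' Adam steps on the student policy (KL) and student critic (squared
#' error); the teacher is read-only.  Student actions are treated as
#' given when differentiating the critic loss (supervised regression
#' onto the teacher's values).
#'
#' @param teacher_policy,teacher_critic Stage-one networks (frozen).
#' @param student A [conditioned_networks()].
#' @param opt Optimizer state list (`pi`, `q1`) from [distill_optimizer()].
#' @param batch Replayed batch.
#' @param field Conditioning field.
#' @param lr Learning rate.
#' @param v_noise_var Conditioning-noise variance.
#' @param seed Seed for this step's draws.
#' @return List `student`, `opt`, `losses`.
#' @export
distill_update <- function(teacher_policy, teacher_critic, student, opt,
                           batch, field = make_target_field(), lr = 1e-4,
                           v_noise_var = 0.1, seed = NULL) {
  dl <- distill_losses(teacher_policy, teacher_critic, student, batch,
                       field, v_noise_var, seed)
  it <- dl$internals
  n <- nrow(it$sv)

  # Policy step: dKL/dmu_s = (mu_s - mu_t)/var_t;
  # dKL/dlog_sigma_s = -1 + var_s/var_t.
  v_t <- exp(2 * it$dt_t$log_sigma)
  g_mu <- (it$dt_s$mu - it$dt_t$mu) / v_t / n
  g_ls <- (-1 + exp(2 * it$dt_s$log_sigma) / v_t) / n
  g_raw <- g_ls * soft_clamp_grad(it$dt_s$raw_log_sigma)
  gp <- nn_backward(student$policy$net, it$dt_s$cache, cbind(g_mu, g_raw))
  stp <- adam_step(student$policy$net, gp, opt$pi, lr)
  student$policy$net <- stp$net
  opt$pi <- stp$state

  # Critic step (q1 head matrix regression onto the teacher's).
  X <- critic_input(student$critic, it$sv, it$a_s)
  fw <- nn_forward(student$critic$q1, X)
  dout <- 2 * (fw$out - it$q_t) / n
  gq <- nn_backward(student$critic$q1, fw$cache, dout)
  stq <- adam_step(student$critic$q1, gq, opt$q1, lr)
  student$critic$q1 <- stq$net
  opt$q1 <- stq$state

  list(student = student, opt = opt,
       losses = list(J_pi_s = dl$J_pi_s, J_Q_s = dl$J_Q_s))
}

#' Optimizer state for distillation
#'
#' @param student A [conditioned_networks()].
#' @return List with Adam states `pi` and `q1`.
#' @export
distill_optimizer <- function(student) {
  list(pi = adam_init(student$policy$net),
       q1 = adam_init(student$critic$q1))
}

#' Run stage-two distillation on a saved replay store
#'
#' Draws uniform batches from the stage-one replay and applies
#' [distill_update()] for a fixed number of steps.
#'
#' @param teacher_policy,teacher_critic Stage-one networks (frozen).
#' @param store The saved stage-one [segment_store()].
#' @param field Conditioning target-velocity field.
#' @param cfg Distillation configuration (see [default_config()]'s
#'   `distill` block).
#' @param seed Master seed.
#' @return List `student`, `loss_log` (data frame per step).
#' @export
distill_stage <- function(teacher_policy, teacher_critic, store,
                          field = make_target_field(),
                          cfg = default_config("reduced")$distill,
                          seed = 1) {
  seeds <- fanout_seeds(seed, cfg$steps + 1)
  student <- conditioned_networks(teacher_policy, teacher_critic,
                                  hidden = cfg$hidden,
                                  from_teacher = TRUE, seed = seeds[1])
  opt <- distill_optimizer(student)
  sched <- priority_schedule(0, 0, 1)   # uniform draws for distillation
  log <- data.frame(step = integer(0), J_pi_s = numeric(0),
                    J_Q_s = numeric(0))
  seg_per_batch <- max(1, ceiling(cfg$batch_size / store$L))
  for (s in seq_len(cfg$steps)) {
    smp <- store_sample(store, seg_per_batch, sched, step = 0,
                        seed = seeds[s + 1])
    batch <- make_train_batch(smp$segments, smp$w_is, n = 1, gamma = 1)
    up <- distill_update(teacher_policy, teacher_critic, student, opt,
                         batch, field, lr = cfg$lr,
                         v_noise_var = cfg$v_noise_var,
                         seed = seeds[s + 1])
    student <- up$student
    opt <- up$opt
    log <- rbind(log, data.frame(step = s, J_pi_s = up$losses$J_pi_s,
                                 J_Q_s = up$losses$J_Q_s))
  }
  list(student = student, loss_log = log)
}
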