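# Multi-head critic: one Q head per reward component, twin copies for
# clipped double-Q bootstrapping, plus a Polyak-averaged target copy.

#' Construct a multi-head critic
#'
#' A dense ReLU network maps `(observation, action)` to one Q value per
#' reward component (the heads are the columns of the output layer).
#' With `twin = TRUE` (the default) two independently initialized critics
#' are kept and bootstrap values take the element-wise minimum across the
#' pair; `twin = FALSE` reproduces the single-critic notation literally.
#' A target copy of each critic is stored for bootstrapping and updated
#' by [polyak_update()].
#'
#' The critic carries its own per-head scalarization weights (default 1),
#' used by [q_scalar()] when no explicit weights are given and updated by
#' [head_surgery()].
#'
#' @param obs_dim,act_dim Observation / action dimensionality.
#' @param head_names Character vector naming the heads (one per reward
#'   component); its length fixes the head count.
#' @param hidden Hidden layer widths (ReLU).
#' @param twin Keep a twin critic pair (clipped double-Q)?
#' @param seed Optional init seed.
#' @return Object of class `multihead_critic`.
#' @export
multihead_critic <- function(obs_dim, act_dim,
                             head_names = reward_component_names(),
                             hidden = c(256, 256, 256, 256),
                             twin = TRUE, seed = NULL) {
  n_heads <- length(head_names)
  seeds <- if (is.null(seed)) c(NA, NA) else fanout_seeds(seed, 2)
  mk <- function(s) nn_init(c(obs_dim + act_dim, hidden, n_heads), "relu",
                            if (is.na(s)) NULL else s)
  q1 <- mk(seeds[1])
  q2 <- if (twin) mk(seeds[2]) else NULL
  structure(
    list(q1 = q1, q2 = q2, target1 = q1, target2 = q2,
         obs_dim = obs_dim, act_dim = act_dim, hidden = hidden,
         head_names = head_names, n_heads = n_heads, twin = twin,
         weights = stats::setNames(rep(1, n_heads), head_names)),
    class = "multihead_critic"
  )
}

#' @export
print.multihead_critic <- function(x, ...) {
  cat(sprintf("<multihead_critic> (%d + %d) -> hidden [%s] -> %d heads%s\n",
              x$obs_dim, x$act_dim, paste(x$hidden, collapse = ", "),
              x$n_heads, if (x$twin) " (twin)" else ""))
  cat(" heads:", paste(x$head_names, collapse = ", "), "\n")
  invisible(x)
}

critic_input <- function(critic, obs, act) {
  if (is.null(dim(obs))) obs <- matrix(obs, nrow = 1)
  if (is.null(dim(act))) act <- matrix(act, nrow = 1)
  if (ncol(obs) != critic$obs_dim || ncol(act) != critic$act_dim) {
    abort_imusac(sprintf(
      "critic expects obs %d / act %d, got %d / %d",
      critic$obs_dim, critic$act_dim, ncol(obs), ncol(act)), "shape")
  }
  cbind(obs, act)
}

#' Per-head Q values
#'
#' @param critic A [multihead_critic()].
#' @param obs,act Batch matrices (or vectors for a single element).
#' @param which "online" or "target" copies.
#' @return List `q1`, `q2` (batch x heads matrices; `q2` NULL when not
#'   twin) and `qmin` (element-wise min across the pair, or `q1`).
#' @export
critic_q <- function(critic, obs, act, which = c("online", "target")) {
  which <- match.arg(which)
  X <- critic_input(critic, obs, act)
  n1 <- if (which == "online") critic$q1 else critic$target1
  q1 <- nn_forward(n1, X)$out
  q2 <- NULL
  if (critic$twin) {
    n2 <- if (which == "online") critic$q2 else critic$target2
    q2 <- nn_forward(n2, X)$out
  }
  qmin <- if (is.null(q2)) q1 else pmin(q1, q2)
  list(q1 = q1, q2 = q2, qmin = qmin)
}

#' Scalarized Q value
#'
#' \eqn{Q(s, a) = \sum_i w_i Q_i(s, a)} over the per-component heads.
#'
#' @param critic A [multihead_critic()].
#' @param obs,act Observation(s) and action(s).
#' @param weights Per-head weights; defaults to the critic's own
#'   scalarization weights.
#' @param which Which copy to evaluate: "q1" (default), "min" (twin
#'   minimum), or "target" (target-copy minimum).
#' @return Numeric vector, one scalar Q per batch row.
#' @export
q_scalar <- function(critic, obs, act, weights = NULL,
                     which = c("q1", "min", "target")) {
  which <- match.arg(which)
  w <- as.numeric(weights %||% critic$weights)
  if (length(w) != critic$n_heads) {
    abort_imusac(sprintf("%d heads but %d weights", critic$n_heads,
                         length(w)), "shape")
  }
  qq <- critic_q(critic, obs, act,
                 which = if (which == "target") "target" else "online")
  Q <- switch(which, q1 = qq$q1, min = qq$qmin, target = qq$qmin)
  as.numeric(Q %*% w)
}

#' Polyak (soft) update of the target critic
#'
#' `target <- tau * online + (1 - tau) * target`, element-wise; `tau = 1`
#' copies the online critic exactly.
#'
#' @param critic A [multihead_critic()].
#' @param tau Mixing coefficient in \[0, 1\].
#' @return The updated critic.
#' @export
polyak_update <- function(critic, tau) {
  mix <- function(tgt, online) {
    for (l in seq_along(online$W)) {
      tgt$W[[l]] <- tau * online$W[[l]] + (1 - tau) * tgt$W[[l]]
      tgt$b[[l]] <- tau * online$b[[l]] + (1 - tau) * tgt$b[[l]]
    }
    tgt
  }
  critic$target1 <- mix(critic$target1, critic$q1)
  if (critic$twin) critic$target2 <- mix(critic$target2, critic$q2)
  critic
}

#' Add or remove a critic head
#'
#' Critic-head surgery for the multivariate reward representation:
#' removing a reward component zeroes that head's output-layer parameters
#' and its scalarization weight; adding one appends a freshly initialized
#' output column with weight 1.  Untouched heads produce bit-identical
#' outputs before and after.
#'
#' @param critic A [multihead_critic()].
#' @param mode "add" or "remove".
#' @param index Head index (required for "remove"; ignored for "add").
#' @param name Name for an added head.
#' @param seed Init seed for the added column.
#' @return The modified critic.
#' @export
head_surgery <- function(critic, mode = c("add", "remove"), index = NULL,
                         name = NULL, seed = NULL) {
  mode <- match.arg(mode)
  L <- length(critic$q1$W)
  if (mode == "remove") {
    if (is.null(index) || index < 1 || index > critic$n_heads) {
      abort_imusac("head index out of range", "contract")
    }
    zero_col <- function(net) {
      net$W[[L]][, index] <- 0
      net$b[[L]][index] <- 0
      net$sizes <- net$sizes  # unchanged; head kept in place, silenced
      net
    }
    for (f in c("q1", "q2", "target1", "target2")) {
      if (!is.null(critic[[f]])) critic[[f]] <- zero_col(critic[[f]])
    }
    critic$weights[index] <- 0
  } else {
    fan_in <- utils::tail(critic$q1$sizes, 2)[1]
    seeds <- if (is.null(seed)) rep(NA, 4) else fanout_seeds(seed, 4)
    new_col <- function(s) {
      with_local_seed(if (is.na(s)) NULL else s,
                      stats::runif(fan_in, -3e-3, 3e-3))
    }
    add_col <- function(net, col) {
      net$W[[L]] <- unname(cbind(net$W[[L]], col))
      net$b[[L]] <- c(net$b[[L]], 0)
      net$sizes[length(net$sizes)] <- net$sizes[length(net$sizes)] + 1L
      net
    }
    cols <- lapply(seeds, new_col)
    i <- 1
    for (f in c("q1", "q2", "target1", "target2")) {
      if (!is.null(critic[[f]])) {
        critic[[f]] <- add_col(critic[[f]], cols[[i]])
        i <- i + 1
      }
    }
    nm <- name %||% sprintf("head_%d", critic$n_heads + 1L)
    critic$head_names <- c(critic$head_names, nm)
    critic$n_heads <- critic$n_heads + 1L
    critic$weights <- c(critic$weights, stats::setNames(1, nm))
  }
  critic
}
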