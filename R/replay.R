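# Overlapping-segment experience replay with n-step TD-error
# prioritization and annealed importance sampling.

#' Construct a transition
#'
#' One environment interaction: `(s, a, r-vector, s', done)` plus the
#' episode id and timestep index that the segmentation invariants rely on.
#'
#' @param obs,action,reward,next_obs Numeric vectors (reward is the
#'   length-10 component vector).
#' @param done Logical: episode ends after this transition?
#' @param episode_id Integer id of the owning episode.
#' @param t Timestep index within the episode (1-based).
#' @return A `transition` list.
#' @export
transition <- function(obs, action, reward, next_obs, done, episode_id, t) {
  structure(list(obs = as.numeric(obs), action = as.numeric(action),
                 reward = as.numeric(reward),
                 next_obs = as.numeric(next_obs),
                 done = isTRUE(done), episode_id = episode_id, t = t),
            class = "transition")
}

#' Cut one episode into half-overlapping fixed-length segments
#'
#' Segments start at offsets `0, L/2, L, ...` within a single episode and
#' never cross episode boundaries.  Full segments are emitted while they
#' fit; if transitions remain uncovered, one final segment is emitted at
#' the next offset, right-padded by repeating the final transition, with
#' a padding mask (1 = real, 0 = pad) excluded from loss computation.
#'
#' @param episode List of [transition()]s from one episode.
#' @param L Segment length: even integer >= 2.
#' @return List of segments; each has `transitions` (length `L`), `mask`,
#'   `episode_id`, `offset`.
#' @export
segmentize <- function(episode, L) {
  if (length(episode) == 0) abort_imusac("empty episode", "input")
  if (L < 2 || L %% 2 != 0) {
    abort_imusac("segment length L must be an even integer >= 2", "config")
  }
  ids <- unique(vapply(episode, function(tr) tr$episode_id, numeric(1)))
  if (length(ids) != 1) {
    abort_imusac("episode contains more than one episode id", "input")
  }
  n <- length(episode)
  half <- L / 2
  offsets <- integer(0)
  o <- 0
  while (o + L <= n) {
    offsets <- c(offsets, o)
    o <- o + half
  }
  covered <- if (length(offsets)) offsets[length(offsets)] + L else 0
  if (covered < n) offsets <- c(offsets, o)
  lapply(offsets, function(off) {
    idx <- off + seq_len(L)
    mask <- as.numeric(idx <= n)
    idx[idx > n] <- n
    list(transitions = episode[idx], mask = mask,
         episode_id = ids, offset = off)
  })
}

#' Segment priority from n-step TD-error magnitudes
#'
#' \eqn{p = \eta \max_i \delta_i + (1 - \eta) \bar\delta} with
#' `eta = 0.9` by default.
#'
#' @param deltas Non-empty vector of non-negative TD-error magnitudes.
#' @param eta Mixing coefficient in \[0, 1\].
#' @return Scalar priority >= 0.
#' @export
priority <- function(deltas, eta = 0.9) {
  if (length(deltas) == 0) abort_imusac("empty delta sequence", "contract")
  if (any(deltas < 0) || any(!is.finite(deltas))) {
    abort_imusac("deltas must be finite and non-negative", "validation")
  }
  if (eta < 0 || eta > 1) abort_imusac("eta must lie in [0, 1]", "validation")
  eta * max(deltas) + (1 - eta) * mean(deltas)
}

#' Linear ramp schedule for the priority exponents
#'
#' Both the prioritization exponent (alpha) and the importance-sampling
#' exponent (beta) start at 0.1 and increase linearly to 0.9 over 3000
#' training steps, then stay clamped.
#'
#' @param start,end Schedule endpoints.
#' @param ramp_steps Number of steps of the linear ramp.
#' @return A `priority_schedule` object.
#' @export
priority_schedule <- function(start = 0.1, end = 0.9, ramp_steps = 3000) {
  structure(list(start = start, end = end, ramp_steps = ramp_steps),
            class = "priority_schedule")
}

#' @rdname priority_schedule
#' @param schedule A `priority_schedule`.
#' @param step Training step (0-based).
#' @return The exponent value at `step`.
#' @export
schedule_value <- function(schedule, step) {
  frac <- min(1, max(0, step / schedule$ramp_steps))
  schedule$start + (schedule$end - schedule$start) * frac
}

#' Create an empty segment replay store
#'
#' A mutable store (an environment) of fixed-length, half-overlapping
#' segments with per-segment priorities.  Eviction is FIFO by insertion
#' order once the stored (unpadded) transition count exceeds `capacity`.
#' Newly inserted segments receive the maximum current priority so each
#' is sampled at least once before its first learner update.
#'
#' @param capacity Transition capacity (250,000 in the full
#'   configuration).
#' @param L Segment length (10 in the full configuration).
#' @param eta Priority mixing coefficient.
#' @return An environment of class `segment_store`.
#' @export
segment_store <- function(capacity = 250000, L = 10, eta = 0.9) {
  st <- new.env(parent = emptyenv())
  st$capacity <- capacity
  st$L <- L
  st$eta <- eta
  st$segments <- list()
  st$priorities <- numeric(0)
  st$inserted <- numeric(0)     # insertion counters, FIFO order
  st$n_transitions <- 0
  st$counter <- 0
  class(st) <- c("segment_store", "environment")
  st
}

#' @export
print.segment_store <- function(x, ...) {
  cat(sprintf("<segment_store> %d segments, %d/%s transitions, L = %d, eta = %.2f\n",
              length(x$segments), x$n_transitions,
              format(x$capacity, big.mark = ","), x$L, x$eta))
  invisible(x)
}

#' Number of stored segments
#' @param store A [segment_store()].
#' @return Integer count.
#' @export
store_size <- function(store) length(store$segments)

#' Insert one episode into the store
#'
#' The episode is segmentized with the store's `L`; segments enter with
#' the maximum current priority (or 1 for an empty store) and the oldest
#' segments are evicted FIFO once the transition capacity is exceeded.
#'
#' @param store A [segment_store()].
#' @param episode List of [transition()]s.
#' @return The segment ids (insertion counters) assigned, invisibly.
#' @export
store_insert_episode <- function(store, episode) {
  segs <- segmentize(episode, store$L)
  p0 <- if (length(store$priorities)) max(store$priorities) else 1
  ids <- numeric(length(segs))
  for (i in seq_along(segs)) {
    store$counter <- store$counter + 1
    ids[i] <- store$counter
    store$segments[[length(store$segments) + 1]] <- segs[[i]]
    store$priorities <- c(store$priorities, p0)
    store$inserted <- c(store$inserted, store$counter)
    store$n_transitions <- store$n_transitions + sum(segs[[i]]$mask)
  }
  while (store$n_transitions > store$capacity && length(store$segments) > 1) {
    store$n_transitions <- store$n_transitions - sum(store$segments[[1]]$mask)
    store$segments <- store$segments[-1]
    store$priorities <- store$priorities[-1]
    store$inserted <- store$inserted[-1]
  }
  invisible(ids)
}

#' Sampling probabilities over stored segments
#'
#' `P(seg) = p^alpha / sum(p^alpha)` with the exponent taken from the
#' schedule at `step`.
#'
#' @param store A [segment_store()].
#' @param schedule A [priority_schedule()].
#' @param step Training step.
#' @return Probability vector over stored segments (sums to 1).
#' @export
sampling_probs <- function(store, schedule = priority_schedule(), step = 0) {
  if (store_size(store) == 0) abort_imusac("empty replay store", "contract")
  a <- schedule_value(schedule, step)
  pa <- pmax(store$priorities, 1e-12)^a
  pa / sum(pa)
}

#' Sample a prioritized batch of segments
#'
#' Segments are drawn with probability proportional to `priority^alpha`;
#' importance weights `(N * P(seg))^(-beta)` are normalized by the
#' maximum over the sampled batch so all are <= 1.
#'
#' @param store A [segment_store()].
#' @param batch_size Number of segments to draw.
#' @param schedule A [priority_schedule()] (applies to both exponents).
#' @param step Training step (for the exponent ramp).
#' @param seed Optional seed for the draw.
#' @param replace Sample with replacement (default TRUE; without
#'   replacement a batch larger than the store is a contract error).
#' @return List `segments`, `ids` (segment ids for
#'   [store_update_priorities()]), `w_is` (importance weights), `probs`.
#' @export
store_sample <- function(store, batch_size, schedule = priority_schedule(),
                         step = 0, seed = NULL, replace = TRUE) {
  N <- store_size(store)
  if (N == 0) abort_imusac("empty replay store", "contract")
  if (!replace && batch_size > N) {
    abort_imusac(sprintf("batch_size %d exceeds %d stored segments",
                         batch_size, N), "contract")
  }
  probs <- sampling_probs(store, schedule, step)
  idx <- with_local_seed(seed,
                         sample.int(N, batch_size, replace = replace,
                                    prob = probs))
  beta <- schedule_value(schedule, step)
  w <- (N * probs[idx])^(-beta)
  w <- w / max(w)
  list(segments = store$segments[idx], ids = store$inserted[idx],
       w_is = w, probs = probs[idx])
}

#' Recompute priorities for stored segments
#'
#' @param store A [segment_store()].
#' @param ids Segment ids as returned by [store_sample()].
#' @param deltas List of per-segment n-step TD-error magnitude vectors.
#' @return The new priorities, invisibly.
#' @export
store_update_priorities <- function(store, ids, deltas) {
  pos <- match(ids, store$inserted)
  if (anyNA(pos)) {
    abort_imusac("unknown segment id in priority update", "contract")
  }
  new_p <- vapply(deltas, priority, numeric(1), eta = store$eta)
  # A segment sampled twice in one batch gets its latest update.
  store$priorities[pos] <- new_p
  invisible(new_p)
}

#' Flatten sampled segments into a train batch
#'
#' Expands each segment into its unpadded elements with within-segment
#' n-step discounted reward sums, the matching discount product
#' `gamma^k`, the bootstrap observation at `t + k`, and the termination
#' flag (episode ends only at the last real transition of a segment,
#' since segments never cross episodes).  Each element inherits its
#' segment's importance weight; `seg_index` maps elements back to
#' segments for priority updates.
#'
#' @param segments List of segments from [store_sample()].
#' @param w_is Per-segment importance weights.
#' @param n n-step horizon.
#' @param gamma Discount factor.
#' @return A `train_batch` list with matrices `obs`, `act`, `reward_n`,
#'   `next_obs`, vectors `gamma_n`, `done`, `w_is`, `seg_index`,
#'   `elem_index`.
#' @export
make_train_batch <- function(segments, w_is = rep(1, length(segments)),
                             n = 5, gamma = 0.99) {
  if (length(segments) == 0) abort_imusac("no segments", "input")
  obs <- list(); act <- list(); rew <- list(); nxt <- list()
  gam <- numeric(0); don <- numeric(0); wv <- numeric(0)
  seg_i <- integer(0); el_i <- integer(0)
  for (s in seq_along(segments)) {
    seg <- segments[[s]]
    m <- sum(seg$mask)
    for (j in seq_len(m)) {
      steps <- min(n, m - j + 1)
      rsum <- 0
      for (k in seq_len(steps)) {
        rsum <- rsum + gamma^(k - 1) * seg$transitions[[j + k - 1]]$reward
      }
      last <- seg$transitions[[j + steps - 1]]
      obs[[length(obs) + 1]] <- seg$transitions[[j]]$obs
      act[[length(act) + 1]] <- seg$transitions[[j]]$action
      rew[[length(rew) + 1]] <- rsum
      nxt[[length(nxt) + 1]] <- last$next_obs
      gam <- c(gam, gamma^steps)
      don <- c(don, as.numeric(last$done))
      wv <- c(wv, w_is[s])
      seg_i <- c(seg_i, s)
      el_i <- c(el_i, j)
    }
  }
  structure(list(
    obs = do.call(rbind, obs), act = do.call(rbind, act),
    reward_n = do.call(rbind, rew), next_obs = do.call(rbind, nxt),
    gamma_n = gam, done = don, w_is = wv,
    seg_index = seg_i, elem_index = el_i, n = n, gamma = gamma
  ), class = "train_batch")
}

#' Split a batch's per-element TD errors back into per-segment deltas
#'
#' Collapses the per-head signed TD-error matrix to one magnitude per
#' element — `|sum_i w_i TD_i|` when scalarization weights are given
#' (so zero-weight heads never drive sampling), otherwise the maximum
#' per-head magnitude — and groups by originating segment, yielding the
#' delta sequences that [priority()] consumes.
#'
#' @param batch A `train_batch`.
#' @param td Batch x heads signed TD-error matrix.
#' @param weights Optional per-head scalarization weights.
#' @return Named list of per-segment numeric delta vectors (names are
#'   the `seg_index` values).
#' @export
segment_deltas <- function(batch, td, weights = NULL) {
  per_elem <- if (is.null(weights)) {
    apply(abs(td), 1, max)
  } else {
    abs(as.numeric(td %*% as.numeric(weights)))
  }
  lapply(split(per_elem, batch$seg_index), as.numeric)
}
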