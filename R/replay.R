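# Teacher-forced replay: per-trial probability of the *recorded* choice
# sequence under a model, feeding the model the recorded choices and rewards
# (distinct from closed-loop simulation; shares the same update rules).

# Exact vectorised replay for the DT family. All three recursions
# (Q, F, S) are linear with constant coefficients given a fixed history, so
# stats::filter() computes them in O(T) without an R-level loop.
dt_family_replay <- function(params, choice, reward) {
  a <- params$alpha
  phi <- params$phi %||% 0
  vth <- params$vartheta %||% 0
  tf <- params$tau_f %||% 0
  ts <- params$tau_s %||% 0
  n <- length(choice)
  dl <- 1 - choice
  dr <- choice
  rec <- function(x, rate, init) {
    # y[t] = x[t] + (1 - rate) * y[t - 1], y[0] = init; state at trial t + 1
    if (rate == 0) return(rep(init, n))
    y <- stats::filter(rate * x, 1 - rate, method = "recursive", init = init)
    c(init, as.numeric(y)[-n])
  }
  ql <- rec(dl * reward, a, 0); qr <- rec(dr * reward, a, 0)
  h <- qr - ql
  if (phi != 0) h <- h + phi * (rec(dr, tf, 0.5) - rec(dl, tf, 0.5))
  if (vth != 0) h <- h + vth * (rec(dr, ts, 0.5) - rec(dl, ts, 0.5))
  1 / (1 + exp(-params$beta * h))
}

# Precomputed teacher-forcing context for repeated likelihood evaluation of
# one dataset under many parameter draws (the annealing inner loop).
make_replay_ctx <- function(model, sessions, mask = NULL) {
  sid <- sessions[["session"]] %||% rep(1L, nrow(sessions))
  idx <- split(seq_len(nrow(sessions)), sid)
  ctx <- list(model = model, idx = idx,
              choice = sessions$choice, reward = sessions$reward,
              mask = mask %||% rep(TRUE, nrow(sessions)),
              sessions = sessions)
  if (model %in% c("dt", "fq", "fq_wc")) {
    lens <- lengths(idx)
    tmax <- max(lens)
    cmat <- rmat <- matrix(0, tmax, length(idx))
    score <- matrix(FALSE, tmax, length(idx))
    flat <- integer(nrow(sessions))
    for (j in seq_along(idx)) {
      ix <- idx[[j]]
      cmat[seq_along(ix), j] <- sessions$choice[ix]
      rmat[seq_along(ix), j] <- sessions$reward[ix]
      score[seq_along(ix), j] <- ctx$mask[ix]
      flat[ix] <- (j - 1L) * tmax + seq_along(ix)
    }
    ctx$cmat <- cmat
    ctx$rmat <- rmat
    ctx$score <- score
    ctx$lens <- as.integer(lens)
    ctx$flat <- flat
  }
  ctx
}

# Mean per-trial log-likelihood of the recorded choices for one parameter
# vector, using the precomputed context.
ctx_mean_ll <- function(params, ctx, seed = NULL) {
  if (!is.null(ctx$cmat)) {
    res <- dt_family_ll_cpp(ctx$cmat, ctx$rmat, ctx$lens, ctx$score,
                            params$alpha, params$beta,
                            params$tau_f %||% 0, params$tau_s %||% 0,
                            params$phi %||% 0, params$vartheta %||% 0)
    return(res[1] / res[2])
  }
  p_right <- replay_probabilities(ctx$model, params, ctx$sessions, seed = seed)
  p_choice <- ifelse(ctx$choice == 1, p_right, 1 - p_right)
  ll <- log(pmin(pmax(p_choice, 1e-12), 1 - 1e-12))
  mean(ll[ctx$mask])
}

# Exact vectorised replay for the indirect actor: each option's value only
# changes on trials where it is chosen, so it is a linear recursion over
# that option's chosen-trial subsequence, expanded back to trial time.
indirect_replay <- function(params, choice, reward) {
  a <- params$alpha
  n <- length(choice)
  qt <- function(sel) {
    idx <- which(sel)
    vals <- c(0, as.numeric(stats::filter(a * reward[idx], 1 - a,
                                          method = "recursive")))
    cnt <- c(0, cumsum(sel))[seq_len(n)]
    vals[cnt + 1]
  }
  qr <- qt(choice == 1)
  ql <- qt(choice == 0)
  1 / (1 + exp(-params$beta * (qr - ql)))
}

# Generic per-trial loop through the shared update rules; used for models
# whose recursions are not linear in the history (LK, direct actor, fq_up,
# IB) and as an independent code path for cross-checks.
loop_replay <- function(agent, choice, reward, env_p = NULL) {
  n <- length(choice)
  state <- agent_init(agent)
  out <- numeric(n)
  for (t in seq_len(n)) {
    pr <- agent_probs(agent, state,
                      env_p = if (is.null(env_p)) NULL else env_p[t, ])
    out[t] <- pr[2]
    state <- agent_update(agent, state, choice[t] + 1L, reward[t], probs = pr)
  }
  out
}

#' Per-trial choice probabilities under teacher-forced replay
#'
#' Replays recorded sessions through a model: on every trial the model's
#' probability of choosing right is computed from the history so far, then
#' the state is updated with the *recorded* choice and reward. The DT family
#' (`dt`, `fq`, `fq_wc`) and the indirect actor are evaluated by exact
#' vectorised linear recursions; other models run the trial loop.
#'
#' @param model Model name (see [vi_models()]; `oracle` requires recorded
#'   true probability columns, `ib` and `fq_up` draw their stochastic
#'   initialisation/resampling from the current RNG stream unless `seed` is
#'   given).
#' @param params Named list or vector of model parameters.
#' @param sessions Session tibble (optionally with a `session` column;
#'   replay state resets at session boundaries).
#' @param seed Optional seed for stochastic replays.
#' @return Numeric vector, one probability of "right" per row of `sessions`.
#' @export
replay_probabilities <- function(model, params, sessions, seed = NULL) {
  params <- as.list(params)
  sid <- sessions[["session"]] %||% rep(1L, nrow(sessions))
  with_seed(seed, {
    parts <- lapply(split(seq_len(nrow(sessions)), sid), function(ix) {
      ch <- sessions$choice[ix]
      rw <- sessions$reward[ix]
      if (model %in% c("dt", "fq", "fq_wc")) {
        dt_family_replay(params, ch, rw)
      } else if (model == "indirect") {
        indirect_replay(params, ch, rw)
      } else {
        agent <- do.call(vi_agent, c(list(model = model), params))
        env_p <- if (model == "oracle") {
          if (!all(c("p_0", "p_1") %in% names(sessions))) {
            abort("oracle replay needs recorded true probabilities p_0/p_1")
          }
          cbind(sessions$p_0[ix], sessions$p_1[ix])
        }
        loop_replay(agent, ch, rw, env_p = env_p)
      }
    })
    unsplit(parts, sid)
  })
}
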