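#' Softmax choice probabilities
#'
#' Numerically stable softmax over action values with inverse temperature
#' `beta`; `beta = 0` gives uniform choice.
#'
#' @param values Numeric vector of per-option values.
#' @param beta Inverse temperature, non-negative.
#' @return Probability vector summing to 1.
#' @examples
#' softmax_probabilities(c(1, 0), beta = 2)
#' @export
softmax_probabilities <- function(values, beta) {
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    abort("`values` must be finite numbers")
  }
  if (!is_scalar_number(beta) || beta < 0) abort("`beta` must be >= 0")
  z <- beta * values
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Greedy choice of the Oracle agent
#'
#' The Oracle sees the true momentary reward probabilities and picks the
#' argmax; exact ties are broken uniformly at random.
#'
#' @param p Per-option true reward probabilities.
#' @return 1-based option index.
#' @export
oracle_choose <- function(p) {
  assert_probability(p)
  best <- which(p == max(p))
  if (length(best) > 1L) best <- best[sample.int(length(best), 1L)]
  best
}

# ---- agent construction -----------------------------------------------------

# Structural parameter box per model: names, hard bounds, defaults.
model_param_spec <- function(model) {
  spec <- switch(model,
    oracle = ,
    random = data.frame(name = character(), lower = numeric(),
                        upper = numeric(), default = numeric()),
    ib = data.frame(
      name = c("n_particles", "jitter", "beta"),
      lower = c(1, 0, 0), upper = c(Inf, 1, Inf),
      default = c(1000, 0.025, 10)),
    lk = data.frame(
      name = c("alpha", "tau_psi", "beta"),
      lower = c(0, 0, 0), upper = c(1, 1, Inf),
      default = c(0.3, 0.3, 5)),
    dt = data.frame(
      name = c("alpha", "beta", "tau_f", "tau_s", "phi", "vartheta"),
      lower = c(0, 0, 0, 0, -Inf, -Inf), upper = c(1, Inf, 1, 1, Inf, Inf),
      default = c(0.5, 2, 0.7, 0.2, -1, 1)),
    fq = data.frame(
      name = c("alpha", "beta"),
      lower = c(0, 0), upper = c(1, Inf), default = c(0.5, 2)),
    fq_wc = data.frame(
      name = c("alpha", "beta", "tau_f", "phi"),
      lower = c(0, 0, 0, -Inf), upper = c(1, Inf, 1, Inf),
      default = c(0.5, 2, 0.7, -1)),
    fq_up = data.frame(
      name = c("alpha", "alpha_up", "cap", "beta"),
      lower = c(0, 0, -Inf, 0), upper = c(1, 1, Inf, Inf),
      default = c(0.5, 0.1, 1, 2)),
    indirect = data.frame(
      name = c("alpha", "beta"),
      lower = c(0, 0), upper = c(1, Inf), default = c(0.5, 2)),
    direct = data.frame(
      name = c("alpha", "beta", "offset"),
      lower = c(0, 0, -Inf), upper = c(1, Inf, Inf),
      default = c(0.1, 2, 0.3)),
    abort(sprintf("unknown model '%s'", model))
  )
  tibble::as_tibble(spec)
}

#' Known agent model names
#' @return Character vector of model identifiers accepted by [vi_agent()].
#' @export
vi_models <- function() {
  c("oracle", "random", "ib", "lk", "dt", "fq", "fq_wc", "fq_up",
    "indirect", "direct")
}

#' Construct a decision agent
#'
#' Available models:
#' \describe{
#'   \item{`oracle`}{greedy on the true momentary probabilities (only agent
#'     with access to them).}
#'   \item{`random`}{uniform choice.}
#'   \item{`ib`}{inference-based agent: a particle cloud per option over the
#'     set probability, reweighted under the baiting likelihood, multinomially
#'     resampled, jittered by U(-jitter, jitter) and clipped to \[0, 1\].}
#'   \item{`lk`}{recursive optimal RL model estimating the set probability
#'     (Rescorla--Wagner, rate `alpha`) and a dynamic baiting factor `psi`
#'     whose learning rate tracks the reward prediction error (fixed rate
#'     `tau_psi`).}
#'   \item{`dt`}{double-trace model: forgetting-Q reward expectation plus a
#'     fast (`tau_f`, scaled by `phi`) and a slow (`tau_s`, scaled by
#'     `vartheta`) choice trace inside the softmax. `constrained = TRUE`
#'     enforces `phi <= 0` and `vartheta >= 0` at construction.}
#'   \item{`fq`}{forgetting Q-learning (unchosen value decays to 0).}
#'   \item{`fq_wc`}{forgetting Q plus a single choice trace.}
#'   \item{`fq_up`}{forgetting Q whose unchosen value grows towards `cap`
#'     with rate `alpha_up`; Q is initialised uniformly on \[0, 1\].}
#'   \item{`indirect`}{indirect actor: only the chosen value is updated.}
#'   \item{`direct`}{direct actor / one-state actor-critic: policy-gradient
#'     style update with average-reward offset `offset`.}
#' }
#'
#' @param model Model name, see [vi_models()].
#' @param ... Named model parameters overriding the defaults.
#' @param constrained For `dt`: enforce the animal-derived sign constraints
#'   `phi <= 0`, `vartheta >= 0`.
#' @return An object of class `vi_agent`.
#' @examples
#' vi_agent("dt", alpha = 0.75, beta = 1.6, tau_f = 0.71, tau_s = 0.24,
#'          phi = -2.22, vartheta = 3.31)
#' @export
vi_agent <- function(model, ..., constrained = FALSE) {
  spec <- model_param_spec(model)
  dots <- list(...)
  unknown <- setdiff(names(dots), spec$name)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown parameter(s) for model '%s': %s", model,
                  paste(unknown, collapse = ", ")))
  }
  params <- as.list(setNames(spec$default, spec$name))
  params[names(dots)] <- dots
  for (i in seq_len(nrow(spec))) {
    v <- params[[spec$name[i]]]
    if (!is_scalar_number(v) || v < spec$lower[i] || v > spec$upper[i]) {
      abort(sprintf("parameter '%s' of model '%s' must lie in [%g, %g]",
                    spec$name[i], model, spec$lower[i], spec$upper[i]))
    }
  }
  if (model == "dt" && constrained) {
    if (params$phi > 0 || params$vartheta < 0) {
      abort("constrained DT model requires phi <= 0 and vartheta >= 0")
    }
  }
  structure(
    list(model = model, params = params, constrained = constrained),
    class = c(paste0("vi_agent_", model), "vi_agent")
  )
}

#' @export
print.vi_agent <- function(x, ...) {
  cat(sprintf("<vi_agent: %s>\n", x$model))
  if (length(x$params)) {
    cat(paste(sprintf("  %s = %g", names(x$params), unlist(x$params)),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

# ---- agent state and update operations -------------------------------------

#' Initialise agent state
#'
#' Q values start at 0 (the forgetting-Q fixed point for never-chosen
#' options), choice traces at 0.5 (making the two-option complement identity
#' exact), the LK baiting factor at 0 with its learning rate at the midpoint
#' 0.5, and IB particles uniform on \[0, 1\]. The `fq_up` model draws its
#' initial Q uniformly on \[0, 1\] from the current RNG stream.
#'
#' @param agent A [vi_agent()].
#' @param n_options Number of options (2 in all study conditions).
#' @return A state list specific to the model.
#' @export
agent_init <- function(agent, n_options = 2L) {
  z <- rep(0, n_options)
  switch(agent$model,
    oracle = ,
    random = list(),
    ib = list(
      theta = matrix(runif(agent$params$n_particles * n_options),
                     nrow = agent$params$n_particles),
      ti = rep(0L, n_options)),
    lk = list(qset = rep(0.5, n_options), q = rep(0.5, n_options),
              psi = z, alpha_psi = 0.5),
    dt = list(q = z, f = rep(0.5, n_options), s = rep(0.5, n_options)),
    fq = list(q = z),
    fq_wc = list(q = z, f = rep(0.5, n_options)),
    fq_up = list(q = runif(n_options)),
    indirect = list(q = z),
    direct = list(q = z)
  )
}

#' Per-option values of an agent state
#'
#' @param agent A [vi_agent()].
#' @param state State list from [agent_init()] / [agent_update()].
#' @return Numeric vector of per-option action values (`NULL` for the
#'   oracle/random agents, which do not use values).
#' @export
agent_values <- function(agent, state) {
  p <- agent$params
  switch(agent$model,
    oracle = NULL,
    random = NULL,
    ib = ib_values(state),
    lk = state$q,
    dt = state$q + p$phi * state$f + p$vartheta * state$s,
    fq = state$q,
    fq_wc = state$q + p$phi * state$f,
    fq_up = state$q,
    indirect = state$q,
    direct = state$q
  )
}

#' Choice probabilities of an agent
#'
#' Softmax over [agent_values()] for value-based agents; the Oracle is
#' greedy on the true probabilities `env_p` (the only agent allowed to see
#' them -- `env_p` is ignored by every other model); the random agent is
#' uniform.
#'
#' @inheritParams agent_values
#' @param env_p True per-option momentary probabilities (Oracle only).
#' @return Probability vector over options.
#' @export
agent_probs <- function(agent, state, env_p = NULL) {
  switch(agent$model,
    oracle = {
      if (is.null(env_p)) abort("the Oracle agent needs the true probabilities")
      best <- env_p == max(env_p)
      as.numeric(best) / sum(best)
    },
    random = rep(1 / 2, 2L),
    softmax_probabilities(agent_values(agent, state), agent$params$beta)
  )
}

#' Update agent state after a trial
#'
#' Dispatches to the model-specific update ([ib_update()], [lk_update()],
#' [dt_update()], [comparison_update()]). Non-Oracle agents consume only
#' their own choice and reward.
#'
#' @inheritParams agent_values
#' @param chosen 1-based index of the chosen option.
#' @param reward Observed reward, 0 or 1.
#' @param probs Choice probabilities used on this trial (required by the
#'   direct actor; supplied automatically by [run_session()]).
#' @return Updated state list.
#' @export
agent_update <- function(agent, state, chosen, reward, probs = NULL) {
  p <- agent$params
  switch(agent$model,
    oracle = ,
    random = state,
    ib = ib_update(state, chosen, reward, jitter = p$jitter),
    lk = lk_update(state, p, chosen, reward),
    dt = dt_update(state, p, chosen, reward),
    fq = comparison_update("fq", p, state, chosen, reward),
    fq_wc = comparison_update("fq_wc", p, state, chosen, reward),
    fq_up = comparison_update("fq_up", p, state, chosen, reward),
    indirect = comparison_update("indirect", p, state, chosen, reward),
    direct = {
      if (is.null(probs)) {
        probs <- softmax_probabilities(state$q, p$beta)
      }
      comparison_update("direct", p, state, chosen, reward, probs = probs)
    }
  )
}

#' Per-option values of the inference-based agent
#'
#' The value of an option is the particle-cloud mean of the predicted reward
#' probability `1 - (1 - theta)^(ti + 1)` at the option's current
#' trials-since-chosen counter.
#'
#' @param state IB state list with elements `theta` (particles x options
#'   matrix of set-probability estimates) and `ti` (per-option counters).
#' @return Numeric vector of per-option values.
#' @export
ib_values <- function(state) {
  vapply(seq_len(ncol(state$theta)), function(i) {
    mean(1 - (1 - state$theta[, i])^(state$ti[i] + 1))
  }, numeric(1))
}

#' Bayesian particle update of the inference-based agent
#'
#' Each particle of the chosen option predicts the reward probability under
#' the baiting closed form at the pre-choice counter; particle weights are
#' multiplied by that prediction (reward) or its complement (no reward),
#' normalised, multinomially resampled, jittered by U(-jitter, jitter) and
#' clipped to \[0, 1\]. The unchosen option's cloud is untouched. Counters
#' are then advanced (chosen resets to 0). If all weights vanish the cloud
#' is resampled uniformly with a warning.
#'
#' @inheritParams ib_values
#' @param chosen 1-based chosen option index.
#' @param reward Observed reward, 0 or 1.
#' @param jitter Half-width of the uniform exploration noise.
#' @return Updated IB state.
#' @export
ib_update <- function(state, chosen, reward, jitter = 0.025) {
  if (!reward %in% c(0, 1)) abort("`reward` must be 0 or 1")
  theta <- state$theta[, chosen]
  n <- length(theta)
  phat <- 1 - (1 - theta)^(state$ti[chosen] + 1)
  w <- if (reward == 1) phat else 1 - phat
  total <- sum(w)
  if (!is.finite(total) || total <= 0) {
    warn("all particle weights vanished; resampling uniformly")
    theta_new <- runif(n)
  } else {
    idx <- sample.int(n, n, replace = TRUE, prob = w / total)
    theta_new <- theta[idx] + runif(n, -jitter, jitter)
    theta_new <- pmin(pmax(theta_new, 0), 1)
  }
  state$theta[, chosen] <- theta_new
  state$ti <- state$ti + 1L
  state$ti[chosen] <- 0L
  state
}

#' One trial of the LK model update
#'
#' Order of operations within a trial: prediction error `PE = R - Q(chosen)`;
#' Rescorla--Wagner update of the chosen option's set-probability estimate;
#' update of the baiting-factor learning rate
#' `alpha_psi <- alpha_psi + tau_psi * ((PE + 1) / 2 - alpha_psi)` (rewards
#' must lie in \[0, 1\] so that `alpha_psi` stays in \[0, 1\]); baiting factor
#' `psi` reset to 0 for the chosen option and grown towards 1 for unchosen
#' options; finally the recursive baiting reconstruction
#' `Q <- 1 - (1 - Qset) * (1 - Q * psi)` for every option.
#'
#' @param state LK state (`qset`, `q`, `psi`, `alpha_psi`).
#' @param params LK parameters (`alpha`, `tau_psi`, `beta`).
#' @param chosen 1-based chosen option index.
#' @param reward Reward in \[0, 1\].
#' @return Updated LK state.
#' @export
lk_update <- function(state, params, chosen, reward) {
  if (!is_scalar_number(reward) || reward < 0 || reward > 1) {
    abort("LK update requires rewards bounded in [0, 1]")
  }
  pe <- reward - state$q[chosen]
  state$qset[chosen] <- state$qset[chosen] +
    params$alpha * (reward - state$qset[chosen])
  state$alpha_psi <- state$alpha_psi +
    params$tau_psi * ((pe + 1) / 2 - state$alpha_psi)
  psi_grown <- state$psi + state$alpha_psi * (1 - state$psi)
  state$psi <- psi_grown
  state$psi[chosen] <- 0
  state$q <- 1 - (1 - state$qset) * (1 - state$q * state$psi)
  state
}

#' One trial of the double-trace model update
#'
#' Every option's reward expectation moves towards the choice-gated reward
#' (`Q <- Q + alpha * (delta * R - Q)`, so unchosen values are forgotten
#' towards 0) and both choice traces decay towards the choice indicator with
#' their own rates.
#'
#' @param state DT state (`q`, `f`, `s`).
#' @param params DT parameters (`alpha`, `tau_f`, `tau_s`, ...).
#' @param chosen 1-based chosen option index.
#' @param reward Reward, 0 or 1.
#' @return Updated DT state.
#' @export
dt_update <- function(state, params, chosen, reward) {
  delta <- rep(0, length(state$q))
  delta[chosen] <- 1
  state$q <- state$q + params$alpha * (delta * reward - state$q)
  state$f <- state$f + params$tau_f * (delta - state$f)
  state$s <- state$s + params$tau_s * (delta - state$s)
  state
}

#' One trial of a comparison RL model update
#'
#' @param model One of `"indirect"`, `"direct"`, `"fq"`, `"fq_wc"`,
#'   `"fq_up"`.
#' @param params Named parameter list for that model.
#' @param state Model state list.
#' @param chosen 1-based chosen option index.
#' @param reward Reward, 0 or 1.
#' @param probs Choice probabilities used on this trial (direct actor only).
#' @return Updated state.
#' @export
comparison_update <- function(model, params, state, chosen, reward,
                              probs = NULL) {
  n <- length(state$q)
  delta <- rep(0, n)
  delta[chosen] <- 1
  switch(model,
    indirect = {
      state$q <- state$q + delta * params$alpha * (reward - state$q)
    },
    direct = {
      if (is.null(probs)) abort("the direct actor update needs `probs`")
      state$q <- state$q +
        params$alpha * (delta - probs) * (reward - params$offset)
    },
    fq = {
      state$q <- state$q + params$alpha * (delta * reward - state$q)
    },
    fq_wc = {
      state$q <- state$q + params$alpha * (delta * reward - state$q)
      state$f <- state$f + params$tau_f * (delta - state$f)
    },
    fq_up = {
      state$q <- state$q +
        delta * params$alpha * (reward - state$q) +
        (1 - delta) * params$alpha_up * (params$cap - state$q)
    },
    abort(sprintf("unknown comparison model '%s'", model))
  )
  state
}

# ---- closed-loop simulation -------------------------------------------------

#' Run one closed-loop session of an agent on a schedule
#'
#' @param agent A [vi_agent()].
#' @param schedule A [vi_schedule()] (or protocol name, built fresh).
#' @param seed Optional integer seed; the same seed reproduces the session
#'   exactly.
#' @return Session tibble with columns `trial`, `choice` (0 = left,
#'   1 = right), `reward`, `block`, `pset_0`, `pset_1`, `p_0`, `p_1` (true
#'   probability traces) and attributes `seed`, `agent`.
#' @examples
#' s <- run_session(vi_agent("random"), vi_schedule("mouse", seed = 1), seed = 2)
#' head(s)
#' @export
run_session <- function(agent, schedule, seed = NULL) {
  if (is.character(schedule)) schedule <- vi_schedule(schedule, seed = seed)
  with_seed(seed, {
    env <- env_init(schedule)
    state <- agent_init(agent)
    n <- env$n_trials
    choice <- integer(n); reward <- integer(n)
    p0 <- numeric(n); p1 <- numeric(n)
    for (t in seq_len(n)) {
      p0[t] <- env$p[1]; p1[t] <- env$p[2]
      pr <- agent_probs(agent, state, env_p = env$p)
      ch <- 1L + as.integer(runif(1) < pr[2])
      st <- env_step(env, ch)
      env <- st$env
      choice[t] <- ch - 1L
      reward[t] <- st$reward
      state <- agent_update(agent, state, ch, st$reward, probs = pr)
    }
    out <- tibble::tibble(
      trial = seq_len(n),
      choice = choice,
      reward = reward,
      block = env$block,
      pset_0 = env$pset[, 1],
      pset_1 = env$pset[, 2],
      p_0 = p0,
      p_1 = p1
    )
    attr(out, "seed") <- seed
    attr(out, "agent") <- agent$model
    attr(out, "agent_state") <- state
    out
  })
}

#' Run several sessions and stack them
#'
#' @inheritParams run_session
#' @param n_sessions Number of sessions.
#' @param schedule A [vi_schedule()] reused for every session, a protocol
#'   name (a fresh schedule is drawn per session), or a function
#'   `function(session_seed)` returning a schedule.
#' @return Session tibble with a `session` id column.
#' @export
run_sessions <- function(agent, schedule, n_sessions, seed = NULL) {
  seeds <- derive_seeds(seed, n_sessions)
  out <- purrr::map2(seq_len(n_sessions), seeds, function(i, s) {
    sch <- if (is.character(schedule)) {
      vi_schedule(schedule, seed = if (is.null(s)) NULL else s + 1L)
    } else if (is.function(schedule)) {
      schedule(s)
    } else {
      schedule
    }
    d <- run_session(agent, sch, seed = s)
    d$session <- i
    d
  })
  res <- dplyr::bind_rows(out)
  attr(res, "seed") <- seed
  attr(res, "agent") <- agent$model
  res
}
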