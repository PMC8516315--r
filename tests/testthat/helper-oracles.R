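# Independent reference implementations used as oracles in the tests.
# These deliberately avoid the package's own computation paths.

# Brute-force bait bookkeeping for the VI schedule: a persistent bait is
# assigned each trial with probability pset and cleared when collected.
bait_env_reward_freq <- function(pset, interval, n_choices, seed) {
  set.seed(seed)
  bait <- FALSE
  hits <- 0L
  for (i in seq_len(n_choices)) {
    # `interval` trials elapse between visits; each offers an assignment
    for (k in seq_len(interval)) {
      if (!bait && runif(1) < pset) bait <- TRUE
    }
    if (bait) {
      hits <- hits + 1L
      bait <- FALSE
    }
  }
  hits / n_choices
}

# Explicit-sum logistic probability of choosing right, expanded over the
# full history (the lag form of the double-trace softmax).
logistic_prob_right <- function(params, choice, reward, t) {
  stopifnot(t >= 2)
  m <- seq_len(t - 1)
  a <- params$alpha
  b_r <- a * (1 - a)^(m - 1)
  b_c <- params$phi * params$tau_f * (1 - params$tau_f)^(m - 1) +
    params$vartheta * params$tau_s * (1 - params$tau_s)^(m - 1)
  dr <- choice[t - m]          # 1 when right chosen at lag m
  dl <- 1 - dr
  rw <- reward[t - m]
  h <- sum(b_r * dr * rw) - sum(b_r * dl * rw) +
    2 * sum(b_c * dr) - (params$phi + params$vartheta)
  1 / (1 + exp(-params$beta * h))
}

# O(n^2) pair-counting AUC.
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Explicit geometric-sum choice trace (decayed initial term plus lag sum).
explicit_choice_trace <- function(delta, tau, init, t) {
  if (t == 1) return(init)
  m <- seq_len(t - 1)
  (1 - tau)^(t - 1) * init + tau * sum((1 - tau)^(m - 1) * delta[t - m])
}

# Random teacher-forcing history.
random_history <- function(n, seed) {
  set.seed(seed)
  list(choice = rbinom(n, 1, 0.5), reward = rbinom(n, 1, 0.5))
}

# Fixed mouse-fit DT parameter set used across tests.
mouse_dt_params <- list(alpha = 0.75, beta = 1.60, tau_f = 0.71,
                        tau_s = 0.24, vartheta = 3.31, phi = -2.22)

history_session <- function(h) {
  tibble::tibble(trial = seq_along(h$choice), choice = h$choice,
                 reward = h$reward, block = 1L)
}
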