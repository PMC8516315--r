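test_that("softmax probabilities are exact, symmetric and stable", {
  expect_equal(softmax_probabilities(c(3, -1, 7), 0), rep(1 / 3, 3))
  expect_equal(softmax_probabilities(c(2, 2), 5), c(0.5, 0.5))
  expect_equal(softmax_probabilities(c(1, 0), 2),
               c(exp(2), 1) / (exp(2) + 1), tolerance = 1e-12)
  big <- softmax_probabilities(c(1e4, 0), 50)
  expect_false(anyNA(big))
  expect_equal(sum(big), 1)
  expect_error(softmax_probabilities(c(Inf, 0), 1), "finite")
})

test_that("oracle choice is greedy with uniform tie-breaking", {
  expect_equal(oracle_choose(c(0.1, 0.4)), 2L)
  expect_equal(oracle_choose(c(0.6, 0.2)), 1L)
  set.seed(2)
  ties <- replicate(200, oracle_choose(c(0.25, 0.25)))
  expect_setequal(unique(ties), 1:2)
  expect_gt(mean(ties == 1), 0.35)
})

test_that("closed-loop oracle on 0.1 vs 0.4 settles into a period-5 cycle", {
  sch <- vi_schedule("fixed", lengths = 300, psets = list(c(0.1, 0.4)))
  s <- run_session(vi_agent("oracle"), sch, seed = 1)
  lows <- which(s$choice == 0 & s$trial > 20)
  expect_true(all(diff(lows) == 5))
})

test_that("IB particle update follows the baiting likelihood", {
  # single particle at 0.5, just-chosen option, rewarded: particle survives
  # resampling and moves only by the jitter
  st <- list(theta = matrix(c(0.5, 0.3), nrow = 1), ti = c(0L, 0L))
  set.seed(1)
  up <- ib_update(st, chosen = 1, reward = 1, jitter = 0.025)
  expect_lt(abs(up$theta[1, 1] - 0.5), 0.025 + 1e-12)
  expect_equal(up$theta[1, 2], 0.3)       # unchosen cloud untouched
  expect_equal(up$ti, c(0L, 1L))
  # zero-probability particle with an observed reward has zero weight;
  # a cloud of them triggers the uniform-resample fallback
  st0 <- list(theta = matrix(c(0, 0.3), nrow = 1), ti = c(0L, 0L))
  expect_warning(ib_update(st0, chosen = 1, reward = 1), "weights")
})

test_that("IB values are particle means of the predicted reward probability", {
  st <- list(theta = matrix(rep(c(0.3, 0.1), each = 4), ncol = 2),
             ti = c(0L, 4L))
  expect_equal(ib_values(st), c(0.3, 1 - 0.9^5))
  st2 <- list(theta = matrix(c(0, 1, 0.5, 0.5), ncol = 2), ti = c(0L, 0L))
  expect_equal(ib_values(st2), c(0.5, 0.5))
})

test_that("IB particle means converge to the set probabilities", {
  sch <- vi_schedule("fixed", lengths = 1000, psets = list(c(0.7, 0.3)))
  est <- rowMeans(sapply(1:8, function(i) {
    s <- run_session(vi_agent("ib"), sch, seed = 50 + i)
    colMeans(attr(s, "agent_state")$theta)
  }))
  expect_lt(abs(est[1] - 0.7), 0.05)
  expect_lt(abs(est[2] - 0.3), 0.08)
})

test_that("LK update follows the stated within-trial order", {
  params <- list(alpha = 0.2, tau_psi = 0, beta = 5)
  st <- list(qset = c(0.5, 0.5), q = c(0.5, 0.5), psi = c(0.1, 0.5),
             alpha_psi = 0.2)
  up <- lk_update(st, params, chosen = 1, reward = 1)
  expect_equal(up$psi[1], 0)                       # chosen baiting factor resets
  expect_equal(up$psi[2], 0.5 + 0.2 * 0.5)         # unchosen grows by alpha_psi
  expect_equal(up$qset[1], 0.5 + 0.2 * (1 - 0.5))  # RW on the chosen option
  expect_equal(up$qset[2], 0.5)
  expect_equal(up$q[1], up$qset[1])                # psi = 0 collapses Q to Qset
  expect_equal(up$q[2], 1 - (1 - 0.5) * (1 - 0.5 * up$psi[2]))
  expect_error(lk_update(st, params, 1, 1.5), "bounded")
})

test_that("LK alpha_psi tracks the reward prediction error midpoint", {
  params <- list(alpha = 0.1, tau_psi = 0.5, beta = 1)
  st <- list(qset = c(0.2, 0.2), q = c(0.4, 0.2), psi = c(0, 0),
             alpha_psi = 0.6)
  up <- lk_update(st, params, chosen = 1, reward = 0)
  pe <- 0 - 0.4
  expect_equal(up$alpha_psi, 0.6 + 0.5 * ((pe + 1) / 2 - 0.6))
  expect_true(up$alpha_psi >= 0 && up$alpha_psi <= 1)
})

test_that("DT update handles rewards, forgetting and trace decay", {
  params <- list(alpha = 0.75, tau_f = 1, tau_s = 0.2)
  st <- list(q = c(0.5, 0.3), f = c(0.5, 0.5), s = c(0.5, 0.5))
  up <- dt_update(st, params, chosen = 1, reward = 0)
  expect_equal(up$q[1], 0.125)                 # 0.5 + 0.75 * (0 - 0.5)
  expect_equal(up$q[2], 0.075)                 # unchosen forgets towards 0
  expect_equal(up$f, c(1, 0))                  # tau_f = 1: one-hot indicator
  expect_equal(up$s, c(0.6, 0.4))
})

test_that("choice traces of the two options sum to one exactly", {
  params <- list(alpha = 0.4, tau_f = 0.71, tau_s = 0.24)
  h <- random_history(500, seed = 9)
  st <- list(q = c(0, 0), f = c(0.5, 0.5), s = c(0.5, 0.5))
  for (t in seq_len(500)) {
    st <- dt_update(st, params, h$choice[t] + 1L, h$reward[t])
    expect_equal(sum(st$f), 1, tolerance = 1e-12)
    expect_equal(sum(st$s), 1, tolerance = 1e-12)
  }
})

test_that("recursive choice trace equals its explicit geometric sum", {
  h <- random_history(200, seed = 4)
  for (tau in c(0.15, 0.5, 0.9)) {
    st <- list(q = c(0, 0), f = c(0.5, 0.5), s = c(0.5, 0.5))
    params <- list(alpha = 0.3, tau_f = tau, tau_s = 0.1)
    dl <- 1 - h$choice
    for (t in 1:199) {
      st <- dt_update(st, params, h$choice[t] + 1L, h$reward[t])
      expect_equal(st$f[1], explicit_choice_trace(dl, tau, 0.5, t + 1),
                   tolerance = 1e-12)
    }
  }
})

test_that("comparison model updates match their defining rules", {
  # indirect actor freezes unchosen values
  st <- list(q = c(0.6, 0.2))
  up <- comparison_update("indirect", list(alpha = 0.3), st, 2, 1)
  expect_equal(up$q, c(0.6, 0.2 + 0.3 * (1 - 0.2)))
  # forgetting Q decays the unchosen value
  up <- comparison_update("fq", list(alpha = 0.3), list(q = c(0.6, 0.2)), 2, 1)
  expect_equal(up$q[1], 0.42)
  # direct actor: reward equal to the offset leaves values untouched
  up <- comparison_update("direct", list(alpha = 0.5, offset = 0.3),
                          list(q = c(0.1, 0.7)), 1, 0.3,
                          probs = c(0.4, 0.6))
  expect_equal(up$q, c(0.1, 0.7))
  # fq_up pulls the unchosen value towards its ceiling
  up <- comparison_update("fq_up",
                          list(alpha = 0.2, alpha_up = 0.1, cap = 1),
                          list(q = c(0.5, 0.5)), 1, 1)
  expect_equal(up$q, c(0.5 + 0.2 * 0.5, 0.5 + 0.1 * 0.5))
  expect_error(comparison_update("nope", list(), st, 1, 1), "unknown")
})

test_that("DT with zero trace scalings reduces to forgetting Q", {
  h <- random_history(100, seed = 3)
  s <- history_session(h)
  p_dt <- replay_probabilities("dt", list(alpha = 0.4, beta = 3, tau_f = 0.7,
                                          tau_s = 0.2, phi = 0, vartheta = 0), s)
  p_fq <- replay_probabilities("fq", list(alpha = 0.4, beta = 3), s)
  expect_equal(p_dt, p_fq, tolerance = 1e-12)
})

test_that("constrained DT construction enforces the animal sign pattern", {
  expect_error(vi_agent("dt", phi = 0.5, constrained = TRUE), "phi")
  expect_error(vi_agent("dt", vartheta = -1, constrained = TRUE), "vartheta")
  expect_s3_class(vi_agent("dt", phi = -1, vartheta = 2, constrained = TRUE),
                  "vi_agent")
  expect_error(vi_agent("dt", alpha = 1.2), "alpha")
  expect_error(vi_agent("dt", banana = 1), "unknown parameter")
})

test_that("sessions are reproducible and the random agent is unbiased", {
  sch <- vi_schedule("mouse", seed = 8)
  a <- vi_agent("oracle")
  expect_identical(run_session(a, sch, seed = 4)$choice,
                   run_session(a, sch, seed = 4)$choice)
  r <- run_session(vi_agent("random"), sch, seed = 1)
  expect_lt(abs(mean(r$choice) - 0.5), 0.07)
})

test_that("non-oracle agents ignore the true environment probabilities", {
  for (m in c("ib", "lk", "dt", "fq", "fq_wc", "indirect", "direct")) {
    a <- vi_agent(m)
    set.seed(1); st <- agent_init(a)
    p_blind <- agent_probs(a, st)
    p_spied <- agent_probs(a, st, env_p = c(0.99, 0.01))
    expect_identical(p_blind, p_spied)
  }
})

test_that("session records are well-formed", {
  s <- run_sessions(vi_agent("dt"), "mouse", 2, seed = 6)
  expect_true(all(s$reward %in% 0:1))
  expect_true(all(s$choice %in% 0:1))
  expect_equal(unique(s$session), 1:2)
  lens <- table(s$session)
  expect_true(all(lens >= 450 & lens <= 1350))
})
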