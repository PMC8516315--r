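make_session <- function(choice, reward, id = 1L) {
  tibble::tibble(trial = seq_along(choice), choice = choice, reward = reward,
                 block = 1L, session = id)
}

test_that("lagged design encodes signed rewards and drops early trials", {
  s <- make_session(c(1L, 0L, 0L, 1L, 1L), c(1L, 1L, 0L, 0L, 1L))
  d <- build_design(s, n_lags = 2)
  expect_equal(nrow(d$x), 3L)                     # 5 trials, M = 2
  expect_equal(d$y, c(0L, 1L, 1L))
  # lag-1 signed reward for row 1 (trial 3) is trial 2: left rewarded -> -1
  expect_equal(unname(d$x[1, "reward_1"]), -1)
  # lag-2 for row 1 is trial 1: right rewarded -> +1
  expect_equal(unname(d$x[1, "reward_2"]), 1)
  # trial 3: left unrewarded -> 0 (lag-1 of row 2)
  expect_equal(unname(d$x[2, "reward_1"]), 0)
  expect_equal(unname(d$x[1, "choice_1"]), 0)
})

test_that("lags never cross session boundaries", {
  s1 <- make_session(rep(1L, 6), rep(1L, 6), id = 1L)   # all right, rewarded
  s2 <- make_session(rep(0L, 6), rep(0L, 6), id = 2L)   # all left, unrewarded
  d <- build_design(dplyr::bind_rows(s1, s2), n_lags = 3)
  expect_equal(nrow(d$x), 6L)                           # (6 - 3) per session
  # session-2 rows must see only session-2 history (choices all 0)
  s2_rows <- d$session == 2L
  expect_true(all(d$x[s2_rows, c("choice_1", "choice_2", "choice_3")] == 0))
  expect_true(all(d$x[!s2_rows, c("choice_1", "choice_2", "choice_3")] == 1))
})

test_that("short sessions are skipped with a warning; all-short errors", {
  long <- make_session(rep(c(0L, 1L), 10), rbinom(20, 1, 0.5), id = 1L)
  short <- make_session(c(1L, 0L), c(0L, 1L), id = 2L)
  expect_warning(d <- build_design(dplyr::bind_rows(long, short), n_lags = 5),
                 "skipping")
  expect_equal(nrow(d$x), 15L)
  expect_error(suppressWarnings(build_design(short, n_lags = 5)), "longer")
})

test_that("extended design decomposes each trial into exclusive outcomes", {
  # all four outcome combinations
  s <- make_session(c(1L, 1L, 0L, 0L, 1L), c(1L, 0L, 1L, 0L, 1L))
  d <- build_extended_design(s, n_lags = 1)
  expect_equal(d$blocks,
               c("unsigned_reward", "choice", "reward_right", "reward_left",
                 "noreward_right", "noreward_left"))
  expect_equal(colnames(d$x), paste0(d$blocks, "_1"))
  # lag-1 regressors of rows 2..5 describe trials 1..4; the outcome
  # partition sums to 1 on every trial
  partition <- d$x[, "reward_right_1"] + d$x[, "reward_left_1"] +
    d$x[, "noreward_right_1"] + d$x[, "noreward_left_1"]
  expect_true(all(partition == 1))
  # trial 2: right chosen, unrewarded
  expect_equal(unname(d$x[2, "noreward_right_1"]), 1)
  expect_equal(unname(d$x[2, "reward_right_1"]), 0)
  expect_equal(unname(d$x[2, "unsigned_reward_1"]), 0)
  # trial 1: right chosen, rewarded
  expect_equal(unname(d$x[1, "reward_right_1"]), 1)
  expect_equal(unname(d$x[1, "unsigned_reward_1"]), 1)
})

test_that("elastic net recovers coefficients of a known logistic generator", {
  set.seed(42)
  m_lags <- 5
  b_r <- c(1.2, 0.7, 0.4, 0.2, 0.1)
  b_c <- c(-1.5, -0.4, 0.3, 0.5, 0.2)
  n <- 40000
  ch <- integer(n); rw <- integer(n)
  ch[1:m_lags] <- rbinom(m_lags, 1, 0.5)
  rw[1:m_lags] <- rbinom(m_lags, 1, 0.5)
  for (t in (m_lags + 1):n) {
    rlag <- ifelse(ch[t - (1:m_lags)] == 1, 1, -1) * rw[t - (1:m_lags)]
    h <- sum(b_r * rlag) + sum(b_c * ch[t - (1:m_lags)])
    ch[t] <- rbinom(1, 1, 1 / (1 + exp(-h)))
    rw[t] <- rbinom(1, 1, 0.4)
  }
  s <- make_session(ch, rw)
  fit <- fit_history_glm(s, n_lags = m_lags)
  est <- tidy(fit)
  expect_lt(max(abs(est$estimate[est$block == "reward"] - b_r)), 0.05)
  expect_lt(max(abs(est$estimate[est$block == "choice"] - b_c)), 0.05)
})

test_that("strict alternation yields a strongly negative lag-1 choice coefficient", {
  s <- edge_fixtures()$alternation
  fit <- fit_history_glm(s, n_lags = 3)
  b <- tidy(fit)
  expect_lt(b$estimate[b$block == "choice" & b$lag == 1], -1)
})

test_that("a huge penalty shrinks every coefficient to zero", {
  set.seed(1)
  s <- make_session(rbinom(300, 1, 0.5), rbinom(300, 1, 0.5))
  fit <- fit_history_glm(s, n_lags = 3, lambda = c(5000, 4999, 4998))
  expect_lt(max(abs(tidy(fit)$estimate)), 1e-6)
})

test_that("selected lambda attains the minimum of the CV deviance path", {
  set.seed(2)
  s <- make_session(rbinom(500, 1, 0.5), rbinom(500, 1, 0.5))
  fit <- fit_history_glm(s, n_lags = 4)
  path <- fit$cv_deviance
  expect_equal(path$deviance[path$lambda == fit$lambda], min(path$deviance))
})

test_that("single-class sessions are rejected by name", {
  expect_error(fit_history_glm(edge_fixtures()$all_left, n_lags = 3),
               "single-class")
})

test_that("decay-model inversion recovers noiseless generating parameters", {
  m <- 1:15
  b_reward <- 0.4 * 0.6^(m - 1)
  b_choice <- -2 * 0.7 * 0.3^(m - 1) + 3 * 0.2 * 0.8^(m - 1)
  dec <- fit_decay_model(list(b_reward = b_reward, b_choice = b_choice))
  expect_equal(dec$alpha, 0.4, tolerance = 1e-6)
  expect_equal(dec$phi, -2, tolerance = 1e-5)
  expect_equal(dec$tau_f, 0.7, tolerance = 1e-5)
  expect_equal(dec$vartheta, 3, tolerance = 1e-5)
  expect_equal(dec$tau_s, 0.2, tolerance = 1e-5)
  expect_false(dec$degenerate)
})

test_that("flat choice coefficients give the flagged degenerate decay fit", {
  dec <- fit_decay_model(list(b_reward = 0.5 * 0.5^(0:9),
                              b_choice = rep(0, 10)))
  expect_true(dec$degenerate)
  expect_equal(dec$phi, 0)
  expect_equal(dec$vartheta, 0)
  expect_error(fit_decay_model(list(b_reward = rep(NA_real_, 10),
                                    b_choice = rep(1, 10))), "non-finite")
})

test_that("condition correlation returns exact self-correlation and rejects degenerate input", {
  set.seed(3)
  fits <- lapply(1:9, function(i) {
    s <- run_session(vi_agent("random"),
                     vi_schedule("fixed", lengths = 200,
                                 psets = list(c(0.2, 0.4))), seed = i)
    fit_history_glm(s, n_lags = 5)
  })
  b1 <- vapply(fits, function(f) {
    b <- tidy(f); b$estimate[b$block == "choice" & b$lag == 1]
  }, numeric(1))
  res <- condition_correlation(fits, b1, which = "choice")
  expect_equal(res$estimate, 1, tolerance = 1e-12)
  expect_equal(nrow(res$groups), 3L)
  expect_error(condition_correlation(fits, rep(1, 9)), "constant")
  expect_error(condition_correlation(fits[1:2], b1[1:2]), "at least 3")
})

test_that("smaller set-probability differences weaken the oracle's alternation", {
  fits <- lapply(c(0.2, 0.6), function(delta) {
    pair <- c(0.5 - delta / 2, 0.5 + delta / 2)
    s <- run_sessions(vi_agent("oracle"),
                      vi_schedule("fixed", lengths = 1000, psets = list(pair)),
                      3, seed = round(delta * 100))
    fit_history_glm(s, n_lags = 5)
  })
  b1 <- vapply(fits, function(f) {
    b <- tidy(f); b$estimate[b$block == "choice" & b$lag == 1]
  }, numeric(1))
  # under the deterministic greedy cycle the lag-1 coefficient is less
  # negative when the options are similar (weight spreads over the short
  # collinear cycle lags)
  expect_gt(b1[1], b1[2])
})
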