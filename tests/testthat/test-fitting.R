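test_that("likelihood of constant-probability and perfect predictors is exact", {
  h <- random_history(64, seed = 1)
  s <- history_session(h)
  # a zero-temperature DT model always emits P = 0.5
  ll <- session_log_likelihood("dt", list(alpha = 0.3, beta = 0, tau_f = 0.7,
                                          tau_s = 0.2, phi = -1, vartheta = 1), s)
  expect_equal(ll$total, -64 * log(2), tolerance = 1e-12)
  # oracle replay of its own deterministic session predicts every recorded
  # choice with probability one
  sch <- vi_schedule("fixed", lengths = 200, psets = list(c(0.1, 0.4)))
  os <- run_session(vi_agent("oracle"), sch, seed = 2)
  llo <- session_log_likelihood("oracle", list(), os)
  expect_equal(llo$total, 0)
})

test_that("out-of-box parameters are rejected", {
  s <- history_session(random_history(30, seed = 2))
  expect_error(session_log_likelihood("dt", list(alpha = 1.4, beta = 1,
                                                 tau_f = 0.5, tau_s = 0.1,
                                                 phi = 0, vartheta = 0), s),
               "alpha")
})

test_that("vectorised DT replay agrees with the generic trial loop", {
  set.seed(5)
  for (i in 1:10) {
    params <- list(alpha = runif(1), beta = runif(1, 0, 5),
                   tau_f = runif(1), tau_s = runif(1),
                   phi = runif(1, -3, 0), vartheta = runif(1, 0, 3))
    h <- random_history(300, seed = 100 + i)
    s <- history_session(h)
    fast <- replay_probabilities("dt", params, s)
    agent <- do.call(vi_agent, c(list(model = "dt"), params))
    slow <- vitrace:::loop_replay(agent, h$choice, h$reward)
    expect_equal(fast, slow, tolerance = 1e-12)
    pi <- list(alpha = params$alpha, beta = params$beta)
    fast_i <- replay_probabilities("indirect", pi, s)
    slow_i <- vitrace:::loop_replay(vi_agent("indirect", alpha = pi$alpha,
                                             beta = pi$beta),
                                    h$choice, h$reward)
    expect_equal(fast_i, slow_i, tolerance = 1e-12)
  }
})

test_that("the generating parameters dominate perturbed ones in likelihood", {
  params <- mouse_dt_params
  sch <- vi_schedule("alternating", pair = c(0.4, 0.1))
  s <- run_sessions(do.call(vi_agent, c(list(model = "dt"), params)),
                    sch, 20, seed = 77)
  bad <- params; bad$alpha <- params$alpha - 0.3
  expect_gt(session_log_likelihood("dt", params, s)$total,
            session_log_likelihood("dt", bad, s)$total)
})

test_that("annealing search matches an exhaustive grid oracle on a 2-parameter model", {
  sch <- vi_schedule("alternating", pair = c(0.4, 0.1), n_trials = 400)
  s <- run_session(vi_agent("fq", alpha = 0.6, beta = 3), sch, seed = 12)
  grid <- expand.grid(alpha = seq(0.01, 0.99, length.out = 41),
                      beta = seq(0.1, 20, length.out = 41))
  grid_ll <- vapply(seq_len(nrow(grid)), function(i) {
    session_log_likelihood("fq", as.list(grid[i, ]), s)$total
  }, numeric(1))
  bounds <- tibble::tibble(name = c("alpha", "beta"), lower = c(0, 0),
                           upper = c(1, 20))
  fit <- anneal_fit("fq", s, bounds = bounds, n_draws = 300, max_iter = 15,
                    seed = 3)
  expect_gte(fit$logLik, max(grid_ll) - 0.05)
})

test_that("annealing is reproducible and its best likelihood does not degrade", {
  s <- history_session(random_history(150, seed = 8))
  f1 <- anneal_fit("fq", s, n_draws = 100, max_iter = 6, seed = 21)
  f2 <- anneal_fit("fq", s, n_draws = 100, max_iter = 6, seed = 21)
  expect_identical(f1$theta_hat, f2$theta_hat)
  expect_gte(dplyr::last(f1$trace$best_mean_ll),
             dplyr::first(f1$trace$best_mean_ll))
  expect_true(all(f1$theta_hat >= f1$bounds$lower &
                  f1$theta_hat <= f1$bounds$upper))
})

test_that("AUC matches hand counts, the pair-counting oracle, and rejects one-class input", {
  expect_equal(auc_score(c(0.9, 0.8, 0.3), c(1, 0, 0)), 1)
  expect_equal(auc_score(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  expect_equal(auc_score(c(0.9, 0.8, 0.3), c(0, 1, 1)), 0)
  expect_equal(auc_score(c(0.5, 0.5, 0.2), c(1, 0, 0)), 0.75)  # tie -> half
  expect_error(auc_score(c(0.1, 0.2), c(1, 1)), "one class")
  set.seed(9)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    sc <- round(runif(n), 2)            # rounding forces ties
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(auc_score(sc, lb), auc_pairs(sc, lb))
  }
})

test_that("cross-validation pairs folds across models and ranks the generator best", {
  params <- mouse_dt_params
  s <- run_sessions(do.call(vi_agent, c(list(model = "dt"), params)),
                    vi_schedule("alternating", pair = c(0.4, 0.1),
                                n_trials = 400), 6, seed = 31)
  cv <- crossval_compare(c("dt", "fq", "indirect"), s, n_folds = 5,
                         n_draws = 150, max_iter = 8, seed = 5)
  expect_s3_class(cv, "vi_cv")
  expect_true(all(cv$mean_test_nll > 0))
  expect_true(all(cv$mean_test_auc >= 0 & cv$mean_test_auc <= 1))
  # the fold partition is identical for every model
  folds <- lapply(cv$per_fold, function(p) p$fold)
  expect_identical(folds[[1]], folds[[2]])
  expect_identical(folds[[1]], folds[[3]])
  # data generated with strong choice traces: DT must beat the trace-free
  # models on held-out likelihood
  nll <- setNames(cv$mean_test_nll, cv$model)
  expect_lt(nll[["dt"]], nll[["fq"]])
  expect_lt(nll[["dt"]], nll[["indirect"]])
})

test_that("fit bounds expose the documented boxes", {
  b <- fit_bounds("dt", "behavior")
  expect_equal(b$upper[b$name == "beta"], 50)
  expect_equal(sort(b$name),
               sort(c("alpha", "beta", "tau_f", "tau_s", "phi", "vartheta")))
  r <- fit_bounds("dt", "recovery")
  expect_equal(r$lower[r$name == "phi"], -4)
  expect_equal(r$upper[r$name == "vartheta"], 4)
  h <- fit_bounds("dt", "harvest")
  expect_equal(h$upper[h$name == "beta"], 10)
  expect_equal(h$upper[h$name == "phi"], 0)
  expect_error(fit_bounds("ib"), "IB")
  expect_error(fit_bounds("fq", "recovery"), "DT")
})
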