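#' Build the lagged design matrix for choice-history regression
#'
#' For each usable trial `t` (the first `n_lags` trials of every session are
#' dropped, so lags never cross session boundaries) the basic design holds
#' signed reward regressors `R(t - 1) ... R(t - M)` with
#' `R = R_right - R_left` in \{-1, 0, 1\} and choice regressors
#' `C(t - 1) ... C(t - M)` in \{0, 1\}; the response is the current choice
#' `C(t)`.
#'
#' @param sessions Session tibble (optionally with a `session` column).
#' @param n_lags Number of history lags M.
#' @return Object of class `vi_design`: list with the model matrix `x`,
#'   response `y`, `n_lags`, the ordered `blocks` (named column groups) and
#'   the per-row session id.
#' @export
build_design <- function(sessions, n_lags = 15) {
  lag_design(sessions, n_lags, extended = FALSE)
}

#' Build the extended lagged design
#'
#' Six regressor blocks, in order: unsigned rewards
#' (`R_right + R_left`), choices, right rewards, left rewards, right
#' no-rewards (1 when right was chosen and unrewarded) and left no-rewards.
#'
#' @inheritParams build_design
#' @export
build_extended_design <- function(sessions, n_lags = 30) {
  lag_design(sessions, n_lags, extended = TRUE)
}

lag_design <- function(sessions, n_lags, extended) {
  if (n_lags < 1) abort("`n_lags` must be at least 1")
  sid <- sessions[["session"]] %||% rep(1L, nrow(sessions))
  parts <- list()
  skipped <- character(0)
  for (id in unique(sid)) {
    ix <- which(sid == id)
    if (length(ix) <= n_lags) {
      skipped <- c(skipped, as.character(id))
      next
    }
    ch <- sessions$choice[ix]
    rw <- sessions$reward[ix]
    r_right <- rw * (ch == 1)
    r_left <- rw * (ch == 0)
    regs <- if (extended) {
      list(unsigned_reward = r_right + r_left,
           choice = ch,
           reward_right = r_right,
           reward_left = r_left,
           noreward_right = as.numeric(ch == 1 & rw == 0),
           noreward_left = as.numeric(ch == 0 & rw == 0))
    } else {
      list(reward = r_right - r_left, choice = ch)
    }
    t_use <- (n_lags + 1L):length(ix)
    cols <- lapply(regs, function(v) {
      sapply(seq_len(n_lags), function(m) v[t_use - m])
    })
    x <- do.call(cbind, cols)
    colnames(x) <- unlist(lapply(names(regs), function(b)
      paste0(b, "_", seq_len(n_lags))))
    parts[[as.character(id)]] <- list(x = x, y = ch[t_use],
                                      session = rep(id, length(t_use)))
  }
  if (length(skipped) > 0L) {
    warn(sprintf("skipping session(s) shorter than n_lags + 1: %s",
                 paste(skipped, collapse = ", ")))
  }
  if (length(parts) == 0L) abort("no session is longer than `n_lags`")
  blocks <- if (extended) {
    c("unsigned_reward", "choice", "reward_right", "reward_left",
      "noreward_right", "noreward_left")
  } else {
    c("reward", "choice")
  }
  structure(
    list(x = do.call(rbind, lapply(parts, `[[`, "x")),
         y = unlist(lapply(parts, `[[`, "y"), use.names = FALSE),
         session = unlist(lapply(parts, `[[`, "session"), use.names = FALSE),
         n_lags = n_lags, blocks = blocks, extended = extended),
    class = "vi_design")
}

default_lambda_grid <- function() {
  exp(seq(log(1e-4), log(10), length.out = 50))
}

#' Fit the cross-validated elastic-net history regression
#'
#' Penalised logistic regression of the current choice on the lagged design,
#' with penalty `lambda * (0.25 * sum(b^2) + 0.5 * sum(|b|))` (elastic-net
#' mixing 0.5; the intercept is never penalised). `lambda` is chosen at the
#' minimum mean binomial deviance over `n_folds` contiguous cross-validation
#' folds, then the coefficients are refit on all rows at that `lambda`.
#'
#' @param design A `vi_design` from [build_design()] /
#'   [build_extended_design()].
#' @param lambda Decreasing grid of penalty values (default: 50 values
#'   log-spaced on \[1e-4, 10\]).
#' @param n_folds Number of CV folds (contiguous row blocks).
#' @param seed Optional seed (fold bookkeeping only; folds are
#'   deterministic).
#' @return Object of class `vi_histfit`: tidy coefficient table, intercept,
#'   selected `lambda`, CV deviance path.
#' @export
fit_elastic_net <- function(design, lambda = default_lambda_grid(),
                            n_folds = 5, seed = NULL) {
  stopifnot(inherits(design, "vi_design"))
  y <- design$y
  if (length(unique(y)) < 2L) {
    abort(sprintf(
      "single-class response: session(s) %s contain only one choice",
      paste(unique(design$session), collapse = ", ")))
  }
  lambda <- sort(lambda, decreasing = TRUE)
  foldid <- contiguous_folds(length(y), n_folds)
  cv <- with_seed(seed, glmnet::cv.glmnet(
    design$x, y, family = "binomial", alpha = 0.5, lambda = lambda,
    foldid = foldid, standardize = FALSE, type.measure = "deviance"))
  sel <- cv$lambda.min
  co <- as.numeric(stats::coef(cv, s = sel))
  names(co) <- c("(Intercept)", colnames(design$x))
  term <- colnames(design$x)
  block <- sub("_[0-9]+$", "", term)
  lag <- as.integer(sub("^.*_", "", term))
  structure(
    list(coef = tibble::tibble(term = term,
                               block = factor(block, levels = design$blocks),
                               lag = lag, estimate = unname(co[-1])),
         intercept = co[[1]],
         lambda = sel,
         cv_deviance = tibble::tibble(lambda = cv$lambda,
                                      deviance = cv$cvm),
         n_lags = design$n_lags,
         n_obs = length(y),
         extended = design$extended),
    class = "vi_histfit")
}

#' @export
print.vi_histfit <- function(x, ...) {
  cat(sprintf("<vi_histfit: %d lags, %d rows, lambda = %.4g>\n",
              x$n_lags, x$n_obs, x$lambda))
  print(utils::head(tidyr::pivot_wider(x$coef[, c("block", "lag", "estimate")],
                                       names_from = "block",
                                       values_from = "estimate"), 10))
  invisible(x)
}

#' One-call history regression on sessions
#'
#' Convenience wrapper: [build_design()] (or the extended design) followed
#' by [fit_elastic_net()].
#'
#' @inheritParams build_design
#' @inheritParams fit_elastic_net
#' @param extended Use the six-block extended design.
#' @return A `vi_histfit`.
#' @examples
#' \donttest{
#' s <- run_sessions(vi_agent("random"), vi_schedule("mouse", seed = 1), 2, seed = 1)
#' fit_history_glm(s, n_lags = 5)
#' }
#' @export
fit_history_glm <- function(sessions, n_lags = if (extended) 30 else 15,
                            extended = FALSE,
                            lambda = default_lambda_grid(), n_folds = 5,
                            seed = NULL) {
  design <- if (extended) build_extended_design(sessions, n_lags)
            else build_design(sessions, n_lags)
  fit_elastic_net(design, lambda = lambda, n_folds = n_folds, seed = seed)
}

# coefficient vector of one block, ordered by lag
histfit_block <- function(fit, block) {
  co <- dplyr::arrange(dplyr::filter(fit$coef, .data$block == !!block),
                       .data$lag)
  co$estimate
}

#' Fit exponential decay models to regression coefficients
#'
#' Least squares of the single-exponential reward decay
#' `b_R(m) = alpha * (1 - alpha)^(m - 1)` to the reward coefficients, and of
#' the two-exponential choice decay
#' `b_C(m) = phi * tau_f * (1 - tau_f)^(m - 1) +
#'   vartheta * tau_s * (1 - tau_s)^(m - 1)`
#' (the form implied by the recursive choice traces) to the choice
#' coefficients, by box-constrained multistart optimisation. Components are
#' relabelled so that `tau_f >= tau_s`. An all-zero choice profile is
#' returned as the flagged degenerate fit `phi = vartheta = 0`.
#'
#' @param fit A `vi_histfit`, or a list with numeric `b_reward` and
#'   `b_choice` lag profiles.
#' @return Tibble with one row: `alpha`, `phi`, `tau_f`, `vartheta`,
#'   `tau_s`, `degenerate`.
#' @export
fit_decay_model <- function(fit) {
  if (inherits(fit, "vi_histfit")) {
    b_reward <- histfit_block(fit, "reward")
    b_choice <- histfit_block(fit, "choice")
  } else {
    b_reward <- fit$b_reward
    b_choice <- fit$b_choice
  }
  if (length(b_choice) < 5L) abort("need at least 5 lags to fit the decays")
  if (anyNA(b_reward) || anyNA(b_choice) ||
      any(!is.finite(c(b_reward, b_choice)))) {
    abort("non-finite regression coefficients")
  }
  m <- seq_along(b_reward)
  alpha <- optimize(function(a) sum((b_reward - a * (1 - a)^(m - 1))^2),
                    c(0, 1), tol = 1e-10)$minimum
  mc <- seq_along(b_choice)
  if (all(abs(b_choice) < 1e-12)) {
    return(tibble::tibble(alpha = alpha, phi = 0, tau_f = NA_real_,
                          vartheta = 0, tau_s = NA_real_, degenerate = TRUE))
  }
  # variable projection: for fixed decay rates the scalings are a linear
  # least-squares solve, leaving a smooth 2-D search over the rates
  basis <- function(tau) tau * (1 - tau)^(mc - 1)
  amps <- function(taus) {
    X <- cbind(basis(taus[1]), basis(taus[2]))
    qr.coef(qr(X), b_choice)
  }
  obj <- function(taus) {
    a <- amps(taus)
    if (anyNA(a)) return(sum(b_choice^2))
    sum((b_choice - cbind(basis(taus[1]), basis(taus[2])) %*% a)^2)
  }
  starts <- expand.grid(tau_f = c(0.3, 0.5, 0.7, 0.9),
                        tau_s = c(0.02, 0.1, 0.2, 0.4))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                 lower = c(1e-6, 1e-6), upper = c(1, 1),
                 control = list(maxit = 1000, factr = 1))
    if (is.null(best) || res$value < best$value) best <- res
  }
  taus <- best$par
  a <- amps(taus)
  a[is.na(a)] <- 0
  par <- c(a[1], taus[1], a[2], taus[2])
  if (par[2] < par[4]) par <- par[c(3, 4, 1, 2)]
  tibble::tibble(alpha = alpha, phi = par[1], tau_f = par[2],
                 vartheta = par[3], tau_s = par[4], degenerate = FALSE)
}

#' Correlate lag-1 history coefficients with a session-level covariate
#'
#' The session-sorting analysis: Pearson correlation of the lag-1 regression
#' coefficient (reward or choice) across per-session fits against a
#' per-session covariate (block length, set-probability difference, reward
#' rate, ...), with tercile group summaries.
#'
#' @param fits List of per-session `vi_histfit` objects.
#' @param covariate Numeric per-session covariate, same length as `fits`.
#' @param which `"choice"` or `"reward"`: which lag-1 coefficient to use.
#' @return List with `estimate` (r), `p.value`, `coef_lag1`, and a `groups`
#'   tibble of tercile means.
#' @export
condition_correlation <- function(fits, covariate,
                                  which = c("choice", "reward")) {
  which <- match.arg(which)
  if (length(fits) < 3L) abort("need at least 3 session fits")
  if (length(covariate) != length(fits)) abort("covariate length mismatch")
  if (sd(covariate) == 0) abort("constant covariate")
  b1 <- vapply(fits, function(f) histfit_block(f, which)[1], numeric(1))
  ct <- cor.test(b1, covariate, method = "pearson")
  # rank-based terciles are robust to tied covariate values
  tercile <- cut(rank(covariate, ties.method = "first"), breaks = 3,
                 labels = c("low", "mid", "high"))
  groups <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(tercile = tercile, coef = b1), tercile),
    mean = mean(coef), sd = sd(coef), n = dplyr::n(), .groups = "drop")
  list(estimate = unname(ct$estimate), p.value = ct$p.value,
       coef_lag1 = b1, groups = groups)
}
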