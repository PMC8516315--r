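#' Regret of recorded sessions
#'
#' Regret is the cumulative maximal expected reward minus the rewards
#' actually collected. Two baselines are available:
#' \describe{
#'   \item{`"trajectory"`}{(default) `mu_star` sums, along the realised
#'     trajectory, the larger of the two true momentary probabilities at
#'     every trial.}
#'   \item{`"oracle_run"`}{`mu_star` is the reward total of an independent
#'     greedy Oracle simulation on the same block schedule.}
#' }
#'
#' @param sessions Session tibble carrying the true probability columns
#'   `p_0`, `p_1` (simulated sessions record them).
#' @param mode `"trajectory"`, `"oracle_run"`, or `"both"`.
#' @param seed Seed for the Oracle baseline runs.
#' @return Tibble of class `vi_regret`, one row per session and mode:
#'   `session`, `baseline_mode`, `mu_star`, `collected`, `regret`,
#'   `n_trials`, and a `per_trial` list-column with the trialwise
#'   decomposition (`max_p`, `reward`).
#' @export
regret <- function(sessions, mode = c("trajectory", "oracle_run", "both"),
                   seed = NULL) {
  mode <- match.arg(mode)
  if (!all(c("p_0", "p_1") %in% names(sessions))) {
    abort("regret needs the true probability trace (columns p_0, p_1)")
  }
  sid <- sessions[["session"]] %||% rep(1L, nrow(sessions))
  ids <- unique(sid)
  seeds <- derive_seeds(seed, length(ids), stream = 23L)
  rows <- purrr::map2(ids, seeds, function(id, s) {
    d <- sessions[sid == id, ]
    maxp <- pmax(d$p_0, d$p_1)
    collected <- sum(d$reward)
    out <- list()
    if (mode %in% c("trajectory", "both")) {
      out$trajectory <- tibble::tibble(
        session = id, baseline_mode = "trajectory",
        mu_star = sum(maxp), collected = collected,
        regret = sum(maxp) - collected, n_trials = nrow(d),
        per_trial = list(tibble::tibble(max_p = maxp, reward = d$reward)))
    }
    if (mode %in% c("oracle_run", "both")) {
      sch <- schedule_from_session(d)
      ob <- run_session(vi_agent("oracle"), sch, seed = s)
      out$oracle <- tibble::tibble(
        session = id, baseline_mode = "oracle_run",
        mu_star = sum(ob$reward), collected = collected,
        regret = sum(ob$reward) - collected, n_trials = nrow(d),
        per_trial = list(tibble::tibble(max_p = pmax(ob$p_0, ob$p_1),
                                        reward = d$reward)))
    }
    dplyr::bind_rows(out)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("vi_regret", class(out))
  out
}

# Rebuild a block schedule from a recorded session's pset columns.
schedule_from_session <- function(d) {
  if (!all(c("block", "pset_0", "pset_1") %in% names(d))) {
    abort("session lacks block/pset columns")
  }
  firsts <- !duplicated(d$block)
  vi_schedule("fixed",
              lengths = as.integer(table(factor(d$block,
                                                levels = d$block[firsts]))),
              psets = lapply(which(firsts), function(i)
                c(d$pset_0[i], d$pset_1[i])))
}

#' Named harvesting conditions
#'
#' Builds the alternating-block environments used for regret optimisation:
#' \describe{
#'   \item{`"volatility"`}{set pair 0.10:0.40 (and its mirror) with block
#'     length 50, 100 or 500.}
#'   \item{`"delta_methods"`}{block length 100, pairs 0.20:0.80, 0.30:0.70
#'     or 0.40:0.60.}
#'   \item{`"delta_fig4"`}{block length 100, pairs 0.45:0.05, 0.40:0.10 or
#'     0.35:0.15.}
#' }
#'
#' @param type Condition family.
#' @param block_length Block length (volatility condition).
#' @param pair Probability pair (delta conditions); defaults to the middle
#'   pair of the family.
#' @param n_trials Session length.
#' @return List with the `vi_schedule` and a descriptive `name`.
#' @export
harvest_condition <- function(type = c("volatility", "delta_methods",
                                       "delta_fig4"),
                              block_length = 100, pair = NULL,
                              n_trials = 1000) {
  type <- match.arg(type)
  if (type == "volatility") {
    if (!block_length %in% c(50, 100, 500)) {
      abort("volatility condition uses block lengths 50, 100 or 500")
    }
    pair <- pair %||% c(0.10, 0.40)
  } else {
    allowed <- if (type == "delta_methods") {
      list(c(0.20, 0.80), c(0.30, 0.70), c(0.40, 0.60))
    } else {
      list(c(0.45, 0.05), c(0.40, 0.10), c(0.35, 0.15))
    }
    pair <- pair %||% allowed[[2]]
    ok <- any(vapply(allowed, function(a)
      isTRUE(all.equal(sort(a), sort(pair))), logical(1)))
    if (!ok) abort("`pair` is not one of the condition's probability pairs")
    block_length <- 100
  }
  list(
    schedule = vi_schedule("alternating", pair = pair,
                           block_length = block_length, n_trials = n_trials),
    name = sprintf("%s:block=%d,pair=%.2f:%.2f", type, block_length,
                   pair[1], pair[2])
  )
}

#' Regret-minimising parameter search in a simulated environment
#'
#' Two-stage sampling search: stage 1 draws `n_initial` parameter vectors
#' uniformly in the bounds and scores each by mean regret over `n_sessions`
#' closed-loop sessions (fresh seeds per draw); the lowest-regret
#' `keep_frac1` are kept. Stage 2 draws `n_refine` Gaussian vectors around
#' the kept set (3 SD spread, clipped to the bounds), keeps the lowest
#' `keep_frac2`, re-tests each survivor `n_retest` times, and returns the
#' vector with the lowest mean regret.
#'
#' @param model Model name (`dt`, `fq`, `fq_wc`, `lk`, `indirect`,
#'   `direct`, `fq_up`).
#' @param condition A [harvest_condition()] (or a `vi_schedule`).
#' @param bounds Bounds tibble, default `fit_bounds(model, "harvest")` (for
#'   DT this enforces the animal sign constraints `phi <= 0`,
#'   `vartheta >= 0`).
#' @param n_initial,n_refine Stage draw counts.
#' @param keep_frac1,keep_frac2 Elite fractions per stage.
#' @param n_retest Re-evaluations per finalist.
#' @param n_sessions Sessions per evaluation.
#' @param seed Master seed; per-draw evaluation seeds are derived from it.
#' @return Object of class `vi_opt`: `theta_star`, `mean_regret` (over the
#'   final re-tests), `condition`, `bounds`, `trace`.
#' @export
optimize_in_env <- function(model, condition,
                            bounds = fit_bounds(model, "harvest"),
                            n_initial = 10000, n_refine = 5000,
                            keep_frac1 = 0.05, keep_frac2 = 0.10,
                            n_retest = 100, n_sessions = 4, seed = NULL) {
  schedule <- if (inherits(condition, "vi_schedule")) {
    condition <- list(schedule = condition, name = "custom")
    condition$schedule
  } else {
    condition$schedule
  }
  p <- nrow(bounds)
  if (p == 0L) abort(sprintf("model '%s' has no parameters to optimise", model))
  with_seed(seed, {
    draw1 <- matrix(runif(n_initial * p, rep(bounds$lower, each = n_initial),
                          rep(bounds$upper, each = n_initial)),
                    nrow = n_initial, dimnames = list(NULL, bounds$name))
    r1 <- batch_mean_regret(model, draw1, schedule, n_sessions,
                            seed = if (is.null(seed)) NULL else seed + 1L)
    k1 <- max(2L, ceiling(keep_frac1 * n_initial))
    elite1 <- draw1[order(r1)[seq_len(k1)], , drop = FALSE]
    mu <- colMeans(elite1)
    sg <- apply(elite1, 2, sd)
    draw2 <- matrix(rnorm(n_refine * p, rep(mu, each = n_refine),
                          rep(pmax(3 * sg, 1e-8), each = n_refine)),
                    nrow = n_refine, dimnames = list(NULL, bounds$name))
    draw2 <- pmin(pmax(draw2, rep(bounds$lower, each = n_refine)),
                  rep(bounds$upper, each = n_refine))
    r2 <- batch_mean_regret(model, draw2, schedule, n_sessions,
                            seed = if (is.null(seed)) NULL else seed + 2L)
    k2 <- max(1L, ceiling(keep_frac2 * n_refine))
    finalists <- draw2[order(r2)[seq_len(k2)], , drop = FALSE]
    # each finalist re-tested n_retest times under fresh scenarios
    rep_draws <- finalists[rep(seq_len(k2), each = n_retest), , drop = FALSE]
    rr <- batch_mean_regret(model, rep_draws, schedule, n_sessions = 1,
                            seed = if (is.null(seed)) NULL else seed + 3L)
    mean_rr <- colMeans(matrix(rr, nrow = n_retest))
    best <- which.min(mean_rr)
    structure(
      list(model = model,
           theta_star = finalists[best, ],
           mean_regret = mean_rr[best],
           condition = condition$name,
           bounds = bounds,
           trace = tibble::tibble(
             stage = c("initial", "refine", "retest"),
             n = c(n_initial, n_refine, k2 * n_retest),
             best_regret = c(min(r1), min(r2), min(mean_rr)))),
      class = "vi_opt")
  })
}

#' @export
print.vi_opt <- function(x, ...) {
  cat(sprintf("<vi_opt: %s on %s>  mean regret = %.2f\n",
              x$model, x$condition, x$mean_regret))
  print(round(x$theta_star, 4))
  invisible(x)
}

#' Implied history-coefficient curves of DT parameters
#'
#' The lag profiles implied by a DT parameter vector:
#' `b_R(m) = alpha * (1 - alpha)^(m - 1)` for rewards and
#' `b_C(m) = phi * tau_f * (1 - tau_f)^(m - 1) +
#'   vartheta * tau_s * (1 - tau_s)^(m - 1)` for choices (the expansion of
#' the recursive choice traces).
#'
#' @param params Named DT parameters (`alpha`, `tau_f`, `tau_s`, `phi`,
#'   `vartheta`; `beta` ignored).
#' @param n_lags Number of lags.
#' @return Tibble with `lag`, `b_reward`, `b_choice`.
#' @export
trace_shapes <- function(params, n_lags = 15) {
  params <- as.list(params)
  m <- seq_len(n_lags)
  tibble::tibble(
    lag = m,
    b_reward = params$alpha * (1 - params$alpha)^(m - 1),
    b_choice = params$phi * params$tau_f * (1 - params$tau_f)^(m - 1) +
      params$vartheta * params$tau_s * (1 - params$tau_s)^(m - 1)
  )
}
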