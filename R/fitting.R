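#' Parameter bounds for model fitting
#'
#' Three presets:
#' \describe{
#'   \item{`"behavior"`}{the wide box used when fitting behavioural data:
#'     learning rates in \[0, 1\], `beta` in \[0, 50\], trace scalings and the
#'     extra scalar (direct actor `offset`, fq_up `cap`) in \[-25, 25\].}
#'   \item{`"recovery"`}{the DT parameter-recovery box: `alpha`, `tau_f`,
#'     `tau_s` in \[0, 1\], `beta`, `vartheta` in \[0, 4\], `phi` in
#'     \[-4, 0\]. DT only.}
#'   \item{`"harvest"`}{the box used for regret optimisation: `beta` in
#'     \[0, 10\], `phi` in \[-2, 0\], `vartheta` in \[0, 2\], rates in
#'     \[0, 1\]; the extra scalars of the comparison models are kept on the
#'     reward scale \[0, 1\].}
#' }
#'
#' @param model Model name.
#' @param preset One of `"behavior"`, `"recovery"`, `"harvest"`.
#' @return Tibble with columns `name`, `lower`, `upper`.
#' @export
fit_bounds <- function(model, preset = c("behavior", "recovery", "harvest")) {
  preset <- match.arg(preset)
  spec <- model_param_spec(model)
  if (model %in% c("oracle", "random")) {
    return(tibble::tibble(name = character(), lower = numeric(),
                          upper = numeric()))
  }
  if (model == "ib") abort("the IB agent is not fitted by likelihood search")
  if (preset == "recovery") {
    if (model != "dt") abort("the recovery preset is defined for the DT model")
    return(tibble::tibble(
      name = c("alpha", "beta", "tau_f", "tau_s", "phi", "vartheta"),
      lower = c(0, 0, 0, 0, -4, 0),
      upper = c(1, 4, 1, 1, 0, 4)))
  }
  beta_hi <- if (preset == "behavior") 50 else 10
  extra <- if (preset == "behavior") c(-25, 25) else c(0, 1)
  lo <- c(alpha = 0, beta = 0, tau_f = 0, tau_s = 0, tau_psi = 0,
          phi = if (preset == "behavior") -25 else -2,
          vartheta = if (preset == "behavior") -25 else 0,
          offset = extra[1], cap = extra[1], alpha_up = 0)
  hi <- c(alpha = 1, beta = beta_hi, tau_f = 1, tau_s = 1, tau_psi = 1,
          phi = if (preset == "behavior") 25 else 0,
          vartheta = if (preset == "behavior") 25 else 2,
          offset = extra[2], cap = extra[2], alpha_up = 1)
  nm <- setdiff(spec$name, c("n_particles", "jitter"))
  tibble::tibble(name = nm, lower = unname(lo[nm]), upper = unname(hi[nm]))
}

#' Bernoulli log-likelihood of recorded choices under a model
#'
#' Teacher-forced replay ([replay_probabilities()]): per trial the model's
#' probability of the recorded choice enters a Bernoulli log-likelihood.
#' Probabilities are clamped to \[1e-12, 1 - 1e-12\] before the log.
#'
#' @inheritParams replay_probabilities
#' @param mask Optional logical vector (one per row) restricting which
#'   trials contribute to the total (replay always runs over all trials so
#'   the state stays faithful to the history).
#' @return List with `total`, `mean` (per contributing trial) and
#'   `per_trial` log-likelihood vector.
#' @export
session_log_likelihood <- function(model, params, sessions, mask = NULL,
                                   seed = NULL) {
  check_params_in_box(model, params)
  p_right <- replay_probabilities(model, params, sessions, seed = seed)
  p_choice <- ifelse(sessions$choice == 1, p_right, 1 - p_right)
  ll <- log(pmin(pmax(p_choice, 1e-12), 1 - 1e-12))
  use <- mask %||% rep(TRUE, length(ll))
  list(total = sum(ll[use]), mean = mean(ll[use]), per_trial = ll)
}

check_params_in_box <- function(model, params) {
  params <- as.list(params)
  spec <- model_param_spec(model)
  for (i in seq_len(nrow(spec))) {
    v <- params[[spec$name[i]]]
    if (is.null(v)) next
    if (v < spec$lower[i] || v > spec$upper[i]) {
      abort(sprintf("parameter '%s' = %g outside [%g, %g]",
                    spec$name[i], v, spec$lower[i], spec$upper[i]))
    }
  }
  invisible(params)
}

# Mean log-likelihood per draw for a matrix of parameter draws (rows),
# evaluated against a precomputed replay context.
draws_log_likelihood <- function(ctx, draws, seed) {
  seeds <- derive_seeds(seed, nrow(draws), stream = 17L)
  vapply(seq_len(nrow(draws)), function(i) {
    res <- try(ctx_mean_ll(as.list(draws[i, ]), ctx, seed = seeds[[i]]),
               silent = TRUE)
    if (inherits(res, "try-error") || !is.finite(res)) -Inf else res
  }, numeric(1))
}

#' Annealing-style likelihood search
#'
#' Iterates: draw `n_draws` parameter vectors (uniform in the bounds on the
#' first pass, Gaussian around the elite of the previous pass afterwards,
#' clipped to the bounds), evaluate the mean per-trial log-likelihood of
#' each, keep the top `top_frac`, and resample around their mean and SD.
#' Stops when the best log-likelihood changes by less than `tol` in relative
#' magnitude for two consecutive iterations, or after `max_iter` iterations.
#'
#' @inheritParams session_log_likelihood
#' @param bounds Bounds tibble from [fit_bounds()].
#' @param n_draws Draws per iteration.
#' @param top_frac Elite fraction resampled around.
#' @param tol Relative-change convergence tolerance.
#' @param max_iter Iteration cap.
#' @return Object of class `vi_fit`: list with `model`, `theta_hat` (named
#'   vector, best draw of the final iteration), `logLik` (its total
#'   log-likelihood), `mean_ll`, `trace` (per-iteration best mean LL),
#'   `converged`, `bounds`.
#' @examples
#' \donttest{
#' s <- run_sessions(vi_agent("dt"), vi_schedule("mouse", seed = 1), 2, seed = 1)
#' anneal_fit("fq", s, n_draws = 100, max_iter = 5, seed = 1)
#' }
#' @export
anneal_fit <- function(model, sessions, bounds = fit_bounds(model),
                       n_draws = 1000, top_frac = 0.01, tol = 1e-4,
                       max_iter = 50, mask = NULL, seed = NULL) {
  if (nrow(bounds) == 0L) abort(sprintf("model '%s' has no free parameters", model))
  ctx <- make_replay_ctx(model, sessions, mask = mask)
  p <- nrow(bounds)
  k <- max(2L, ceiling(top_frac * n_draws))
  trace <- numeric(0)
  best_prev <- NA_real_
  hits <- 0L
  draws <- NULL
  with_seed(seed, {
    mu <- NULL; sg <- NULL
    for (iter in seq_len(max_iter)) {
      draws <- if (is.null(mu)) {
        matrix(runif(n_draws * p, rep(bounds$lower, each = n_draws),
                     rep(bounds$upper, each = n_draws)),
               nrow = n_draws, dimnames = list(NULL, bounds$name))
      } else {
        d <- matrix(rnorm(n_draws * p, rep(mu, each = n_draws),
                          rep(pmax(sg, 1e-8), each = n_draws)),
                    nrow = n_draws, dimnames = list(NULL, bounds$name))
        pmin(pmax(d, rep(bounds$lower, each = n_draws)),
             rep(bounds$upper, each = n_draws))
      }
      ll <- draws_log_likelihood(ctx, draws,
                                 seed = if (is.null(seed)) NULL else seed + iter)
      if (all(!is.finite(ll))) abort("likelihood non-finite for every draw")
      ord <- order(ll, decreasing = TRUE)
      elite <- draws[ord[seq_len(k)], , drop = FALSE]
      mu <- colMeans(elite)
      sg <- apply(elite, 2, sd)
      sg[!is.finite(sg)] <- 1e-8
      best <- ll[ord[1]]
      trace <- c(trace, best)
      if (!is.na(best_prev) && best_prev < 0 &&
          abs(best - best_prev) < tol * abs(best_prev)) {
        hits <- hits + 1L
      } else {
        hits <- 0L
      }
      best_prev <- best
      if (hits >= 2L) break
    }
    theta <- draws[order(ll, decreasing = TRUE)[1], ]
    final <- session_log_likelihood(model, as.list(theta), sessions,
                                    mask = mask,
                                    seed = if (is.null(seed)) NULL else seed)
    structure(
      list(model = model, theta_hat = theta, logLik = final$total,
           mean_ll = final$mean,
           trace = tibble::tibble(iteration = seq_along(trace),
                                  best_mean_ll = trace),
           converged = hits >= 2L, bounds = bounds),
      class = "vi_fit")
  })
}

#' @export
print.vi_fit <- function(x, ...) {
  cat(sprintf("<vi_fit: %s>  logLik = %.3f (%s)\n", x$model, x$logLik,
              if (x$converged) "converged" else "iteration cap"))
  print(round(x$theta_hat, 4))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank (Mann--Whitney) formulation: the probability that a random positive
#' outscores a random negative, ties counted one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1); both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_score(c(0.9, 0.8, 0.3), c(1, 0, 0))
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels)) abort("length mismatch")
  if (!all(labels %in% c(0, 1))) abort("`labels` must be 0/1")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    abort("AUC undefined: only one class present")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Cross-validated model comparison
#'
#' Concatenated trials are split into `n_folds` contiguous folds (shared
#' across models). For each fold, [anneal_fit()] is run on the remaining
#' trials and the held-out fold is scored by mean per-trial negative
#' log-likelihood and AUC (score = predicted probability of "right", label =
#' the recorded choice).
#'
#' @inheritParams anneal_fit
#' @param models Character vector of model names.
#' @param n_folds Number of folds.
#' @param bounds_preset Preset passed to [fit_bounds()].
#' @return Tibble of class `vi_cv` with per-model `mean_test_nll`,
#'   `mean_test_auc`, and a `per_fold` list-column of fold-level metrics.
#' @export
crossval_compare <- function(models, sessions, n_folds = 5, n_draws = 1000,
                             max_iter = 50, bounds_preset = "behavior",
                             seed = NULL) {
  n <- nrow(sessions)
  fold <- contiguous_folds(n, n_folds)
  rows <- purrr::imap(models, function(model, im) {
    per_fold <- purrr::map(seq_len(n_folds), function(f) {
      train <- fold != f
      fit <- anneal_fit(model, sessions,
                        bounds = fit_bounds(model, bounds_preset),
                        n_draws = n_draws, max_iter = max_iter, mask = train,
                        seed = if (is.null(seed)) NULL else seed + 131L * f)
      p_right <- replay_probabilities(model, as.list(fit$theta_hat), sessions,
                                      seed = if (is.null(seed)) NULL else seed)
      test <- !train
      p_choice <- ifelse(sessions$choice == 1, p_right, 1 - p_right)
      nll <- -mean(log(pmin(pmax(p_choice[test], 1e-12), 1 - 1e-12)))
      auc <- auc_score(p_right[test], sessions$choice[test])
      tibble::tibble(fold = f, test_nll = nll, test_auc = auc,
                     theta = list(fit$theta_hat))
    })
    pf <- dplyr::bind_rows(per_fold)
    tibble::tibble(model = model,
                   mean_test_nll = mean(pf$test_nll),
                   mean_test_auc = mean(pf$test_auc),
                   per_fold = list(pf))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("vi_cv", class(out))
  out
}
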