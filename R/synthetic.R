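#' Draw random DT parameter vectors
#'
#' Uniform draws inside a bounds box, by default the recovery box
#' (`alpha`, `tau_f`, `tau_s` in \[0, 1\], `beta`, `vartheta` in \[0, 4\],
#' `phi` in \[-4, 0\]).
#'
#' @param n Number of draws.
#' @param bounds Bounds tibble (`name`, `lower`, `upper`).
#' @param seed Optional seed.
#' @return Tibble of parameter draws, one row per vector.
#' @export
random_dt_params <- function(n, bounds = fit_bounds("dt", "recovery"),
                             seed = NULL) {
  if (any(bounds$lower > bounds$upper)) abort("inverted bounds")
  with_seed(seed, {
    draws <- matrix(runif(n * nrow(bounds),
                          rep(bounds$lower, each = n),
                          rep(bounds$upper, each = n)),
                    nrow = n, dimnames = list(NULL, bounds$name))
    tibble::as_tibble(draws)
  })
}

#' Generate a ground-truth DT dataset for parameter recovery
#'
#' Closed-loop DT simulations from known parameters, with a manifest
#' recording the truth and every seed so the dataset is reproducible from
#' one integer. Degenerate parameterisations with `tau_f == tau_s` (fast
#' and slow traces identical, so `phi` and `vartheta` are only identified
#' through their sum) are flagged in the manifest.
#'
#' @param true_params Named list/vector or 1-row data frame of DT
#'   parameters.
#' @param n_sessions Number of sessions (0 gives an empty dataset with a
#'   valid manifest).
#' @param schedule Schedule for every session; default the recovery
#'   protocol (alternating 0.1:0.4 / 0.4:0.1 in 100-trial blocks, 1000
#'   trials).
#' @param seed Master seed.
#' @return List with `sessions` (tibble, possibly empty) and `manifest`.
#' @export
generate_recovery_dataset <- function(true_params, n_sessions,
                                      schedule = vi_schedule(
                                        "alternating", pair = c(0.1, 0.4),
                                        block_length = 100, n_trials = 1000),
                                      seed = NULL) {
  tp <- as.list(tibble::as_tibble(as.list(true_params))[1, ])
  agent <- do.call(vi_agent, c(list(model = "dt"), tp))
  seeds <- derive_seeds(seed, max(n_sessions, 0L))  # matches run_sessions()
  sessions <- if (n_sessions > 0) {
    run_sessions(agent, schedule, n_sessions, seed = seed)
  } else {
    tibble::tibble()
  }
  manifest <- list(
    schema = "vitrace-recovery-1",
    model = "dt",
    true_params = tp,
    n_sessions = n_sessions,
    n_trials = sum(schedule$n_trials),
    seed = seed,
    session_seeds = unlist(seeds) %||% integer(0),
    degenerate_traces = isTRUE(all.equal(tp$tau_f, tp$tau_s))
  )
  list(sessions = sessions, manifest = manifest)
}

#' Deterministic edge-case session fixtures
#'
#' Small hand-built sessions used across the test-suite and useful for
#' exercising degenerate code paths: an all-left session (single-class
#' response), a strict left/right alternation, a single-trial session, a
#' session shorter than a typical regression lag, and an all-rewarded
#' session.
#'
#' @return Named list of session tibbles.
#' @export
edge_fixtures <- function() {
  mk <- function(choice, reward) {
    n <- length(choice)
    tibble::tibble(
      trial = seq_len(n), choice = choice, reward = reward,
      block = rep(1L, n), pset_0 = rep(0.4, n), pset_1 = rep(0.1, n))
  }
  list(
    all_left = mk(rep(0L, 40), rep(c(1L, 0L), 20)),
    alternation = mk(rep(c(0L, 1L), 30), rep(c(0L, 1L, 1L, 0L), 15)),
    single_trial = mk(1L, 1L),
    shorter_than_lag = mk(c(0L, 1L, 0L, 1L, 1L), c(0L, 0L, 1L, 0L, 1L)),
    all_rewarded = mk(rep(c(1L, 1L, 0L), 10), rep(1L, 30))
  )
}
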