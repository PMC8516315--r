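# Vectorised closed-loop simulation across many parameter draws at once.
# Each row of `theta` is an independent agent; per-trial state is held in
# vectors over draws, so one session costs O(n_trials) vector operations
# instead of an R-level loop per draw. Used by the regret optimiser and the
# efficiency benchmarks.

batch_sim_regret <- function(model, theta, schedule, n_sessions, seed = NULL) {
  tr <- schedule_trace(schedule)
  n <- nrow(theta)
  g <- function(col) if (col %in% colnames(theta)) theta[, col] else rep(0, n)
  out <- matrix(NA_real_, n, n_sessions)
  seeds <- derive_seeds(seed, n_sessions, stream = 31L)
  for (s in seq_len(n_sessions)) {
    out[, s] <- with_seed(seeds[[s]], {
      alpha <- g("alpha"); beta <- g("beta")
      tau_f <- g("tau_f"); tau_s <- g("tau_s")
      phi <- g("phi"); vth <- g("vartheta")
      tau_psi <- g("tau_psi"); offset <- g("offset")
      cap <- g("cap"); alpha_up <- g("alpha_up")
      p1 <- rep(tr$pset[1, 1], n); p2 <- rep(tr$pset[1, 2], n)
      q1 <- q2 <- numeric(n)
      f1 <- f2 <- s1 <- s2 <- rep(0.5, n)
      qs1 <- qs2 <- rep(0.5, n)
      lkq1 <- lkq2 <- rep(0.5, n)
      psi1 <- psi2 <- numeric(n)
      apsi <- rep(0.5, n)
      if (model == "fq_up") { q1 <- runif(n); q2 <- runif(n) }
      mu <- coll <- numeric(n)
      nt <- tr$n_trials
      for (t in seq_len(nt)) {
        dv <- switch(model,
          dt = (q2 + phi * f2 + vth * s2) - (q1 + phi * f1 + vth * s1),
          fq_wc = (q2 + phi * f2) - (q1 + phi * f1),
          fq = ,
          fq_up = ,
          indirect = ,
          direct = q2 - q1,
          lk = lkq2 - lkq1,
          random = numeric(n),
          oracle = numeric(n),
          abort(sprintf("model '%s' is not batch-simulable", model)))
        pr <- if (model == "oracle") {
          (p2 > p1) + 0.5 * (p2 == p1)
        } else if (model == "random") {
          rep(0.5, n)
        } else {
          1 / (1 + exp(-beta * dv))
        }
        ch <- as.numeric(runif(n) < pr)           # 1 = right
        pc <- ch * p2 + (1 - ch) * p1
        rw <- as.numeric(runif(n) < pc)
        mu <- mu + pmax(p1, p2)
        coll <- coll + rw
        nxt <- min(t + 1L, nt)
        ps1 <- tr$pset[nxt, 1]; ps2 <- tr$pset[nxt, 2]
        p1 <- ch * (1 - (1 - ps1) * (1 - p1)) + (1 - ch) * ps1
        p2 <- ch * ps2 + (1 - ch) * (1 - (1 - ps2) * (1 - p2))
        if (model %in% c("dt", "fq", "fq_wc")) {
          q1 <- q1 + alpha * ((1 - ch) * rw - q1)
          q2 <- q2 + alpha * (ch * rw - q2)
          if (model != "fq") {
            f1 <- f1 + tau_f * ((1 - ch) - f1)
            f2 <- f2 + tau_f * (ch - f2)
          }
          if (model == "dt") {
            s1 <- s1 + tau_s * ((1 - ch) - s1)
            s2 <- s2 + tau_s * (ch - s2)
          }
        } else if (model == "indirect") {
          q1 <- q1 + (1 - ch) * alpha * (rw - q1)
          q2 <- q2 + ch * alpha * (rw - q2)
        } else if (model == "direct") {
          q1 <- q1 + alpha * ((1 - ch) - (1 - pr)) * (rw - offset)
          q2 <- q2 + alpha * (ch - pr) * (rw - offset)
        } else if (model == "fq_up") {
          q1 <- q1 + (1 - ch) * alpha * (rw - q1) + ch * alpha_up * (cap - q1)
          q2 <- q2 + ch * alpha * (rw - q2) + (1 - ch) * alpha_up * (cap - q2)
        } else if (model == "lk") {
          pe <- rw - (ch * lkq2 + (1 - ch) * lkq1)
          qs1 <- qs1 + (1 - ch) * alpha * (rw - qs1)
          qs2 <- qs2 + ch * alpha * (rw - qs2)
          apsi <- apsi + tau_psi * ((pe + 1) / 2 - apsi)
          psi1 <- ch * (psi1 + apsi * (1 - psi1))
          psi2 <- (1 - ch) * (psi2 + apsi * (1 - psi2))
          lkq1 <- 1 - (1 - qs1) * (1 - lkq1 * psi1)
          lkq2 <- 1 - (1 - qs2) * (1 - lkq2 * psi2)
        }
      }
      mu - coll
    })
  }
  out
}

batch_mean_regret <- function(model, theta, schedule, n_sessions,
                              seed = NULL) {
  rowMeans(batch_sim_regret(model, theta, schedule, n_sessions, seed = seed))
}
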