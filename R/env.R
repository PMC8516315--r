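#' Reward probability of an option left unchosen for `ti` trials
#'
#' In the discrete variable-interval (VI, "baiting") schedule a reward, once
#' assigned to an option, persists until collected. Under a constant set
#' probability `pset` the momentary reward probability of an option that was
#' chosen `ti` trials ago is the closed form `1 - (1 - pset)^(ti + 1)`:
#' `ti = 0` (just chosen) gives `pset`, and the probability grows towards 1
#' while the option stays unchosen.
#'
#' @param pset Set reward probability, in \[0, 1\]. Vectorised.
#' @param ti Number of completed trials since the option was last chosen
#'   (non-negative integer). Vectorised.
#' @return Numeric vector of reward probabilities.
#' @examples
#' vi_reward_probability(0.1, 0:5)
#' @export
vi_reward_probability <- function(pset, ti) {
  assert_probability(pset)
  if (!is.numeric(ti) || anyNA(ti) || any(ti < 0)) {
    abort("`ti` must be a non-negative count.")
  }
  1 - (1 - pset)^(ti + 1)
}

#' Build a block schedule for the VI task
#'
#' A schedule is a tibble with one row per block: the block length and the
#' pair of set reward probabilities (left, right) that hold during it.
#' Named protocols reproduce the study conditions:
#' \describe{
#'   \item{`"mouse"`}{9 blocks of 50--150 trials (uniform), pairs drawn from
#'     \{0.25:0.25, 0.40:0.10, 0.10:0.40\}.}
#'   \item{`"human"`}{`n_blocks` (default 8, at least 6) blocks of 20--30
#'     trials, pairs drawn from \{0.40:0.10, 0.10:0.40\}.}
#'   \item{`"oracle_uniform"`}{a single block of `n_trials` trials with each
#'     set probability drawn independently from U\[0, 0.5\].}
#'   \item{`"alternating"`}{blocks of `block_length` trials alternating
#'     `pair` and its mirror until `n_trials` trials are covered.}
#'   \item{`"fixed"`}{explicit `lengths` and `psets` echoed back.}
#' }
#'
#' @param protocol Protocol name (see Details).
#' @param n_blocks Number of blocks (mouse/human protocols).
#' @param n_trials Total trial count (oracle_uniform/alternating protocols).
#' @param block_length Block length for the alternating protocol.
#' @param pair Length-2 probability pair (left, right) for the alternating
#'   protocol.
#' @param lengths,psets Explicit block lengths and a list (or 2-column
#'   matrix) of probability pairs for the fixed protocol.
#' @param seed Optional integer seed controlling block randomisation.
#' @return A tibble of class `vi_schedule` with columns `block`, `n_trials`,
#'   `pset_0` (left), `pset_1` (right).
#' @examples
#' vi_schedule("mouse", seed = 1)
#' vi_schedule("alternating", pair = c(0.4, 0.1), block_length = 100, n_trials = 1000)
#' @export
vi_schedule <- function(protocol = c("mouse", "human", "oracle_uniform",
                                     "alternating", "fixed"),
                        n_blocks = NULL, n_trials = 1000, block_length = 100,
                        pair = c(0.4, 0.1), lengths = NULL, psets = NULL,
                        seed = NULL) {
  protocol <- match.arg(protocol)
  with_seed(seed, {
    if (protocol == "mouse") {
      n_blocks <- n_blocks %||% 9L
      pairs <- list(c(0.25, 0.25), c(0.40, 0.10), c(0.10, 0.40))
      lens <- sample(50:150, n_blocks, replace = TRUE)
      ps <- pairs[sample.int(3L, n_blocks, replace = TRUE)]
    } else if (protocol == "human") {
      n_blocks <- n_blocks %||% 8L
      if (n_blocks < 6L) abort("the human protocol uses at least 6 blocks")
      pairs <- list(c(0.40, 0.10), c(0.10, 0.40))
      lens <- sample(20:30, n_blocks, replace = TRUE)
      ps <- pairs[sample.int(2L, n_blocks, replace = TRUE)]
    } else if (protocol == "oracle_uniform") {
      lens <- as.integer(n_trials)
      ps <- list(runif(2, 0, 0.5))
    } else if (protocol == "alternating") {
      assert_probability(pair)
      if (length(pair) != 2L) abort("`pair` must have length 2")
      nb <- ceiling(n_trials / block_length)
      lens <- rep(as.integer(block_length), nb)
      lens[nb] <- n_trials - block_length * (nb - 1)
      ps <- lapply(seq_len(nb), function(b) if (b %% 2L == 1L) pair else rev(pair))
    } else {
      if (is.null(lengths) || is.null(psets) || length(lengths) == 0L) {
        abort("the fixed protocol needs non-empty `lengths` and `psets`")
      }
      if (is.matrix(psets)) psets <- asplit(psets, 1)
      if (length(lengths) != length(psets)) {
        abort("`lengths` and `psets` must have the same length")
      }
      lens <- as.integer(lengths)
      ps <- lapply(psets, as.numeric)
    }
    if (any(lens < 1L)) abort("every block length must be at least 1")
    pm <- do.call(rbind, ps)
    assert_probability(pm, "psets")
    out <- tibble::tibble(
      block = seq_along(lens),
      n_trials = lens,
      pset_0 = pm[, 1],
      pset_1 = pm[, 2]
    )
    class(out) <- c("vi_schedule", class(out))
    out
  })
}

# Expand a schedule into a per-trial matrix of set probabilities and a block
# id vector.
schedule_trace <- function(schedule) {
  stopifnot(inherits(schedule, "vi_schedule") || all(
    c("block", "n_trials", "pset_0", "pset_1") %in% names(schedule)))
  idx <- rep(seq_len(nrow(schedule)), schedule$n_trials)
  list(
    pset = cbind(schedule$pset_0[idx], schedule$pset_1[idx]),
    block = schedule$block[idx],
    n_trials = length(idx)
  )
}

#' Initialise the VI environment
#'
#' Momentary reward probabilities start at the set probabilities of the first
#' block (the closed form with `ti = 0`), trial counters at zero.
#'
#' @param schedule A [vi_schedule()].
#' @return An environment-state list with elements `t` (current trial,
#'   1-based), `p` (per-option momentary probabilities, left then right),
#'   `ti` (per-option trials since last chosen), and the expanded per-trial
#'   set-probability trace.
#' @export
env_init <- function(schedule) {
  tr <- schedule_trace(schedule)
  if (tr$n_trials < 1L) abort("empty schedule")
  list(
    t = 1L,
    p = tr$pset[1L, ],
    ti = c(0L, 0L),
    pset = tr$pset,
    block = tr$block,
    n_trials = tr$n_trials
  )
}

#' Advance the VI environment by one trial
#'
#' Draws the reward as a Bernoulli trial on the chosen option's momentary
#' probability, then applies the baiting update: the chosen option resets to
#' the (possibly new, at block boundaries) set probability; each unchosen
#' option accumulates `p <- 1 - (1 - pset_next) * (1 - p)`.
#'
#' @param env Environment state from [env_init()] or a previous step.
#' @param choice Chosen option index, 1 (left) or 2 (right).
#' @return List with `reward` (0/1) and the updated `env`.
#' @export
env_step <- function(env, choice) {
  if (!is_scalar_number(choice) || !(choice %in% c(1, 2))) {
    abort("`choice` must be option index 1 or 2")
  }
  t <- env$t
  if (t > env$n_trials) abort("the session is over")
  reward <- as.integer(runif(1) < env$p[choice])
  nxt <- min(t + 1L, env$n_trials)
  pset_next <- env$pset[nxt, ]
  p <- 1 - (1 - pset_next) * (1 - env$p)
  p[choice] <- pset_next[choice]
  ti <- env$ti + 1L
  ti[choice] <- 0L
  env$p <- p
  env$ti <- ti
  env$t <- t + 1L
  list(reward = reward, env = env)
}

#' Write behavioural sessions to CSV
#'
#' One CSV per session with header
#' `trial,choice,reward,block,pset_0,pset_1[,p_0,p_1]` (`choice` coded 0 =
#' left, 1 = right), plus a JSON sidecar per session holding the seed and
#' agent metadata when present.
#'
#' @param sessions Session tibble (optionally with a `session` column).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_sessions <- function(sessions, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- unique(sessions[["session"]] %||% 1L)
  paths <- character(0)
  for (id in ids) {
    one <- if (is.null(sessions[["session"]])) sessions else
      dplyr::filter(sessions, .data$session == id)
    keep <- intersect(
      c("trial", "choice", "reward", "block", "pset_0", "pset_1", "p_0", "p_1"),
      names(one))
    path <- file.path(dir, sprintf("session_%03d.csv", as.integer(id)))
    write.csv(one[keep], path, row.names = FALSE, quote = FALSE)
    meta <- list(
      session = as.integer(id),
      seed = attr(sessions, "seed"),
      agent = attr(sessions, "agent"),
      schema = "vitrace-session-1"
    )
    jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, null = "null")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read behavioural sessions from CSV
#'
#' Accepts a single CSV file or a directory of `session_*.csv` files written
#' by [write_sessions()] (or following the same schema). Multiple files are
#' concatenated with a `session` id column.
#'
#' @param path CSV file or directory.
#' @return Session tibble.
#' @export
read_sessions <- function(path) {
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "^session_.*\\.csv$", full.names = TRUE))
  } else if (file.exists(path)) {
    path
  } else {
    character(0)
  }
  if (length(files) == 0L) abort(sprintf("no session CSVs found under '%s'", path))
  out <- purrr::imap(files, function(f, i) {
    d <- tibble::as_tibble(read.csv(f))
    need <- c("trial", "choice", "reward", "block")
    if (!all(need %in% names(d))) {
      abort(sprintf("'%s' is missing required columns %s", f,
                    paste(setdiff(need, names(d)), collapse = ", ")))
    }
    if (!all(d$reward %in% c(0, 1)) || !all(d$choice %in% c(0, 1))) {
      abort(sprintf("'%s' has out-of-range choice or reward codes", f))
    }
    d$session <- i
    d
  })
  dplyr::bind_rows(out)
}
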