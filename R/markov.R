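#' Stochastic coordination-state series generator
#'
#' Generates a piecewise-constant coordination-number series with exponential
#' dwell times, per-frame shell-member identity sets, and per-state Gaussian
#' drift velocities. This is an exact-oracle bed for the survival-correlation,
#' histogram and current-decomposition analyses: every generating parameter is
#' recorded so recovery tests can compare against ground truth.
#'
#' Two independent stochastic mechanisms are available:
#' \itemize{
#'   \item state switching: the integer CN jumps between `cn_states` with
#'     exponential dwell times of rate `dwell_rates\[state\]` (per fs); on a
#'     jump, members are added (fresh identities) or removed at random to
#'     match the new CN;
#'   \item within-state exchange: while the CN is constant, each member is
#'     independently replaced by a fresh identity at rate `exchange_rate`
#'     (per fs) - a Poisson ligand-exchange process with per-member survival
#'     `exp(-k tau)`.
#' }
#'
#' @param n_frames Number of frames (>= 1).
#' @param dt Frame spacing (fs).
#' @param cn_states Integer vector of coordination states.
#' @param dwell_rates Rate (1/fs) of leaving each state; scalar recycled.
#'   Ignored when only one state is given.
#' @param drifts Mean scalar drift velocity per state (A/fs).
#' @param drift_sd Gaussian noise SD added to the per-frame drift.
#' @param exchange_rate Within-state per-member replacement rate (1/fs), 0 to
#'   disable.
#' @param seed Optional seed.
#' @return Object of class `markov_cn_series`: list with `cn` (integer per
#'   frame), `members` (list of identity vectors), `drift` (numeric per
#'   frame), `state_index`, `dt`, `times`, and `params` (the generator
#'   arguments).
#' @export
markov_cn_series <- function(n_frames, dt = 1, cn_states = 6L,
                             dwell_rates = 1e-3, drifts = 0,
                             drift_sd = 0, exchange_rate = 0, seed = NULL) {
  stopifnot(n_frames >= 1, dt > 0, all(cn_states >= 0),
            all(dwell_rates > 0), exchange_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_states <- length(cn_states)
  dwell_rates <- rep_len(dwell_rates, n_states)
  drifts <- rep_len(drifts, n_states)

  cn <- integer(n_frames)
  state_index <- integer(n_frames)
  members <- vector("list", n_frames)
  drift <- numeric(n_frames)

  next_id <- 1L
  fresh <- function(k) {
    ids <- seq.int(next_id, length.out = k)
    next_id <<- next_id + k
    ids
  }
  s <- sample.int(n_states, 1)
  cur <- fresh(cn_states[s])
  # dwell countdown in frames (at least one frame per dwell)
  draw_dwell <- function(s) {
    if (n_states == 1) return(n_frames + 1L)
    max(1L, as.integer(ceiling(stats::rexp(1, dwell_rates[s]) / dt)))
  }
  remaining <- draw_dwell(s)
  p_exch <- if (exchange_rate > 0) 1 - exp(-exchange_rate * dt) else 0

  for (f in seq_len(n_frames)) {
    if (remaining == 0L) {
      s_new <- if (n_states == 2) 3L - s else {
        sample(setdiff(seq_len(n_states), s), 1)
      }
      k_old <- cn_states[s]; k_new <- cn_states[s_new]
      if (k_new > k_old) {
        cur <- c(cur, fresh(k_new - k_old))
      } else if (k_new < k_old) {
        cur <- sample(cur, k_new)
      } else {
        cur <- c(sample(cur, k_old - 1), fresh(1L)) # swap one on equal-CN jump
      }
      s <- s_new
      remaining <- draw_dwell(s)
    }
    if (p_exch > 0 && length(cur) > 0) {
      swap <- stats::runif(length(cur)) < p_exch
      if (any(swap)) cur[swap] <- fresh(sum(swap))
    }
    cn[f] <- cn_states[s]
    state_index[f] <- s
    members[[f]] <- sort(cur)
    drift[f] <- drifts[s] + if (drift_sd > 0) stats::rnorm(1, sd = drift_sd) else 0
    remaining <- remaining - 1L
  }
  structure(list(cn = cn, members = members, drift = drift,
                 state_index = state_index,
                 dt = dt, times = (seq_len(n_frames) - 1) * dt,
                 params = list(cn_states = cn_states,
                               dwell_rates = dwell_rates, drifts = drifts,
                               drift_sd = drift_sd,
                               exchange_rate = exchange_rate, seed = seed)),
            class = "markov_cn_series")
}

#' @export
print.markov_cn_series <- function(x, ...) {
  cat(sprintf("markov_cn_series: %d frames, dt %g fs, CN states {%s}\n",
              length(x$cn), x$dt, paste(x$params$cn_states, collapse = ", ")))
  occ <- table(x$cn) / length(x$cn)
  cat("  occupancy:", paste(sprintf("%s: %.3f", names(occ), occ),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Convert a Markov coordination series to a shell series
#'
#' @param x A [markov_cn_series()].
#' @return A `shell_series` (see [shell_series()]), with smooth CN equal to
#'   the integer CN.
#' @export
as_shell_series <- function(x) {
  stopifnot(inherits(x, "markov_cn_series"))
  structure(list(members = x$members, cn = x$cn, smooth_cn = as.numeric(x$cn),
                 times = x$times, dt = x$dt, R0 = NA_real_,
                 NN = NA, ND = NA),
            class = "shell_series")
}
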