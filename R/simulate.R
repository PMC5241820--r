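#' Exact Gillespie simulation of the idea chain
#'
#' Simulates the 1D or 2D birth-death chain by the stochastic simulation
#' algorithm: exponential waiting times with the total exit rate, events
#' chosen proportionally to the individual rates. A run terminates at
#' absorption, at \code{t_max}, or at \code{max_events}; the latter two are
#' flagged as censored, distinctly from absorption. Times are in
#' generations (rates carry the explicit factor \eqn{N}).
#'
#' @param rates a \code{bd_rates_1d} or \code{bd_rates_2d} object.
#' @param init initial state: \code{n} (1D) or \code{c(n, m)} (2D).
#' @param seed RNG seed (integer); a fixed seed gives a bit-identical
#'   trajectory on repeated runs.
#' @param t_max time horizon in generations.
#' @param max_events event cap (censoring guard).
#' @param record_path keep the full event-level path (memory grows with the
#'   event count; disable for long absorption runs).
#' @return an \code{ssa_trajectory} list: \code{absorbed}, \code{censored},
#'   \code{state}, \code{time}, \code{events}, and when recorded the event
#'   \code{times} plus \code{states} (1D) or \code{n}, \code{m} (2D).
#' @export
gillespie <- function(rates, init, seed = NULL, t_max = Inf,
                      max_events = 1e9, record_path = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  out <- if (inherits(rates, "bd_rates_1d")) {
    stopifnot(length(init) == 1L)
    ssa_1d_cpp(rates$Tplus, rates$Tminus, as.integer(init), t_max,
               max_events, record_path)
  } else if (inherits(rates, "bd_rates_2d")) {
    stopifnot(length(init) == 2L)
    ssa_2d_cpp(rates$TAp, rates$TAm, rates$TBp, rates$TBm,
               as.integer(init[1]), as.integer(init[2]), t_max,
               max_events, record_path)
  } else stop("rates must come from rates_1d() or rates_2d()", call. = FALSE)
  structure(out, class = "ssa_trajectory", N = rates$N)
}

#' Simulate an ensemble of independent replicates
#'
#' Runs \code{n_reps} independent Gillespie replicates; replicate \eqn{r}
#' is seeded with \code{seed + (r - 1)}, so ensembles are reproducible and
#' trivially parallelisable by splitting the replicate range.
#'
#' @inheritParams gillespie
#' @param n_reps number of replicates.
#' @param sample_times optional increasing vector of times (generations) at
#'   which to record the state of every replicate; when given, the result
#'   carries a \code{samples} matrix (replicates x times; 2D chains return
#'   \code{samples_n} and \code{samples_m}).
#' @return an \code{ssa_ensemble} list with per-replicate vectors
#'   \code{absorbed}, \code{censored}, \code{time}, \code{events}, final
#'   states, and optional sample matrices.
#' @export
simulate_ensemble <- function(rates, init, n_reps, seed, t_max = Inf,
                              max_events = 1e9, sample_times = NULL) {
  two_d <- inherits(rates, "bd_rates_2d")
  absorbed <- censored <- logical(n_reps)
  time <- events <- numeric(n_reps)
  state <- if (two_d) matrix(0L, n_reps, 2L) else integer(n_reps)
  samples <- samples_m <- NULL
  if (!is.null(sample_times)) {
    samples <- matrix(NA_integer_, n_reps, length(sample_times))
    if (two_d) samples_m <- matrix(NA_integer_, n_reps, length(sample_times))
  }
  for (r in seq_len(n_reps)) {
    set.seed(as.integer(seed) + r - 1L)
    if (is.null(sample_times)) {
      res <- if (two_d) {
        ssa_2d_cpp(rates$TAp, rates$TAm, rates$TBp, rates$TBm,
                   as.integer(init[1]), as.integer(init[2]), t_max,
                   max_events, FALSE)
      } else {
        ssa_1d_cpp(rates$Tplus, rates$Tminus, as.integer(init), t_max,
                   max_events, FALSE)
      }
    } else {
      res <- if (two_d) {
        ssa_2d_sampled_cpp(rates$TAp, rates$TAm, rates$TBp, rates$TBm,
                           as.integer(init[1]), as.integer(init[2]),
                           sample_times, max_events)
      } else {
        ssa_1d_sampled_cpp(rates$Tplus, rates$Tminus, as.integer(init),
                           sample_times, max_events)
      }
      if (two_d) { samples[r, ] <- res$n; samples_m[r, ] <- res$m }
      else samples[r, ] <- res$samples
    }
    absorbed[r] <- res$absorbed; censored[r] <- res$censored
    time[r] <- res$time; events[r] <- res$events
    if (two_d) state[r, ] <- res$state else state[r] <- res$state
  }
  structure(list(absorbed = absorbed, censored = censored, time = time,
                 events = events, state = state, N = rates$N,
                 sample_times = sample_times, samples = samples,
                 samples_m = samples_m, seed = seed, init = init),
            class = "ssa_ensemble")
}

#' @export
print.ssa_ensemble <- function(x, ...) {
  cat(sprintf("SSA ensemble: %d replicates (N = %d), %d absorbed, %d censored\n",
              length(x$absorbed), x$N, sum(x$absorbed), sum(x$censored)))
  if (any(x$absorbed))
    cat(sprintf("mean absorption time %.4g generations\n",
                mean(x$time[x$absorbed])))
  invisible(x)
}

#' Triplet-sampling microsimulation of the pairwise comparison process
#'
#' Runs the microscopic construction underlying the birth-death rates: per
#' event an ordered triplet (primary, secondary, adversary) is drawn with
#' replacement from the population; primary and secondary both play the
#' adversary, and the secondary is replaced by an individual of the
#' primary's type with probability \eqn{g(a_{i_1 i_a}, a_{i_2 i_a})}. With
#' the linear comparison function, averaging over the adversary reproduces
#' exactly the payoff-based birth-death rates, which the returned empirical
#' per-state transition frequencies let you verify. Defined for
#' payoff-based fitness only (\eqn{\lambda = 0}): the entropic penalty is a
#' population-level quantity with no per-encounter counterpart.
#'
#' @param game a \code{payoff_matrix}.
#' @param params a [chain_params()] with \code{lam = 0}.
#' @param init initial count of type 1.
#' @param n_events number of triplet draws.
#' @param restart_on_absorption restart from \code{init} whenever the
#'   population absorbs, accumulating statistics over independent passes
#'   until the event budget is spent (the absorbed composition is frozen,
#'   so continuing a single absorbed run carries no information).
#' @param seed RNG seed (defaults to \code{params$seed}).
#' @return a \code{triplet_sim} list: per-state vectors \code{attempts},
#'   \code{ups}, \code{downs} (indexed \code{n = 0..N}), the empirical
#'   per-attempt transition frequencies \code{up_freq}, \code{down_freq},
#'   the rate-based predictions \code{up_pred}, \code{down_pred}
#'   (\eqn{T^\pm_n / N}), and the final \code{state}.
#' @export
triplet_microsim <- function(game, params, init, n_events,
                             restart_on_absorption = FALSE, seed = NULL) {
  if (params$lam != 0)
    stop("the triplet construction is defined for lam = 0 only: ",
         "the entropic fitness term has no per-encounter interpretation",
         call. = FALSE)
  set.seed(if (is.null(seed)) params$seed else as.integer(seed))
  res <- triplet_sim_cpp(unclass(game), params$N, params$Gamma,
                         as.integer(init), n_events, restart_on_absorption)
  r <- rates_1d(game, params)
  with_attempts <- res$attempts > 0
  up_freq <- ifelse(with_attempts, res$ups / pmax(res$attempts, 1), NA_real_)
  down_freq <- ifelse(with_attempts, res$downs / pmax(res$attempts, 1),
                      NA_real_)
  structure(list(attempts = res$attempts, ups = res$ups, downs = res$downs,
                 up_freq = up_freq, down_freq = down_freq,
                 up_pred = r$Tplus / params$N, down_pred = r$Tminus / params$N,
                 state = res$state, N = params$N),
            class = "triplet_sim")
}
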