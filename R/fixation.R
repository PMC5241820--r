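# Mean fixation times and fixation probabilities for the idea chains:
# exact closed-form birth-death sums, backward-master-equation linear
# solves, and Monte-Carlo estimates from Gillespie ensembles.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Closed-form fixation statistics of the 1D chain
#'
#' Standard birth-death first-passage solution built from the rate ratios
#' \eqn{\gamma_k = T^-_k / T^+_k}: the probability of absorption at
#' \eqn{n = N} from \eqn{n_0} is
#' \deqn{\phi_{n_0} = \sum_{k=0}^{n_0 - 1} q_k \Big/ \sum_{k=0}^{N-1} q_k,
#'       \qquad q_k = \prod_{m=1}^{k} \gamma_m,}
#' and the unconditional mean absorption time follows from the exact
#' solution of the backward recursion for the increments
#' \eqn{d_j = \tau_{j+1} - \tau_j}. All running products and their sums are
#' accumulated in log space, so strong selection and large \eqn{N} cannot
#' overflow.
#'
#' @param rates a \code{bd_rates_1d}.
#' @param n0 initial state (may be a vector; absorbing states give 0).
#' @return a \code{fixation_result} list: \code{mean_time} (at \code{n0}),
#'   \code{tau} (all states 0..N), \code{fixation_prob_upper} (at
#'   \code{n0}), \code{phi} (all states), \code{method = "closed_form"}.
#' @export
fixation_closed_form_1d <- function(rates, n0) {
  N <- rates$N
  stopifnot(all(n0 >= 0), all(n0 <= N))
  Tp <- rates$Tplus[2:N]   # T+_j, j = 1..N-1
  Tm <- rates$Tminus[2:N]
  if (any(Tp <= 0))
    stop("T+ vanishes at an interior state; closed form undefined",
         call. = FALSE)
  lgam <- log(Tm) - log(Tp)
  lq <- c(0, cumsum(lgam))              # log q_k, k = 0..N-1
  # lS_j: log of S_j = sum_l (1/T+_l) prod_{m=l+1}^j gamma_m, j = 1..N-1
  lS <- numeric(N - 1)
  lS[1] <- -log(Tp[1])
  for (j in seq_len(N - 2)) {
    lS[j + 1] <- logsumexp(c(lgam[j + 1] + lS[j], -log(Tp[j + 1])))
  }
  lB <- logsumexp(lq)
  lA <- logsumexp(lS)
  d <- exp(lA - lB + lq) - c(0, exp(lS))  # d_j, j = 0..N-1
  tau <- c(0, cumsum(d))
  tau[N + 1] <- 0  # exact by construction; clears the rounding residual
  phi <- exp(cumsum_logsumexp(lq) - lB)
  phi_all <- c(0, phi)  # phi_0 = 0, phi_j for j = 1..N (phi_N = 1)
  phi_all[N + 1] <- 1
  structure(list(mean_time = tau[n0 + 1], tau = tau,
                 fixation_prob_upper = phi_all[n0 + 1], phi = phi_all,
                 method = "closed_form", N = N, n0 = n0),
            class = "fixation_result")
}

cumsum_logsumexp <- function(lx) {
  out <- numeric(length(lx))
  acc <- -Inf
  for (i in seq_along(lx)) {
    acc <- logsumexp(c(acc, lx[i]))
    out[i] <- acc
  }
  out
}

#' Mean fixation times from the backward master equation
#'
#' Solves the backward master equation for the mean absorption time as a
#' sparse linear system over all transient states, with \eqn{\tau = 0}
#' imposed at the absorbing states (\eqn{n = 0, N} in 1D; the four lattice
#' corners in 2D, giving \eqn{(N+1)^2 - 4} unknowns). Any non-absorbing
#' state with zero total exit rate would make the system singular and is
#' reported explicitly.
#'
#' @param rates a \code{bd_rates_1d} or \code{bd_rates_2d}.
#' @return a \code{fixation_result}; \code{tau} is a vector over
#'   \code{n = 0..N} (1D) or an \eqn{(N+1) \times (N+1)} matrix with
#'   \code{tau[n + 1, m + 1]} (2D). \code{method = "linear_solve"}.
#' @export
fixation_linear_solve <- function(rates) {
  if (inherits(rates, "bd_rates_1d")) fixation_solve_1d(rates)
  else fixation_solve_2d(rates)
}

fixation_solve_1d <- function(rates) {
  N <- rates$N
  Tp <- rates$Tplus; Tm <- rates$Tminus
  j <- 2:N  # interior, R index
  i <- seq_len(N - 1)
  rows <- c(i, i[-(N - 1)], i[-1])
  cols <- c(i, i[-(N - 1)] + 1L, i[-1] - 1L)
  vals <- c(-(Tp[j] + Tm[j]), Tp[j][-(N - 1)], Tm[j][-1])
  M <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(N - 1, N - 1))
  tau_int <- as.numeric(Matrix::solve(M, rep(-1, N - 1)))
  tau <- c(0, tau_int, 0)
  structure(list(mean_time = NULL, tau = tau, fixation_prob_upper = NULL,
                 method = "linear_solve", N = N),
            class = "fixation_result")
}

fixation_solve_2d <- function(rates) {
  N <- rates$N
  L <- N + 1L
  exit <- rates$TAp + rates$TAm + rates$TBp + rates$TBm
  absorbing <- which(exit == 0)
  corners <- c(1L, L, (L - 1L) * L + 1L, L * L)  # (0,0),(N,0),(0,N),(N,N)
  if (!setequal(absorbing, corners)) {
    extra <- setdiff(absorbing, corners)
    stop("zero-exit-rate states outside the four corners: linear index ",
         paste(utils::head(extra, 5), collapse = ", "),
         " (disconnected transient states)", call. = FALSE)
  }
  transient <- setdiff(seq_len(L * L), absorbing)
  idx <- integer(L * L)
  idx[transient] <- seq_along(transient)
  nt <- length(transient)
  n_of <- (transient - 1L) %% L        # n coordinate, 0..N
  m_of <- (transient - 1L) %/% L
  rows <- idx[transient]; cols <- idx[transient]
  vals <- -exit[transient]
  add_jump <- function(rate_mat, dn, dm) {
    r <- rate_mat[transient]
    pos <- which(r > 0)  # a positive rate implies an in-lattice destination
    dest <- (n_of[pos] + dn) + (m_of[pos] + dm) * L + 1L
    keep <- idx[dest] > 0  # jumps into absorbing states drop out
    rows <<- c(rows, idx[transient][pos][keep])
    cols <<- c(cols, idx[dest][keep])
    vals <<- c(vals, r[pos][keep])
  }
  add_jump(rates$TAp, 1L, 0L)
  add_jump(rates$TAm, -1L, 0L)
  add_jump(rates$TBp, 0L, 1L)
  add_jump(rates$TBm, 0L, -1L)
  M <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(nt, nt))
  tau_t <- as.numeric(Matrix::solve(M, rep(-1, nt)))
  tau <- matrix(0, L, L)
  tau[transient] <- tau_t
  structure(list(mean_time = NULL, tau = tau, fixation_prob_upper = NULL,
                 method = "linear_solve", N = N),
            class = "fixation_result")
}

#' Monte-Carlo fixation statistics from a simulated ensemble
#'
#' @param ens an \code{ssa_ensemble} from [simulate_ensemble()]. Censored
#'   replicates are excluded from the mean and reported separately.
#' @return a \code{fixation_result} with \code{mean_time}, \code{se} (plain
#'   ensemble standard deviation over \eqn{\sqrt{reps}}; replicates are
#'   independent), \code{absorption_table} (distribution over absorbing
#'   states), \code{n_absorbed}, \code{n_censored},
#'   \code{fixation_prob_upper} (1D: fraction absorbed at \eqn{n = N}).
#' @export
mc_fixation_stats <- function(ens) {
  ok <- ens$absorbed & !ens$censored
  if (sum(ok) < 1L) stop("all replicates censored", call. = FALSE)
  t_abs <- ens$time[ok]
  if (is.matrix(ens$state)) {
    st <- paste0("(", ens$state[ok, 1], ",", ens$state[ok, 2], ")")
    prob_upper <- NULL
  } else {
    st <- ens$state[ok]
    prob_upper <- mean(st == ens$N)
  }
  se <- if (sum(ok) > 1L) stats::sd(t_abs) / sqrt(sum(ok)) else 0
  structure(list(mean_time = mean(t_abs), se = se,
                 absorption_table = table(st),
                 n_absorbed = sum(ok), n_censored = sum(ens$censored),
                 fixation_prob_upper = prob_upper,
                 method = "monte_carlo", N = ens$N),
            class = "fixation_result")
}

#' @export
print.fixation_result <- function(x, ...) {
  cat("Fixation result (", x$method, ", N = ", x$N, ")\n", sep = "")
  if (!is.null(x$mean_time) && length(x$mean_time) == 1L)
    cat(sprintf("mean fixation time: %.6g generations%s\n", x$mean_time,
                if (!is.null(x$se)) sprintf(" (se %.3g)", x$se) else ""))
  if (!is.null(x$fixation_prob_upper) &&
      length(x$fixation_prob_upper) == 1L)
    cat(sprintf("upper fixation probability: %.6g\n", x$fixation_prob_upper))
  invisible(x)
}

#' Fit a scaling law to fixation times
#'
#' Least-squares fit on the model's own linearisation:
#' \code{power_law} fits \eqn{\log\tau \sim \log x} (slope = exponent),
#' \code{exponential} fits \eqn{\log\tau \sim x},
#' \code{logarithmic} fits \eqn{\tau \sim \log x}. Distinguishes the three
#' fixation mechanisms: diffusive (\eqn{\tau \propto N}), activated
#' (\eqn{\tau \sim e^{cN}}) and relaxational (\eqn{\tau \sim \ln N}).
#'
#' @param xs predictor values (e.g. population sizes), >= 4 of them.
#' @param taus positive fixation times.
#' @param model one of \code{"power_law"}, \code{"exponential"},
#'   \code{"logarithmic"}.
#' @return a \code{scaling_fit} list: \code{model}, \code{slope} (exponent
#'   for \code{power_law}), \code{se}, \code{r_squared}, \code{window}
#'   (range of \code{xs} used), \code{n_points}.
#' @export
fit_scaling <- function(xs, taus,
                        model = c("power_law", "exponential", "logarithmic")) {
  model <- match.arg(model)
  stopifnot(length(xs) == length(taus), length(xs) >= 4L)
  if (any(taus <= 0)) stop("fixation times must be positive", call. = FALSE)
  fit <- switch(model,
    power_law   = stats::lm(log(taus) ~ log(xs)),
    exponential = stats::lm(log(taus) ~ xs),
    logarithmic = stats::lm(taus ~ log(xs)))
  sm <- summary(fit)
  structure(list(model = model,
                 slope = unname(stats::coef(fit)[2]),
                 se = sm$coefficients[2, 2],
                 r_squared = sm$r.squared,
                 window = range(xs), n_points = length(xs)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("%s fit over [%g, %g] (%d points): slope %.4g +/- %.2g, R^2 = %.4f\n",
              x$model, x$window[1], x$window[2], x$n_points, x$slope, x$se,
              x$r_squared))
  invisible(x)
}

#' Compare the three scaling models side by side
#'
#' @inheritParams fit_scaling
#' @return named list of \code{scaling_fit}s, plus attribute \code{best}
#'   (highest \eqn{R^2} on each model's own linearisation; reported side by
#'   side, no formal model-selection criterion is claimed).
#' @export
compare_scaling <- function(xs, taus) {
  fits <- lapply(c(power_law = "power_law", exponential = "exponential",
                   logarithmic = "logarithmic"),
                 function(m) fit_scaling(xs, taus, m))
  attr(fits, "best") <- names(fits)[which.max(vapply(fits, `[[`,
                                                     numeric(1), "r_squared"))]
  fits
}

#' Estimate the early-time diffusion exponent of the two-population chain
#'
#' Simulates replicates from the centre of the lattice, computes the
#' ensemble RMS distance \eqn{d(t)} of \eqn{(x^A, x^B)} from
#' \eqn{(1/2, 1/2)}, and fits the slope of \eqn{\log d} against
#' \eqn{\log t} over the automatic pre-saturation window
#' \eqn{2/N \le d \le 0.25}. For a game with zero radial deterministic flow
#' (matching-pennies class at \eqn{\lambda = 0}) the motion is purely
#' diffusive and the exponent is 1/2; with memory loss the distance
#' saturates at a metastable plateau instead and no valid long-time window
#' exists.
#'
#' @param game a \code{payoff_bimatrix}.
#' @param params a [chain_params()].
#' @param n_reps replicates.
#' @param seed base seed (defaults to \code{params$seed}).
#' @param n_times log-spaced sample times.
#' @return a \code{diffusion_fit} list: \code{exponent}, \code{se},
#'   \code{r_squared}, \code{window_points}, and the \code{d_of_t}
#'   data.frame (t, d).
#' @export
diffusion_exponent <- function(game, params, n_reps = 200L, seed = NULL,
                               n_times = 60L) {
  N <- params$N
  r <- rates_2d(game, params)
  t_lo <- 2 / N
  t_hi <- 0.5 * N
  tgrid <- exp(seq(log(t_lo), log(t_hi), length.out = n_times))
  ens <- simulate_ensemble(r, c(N / 2, N / 2), n_reps,
                           seed = if (is.null(seed)) params$seed else seed,
                           sample_times = tgrid)
  dxa <- ens$samples / N - 0.5
  dxb <- ens$samples_m / N - 0.5
  d <- sqrt(colMeans(dxa^2 + dxb^2))
  win <- which(d >= 2 / N & d <= 0.25)
  if (length(win) < 10L)
    stop("fewer than 10 time points in the diffusive window ",
         "(2/N <= d <= 0.25); no power-law regime", call. = FALSE)
  fit <- stats::lm(log(d[win]) ~ log(tgrid[win]))
  sm <- summary(fit)
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 se = sm$coefficients[2, 2], r_squared = sm$r.squared,
                 window_points = length(win),
                 d_of_t = data.frame(t = tgrid, d = d)),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("diffusion exponent %.3f +/- %.3f (R^2 = %.4f, %d window points)\n",
              x$exponent, x$se, x$r_squared, x$window_points))
  invisible(x)
}

#' Deterministic relaxation time to within c/N of a stable fixed point
#'
#' Integrates the deterministic flow from \code{x0} and reports the first
#' time the trajectory comes within \eqn{c/N} (the lattice spacing scale) of
#' the target stable fixed point; a proxy for the relaxational part of
#' finite-\eqn{N} fixation. The order-one constant \code{c} is a free
#' calibration parameter.
#'
#' @param game a \code{payoff_matrix}.
#' @param params a [dyn_params()].
#' @param x0 initial frequency.
#' @param x_star target fixed point.
#' @param N population size setting the distance scale.
#' @param c_const order-one constant (default 1).
#' @param t_cap integration horizon.
#' @return the relaxation time (generations), or \code{NA} if the target is
#'   not approached within \code{t_cap}.
#' @export
relaxation_time <- function(game, params, x0, x_star, N, c_const = 1,
                            t_cap = 1e4) {
  traj <- integrate_flow(function(x) sc_flow_1d(game, x, params), x0, t_cap,
                         n_out = 4001L)
  hit <- which(abs(traj$x - x_star) <= c_const / N)
  if (!length(hit)) return(NA_real_)
  traj$t[hit[1]]
}
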