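#' Parameters of the learning dynamics
#'
#' @param Gamma intensity of choice, \eqn{\Gamma \ge 0}; scales the selection
#'   strength of the pairwise comparison and the speed of the deterministic
#'   flow. Default 0.1, the conventional compromise between best-response and
#'   weak-selection regimes.
#' @param lam memory-loss strength \eqn{\lambda \ge 0} (\eqn{\lambda =
#'   \alpha/\Gamma} in terms of the discounting rate of the underlying
#'   learning rule); strength of the entropic restoring force towards the
#'   uniformly mixed strategy.
#' @param u mutation rate \eqn{u \ge 0}, used only by the replicator-mutator
#'   comparison flow.
#' @return a \code{dyn_params} list.
#' @export
dyn_params <- function(Gamma = 0.1, lam = 0, u = 0) {
  stopifnot(is.finite(Gamma), Gamma >= 0, is.finite(lam), lam >= 0,
            is.finite(u), u >= 0)
  structure(list(Gamma = Gamma, lam = lam, u = u), class = "dyn_params")
}

#' Average payoffs in a one-population game
#'
#' \eqn{\pi_i(x) = a_{i1} x + a_{i2} (1 - x)} is the expected payoff per
#' interaction to a type-\eqn{i} idea in a population with a fraction \eqn{x}
#' of type 1. The finite-population fitness \eqn{\pi_1 = [a_{11} n + a_{12}
#' (N - n)]/N} is this formula evaluated at \eqn{x = n/N}.
#'
#' @param game a \code{payoff_matrix}.
#' @param x frequency of type 1, in \eqn{[0, 1]} (vectorised).
#' @return matrix with columns \code{pi1}, \code{pi2}.
#' @export
avg_payoff_1d <- function(game, x) {
  stopifnot(all(x >= 0 & x <= 1))
  cbind(pi1 = game[1, 1] * x + game[1, 2] * (1 - x),
        pi2 = game[2, 1] * x + game[2, 2] * (1 - x))
}

#' Average payoffs in a two-population game
#'
#' Each player's payoff depends on the \emph{other} player's mixed strategy:
#' \eqn{\pi^A_i = a_{i1} x^B + a_{i2} (1 - x^B)} and \eqn{\pi^B_i = b_{i1}
#' x^A + b_{i2} (1 - x^A)}.
#'
#' @param game a \code{payoff_bimatrix}.
#' @param state numeric \code{c(xA, xB)}, components in \eqn{[0, 1]}.
#' @return named vector \code{(piA1, piA2, piB1, piB2)}.
#' @export
avg_payoff_2d <- function(game, state) {
  stopifnot(length(state) == 2L, all(state >= 0 & state <= 1))
  xA <- state[1]; xB <- state[2]
  c(piA1 = game$A[1, 1] * xB + game$A[1, 2] * (1 - xB),
    piA2 = game$A[2, 1] * xB + game$A[2, 2] * (1 - xB),
    piB1 = game$B[1, 1] * xA + game$B[1, 2] * (1 - xA),
    piB2 = game$B[2, 1] * xA + game$B[2, 2] * (1 - xA))
}

#' Entropically modified fitness
#'
#' \eqn{f_i = \pi_i - \lambda \ln x_i}: the payoff penalised by the
#' log-frequency of the type. Frequent ideas are entropically penalised and
#' rare ideas favoured; this single modification turns the Sato-Crutchfield
#' learning dynamics into a standard-form replicator system.
#'
#' @param pi_i payoff of the type.
#' @param x_i its frequency, in \eqn{(0, 1]} (must be positive when
#'   \code{lam > 0}: fitness diverges in an absorbed state).
#' @param lam memory-loss strength \eqn{\lambda \ge 0}.
#' @return modified fitness value(s).
#' @export
modified_fitness <- function(pi_i, x_i, lam) {
  stopifnot(lam >= 0)
  if (lam > 0 && any(x_i <= 0))
    stop("modified fitness diverges at x_i = 0 for lam > 0", call. = FALSE)
  if (lam == 0) return(pi_i + numeric(length(x_i)))
  pi_i - lam * log(x_i)
}

# fitness difference f1 - f2 as a function of x, the driver of all flows;
# written with log((1-x)/x) so the lam = 0 case never touches log(0)
fitness_diff_1d <- function(game, x, lam) {
  pis <- avg_payoff_1d(game, x)
  d <- pis[, "pi1"] - pis[, "pi2"]
  if (lam > 0) d <- d - lam * log(x / (1 - x))
  d
}

#' Deterministic Sato-Crutchfield flow, one population
#'
#' The infinite-population limit of the idea-chain:
#' \eqn{\dot x = \Gamma x (1 - x) (f_1 - f_2)} with the modified fitness
#' \eqn{f_i = \pi_i - \lambda \ln x_i}. For \eqn{\lambda = 0} this is
#' \eqn{\Gamma} times the replicator velocity. The boundary points
#' \eqn{x = 0, 1} are fixed points for every game and every \eqn{\lambda}
#' (the \eqn{x(1-x)} prefactor dominates the log divergence;
#' \eqn{\lim_{x\to0} x \ln x = 0}), and the flow returns exactly 0 there.
#'
#' @param game a \code{payoff_matrix}.
#' @param x frequency in \eqn{[0, 1]} (vectorised).
#' @param params a [dyn_params()].
#' @return \eqn{dx/dt} at each \code{x}.
#' @export
sc_flow_1d <- function(game, x, params) {
  stopifnot(all(x >= 0 & x <= 1))
  v <- numeric(length(x))
  inside <- x > 0 & x < 1
  if (any(inside)) {
    xi <- x[inside]
    v[inside] <- params$Gamma * xi * (1 - xi) *
      fitness_diff_1d(game, xi, params$lam)
  }
  v
}

#' Deterministic Sato-Crutchfield flow, two populations
#'
#' Componentwise flows \eqn{\dot x^A = \Gamma x^A (1 - x^A)(f^A_1 - f^A_2)}
#' (and likewise for B), where each population's payoffs are evaluated
#' against the other population's composition and each population's entropic
#' term uses its own frequencies. Boundary components are exact fixed
#' directions (velocity 0).
#'
#' @param game a \code{payoff_bimatrix}.
#' @param state \code{c(xA, xB)} in the unit square.
#' @param params a [dyn_params()].
#' @return velocity \code{c(dxA, dxB)}.
#' @export
sc_flow_2d <- function(game, state, params) {
  stopifnot(length(state) == 2L, all(state >= 0 & state <= 1))
  pis <- avg_payoff_2d(game, state)
  out <- numeric(2L)
  dA <- pis[["piA1"]] - pis[["piA2"]]
  dB <- pis[["piB1"]] - pis[["piB2"]]
  xA <- state[1]; xB <- state[2]
  if (xA > 0 && xA < 1) {
    if (params$lam > 0) dA <- dA - params$lam * log(xA / (1 - xA))
    out[1] <- params$Gamma * xA * (1 - xA) * dA
  }
  if (xB > 0 && xB < 1) {
    if (params$lam > 0) dB <- dB - params$lam * log(xB / (1 - xB))
    out[2] <- params$Gamma * xB * (1 - xB) * dB
  }
  out
}

#' Replicator-mutator flow (comparison model)
#'
#' \eqn{\dot x = \Gamma x (1 - x)(\pi_1 - \pi_2) + u (1 - 2x)}: the standard
#' two-type replicator term plus a symmetric mutation flux between the two
#' types. For \eqn{u > 0} the flow is strictly positive at \eqn{x = 0} and
#' strictly negative at \eqn{x = 1} — mutation-selection dynamics has no
#' absorbing states, the key structural contrast with the entropic
#' idea-chain, whose boundaries remain absorbing for every \eqn{\lambda}.
#'
#' @inheritParams sc_flow_1d
#' @return \eqn{dx/dt} at each \code{x}.
#' @export
replicator_mutator_flow <- function(game, x, params) {
  stopifnot(all(x >= 0 & x <= 1))
  pis <- avg_payoff_1d(game, x)
  unname(params$Gamma * x * (1 - x) * (pis[, "pi1"] - pis[, "pi2"]) +
           params$u * (1 - 2 * x))
}

#' Integrate a deterministic flow
#'
#' Adaptive stiff-capable integration (\code{deSolve::ode}, lsoda) of a 1D or
#' 2D flow, used e.g. to overlay deterministic trajectories on stochastic
#' sample paths. States are clipped to \eqn{[0, 1]} only within the absolute
#' tolerance of the boundary.
#'
#' @param flow function \code{(state) -> velocity} (length 1 or 2).
#' @param x0 initial state.
#' @param t_end final time (generations); output on \code{n_out} points.
#' @param rel_tol,abs_tol integrator tolerances.
#' @param n_out number of output times.
#' @return data.frame with column \code{t} and state columns \code{x} (1D) or
#'   \code{xA}, \code{xB} (2D).
#' @export
integrate_flow <- function(flow, x0, t_end, rel_tol = 1e-9, abs_tol = 1e-9,
                           n_out = 201L) {
  stopifnot(t_end > 0)
  # the adaptive integrator may probe marginally outside the unit interval;
  # the flow is only defined on it, so clamp the probe point
  deriv <- function(t, y, parms) list(flow(pmin(pmax(y, 0), 1)))
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(y = as.numeric(x0), times = times, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = rel_tol, atol = abs_tol)
  if (attr(sol, "istate")[1L] < 0)
    stop("ODE integration failed (t_end = ", t_end, ")", call. = FALSE)
  st <- as.matrix(sol[, -1, drop = FALSE])
  st[st < 0 & st > -abs_tol] <- 0
  st[st > 1 & st < 1 + abs_tol] <- 1
  out <- data.frame(t = sol[, 1L])
  if (ncol(st) == 1L) out$x <- st[, 1L]
  else { out$xA <- st[, 1L]; out$xB <- st[, 2L] }
  out
}
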