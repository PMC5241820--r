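#' Chain parameters for the finite population of ideas
#'
#' @param N population size (integer >= 2). Rates carry an explicit factor
#'   \eqn{N}, so time is measured in generations.
#' @param Gamma,lam as in [dyn_params()].
#' @param seed base RNG seed for simulation ensembles; replicate \eqn{r}
#'   uses \code{seed + (r - 1)}.
#' @return a \code{chain_params} list.
#' @export
chain_params <- function(N, Gamma = 0.1, lam = 0, seed = 1L) {
  N <- as.integer(N)
  stopifnot(N >= 2L, Gamma >= 0, lam >= 0)
  structure(list(N = N, Gamma = Gamma, lam = lam, seed = as.integer(seed)),
            class = "chain_params")
}

#' Linear pairwise comparison probability
#'
#' \eqn{g(f_1, f_2) = [1 + \Gamma (f_1 - f_2)]/2}: the probability that in a
#' pairwise comparison the first idea replaces the second. The linear form is
#' what makes the rate difference reproduce \eqn{\Gamma} times the replicator
#' drift. \eqn{g} is \emph{not} clipped to \eqn{[0, 1]}; parameter choices
#' that push it outside are a validation error ([validate_rates()]), mirroring
#' the model's admissibility constraint \eqn{\lambda < \lambda_c}.
#'
#' @param f1,f2 fitness values (vectorised).
#' @param Gamma intensity of choice.
#' @return comparison probabilities (callers must validate to \eqn{[0,1]}).
#' @export
pairwise_comparison_g <- function(f1, f2, Gamma) {
  (1 + Gamma * (f1 - f2)) / 2
}

#' Birth-death rates of the one-population idea chain
#'
#' For \eqn{0 < n < N}, with \eqn{x = n/N} and modified fitness
#' \eqn{f_i = \pi_i - \lambda \ln x_i} (finite-population payoffs
#' \eqn{\pi_1 = [a_{11} n + a_{12}(N-n)]/N}, including the focal individual):
#' \deqn{T^+_n = N x (1 - x)\, g(f_1, f_2), \qquad
#'       T^-_n = N x (1 - x)\, g(f_2, f_1).}
#' The states \eqn{n = 0} and \eqn{n = N} are absorbing (all rates zero), so
#' ideas can reach fixation or go extinct for every \eqn{\lambda} — unlike
#' mutation-selection chains. Construction fails if [validate_rates()] finds
#' a negative rate.
#'
#' @param game a \code{payoff_matrix}.
#' @param params a [chain_params()].
#' @return a \code{bd_rates_1d} list with vectors \code{Tplus}, \code{Tminus}
#'   indexed by \code{n = 0..N}, plus \code{N} and \code{params}.
#' @export
rates_1d <- function(game, params) {
  v <- validate_rates(game, params)
  if (!v$ok)
    stop("invalid rates: g outside [0, 1] at n = ",
         paste(utils::head(v$offending, 5), collapse = ", "),
         "; maximal admissible lambda at this Gamma is ",
         signif(v$lam_max, 4), call. = FALSE)
  r <- rates_1d_raw(game, params)
  structure(c(r, list(N = params$N, params = params)),
            class = "bd_rates_1d")
}

rates_1d_raw <- function(game, params) {
  N <- params$N
  n <- 0:N
  x <- n / N
  Tplus <- Tminus <- numeric(N + 1L)
  inner <- 2:N  # n = 1..N-1
  xi <- x[inner]
  pis <- avg_payoff_1d(game, xi)
  f1 <- modified_fitness(pis[, "pi1"], xi, params$lam)
  f2 <- modified_fitness(pis[, "pi2"], 1 - xi, params$lam)
  pref <- N * xi * (1 - xi)
  Tplus[inner] <- pref * pairwise_comparison_g(f1, f2, params$Gamma)
  Tminus[inner] <- pref * pairwise_comparison_g(f2, f1, params$Gamma)
  list(Tplus = Tplus, Tminus = Tminus)
}

#' Birth-death rates of the two-population idea chain
#'
#' Rate lattices over \eqn{(n, m) \in \{0..N\}^2} for transitions
#' \eqn{(n, m) \to (n \pm 1, m)} (population A) and
#' \eqn{(n, m) \to (n, m \pm 1)} (population B). Each population's fitness
#' is evaluated against the \emph{other} population's composition, with its
#' own entropic penalty. The four corners are the chain's only absorbing
#' states.
#'
#' @param game a \code{payoff_bimatrix}.
#' @param params a [chain_params()].
#' @return a \code{bd_rates_2d} list with \eqn{(N+1) \times (N+1)} matrices
#'   \code{TAp}, \code{TAm}, \code{TBp}, \code{TBm} (row = n+1, col = m+1).
#' @export
rates_2d <- function(game, params) {
  v <- validate_rates(game, params)
  if (!v$ok)
    stop("invalid rates: g outside [0, 1]; maximal admissible lambda at ",
         "this Gamma is ", signif(v$lam_max, 4), call. = FALSE)
  N <- params$N
  x <- (0:N) / N
  # population A moves in n (rows); its payoffs depend on xB = m/N (cols)
  piA <- avg_payoff_1d(game$A, x)  # row i: opponent composition x[i]
  piB <- avg_payoff_1d(game$B, x)
  lam <- params$lam
  ent <- if (lam > 0) {
    e <- numeric(N + 1L)
    e[2:N] <- -lam * log(x[2:N] / (1 - x[2:N]))  # -lam*[ln x - ln(1-x)]
    e
  } else numeric(N + 1L)
  # fitness difference f1 - f2 for A at (n, m): piA1(m) - piA2(m) + ent[n]
  dA <- outer(ent, piA[, "pi1"] - piA[, "pi2"], `+`)     # [n+1, m+1]
  dB <- t(outer(ent, piB[, "pi1"] - piB[, "pi2"], `+`))  # [n+1, m+1]
  prefA <- matrix(N * x * (1 - x), N + 1L, N + 1L)         # depends on n
  prefB <- matrix(N * x * (1 - x), N + 1L, N + 1L, byrow = TRUE)
  gA <- (1 + params$Gamma * dA) / 2
  gB <- (1 + params$Gamma * dB) / 2
  out <- list(TAp = prefA * gA, TAm = prefA * (1 - gA),
              TBp = prefB * gB, TBm = prefB * (1 - gB),
              N = N, params = params)
  # boundary rows/cols: the x(1-x) prefactor already zeroes them exactly
  structure(out, class = "bd_rates_2d")
}

#' Validate the positivity of the birth-death rates
#'
#' Checks \eqn{g \in [0, 1]} (equivalently both rates nonnegative) at every
#' interior state of the 1D or 2D lattice. On failure the diagnostic lists
#' the offending states and the maximal admissible \eqn{\lambda} at the given
#' \eqn{\Gamma} (found by bisection); this is the finite-\eqn{N} counterpart
#' of the admissibility constraint \eqn{\lambda < \lambda_c = O(1/\ln N)}:
#' the entropic term \eqn{\lambda |\ln(n/N)|} is largest one step from the
#' boundary, so the admissible \eqn{\lambda} shrinks logarithmically as
#' \eqn{N} grows.
#'
#' @param game a \code{payoff_matrix} or \code{payoff_bimatrix}.
#' @param params a [chain_params()].
#' @return a list with \code{ok} (logical), \code{offending} (states where g
#'   leaves \eqn{[0,1]}; empty when ok), \code{max_violation}, and
#'   \code{lam_max} (maximal admissible \eqn{\lambda} at this \eqn{\Gamma}
#'   and \eqn{N}).
#' @export
validate_rates <- function(game, params) {
  gex <- function(lam) g_excess(game, params, lam)
  ex <- gex(params$lam)
  ok <- ex$max <= 0
  lam_max <- if (gex(0)$max > 0) {
    0  # inadmissible even without memory loss (Gamma too large)
  } else {
    lo <- 0; hi <- max(params$lam, 1)
    while (hi < 1e9 && gex(hi)$max <= 0) hi <- hi * 2
    if (hi >= 1e9) Inf  # no entropic constraint (e.g. neutral game, N = 2)
    else {
      while (hi - lo > 1e-10 * max(1, hi)) {
        mid <- (lo + hi) / 2
        if (gex(mid)$max <= 0) lo <- mid else hi <- mid
      }
      lo
    }
  }
  list(ok = ok, offending = ex$offending, max_violation = max(ex$max, 0),
       lam_max = lam_max)
}

# largest excursion of g outside [0, 1] over the interior lattice, i.e.
# max(|Gamma * (f1 - f2)| - 1)/2, and the states achieving it
g_excess <- function(game, params, lam) {
  N <- params$N
  x <- (1:(N - 1)) / N
  if (is_bimatrix(game)) {
    ent <- -lam * log(x / (1 - x))
    dmaxA <- range(pidiff_at(game$A, c(0:N) / N))
    dmaxB <- range(pidiff_at(game$B, c(0:N) / N))
    # f-diff for A at (n, m): pidiff_A(m/N) + ent(n/N); worst case over m
    # is attained at a lattice endpoint since pidiff is linear
    exA <- abs(outer(ent, pidiff_at(game$A, c(0, 1)), `+`))
    exB <- abs(outer(ent, pidiff_at(game$B, c(0, 1)), `+`))
    viol <- params$Gamma * pmax(apply(exA, 1, max), apply(exB, 1, max)) - 1
  } else {
    d <- pidiff_at(game, x) - lam * log(x / (1 - x))
    viol <- params$Gamma * abs(d) - 1
  }
  list(max = max(viol) / 2, offending = (1:(N - 1))[viol > 0])
}
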