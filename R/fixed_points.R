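# Fixed-point location and classification for the deterministic flows.
#
# All interior fixed points of the Sato-Crutchfield flow are roots of the
# fitness difference phi = pi_1 - pi_2 - lam * logit(x) (the x(1-x) prefactor
# never vanishes inside).  For lam > 0 a root can lie at logit values of
# order max|pi_1 - pi_2| / lam, i.e. exponentially close to the boundary in
# x, so bracketing and deduplication are done in logit space where these
# roots are well separated from the boundary fixed points.

LOGIT_CAP <- 500  # beyond this, plogis() underflows; roots are untrackable

logit_range <- function(max_pidiff, lam) {
  min(LOGIT_CAP, (max_pidiff + 1) / lam)
}

# slope of pi_1 - pi_2 in x (constant: payoffs are linear in frequencies)
pidiff_slope <- function(game) {
  (game[1, 1] - game[2, 1]) - (game[1, 2] - game[2, 2])
}

pidiff_at <- function(game, x) {
  (game[1, 1] - game[2, 1]) * x + (game[1, 2] - game[2, 2]) * (1 - x)
}

#' Locate and classify fixed points of the one-population flow
#'
#' Finds all roots of the Sato-Crutchfield flow on \eqn{[0, 1]}: the two
#' boundary points (fixed for every game and every \eqn{\lambda}) plus all
#' interior roots of the fitness difference, located by sign-change
#' bracketing on a uniform grid in logit space (\eqn{\lambda > 0}) or in
#' \eqn{x} (\eqn{\lambda = 0}) and refined with \code{uniroot}. Each root is
#' classified by the flow derivative: at an interior root the eigenvalue is
#' \eqn{\Gamma [k\, x(1-x) - \lambda]} with \eqn{k} the slope of
#' \eqn{\pi_1 - \pi_2}.
#'
#' @param game a \code{payoff_matrix}.
#' @param params a [dyn_params()].
#' @param n_grid number of grid points for bracketing (>= 64).
#' @param tol root tolerance on the fitness difference.
#' @return a \code{fixed_point_set}: data.frame with columns \code{x},
#'   \code{logit_x}, \code{stability}, \code{eigenvalue}, \code{boundary}.
#' @examples
#' find_fixed_points_1d(make_symmetric_game("coordination"),
#'                      dyn_params(lam = 0.1))
#' @export
find_fixed_points_1d <- function(game, params, n_grid = 1024L, tol = 1e-10) {
  stopifnot(n_grid >= 64L)
  lam <- params$lam
  k <- pidiff_slope(game)
  phi <- function(y) {
    x <- stats::plogis(y)
    pidiff_at(game, x) - lam * y
  }

  roots_y <- numeric(0)
  if (lam > 0) {
    ymax <- logit_range(max(abs(pidiff_at(game, c(0, 1)))), lam)
    grid <- seq(-ymax, ymax, length.out = n_grid)
    roots_y <- bracket_roots(phi, grid, tol)
  } else if (k != 0) {
    # pi_1 - pi_2 is linear in x: at most one interior root
    xr <- -pidiff_at(game, 0) / k
    if (xr > 0 && xr < 1) roots_y <- stats::qlogis(xr)
  }
  roots_y <- dedup_sorted(sort(roots_y), 1e-6)

  xr <- stats::plogis(roots_y)
  eig <- params$Gamma * (k * xr * (1 - xr) - lam)
  interior <- data.frame(
    x = xr, logit_x = roots_y,
    stability = ifelse(eig < 0, "stable", ifelse(eig > 0, "unstable", "center")),
    eigenvalue = eig, boundary = FALSE, stringsAsFactors = FALSE)

  bnd <- boundary_stability_1d(game, lam)
  out <- rbind(bnd, interior)
  out <- out[order(out$x, out$logit_x), ]
  rownames(out) <- NULL
  structure(out, class = c("fixed_point_set", "data.frame"),
            tol = tol, params = params)
}

# x = 0 and x = 1 are always fixed; for lam > 0 the entropic force makes
# both unstable (flow points inward just inside the boundary).
boundary_stability_1d <- function(game, lam) {
  stab0 <- if (lam > 0) "unstable" else {
    d0 <- pidiff_at(game, 0)
    if (d0 > 0) "unstable" else if (d0 < 0) "stable" else "center"
  }
  stab1 <- if (lam > 0) "unstable" else {
    d1 <- pidiff_at(game, 1)
    if (d1 < 0) "unstable" else if (d1 > 0) "stable" else "center"
  }
  eig0 <- if (lam > 0) Inf else NA_real_
  data.frame(x = c(0, 1), logit_x = c(-Inf, Inf),
             stability = c(stab0, stab1),
             eigenvalue = c(eig0, eig0),
             boundary = TRUE, stringsAsFactors = FALSE)
}

bracket_roots <- function(f, grid, tol) {
  fv <- vapply(grid, f, numeric(1))
  roots <- grid[fv == 0]
  sgn <- sign(fv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in idx) {
    r <- stats::uniroot(f, lower = grid[i], upper = grid[i + 1],
                        tol = min(tol, 1e-12))
    roots <- c(roots, r$root)
  }
  roots
}

dedup_sorted <- function(x, sep) {
  if (length(x) < 2L) return(x)
  keep <- c(TRUE, diff(x) > sep)
  x[keep]
}

#' Locate and classify fixed points of the two-population flow
#'
#' Fixed points of the two-population Sato-Crutchfield flow on the unit
#' square come in three kinds, each searched separately: the four corners
#' (always fixed), edge points (one frozen coordinate; for \eqn{\lambda > 0}
#' exactly one per edge, always a saddle: attracting along the edge,
#' repelled into the interior by the entropic force), and interior roots of
#' the pair of fitness differences, found by grid seeding plus damped Newton
#' refinement with the analytic Jacobian, deduplicated in logit space.
#' Interior points are classified by the Jacobian of the flow; a point is a
#' \emph{center} when the eigenvalues' real parts vanish (within
#' \code{eig_tol}) with nonzero imaginary parts.
#'
#' @param game a \code{payoff_bimatrix}.
#' @param params a [dyn_params()].
#' @param n_grid seeds per axis for the interior search.
#' @param tol root tolerance on the fitness-difference vector.
#' @param eig_tol tolerance on real parts for center classification.
#' @return a \code{fixed_point_set} data.frame with columns \code{xA},
#'   \code{xB}, \code{stability}, \code{eig1}, \code{eig2} (complex),
#'   \code{kind} (corner/edge/interior).
#' @export
find_fixed_points_2d <- function(game, params, n_grid = 64L, tol = 1e-10,
                                 eig_tol = 1e-8) {
  stopifnot(n_grid >= 16L)
  lam <- params$lam
  kA <- pidiff_slope(game$A)
  kB <- pidiff_slope(game$B)
  pidA <- function(xB) pidiff_at(game$A, xB)
  pidB <- function(xA) pidiff_at(game$B, xA)

  pts <- corner_points_2d(game, params)
  pts <- rbind(pts, edge_points_2d(game, params))

  # interior roots of (piA_diff - lam*yA, piB_diff - lam*yB) in logit space
  seeds <- interior_seeds(game, lam, n_grid)
  found <- matrix(numeric(0), ncol = 2)
  for (s in seq_len(nrow(seeds))) {
    r <- newton_2d(seeds[s, ], pidA, pidB, kA, kB, lam, tol)
    if (!is.null(r)) found <- rbind(found, r)
  }
  if (nrow(found)) {
    # 1e-3 in logit space: far below genuine root separations at the
    # bifurcation-refinement width, far above the flat-residual noise that
    # Newton leaves exactly at a degenerate parameter value
    found <- dedup_rows(found, 1e-3)
    for (s in seq_len(nrow(found))) {
      yA <- found[s, 1]; yB <- found[s, 2]
      xA <- stats::plogis(yA); xB <- stats::plogis(yB)
      J <- flow_jacobian_interior(xA, xB, kA, kB, params)
      ev <- eigen(J, only.values = TRUE)$values
      pts <- rbind(pts, data.frame(
        xA = xA, xB = xB, stability = classify_eigenvalues(ev, eig_tol),
        eig1 = complex_or_real(ev[1]), eig2 = complex_or_real(ev[2]),
        kind = "interior", stringsAsFactors = FALSE))
    }
  }
  rownames(pts) <- NULL
  structure(pts, class = c("fixed_point_set", "data.frame"),
            tol = tol, params = params)
}

complex_or_real <- function(z) as.complex(z)

interior_seeds <- function(game, lam, n_grid) {
  if (lam > 0) {
    mA <- max(abs(pidiff_at(game$A, c(0, 1))))
    mB <- max(abs(pidiff_at(game$B, c(0, 1))))
    ya <- seq(-logit_range(mA, lam), logit_range(mA, lam), length.out = n_grid)
    yb <- seq(-logit_range(mB, lam), logit_range(mB, lam), length.out = n_grid)
  } else {
    ya <- yb <- stats::qlogis(seq(0.02, 0.98, length.out = n_grid))
  }
  as.matrix(expand.grid(yA = ya, yB = yb))
}

newton_2d <- function(y, pidA, pidB, kA, kB, lam, tol, max_iter = 200L) {
  for (it in seq_len(max_iter)) {
    xA <- stats::plogis(y[1]); xB <- stats::plogis(y[2])
    FA <- pidA(xB) - lam * y[1]
    FB <- pidB(xA) - lam * y[2]
    J <- matrix(c(-lam, kA * xB * (1 - xB),
                  kB * xA * (1 - xA), -lam), 2L, 2L, byrow = TRUE)
    det_j <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
    if (abs(det_j) < 1e-14) return(NULL)
    step <- solve(J, c(FA, FB))
    # damp large steps to keep the iteration inside the searchable band
    sn <- sqrt(sum(step^2))
    if (sn > 10) step <- step * (10 / sn)
    y <- y - step
    # accept only on step convergence as well as a small residual, so a
    # near-degenerate (bifurcating) root collapses to a single point
    # instead of a flat band of small-residual pseudo-roots
    if (max(abs(FA), abs(FB)) < tol && sn < 1e-9) {
      if (max(abs(y)) > LOGIT_CAP) return(NULL)
      return(y)
    }
    if (max(abs(y)) > 2 * LOGIT_CAP) return(NULL)
  }
  NULL  # non-convergent seed: skipped
}

dedup_rows <- function(m, sep) {
  if (nrow(m) < 2L) return(m)
  keep <- rep(TRUE, nrow(m))
  for (i in 2:nrow(m)) {
    for (j in which(keep[seq_len(i - 1L)])) {
      if (max(abs(m[i, ] - m[j, ])) < sep) { keep[i] <- FALSE; break }
    }
  }
  m[keep, , drop = FALSE]
}

# Jacobian of the flow at an interior root: the diagonal is -Gamma*lam
# (entropic self-damping), the off-diagonal the cross-population coupling.
flow_jacobian_interior <- function(xA, xB, kA, kB, params) {
  G <- params$Gamma
  matrix(c(-G * params$lam, G * xA * (1 - xA) * kA,
           G * xB * (1 - xB) * kB, -G * params$lam), 2L, 2L, byrow = TRUE)
}

classify_eigenvalues <- function(ev, eig_tol) {
  re <- Re(ev); im <- Im(ev)
  if (all(abs(re) < eig_tol) && any(abs(im) > eig_tol)) return("center")
  if (all(re < -eig_tol)) return("stable")
  if (all(re > eig_tol)) return("unstable")
  if (any(re > eig_tol) && any(re < -eig_tol)) return("saddle")
  "center"
}

corner_points_2d <- function(game, params) {
  lam <- params$lam
  G <- params$Gamma
  out <- NULL
  for (cA in c(0, 1)) for (cB in c(0, 1)) {
    if (lam > 0) {
      # entropic force repels from both faces: every corner is unstable
      stab <- "unstable"; e1 <- e2 <- complex(real = Inf)
    } else {
      gA <- if (cA == 0) G * pidiff_at(game$A, cB) else -G * pidiff_at(game$A, cB)
      gB <- if (cB == 0) G * pidiff_at(game$B, cA) else -G * pidiff_at(game$B, cA)
      stab <- classify_eigenvalues(complex(real = c(gA, gB)), 1e-12)
      e1 <- complex(real = gA); e2 <- complex(real = gB)
    }
    out <- rbind(out, data.frame(xA = cA, xB = cB, stability = stab,
                                 eig1 = e1, eig2 = e2, kind = "corner",
                                 stringsAsFactors = FALSE))
  }
  out
}

# Edge fixed points: one coordinate frozen at 0 or 1, the other at the root
# of its fitness difference. The frozen player's payoff difference is a
# constant there, so for lam > 0 each edge carries exactly one fixed point,
# at logit(x) = pidiff/lam; for lam = 0 edges hold no isolated fixed points
# (the moving player's payoff difference is constant in its own frequency).
edge_points_2d <- function(game, params) {
  lam <- params$lam
  if (lam <= 0) return(NULL)
  G <- params$Gamma
  out <- NULL
  for (edge in c("A0", "A1", "B0", "B1")) {
    frozen_val <- if (substr(edge, 2, 2) == "0") 0 else 1
    if (substr(edge, 1, 1) == "A") {
      cst <- pidiff_at(game$B, frozen_val)  # B moves, A frozen
    } else {
      cst <- pidiff_at(game$A, frozen_val)  # A moves, B frozen
    }
    y <- cst / lam
    if (abs(y) > LOGIT_CAP) next
    xm <- stats::plogis(y)
    if (substr(edge, 1, 1) == "A") { xA <- frozen_val; xB <- xm }
    else { xA <- xm; xB <- frozen_val }
    # attracting along the edge (eigenvalue -Gamma*lam), repelled transversally
    out <- rbind(out, data.frame(
      xA = xA, xB = xB, stability = "saddle",
      eig1 = complex(real = -G * lam), eig2 = complex(real = Inf),
      kind = "edge", stringsAsFactors = FALSE))
  }
  out
}

#' Locate fixed points of the replicator-mutator flow
#'
#' Generic 1D sign-change scan of [replicator_mutator_flow()] on a uniform
#' grid with \code{uniroot} refinement. For \eqn{u > 0} the flow is nonzero
#' at both boundaries (no absorbing states), so only interior roots exist.
#'
#' @inheritParams find_fixed_points_1d
#' @return a \code{fixed_point_set} data.frame (columns as in
#'   [find_fixed_points_1d()], without \code{logit_x}).
#' @export
find_fixed_points_rm <- function(game, params, n_grid = 512L, tol = 1e-12) {
  f <- function(x) replicator_mutator_flow(game, x, params)
  grid <- seq(0, 1, length.out = n_grid)
  roots <- dedup_sorted(sort(bracket_roots(f, grid, tol)), 1e-9)
  h <- 1e-7
  eig <- vapply(roots, function(r) {
    (f(min(r + h, 1)) - f(max(r - h, 0))) / (min(r + h, 1) - max(r - h, 0))
  }, numeric(1))
  structure(data.frame(
    x = roots,
    stability = ifelse(eig < 0, "stable", ifelse(eig > 0, "unstable", "center")),
    eigenvalue = eig, boundary = roots %in% c(0, 1),
    stringsAsFactors = FALSE),
    class = c("fixed_point_set", "data.frame"), tol = tol, params = params)
}

#' @export
print.fixed_point_set <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Fixed points (Gamma = %g, lambda = %g%s): %d\n",
              p$Gamma, p$lam,
              if (p$u > 0) sprintf(", u = %g", p$u) else "", nrow(x)))
  print(as.data.frame(x))
  invisible(x)
}

#' Scan the fixed-point structure across the memory-loss parameter
#'
#' Tracks the number and location of fixed points of the one- or
#' two-population Sato-Crutchfield flow over a grid of \eqn{\lambda} values
#' and reports every \eqn{\lambda_c} at which the count changes (saddle-node
#' or symmetric merges), refined by bisection on the count to a stated width.
#' A scan with no count change (e.g. a coexistence game) reports no
#' \eqn{\lambda_c}, a valid outcome.
#'
#' @param game a \code{payoff_matrix} or \code{payoff_bimatrix}.
#' @param params_base a [dyn_params()]; its \code{lam} is ignored.
#' @param lam_grid increasing grid of \eqn{\lambda} values (>= 16 points).
#' @param refine_tol bisection width for each \eqn{\lambda_c}.
#' @return a \code{bifurcation_result} list: \code{lam_grid}, \code{counts},
#'   \code{branches} (one \code{fixed_point_set} per grid value),
#'   \code{lam_c} (possibly empty), \code{bracket} (matrix of bounding
#'   intervals), \code{count_change} (count just below -> just above).
#' @export
bifurcation_scan <- function(game, params_base, lam_grid,
                             refine_tol = 1e-4) {
  stopifnot(length(lam_grid) >= 16L, !is.unsorted(lam_grid, strictly = TRUE))
  fp_at <- function(lam) {
    p <- dyn_params(Gamma = params_base$Gamma, lam = lam, u = params_base$u)
    if (is_bimatrix(game)) find_fixed_points_2d(game, p)
    else find_fixed_points_1d(game, p)
  }
  branches <- lapply(lam_grid, fp_at)
  counts <- vapply(branches, nrow, integer(1))
  lam_c <- numeric(0)
  bracket <- matrix(numeric(0), ncol = 2,
                    dimnames = list(NULL, c("lower", "upper")))
  change <- matrix(integer(0), ncol = 2,
                   dimnames = list(NULL, c("below", "above")))
  for (i in which(diff(counts) != 0)) {
    lo <- lam_grid[i]; hi <- lam_grid[i + 1]
    c_lo <- counts[i]
    while (hi - lo > refine_tol) {
      mid <- (lo + hi) / 2
      if (nrow(fp_at(mid)) == c_lo) lo <- mid else hi <- mid
    }
    lam_c <- c(lam_c, (lo + hi) / 2)
    bracket <- rbind(bracket, c(lo, hi))
    change <- rbind(change, c(counts[i], counts[i + 1]))
  }
  structure(list(lam_grid = lam_grid, counts = counts, branches = branches,
                 lam_c = lam_c, bracket = bracket, count_change = change),
            class = "bifurcation_result")
}

#' @export
print.bifurcation_result <- function(x, ...) {
  cat(sprintf("Bifurcation scan over lambda in [%g, %g] (%d points)\n",
              min(x$lam_grid), max(x$lam_grid), length(x$lam_grid)))
  cat("fixed-point counts:", paste(unique(x$counts), collapse = " -> "), "\n")
  if (length(x$lam_c)) {
    for (i in seq_along(x$lam_c)) {
      cat(sprintf("lambda_c = %.5f (count %d -> %d, bracket width %.2g)\n",
                  x$lam_c[i], x$count_change[i, 1], x$count_change[i, 2],
                  x$bracket[i, 2] - x$bracket[i, 1]))
    }
  } else cat("no count change on the grid\n")
  invisible(x)
}
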