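#' Construct a symmetric 2x2 game
#'
#' A symmetric two-player two-strategy game is specified by a payoff matrix
#' \eqn{A = (a_{ij})}: \eqn{a_{ij}} is the payoff to an individual (idea) of
#' type \eqn{i} interacting with one of type \eqn{j}. Named fixtures cover the
#' three qualitatively distinct replicator flow patterns on \eqn{x \in [0,1]}
#' plus the neutral game.
#'
#' The fixture catalogue is
#' \describe{
#'   \item{coexistence}{\code{(1, 2, 2, 1)}: both boundary fixed points
#'     unstable, stable interior point.}
#'   \item{dominance}{\code{(3, 1, 2, 0)}: type 1 strictly dominant, flow
#'     towards \eqn{x = 1}.}
#'   \item{coordination}{\code{(2, 0, 0, 1)}: both boundaries stable, interior
#'     unstable point at \eqn{x = 1/3}.}
#'   \item{neutral}{\code{(1, 1, 1, 1)}: no selection.}
#' }
#'
#' @param name_or_entries either a fixture name (see Details) or a numeric
#'   vector \code{c(a11, a12, a21, a22)} / 2x2 matrix of finite payoffs.
#' @return a \code{payoff_matrix}: a 2x2 numeric matrix with class attribute.
#' @seealso [classify_symmetric()], [make_asymmetric_game()]
#' @examples
#' make_symmetric_game("coordination")
#' make_symmetric_game(c(1, 2, 2, 1))
#' @export
make_symmetric_game <- function(name_or_entries) {
  if (is.character(name_or_entries)) {
    name <- match_game_name(name_or_entries, names(.symmetric_fixtures))
    entries <- .symmetric_fixtures[[name]]
  } else {
    entries <- as_payoff_entries(name_or_entries)
  }
  m <- matrix(entries, 2L, 2L, byrow = TRUE,
              dimnames = list(paste0("i", 1:2), paste0("j", 1:2)))
  structure(m, class = c("payoff_matrix", "matrix"))
}

.symmetric_fixtures <- list(
  coexistence  = c(1, 2, 2, 1),
  dominance    = c(3, 1, 2, 0),
  coordination = c(2, 0, 0, 1),
  neutral      = c(1, 1, 1, 1)
)

#' Construct an asymmetric 2x2 game (payoff bi-matrix)
#'
#' An asymmetric game couples two distinct players (hence two populations of
#' ideas). Entry \code{A[i, j]} is the payoff to player A choosing action
#' \eqn{i} against player B's action \eqn{j}; \code{B[j, i]} is B's payoff in
#' the same encounter (so \code{B} is indexed by B's own action first).
#'
#' Fixtures:
#' \describe{
#'   \item{matching_pennies}{zero-sum (\eqn{a_{ij} + b_{ji} = 0}); the
#'     replicator flow has closed orbits around \eqn{(1/2, 1/2)}.}
#'   \item{asym_dominance}{player A's action 1 strictly dominates; the flow
#'     has one stable pure-strategy fixed point.}
#'   \item{hyperbolic}{interior saddle, two stable and two unstable corners;
#'     the payoffs are symmetric under simultaneously swapping players and
#'     action labels, so under memory loss the two stable points merge with
#'     the saddle at a single critical \eqn{\lambda_c}.}
#' }
#'
#' @param name_or_entries a fixture name, or a list with components \code{a}
#'   and \code{b} (each a 2x2 matrix or length-4 row-major vector).
#' @return a \code{payoff_bimatrix}: list with \code{payoff_matrix} components
#'   \code{A} and \code{B}.
#' @examples
#' g <- make_asymmetric_game("matching_pennies")
#' g$A + t(g$B)  # zero-sum identity a_ij + b_ji = 0
#' @export
make_asymmetric_game <- function(name_or_entries) {
  if (is.character(name_or_entries)) {
    name <- match_game_name(name_or_entries, names(.asymmetric_fixtures))
    fix <- .asymmetric_fixtures[[name]]
    a <- fix$a
    b <- fix$b
  } else if (is.list(name_or_entries) &&
             all(c("a", "b") %in% names(name_or_entries))) {
    a <- as_payoff_entries(name_or_entries$a)
    b <- as_payoff_entries(name_or_entries$b)
  } else {
    stop("supply a fixture name or list(a = ..., b = ...)", call. = FALSE)
  }
  out <- list(A = make_symmetric_game(a), B = make_symmetric_game(b))
  class(out) <- "payoff_bimatrix"
  out
}

# b is stored with B's own action as the row index, so zero-sum means
# B = -t(A); for the symmetric-entry matching pennies matrix -t(A) = -A.
.asymmetric_fixtures <- list(
  matching_pennies = list(a = c(1, -1, -1, 1), b = c(-1, 1, 1, -1)),
  asym_dominance   = list(a = c(2, 1, 1, 0),  b = c(2, 0, 0, 1)),
  hyperbolic       = list(a = c(1, 0, 0, 1),  b = c(1, 0, 0, 1))
)

#' Classify a symmetric 2x2 game
#'
#' The replicator flow pattern on \eqn{[0, 1]} is a pure function of the sign
#' pattern of \eqn{a_{11} - a_{21}} and \eqn{a_{22} - a_{12}}:
#' \emph{coordination} if both positive (bistable), \emph{coexistence} if both
#' negative (stable interior point), \emph{dominance} if one strategy weakly
#' dominates with at least one strict inequality, \emph{other} otherwise
#' (e.g. fully neutral games).
#'
#' @param game a \code{payoff_matrix}.
#' @return one of \code{"coordination"}, \code{"coexistence"},
#'   \code{"dominance"}, \code{"other"}.
#' @export
classify_symmetric <- function(game) {
  game <- make_symmetric_game(unclass(game))
  d1 <- game[1, 1] - game[2, 1]  # advantage of 1 against a type-1 opponent
  d2 <- game[2, 2] - game[1, 2]  # advantage of 2 against a type-2 opponent
  if (d1 > 0 && d2 > 0) return("coordination")
  if (d1 < 0 && d2 < 0) return("coexistence")
  # weak dominance of one row with at least one strict inequality
  if (d1 >= 0 && d2 <= 0 && (d1 > 0 || d2 < 0)) return("dominance")
  if (d1 <= 0 && d2 >= 0 && (d1 < 0 || d2 > 0)) return("dominance")
  "other"
}

#' Read a game from a config list or YAML/JSON file
#'
#' Accepts `game: {name: coordination}` or explicit entries
#' `game: {a: [[2,0],[0,1]]}` (bi-matrices add `b: [[...]]`).
#'
#' @param config a file path (YAML or JSON) or an already-parsed list with a
#'   \code{game} entry or the game fields themselves.
#' @return a \code{payoff_matrix} or \code{payoff_bimatrix}.
#' @export
game_from_config <- function(config) {
  if (is.character(config) && length(config) == 1L && file.exists(config)) {
    config <- read_config_file(config)
  }
  spec <- if (!is.null(config$game)) config$game else config
  if (!is.null(spec$name)) {
    if (spec$name %in% names(.symmetric_fixtures))
      return(make_symmetric_game(spec$name))
    return(make_asymmetric_game(spec$name))
  }
  if (!is.null(spec$b)) {
    return(make_asymmetric_game(list(a = to_matrix(spec$a),
                                     b = to_matrix(spec$b))))
  }
  if (!is.null(spec$a)) return(make_symmetric_game(to_matrix(spec$a)))
  stop("config must contain game$name or game$a (and game$b)", call. = FALSE)
}

read_config_file <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    cfg <- yaml::read_yaml(path)
    # YAML 1.1 reads a bare `N:` key as the boolean FALSE; restore the
    # population-size key (no other config key collides with a bool literal)
    names(cfg)[names(cfg) == "FALSE"] <- "N"
    cfg
  }
}

to_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x)) return(do.call(rbind, lapply(x, as.numeric)))
  matrix(as.numeric(x), 2L, 2L, byrow = TRUE)
}

as_payoff_entries <- function(x) {
  if (is.matrix(x)) x <- as.numeric(t(x))  # row-major
  x <- as.numeric(x)
  if (length(x) != 4L) stop("a 2x2 game needs exactly 4 payoff entries",
                            call. = FALSE)
  if (!all(is.finite(x))) stop("payoff entries must be finite", call. = FALSE)
  x
}

match_game_name <- function(name, catalogue) {
  if (!name %in% catalogue) {
    stop(sprintf("unknown game '%s'; available: %s", name,
                 paste(catalogue, collapse = ", ")), call. = FALSE)
  }
  name
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat("2x2 payoff matrix (", classify_symmetric(x), " class)\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' @export
print.payoff_bimatrix <- function(x, ...) {
  cat("2x2 payoff bi-matrix\nPlayer A (rows = A's action):\n")
  print(unclass(x$A))
  cat("Player B (rows = B's action):\n")
  print(unclass(x$B))
  invisible(x)
}

is_bimatrix <- function(game) inherits(game, "payoff_bimatrix")
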