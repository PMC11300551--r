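#' Specify a cooperation dilemma
#'
#' Constructs a game specification for one of the two cooperation dilemmas
#' supported by the package: the Donation Game (DG), a two-player dilemma in
#' which cooperation confers a benefit \code{B} on the partner at a personal
#' cost \code{c}, and the Public Goods Game (PGG), an n-player dilemma in
#' which contributions \code{c} are multiplied by \code{r} and shared equally
#' within groups of size \code{n} drawn by multivariate hypergeometric
#' sampling from the population.
#'
#' Both games share a defining property: the payoff gap
#' \eqn{\delta = \Pi_C(j) - \Pi_D(j)} between the average cooperator and
#' defector payoffs does not depend on the number of cooperators \eqn{j},
#' and is strictly negative (cooperation is dominated). Every analytic
#' result in the package relies on this, so construction rejects any
#' parameterisation with \eqn{\delta \ge 0} unless \code{force = TRUE}.
#'
#' @param variant "dg" or "pgg".
#' @param N population size, integer >= 2.
#' @param B benefit conferred by a cooperator (DG only), must exceed `c`.
#' @param c cost of cooperation (both games), > 0.
#' @param r multiplication factor of the common pool (PGG only), 1 < r < n.
#' @param n group size (PGG only), 2 <= n <= N.
#' @param force if TRUE, allow delta >= 0 parameterisations (exploration
#'   only; the analytic machinery assumes delta < 0).
#' @return An object of class \code{game_spec}.
#' @examples
#' g <- game_spec("dg", N = 3, B = 2, c = 1)
#' payoff_difference(g) # -2
#' @export
game_spec <- function(variant = c("dg", "pgg"), N, B = NULL, c = NULL,
                      r = NULL, n = NULL, force = FALSE) {
  variant <- match.arg(variant)
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N))
    stop("N must be a single integer >= 2", call. = FALSE)
  N <- as.integer(N)
  if (variant == "dg") {
    if (is.null(B) || is.null(c))
      stop("DG requires B and c", call. = FALSE)
    if (!(B > c && c > 0))
      stop("DG requires B > c > 0", call. = FALSE)
    g <- structure(list(variant = "dg", N = N, B = B, c = c),
                   class = "game_spec")
  } else {
    if (is.null(c) || is.null(r) || is.null(n))
      stop("PGG requires c, r and n", call. = FALSE)
    if (!(c > 0)) stop("PGG requires c > 0", call. = FALSE)
    if (n != round(n) || n < 2 || n > N)
      stop("PGG requires integer group size 2 <= n <= N", call. = FALSE)
    if (!force && !(r > 1 && r < n))
      stop("PGG requires 1 < r < n (use force = TRUE to explore outside ",
           "the social-dilemma range)", call. = FALSE)
    if (r <= 0) stop("PGG requires r > 0", call. = FALSE)
    g <- structure(list(variant = "pgg", N = N, c = c, r = r, n = as.integer(n)),
                   class = "game_spec")
  }
  if (!force && payoff_difference(g) >= 0)
    stop("parameterisation yields payoff gap delta >= 0, outside the ",
         "model's scope; use force = TRUE to explore anyway", call. = FALSE)
  g
}

#' @export
print.game_spec <- function(x, ...) {
  if (x$variant == "dg") {
    cat(sprintf("Donation Game: N = %d, B = %g, c = %g\n", x$N, x$B, x$c))
  } else {
    cat(sprintf("Public Goods Game: N = %d, c = %g, r = %g, n = %d\n",
                x$N, x$c, x$r, x$n))
  }
  cat(sprintf("  payoff gap delta = %g\n", payoff_difference(x)))
  invisible(x)
}

#' Average payoffs in the Donation Game
#'
#' Average payoffs of a cooperator and a defector in a population with
#' \code{j} cooperators, each individual playing the DG pairwise against
#' every other member: \eqn{\Pi_C(j) = ((j-1)(B-c) + (N-j)(-c))/(N-1)},
#' \eqn{\Pi_D(j) = jB/(N-1)}.
#'
#' @param game a DG \code{game_spec}.
#' @param j number of cooperators; the cooperator payoff requires
#'   \code{1 <= j <= N-1}, the defector payoff \code{0 <= j <= N-1}.
#' @return Named numeric vector \code{c(PiC =, PiD =)}; \code{PiC} is
#'   \code{NA} at \code{j = 0} (no cooperator to average over).
#' @export
dg_payoffs <- function(game, j) {
  stopifnot(inherits(game, "game_spec"), game$variant == "dg")
  N <- game$N
  if (j != round(j) || j < 0 || j > N - 1)
    stop("j must be an integer in [0, N-1]", call. = FALSE)
  PiD <- j * game$B / (N - 1)
  PiC <- if (j >= 1) ((j - 1) * (game$B - game$c) + (N - j) * (-game$c)) / (N - 1) else NA_real_
  c(PiC = PiC, PiD = PiD)
}

#' Average payoffs in the Public Goods Game
#'
#' Average payoffs of a cooperator and a defector when groups of size
#' \code{n} are formed by sampling without replacement from the remaining
#' \code{N-1} players (multivariate hypergeometric sampling). The closed
#' forms are \eqn{\Pi_C(j) = (rc/n)(1 + (j-1)(n-1)/(N-1)) - c} and
#' \eqn{\Pi_D(j) = rc(n-1)j / (n(N-1))}.
#'
#' @inheritParams dg_payoffs
#' @param game a PGG \code{game_spec}.
#' @return Named numeric vector \code{c(PiC =, PiD =)}.
#' @export
pgg_payoffs <- function(game, j) {
  stopifnot(inherits(game, "game_spec"), game$variant == "pgg")
  N <- game$N
  if (j != round(j) || j < 0 || j > N - 1)
    stop("j must be an integer in [0, N-1]", call. = FALSE)
  r <- game$r; n <- game$n; cc <- game$c
  PiD <- r * cc * (n - 1) * j / (n * (N - 1))
  PiC <- if (j >= 1) r * cc / n * (1 + (j - 1) * (n - 1) / (N - 1)) - cc else NA_real_
  c(PiC = PiC, PiD = PiD)
}

#' Average payoffs for either game
#'
#' Dispatches to [dg_payoffs()] or [pgg_payoffs()].
#' @inheritParams dg_payoffs
#' @return Named numeric vector \code{c(PiC =, PiD =)}.
#' @export
game_payoffs <- function(game, j) {
  if (game$variant == "dg") dg_payoffs(game, j) else pgg_payoffs(game, j)
}

#' Payoff gap between cooperators and defectors
#'
#' The constant \eqn{\delta = \Pi_C(j) - \Pi_D(j)}, independent of \eqn{j}
#' in both games: \eqn{-(c + B/(N-1))} for DG and
#' \eqn{-c(1 - r(N-n)/(n(N-1)))} for PGG. Negative for every valid
#' parameterisation; a single cooperator (defector) always earns less
#' (more) than the average opponent of the other type.
#'
#' @param game a \code{game_spec}.
#' @return The payoff gap, a scalar in payoff units.
#' @export
payoff_difference <- function(game) {
  stopifnot(inherits(game, "game_spec"))
  N <- game$N
  if (game$variant == "dg") {
    -(game$c + game$B / (N - 1))
  } else {
    -game$c * (1 - game$r * (N - game$n) / (game$n * (N - 1)))
  }
}
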