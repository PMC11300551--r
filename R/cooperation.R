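logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Fixation probabilities of a single mutant
#'
#' Probability that a single cooperator takes over an all-defector
#' population (\code{rho_DC}) and vice versa (\code{rho_CD}) in the
#' small-mutation limit, from the standard birth-death product form
#' \deqn{\rho_{D,C} = \Big(1 + \sum_{i=1}^{N-1} \prod_{k=1}^{i}
#'   \frac{T^-_k}{T^+_k}\Big)^{-1}, \qquad
#'   \frac{T^-_k}{T^+_k} = e^{-\beta(\delta + \theta_k/k)},}
#' where the incentive shift \eqn{\theta_k/k} is active only on states
#' with at most \code{t} cooperators. All sums are accumulated in log
#' space, so the result is overflow-safe for arbitrarily strong
#' selection. At \eqn{\beta = 0} both probabilities equal \eqn{1/N}.
#'
#' The ratio satisfies the telescoping identity
#' \eqn{\rho_{D,C}/\rho_{C,D} = e^{\beta[(N-1)\delta + t\theta]}} (for a
#' reward scheme with efficiency 1).
#'
#' @inheritParams transition_matrix
#' @param delta optional payoff-gap override.
#' @return Object of class \code{fixation_pair}: list with
#'   \code{rho_DC}, \code{rho_CD} and their logarithms.
#' @export
fixation_probabilities <- function(game, scheme, params, delta = NULL,
                                   exponent_shift = c("theta_over_i", "per_capita")) {
  stopifnot(inherits(scheme, "incentive_scheme"),
            inherits(params, "evolution_params"))
  if (params$mu != 0)
    stop("fixation probabilities are defined in the small-mutation limit ",
         "(mu = 0)", call. = FALSE)
  N <- params$N
  if (scheme$t > N - 1) stop("threshold t must satisfy t <= N-1", call. = FALSE)
  if (is.null(delta)) delta <- payoff_difference(game)
  beta <- params$beta
  k <- seq_len(N - 1)
  x <- delta + gap_shift(scheme, k, N, match.arg(exponent_shift))
  # invading cooperator: product over k = 1..i of e^{-beta x_k}
  log_rho_dc <- -logsumexp(c(0, -beta * cumsum(x)))
  # invading defector: product over k = 1..i of e^{+beta x_{N-k}}
  log_rho_cd <- -logsumexp(c(0, beta * cumsum(rev(x))))
  structure(list(rho_DC = exp(log_rho_dc), rho_CD = exp(log_rho_cd),
                 log_rho_DC = log_rho_dc, log_rho_CD = log_rho_cd),
            class = "fixation_pair")
}

#' @export
print.fixation_pair <- function(x, ...) {
  cat(sprintf("rho_DC = %.6g, rho_CD = %.6g (ratio %.6g)\n",
              x$rho_DC, x$rho_CD, exp(x$log_rho_DC - x$log_rho_CD)))
  invisible(x)
}

#' Long-run cooperation frequency
#'
#' Fraction of time the population spends in the all-cooperator state in
#' the small-mutation limit: \eqn{\rho_{D,C}/(\rho_{D,C} +
#' \rho_{C,D})}, equivalently the logistic of
#' \eqn{\beta[(N-1)\delta + t\theta]}. Strictly increasing in the
#' incentive \eqn{\theta} and equal to 1/2 under neutral drift.
#'
#' @inheritParams fixation_probabilities
#' @return Frequency in (0, 1).
#' @export
cooperation_frequency <- function(game, scheme, params, delta = NULL,
                                  exponent_shift = c("theta_over_i", "per_capita")) {
  fp <- fixation_probabilities(game, scheme, params, delta, exponent_shift)
  stats::plogis(fp$log_rho_DC - fp$log_rho_CD)
}

#' Minimal incentive guaranteeing a cooperation level
#'
#' Inverts the cooperation frequency: the smallest per-capita incentive
#' \eqn{\theta_0(\omega)} such that at least an \eqn{\omega} fraction of
#' cooperation is expected in the long run,
#' \deqn{\theta_0(\omega) = \frac{1}{t}\Big(\frac{1}{\beta}
#'   \log\frac{\omega}{1-\omega} - (N-1)\delta\Big).}
#' \eqn{\theta_0} is strictly increasing in \eqn{\omega} and can be
#' negative for small targets (no incentive needed).
#'
#' @param omega target cooperation fraction in (0, 1).
#' @param beta intensity of selection, > 0.
#' @param N population size.
#' @param delta payoff gap (negative).
#' @param t incentive threshold.
#' @return Object of class \code{threshold_result}: list with
#'   \code{omega} and \code{theta0}.
#' @examples
#' theta_min(0.5, beta = 1, N = 3, delta = -2, t = 1) # theta0 = 4
#' @export
theta_min <- function(omega, beta, N, delta, t = 1) {
  if (!is.numeric(omega) || any(omega <= 0 | omega >= 1))
    stop("omega must lie in (0, 1)", call. = FALSE)
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  theta0 <- (log(omega / (1 - omega)) / beta - (N - 1) * delta) / t
  structure(list(omega = omega, theta0 = theta0), class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("omega = %g  ->  theta0 = %.10g\n", x$omega, x$theta0))
  invisible(x)
}

#' Cheapest incentive meeting a cooperation target
#'
#' Solves \eqn{\min_{\theta \ge \theta_0(\omega)} E(\theta)} subject to a
#' non-negative incentive. For t = 1 the reward cost function is proven
#' increasing, so the minimiser is \eqn{\theta^* = \max(\theta_0, 0)}
#' exactly. For other thresholds the cost is only conjectured monotone up
#' to a critical threshold, so a deterministic dense-grid search with
#' golden-section refinement over
#' \eqn{[\max(\theta_0,0),\ \theta_{max}]} is used instead.
#'
#' @param game a [game_spec()].
#' @param scheme an [incentive_scheme()] acting as a template: its
#'   \code{kind}, \code{t}, \code{a}, \code{b} are used and its
#'   \code{theta} is ignored.
#' @param params an [evolution_params()] with \code{mu = 0} and a start
#'   convention.
#' @param omega target cooperation fraction in (0, 1).
#' @param theta_max upper end of the search interval; defaults to
#'   \eqn{\max(\theta_0,0) + 10|\delta|(N-1)/t}.
#' @param grid_points number of grid points for the non-analytic case.
#' @return List with \code{theta_star}, \code{E_star}, \code{theta0},
#'   \code{omega} and \code{method} ("analytic" or "grid").
#' @export
optimise_cost <- function(game, scheme, params, omega, theta_max = NULL,
                          grid_points = 2001L) {
  stopifnot(inherits(game, "game_spec"), inherits(scheme, "incentive_scheme"),
            inherits(params, "evolution_params"))
  if (params$mu != 0)
    stop("optimise_cost assumes the small-mutation limit (mu = 0)",
         call. = FALSE)
  delta <- payoff_difference(game)
  N <- params$N
  t <- scheme$t
  theta0 <- theta_min(omega, params$beta, N, delta, t)$theta0
  lo <- max(theta0, 0)
  cost_at <- function(th) {
    sch <- incentive_scheme(scheme$kind, theta = th, t = t,
                            a = scheme$a, b = scheme$b)
    if (scheme$kind == "reward" && t <= 2 &&
        params$start %in% c("equal", "alldef", "weighted")) {
      cost_closed_form(game, sch, params)
    } else {
      expected_cost(game, sch, params)
    }
  }
  if (t == 1) {
    return(list(theta_star = lo, E_star = cost_at(lo), theta0 = theta0,
                omega = omega, method = "analytic"))
  }
  if (is.null(theta_max)) theta_max <- lo + 10 * abs(delta) * (N - 1) / t
  if (theta_max < theta0)
    stop("infeasible: theta_max < theta0(omega); no admissible incentive ",
         "meets the cooperation target", call. = FALSE)
  grid <- seq(lo, theta_max, length.out = grid_points)
  vals <- vapply(grid, cost_at, numeric(1))
  k <- which.min(vals)
  bl <- grid[max(k - 1L, 1L)]
  bu <- grid[min(k + 1L, length(grid))]
  refined <- if (bu > bl) stats::optimize(cost_at, c(bl, bu)) else
    list(minimum = grid[k], objective = vals[k])
  if (refined$objective <= vals[k]) {
    ts <- refined$minimum; es <- refined$objective
  } else {
    ts <- grid[k]; es <- vals[k]
  }
  list(theta_star = ts, E_star = es, theta0 = theta0, omega = omega,
       method = "grid", grid_points = grid_points,
       grid_range = c(lo, theta_max))
}
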