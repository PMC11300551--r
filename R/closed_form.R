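#' Logistic coefficients of the incentivised chain
#'
#' The four probabilities that parameterise the scaled tridiagonal system
#' behind the transition matrix:
#' \eqn{a = (1+e^{-\beta(\delta+\theta)})^{-1}} and
#' \eqn{c = (1+e^{\beta(\delta+\theta)})^{-1}} govern up/down moves on
#' incentivised rows, \eqn{b = (1+e^{-\beta\delta})^{-1}} and
#' \eqn{d = (1+e^{\beta\delta})^{-1}} on unincentivised rows. Identities:
#' \eqn{a + c = 1}, \eqn{b + d = 1}, and \eqn{bd < 1/4} whenever
#' \eqn{\beta\delta \neq 0}.
#'
#' The fields carry a \code{_co} suffix to avoid colliding with the
#' incentive-efficiency ratios, which the literature also calls
#' \eqn{a, b}.
#'
#' @param beta intensity of selection, >= 0.
#' @param delta payoff gap (negative for cooperation dilemmas).
#' @param theta gap shift on incentivised rows (the per-capita incentive
#'   effect).
#' @return Object of class \code{logistic_coefficients} with fields
#'   \code{a_co, b_co, c_co, d_co} and the precomputed products
#'   \code{ad, ac, bd}.
#' @examples
#' logistic_coefficients(1, -1, 0.5)
#' @export
logistic_coefficients <- function(beta, delta, theta) {
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  x <- beta * (delta + theta)
  y <- beta * delta
  a <- stats::plogis(x); c_ <- stats::plogis(-x)
  b <- stats::plogis(y); d <- stats::plogis(-y)
  structure(list(a_co = a, b_co = b, c_co = c_, d_co = d,
                 ad = a * d, ac = a * c_,
                 bd = 1 / (2 + exp(y) + exp(-y)),  # stable b*d
                 beta = beta, delta = delta, theta = theta),
            class = "logistic_coefficients")
}

#' @export
print.logistic_coefficients <- function(x, ...) {
  cat(sprintf("logistic coefficients (beta=%g, delta=%g, theta=%g):\n",
              x$beta, x$delta, x$theta))
  cat(sprintf("  a=%.6g b=%.6g c=%.6g d=%.6g  bd=%.6g\n",
              x$a_co, x$b_co, x$c_co, x$d_co, x$bd))
  invisible(x)
}

#' Scaled tridiagonal system matrix W
#'
#' The \eqn{(N-1) \times (N-1)} tridiagonal matrix satisfying
#' \eqn{I - U_{transient} = diag\{i(N-i)/N^2\}\, W}, so the fundamental
#' matrix is \eqn{n_{ij} = (W^{-1})_{ij}\, N^2/(j(N-j))}. Rows
#' \eqn{1..t} (incentivised) carry the couple \eqn{(-c, 1, -a)}; rows
#' below the threshold carry \eqn{(-d, 1, -b)}.
#'
#' @param N population size.
#' @param t incentive threshold, 1 <= t <= N-1.
#' @param coeffs a [logistic_coefficients()] object.
#' @return The W matrix.
#' @export
w_matrix <- function(N, t, coeffs) {
  stopifnot(inherits(coeffs, "logistic_coefficients"))
  if (t < 1 || t > N - 1) stop("t must lie in 1..N-1", call. = FALSE)
  m <- N - 1
  W <- diag(m)
  for (i in seq_len(m)) {
    up <- if (i <= t) coeffs$a_co else coeffs$b_co
    dn <- if (i <= t) coeffs$c_co else coeffs$d_co
    if (i < m) W[i, i + 1] <- -up
    if (i > 1) W[i, i - 1] <- -dn
  }
  W
}

#' Integer coefficients of the sojourn polynomial
#'
#' The polynomial \eqn{\hat y_j = \sum_k m_k (bd)^k} generated by the
#' recurrence \eqn{\hat y_j = \hat y_{j-1} - bd\,\hat y_{j-2}},
#' \eqn{\hat y_0 = \hat y_1 = 1}, has exact integer coefficients
#' \eqn{m_k = (-1)^k \binom{j-k}{k}} for \eqn{0 \le k \le \lfloor j/2
#' \rfloor}. Returned as integer-valued numerics (exact for j <= 40).
#'
#' @param j polynomial index, >= 0.
#' @return Numeric vector of length \code{floor(j/2) + 1}, entry k+1 is
#'   the coefficient of \eqn{(bd)^k}.
#' @examples
#' yhat_coefficients(9) # 1 -8 21 -20 5
#' @export
yhat_coefficients <- function(j) {
  if (j != round(j) || j < 0) stop("j must be an integer >= 0", call. = FALSE)
  if (j > 40) stop("exact integer coefficients are guaranteed for j <= 40",
                   call. = FALSE)
  k <- 0:(j %/% 2)
  (-1)^k * choose(j - k, k)
}

#' Real roots of the sojourn recurrence
#'
#' Roots of the characteristic equation \eqn{x^2 - x + bd = 0}:
#' \eqn{x_{1,2} = (1 \pm \sqrt{1-4bd})/2}. Both lie in (0, 1), sum to 1
#' and multiply to \eqn{bd}; real iff \eqn{bd \le 1/4}.
#'
#' @param bd product of the unincentivised logistic coefficients, in
#'   \[0, 1/4\].
#' @return Named vector \code{c(x1 =, x2 =)} with \code{x1 >= x2}.
#' @export
root_pair <- function(bd) {
  if (bd > 0.25) stop("roots are complex for bd > 1/4", call. = FALSE)
  s <- sqrt(1 - 4 * bd)
  c(x1 = (1 + s) / 2, x2 = (1 - s) / 2)
}

#' Evaluate the sojourn polynomial
#'
#' Evaluates \eqn{\hat y_j} at a given \eqn{bd} by one of three
#' interchangeable routes: the forward recurrence, the binomial closed
#' form, or the characteristic-root form
#' \eqn{(x_1 x_2 (x_1^{j-1} - x_2^{j-1}) - (x_1^j - x_2^j)) / (x_2 -
#' x_1)}. \code{"auto"} uses the recurrence, which is valid for every
#' \eqn{bd} including the degenerate repeated root at \eqn{bd = 1/4};
#' requests for the root form within 1e-8 of the repeated root are
#' rerouted to the recurrence.
#'
#' @param j polynomial index, >= 0 (vectorised).
#' @param bd evaluation point (scalar).
#' @param method "auto", "recurrence", "binomial" or "roots".
#' @return \eqn{\hat y_j(bd)}, same length as \code{j}.
#' @export
yhat <- function(j, bd, method = c("auto", "recurrence", "binomial", "roots")) {
  method <- match.arg(method)
  if (any(j != round(j) | j < 0)) stop("j must be integers >= 0", call. = FALSE)
  if (method == "roots" && abs(bd - 0.25) < 1e-8) method <- "recurrence"
  if (method == "auto") method <- "recurrence"
  jmax <- max(j)
  switch(method,
    recurrence = {
      v <- numeric(jmax + 1)
      v[1] <- 1
      if (jmax >= 1) v[2] <- 1
      if (jmax >= 2) for (m in 2:jmax) v[m + 1] <- v[m] - bd * v[m - 1]
      v[j + 1]
    },
    binomial = vapply(j, function(jj)
      sum(yhat_coefficients(jj) * bd^(0:(jj %/% 2))), numeric(1)),
    roots = {
      r <- root_pair(bd)
      x1 <- r[["x1"]]; x2 <- r[["x2"]]
      (x1 * x2 * (x1^(j - 1) - x2^(j - 1)) - (x1^j - x2^j)) / (x2 - x1)
    })
}

# Huang-McColl second-order recurrences for a tridiagonal matrix given as
# diagonals: b (length n), asub = (a_2..a_n), csup = (c_1..c_{n-1}).
# Returns z_0..z_n and y_1..y_{n+1}.
tridiag_zy <- function(b, asub, csup) {
  n <- length(b)
  z <- numeric(n + 1)          # z[i+1] = z_i
  z[1] <- 1; z[2] <- b[1]
  if (n >= 2) for (i in 2:n)
    z[i + 1] <- b[i] * z[i] - asub[i - 1] * csup[i - 1] * z[i - 1]
  y <- numeric(n + 1)          # y[j] = y_j, j = 1..n+1
  y[n + 1] <- 1
  y[n] <- b[n]
  if (n >= 2) for (jj in (n - 1):1)
    y[jj] <- b[jj] * y[jj + 1] - asub[jj] * csup[jj] * y[jj + 2]
  if (any(abs(z) < 1e-300) || any(abs(y) < 1e-300))
    stop("degenerate tridiagonal matrix: zero pivot in the z/y recurrences",
         call. = FALSE)
  list(z = z, y = y)
}

#' Entry of the inverse of a tridiagonal matrix
#'
#' Computes \eqn{(A^{-1})_{ij}} for a nonsingular tridiagonal matrix by
#' the Huang-McColl second-order recurrences
#' \eqn{z_i = b_i z_{i-1} - a_i c_{i-1} z_{i-2}} (forward) and its
#' backward counterpart, combined through the product form for
#' off-diagonal entries. No dense factorisation is performed.
#'
#' @param A a square tridiagonal matrix.
#' @param i,j entry indices.
#' @return \eqn{(A^{-1})_{ij}}.
#' @export
tridiag_inverse_entry <- function(A, i, j) {
  n <- nrow(A)
  stopifnot(ncol(A) == n, i >= 1, i <= n, j >= 1, j <= n)
  b <- diag(A)
  asub <- if (n >= 2) A[cbind(2:n, 1:(n - 1))] else numeric(0)
  csup <- if (n >= 2) A[cbind(1:(n - 1), 2:n)] else numeric(0)
  zy <- tridiag_zy(b, asub, csup)
  z <- zy$z; y <- zy$y
  aj <- function(k) if (k >= 2 && k <= n) asub[k - 1] else 0
  cj <- function(k) if (k >= 1 && k <= n - 1) csup[k] else 0
  yj <- function(k) if (k <= n + 1) y[k] else 1
  phi_jj <- 1 / (b[j] - aj(j) * cj(j - 1) * (if (j >= 2) z[j - 1] / z[j] else 0) -
                   aj(j + 1) * cj(j) * yj(j + 2) / yj(j + 1))
  if (i == j) return(phi_jj)
  if (i < j) {
    k <- 1:(j - i)
    (-1)^(j - i) * prod(vapply(k, function(kk) cj(j - kk), numeric(1))) *
      z[i] / z[j] * phi_jj
  } else {
    k <- 1:(i - j)
    (-1)^(i - j) * prod(vapply(k, function(kk) aj(j + kk), numeric(1))) *
      yj(i + 1) / yj(j + 1) * phi_jj
  }
}

# Validate inputs common to the closed-form cost functions and return the
# effective gap shift (theta/a for a reward scheme).
closed_form_theta_eff <- function(scheme, params) {
  if (scheme$kind != "reward")
    stop("closed-form cost functions cover the reward incentive; use ",
         "expected_cost() for punishment/mixed schemes", call. = FALSE)
  if (params$mu != 0)
    stop("closed-form cost functions assume the small-mutation limit ",
         "(mu = 0)", call. = FALSE)
  scheme$theta / scheme$a
}

# Rows 1 and N-1 of W^{-1} restricted to columns 1..t, via the
# Huang-McColl recurrences on W; used by the generic-threshold closed path.
winv_edge_rows <- function(N, t, coeffs) {
  W <- w_matrix(N, t, coeffs)
  phi1 <- vapply(seq_len(t), function(j) tridiag_inverse_entry(W, 1L, j),
                 numeric(1))
  phiN <- vapply(seq_len(t), function(j)
    tridiag_inverse_entry(W, N - 1L, j), numeric(1))
  list(phi1 = phi1, phiN = phiN)
}

#' Closed-form expected reward cost
#'
#' Exact expected total reward cost in the small-mutation limit, computed
#' from the tridiagonal structure of the chain rather than from a linear
#' solve: \deqn{E_r(\theta) = N^2\theta \sum_{j=1}^{t} \frac{w_D
#' (W^{-1})_{1j} + w_C (W^{-1})_{N-1,j}}{N-j}.} Thresholds t = 1 and
#' t = 2 use the fully explicit formulas in terms of the sojourn
#' polynomials \eqn{\hat y_j}; other thresholds evaluate the
#' \eqn{W^{-1}} entries by the Huang-McColl recurrences.
#'
#' @param game a [game_spec()]; ignored when \code{delta} is given.
#' @param scheme a reward [incentive_scheme()].
#' @param params an [evolution_params()] with \code{mu = 0}.
#' @param start starting-state convention ("equal", "alldef",
#'   "weighted"); defaults to \code{params$start}.
#' @param delta optional direct payoff gap, overriding the game formula.
#' @return Expected total cost (payoff units).
#' @seealso [cost_t1()], [cost_t2()], [expected_cost()] for the
#'   fundamental-matrix route.
#' @export
cost_closed_form <- function(game, scheme, params, start = NULL,
                             delta = NULL) {
  N <- params$N
  t <- scheme$t
  if (t == 1) return(cost_t1(game, scheme, params, start, delta))
  if (t == 2 && N >= 4) return(cost_t2(game, scheme, params, start, delta))
  if (t == 2 && N == 3)
    warning("t = 2 with N = 3 is the full-invest threshold t = N-1; ",
            "using the generic tridiagonal-inverse path")
  if (is.null(delta)) delta <- payoff_difference(game)
  if (is.null(start)) start <- params$start
  theta_eff <- closed_form_theta_eff(scheme, params)
  co <- logistic_coefficients(params$beta, delta, theta_eff)
  w <- start_weights(start, params$beta, N, delta, theta_eff)
  rows <- winv_edge_rows(N, t, co)
  j <- seq_len(t)
  N^2 * theta_eff * sum((w[1] * rows$phi1 + w[2] * rows$phiN) / (N - j))
}

#' Explicit t = 1 reward cost
#'
#' The fully explicit cost when rewards are paid only while a single
#' cooperator is present. With \eqn{y_2 = \hat y_{N-2}(bd)},
#' \eqn{y_3 = \hat y_{N-3}(bd)}:
#' \deqn{E_r^{equal} = \frac{N^2\theta}{2(N-1)}\Big(1 +
#'   \frac{d^{N-2}}{y_2}\Big)\frac{1}{1 - ad\,y_3/y_2}, \qquad
#'   E_r^{alldef} = \frac{N^2\theta}{N-1}\,\frac{1}{1 - ad\,y_3/y_2}.}
#'
#' @inheritParams cost_closed_form
#' @return Expected total cost (payoff units).
#' @export
cost_t1 <- function(game, scheme, params, start = NULL, delta = NULL) {
  if (scheme$t != 1) stop("cost_t1 requires t = 1", call. = FALSE)
  if (is.null(delta)) delta <- payoff_difference(game)
  if (is.null(start)) start <- params$start
  N <- params$N
  theta_eff <- closed_form_theta_eff(scheme, params)
  co <- logistic_coefficients(params$beta, delta, theta_eff)
  y2 <- yhat(N - 2, co$bd)
  y3 <- if (N >= 3) yhat(N - 3, co$bd) else 0
  # y2 - ad*y3 rewritten without cancellation via the exact identity
  # yhat_k - d*yhat_{k-1} = b^k:  y2 - ad*y3 = b^(N-2) + c*d*y3
  denom <- co$b_co^(N - 2) + co$c_co * co$d_co * y3
  w <- start_weights(start, params$beta, N, delta, theta_eff)
  N^2 * theta_eff * (w[1] * y2 + w[2] * co$d_co^(N - 2)) / ((N - 1) * denom)
}

#' Derivative of the t = 1 reward cost
#'
#' \eqn{dE_r/d\theta} for the equal and all-defector starting
#' conventions. Strictly positive for \eqn{\theta > 0}: spending more per
#' capita always raises the expected total bill at threshold 1, so the
#' constrained cost minimisation attains its optimum at the smallest
#' feasible incentive.
#'
#' @inheritParams cost_closed_form
#' @param start "equal" or "alldef".
#' @return The derivative (dimensionless: payoff units per payoff unit).
#' @export
cost_t1_derivative <- function(game, scheme, params, start = NULL,
                               delta = NULL) {
  if (scheme$t != 1) stop("cost_t1_derivative requires t = 1", call. = FALSE)
  if (is.null(delta)) delta <- payoff_difference(game)
  if (is.null(start)) start <- params$start
  if (!start %in% c("equal", "alldef"))
    stop("derivative formulas cover the 'equal' and 'alldef' starts",
         call. = FALSE)
  N <- params$N
  theta_eff <- closed_form_theta_eff(scheme, params)
  beta <- params$beta
  co <- logistic_coefficients(beta, delta, theta_eff)
  y2 <- yhat(N - 2, co$bd)
  y3 <- if (N >= 3) yhat(N - 3, co$bd) else 0
  x <- beta * (delta + theta_eff)
  # a'(theta) = beta e^{-x} a^2, evaluated in log space to avoid overflow
  aprime <- beta * exp(2 * stats::plogis(x, log.p = TRUE) - x)
  # y2 - ad*y3 in the cancellation-free form b^(N-2) + c*d*y3
  denom <- co$b_co^(N - 2) + co$c_co * co$d_co * y3
  bracket <- 1 + theta_eff * co$d_co * y3 * aprime / denom
  core <- if (start == "equal") {
    N^2 / (2 * (N - 1)) * (y2 + co$d_co^(N - 2)) / denom
  } else {
    N^2 / (N - 1) * y2 / denom
  }
  core * bracket / scheme$a    # chain rule: theta_eff = theta / a
}

#' Explicit t = 2 reward cost
#'
#' The explicit cost when rewards are paid while at most two cooperators
#' are present (requires \eqn{N \ge 4}; for \eqn{N = 3}, t = 2 is the
#' full-invest threshold and is routed through the generic path by
#' [cost_closed_form()]). Uses the four edge entries of \eqn{W^{-1}}
#' expressed through \eqn{y_3 = \hat y_{N-3}},
#' \eqn{y_4 = \hat y_{N-4}} and \eqn{y_2 = y_3 - ad\,y_4}.
#'
#' @inheritParams cost_closed_form
#' @return Expected total cost (payoff units).
#' @export
cost_t2 <- function(game, scheme, params, start = NULL, delta = NULL) {
  if (scheme$t != 2) stop("cost_t2 requires t = 2", call. = FALSE)
  N <- params$N
  if (N < 4)
    return(cost_closed_form(game, scheme, params, start, delta))
  if (is.null(delta)) delta <- payoff_difference(game)
  if (is.null(start)) start <- params$start
  theta_eff <- closed_form_theta_eff(scheme, params)
  co <- logistic_coefficients(params$beta, delta, theta_eff)
  y3 <- yhat(N - 3, co$bd)
  y4 <- yhat(N - 4, co$bd)
  # the backward tridiagonal-inverse recurrence couples row 2 through
  # the a*d product: y2 = y3 - ad*y4.
  # All four W^{-1} entries share the denominator y2 - ac*y3, rewritten
  # without cancellation (yhat_k - d*yhat_{k-1} = b^k) as
  # S = c^2*y3 + a*b^(N-3), with y2 = b^(N-3) + c*d*y4.
  a <- co$a_co; b <- co$b_co; cc <- co$c_co; d <- co$d_co
  S <- cc^2 * y3 + a * b^(N - 3)
  y2 <- b^(N - 3) + cc * d * y4
  phi11 <- y2 / S
  phiN1 <- cc * d^(N - 3) / S
  phi12 <- a * y3 / S                     # a * phi22, phi22 = y3 / S
  phiN2 <- d^(N - 3) / S
  w <- start_weights(start, params$beta, N, delta, theta_eff)
  N^2 * theta_eff * ((w[1] * phi11 + w[2] * phiN1) / (N - 1) +
                     (w[1] * phi12 + w[2] * phiN2) / (N - 2))
}

#' Neutral-drift limit of the t = 1 reward cost
#'
#' The limit of the cost as selection vanishes (\eqn{\beta \to 0}). At
#' \eqn{bd = 1/4} the sojourn recurrence has the repeated root 1/2 and
#' \eqn{\hat y_j(1/4) = (j+1)/2^j} exactly, so
#' \eqn{P(N) = \hat y_{N-2}(1/4) = (N-1)/2^{N-2}} and
#' \eqn{Q(N) = \hat y_{N-3}(1/4) = (N-2)/2^{N-3}} are evaluated in closed
#' form with no alternating-sum cancellation. The limit is
#' \deqn{\frac{N^2\theta}{N-1}\Big(P(N) + 2^{-(N-2)}\Big)
#'   \frac{2}{4P(N) - Q(N)} \quad (equal), \qquad
#'   \frac{N^2\theta}{N-1}\,\frac{4P(N)}{4P(N) - Q(N)} \quad (alldef).}
#'
#' @param N population size, >= 3.
#' @param theta per-capita incentive.
#' @param start "equal" or "alldef".
#' @return The limiting expected cost.
#' @export
neutral_drift_limit <- function(N, theta, start = c("equal", "alldef")) {
  start <- match.arg(start)
  if (N < 3) stop("N must be >= 3", call. = FALSE)
  P <- (N - 1) / 2^(N - 2)
  Q <- (N - 2) / 2^(N - 3)
  if (start == "equal") {
    N^2 * theta / (N - 1) * (P + 2^-(N - 2)) * 2 / (4 * P - Q)
  } else {
    N^2 * theta / (N - 1) * 4 * P / (4 * P - Q)
  }
}

#' Strong-selection limit of the t = 1 reward cost
#'
#' The limit of the cost as \eqn{\beta \to \infty}, identical for the
#' equal and all-defector starting conventions:
#' \eqn{+\infty} when \eqn{\delta + \theta > 0} (the incentive overturns
#' the dilemma and the chain lingers in the rewarded state),
#' \eqn{2N^2\theta/(N-1)} on the knife edge \eqn{\delta + \theta = 0},
#' and \eqn{N^2\theta/(N-1)} when \eqn{\delta + \theta < 0}.
#'
#' @param N population size.
#' @param theta per-capita incentive.
#' @param delta payoff gap (negative).
#' @param start "equal" or "alldef" (the limit does not depend on it).
#' @return The limiting expected cost, possibly \code{Inf}.
#' @export
strong_selection_limit <- function(N, theta, delta,
                                   start = c("equal", "alldef")) {
  match.arg(start)
  s <- delta + theta
  if (s > 0) return(Inf)
  if (s == 0) return(2 * N^2 * theta / (N - 1))
  N^2 * theta / (N - 1)
}
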