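#' Fermi imitation probability
#'
#' Probability that a focal player adopts the strategy of a model player
#' whose fitness exceeds the focal player's by \code{payoff_gap}:
#' \eqn{(1 + e^{-\beta \cdot gap})^{-1}}. Computed with the numerically
#' stable logistic; saturates to 0/1 without overflow for arbitrarily
#' large \eqn{|\beta \cdot gap|}.
#'
#' @param beta intensity of selection, >= 0.
#' @param payoff_gap fitness of the model minus fitness of the focal
#'   player (payoff units). Vectorised.
#' @return Probability in [0, 1].
#' @examples
#' fermi_probability(1, 0)    # 0.5
#' fermi_probability(1e3, -1) # underflows cleanly to 0
#' @export
fermi_probability <- function(beta, payoff_gap) {
  if (any(beta < 0)) stop("beta must be >= 0", call. = FALSE)
  stats::plogis(beta * payoff_gap)
}

#' Per-generation incentive budget
#'
#' The amount the institution spends in one generation when the population
#' holds \code{j} cooperators: \eqn{j\theta/a} (reward),
#' \eqn{(N-j)\theta/b} (punishment), or \eqn{\min(j/a,(N-j)/b)\theta}
#' (mixed) while \eqn{1 \le j \le t}; zero otherwise (in particular at the
#' homogeneous states \code{j = 0} and \code{j = N}).
#'
#' @param scheme an [incentive_scheme()].
#' @param j number of cooperators, 0..N (vectorised).
#' @param N population size.
#' @return Cost in payoff units, same length as \code{j}.
#' @export
per_generation_cost <- function(scheme, j, N) {
  stopifnot(inherits(scheme, "incentive_scheme"))
  if (any(j != round(j) | j < 0 | j > N))
    stop("j must be integers in [0, N]", call. = FALSE)
  base <- switch(scheme$kind,
    reward     = j / scheme$a * scheme$theta,
    punishment = (N - j) / scheme$b * scheme$theta,
    mixed      = pmin(j / scheme$a, (N - j) / scheme$b) * scheme$theta)
  ifelse(j >= 1 & j <= scheme$t, base, 0)
}

# Shift added to the cooperator-defector payoff gap inside the Fermi
# exponent at state j. The default follows the transition-matrix
# convention theta_j / j for every scheme; "per_capita" instead uses the
# per-individual payoff effect theta (identical for reward with a = 1,
# different for punishment/mixed).
gap_shift <- function(scheme, j, N, exponent_shift = c("theta_over_i", "per_capita")) {
  exponent_shift <- match.arg(exponent_shift)
  if (exponent_shift == "theta_over_i") {
    ifelse(j >= 1, per_generation_cost(scheme, j, N) / pmax(j, 1), 0)
  } else {
    ifelse(j >= 1 & j <= scheme$t, scheme$theta, 0)
  }
}

#' Transition matrix of the incentivised birth-death chain
#'
#' Builds the row-stochastic tridiagonal transition matrix over the states
#' \eqn{S_0, \ldots, S_N} (state \eqn{S_j} = \code{j} cooperators). In
#' one time step a random pair is sampled and the focal player imitates
#' the model with the Fermi probability evaluated at the incentive-shifted
#' payoff gap \eqn{\delta + \theta_i/i}; with a mutation rate
#' \eqn{\mu > 0} the focal player instead adopts a random strategy with
#' probability \eqn{\mu}, so no state is absorbing.
#'
#' @param game a [game_spec()].
#' @param scheme an [incentive_scheme()].
#' @param params an [evolution_params()]; \code{params$N} must equal
#'   \code{game$N}.
#' @param exponent_shift how the incentive enters the Fermi exponent:
#'   \code{"theta_over_i"} (default) adds \eqn{\theta_i/i} to the
#'   cooperator payoff for every scheme; \code{"per_capita"} adds the
#'   per-individual payoff effect \eqn{\theta} instead (documented
#'   alternative for punishment/mixed schemes).
#' @return An \code{(N+1) x (N+1)} matrix of class
#'   \code{transition_matrix} with dimnames \code{S0..SN}.
#' @export
transition_matrix <- function(game, scheme, params,
                              exponent_shift = c("theta_over_i", "per_capita")) {
  stopifnot(inherits(game, "game_spec"), inherits(scheme, "incentive_scheme"),
            inherits(params, "evolution_params"))
  N <- params$N
  if (N != game$N) stop("params$N must equal game$N", call. = FALSE)
  if (scheme$t > N - 1) stop("threshold t must satisfy t <= N-1", call. = FALSE)
  exponent_shift <- match.arg(exponent_shift)
  delta <- payoff_difference(game)
  beta <- params$beta; mu <- params$mu

  U <- matrix(0, N + 1, N + 1,
              dimnames = list(paste0("S", 0:N), paste0("S", 0:N)))
  i <- seq_len(N - 1)                      # interior states
  gap <- delta + gap_shift(scheme, i, N, exponent_shift)
  p_up_im <- (i / N) * fermi_probability(beta, gap)        # imitation part
  p_dn_im <- ((N - i) / N) * fermi_probability(beta, -gap)
  up <- ((N - i) / N) * (mu + (1 - mu) * p_up_im)
  dn <- (i / N) * (mu + (1 - mu) * p_dn_im)
  U[cbind(i + 1L, i + 2L)] <- up
  U[cbind(i + 1L, i)] <- dn
  # homogeneous states: only mutation moves them
  U[1L, 2L] <- mu
  U[N + 1L, N] <- mu
  diag(U) <- 1 - rowSums(U)
  class(U) <- c("transition_matrix", class(U))
  attr(U, "mu") <- mu
  U
}

# (N-1) x (N-1) restriction of U to the interior states S1..S_{N-1}
transient_block <- function(U) {
  n <- nrow(U)
  unclass(U)[2:(n - 1), 2:(n - 1), drop = FALSE]
}

#' Fundamental matrix of the absorbing chain
#'
#' Expected sojourn counts \eqn{n_{ij}}: the expected number of time steps
#' the population spends in state \eqn{S_j} before reaching a homogeneous
#' state, starting from \eqn{S_i}, for interior states
#' \eqn{i, j \in \{1, \ldots, N-1\}}. Computed as
#' \eqn{(I - U_{transient})^{-1}} by LU-factorised linear solves.
#'
#' @param U a \code{transition_matrix} (the interior restriction is taken
#'   automatically) or an already-restricted transient matrix.
#' @return The \code{(N-1) x (N-1)} visit matrix.
#' @export
fundamental_matrix <- function(U) {
  Ut <- if (inherits(U, "transition_matrix")) transient_block(U) else as.matrix(U)
  A <- diag(nrow(Ut)) - Ut
  if (rcond(A) < 1e-14)
    stop("I - U is singular or near-singular: the chain restricted to the ",
         "interior states is not substochastic (no absorbing/stopping ",
         "states reachable)", call. = FALSE)
  M <- solve(A, diag(nrow(A)))
  dimnames(M) <- dimnames(Ut)
  M
}

# Expected cost-to-absorption from every interior start, as the solution
# of (I - U_transient) x = theta_vec.
#
# The system is a tridiagonal M-matrix whose diagonal equals the sum of
# the adjacent off-diagonal rates plus a (possibly astronomically small)
# leak to the absorbing states, so an ordinary factorisation destroys
# the pivots by cancellation under strong selection. Normalising each
# row by its total rate s_i (so up'_i + dn'_i = 1) and writing the
# Thomas pivot as p_i = up'_i + h_i with h_i = dn'_i h_{i-1} / p_{i-1},
# h_1 = dn'_1, makes every operation a sum, product or quotient of
# positive quantities -- a subtraction-free elimination in the spirit of
# the Grassmann-Taksar-Heyman algorithm, accurate to full relative
# precision at any selection intensity.
chain_cost_vector <- function(game, scheme, params,
                              exponent_shift = "theta_over_i") {
  N <- params$N
  if (scheme$t > N - 1) stop("threshold t must satisfy t <= N-1", call. = FALSE)
  delta <- payoff_difference(game)
  beta <- params$beta; mu <- params$mu
  i <- seq_len(N - 1)
  gap <- delta + gap_shift(scheme, i, N, exponent_shift)
  fup <- stats::plogis(beta * gap)        # exact complements: fup + fdn = 1
  fdn <- stats::plogis(-beta * gap)
  if (mu == 0) {
    up <- fup; dn <- fdn                  # row total s_i = i(N-i)/N^2 cancels
    s <- i * (N - i) / N^2
  } else {
    up_raw <- ((N - i) / N) * (mu + (1 - mu) * (i / N) * fup)
    dn_raw <- (i / N) * (mu + (1 - mu) * ((N - i) / N) * fdn)
    s <- up_raw + dn_raw
    up <- up_raw / s; dn <- dn_raw / s
  }
  rhs <- per_generation_cost(scheme, i, N) / s
  m <- N - 1L
  if (m == 1L) return(rhs / 1)            # p_1 = 1 in normalised coordinates
  p <- numeric(m); h <- numeric(m); r <- numeric(m)
  p[1] <- 1; h[1] <- dn[1]; r[1] <- rhs[1]
  for (k in 2:m) {
    q <- dn[k] / p[k - 1]
    h[k] <- q * h[k - 1]
    p[k] <- up[k] + h[k]
    r[k] <- rhs[k] + q * r[k - 1]
  }
  x <- numeric(m)
  x[m] <- r[m] / p[m]
  for (k in (m - 1):1) x[k] <- (r[k] + up[k] * x[k + 1]) / p[k]
  x
}

# Start-convention weights (wD on the S1 row, wC on the S_{N-1} row) used
# by the small-mutation expected cost. theta_eff is the gap shift used in
# the weighted convention's long-run frequencies.
start_weights <- function(start, beta, N, delta, theta_eff) {
  switch(start,
    equal  = c(0.5, 0.5),
    alldef = c(1, 0),
    weighted = {
      fC <- stats::plogis(beta * (N - 1) * (delta + theta_eff))
      c(1 - fC, fC)
    },
    stop("start convention must be one of 'equal', 'alldef', 'weighted'",
         call. = FALSE))
}

#' Expected total incentive cost (small-mutation limit)
#'
#' The expected institutional expenditure accumulated over all generations
#' until the population fixates in a homogeneous state, under the
#' small-mutation limit (\code{mu = 0}). With visit counts \eqn{n_{ij}}
#' from the fundamental matrix and the per-generation budget
#' \eqn{\theta_j},
#' \deqn{E(\theta) = \sum_j (w_D\, n_{1j} + w_C\, n_{N-1,j})\, \theta_j,}
#' where the weights \eqn{(w_D, w_C)} are (1/2, 1/2) for the "equal"
#' start, (1, 0) for "alldef", and the long-run frequencies
#' \eqn{(f_D, f_C)} for "weighted".
#'
#' @inheritParams transition_matrix
#' @return Expected total cost (payoff units).
#' @seealso [cost_closed_form()] for the exact t = 1 and t = 2 formulas,
#'   [expected_cost_general_mutation()] for mu > 0.
#' @export
expected_cost <- function(game, scheme, params,
                          exponent_shift = c("theta_over_i", "per_capita")) {
  stopifnot(inherits(params, "evolution_params"))
  if (params$mu != 0)
    stop("expected_cost assumes the small-mutation limit (mu = 0); use ",
         "expected_cost_general_mutation() for mu > 0", call. = FALSE)
  if (params$start == "state")
    stop("integer start states require mu > 0; use the 'equal', 'alldef' ",
         "or 'weighted' convention here", call. = FALSE)
  N <- params$N
  exponent_shift <- match.arg(exponent_shift)
  x <- chain_cost_vector(game, scheme, params, exponent_shift)
  w <- start_weights(params$start, params$beta, N, payoff_difference(game),
                     gap_shift(scheme, 1L, N, exponent_shift))
  w[1] * x[1] + w[2] * x[N - 1]
}

#' Expected incentive cost under a general mutation rate
#'
#' With \eqn{\mu > 0} no state is absorbing, so the cost is accumulated
#' from the starting state until the population first visits a
#' homogeneous state (all defectors or all cooperators) — strictly after
#' leaving the start when the start is itself homogeneous. This is the
#' quantity the interior-restricted fundamental matrix computes: for an
#' interior start \eqn{S_i},
#' \eqn{E^i(\theta) = \sum_{j=1}^{N-1} n_{ij}\theta_j}; a homogeneous
#' start first dwells at zero per-generation cost and then enters the
#' adjacent interior state with probability one.
#'
#' @inheritParams transition_matrix
#' @param i_start starting state (number of cooperators, 0..N). Defaults
#'   to \code{params$start_state} when \code{params} carries an integer
#'   start.
#' @return Expected cost accumulated until the first homogeneous visit.
#' @export
expected_cost_general_mutation <- function(game, scheme, params,
                                           i_start = params$start_state,
                                           exponent_shift = c("theta_over_i", "per_capita")) {
  stopifnot(inherits(params, "evolution_params"))
  N <- params$N
  if (is.na(i_start) || i_start != round(i_start) || i_start < 0 || i_start > N)
    stop("i_start must be an integer in 0..N", call. = FALSE)
  if (params$mu == 0 && (i_start == 0 || i_start == N))
    stop("mu = 0 with a homogeneous start never pays anything; use ",
         "expected_cost() with a start convention instead", call. = FALSE)
  x <- chain_cost_vector(game, scheme, params, match.arg(exponent_shift))
  if (i_start >= 1 && i_start <= N - 1) return(x[i_start])
  # homogeneous start: expected dwell at the start costs nothing
  # (per-generation cost is zero at j = 0 and j = N), after which the
  # chain enters S1 (from S0) or S_{N-1} (from SN) with probability one
  x[if (i_start == 0) 1L else N - 1L]
}
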