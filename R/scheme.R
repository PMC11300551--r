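#' Specify an incentive scheme
#'
#' Defines how the institution intervenes. With \code{j} cooperators and
#' \code{1 <= j <= t}, the per-generation budget is \eqn{j\theta/a}
#' (reward every cooperator), \eqn{(N-j)\theta/b} (punish every defector),
#' or \eqn{\min(j/a, (N-j)/b)\,\theta} (whichever side is cheaper). Above
#' the threshold (\code{j > t}) nothing is paid: if cooperation is already
#' frequent the cooperators are assumed to survive on their own.
#'
#' \code{a} and \code{b} are efficiency ratios: the institution pays
#' \eqn{\theta/a} per rewarded cooperator so that their payoff changes by
#' \eqn{\theta} (analogously \eqn{\theta/b} per punished defector).
#'
#' @param kind "reward", "punishment" or "mixed".
#' @param theta per-capita incentive, >= 0 (payoff units).
#' @param t threshold: incentives are paid only while the number of
#'   cooperators is at most \code{t}, with \code{1 <= t <= N-1}.
#' @param a,b efficiency ratios, > 0.
#' @return An object of class \code{incentive_scheme}.
#' @examples
#' incentive_scheme("reward", theta = 1, t = 1)
#' @export
incentive_scheme <- function(kind = c("reward", "punishment", "mixed"),
                             theta, t, a = 1, b = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0)
    stop("theta must be a single number >= 0", call. = FALSE)
  if (!is.numeric(t) || length(t) != 1L || t < 1 || t != round(t))
    stop("t must be a single integer >= 1", call. = FALSE)
  if (a <= 0 || b <= 0) stop("efficiency ratios a, b must be > 0", call. = FALSE)
  structure(list(kind = kind, theta = theta, t = as.integer(t), a = a, b = b),
            class = "incentive_scheme")
}

#' @export
print.incentive_scheme <- function(x, ...) {
  cat(sprintf("%s incentive: theta = %g, t = %d, a = %g, b = %g\n",
              x$kind, x$theta, x$t, x$a, x$b))
  invisible(x)
}

#' Specify the evolutionary dynamics
#'
#' Parameters of the pairwise-comparison (Fermi) imitation process: the
#' intensity of selection \code{beta} weights payoff differences
#' (\eqn{\beta \to 0} neutral drift, \eqn{\beta \to \infty} strong
#' selection), \code{mu} is the per-step mutation probability, and
#' \code{start} fixes the starting-state convention used by the expected
#' total cost:
#' \describe{
#'   \item{"equal"}{the process starts in the all-defector and
#'     all-cooperator states with probability 1/2 each;}
#'   \item{"alldef"}{the process starts with all defectors;}
#'   \item{"weighted"}{the two homogeneous states are weighted by the
#'     long-run frequencies \eqn{f_D = 1/(r+1)}, \eqn{f_C = r/(r+1)} with
#'     \eqn{r = e^{\beta(N-1)(\delta+\theta)}};}
#'   \item{an integer i}{the process starts with exactly i cooperators
#'     (used with positive mutation rates).}
#' }
#'
#' @param N population size, integer >= 2.
#' @param beta intensity of selection, >= 0 (1/payoff units); beta = 0 is
#'   permitted for neutral-drift checks.
#' @param mu mutation probability in [0, 1]; mu = 0 selects the
#'   small-mutation (absorbing-chain) machinery.
#' @param start "equal", "alldef", "weighted", or an integer state 0..N.
#' @return An object of class \code{evolution_params}.
#' @export
evolution_params <- function(N, beta, mu = 0, start = "equal") {
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N))
    stop("N must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0)
    stop("beta must be a single number >= 0", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0 || mu > 1)
    stop("mu must lie in [0, 1]", call. = FALSE)
  start_state <- NA_integer_
  if (is.numeric(start)) {
    if (start != round(start) || start < 0 || start > N)
      stop("integer start state must lie in 0..N", call. = FALSE)
    start_state <- as.integer(start)
    start <- "state"
  } else {
    start <- match.arg(start, c("equal", "alldef", "weighted"))
  }
  structure(list(N = as.integer(N), beta = beta, mu = mu,
                 start = start, start_state = start_state),
            class = "evolution_params")
}

#' @export
print.evolution_params <- function(x, ...) {
  st <- if (x$start == "state") sprintf("S_%d", x$start_state) else x$start
  cat(sprintf("evolution: N = %d, beta = %g, mu = %g, start = %s\n",
              x$N, x$beta, x$mu, st))
  invisible(x)
}
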