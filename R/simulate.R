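# One literal time step of the chain for a vector of current states s
# (0-based states); U is the full (N+1)x(N+1) transition matrix.
step_once <- function(U, s) {
  n <- length(s)
  N <- nrow(U) - 1L
  pup <- U[cbind(s + 1L, pmin(s + 2L, N + 1L))]
  pdn <- U[cbind(s + 1L, pmax(s, 1L))]
  pup[s == N] <- 0
  pdn[s == 0L] <- 0
  u <- stats::runif(n)
  s + (u < pup) - (u >= pup & u < pup + pdn)
}

#' Monte-Carlo estimate of the expected incentive cost
#'
#' Simulates the incentivised birth-death chain from a given starting
#' state, accumulating the per-generation incentive budget at every time
#' step spent in an interior state, until the population first visits a
#' homogeneous state (the absorbing states when \code{mu = 0}; the
#' stopping states otherwise, taken strictly after leaving a homogeneous
#' start). Serves as the independent verification oracle for
#' [expected_cost()] and [expected_cost_general_mutation()].
#'
#' The default \code{method = "jump"} samples the embedded jump chain
#' with geometric sojourn times — an exact, much faster equivalent of the
#' per-generation walk. \code{method = "step"} performs the literal
#' per-generation simulation.
#'
#' @inheritParams transition_matrix
#' @param i_start starting state (number of cooperators, 0..N).
#' @param replicates number of independent replicates, >= 1.
#' @param seed integer seed; identical seeds give bit-identical results.
#' @param method "jump" (geometric sojourns) or "step" (literal steps).
#' @param max_steps guard against non-termination: a replicate exceeding
#'   this many generations is censored and counted in
#'   \code{guard_hits}, never silently truncated.
#' @param keep_costs if TRUE, attach the per-replicate cost vector.
#' @return Object of class \code{simulation_result}: replicate count,
#'   mean and standard error of the accumulated cost, per-state mean
#'   sojourn counts, fraction absorbed at the all-cooperator state,
#'   guard-hit count, and the sufficient statistics used for exact
#'   pooling by [pool_simulations()].
#' @export
simulate_cost <- function(game, scheme, params, i_start, replicates, seed,
                          method = c("jump", "step"), max_steps = 1e7,
                          keep_costs = FALSE,
                          exponent_shift = c("theta_over_i", "per_capita")) {
  method <- match.arg(method)
  stopifnot(replicates >= 1)
  if (missing(seed) || is.null(seed)) stop("a seed is required", call. = FALSE)
  N <- params$N
  if (i_start != round(i_start) || i_start < 0 || i_start > N)
    stop("i_start must be an integer in 0..N", call. = FALSE)
  if (params$mu == 0 && (i_start == 0 || i_start == N))
    stop("non-absorbing start: with mu = 0 a homogeneous start never ",
         "leaves, so no stopping rule applies", call. = FALSE)
  U <- transition_matrix(game, scheme, params, exponent_shift)
  theta_full <- per_generation_cost(scheme, 0:N, N)
  set.seed(seed)
  R <- as.integer(replicates)
  cost <- numeric(R)
  steps <- numeric(R)
  visits_sum <- numeric(N + 1)     # total sojourn steps per state, pooled
  final <- integer(R)
  guard <- logical(R)

  if (method == "jump") {
    s <- rep.int(i_start, R)
    if (i_start == 0L || i_start == N) {
      # dwell at the homogeneous start (exit probability mu), then enter
      # the adjacent interior state with probability one
      dwell <- 1 + stats::rgeom(R, params$mu)
      cost <- cost + dwell * theta_full[i_start + 1L]
      steps <- steps + dwell
      visits_sum[i_start + 1L] <- visits_sum[i_start + 1L] + sum(dwell)
      s <- rep.int(if (i_start == 0L) 1L else N - 1L, R)
    }
    pup <- U[cbind(2:N, 3:(N + 1))]       # up-rate from interior state i
    pdn <- U[cbind(2:N, 1:(N - 1))]
    pmv <- pup + pdn
    alive <- seq_len(R)
    while (length(alive)) {
      si <- s[alive]
      dwell <- 1 + stats::rgeom(length(alive), pmv[si])
      cost[alive] <- cost[alive] + dwell * theta_full[si + 1L]
      steps[alive] <- steps[alive] + dwell
      agg <- rowsum(dwell, si)
      idx <- as.integer(rownames(agg)) + 1L
      visits_sum[idx] <- visits_sum[idx] + agg[, 1L]
      up <- stats::runif(length(alive)) < pup[si] / pmv[si]
      s[alive] <- si + ifelse(up, 1L, -1L)
      over <- steps[alive] > max_steps & s[alive] >= 1L & s[alive] <= N - 1L
      if (any(over)) guard[alive[over]] <- TRUE
      done <- s[alive] == 0L | s[alive] == N | over
      final[alive[done]] <- s[alive[done]]
      alive <- alive[!done]
    }
  } else {
    s <- rep.int(i_start, R)
    entered <- rep.int(i_start >= 1L && i_start <= N - 1L, R)
    alive <- seq_len(R)
    while (length(alive)) {
      si <- s[alive]
      cost[alive] <- cost[alive] + theta_full[si + 1L]
      steps[alive] <- steps[alive] + 1
      agg <- rowsum(rep(1, length(si)), si)
      idx <- as.integer(rownames(agg)) + 1L
      visits_sum[idx] <- visits_sum[idx] + agg[, 1L]
      snew <- step_once(U, si)
      entered[alive] <- entered[alive] | (snew >= 1L & snew <= N - 1L)
      s[alive] <- snew
      over <- steps[alive] > max_steps
      if (any(over)) guard[alive[over]] <- TRUE
      done <- ((snew == 0L | snew == N) & entered[alive]) | over
      final[alive[done]] <- snew[done]
      alive <- alive[!done]
    }
  }

  res <- structure(list(
    replicates = R,
    mean_cost = mean(cost),
    se_cost = stats::sd(cost) / sqrt(R),
    sum_cost = sum(cost),
    sumsq_cost = sum(cost^2),
    mean_visits = stats::setNames(visits_sum / R, paste0("S", 0:N)),
    visits_sum = visits_sum,
    absorbed_at = mean(final == N),
    absorbed_n = sum(final == N),
    guard_hits = sum(guard),
    seed = seed, method = method, i_start = i_start, N = N
  ), class = "simulation_result")
  if (keep_costs) res$costs <- cost
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo cost: %.6g (se %.3g, %d replicates, seed %s)\n",
              x$mean_cost, x$se_cost, x$replicates, format(x$seed)))
  if (x$guard_hits > 0)
    cat(sprintf("  WARNING: %d replicates hit the max-steps guard\n",
                x$guard_hits))
  cat(sprintf("  absorbed at all-cooperator state: %.4f\n", x$absorbed_at))
  invisible(x)
}

#' Pool simulation results exactly
#'
#' Merges independent [simulate_cost()] runs of the same configuration by
#' their sufficient statistics (sums, sums of squares, sojourn totals),
#' so two runs of n replicates each are statistically identical to one
#' run of 2n replicates with the concatenated samples.
#'
#' @param ... \code{simulation_result} objects from the same
#'   configuration (different seeds).
#' @return A pooled \code{simulation_result}.
#' @export
pool_simulations <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1,
            all(vapply(parts, inherits, logical(1), "simulation_result")))
  R <- sum(vapply(parts, `[[`, numeric(1), "replicates"))
  sc <- sum(vapply(parts, `[[`, numeric(1), "sum_cost"))
  sq <- sum(vapply(parts, `[[`, numeric(1), "sumsq_cost"))
  vs <- Reduce(`+`, lapply(parts, `[[`, "visits_sum"))
  an <- sum(vapply(parts, `[[`, numeric(1), "absorbed_n"))
  v <- (sq - sc^2 / R) / (R - 1)
  structure(list(
    replicates = R, mean_cost = sc / R, se_cost = sqrt(max(v, 0) / R),
    sum_cost = sc, sumsq_cost = sq,
    mean_visits = stats::setNames(vs / R, names(parts[[1]]$mean_visits)),
    visits_sum = vs, absorbed_at = an / R, absorbed_n = an,
    guard_hits = sum(vapply(parts, `[[`, numeric(1), "guard_hits")),
    seed = NA, method = parts[[1]]$method, i_start = parts[[1]]$i_start,
    N = parts[[1]]$N
  ), class = "simulation_result")
}

#' Parameter-sweep table of expected costs
#'
#' Expands a grid over incentive, selection and threshold parameters and
#' tabulates the analytic expected cost (fundamental-matrix route for
#' \code{mu = 0} start conventions, stopped-chain route for \code{mu >
#' 0}), optionally alongside seeded Monte-Carlo estimates. Output is one
#' long-format row per grid cell; rerunning with the same seed
#' reproduces the table bit-identically.
#'
#' @param config a list with components \code{game} (a [game_spec()]),
#'   \code{theta}, \code{beta}, \code{t} (numeric vectors), and
#'   optionally \code{mu} (default 0), \code{start} (character vector:
#'   conventions "equal"/"alldef"/"weighted" for mu = 0 rows, or integer
#'   states as strings for mu > 0 rows; default "equal"), \code{scheme}
#'   (kinds, default "reward"), \code{a}, \code{b} (default 1).
#' @param simulate if TRUE, add Monte-Carlo columns.
#' @param replicates replicates per cell when simulating.
#' @param seed base seed; cell i uses \code{seed + i - 1}.
#' @return A long-format \code{data.frame}.
#' @export
generate_sweep <- function(config, simulate = FALSE, replicates = 10000L,
                           seed = 1L) {
  req <- c("game", "theta", "beta", "t")
  if (!all(req %in% names(config)))
    stop("config must supply: ", paste(req, collapse = ", "), call. = FALSE)
  game <- config$game
  stopifnot(inherits(game, "game_spec"))
  N <- game$N
  grid <- expand.grid(theta = config[["theta"]], beta = config[["beta"]],
                      t = config[["t"]],
                      mu = if (is.null(config[["mu"]])) 0 else config[["mu"]],
                      start = if (is.null(config[["start"]])) "equal" else config[["start"]],
                      scheme = if (is.null(config[["scheme"]])) "reward" else config[["scheme"]],
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  if (any(grid$t < 1 | grid$t > N - 1))
    stop("invalid grid: t must lie in 1..N-1", call. = FALSE)
  # [[ ]] throughout: $ would partial-match "a" or "b" against "beta"
  a <- if (is.null(config[["a"]])) 1 else config[["a"]]
  b <- if (is.null(config[["b"]])) 1 else config[["b"]]
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sch <- incentive_scheme(g$scheme, theta = g$theta, t = g$t, a = a, b = b)
    st <- suppressWarnings(as.integer(g$start))
    is_state <- !is.na(st)
    if (g$mu > 0 && !is_state)
      stop("invalid grid: mu > 0 rows need an integer starting state",
           call. = FALSE)
    prm <- evolution_params(N, beta = g$beta, mu = g$mu,
                            start = if (is_state) st else g$start)
    E <- if (g$mu == 0 && !is_state) expected_cost(game, sch, prm)
         else expected_cost_general_mutation(game, sch, prm,
                i_start = if (is_state) st else 1L)
    row <- data.frame(game = game$variant, N = N, t = g$t, beta = g$beta,
                      mu = g$mu, theta = g$theta, start = g$start,
                      scheme = g$scheme, a = a, b = b, E_analytic = E,
                      method = "matrix", stringsAsFactors = FALSE)
    if (simulate) {
      i0 <- if (is_state) st else 1L
      sim <- simulate_cost(game, sch, prm, i_start = i0,
                           replicates = replicates, seed = seed + i - 1L)
      row$E_sim <- sim$mean_cost
      row$se_sim <- sim$se_cost
      row$replicates <- sim$replicates
      row$seed <- seed + i - 1L
    }
    out[[i]] <- row
  }
  do.call(rbind, out)
}
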