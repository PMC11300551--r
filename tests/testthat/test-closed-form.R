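# frozen integer coefficient table for the sojourn polynomials y-hat_0..9
YHAT_TABLE <- list(
  1, 1, c(1, -1), c(1, -2), c(1, -3, 1), c(1, -4, 3),
  c(1, -5, 6, -1), c(1, -6, 10, -4), c(1, -7, 15, -10, 1),
  c(1, -8, 21, -20, 5))

test_that("logistic coefficients satisfy their identities", {
  co <- logistic_coefficients(0, -1.3, 0.4)
  expect_equal(unlist(co[c("a_co", "b_co", "c_co", "d_co")]),
               rep(0.5, 4), ignore_attr = TRUE)
  set.seed(31)
  for (rep in 1:20) {
    co <- logistic_coefficients(10^runif(1, -3, 1.5), runif(1, -3, -0.1),
                                runif(1, 0, 5))
    expect_equal(co$a_co + co$c_co, 1, tolerance = 1e-12)
    expect_equal(co$b_co + co$d_co, 1, tolerance = 1e-12)
    expect_lt(co$bd, 0.25)
    expect_equal(co$bd, co$b_co * co$d_co, tolerance = 1e-12)
  }
  expect_equal(logistic_coefficients(1, -1, 0)$bd, 1 / (2 + exp(1) + exp(-1)),
               tolerance = 1e-15)
})

test_that("sojourn polynomial coefficients reproduce the integer table exactly", {
  for (j in 0:9) {
    expect_identical(yhat_coefficients(j), as.numeric(YHAT_TABLE[[j + 1]]))
    # integer polynomial recurrence, carried exactly, agrees
    expect_identical(oracle_poly_coefficients(j), as.numeric(YHAT_TABLE[[j + 1]]))
  }
  # binomial form for larger j remains integer and matches the recurrence
  for (j in c(15, 27, 40))
    expect_identical(yhat_coefficients(j), oracle_poly_coefficients(j))
  expect_error(yhat_coefficients(41), "j <= 40")
})

test_that("the three sojourn evaluators agree and stay positive", {
  for (bd in c(0.01, 0.05, 0.1, 0.2, 0.24)) {
    for (j in c(0:10, 20, 30)) {
      v <- yhat(j, bd, "recurrence")
      # absolute agreement: all values lie in (0, 1]
      expect_lt(abs(yhat(j, bd, "binomial") - v), 1e-12)
      expect_lt(abs(yhat(j, bd, "roots") - v), 1e-12)
      expect_gt(v, 0)
    }
  }
  # degenerate repeated root: the root form is rerouted, and the exact
  # value at bd = 1/4 is (j+1)/2^j
  for (j in 0:12)
    expect_equal(yhat(j, 0.25, "roots"), (j + 1) / 2^j, tolerance = 1e-12)
  r <- root_pair(0.2)
  expect_equal(unname(r["x1"] + r["x2"]), 1)
  expect_equal(unname(r["x1"] * r["x2"]), 0.2, tolerance = 1e-12)
  expect_true(all(r > 0 & r < 1))
  expect_error(root_pair(0.3), "complex")
})

test_that("tridiagonal inverse entries match dense solves", {
  expect_equal(tridiag_inverse_entry(diag(5), 2, 2), 1)
  expect_equal(tridiag_inverse_entry(diag(5), 1, 4), 0)
  set.seed(32)
  for (rep in 1:15) {
    n <- sample(2:12, 1)
    A <- diag(runif(n, 2, 3))
    for (i in seq_len(n - 1)) {
      A[i, i + 1] <- runif(1, -0.6, 0.6)
      A[i + 1, i] <- runif(1, -0.6, 0.6)
    }
    Ainv <- solve(A)
    for (k in 1:6) {
      i <- sample(n, 1); j <- sample(n, 1)
      expect_equal(tridiag_inverse_entry(A, i, j), Ainv[i, j],
                   tolerance = 1e-10)
    }
  }
  # zero pivot in the forward recurrence is reported, not silently wrong
  expect_error(tridiag_inverse_entry(matrix(c(0, 1, 1, 0), 2), 1, 1),
               "degenerate")
})

test_that("W matrix is the scaled transient system", {
  # beta = 0: every coefficient is 1/2
  co0 <- logistic_coefficients(0, -2, 1)
  expect_equal(w_matrix(3, 1, co0),
               matrix(c(1, -0.5, -0.5, 1), 2), tolerance = 1e-12)
  # diag{i(N-i)/N^2} W  ==  I - U_transient, across schemes of threshold t
  set.seed(33)
  for (rep in 1:12) {
    N <- sample(3:12, 1); t <- sample(1:(N - 1), 1)
    g <- make_dg(N); th <- runif(1, 0, 4); beta <- 10^runif(1, -2, 1)
    sch <- incentive_scheme("reward", th, t)
    U <- transition_matrix(g, sch, evolution_params(N, beta))
    co <- logistic_coefficients(beta, payoff_difference(g), th)
    W <- w_matrix(N, t, co)
    i <- 1:(N - 1)
    lhs <- diag(i * (N - i) / N^2, N - 1) %*% W
    rhs <- diag(N - 1) - U[i + 1, i + 1]
    expect_equal(lhs, rhs, tolerance = 1e-12, ignore_attr = TRUE)
  }
  # t = N-1: fully incentivised, no (b, d) rows remain
  W <- w_matrix(5, 4, logistic_coefficients(1, -1, 0.5))
  co <- logistic_coefficients(1, -1, 0.5)
  expect_equal(W[cbind(1:3, 2:4)], rep(-co$a_co, 3))
  expect_equal(W[cbind(2:4, 1:3)], rep(-co$c_co, 3))
})

test_that("closed-form costs equal the fundamental-matrix route", {
  for (N in c(3, 5, 9)) {
    for (t in 1:2) {
      for (beta in c(0.01, 1, 8)) {
        for (st in c("equal", "alldef", "weighted")) {
          g <- make_dg(N)
          sch <- incentive_scheme("reward", 1.7, t)
          prm <- evolution_params(N, beta, start = st)
          e_cf <- suppressWarnings(cost_closed_form(g, sch, prm))
          e_fm <- expected_cost(g, sch, prm)
          expect_equal(e_cf, e_fm, tolerance = 1e-9)
        }
      }
    }
  }
  # generic-threshold path (3 <= t <= N-2) against the matrix route
  g <- make_dg(8)
  for (t in 3:6) {
    sch <- incentive_scheme("reward", 2, t)
    prm <- evolution_params(8, 1.5)
    expect_equal(cost_closed_form(g, sch, prm), expected_cost(g, sch, prm),
                 tolerance = 1e-9)
  }
  # theta = 0 is free
  expect_equal(cost_t1(make_dg(6), incentive_scheme("reward", 0, 1),
                       evolution_params(6, 2)), 0)
  # t = 2 with N = 3 is full-invest and is routed with a warning
  expect_warning(
    e <- cost_closed_form(make_dg(3), incentive_scheme("reward", 1, 2),
                          evolution_params(3, 1)),
    "full-invest")
  expect_equal(e, expected_cost(make_dg(3), incentive_scheme("reward", 1, 2),
                                evolution_params(3, 1)), tolerance = 1e-9)
  # closed forms refuse what they do not cover
  expect_error(cost_t1(make_dg(4), incentive_scheme("punishment", 1, 1),
                       evolution_params(4, 1)), "reward")
  expect_error(cost_t1(make_dg(4), incentive_scheme("reward", 1, 1),
                       evolution_params(4, 1, mu = 0.1)), "mu = 0")
})

test_that("the t = 1 derivative formula matches finite differences and is positive", {
  h <- 1e-5
  for (st in c("equal", "alldef")) {
    for (beta in c(1e-3, 0.1, 1, 5, 10)) {
      for (th in c(0.3, 1, 2.5, 5)) {
        g <- make_dg(7)
        prm <- evolution_params(7, beta, start = st)
        fd <- (cost_t1(g, incentive_scheme("reward", th + h, 1), prm) -
               cost_t1(g, incentive_scheme("reward", th - h, 1), prm)) / (2 * h)
        an <- cost_t1_derivative(g, incentive_scheme("reward", th, 1), prm)
        expect_equal(an, fd, tolerance = 1e-6)
        expect_gt(an, 0)
      }
    }
  }
  # non-unit efficiency enters through the chain rule
  g <- make_dg(5)
  prm <- evolution_params(5, 2, start = "alldef")
  fd <- (cost_t1(g, incentive_scheme("reward", 1 + h, 1, a = 2), prm) -
         cost_t1(g, incentive_scheme("reward", 1 - h, 1, a = 2), prm)) / (2 * h)
  expect_equal(cost_t1_derivative(g, incentive_scheme("reward", 1, 1, a = 2), prm),
               fd, tolerance = 1e-6)
})

test_that("neutral-drift limits match the binomial-sum forms and the small-beta cost", {
  # closed forms P(N) = (N-1)/2^(N-2), Q(N) = (N-2)/2^(N-3) equal the
  # alternating binomial sums evaluated independently
  for (N in 3:12) {
    expect_equal((N - 1) / 2^(N - 2), oracle_PQ_sum(N - 2), tolerance = 1e-14)
    expect_equal((N - 2) / 2^(N - 3), oracle_PQ_sum(N - 3), tolerance = 1e-14)
  }
  expect_equal(neutral_drift_limit(3, 1, "equal"), 4.5)
  expect_equal(neutral_drift_limit(3, 1, "alldef"), 6)
  for (N in 3:8) {
    for (st in c("equal", "alldef")) {
      lim <- neutral_drift_limit(N, 1, st)
      e <- cost_t1(make_dg(N), incentive_scheme("reward", 1, 1),
                   evolution_params(N, 1e-6, start = st))
      expect_lt(abs(e - lim), 1e-3)
    }
  }
})

test_that("strong-selection limits are attained and divergence is flagged", {
  expect_equal(strong_selection_limit(7, 1, -1.5), 49 / 6)
  expect_equal(strong_selection_limit(7, 1, -1), 2 * 49 / 6)
  expect_identical(strong_selection_limit(7, 1, -0.5), Inf)
  sch <- incentive_scheme("reward", 1, 1)
  for (N in c(3, 7)) {
    p50 <- evolution_params(N, 50, start = "equal")
    expect_equal(cost_t1(NULL, sch, p50, delta = -1.5),
                 strong_selection_limit(N, 1, -1.5), tolerance = 1e-6)
    expect_equal(cost_t1(NULL, sch, p50, delta = -1),
                 strong_selection_limit(N, 1, -1), tolerance = 1e-6)
  }
  # delta + theta > 0: the cost grows without bound along a beta ladder
  e <- sapply(c(10, 20, 40), function(b)
    cost_t1(NULL, sch, evolution_params(7, b, start = "equal"), delta = -0.5))
  expect_true(all(diff(e) > 0))
  expect_gt(e[3] / e[1], 100)
})
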