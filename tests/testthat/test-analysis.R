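test_that("effective rates split alpha by the slope parameter", {
  er <- effective_rates(learning_params(0.3, 1, 0.01))
  expect_equal(c(er$alpha_Q, er$alpha_S), c(0.3, 0))
  er <- effective_rates(learning_params(0.3, 0, 0.01))
  expect_equal(c(er$alpha_Q, er$alpha_S), c(0.15, 0.15))
  er <- effective_rates(learning_params(0.3, 0.443, 0.01))
  expect_equal(c(er$alpha_Q, er$alpha_S), c(0.21645, 0.08355))
  expect_identical(er$alpha_Q + er$alpha_S, 0.3)
})

test_that("equilibrium coefficients match direct arithmetic and flag lam = 0", {
  co <- equilibrium_coefficients(ref_params())
  expect_equal(co$c_Q, 0.21645 / (0.21645 + 0.093), tolerance = 1e-12)
  expect_equal(co$c_S, 0.08355 / 0.093, tolerance = 1e-12)
  expect_equal(co$c_Q, 0.6995, tolerance = 1e-4)
  expect_equal(co$c_S, 0.8984, tolerance = 1e-4)

  co0 <- equilibrium_coefficients(learning_params(0.3, 0.4, 0))
  expect_identical(co0$c_Q, 1)
  expect_false(co0$c_S_defined)
  expect_true(is.na(co0$c_S))

  co1 <- equilibrium_coefficients(learning_params(0.3, 1, 0.05))
  expect_identical(co1$c_S, 0)  # alpha_S = 0 at epsilon = 1
})

test_that("parameter inversion reproduces the reference settings and round-trips", {
  sol <- solve_parameters(0.3, 0.7, 0.9)
  expect_equal(round(sol$epsilon, 3), 0.443)
  expect_equal(round(sol$lam, 3), 0.093)

  sol2 <- solve_parameters(0.1, 0.8, 0.9)
  expect_equal(round(sol2$epsilon, 4), 0.6327)
  expect_equal(round(sol2$lam, 4), 0.0204)

  set.seed(5)
  for (i in 1:50) {
    alpha <- stats::runif(1, 0.05, 1)
    c_Q <- stats::runif(1, 0.4, 0.99)
    c_S <- stats::runif(1, 0.2, 1 / (1 / c_Q - 1) * 0.99)
    sol <- solve_parameters(alpha, c_Q, c_S)
    co <- equilibrium_coefficients(learning_params(alpha, sol$epsilon, sol$lam))
    expect_equal(co$c_Q, c_Q, tolerance = 1e-12)
    expect_equal(co$c_S, c_S, tolerance = 1e-12)
  }
  expect_error(solve_parameters(0.3, 1.0, 0.9), "c_Q")
  expect_error(solve_parameters(0.3, 0.3, 0.9), "incompatible")
})

test_that("condition report exposes the slack of each parameter relation", {
  rep <- check_conditions(ref_params())
  expect_equal(rep$cs_residual, abs(2 * 0.093 - 0.3 * (1 - 0.443)),
               tolerance = 1e-12)
  expect_equal(rep$cs_residual, 0.0189, tolerance = 1e-4)
  expect_equal(rep$cq_ratio, 2 * 0.093 / (0.3 * 1.443), tolerance = 1e-12)

  rep0 <- check_conditions(learning_params(0.3, 0.4, 0))
  expect_identical(rep0$cq_ratio, 0)
  expect_equal(rep0$cs_residual, 0.3 * 0.6)

  rep1 <- check_conditions(learning_params(0.05, 1, 0))
  expect_true(rep1$cq_ok)
  expect_true(rep1$cs_ok)  # both sides vanish at epsilon = 1, lam = 0
  expect_false(rep1$c_S_defined)
})

test_that("balanced epsilon equalises the two coefficients", {
  expect_identical(balanced_epsilon(0.5, 0), 1)
  expect_equal(balanced_epsilon(0.3, 0.03), 0.8198, tolerance = 1e-4)
  expect_lt(balanced_epsilon(0.01, 10), 1e-3)  # strong-decay limit
  set.seed(9)
  for (i in 1:50) {
    alpha <- stats::runif(1, 0.05, 1)
    lam <- stats::runif(1, 1e-4, 0.5)
    eps <- balanced_epsilon(alpha, lam)
    expect_true(eps > 0 && eps <= 1)
    co <- equilibrium_coefficients(learning_params(alpha, eps, lam))
    expect_equal(co$c_Q, co$c_S, tolerance = 1e-12)
  }
  expect_error(balanced_epsilon(0, 0.1), "alpha")
})

test_that("stochastic equilibrium matches closed forms and quadrature", {
  p <- ref_params()
  eq <- stochastic_equilibrium(schedule_spec("two_point", p = 20, n = 20), p)
  expect_equal(eq$Q_star, 0)
  expect_equal(eq$S_star, equilibrium_coefficients(p)$c_S * 20,
               tolerance = 1e-12)
  expect_equal(eq$S_star, 17.97, tolerance = 1e-3)

  # unit coefficients: weights recover payoff and cost exactly (approx form)
  sol <- solve_parameters(0.2, 0.999999, 1)
  p_unit <- learning_params(0.2, sol$epsilon, sol$lam)
  eq_u <- stochastic_equilibrium(schedule_spec("two_point", p = 12, n = 5), p_unit)
  expect_equal(eq_u$G_star_approx, 12, tolerance = 1e-4)
  expect_equal(eq_u$N_star_approx, 5, tolerance = 1e-4)

  # gaussian closed form vs independent numeric quadrature
  spec_g <- schedule_spec("gaussian", p = 20, n = 14)
  eq_g <- stochastic_equilibrium(spec_g, p)
  mu_r <- (20 - 14) / 2
  sd_r <- 0.5 * sqrt(pi / 2) * 34
  dens <- function(x) stats::dnorm(x, mu_r, sd_r)
  mad_quad <- stats::integrate(function(x) abs(x - eq_g$Q_star) * dens(x),
                               -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(eq_g$S_star, equilibrium_coefficients(p)$c_S * mad_quad,
               tolerance = 1e-8)

  # fixed-cost mixture vs quadrature + point mass
  spec_f <- schedule_spec("fixed_cost_stochastic_payoff", p = 20, n = 14,
                          payoff_sd = 4)
  eq_f <- stochastic_equilibrium(spec_f, p)
  m <- eq_f$Q_star
  mad_mix <- 0.5 * abs(-14 - m) +
    0.5 * stats::integrate(function(x) abs(x - m) * stats::dnorm(x, 20, 4),
                           -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(eq_f$S_star, equilibrium_coefficients(p)$c_S * mad_mix,
               tolerance = 1e-8)

  expect_error(
    stochastic_equilibrium(schedule_spec("two_point", p = 1, n = 1),
                           learning_params(0.3, 0.5, 0)),
    "lam = 0")
})

test_that("deterministic fixed point: printed form, exact form, and simulation agree", {
  p <- ref_params()
  fp <- deterministic_fixed_point(action_spec(20, 20), p)
  expect_equal(fp$Q_printed, 3.661, tolerance = 1e-3)
  expect_equal(fp$Q_exact, 2.561, tolerance = 1e-3)

  # printed value is the exact value divided by c_Q (documented discrepancy)
  co <- equilibrium_coefficients(p)
  expect_equal(fp$Q_printed, fp$Q_exact / co$c_Q, tolerance = 1e-9)

  # independent oracle: iterate the raw update rules to convergence
  lim <- oracle_alternating_limit(20, 20, p)
  expect_equal(fp$Q_exact, unname(lim["Q"]), tolerance = 1e-9)
  expect_equal(fp$S_exact, unname(lim["S"]), tolerance = 1e-9)
  expect_equal(fp$G_star, unname(lim["G"]), tolerance = 1e-8)
  expect_equal(fp$N_star, unname(lim["N"]), tolerance = 1e-8)

  # alpha_Q + lam -> 0 limit: Q* -> (p - n) / 2
  p_small <- learning_params(0.002, 0.999, 1e-5)
  fp_small <- deterministic_fixed_point(action_spec(14, 6), p_small)
  expect_equal(fp_small$Q_printed, (14 - 6) / 2, tolerance = 0.02)
  expect_equal(fp_small$Q_exact, (14 - 6) / 2, tolerance = 0.02)
})

test_that("detuned thalamic activity reduces to the expected limits", {
  # c_Q = c_S = c: activity is the scaled baseline c (p - n) / 2 at D = 0.5
  alpha <- 0.3; lam <- 0.05
  eps <- balanced_epsilon(alpha, lam)
  p_bal <- learning_params(alpha, eps, lam)
  co <- equilibrium_coefficients(p_bal)
  a <- action_spec(18, 7)
  expect_equal(thalamic_detuned(a, 0.5, p_bal),
               co$c_S * (18 - 7) / 2, tolerance = 1e-12)

  # c_Q = c_S = 1: D = 1 weighs payoff only, D = 0 cost only
  sol <- solve_parameters(0.2, 1 - 1e-9, 1)
  p_unit <- learning_params(0.2, sol$epsilon, sol$lam)
  expect_equal(thalamic_detuned(a, 1, p_unit), 18, tolerance = 1e-6)
  expect_equal(thalamic_detuned(a, 0, p_unit), -7, tolerance = 1e-6)
})

test_that("equilibrium report writes parseable JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  rep <- write_equilibrium_report(ref_params(), path, a = action_spec(20, 20))
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$coefficients$c_Q, rep$coefficients$c_Q, tolerance = 1e-12)
  expect_equal(parsed$deterministic_fixed_point$Q_exact,
               rep$deterministic_fixed_point$Q_exact, tolerance = 1e-12)
  expect_equal(parsed$stochastic_equilibrium$S_star,
               rep$stochastic_equilibrium$S_star, tolerance = 1e-12)
})
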