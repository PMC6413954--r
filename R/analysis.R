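#' Action payoff/cost specification
#'
#' An action that yields a cost of magnitude `n` followed by a payoff of
#' magnitude `p` each time it is executed. The reinforcement distribution it
#' generates has mean `q = (p - n) / 2` and mean spread `s = (p + n) / 2`;
#' equivalently `p = q + s` and `-n = q - s`.
#'
#' @param p Payoff magnitude, >= 0.
#' @param n Cost magnitude, >= 0.
#' @return An object of class `action_spec`.
#' @export
action_spec <- function(p, n) {
  stopifnot(is.numeric(p), length(p) == 1L, is.finite(p),
            is.numeric(n), length(n) == 1L, is.finite(n))
  if (p < 0 || n < 0) stop("payoff and cost magnitudes must be >= 0", call. = FALSE)
  structure(list(p = p, n = n, q = (p - n) / 2, s = (p + n) / 2),
            class = "action_spec")
}

#' @export
print.action_spec <- function(x, ...) {
  cat(sprintf("action_spec: payoff p = %g, cost n = %g  (q = %g, s = %g)\n",
              x$p, x$n, x$q, x$s))
  invisible(x)
}

#' Effective learning rates for the (Q, S) variables
#'
#' `alpha_Q = alpha (1 + epsilon) / 2` drives the mean estimate and
#' `alpha_S = alpha (1 - epsilon) / 2` the spread estimate. They always sum
#' to `alpha` exactly.
#'
#' @param p A [learning_params()] object.
#' @return List with elements `alpha_Q` and `alpha_S`.
#' @export
effective_rates <- function(p) {
  stopifnot(inherits(p, "learning_params"))
  list(alpha_Q = p$alpha * (1 + p$epsilon) / 2,
       alpha_S = p$alpha * (1 - p$epsilon) / 2)
}

#' Equilibrium coefficients c_Q and c_S
#'
#' After learning on stochastic reinforcements, `Q* = c_Q * q` and
#' `S* ~ c_S * E|R - c_Q q|`, with `c_Q = alpha_Q / (alpha_Q + lam)` and
#' `c_S = alpha_S / lam`. Unbiased payoff/cost coding needs both close to 1.
#'
#' With `lam = 0` the spread estimate has no finite equilibrium: `c_Q` is
#' exactly 1 and `c_S` is reported as `NA` with `c_S_defined = FALSE` rather
#' than an infinity.
#'
#' @param p A [learning_params()] object.
#' @return List with `c_Q`, `c_S` and the flag `c_S_defined`.
#' @examples
#' equilibrium_coefficients(learning_params(0.3, 0.443, 0.093))
#' @export
equilibrium_coefficients <- function(p) {
  stopifnot(inherits(p, "learning_params"))
  er <- effective_rates(p)
  if (p$lam == 0) {
    return(list(c_Q = 1, c_S = NA_real_, c_S_defined = FALSE))
  }
  list(c_Q = er$alpha_Q / (er$alpha_Q + p$lam),
       c_S = er$alpha_S / p$lam,
       c_S_defined = TRUE)
}

#' Invert the equilibrium coefficients for (epsilon, lam)
#'
#' Given a learning rate `alpha` and target coefficients `c_Q` (< 1) and
#' `c_S`, returns the unique slope and decay parameters producing them:
#' `epsilon = (1 - k) / (1 + k)` with `k = c_S (1 / c_Q - 1)`, and
#' `lam = alpha (1 - epsilon) / (2 c_S)`.
#'
#' @param alpha Learning rate in (0, 1].
#' @param c_Q Target mean coefficient, in (0, 1).
#' @param c_S Target spread coefficient, > 0. Additionally
#'   `c_S * (1 / c_Q - 1) < 1` is required so that `epsilon` lands in (0, 1).
#' @return List with `epsilon` and `lam`.
#' @examples
#' solve_parameters(0.3, 0.7, 0.9)  # epsilon ~ 0.443, lam ~ 0.093
#' @export
solve_parameters <- function(alpha, c_Q, c_S) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1,
            is.numeric(c_Q), length(c_Q) == 1L,
            is.numeric(c_S), length(c_S) == 1L)
  if (c_Q <= 0 || c_Q >= 1) {
    stop("`c_Q` must lie strictly in (0, 1); c_Q >= 1 would force lam <= 0",
         call. = FALSE)
  }
  if (c_S <= 0) stop("`c_S` must be > 0", call. = FALSE)
  k <- c_S * (1 / c_Q - 1)
  if (k >= 1) {
    stop("targets incompatible: c_S * (1/c_Q - 1) must be < 1 for epsilon in (0, 1)",
         call. = FALSE)
  }
  epsilon <- (1 - k) / (1 + k)
  lam <- alpha * (1 - epsilon) / (2 * c_S)
  list(epsilon = epsilon, lam = lam)
}

#' Parameter-condition report
#'
#' Learning unbiased payoffs and costs requires `2 lam << alpha (1 + epsilon)`
#' (so that `c_Q ~ 1`), `2 lam = alpha (1 - epsilon)` (so that `c_S = 1`),
#' and, for deterministic cost-then-payoff patterns, `alpha << 1`. The report
#' gives the numeric slack of each condition; the "much less than" flags use
#' a configurable ratio threshold since no sharp cutoff exists.
#'
#' @param p A [learning_params()] object.
#' @param ratio_threshold Ratio below which a `<<` condition is flagged as
#'   satisfied (default 0.2).
#' @return List with `cq_ratio` (`2 lam / (alpha (1 + epsilon))`),
#'   `cs_residual` (`|2 lam - alpha (1 - epsilon)|`), `alpha`, the
#'   corresponding logical flags, and the equilibrium coefficients.
#' @export
check_conditions <- function(p, ratio_threshold = 0.2) {
  stopifnot(inherits(p, "learning_params"),
            is.numeric(ratio_threshold), ratio_threshold > 0)
  co <- equilibrium_coefficients(p)
  cq_ratio <- 2 * p$lam / (p$alpha * (1 + p$epsilon))
  cs_residual <- abs(2 * p$lam - p$alpha * (1 - p$epsilon))
  list(
    cq_ratio = cq_ratio,
    cq_ok = cq_ratio < ratio_threshold,
    cs_residual = cs_residual,
    cs_ok = cs_residual < ratio_threshold * p$alpha,
    alpha = p$alpha,
    alpha_ok = p$alpha < ratio_threshold,
    c_Q = co$c_Q,
    c_S = co$c_S,
    c_S_defined = co$c_S_defined
  )
}

#' Slope parameter balancing c_Q and c_S
#'
#' The unique admissible solution of `c_Q = c_S` for given `alpha` and `lam`:
#' `epsilon = sqrt((2 lam / alpha)^2 + 1) - 2 lam / alpha`. When the two
#' coefficients are equal the pathway weights converge to values proportional
#' to the true payoff and cost even away from the ideal conditions. (The
#' second algebraic root is negative and discarded.)
#'
#' @param alpha Learning rate, > 0.
#' @param lam Decay rate, >= 0.
#' @return The balancing `epsilon`, in (0, 1].
#' @examples
#' balanced_epsilon(0.3, 0.03)  # ~0.8198
#' @export
balanced_epsilon <- function(alpha, lam) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(lam), length(lam) == 1L, lam >= 0)
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  u <- 2 * lam / alpha
  sqrt(u^2 + 1) - u
}

# Mean absolute deviation E|X - m| for X ~ Normal(mu, sd): folded-normal mean.
folded_normal_mad <- function(mu, sd, m) {
  d <- mu - m
  if (sd == 0) return(abs(d))
  sd * sqrt(2 / pi) * exp(-d^2 / (2 * sd^2)) + d * (2 * stats::pnorm(d / sd) - 1)
}

# E|R - m| for the per-event reinforcement distribution of a schedule spec.
# Closed forms for the shipped kinds; adaptive quadrature for general
# density functions (used as an internal cross-check).
schedule_mad_about <- function(spec, m) {
  switch(spec$kind,
    alternating = ,
    two_point = 0.5 * abs(spec$p - m) + 0.5 * abs(-spec$n - m),
    fixed_cost_stochastic_payoff =
      0.5 * abs(-spec$n - m) + 0.5 * folded_normal_mad(spec$p, spec$payoff_sd, m),
    gaussian = {
      mu_r <- (spec$p - spec$n) / 2
      sd_r <- 0.5 * sqrt(pi / 2) * (spec$p + spec$n)
      folded_normal_mad(mu_r, sd_r, m)
    },
    stop("unknown schedule kind: ", spec$kind, call. = FALSE)
  )
}

# Numeric-quadrature E|X - m| for an arbitrary density, tolerance 1e-9.
numeric_mad_about <- function(density, m, lower = -Inf, upper = Inf) {
  f <- function(x) abs(x - m) * density(x)
  left <- stats::integrate(f, lower, m, rel.tol = 1e-9, abs.tol = 1e-9)$value
  right <- stats::integrate(f, m, upper, rel.tol = 1e-9, abs.tol = 1e-9)$value
  left + right
}

#' Stochastic equilibrium of the learning rules
#'
#' The values about which Q and S fluctuate after learning on reinforcements
#' drawn from the per-event distribution of `spec`: `Q* = c_Q * q` and
#' `S* = c_S * E|R - c_Q q|` (the spread expectation in closed form for the
#' shipped schedule kinds), with `G* = S* + Q*` and `N* = S* - Q*`. Also
#' returns the payoff/cost approximation
#' `G* ~ (c_Q + c_S) p / 2 - (c_Q - c_S) n / 2` (and symmetrically for `N*`),
#' which shows that `c_Q = c_S` keeps payoff and cost separately encoded.
#'
#' @param spec A [schedule_spec()] describing the reinforcement distribution.
#' @param p A [learning_params()] object with `lam > 0`.
#' @return List with `Q_star`, `S_star`, `G_star`, `N_star`, the
#'   approximations `G_star_approx`, `N_star_approx`, and the coefficients.
#' @examples
#' pars <- learning_params(0.3, 0.443, 0.093)
#' stochastic_equilibrium(schedule_spec("two_point", p = 20, n = 20), pars)
#' @export
stochastic_equilibrium <- function(spec, p) {
  stopifnot(inherits(spec, "schedule_spec"), inherits(p, "learning_params"))
  if (p$lam == 0) {
    stop("no finite spread equilibrium with lam = 0 (c_S undefined)",
         call. = FALSE)
  }
  co <- equilibrium_coefficients(p)
  st <- schedule_stats(spec)
  Q_star <- co$c_Q * st$q
  S_star <- co$c_S * schedule_mad_about(spec, Q_star)
  list(
    Q_star = Q_star, S_star = S_star,
    G_star = S_star + Q_star, N_star = S_star - Q_star,
    G_star_approx = 0.5 * (co$c_Q + co$c_S) * spec$p - 0.5 * (co$c_Q - co$c_S) * spec$n,
    N_star_approx = -0.5 * (co$c_Q - co$c_S) * spec$p + 0.5 * (co$c_Q + co$c_S) * spec$n,
    c_Q = co$c_Q, c_S = co$c_S
  )
}

#' Fixed point of learning on a deterministic cost-then-payoff pattern
#'
#' For an action that reliably delivers cost `-n` then payoff `+p` on every
#' trial, the two-event composition of the update rules is linear and has a
#' unique fixed point. Two values of the mean estimate are returned:
#'
#' * `Q_printed = (n (alpha_Q + lam - 1) + p) / (2 - alpha_Q - lam)`, the
#'   commonly quoted closed form;
#' * `Q_exact`, the true invariant point of the stated composition, which
#'   equals `c_Q * Q_printed`. Both agree in the intended regime
#'   `alpha_Q + lam ~ 0`; `Q_exact` is what trajectories converge to and is
#'   canonical here.
#'
#' The spread fixed point `S_exact` is found by damped iteration of the
#' coupled two-event (Q, S) map to an increment below `tol` (the map is
#' linear given the Q cycle, so convergence is geometric).
#'
#' @param a An [action_spec()].
#' @param p A [learning_params()] object.
#' @param tol Iteration stopping tolerance (default 1e-12).
#' @param max_iter Iteration cap; exceeding it is a numeric error.
#' @return List with `Q_printed`, `Q_exact`, `S_exact`, `G_star`, `N_star`,
#'   and the iteration count `iterations`.
#' @examples
#' pars <- learning_params(0.3, 0.443, 0.093)
#' deterministic_fixed_point(action_spec(20, 20), pars)
#' @export
deterministic_fixed_point <- function(a, p, tol = 1e-12, max_iter = 1e6) {
  stopifnot(inherits(a, "action_spec"), inherits(p, "learning_params"))
  er <- effective_rates(p)
  shrink <- 1 - er$alpha_Q - p$lam  # per-event linear contraction of Q
  Q_printed <- (a$n * (er$alpha_Q + p$lam - 1) + a$p) / (2 - er$alpha_Q - p$lam)
  # exact invariant of Q -> shrink^2 Q + alpha_Q (p - shrink * n)
  Q_exact <- er$alpha_Q * (a$p - shrink * a$n) / (1 - shrink^2)

  two_event <- function(Q, S) {
    d1 <- -a$n - Q
    Q1 <- Q + er$alpha_Q * d1 - p$lam * Q
    S1 <- S + er$alpha_S * abs(d1) - p$lam * S
    d2 <- a$p - Q1
    Q2 <- Q1 + er$alpha_Q * d2 - p$lam * Q1
    S2 <- S1 + er$alpha_S * abs(d2) - p$lam * S1
    c(Q2, S2)
  }
  state <- c(0, 0)
  it <- 0L
  repeat {
    nxt <- two_event(state[1], state[2])
    it <- it + 1L
    if (max(abs(nxt - state)) < tol) { state <- nxt; break }
    if (it >= max_iter) {
      stop(sprintf(
        "fixed-point iteration did not converge within %d steps (last increment %.3e)",
        as.integer(max_iter), max(abs(nxt - state))), call. = FALSE)
    }
    state <- nxt
  }
  list(Q_printed = Q_printed, Q_exact = Q_exact, S_exact = state[2],
       G_star = state[2] + state[1], N_star = state[2] - state[1],
       iterations = it)
}

#' Thalamic activity after learning, under parameter detuning
#'
#' The choice signal produced at equilibrium for an action with payoff `p`
#' and cost `n`, as a function of the dopamine level `D`:
#' `T = p (c_Q/2 - c_S/2 + D c_S) - n (c_Q/2 + c_S/2 - D c_S)`.
#' With `c_Q = c_S` the activity is just a common rescaling of the ideal
#' payoff/cost weighting, so action selection survives detuning.
#'
#' @param a An [action_spec()].
#' @param D Dopamine level in \[0, 1\] (0.5 is baseline).
#' @param p A [learning_params()] object (used for its coefficients).
#' @return Scalar thalamic activity.
#' @export
thalamic_detuned <- function(a, D, p) {
  stopifnot(inherits(a, "action_spec"), inherits(p, "learning_params"),
            is.numeric(D), length(D) == 1L, D >= 0, D <= 1)
  co <- equilibrium_coefficients(p)
  if (!co$c_S_defined) stop("c_S undefined at lam = 0", call. = FALSE)
  a$p * (0.5 * co$c_Q - 0.5 * co$c_S + D * co$c_S) -
    a$n * (0.5 * co$c_Q + 0.5 * co$c_S - D * co$c_S)
}

#' Equilibrium and condition report as JSON
#'
#' Serialises the condition checks and (optionally) the deterministic and
#' stochastic equilibrium predictions for an action to a JSON file.
#'
#' @param p A [learning_params()] object.
#' @param path Output file path.
#' @param a Optional [action_spec()]; when given, fixed points and
#'   equilibria for the alternating schedule on this action are included.
#' @return The report list, invisibly.
#' @export
write_equilibrium_report <- function(p, path, a = NULL) {
  stopifnot(inherits(p, "learning_params"))
  report <- list(
    params = unclass(p),
    effective_rates = effective_rates(p),
    coefficients = equilibrium_coefficients(p),
    conditions = check_conditions(p)
  )
  if (!is.null(a)) {
    stopifnot(inherits(a, "action_spec"))
    report$action <- unclass(a)
    report$deterministic_fixed_point <- deterministic_fixed_point(a, p)
    if (p$lam > 0) {
      spec <- schedule_spec("alternating", p = a$p, n = a$n)
      report$stochastic_equilibrium <- stochastic_equilibrium(spec, p)
    }
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(report)
}
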