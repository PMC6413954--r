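# Shared parameter sets and small oracles for the test suite.

# Reference plasticity parameters: alpha = 0.3 with (c_Q, c_S) = (0.7, 0.9).
ref_params <- function() learning_params(0.3, 0.443, 0.093)

# Parameters of the two-action comparator task (alpha = 0.4, beta = 0.9).
comparator_params <- function() learning_params(0.4, 0.519, 0.1013)

# Independent scalar oracle for one dual-pathway update (no vectorisation,
# spelled out straight from the update-rule definition).
oracle_update <- function(G, N, delta, alpha, epsilon, lam) {
  f <- function(x) if (x >= 0) x else epsilon * x
  c(G = max(0, G + alpha * f(delta) - lam * G),
    N = max(0, N + alpha * f(-delta) - lam * N))
}

# Iterate the learning rules on the alternating cost-then-payoff pattern
# until the (Q, S) increment drops below tol; independent of the package's
# fixed-point code path.
oracle_alternating_limit <- function(p, n, params, tol = 1e-13,
                                     max_trials = 1e5) {
  G <- 0; N <- 0
  for (t in seq_len(max_trials)) {
    G_old <- G; N_old <- N
    for (r in c(-n, p)) {
      d <- r - (G - N) / 2
      upd <- oracle_update(G, N, d, params$alpha, params$epsilon, params$lam)
      G <- upd[["G"]]; N <- upd[["N"]]
    }
    if (max(abs(c(G - G_old, N - N_old))) < tol) break
  }
  c(Q = (G - N) / 2, S = (G + N) / 2, G = G, N = N)
}
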