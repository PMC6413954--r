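#' Critic state for the actor-critic variant
#'
#' A situation-level (action-unspecific) pair of Go/No-Go strengths that
#' learn by the same dual-pathway rules as the actor. The state value is
#' their difference: `V = (G_c - N_c) / 2`.
#'
#' @param G_c,N_c Non-negative critic strengths.
#' @return An object of class `critic_state`.
#' @export
critic_state <- function(G_c = 0, N_c = 0) {
  stopifnot(is.numeric(G_c), length(G_c) == 1L, G_c >= 0,
            is.numeric(N_c), length(N_c) == 1L, N_c >= 0)
  structure(list(G_c = G_c, N_c = N_c), class = "critic_state")
}

#' @export
print.critic_state <- function(x, ...) {
  cat(sprintf("critic_state: G_c = %g, N_c = %g  (V = %g)\n",
              x$G_c, x$N_c, (x$G_c - x$N_c) / 2))
  invisible(x)
}

#' State value of a critic
#'
#' @param critic A [critic_state()].
#' @return `V = (G_c - N_c) / 2`.
#' @export
critic_value <- function(critic) {
  stopifnot(inherits(critic, "critic_state"))
  (critic$G_c - critic$N_c) / 2
}

#' One actor-critic plasticity event
#'
#' The critic supplies the outcome prediction: `delta = r - V_critic`. The
#' chosen action's actor weights and the critic's own weights are then both
#' updated by the dual-pathway rules with this shared `delta`. The implied
#' value dynamics are `Delta V = alpha (1 + epsilon) / 2 * delta - lam * V`
#' (when no clipping fires).
#'
#' @param actor [pathway_weights()] of the chosen action.
#' @param critic A [critic_state()].
#' @param r Instantaneous reinforcement.
#' @param params A [learning_params()] object.
#' @return List with updated `actor`, `critic`, and the `delta` used.
#' @export
actor_critic_step <- function(actor, critic, r, params) {
  stopifnot(inherits(actor, "pathway_weights"),
            inherits(critic, "critic_state"),
            is.numeric(r), length(r) == 1L, is.finite(r),
            inherits(params, "learning_params"))
  delta <- r - critic_value(critic)
  actor_new <- apply_update(actor, delta, params)
  critic_w <- apply_update(pathway_weights(critic$G_c, critic$N_c),
                           delta, params)
  list(actor = actor_new,
       critic = critic_state(critic_w$G, critic_w$N),
       delta = delta)
}

#' Two-action task under actor-only or actor-critic learning
#'
#' On each trial an action is drawn from a softmax over the current action
#' values `Q(a) = (G_a - N_a) / 2` with temperature `beta`; the chosen
#' action delivers its cost then its payoff, and each event drives one
#' plasticity step. Under `"actor_only"` the prediction comes from the
#' chosen action's own weights; under `"actor_critic"` it comes from a
#' shared situation-level critic that learns alongside.
#'
#' @param actions Named list of [action_spec()] objects.
#' @param params A [learning_params()] object.
#' @param beta Softmax temperature, >= 0 (0 = uniform choice).
#' @param n_trials Number of trials.
#' @param architecture `"actor_critic"` or `"actor_only"`.
#' @param init Initial [pathway_weights()] for every actor (and the critic).
#' @param seed Optional integer seed.
#' @return A data.frame with one row per trial: `trial`, `choice`, and per
#'   action `G_<name>`, `N_<name>`, plus `V` (critic value; for the
#'   actor-only architecture `V` is `NA`).
#' @export
run_actor_critic_task <- function(actions, params, beta = 0.9,
                                  n_trials = 500L,
                                  architecture = c("actor_critic", "actor_only"),
                                  init = pathway_weights(0, 0), seed = NULL) {
  architecture <- match.arg(architecture)
  stopifnot(is.list(actions), length(actions) >= 1L,
            all(vapply(actions, inherits, logical(1), "action_spec")),
            inherits(params, "learning_params"), beta >= 0, n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_act <- length(actions)
  G <- rep(init$G, n_act); N <- rep(init$N, n_act)
  crit <- critic_state(init$G, init$N)
  out_G <- matrix(0, n_trials, n_act); out_N <- matrix(0, n_trials, n_act)
  V <- rep(NA_real_, n_trials); choice <- integer(n_trials)
  for (t in seq_len(n_trials)) {
    Qv <- (G - N) / 2
    pr <- exp(beta * (Qv - max(Qv)))
    a <- sample.int(n_act, 1L, prob = pr / sum(pr))
    for (r in c(-actions[[a]]$n, actions[[a]]$p)) {
      if (architecture == "actor_critic") {
        step <- actor_critic_step(pathway_weights(G[a], N[a]), crit, r, params)
        G[a] <- step$actor$G; N[a] <- step$actor$N; crit <- step$critic
      } else {
        w <- pathway_weights(G[a], N[a])
        w <- apply_update(w, prediction_error(r, w), params)
        G[a] <- w$G; N[a] <- w$N
      }
    }
    out_G[t, ] <- G; out_N[t, ] <- N; choice[t] <- a
    if (architecture == "actor_critic") V[t] <- critic_value(crit)
  }
  out <- data.frame(trial = seq_len(n_trials), choice = choice)
  nm <- names(actions)
  if (is.null(nm)) nm <- paste0("a", seq_len(n_act))
  for (a in seq_len(n_act)) {
    out[[paste0("G_", nm[a])]] <- out_G[, a]
    out[[paste0("N_", nm[a])]] <- out_N[, a]
  }
  out$V <- V
  out
}

#' Opponent-actor-learning (OpAL) state
#'
#' The comparator model: a scalar critic value `V` plus actor weights
#' `G`, `N` that are updated multiplicatively by the prediction error.
#'
#' @param V Critic value.
#' @param G,N Non-negative actor weights.
#' @return An object of class `opal_state`.
#' @export
opal_state <- function(V = 0, G = 1, N = 1) {
  stopifnot(is.numeric(V), length(V) == 1L, is.finite(V),
            is.numeric(G), length(G) == 1L, G >= 0,
            is.numeric(N), length(N) == 1L, N >= 0)
  structure(list(V = V, G = G, N = N), class = "opal_state")
}

#' @export
print.opal_state <- function(x, ...) {
  cat(sprintf("opal_state: V = %g, G = %g, N = %g\n", x$V, x$G, x$N))
  invisible(x)
}

#' One OpAL plasticity event
#'
#' `delta = r - V`; the critic moves by `alpha_V * delta` and the actor
#' weights multiplicatively by their own value: `G' = G + alpha_G G delta`,
#' `N' = N - alpha_N N delta` (no nonlinearity, no decay; all updates from
#' pre-step values; weights floored at zero). Separate learning rates are
#' allowed because the weight-collapse analysis is rate-independent.
#'
#' @param state An [opal_state()].
#' @param r Instantaneous reinforcement.
#' @param alpha Learning rate used for any of `alpha_V`, `alpha_G`,
#'   `alpha_N` left `NULL`.
#' @param alpha_V,alpha_G,alpha_N Optional separate rates.
#' @return The updated [opal_state()].
#' @export
opal_step <- function(state, r, alpha = 0.3,
                      alpha_V = NULL, alpha_G = NULL, alpha_N = NULL) {
  stopifnot(inherits(state, "opal_state"),
            is.numeric(r), length(r) == 1L, is.finite(r))
  if (is.null(alpha_V)) alpha_V <- alpha
  if (is.null(alpha_G)) alpha_G <- alpha
  if (is.null(alpha_N)) alpha_N <- alpha
  delta <- r - state$V
  opal_state(state$V + alpha_V * delta,
             max(0, state$G + alpha_G * state$G * delta),
             max(0, state$N - alpha_N * state$N * delta))
}

#' Simulate OpAL on an alternating cost-then-payoff action
#'
#' Each trial delivers `-n` then `+p`, each driving one [opal_step()]. The
#' critic `V` converges to an oscillation around the mean reinforcement,
#' after which the prediction error alternates between `-d` and `+d` with
#' `d = (p + n) / (2 - alpha_V)`; the multiplicative actor updates then
#' contract the weights per trial by `1 - alpha_G^2 d^2` (Go) and
#' `1 - alpha_N^2 d^2` (No-Go) when those factors lie in (0, 1) — and hit
#' the zero floor outright when they do not — so `G` and `N` collapse to
#' zero instead of converging to the payoff and cost.
#'
#' @param p Payoff magnitude.
#' @param n Cost magnitude.
#' @param alpha Common learning rate (see [opal_step()] for separate rates).
#' @param alpha_V,alpha_G,alpha_N Optional separate rates.
#' @param init An [opal_state()] (default `V = 0`, `G = N = 1`).
#' @param n_trials Number of trials.
#' @return A data.frame with per-event rows: `trial`, `event_index`, `r`,
#'   `V`, `G`, `N` (initial state in row 1).
#' @export
run_opal <- function(p, n, alpha = 0.3,
                     alpha_V = NULL, alpha_G = NULL, alpha_N = NULL,
                     init = opal_state(0, 1, 1), n_trials = 100L) {
  stopifnot(p >= 0, n >= 0, inherits(init, "opal_state"), n_trials >= 1)
  events <- as.vector(rbind(rep(-n, n_trials), rep(p, n_trials)))
  m <- length(events)
  V <- numeric(m + 1L); G <- numeric(m + 1L); N <- numeric(m + 1L)
  V[1L] <- init$V; G[1L] <- init$G; N[1L] <- init$N
  st <- init
  for (i in seq_len(m)) {
    st <- opal_step(st, events[i], alpha, alpha_V, alpha_G, alpha_N)
    V[i + 1L] <- st$V; G[i + 1L] <- st$G; N[i + 1L] <- st$N
  }
  data.frame(
    trial = c(0L, rep(seq_len(n_trials), each = 2L)),
    event_index = c(0L, rep(1:2, times = n_trials)),
    r = c(NA_real_, events),
    V = V, G = G, N = N
  )
}
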