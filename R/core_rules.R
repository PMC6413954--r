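#' Piecewise-linear prediction-error transform
#'
#' Transmits positive prediction errors unchanged and scales negative ones
#' down by the slope `epsilon`. This asymmetry is what lets the Go pathway
#' learn mostly from positive errors (payoffs) and the No-Go pathway, which
#' receives the sign-flipped error, mostly from negative ones (costs).
#'
#' The transform satisfies two identities used throughout the equilibrium
#' analysis: `f(x) - f(-x) = (1 + epsilon) * x` and
#' `f(x) + f(-x) = (1 - epsilon) * abs(x)`.
#'
#' @param x Numeric vector of (signed) prediction errors.
#' @param epsilon Slope applied to negative arguments, in \[0, 1\].
#'   `epsilon = 1` recovers the identity.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' f_eps(5, 0.443)    # positive arguments pass through
#' f_eps(-10, 0.443)  # negative arguments are scaled by the slope
#' @export
f_eps <- function(x, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon < 0 || epsilon > 1) {
    stop("`epsilon` must be a single number in [0, 1]", call. = FALSE)
  }
  ifelse(x >= 0, x, epsilon * x)
}

#' Learning-rule parameters
#'
#' Bundles the three plasticity constants: the learning rate `alpha`, the
#' slope `epsilon` of the prediction-error transform for negative arguments,
#' and the per-event weight decay rate `lam`.
#'
#' @param alpha Learning rate, in (0, 1].
#' @param epsilon Slope parameter, in \[0, 1\].
#' @param lam Decay rate, >= 0.
#' @return An object of class `learning_params` (a named list).
#' @examples
#' learning_params(0.3, 0.443, 0.093)
#' @export
learning_params <- function(alpha, epsilon, lam) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon),
            is.numeric(lam), length(lam) == 1L, is.finite(lam))
  if (alpha <= 0 || alpha > 1) stop("`alpha` must lie in (0, 1]", call. = FALSE)
  if (epsilon < 0 || epsilon > 1) stop("`epsilon` must lie in [0, 1]", call. = FALSE)
  if (lam < 0) stop("`lam` must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, epsilon = epsilon, lam = lam),
            class = "learning_params")
}

#' @export
print.learning_params <- function(x, ...) {
  cat(sprintf("learning_params: alpha = %g, epsilon = %g, lam = %g\n",
              x$alpha, x$epsilon, x$lam))
  er <- effective_rates(x)
  cat(sprintf("  effective rates: alpha_Q = %g, alpha_S = %g\n",
              er$alpha_Q, er$alpha_S))
  invisible(x)
}

#' Go/No-Go pathway weights
#'
#' The collective synaptic strengths of the Go (direct) and No-Go (indirect)
#' pathway for one action. Both are non-negative scalars; after successful
#' learning `G` approximates the action's mean payoff and `N` its mean cost.
#'
#' @param G Go strength, >= 0.
#' @param N No-Go strength, >= 0.
#' @return An object of class `pathway_weights`.
#' @export
pathway_weights <- function(G = 0, N = 0) {
  stopifnot(is.numeric(G), length(G) == 1L, is.finite(G),
            is.numeric(N), length(N) == 1L, is.finite(N))
  if (G < 0 || N < 0) stop("pathway weights must be non-negative", call. = FALSE)
  structure(list(G = G, N = N), class = "pathway_weights")
}

#' @export
print.pathway_weights <- function(x, ...) {
  cat(sprintf("pathway_weights: G = %g, N = %g  (Q = %g, S = %g)\n",
              x$G, x$N, (x$G - x$N) / 2, (x$G + x$N) / 2))
  invisible(x)
}

#' Outcome prediction error
#'
#' The teaching signal: received reinforcement minus the model's outcome
#' expectation, which is the average of expected payoff and expected cost,
#' `(G - N) / 2`.
#'
#' @param r Instantaneous reinforcement (negative values are costs).
#' @param w A [pathway_weights()] object.
#' @return The scalar prediction error `delta`.
#' @examples
#' prediction_error(10, pathway_weights(8, 2))  # 10 - 3 = 7
#' @export
prediction_error <- function(r, w) {
  stopifnot(is.numeric(r), all(is.finite(r)), inherits(w, "pathway_weights"))
  r - (w$G - w$N) / 2
}

#' One plasticity event
#'
#' Applies the dual-pathway update for a single prediction error `delta`:
#' `G' = G + alpha * f_eps(delta) - lam * G` and
#' `N' = N + alpha * f_eps(-delta) - lam * N`, both computed from the
#' pre-update weights. An update that would drive a weight negative clips
#' that weight to zero instead.
#'
#' @param w A [pathway_weights()] object.
#' @param delta Scalar prediction error (see [prediction_error()]).
#' @param p A [learning_params()] object.
#' @return The updated [pathway_weights()].
#' @examples
#' p <- learning_params(0.3, 0.443, 0.093)
#' apply_update(pathway_weights(5, 5), delta = 7, p)
#' @export
apply_update <- function(w, delta, p) {
  stopifnot(inherits(w, "pathway_weights"), inherits(p, "learning_params"),
            is.numeric(delta), length(delta) == 1L, is.finite(delta))
  G_new <- w$G + p$alpha * f_eps(delta, p$epsilon) - p$lam * w$G
  N_new <- w$N + p$alpha * f_eps(-delta, p$epsilon) - p$lam * w$N
  pathway_weights(max(0, G_new), max(0, N_new))
}

#' Mean/spread (Q, S) view of the pathway weights
#'
#' Changes variables from (G, N) to `Q = (G - N) / 2` (an estimate of the
#' mean reinforcement) and `S = (G + N) / 2` (an estimate of the mean
#' spread). The map is invertible via `G = S + Q`, `N = S - Q` as long as
#' `S >= |Q|`, which is exactly non-negativity of both weights.
#'
#' @param Q Mean-reinforcement estimate.
#' @param S Spread estimate; must satisfy `S >= |Q|`.
#' @return `qs_view()` and `qs_transform()` return a `qs_view` object;
#'   `qs_inverse()` returns a [pathway_weights()] object.
#' @export
qs_view <- function(Q, S) {
  stopifnot(is.numeric(Q), length(Q) == 1L, is.finite(Q),
            is.numeric(S), length(S) == 1L, is.finite(S))
  if (S < abs(Q)) {
    stop("invalid (Q, S) pair: S < |Q| would imply a negative weight",
         call. = FALSE)
  }
  structure(list(Q = Q, S = S), class = "qs_view")
}

#' @export
print.qs_view <- function(x, ...) {
  cat(sprintf("qs_view: Q = %g, S = %g  (G = %g, N = %g)\n",
              x$Q, x$S, x$S + x$Q, x$S - x$Q))
  invisible(x)
}

#' @rdname qs_view
#' @param w A [pathway_weights()] object.
#' @export
qs_transform <- function(w) {
  stopifnot(inherits(w, "pathway_weights"))
  qs_view((w$G - w$N) / 2, (w$G + w$N) / 2)
}

#' @rdname qs_view
#' @param qs A `qs_view` object.
#' @export
qs_inverse <- function(qs) {
  stopifnot(inherits(qs, "qs_view"))
  pathway_weights(qs$S + qs$Q, qs$S - qs$Q)
}

#' One plasticity event in (Q, S) coordinates
#'
#' The equivalent update in the transformed variables:
#' `Q' = Q + alpha_Q * delta - lam * Q` and
#' `S' = S + alpha_S * abs(delta) - lam * S`, with the effective rates
#' `alpha_Q = alpha (1 + epsilon) / 2` and `alpha_S = alpha (1 - epsilon) / 2`.
#' Agrees with [apply_update()] mapped through [qs_transform()] whenever no
#' clipping fires in (G, N) space; when clipping matters, (G, N) is the
#' canonical state and this view is only derived.
#'
#' @param qs A [qs_view()] object.
#' @param delta Scalar prediction error.
#' @param p A [learning_params()] object.
#' @return The updated `qs_view`.
#' @export
qs_update <- function(qs, delta, p) {
  stopifnot(inherits(qs, "qs_view"), inherits(p, "learning_params"),
            is.numeric(delta), length(delta) == 1L, is.finite(delta))
  er <- effective_rates(p)
  Q_new <- qs$Q + er$alpha_Q * delta - p$lam * qs$Q
  S_new <- qs$S + er$alpha_S * abs(delta) - p$lam * qs$S
  qs_view(Q_new, S_new)
}
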