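#' Reinforcement-schedule specification
#'
#' Declarative description of a reinforcement sequence. Four kinds are
#' supported:
#'
#' * `"alternating"` — each trial delivers the fixed cost `-n` followed by
#'   the fixed payoff `+p` (two events per trial);
#' * `"fixed_cost_stochastic_payoff"` — fixed cost `-n` followed by a payoff
#'   drawn from Normal(`p`, `payoff_sd`^2);
#' * `"two_point"` — one event per trial, `+p` or `-n` with probability 1/2
#'   each;
#' * `"gaussian"` — one event per trial drawn from a normal distribution
#'   with mean `(p - n) / 2` and standard deviation
#'   `sqrt(pi / 2) (p + n) / 2`, matched so its mean spread equals
#'   `(p + n) / 2`.
#'
#' All four kinds share the analytic statistics `q = (p - n) / 2`; the mean
#' spread is `(p + n) / 2` except for the fixed-cost kind, where the payoff
#' noise enters through a folded-normal correction (see [schedule_stats()]).
#'
#' @param kind Schedule kind (see above).
#' @param p Payoff magnitude, >= 0.
#' @param n Cost magnitude, >= 0.
#' @param payoff_sd Payoff standard deviation for
#'   `"fixed_cost_stochastic_payoff"`; defaults to `0.2 * p`.
#' @param n_trials Number of trials, >= 1.
#' @return An object of class `schedule_spec`.
#' @examples
#' schedule_spec("alternating", p = 20, n = 20, n_trials = 30)
#' @export
schedule_spec <- function(kind = c("alternating", "fixed_cost_stochastic_payoff",
                                   "two_point", "gaussian"),
                          p, n, payoff_sd = NULL, n_trials = 30L) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(p), length(p) == 1L, is.finite(p), p >= 0,
            is.numeric(n), length(n) == 1L, is.finite(n), n >= 0,
            is.numeric(n_trials), length(n_trials) == 1L, n_trials >= 1)
  if (kind == "fixed_cost_stochastic_payoff") {
    if (is.null(payoff_sd)) payoff_sd <- 0.2 * p
    stopifnot(is.numeric(payoff_sd), length(payoff_sd) == 1L, payoff_sd > 0)
  } else {
    payoff_sd <- NA_real_
  }
  structure(list(kind = kind, p = p, n = n, payoff_sd = payoff_sd,
                 n_trials = as.integer(n_trials)),
            class = "schedule_spec")
}

#' @export
print.schedule_spec <- function(x, ...) {
  extra <- if (!is.na(x$payoff_sd)) sprintf(", payoff_sd = %g", x$payoff_sd) else ""
  cat(sprintf("schedule_spec: %s, p = %g, n = %g%s, %d trials\n",
              x$kind, x$p, x$n, extra, x$n_trials))
  invisible(x)
}

#' Generate the reinforcement events of a schedule
#'
#' Materialises a [schedule_spec()] into an ordered event table. Within a
#' trial of the two-event kinds the cost is delivered first, then the
#' payoff. Stochastic kinds draw from the session RNG, so wrap the call in
#' `set.seed()` (or use `seed`) for reproducibility.
#'
#' @param spec A [schedule_spec()].
#' @param seed Optional integer seed applied before sampling.
#' @return A data.frame with columns `trial`, `event_index`, `r`.
#' @examples
#' make_schedule(schedule_spec("alternating", p = 20, n = 20, n_trials = 2))
#' @export
make_schedule <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "schedule_spec"))
  if (!is.null(seed)) set.seed(seed)
  nt <- spec$n_trials
  r <- switch(spec$kind,
    alternating = as.vector(rbind(-spec$n, rep(spec$p, nt))),
    fixed_cost_stochastic_payoff =
      as.vector(rbind(-spec$n, stats::rnorm(nt, spec$p, spec$payoff_sd))),
    two_point = ifelse(stats::runif(nt) < 0.5, spec$p, -spec$n),
    gaussian = stats::rnorm(nt, (spec$p - spec$n) / 2,
                            0.5 * sqrt(pi / 2) * (spec$p + spec$n))
  )
  events_per_trial <- if (spec$kind %in% c("alternating", "fixed_cost_stochastic_payoff")) 2L else 1L
  data.frame(
    trial = rep(seq_len(nt), each = events_per_trial),
    event_index = rep(seq_len(events_per_trial), times = nt),
    r = r
  )
}

#' Analytic statistics of a schedule's reinforcement distribution
#'
#' The mean `q = E(R)` and mean spread `s = E|R - q|` of the per-event
#' reinforcement distribution. All kinds give `q = (p - n) / 2`. The spread
#' is `(p + n) / 2` for the alternating, two-point and gaussian kinds; for
#' the fixed-cost kind the payoff noise adds a folded-normal contribution.
#'
#' @param spec A [schedule_spec()].
#' @return List with elements `q` and `s`.
#' @examples
#' schedule_stats(schedule_spec("two_point", p = 20, n = 20))
#' @export
schedule_stats <- function(spec) {
  stopifnot(inherits(spec, "schedule_spec"))
  q <- (spec$p - spec$n) / 2
  s <- schedule_mad_about(spec, q)
  list(q = q, s = s)
}

#' Write / read a schedule event table as CSV
#'
#' @param events A data.frame from [make_schedule()].
#' @param path File path.
#' @return `write_schedule_csv()` returns `path` invisibly;
#'   `read_schedule_csv()` returns the event data.frame.
#' @export
write_schedule_csv <- function(events, path) {
  stopifnot(is.data.frame(events),
            all(c("trial", "event_index", "r") %in% names(events)))
  utils::write.csv(events[, c("trial", "event_index", "r")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  ev <- utils::read.csv(path)
  stopifnot(all(c("trial", "event_index", "r") %in% names(ev)))
  ev
}
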