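#' Simulate learning on a reinforcement schedule
#'
#' Runs the dual-pathway plasticity rules over every event of a schedule:
#' for each reinforcement the prediction error `delta = r - (G - N) / 2` is
#' computed, then both weights are updated (with decay and zero-clipping)
#' from their pre-update values. The returned trajectory starts with a row
#' for the initial state (`trial = 0`).
#'
#' @param spec A [schedule_spec()], or `NULL` if `events` is supplied.
#' @param params A [learning_params()] object.
#' @param init Initial [pathway_weights()] (default both zero, matching
#'   learning an unfamiliar action from scratch).
#' @param seed Optional integer seed for stochastic schedules.
#' @param events Optional pre-generated event table (from [make_schedule()]
#'   or [read_schedule_csv()]); overrides `spec` generation.
#' @return A data.frame with columns `trial`, `event_index`, `r`, `delta`,
#'   `G`, `N`, `Q`, `S`, one row per event plus the initial row.
#' @examples
#' pars <- learning_params(0.3, 0.443, 0.093)
#' traj <- run_learning(schedule_spec("alternating", p = 20, n = 20), pars)
#' tail(traj)
#' @export
run_learning <- function(spec, params, init = pathway_weights(0, 0),
                         seed = NULL, events = NULL) {
  stopifnot(inherits(params, "learning_params"),
            inherits(init, "pathway_weights"))
  if (is.null(events)) {
    stopifnot(inherits(spec, "schedule_spec"))
    events <- make_schedule(spec, seed = seed)
  }
  n <- nrow(events)
  alpha <- params$alpha; eps <- params$epsilon; lam <- params$lam
  G <- numeric(n + 1L); N <- numeric(n + 1L); delta <- rep(NA_real_, n + 1L)
  G[1L] <- init$G; N[1L] <- init$N
  g <- init$G; nn <- init$N
  r <- events$r
  for (i in seq_len(n)) {
    d <- r[i] - (g - nn) / 2
    fd <- if (d >= 0) d else eps * d
    fmd <- if (d <= 0) -d else -eps * d  # f_eps(-d)
    g_new <- g + alpha * fd - lam * g
    n_new <- nn + alpha * fmd - lam * nn
    g <- if (g_new > 0) g_new else 0
    nn <- if (n_new > 0) n_new else 0
    G[i + 1L] <- g; N[i + 1L] <- nn; delta[i + 1L] <- d
  }
  data.frame(
    trial = c(0L, events$trial),
    event_index = c(0L, events$event_index),
    r = c(NA_real_, r),
    delta = delta,
    G = G, N = N,
    Q = (G - N) / 2, S = (G + N) / 2
  )
}

#' Ensemble of learning runs
#'
#' Repeats [run_learning()] `n_runs` times with independent schedule
#' realisations (seeds derived from `seed`) and summarises the weight
#' trajectories across runs.
#'
#' @param spec A [schedule_spec()].
#' @param params A [learning_params()] object.
#' @param init Initial [pathway_weights()].
#' @param n_runs Number of runs, >= 1.
#' @param seed Master seed; identical seeds give bit-identical ensembles.
#' @return A list with `summary` (data.frame: `event`, `mean_G`, `sd_G`,
#'   `mean_N`, `sd_N`, where `event = 0` is the initial state), `terminal`
#'   (per-run terminal `G` and `N`), and `n_runs`.
#' @export
run_ensemble <- function(spec, params, init = pathway_weights(0, 0),
                         n_runs = 500L, seed = 1L) {
  stopifnot(inherits(spec, "schedule_spec"), n_runs >= 1)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, n_runs)
  Gs <- Ns <- NULL
  for (k in seq_len(n_runs)) {
    traj <- run_learning(spec, params, init, seed = run_seeds[k])
    if (is.null(Gs)) {
      Gs <- matrix(0, nrow(traj), n_runs)
      Ns <- matrix(0, nrow(traj), n_runs)
    }
    Gs[, k] <- traj$G; Ns[, k] <- traj$N
  }
  sd0 <- function(m) apply(m, 1L, stats::sd)
  list(
    summary = data.frame(
      event = seq_len(nrow(Gs)) - 1L,
      mean_G = rowMeans(Gs), sd_G = if (n_runs > 1) sd0(Gs) else 0,
      mean_N = rowMeans(Ns), sd_N = if (n_runs > 1) sd0(Ns) else 0
    ),
    terminal = data.frame(run = seq_len(n_runs),
                          G = Gs[nrow(Gs), ], N = Ns[nrow(Ns), ]),
    n_runs = n_runs
  )
}

#' Trajectory CSV and run-metadata helpers
#'
#' `write_trajectory()` / `read_trajectory()` round-trip the trajectory
#' table produced by [run_learning()]. `write_run_metadata()` records the
#' parameters, initial weights, seed and schedule of a run as JSON so that
#' any artifact can be regenerated from its metadata alone.
#'
#' @param traj Trajectory data.frame.
#' @param path File path.
#' @return `write_*` return `path` invisibly; `read_trajectory()` returns
#'   the data.frame.
#' @export
write_trajectory <- function(traj, path) {
  cols <- c("trial", "event_index", "r", "delta", "G", "N", "Q", "S")
  stopifnot(is.data.frame(traj), all(cols %in% names(traj)))
  utils::write.csv(traj[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  traj <- utils::read.csv(path)
  stopifnot(all(c("trial", "G", "N") %in% names(traj)))
  traj
}

#' @rdname write_trajectory
#' @param spec A [schedule_spec()] (or `NULL`).
#' @param params A [learning_params()] object.
#' @param init Initial [pathway_weights()].
#' @param seed Seed used for the run.
#' @param extra Optional named list of additional metadata fields.
#' @export
write_run_metadata <- function(path, params, spec = NULL,
                               init = pathway_weights(0, 0), seed = NULL,
                               extra = NULL) {
  meta <- list(
    params = unclass(params),
    schedule = if (!is.null(spec)) unclass(spec),
    init = unclass(init),
    seed = seed
  )
  if (!is.null(extra)) meta <- c(meta, extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
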