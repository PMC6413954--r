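#' Choice-stage parameters
#'
#' Parameters of the dopamine-modulated choice model: the dopamine level
#' `D` (0.5 is the baseline at which both pathways weigh equally), the
#' D2-coupling factor `kappa_N` (1 = intact coupling; values below 1 model
#' D2-antagonist blockade, 0 = total blocking), and the standard deviation
#' `sigma` of the Gaussian decision noise added to each option's thalamic
#' activity.
#'
#' @param D Dopamine level in \[0, 1\].
#' @param kappa_N D2-coupling factor in \[0, 1\].
#' @param sigma Decision-noise standard deviation, >= 0.
#' @return An object of class `choice_params`.
#' @export
choice_params <- function(D = 0.5, kappa_N = 1, sigma = 0) {
  stopifnot(is.numeric(D), length(D) == 1L, D >= 0, D <= 1,
            is.numeric(kappa_N), length(kappa_N) == 1L,
            kappa_N >= 0, kappa_N <= 1,
            is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  structure(list(D = D, kappa_N = kappa_N, sigma = sigma),
            class = "choice_params")
}

#' @export
print.choice_params <- function(x, ...) {
  cat(sprintf("choice_params: D = %g, kappa_N = %g, sigma = %g\n",
              x$D, x$kappa_N, x$sigma))
  invisible(x)
}

#' Thalamic activity of one option
#'
#' The basal-ganglia output driving choice:
#' `T = D * G - (1 - kappa_N * D) * N`. With intact D2 coupling
#' (`kappa_N = 1`) this is the plain dopamine-weighted payoff/cost
#' comparison `D G - (1 - D) N`; lowering `kappa_N` releases the No-Go
#' population from dopaminergic inhibition, so costs weigh more.
#'
#' @param w A [pathway_weights()] object.
#' @param cp A [choice_params()] object.
#' @return Scalar thalamic activity.
#' @examples
#' thalamic_activity(pathway_weights(10, 4), choice_params(D = 0.5))
#' @export
thalamic_activity <- function(w, cp) {
  stopifnot(inherits(w, "pathway_weights"), inherits(cp, "choice_params"))
  cp$D * w$G - (1 - cp$kappa_N * cp$D) * w$N
}

#' Noisy action selection with an inaction default
#'
#' Adds independent Gaussian noise to each option's thalamic activity and
#' picks the largest noisy value — unless every noisy value is negative, in
#' which case no action is taken. The inaction default is what lets the
#' model consume less overall under D2 blockade, something a softmax rule
#' (which always forces a choice) cannot produce.
#'
#' @param T_values Numeric vector of thalamic activities, one per option.
#' @param sigma Decision-noise standard deviation.
#' @return The selected option index, or `0L` for inaction.
#' @examples
#' select_action(c(-1, -2), sigma = 0)  # 0 (inactive)
#' select_action(c(1, 3), sigma = 0)    # 2
#' @export
select_action <- function(T_values, sigma = 0) {
  stopifnot(is.numeric(T_values), length(T_values) >= 1L, sigma >= 0)
  noisy <- T_values + stats::rnorm(length(T_values), 0, sigma)
  if (all(noisy < 0)) return(0L)
  top <- which(noisy == max(noisy))
  if (length(top) > 1L) top <- sample(top, 1L)  # ties: uniform at random
  top
}

#' Configuration of the effort-based choice experiment
#'
#' @param n_train Training trials (each action experienced once per trial).
#' @param n_test Testing trials.
#' @param n_rats Number of simulated animals per condition and state.
#' @param init_weight Initial value of every G and N weight.
#' @param p_chow Payoff of the freely available lab chow.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_train = 180L, n_test = 180L, n_rats = 100L,
                              init_weight = 0.1, p_chow = 1) {
  stopifnot(n_train >= 0, n_test >= 1, n_rats >= 1,
            init_weight >= 0, p_chow >= 0)
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 n_rats = as.integer(n_rats), init_weight = init_weight,
                 p_chow = p_chow),
            class = "experiment_config")
}

#' Train the weights of a set of actions
#'
#' For each of `cfg$n_train` trials the model experiences every action
#' once: it receives the action's cost, updates that action's weights, then
#' receives the payoff and updates again. Actions update disjoint weights,
#' so the within-trial ordering across actions is irrelevant. Training is
#' deterministic.
#'
#' @param actions Named list of [action_spec()] objects.
#' @param params A [learning_params()] object.
#' @param cfg An [experiment_config()].
#' @return Named list of trained [pathway_weights()].
#' @export
train_actions <- function(actions, params, cfg = experiment_config()) {
  stopifnot(is.list(actions), length(actions) >= 1L,
            all(vapply(actions, inherits, logical(1), "action_spec")),
            inherits(params, "learning_params"),
            inherits(cfg, "experiment_config"))
  lapply(actions, function(a) {
    w <- pathway_weights(cfg$init_weight, cfg$init_weight)
    for (t in seq_len(cfg$n_train)) {
      w <- apply_update(w, prediction_error(-a$n, w), params)
      w <- apply_update(w, prediction_error(a$p, w), params)
    }
    w
  })
}

# Vectorised f_eps over a numeric vector (no argument checking; internal).
f_eps_vec <- function(x, eps) ifelse(x >= 0, x, eps * x)

#' Run a block of test trials
#'
#' Simulates `cfg$n_test` choice trials for `n_rats` independent animals,
#' all starting from the same trained weights. On each trial the thalamic
#' activity of every option is computed from the current weights, decision
#' noise is added, and the best positive option is executed (otherwise the
#' animal stays inactive). Executed actions deliver their cost then payoff,
#' updating that animal's weights for that action; inactive trials update
#' nothing.
#'
#' @param weights Named list of trained [pathway_weights()], one per action.
#' @param actions Named list of [action_spec()] objects (same names).
#' @param cp A [choice_params()] object.
#' @param params A [learning_params()] object.
#' @param cfg An [experiment_config()].
#' @param n_rats Number of independent replicate animals.
#' @return List with `counts` (matrix `n_rats` x actions of executed
#'   choices), `inactive` (per-rat inactive-trial counts) and `weights`
#'   (final per-rat weight matrices `G`, `N`).
#' @export
run_test_block <- function(weights, actions, cp, params,
                           cfg = experiment_config(), n_rats = 1L) {
  stopifnot(is.list(weights), is.list(actions),
            length(weights) == length(actions),
            inherits(cp, "choice_params"), inherits(params, "learning_params"),
            inherits(cfg, "experiment_config"), n_rats >= 1)
  n_act <- length(actions)
  G <- matrix(vapply(weights, `[[`, numeric(1), "G"),
              nrow = n_rats, ncol = n_act, byrow = TRUE)
  N <- matrix(vapply(weights, `[[`, numeric(1), "N"),
              nrow = n_rats, ncol = n_act, byrow = TRUE)
  p_vec <- vapply(actions, `[[`, numeric(1), "p")
  n_vec <- vapply(actions, `[[`, numeric(1), "n")
  counts <- matrix(0L, n_rats, n_act,
                   dimnames = list(NULL, names(actions)))
  inactive <- integer(n_rats)
  alpha <- params$alpha; eps <- params$epsilon; lam <- params$lam
  rows <- seq_len(n_rats)
  for (t in seq_len(cfg$n_test)) {
    Tm <- cp$D * G - (1 - cp$kappa_N * cp$D) * N
    noisy <- Tm + matrix(stats::rnorm(n_rats * n_act, 0, cp$sigma),
                         n_rats, n_act)
    best <- max.col(noisy, ties.method = "random")
    executed <- noisy[cbind(rows, best)] >= 0
    inactive <- inactive + !executed
    for (a in seq_len(n_act)) {
      idx <- executed & best == a
      if (!any(idx)) next
      counts[idx, a] <- counts[idx, a] + 1L
      # cost event, then payoff event, each from pre-update weights
      for (r in c(-n_vec[a], p_vec[a])) {
        d <- r - (G[idx, a] - N[idx, a]) / 2
        g_new <- G[idx, a] + alpha * f_eps_vec(d, eps) - lam * G[idx, a]
        n_new <- N[idx, a] + alpha * f_eps_vec(-d, eps) - lam * N[idx, a]
        G[idx, a] <- pmax(0, g_new)
        N[idx, a] <- pmax(0, n_new)
      }
    }
  }
  list(counts = counts, inactive = inactive, weights = list(G = G, N = N))
}

#' Learning parameters used for the lever-pressing experiment
#'
#' The plasticity constants with which the model of the Salamone
#' lever-pressing experiment is trained (`alpha = 0.1`, `epsilon = 0.6327`,
#' `lam = 0.0204`, i.e. `c_Q = 0.8`, `c_S = 0.9`).
#'
#' @return A [learning_params()] object.
#' @export
salamone_learning_params <- function() learning_params(0.1, 0.6327, 0.0204)

#' Reference fitted choice parameters for the lever-pressing experiment
#'
#' The parameter set obtained by fitting the model to the haloperidol
#' consumption data: pellet payoff, lever-press cost, D2-coupling under
#' blockade and decision noise.
#'
#' @return Named list with `p_pellet`, `n_lever`, `kappa_N`, `sigma`.
#' @export
salamone_reference_fit <- function() {
  list(p_pellet = 15.511751, n_lever = 14.510517,
       kappa_N = 0.7507, sigma = 1.066246)
}

#' Experimental consumption table of the lever-pressing experiment
#'
#' Grams of pellets and lab chow consumed by rats in control and
#' D2-blocked (haloperidol) states, in the free-pellet and lever-press
#' conditions. Used only in per-condition normalised form, where grams act
#' as choice masses.
#'
#' @return A data.frame with columns `option`, `state`, `condition`,
#'   `amount`.
#' @export
salamone_consumption <- function() {
  path <- system.file("extdata", "salamone_consumption.csv",
                      package = "gonogo", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Simulate the full lever-pressing experiment
#'
#' Trains the model on the pellet and chow actions and runs test blocks for
#' every condition (free pellets vs lever pressing, which adds the cost
#' `n_lever` to the pellet) and state (control, `kappa_N = 1`, vs blocked,
#' `kappa_N` as given). Haloperidol acts at choice only: training is
#' identical across states. The dopamine level is fixed at `D = 0.5`.
#'
#' @param p_pellet Pellet payoff magnitude.
#' @param n_lever Lever-pressing cost magnitude.
#' @param kappa_N D2-coupling in the blocked state.
#' @param sigma Decision-noise standard deviation.
#' @param params A [learning_params()] object (default
#'   [salamone_learning_params()]).
#' @param cfg An [experiment_config()].
#' @param seed Optional integer seed set before the test blocks.
#' @return List with `table` (mean choice counts: `option`, `state`,
#'   `condition`, `amount`), `inactive` (mean inactive trials per state and
#'   condition) and `trained` (per-condition trained weights).
#' @export
simulate_salamone <- function(p_pellet, n_lever, kappa_N, sigma,
                              params = salamone_learning_params(),
                              cfg = experiment_config(), seed = NULL) {
  stopifnot(p_pellet >= 0, n_lever >= 0, kappa_N >= 0, kappa_N <= 1,
            sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  conditions <- list(free = 0, lever = n_lever)
  states <- list(control = 1, blocked = kappa_N)
  rows <- list(); inact <- list(); trained_all <- list()
  for (k in names(conditions)) {
    actions <- list(
      pellet = action_spec(p_pellet, conditions[[k]]),
      chow = action_spec(cfg$p_chow, 0)
    )
    trained <- train_actions(actions, params, cfg)
    trained_all[[k]] <- trained
    for (j in names(states)) {
      cp <- choice_params(D = 0.5, kappa_N = states[[j]], sigma = sigma)
      block <- run_test_block(trained, actions, cp, params, cfg,
                              n_rats = cfg$n_rats)
      mean_counts <- colMeans(block$counts)
      rows[[length(rows) + 1L]] <- data.frame(
        option = names(actions), state = j, condition = k,
        amount = as.numeric(mean_counts)
      )
      inact[[length(inact) + 1L]] <- data.frame(
        state = j, condition = k, inactive = mean(block$inactive)
      )
    }
  }
  list(table = do.call(rbind, rows),
       inactive = do.call(rbind, inact),
       trained = trained_all)
}

#' Normalised consumption mismatch
#'
#' Squared mismatch between two consumption tables, each normalised within
#' condition by its total consumption `Z_k` (summed over options and
#' states): `sum_k sum_j sum_i (sim_ijk / Z_k_sim - exp_ijk / Z_k_exp)^2`.
#' The normalisation makes the cost invariant to per-condition rescaling,
#' so simulated choice counts can be compared with consumed grams.
#'
#' @param sim,exp Data.frames with columns `option`, `state`, `condition`,
#'   `amount`.
#' @return Scalar cost.
#' @export
consumption_cost <- function(sim, exp) {
  cols <- c("option", "state", "condition", "amount")
  stopifnot(is.data.frame(sim), all(cols %in% names(sim)),
            is.data.frame(exp), all(cols %in% names(exp)))
  m <- merge(sim, exp, by = c("option", "state", "condition"),
             suffixes = c("_sim", "_exp"))
  if (nrow(m) != nrow(exp)) stop("tables do not share all cells", call. = FALSE)
  total <- 0
  for (k in unique(m$condition)) {
    mk <- m[m$condition == k, ]
    Z_sim <- sum(mk$amount_sim); Z_exp <- sum(mk$amount_exp)
    if (Z_sim <= 0 || Z_exp <= 0) {
      stop("undefined normalisation: zero total consumption in condition '",
           k, "' (degenerate, e.g. all-inactive, simulation)", call. = FALSE)
    }
    total <- total + sum((mk$amount_sim / Z_sim - mk$amount_exp / Z_exp)^2)
  }
  total
}

#' Fit the choice model to a consumption table
#'
#' Minimises [consumption_cost()] between the mean simulated consumption
#' table (over `cfg$n_rats` animals) and an experimental table, over the
#' four free parameters `p_pellet`, `n_lever`, `kappa_N` and `sigma`, using
#' Nelder-Mead simplex search. `kappa_N` is kept in \[0, 1\] by a logistic
#' transform and the magnitudes positive by log transforms. Every objective
#' evaluation reuses the same RNG seed (common random numbers), which makes
#' the stochastic objective quasi-deterministic for the simplex. The
#' control state always pins `kappa_N = 1` and `D = 0.5` throughout.
#'
#' @param exp Experimental consumption table (see [salamone_consumption()]).
#' @param params A [learning_params()] object.
#' @param cfg An [experiment_config()].
#' @param start Named list of starting values (`p_pellet`, `n_lever`,
#'   `kappa_N`, `sigma`).
#' @param seed Seed used for every objective evaluation.
#' @param maxit Maximum simplex iterations per start.
#' @param restarts Number of simplex restarts from the best point so far.
#'   The mean counts are averages over finitely many animals, so the
#'   objective is a step function at fine scales and a single simplex run
#'   can report convergence on a plateau; re-initialising the simplex
#'   around the incumbent escapes such stalls.
#' @return List of class `fit_result`: fitted parameters, `objective`,
#'   `convergence` (0 = converged), optimizer `counts`, and `table`, the
#'   simulated consumption table at the optimum.
#' @export
fit_experiment <- function(exp, params = salamone_learning_params(),
                           cfg = experiment_config(),
                           start = list(p_pellet = 10, n_lever = 10,
                                        kappa_N = 0.8, sigma = 1),
                           seed = 1L, maxit = 300L, restarts = 3L) {
  stopifnot(is.data.frame(exp))
  to_theta <- function(s) c(log(s$p_pellet), log(s$n_lever),
                            stats::qlogis(s$kappa_N), log(s$sigma))
  from_theta <- function(th) list(p_pellet = exp(th[1]), n_lever = exp(th[2]),
                                  kappa_N = stats::plogis(th[3]),
                                  sigma = exp(th[4]))
  objective <- function(th) {
    pars <- from_theta(th)
    sim <- simulate_salamone(pars$p_pellet, pars$n_lever, pars$kappa_N,
                             pars$sigma, params, cfg, seed = seed)
    consumption_cost(sim$table, exp)
  }
  theta <- to_theta(start)
  opt <- NULL
  for (run in seq_len(1L + max(0L, restarts))) {
    cand <- stats::optim(theta, objective, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-10))
    if (is.null(opt) || cand$value < opt$value) opt <- cand
    theta <- opt$par
  }
  fitted <- from_theta(opt$par)
  sim <- simulate_salamone(fitted$p_pellet, fitted$n_lever, fitted$kappa_N,
                           fitted$sigma, params, cfg, seed = seed)
  structure(c(fitted,
              list(objective = opt$value, convergence = opt$convergence,
                   counts = opt$counts, table = sim$table)),
            class = "fit_result")
}

#' Multistage fit with a scan along the weakly identified scale direction
#'
#' The consumption objective is nearly flat along a direction that scales
#' `p_pellet`, `n_lever` and `sigma` together (with a compensating change
#' in `kappa_N`): jointly enlarging all magnitudes and the decision noise
#' changes the choice fractions only through the fixed chow payoff, so a
#' single simplex run from a distant start can settle into a shallow false
#' basin created by Monte-Carlo noise. This wrapper therefore (1) runs a
#' coarse [fit_experiment()] at `cfg$n_rats` animals, (2) restarts short
#' simplex runs from rescaled copies of the coarse fit along the flat
#' direction at `n_rats_scan` animals, and (3) polishes the best candidate
#' at `n_rats_refine` animals, where the Monte-Carlo noise is small enough
#' for the true minimum to dominate its false neighbours.
#'
#' @inheritParams fit_experiment
#' @param scales Scale factors applied to the coarse fit's `p_pellet`,
#'   `n_lever` and `sigma` to seed the scan.
#' @param n_rats_scan,n_rats_refine Simulated animals per objective
#'   evaluation in the scan and polish stages.
#' @return A `fit_result` (see [fit_experiment()]).
#' @export
fit_experiment_multistage <- function(exp, params = salamone_learning_params(),
                                      cfg = experiment_config(),
                                      start = list(p_pellet = 10, n_lever = 10,
                                                   kappa_N = 0.8, sigma = 1),
                                      seed = 1L,
                                      scales = c(0.7, 0.85, 1, 1.15),
                                      n_rats_scan = 500L,
                                      n_rats_refine = 2000L) {
  coarse <- fit_experiment(exp, params, cfg, start, seed = seed,
                           maxit = 250L, restarts = 1L)
  scan_cfg <- experiment_config(n_rats = n_rats_scan)
  best <- NULL
  for (sc in scales) {
    cand <- fit_experiment(
      exp, params, scan_cfg,
      start = list(p_pellet = sc * coarse$p_pellet,
                   n_lever = sc * coarse$n_lever,
                   kappa_N = coarse$kappa_N,
                   sigma = sc * coarse$sigma),
      seed = seed, maxit = 80L, restarts = 0L)
    if (is.null(best) || cand$objective < best$objective) best <- cand
  }
  fit_experiment(exp, params, experiment_config(n_rats = n_rats_refine),
                 start = best[c("p_pellet", "n_lever", "kappa_N", "sigma")],
                 seed = seed, maxit = 150L, restarts = 0L)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(paste0(
    "fit_result: p_pellet = %.4f, n_lever = %.4f, kappa_N = %.4f, ",
    "sigma = %.4f\n  objective = %.6g (convergence code %d)\n"),
    x$p_pellet, x$n_lever, x$kappa_N, x$sigma, x$objective, x$convergence))
  invisible(x)
}
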