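test_that("thalamic activity combines pathways under dopaminergic gain", {
  expect_equal(thalamic_activity(pathway_weights(7, 7),
                                 choice_params(D = 0.5, kappa_N = 1)), 0)
  # D = 1 with intact coupling silences the No-Go contribution entirely
  expect_equal(thalamic_activity(pathway_weights(10, 4),
                                 choice_params(D = 1, kappa_N = 1)), 10)
  expect_equal(thalamic_activity(pathway_weights(10, 4),
                                 choice_params(D = 0.5, kappa_N = 1)), 3)
  # total blocking leaves N unscaled by dopamine
  expect_equal(thalamic_activity(pathway_weights(10, 4),
                                 choice_params(D = 0.5, kappa_N = 0)), 1)
})

test_that("lowering kappa_N never increases thalamic activity", {
  set.seed(31)
  for (i in 1:200) {
    w <- pathway_weights(stats::runif(1, 0, 20), stats::runif(1, 0, 20))
    D <- stats::runif(1)
    k <- sort(stats::runif(2))
    T_low <- thalamic_activity(w, choice_params(D = D, kappa_N = k[1]))
    T_high <- thalamic_activity(w, choice_params(D = D, kappa_N = k[2]))
    expect_lte(T_low, T_high + 1e-12)
  }
})

test_that("noiseless selection picks the argmax and defaults to inaction", {
  expect_identical(select_action(5, sigma = 0), 1L)
  expect_identical(select_action(c(-1, -2), sigma = 0), 0L)
  expect_identical(select_action(c(1, 3), sigma = 0), 2L)
})

test_that("training follows the pure-decay closed form when reinforcements vanish", {
  p <- salamone_learning_params()
  cfg <- experiment_config(n_train = 40, init_weight = 0.1)
  trained <- train_actions(list(null_act = action_spec(0, 0)), p, cfg)
  # r = 0 and G = N keeps delta = 0 throughout: both weights decay
  # geometrically, one factor per event (two events per trial)
  expect_equal(trained$null_act$G, 0.1 * (1 - p$lam)^(2 * 40),
               tolerance = 1e-12)
  expect_equal(trained$null_act$N, trained$null_act$G, tolerance = 1e-14)

  cfg0 <- experiment_config(n_train = 0)
  w0 <- train_actions(list(a = action_spec(3, 1)), p, cfg0)
  expect_equal(c(w0$a$G, w0$a$N), c(0.1, 0.1))
})

test_that("trained weights approach the per-action deterministic fixed points", {
  p <- salamone_learning_params()
  ref <- salamone_reference_fit()
  actions <- list(pellet = action_spec(ref$p_pellet, ref$n_lever),
                  chow = action_spec(1, 0))
  trained <- train_actions(actions, p, experiment_config(n_train = 180))
  fp_pellet <- deterministic_fixed_point(actions$pellet, p)
  fp_chow <- deterministic_fixed_point(actions$chow, p)
  expect_equal(trained$pellet$G, fp_pellet$G_star, tolerance = 0.05)
  expect_equal(trained$pellet$N, fp_pellet$N_star, tolerance = 0.05)
  expect_equal(trained$chow$G, fp_chow$G_star, tolerance = 0.05)
  # payoff-and-cost action dwarfs the cheap low-payoff one
  expect_gt(trained$pellet$G, 10 * trained$chow$G)
  expect_gt(trained$pellet$N, 100 * trained$chow$N)
})

test_that("test blocks respect the inaction default and the trivial limits", {
  p <- salamone_learning_params()
  cfg <- experiment_config(n_test = 25)
  # both activities negative throughout, no noise: always inactive
  weights <- list(a = pathway_weights(0, 5), b = pathway_weights(0, 3))
  actions <- list(a = action_spec(0, 10), b = action_spec(0, 6))
  block <- run_test_block(weights, actions, choice_params(sigma = 0), p, cfg,
                          n_rats = 3)
  expect_true(all(block$counts == 0))
  expect_equal(block$inactive, rep(25L, 3))

  # single clearly positive option, no noise: chosen on every trial
  block1 <- run_test_block(list(a = pathway_weights(10, 0)),
                           list(a = action_spec(10, 0)),
                           choice_params(sigma = 0), p, cfg, n_rats = 2)
  expect_equal(as.vector(block1$counts), c(25L, 25L))
})

test_that("consumption cost is zero on matching tables and scale-invariant", {
  exp_tab <- salamone_consumption()
  expect_equal(consumption_cost(exp_tab, exp_tab), 0)
  scaled <- exp_tab
  scaled$amount <- ifelse(scaled$condition == "free",
                          exp_tab$amount * 3.7, exp_tab$amount * 0.21)
  expect_equal(consumption_cost(scaled, exp_tab), 0, tolerance = 1e-14)

  degenerate <- exp_tab
  degenerate$amount[degenerate$condition == "lever"] <- 0
  expect_error(consumption_cost(degenerate, exp_tab), "normalisation")
})

test_that("the packaged consumption table carries the published normalisation", {
  exp_tab <- salamone_consumption()
  free <- exp_tab[exp_tab$condition == "free", ]
  expect_equal(sum(free$amount), 32.2)
  cell <- free$amount[free$option == "pellet" & free$state == "control"]
  expect_equal(cell / sum(free$amount), 0.4814, tolerance = 1e-4)
})

test_that("the reference parameters reproduce the D2-blocking choice pattern", {
  ref <- salamone_reference_fit()
  sim <- simulate_salamone(ref$p_pellet, ref$n_lever, ref$kappa_N, ref$sigma,
                           seed = 11)
  tab <- sim$table
  pick <- function(opt, st, cond) {
    tab$amount[tab$option == opt & tab$state == st & tab$condition == cond]
  }
  # free pellets: pellet preferred with and without blocking
  expect_gt(pick("pellet", "control", "free"), pick("chow", "control", "free"))
  expect_gt(pick("pellet", "blocked", "free"), pick("chow", "blocked", "free"))
  # lever: preference reverses under blocking
  expect_gt(pick("pellet", "control", "lever"), pick("chow", "control", "lever"))
  expect_lt(pick("pellet", "blocked", "lever"), pick("chow", "blocked", "lever"))
  # blocked animals execute fewer choices in the lever condition
  total_control <- pick("pellet", "control", "lever") + pick("chow", "control", "lever")
  total_blocked <- pick("pellet", "blocked", "lever") + pick("chow", "blocked", "lever")
  expect_lt(total_blocked, total_control)
  inact <- sim$inactive
  expect_gt(inact$inactive[inact$state == "blocked" & inact$condition == "lever"],
            inact$inactive[inact$state == "control" & inact$condition == "lever"])
})

test_that("a huge decision noise drives choices toward uniformity", {
  ref <- salamone_reference_fit()
  sim <- simulate_salamone(ref$p_pellet, ref$n_lever, ref$kappa_N,
                           sigma = 1e4, seed = 21)
  tab <- sim$table
  # each option drawn ~ uniformly among {a, b, inactive}: fractions near 1/2
  # of executed choices, and executed ~ 3/4 of trials
  for (cond in c("free", "lever")) for (st in c("control", "blocked")) {
    cell <- tab$amount[tab$state == st & tab$condition == cond]
    expect_equal(cell[1] / sum(cell), 0.5, tolerance = 0.05)
  }
})
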