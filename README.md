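# gonogo

Simulation and analysis of a dual-pathway basal-ganglia model in which the
direct (Go) and indirect (No-Go) striatal pathways learn the mean **payoff**
and the mean **cost** of individual actions from a single outcome
prediction-error signal. The package is aimed at computational
neuroscientists and modellers studying reinforcement learning in the
basal ganglia, dopaminergic modulation of effort-based choice, and the
behaviour of opponent learning rules.

## The model

For one action, the collective Go and No-Go strengths `G, N >= 0` learn from
the prediction error

    delta = r - (G - N)/2

via

    dG = alpha * f_eps(delta)  - lambda * G
    dN = alpha * f_eps(-delta) - lambda * N

where `f_eps(x) = x` for `x >= 0` and `eps * x` for `x < 0`; a weight an
update would drive negative is clipped to zero. In the variables
`Q = (G - N)/2`, `S = (G + N)/2` the rules track the mean and the mean
spread of reinforcement with effective rates `alpha_Q = alpha(1 + eps)/2`,
`alpha_S = alpha(1 - eps)/2`. After learning,

    Q* = c_Q * q,   S* ~ c_S * E|R - c_Q q|,
    c_Q = alpha_Q / (alpha_Q + lambda),   c_S = alpha_S / lambda,

so `G = S + Q` and `N = S - Q` approximate the payoff `p = q + s` and cost
`n = s - q` exactly when `c_Q ~ 1` and `c_S = 1`. At choice time the
thalamic activity of an option is `T = D*G - (1 - kappa_N*D)*N`: the
dopamine level `D` trades payoffs against costs, and `kappa_N < 1` models
D2-receptor blockade (haloperidol). Noisy selection with an inaction
default reproduces the classic lever-pressing result that blocked animals
both switch to the effort-free option and consume less overall.
Actor-critic and opponent-actor-learning (OpAL) comparators are included;
the latter's multiplicative updates provably collapse its actor weights on
cost-then-payoff actions.

## Worked example

```r
library(gonogo)

params <- learning_params(0.3, 0.443, 0.093)  # alpha, eps, lambda
params
#> learning_params: alpha = 0.3, epsilon = 0.443, lam = 0.093
#>   effective rates: alpha_Q = 0.21645, alpha_S = 0.08355

# the (eps, lambda) above come from inverting the equilibrium coefficients:
solve_parameters(0.3, 0.7, 0.9)
#> $epsilon
#> [1] 0.4432990
#> $lam
#> [1] 0.09278351

# learn an action that costs 20 and then pays 20, for 200 trials
traj <- run_learning(schedule_spec("alternating", p = 20, n = 20,
                                   n_trials = 200), params)
tail(traj[, c("trial", "r", "G", "N", "Q", "S")], 1)
#>     trial  r        G        N        Q        S
#> 401   200 20 22.82895 17.70754 2.560705 20.26825

# the closed-form fixed point the trajectory converged to
deterministic_fixed_point(action_spec(20, 20), params)[c("Q_exact", "G_star", "N_star")]
#> $Q_exact
#> [1] 2.560705
#> $G_star
#> [1] 22.82895
#> $N_star
#> [1] 17.70754

# stochastic schedule: both weights converge near c_S * 20
stochastic_equilibrium(schedule_spec("two_point", p = 20, n = 20), params)$S_star
#> [1] 17.96774
```

After learning, `G` and `N` sit near the true payoff and cost magnitudes
(22.8 and 17.7 versus 20 and 20 at these deliberately detuned
coefficients; with `c_Q`, `c_S` closer to 1 they converge tighter). The
lever-pressing experiment, its fit, and the comparator models are run via
`simulate_salamone()`, `fit_experiment()` / `fit_experiment_multistage()`,
`run_actor_critic_task()` and `run_opal()`, or from the shell through the
`inst/scripts/gonogo` CLI (`simulate`, `ensemble`, `equilibria`,
`solve-params`, `salamone`, `fit`, `compare`).

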