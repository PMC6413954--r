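---
title: "Learning payoffs and costs in the dual-pathway basal-ganglia model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning payoffs and costs in the dual-pathway basal-ganglia model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gonogo)
```

## The model

The basal ganglia route cortical input through two opposing pathways: the
direct (Go) pathway, whose striatal neurons carry D1 receptors and promote
action, and the indirect (No-Go) pathway, whose neurons carry D2 receptors
and suppress it. `gonogo` implements a reinforcement-learning model in
which the collective corticostriatal strengths of these pathways for one
action, written $G \ge 0$ and $N \ge 0$, come to encode that action's mean
*payoff* and mean *cost* — the separately stored positive and negative
consequences — so that the tonic dopamine level can reweight them at
choice time according to motivational state.

Both weights learn from a single teaching signal, the outcome prediction
error

$$\delta = r - \tfrac{1}{2}(G - N),$$

where $r$ is the instantaneous reinforcement (negative while effort is
exerted, positive when the payoff arrives). One plasticity event updates

$$\Delta G = \alpha f_\epsilon(\delta) - \lambda G, \qquad
  \Delta N = \alpha f_\epsilon(-\delta) - \lambda N,$$

with learning rate $\alpha$, decay rate $\lambda$, and the piecewise-linear
transform $f_\epsilon(x) = x$ for $x \ge 0$ and $\epsilon x$ for $x < 0$
($0 \le \epsilon \le 1$). A weight that an update would drive negative is
clipped to zero; both raw updates are always computed from the pre-update
weights (the simultaneous-update convention also used in the closed-form
fixed-point derivation below). The asymmetry of $f_\epsilon$ is the load-
bearing ingredient: positive errors (payoffs) teach mostly $G$, negative
errors (costs) mostly $N$; at $\epsilon = 1$ the rules become
antisymmetric ($\Delta G = -\Delta N$ when $\lambda = 0$) and the pair can
only oscillate, never grow to store the size of payoff and cost.

In the transformed variables $Q = \tfrac{1}{2}(G-N)$ (mean estimate) and
$S = \tfrac{1}{2}(G+N)$ (spread estimate) the rules become
$\Delta Q = \alpha_Q \delta - \lambda Q$ and
$\Delta S = \alpha_S |\delta| - \lambda S$ with the effective rates
$\alpha_Q = \alpha(1+\epsilon)/2$, $\alpha_S = \alpha(1-\epsilon)/2$.
`qs_update()` and `apply_update()` agree exactly as long as no clipping
fires; when clipping matters, $(G, N)$ is the canonical state and the
$(Q, S)$ view is derived from it, because the linear $(Q, S)$ analysis
implicitly assumes the clip is inactive.

## Equilibrium theory

On reinforcements drawn from a fixed distribution with mean
$q = \mathrm{E}R$ and mean spread $s = \mathrm{E}|R - q|$, the weights
stop changing systematically at

$$Q^\* = c_Q\, q, \qquad S^\* \approx c_S\, \mathrm{E}|R - c_Q q|,$$

with $c_Q = \alpha_Q/(\alpha_Q + \lambda)$ and $c_S = \alpha_S/\lambda$
(`stochastic_equilibrium()`). Unbiased coding of payoff
$p = q + s$ and cost $n = s - q$ needs $c_Q \approx 1$ and $c_S = 1$,
i.e. $2\lambda \ll \alpha(1+\epsilon)$ and $2\lambda = \alpha(1-\epsilon)$
(`check_conditions()`; the "$\ll$" flag defaults to a ratio below 0.2, a
declared choice since no sharp cutoff exists). `solve_parameters()`
inverts the coefficient definitions: given $\alpha$ and targets
$(c_Q, c_S)$ it returns
$\epsilon = (1 - k)/(1 + k)$ with $k = c_S(1/c_Q - 1)$ and
$\lambda = \alpha(1-\epsilon)/(2 c_S)$. The package's reference setting
$\alpha = 0.3$, $(c_Q, c_S) = (0.7, 0.9)$ gives $\epsilon = 0.443$,
$\lambda = 0.093$:

```{r}
solve_parameters(0.3, 0.7, 0.9)
```

`balanced_epsilon()` returns the slope that makes $c_Q = c_S$ for given
$(\alpha, \lambda)$ — the detuning-robust line along which the two weights
remain proportional to payoff and cost even far from the ideal conditions,
and the thalamic read-out (`thalamic_detuned()`) is merely rescaled.

### The deterministic fixed point, exactly and as commonly printed

For an action that reliably yields cost $-n$ then payoff $+p$ each trial,
the two-event composition of the $Q$ update is linear with per-event
contraction $1 - \alpha_Q - \lambda$, and its unique fixed point is

$$Q^\*_{\text{exact}}
  = \frac{\alpha_Q\,\bigl(p - (1-\alpha_Q-\lambda)\,n\bigr)}
         {1 - (1-\alpha_Q-\lambda)^2}
  = c_Q \cdot \frac{n(\alpha_Q + \lambda - 1) + p}{2 - \alpha_Q - \lambda}.$$

The right-hand fraction alone is the commonly quoted closed form. Our own
derivation shows it omits the factor $c_Q$ relative to the invariant point
of the stated composition; both agree in the intended regime
$\alpha_Q + \lambda \approx 0$ ($\alpha \ll 1$).
`deterministic_fixed_point()` deliberately exposes both values
(`Q_printed`, `Q_exact`) rather than silently correcting either; the exact
value is canonical in the tests because simulated trajectories converge to
it (to $10^{-6}$ after 200 trials at the reference parameters), and
`Q_printed = Q_exact / c_Q` holds to $10^{-9}$ as an algebraic identity.
The spread fixed point is found by damped iteration of the coupled
two-event $(Q, S)$ map to an increment below $10^{-12}$; the map is linear
given the $Q$ cycle, so convergence is geometric and an iteration cap of
$10^6$ is purely defensive.

## The schedule generators

`schedule_spec()` declares the reinforcement regime used everywhere else:
alternating fixed cost/payoff; fixed cost followed by a Gaussian payoff;
a symmetric two-point draw; or a single Gaussian event whose standard
deviation $\tfrac{1}{2}\sqrt{\pi/2}\,(p+n)$ is matched so that its mean
spread equals $(p+n)/2$. All kinds share $q = (p-n)/2$. Two declared
choices close gaps the protocol leaves open: the payoff noise of the
fixed-cost kind defaults to `0.2 * p` ("non-vanishing variance" is
otherwise unquantified), and within a trial the cost is delivered and
learned from *before* the payoff, the ordering assumed by the fixed-point
composition above. Initial weights for trajectory simulations default to
$(0, 0)$ — learning an unfamiliar action from scratch — a declared choice
rather than an inferred one; they are overridable and recorded in the run
metadata.

These generators emulate the *statistical structure* of reinforcement
(means, spreads, within-trial ordering) and nothing else: no satiety,
no nonstationarity, no correlation between payoff and cost noise, no
within-session drift of motivation. Tests passing on them show that the
implementation realises the model's mathematics, not that the model fits
any particular animal's data.

## The choice model and the D2-blocking experiment

After learning, an option's thalamic activity is
$T = D\,G - (1 - \kappa_N D)\,N$, with dopamine level $D \in [0,1]$
($D = 0.5$ the baseline at which both pathways weigh equally) and
$\kappa_N \in [0,1]$ the coupling of dopamine to the D2-bearing No-Go
population; $\kappa_N < 1$ models haloperidol. Choice adds independent
Gaussian noise (sd $\sigma$) to each option's $T$ and executes the largest
positive value; if all noisy activities are negative the model stays
inactive. The inaction default — rather than a softmax — is what lets
total consumption fall under blockade.

`simulate_salamone()` reproduces the classic lever-pressing protocol: 180
deterministic training trials per action (pellet, and freely available
chow with payoff fixed at 1) from initial weights 0.1, then 180 test
trials per animal in each condition (free vs lever, the lever adding cost
$n_{\text{lever}}$ to the pellet) and state (control $\kappa_N = 1$ vs
blocked). Blocking acts at choice only; training is identical across
states, and $D$ stays at 0.5 throughout. Executed test actions keep
updating their weights, as the protocol describes. With the reference
fitted parameters (`salamone_reference_fit()`) the simulation reproduces
the qualitative pattern: pellet preference in both states when free,
reversal to chow under blocking with a lever, and fewer executed choices
in the blocked lever condition.

`fit_experiment()` minimises the per-condition-normalised squared mismatch
(`consumption_cost()`, invariant to rescaling grams to choice counts) over
$(p_{\text{pellet}}, n_{\text{lever}}, \kappa_N, \sigma)$ with
Nelder-Mead, log/logistic transforms keeping magnitudes positive and
$\kappa_N$ in $[0,1]$, and common random numbers (one base seed per
objective evaluation) making the stochastic objective quasi-deterministic.
Two numerical facts shaped the design:

* the objective is nearly flat along the direction that scales
  $(p_{\text{pellet}}, n_{\text{lever}}, \sigma)$ together — only the
  fixed chow payoff breaks the scale — and finite-ensemble noise carves
  shallow false minima into that valley. `fit_experiment_multistage()`
  therefore follows a coarse 100-animal fit with short simplex runs from
  rescaled copies of the incumbent and a polish at 2000 animals, where the
  true minimum demonstrably dominates its false neighbours. Recovery of
  self-generated ground truth lands within 10% for the magnitudes and a
  few percent for $\kappa_N$.
* because several basins fit comparably, the *location* of the best fit to
  the published gram table is optimizer-dependent; only the qualitative
  pattern and synthetic-ground-truth recovery are stable claims, and only
  those are asserted in the tests.

Ties in the noisy argmax (probability zero for $\sigma > 0$) break
uniformly at random. Within a training trial the pellet is experienced
before the chow; the order is immaterial because the two actions update
disjoint weights.

## Comparator architectures

`actor_critic_step()` moves the outcome prediction into a situation-level
critic learning by the same dual-pathway rules; $\delta = r - V$ with
$V = \tfrac{1}{2}(G_c - N_c)$ teaches actor and critic alike. With a
single action the critic's $V$ coincides with the actor's $Q$ at every
step, so the actor-critic and actor-only models agree exactly — the test
asserts $10^{-8}$ after 500 trials. With two actions
(`run_actor_critic_task()`, softmax on $Q$ with temperature $\beta$) the
critic converges to the neighbourhood of the superior action's value and
that action's weights approach its payoff and cost; the inferior action is
under-sampled and its estimates stay biased. The two-action task defaults
to superior $(p, n) = (20, 10)$ vs inferior $(10, 20)$, magnitudes chosen
on the same scale as the headline trajectory simulations.

`opal_step()`/`run_opal()` implement the opponent-actor-learning
comparator: critic $\Delta V = \alpha_V \delta$ and *multiplicative* actor
updates $\Delta G = \alpha_G G \delta$, $\Delta N = -\alpha_N N \delta$.
On a cost-then-payoff action the converged prediction error alternates
$\pm d$ with $d = (p+n)/(2-\alpha_V)$, so each trial contracts $G$ by
$(1 - \alpha_G d)(1 + \alpha_G d) = 1 - \alpha_G^2 d^2$: the actor weights
collapse to zero instead of storing payoff and cost, for *any* rate triple
$(\alpha_V, \alpha_G, \alpha_N)$. One numerical caveat: at reinforcement
magnitude 20 and $\alpha = 0.3$ the factor $1 - \alpha^2 d^2$ is negative
— the update overshoots and the zero floor truncates it immediately, which
is collapse but not geometric decay. The log-linear slope check therefore
runs at magnitude 2 (the contractive regime $\alpha^2 d^2 < 1$), while the
magnitude-20 run demonstrates outright collapse next to the dual-pathway
model's convergence to $(p, n)$ on the identical schedule.

## Problem sizes and degenerate inputs

The shipped tests use 200-trial trajectories, 300–500-run ensembles,
$10^4$–$10^5$-draw Monte-Carlo checks against analytic statistics (3
standard-error bands), and 100–4000-animal choice ensembles — sizes at
which every stochastic band is comfortably resolved while the whole suite
stays quick. Degenerate inputs are handled explicitly rather than
silently: $\lambda = 0$ reports $c_Q = 1$ with $c_S$ flagged undefined
(never an infinity), an all-inactive simulation raises an undefined-
normalisation error in `consumption_cost()`, inverse transforms reject
$S < |Q|$, and `solve_parameters()` rejects targets that would force
$\lambda \le 0$ or $\epsilon \notin (0,1)$.

## Known limitations

Weights are scalar per action (no synapse-level vectors, eligibility
traces or spiking dynamics); decay applies only on events of the acted-on
action — the alternative, decaying unvisited actions too, is a plausible
reading the rules leave open; the spread equilibrium uses the
small-fluctuation approximation $\mathrm{E}|R - Q| \approx
\mathrm{E}|R - Q^\*|$, whose bias is visible (a fraction of one unit at
$\alpha = 0.3$ on Gaussian schedules) but stays within the 3-SE bands
tested; and the choice stage is a linear read-out — no saturation of
dopaminergic gain, no learning of $D$ itself.
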