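---
title: "Modelling direct and indirect social influence in innovation adoption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling direct and indirect social influence in innovation adoption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(innodiff)
library(dplyr)
```

## The scientific problem

When people adopt an innovation — a behaviour, technology or idea that is new
to them — the classical network view is that only *direct* ties matter:
I adopt because my friends adopted. But humans also imitate people they
perceive as socially close without talking to them, an observational-learning
channel that operates "through space" rather than through edges. `innodiff`
implements a complete analysis pipeline for quantifying how strong this
indirect peer pressure is, as a function of social distance, from round-based
colour-consensus experiments on a fixed social network.

The pipeline has four stages, each usable on its own:

1. **Diffusion model.** A consensus dynamics on the network driven by d-path
   Laplacians, solved by matrix exponential and discretised into rounds.
2. **Estimation.** A grid search matching the model's cumulative adopter
   curve to an observed one, per session and informational setting, yielding
   the indirect influence strength $c_d$ for that setting's distance.
3. **Session generation.** A seeded agent-based simulator of the experiment
   protocol itself, standing in for human-subject data.
4. **Aggregation and decision analysis.** Across-session coefficient
   statistics, mean-difference tests, outlier and stubborn-participant
   detection, and random-forest feature importance of individual choices.

## The model

Each node $i$ carries an adoption propensity $u_i(t)$. Let $L_d$ be the
**d-path Laplacian**: the Laplacian of the auxiliary graph joining node
pairs at shortest-path distance exactly $d$ in the social network,

$$(L_d f)(v) = \sum_{w:\, d(v,w)=d} \big(f(w) - f(v)\big).$$

With the direct strength normalised to $c_1 = 1$ and the network diameter
$D$, propensities evolve under

$$\dot u(t) = -\Big(L_1 + \sum_{d=2}^{D} c_d L_d\Big)\, u(t),
\qquad u(0) = u_0,$$

whose solution is $u(t) = e^{-tM} u_0$ with
$M = L_1 + \sum_{d \ge 2} c_d L_d$. Because every $L_d$ is symmetric
positive semidefinite with zero row sums, $M$ conserves the mean of $u$ and
drives every node towards the consensus value $\bar u_0 = \mathrm{mean}(u_0)$.
`evolve()` computes this through the eigendecomposition of $M$ — the study
scale is $n = 31$ nodes, so dense linear algebra is the right tool and no
Krylov or sparse machinery is used.

An experiment is discrete: $r$ rounds are mapped onto $[0, T]$ by
$t_i = (i-1)\,T/(r-1)$ (`discretize_rounds()`), so round 1 reproduces the
initial condition exactly. Choices are binary, so propensities are
thresholded: node $i$ counts as an **adopter** at round $k$ if
$u_i(t_j) > \Delta\,\bar u_0$ for some $j \le k$ — once an adopter, always an
adopter, matching how experimental adopter curves are counted cumulatively.

### The threshold convention

Two readings of the threshold are possible: compare $u_i$ against
$\Delta \cdot \bar u_0$ (a fraction of the consensus value) or against
$\Delta$ itself. With a binary start of 4 adopters among 31 nodes,
$\bar u_0 \approx 0.129$, and the literal comparison $u_i > \Delta$ with
$\Delta \ge 0.4$ can never classify a late adopter: every propensity relaxes
towards $0.129$. The normalised form makes the threshold grid
$\Delta \in \{0.4, \dots, 0.99\}$ meaningful at any adopter fraction, so it
is the default; `normalize = FALSE` in `adopter_curve()` and `grid_search()`
exposes the literal variant for sensitivity analysis.

### Decay laws

Three closed-form laws describe how influence decays with distance:
$c_d = (4-d)/3$, $c_d = (5-d)/4$, and $c_d = 2/(1+d)$. The first takes the
values $2/3$ and $1/3$ at $d = 2, 3$ — second and third circles exerting
two-thirds and one-third of the direct pressure. Linear laws go negative at
large $d$ (e.g. $(4-d)/3 < 0$ for $d \ge 5$); since a negative influence
strength has no behavioural interpretation and can destroy positive
semidefiniteness of $M$, `decay_law()` clamps at zero by default and offers
`clamp = FALSE` for sensitivity analysis.

```{r decay}
decay_law("linear_3", 1:5)
```

## Estimation by grid search

For one session and one informational setting, the observed curve is the
per-round fraction of cumulative adopters. The model counterpart uses a
single free coefficient — $c_2$ in setting II, $c_3$ in III, $c_4$ in IV,
none in setting I — and the free threshold $\Delta$ and horizon $T$:

* $c$ over $[0, 1]$ in steps of $0.01$,
* $T$ over $10$–$1000$ in steps of $10$,
* $\Delta \in \{0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.99\}$.

`grid_search()` evaluates all $101 \times 100 \times 7$ combinations
exhaustively (one eigendecomposition per $c$ serves every $(T, \Delta)$
cell) and returns the mean-squared-error minimiser, with the Pearson
correlation at the optimum reported alongside. MSE ties are resolved to the
smallest $(c, T, \Delta)$ lexicographically — the most parsimonious model —
and a message is logged whenever a tie occurs. Step-shaped curves that jump
to consensus in one round are reproduced exactly by many parameter
combinations; the tie rule keeps the result deterministic, and the fitted
*curve* (not the triplet) is the meaningful recovery target in that regime.
Sessions that reached consensus early are padded at the consensus value to
the setting length before fitting (`pad_to`), mirroring the flat tails of
observed curves; truncation is available by leaving `pad_to = NULL`.

A joint multi-coefficient variant (`grid_search_joint()`) fits several
$c_d$ simultaneously on user-supplied coarse grids.

## What the session generator emulates — and what it does not

`simulate_session()` reproduces the protocol of the experiment: 31 seats on
a fixed friendship-like network, four informational settings with fresh
colour pairs, 13–15 rounds each, initialisation with 4 innovation seats
(13%), two displayed direct neighbours everywhere plus two displayed
distance-$k$ peers in settings II–IV, bots replacing inactive seats (50%
random colour, 50% displayed majority, ties uniform), payoffs of 1 point per
active round plus 5 points per round saved before round 15 when consensus is
reached, and optional stubborn agents who never leave their colour.

Displayed peers are sampled once per setting and held fixed across rounds,
with colours refreshed each round; whether the real experiment redrew the
sample every round is ambiguous, so `resample_displays = TRUE` exposes the
alternative. Initial adopters are placed uniformly at random, the placement
used in the sessions being unknown.

The human choice rule is this package's construction (the experiment
measured choices, it did not model them): a seat that has not yet adopted
does so with probability
$\sigma(\alpha f_{\text{direct}} + \beta f_{\text{distant}} + \gamma a - \theta)$,
where $f$ are the innovation fractions among the displayed direct/distant
peers, $a$ is the seat's adopter status and $\sigma$ the logistic function.
The defaults ($\alpha = 2.5$, $\beta = 1.5$, $\gamma = 2$, $\theta = 1.8$)
were calibrated once so that generated sessions behave like the experimental
ones — S-shaped curves reaching consensus in roughly 3–8 rounds, essentially
all stubborn-free sessions consensual within 15 rounds — and so that fitted
$c_2$ exceeds fitted $c_3$ on generated data. They are study conditions, not
tuning knobs.

At the pipeline level (`pipeline_config()`), each session-setting plants a
Poisson($\lambda = 0.4$)-distributed number of stubborn agents (capped at 2):
the experimental sessions contained roughly 35 stubborn individuals over
$21 \times 4$ session-settings, and with this rate about a third of sessions
fail to reach full consensus, as observed. Set `stubborn_lambda = 0` for
fully compliant populations.

What the generator does **not** emulate: reaction times, payment conversion,
demographics, visual-salience biases of the colour display, and any
systematic heterogeneity between human participants beyond the
stubborn/bot/human trichotomy. Passing tests on generated data therefore
demonstrate that the estimation machinery recovers known signals under the
stated protocol — not that human sessions obey the logistic rule.

## Synthetic networks

The experimental friendship network is not bundled. `read_pajek()` ingests
any Pajek file (the original is distributed in that format), and
`apply_study_modification()` applies the documented one-edge adjustment
(remove \{10,30\}, add \{2,17\}) separately, so any variant of the source
network can be used without hard-coding an unverifiable adjacency.
For testing, `generate_constrained_network()` builds random connected graphs
in which every node has at least two nodes at distance one and two at
distance four (the property the experimental network was adjusted to
satisfy), from a random cycle backbone plus random chords, resampling until
the constraints hold. `study_like_network()` additionally requires diameter
exactly 5 (the study network's), at least two peers in *every* circle up to
distance 4 (so all four settings can display two peers), and the
modification preconditions — before and after modification. A copy of one
such graph ships as `inst/extdata/study_network_synthetic.net`; the
`_synthetic` suffix is deliberate: it is a stand-in with the stated
properties, not the real friendship network.

## Statistical analysis choices

* **Mean differences.** The test family behind the reported p-values is not
  fixed by the analysis design; `mean_difference_test()` defaults to Welch's
  unequal-variance two-sided t-test (a robust default given visibly unequal
  coefficient spreads) with a permutation test as an option. No
  multiple-testing correction is applied to the three pairwise p-values —
  they are reported raw.
* **Outliers.** Three detectors over per-session fitted coefficients:
  z-score with cutoff 2 (at $n = 21$ sessions a cutoff of 3 can flag almost
  nothing, since the maximum attainable $|z|$ is $(n-1)/\sqrt n \approx 4.4$
  and typical deviants sit well below it), Tukey fences at $1.5 \cdot IQR$,
  and the leave-one-out mean-shift score $s_i = |\bar x - \bar x_{-i}|$
  flagged above $3 \cdot \mathrm{median}(s)$ (the score has no canonical
  cutoff; the multiplier is configurable).
* **Stubborn participants.** If the modal colour of the final round covers
  at least 80% of seats, any participant off that colour in *both* of the
  last two rounds is flagged; with no near-consensus there is no consensus
  to defect from and nobody is flagged. Bot seats are excluded by default.
* **Decision classification.** One row per human decision from round 2
  (round-1 colours are assignments, not choices), with four features:
  innovation as initial colour, innovation as displayed majority (ties count
  as no majority), displayed direct innovation fraction, displayed
  distance-$k$ innovation fraction (constant 0 in setting I). Outputs are
  always labelled by feature *name*, never by index. Random forests are fit
  per setting; importance is the unscaled out-of-bag permutation importance
  (mean increase in OOB error when the feature is permuted), and accuracy
  comes from nested cross-validation (5-fold outer for test error, 5-fold
  inner over a small grid of tree counts and depth limits). Bot decisions
  are excluded by default since their policy is known.

## Numerical choices and degenerate inputs

* Mean conservation of `evolve()` holds to $10^{-10}$ and is tested; the
  threshold comparison is strict (`>`), so at $t = 0$ exactly the initial
  adopters are counted for any $\Delta \in (0, 1]$.
* Constant observed curves have undefined Pearson correlation: the fit is
  still returned by MSE with `pearson = NA` and a warning.
* All-adopter or no-adopter initial states are rejected — there is no
  dynamics to threshold.
* Every stochastic function takes a `seed` and restores the caller's RNG
  state; a master seed expands into per-stage sub-seeds
  (`run_pipeline()`), making full artifact sets byte-reproducible.

## Problem sizes used in the test suite

The packaged tests run the complete machinery at the study's own scale
(31 nodes, 13–15 rounds, the full $101 \times 100 \times 7$ grid): 30
parameter-recovery refits, a 50-vs-50-seed simulation study of the fitted
$c_2$ response, a 3-level monotonicity check of $c_2$ in the generator's
distant-influence weight (30 seeds per level), 200 initial conditions for
the decay-law comparison, 2000 null replicates for the Welch test's type-I
calibration, and 20-seed planted-signal recovery for the feature
importances. These sizes give stable orderings for the stochastic checks
while keeping a full run at desk scale.

## Known limitations

* The diffusion model has no stubborn agents: every node is predisposed to
  consensus. Fits to sessions containing stubborn participants are
  systematically better in early rounds than late ones, which is precisely
  why the outlier analysis is part of the pipeline.
* Fitted $c_d$ from generated sessions are attenuated relative to the
  generating responsiveness (the simulator couples each seat to two
  displayed peers, the model to the whole circle), so recovery is assessed
  as ordering/monotonicity, not as equality of parameters.
* Weighted or directed diffusion is out of scope; the indirect channel is
  parameterised entirely by the $c_d$ coefficients.

## A small worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(n_sessions = 21, seed = 1, pad_to = 15)
res <- run_pipeline(cfg, out_dir = "innodiff-artifacts")
res$coefficients
res$p_values
plot_adoption_curves(observed_curve(res$records, pad_to = 15))
plot_importance(res$importance)
```

The same end-to-end computation, reduced to its headline numbers, is what
`scripts/acceptance.R` writes as JSON.
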