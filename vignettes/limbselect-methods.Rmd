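---
title: "Modeling perseverative limb selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling perseverative limb selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbselect)
```

## The model

`limbselect` treats the choice of hand for a unimanual grasp as a
winner-take-all competition between two activation sites, one per
limb. Site activations $u_P$ (preferred hand) and $u_{NP}$
(nonpreferred hand) evolve as

$$\tau\,\dot u_P = -u_P + h - c_P\,\sigma(u_{NP}) + I_P + n\,\xi_P(t),$$
$$\tau\,\dot u_{NP} = -u_{NP} + h - c_{NP}\,\sigma(u_P) + I_{NP} + n\,\xi_{NP}(t),$$

with logistic gating $\sigma(u) = 1/(1+e^{-\beta u})$ and independent
unit-variance white noise per site. Three ingredients produce the
behavioral phenomena:

* **Handedness as dynamical asymmetry.** The cross-inhibition is
  asymmetric, $c_P < c_{NP}$: the active preferred site suppresses its
  competitor more strongly than the reverse. Under symmetric input the
  preferred site therefore wins more often, and the size of the
  asymmetry plays the role of handedness *strength*.
* **Motor memory as accumulating input.** Each selection adds 1.2
  input units to the chosen limb's site for all subsequent trials of
  the condition ($I = $ sensory $+$ memory). This is the
  intermediate-timescale trace that carries a training bias into
  later trials; it is reset to zero before and between conditions.
* **Noise as selection variability.** The noise amplitude $n$ sets
  how reliably input differences translate into selections; it is the
  model's account of the high trial-to-trial variability of younger
  children.

The age presets (`age_preset()`) implement a developmental
progression: `14mo` $c_P{=}0.5, c_{NP}{=}3.5, n{=}3.3$; `24mo`
$2.0, 5.0, 2.0$; `36mo` $3.0, 7.0, 1.7$, with $\tau{=}3$, $h{=}-2$,
$\beta{=}2$ shared. Activations and inputs are dimensionless; $\tau$
and the Euler step share one model time unit.

## The simulated experiment

A condition is six object presentations (`build_condition()`): four
lateral *training* trials (T1–T4) followed by two midline *neutral*
trials (N1, N2). Lateral presentations drive the cued site with 6.0
and the other with 1.0; neutral presentations drive both with 6.0.
The *control* condition trains the preferred hand, the *test*
condition the nonpreferred hand. `run_participant()` runs both
conditions with the memory trace carried within and reset between
them; `run_cohort()` runs many independent participants;
`filter_perfect_training()` implements the subgroup restriction to
participants whose test-condition training fully took (all four
selections nonpreferred), and `reproduce_table2()` assembles the
standard summary of preferred-hand proportions in T3, T4, N1, N2.

```{r noise-free}
# the deterministic limit: training takes, memory perseveres
r <- run_participant(age_preset("24mo", noise_strength = 0))
subset(r$trials, condition == "test")[, c("label", "m_p", "m_np", "selected")]
```

## Numerical scheme and the noise dialect

Trials are integrated by stochastic Euler from the resting state
$u_P = u_{NP} = h$ (trials are separated by inter-trial intervals, so
activation has decayed back to rest). Two discretizations of the
noise term are provided (`noise_dialect` in `model_params()`):

* `"per-step"` (default): the printed noise term is treated literally
  as part of the rate, $u \leftarrow u + \frac{dt}{\tau}(\text{drift}
  + n\,\xi)$, $\xi \sim N(0,1)$ per site per step;
* `"sqrt-dt"`: the Euler–Maruyama form, $u \leftarrow u +
  \frac{dt}{\tau}\,\text{drift} + \frac{n}{\tau}\sqrt{dt}\,\xi$.

The dialect and the step size jointly determine the *effective*
stationary noise of the selection process (roughly
$n\sqrt{dt/2\tau}$ for small steps under `per-step`), and neither is
pinned down by the model's published description — the equations are
continuous-time, but $\tau = 3$ is never reconciled with a concrete
step length. `model_params()` defaults to `dt = 0.05` (so
$dt/\tau \approx 0.017$, a faithful ODE discretization that relaxes
well within a 400-step trial and is used by the accuracy and
fixed-point tests). For *cohort* simulations this fine step makes the
dynamics effectively deterministic: every selection follows the mean
field and the interesting stochastic regime disappears.
`calibrate_table2()` therefore sweeps `{noise_dialect, dt}` against
the reference summary table of the filtered 14-month cohort; the
sweep selects `per-step` with `dt = 4` (stable, oscillatory Euler,
$dt/\tau = 4/3$), which reproduces all four control-condition cells
to within $\pm 0.05$ at 500 participants. `age_preset()` carries
these calibrated integration settings by default and every preset
still relaxes to a fixed point within a noise-free trial.

```{r calibration, eval = FALSE}
# the documented sweep (a few seconds per configuration)
calibrate_table2(dialects = c("per-step", "sqrt-dt"),
                 dts = c(0.05, 1, 2, 3, 4, 5), n_participants = 500)
```

Selection is read out as the argmax of the final-step activations,
with an exact tie broken by a fair coin and flagged
(`select_limb()`); no selection threshold is published, and the
argmax is the simplest rule consistent with activations encoding
selection likelihood. Non-finite activations abort integration with
an error naming the step.

## What the test-condition neutral trials can and cannot reproduce

The reference summary row for the filtered 14-month cohort reports
preferred-hand proportions of 0.54 (N1) and 0.65 (N2) in the test
condition. Under the equations above these values are structurally
unreachable, for any noise dialect, step size or noise level: the
filtered subgroup enters N1 with a memory advantage of
$4 \times 1.2 = 4.8$ on the nonpreferred site, while the maximum
inhibition asymmetry the gating can deliver is
$c_{NP} - c_P = 3.0$ ($\sigma \in (0,1)$). Every fixed point of the
neutral-trial dynamics therefore has $u_{NP}^* > u_P^*$, and any
final-state readout selects the preferred hand with probability below
one half — Monte-Carlo sweeps plateau near 0.33–0.46, and
configurations that push the test cells higher destroy the control
row first. The package reproduces the control condition
quantitatively and the test-condition *training* cells exactly, and
reports the test-condition neutral cells as the model actually
produces them.

The discrepancy is informative. If the memory trace *decays* between
trials, $m \leftarrow \lambda m + 1.2$ on the selected site
(`memory_decay` in `run_cohort()` and `reproduce_table2()`), the
memory advantage saturates near $1.2/(1-\lambda)$ instead of growing
linearly. With $\lambda = 0.5$ the advantage (2.4) drops below the
inhibition asymmetry, and the whole reference pattern re-emerges: the
test N1 cell rises above 0.4, N2 exceeds N1 (selections of the
preferred hand at N1 re-bias memory toward it), and the control row
stays high — the package's tests verify exactly this contrast. A
plausible reading is that the original implementation's memory trace
leaked, a detail its published description omits. The default remains
the non-decaying trace, which is what the published description
states; the leaky variant is a documented sensitivity analysis, not
the reference protocol.

The same structure explains a second systematic difference: with
non-decaying memory, the control-minus-test difference in
preferred-hand use *grows* from N1 to N2 (reinforcement pushes the
conditions apart when the test N1 proportion is below one half),
whereas the reference pattern has the effect fading by N2. The fading
also re-emerges under the leaky trace.

## Randomness and reproducibility

A cohort seed determines everything. Participant $i$ receives a
substream seed drawn once from the cohort seed
(`sample.int(2^31-2, n)`), so cohorts are prefix-stable in $n$ and a
scalar `run_participant()` started from the same substream seed
reproduces that cohort member selection-for-selection. Each
participant consumes its stream trial by trial (preferred-site noise
block, then nonpreferred-site block), which is what makes the
vectorized cohort engine and the scalar path interchangeable.
Identical seeds yield byte-identical exported CSVs; every exported
artifact embeds the resolved configuration as a JSON provenance
header.

## Statistics layer

The behavioral operations mirror how such experiments are scored:

* `classify_handedness()`: strict majority over neutral-presentation
  selections; bimanual grasps count toward neither hand; ties are
  `undetermined`.
* `to_preferred_frame()`: maps left/right records through each
  participant's handedness so left- and right-handers can be pooled.
* `chi_squared()`: Pearson statistic (optional Yates correction;
  goodness-of-fit against uniform for single rows), via
  `stats::chisq.test()`.
* `mcnemar_test()`: exact binomial form by default — appropriate at
  the subgroup sample sizes (tens of children) where the chi-squared
  approximation is unreliable; no discordant pairs gives $p = 1$ by
  convention.
* `generate_fixture_cohort()`: independent Bernoulli hand choices
  with configurable per-trial probabilities, so the statistics layer
  is testable without study data. This generator deliberately lacks
  the sequential dependence the dynamical model produces (memory
  makes real and simulated selections autocorrelated across trials);
  conclusions about test *power* drawn from it transfer to real data
  only insofar as the per-trial margins match.

## Problem sizes and numerical choices

The packaged tests run cohorts of 500 (summary-table checks) and
2000 participants (age-trend and perseveration-signature checks,
where confidence intervals must separate); 400 Euler steps per trial
throughout. Integration accuracy is property-tested (halving the
step at least halves the endpoint error against a fine-step
reference); exact ties are resolved by a fair coin and flagged;
degenerate inputs (empty filtered subgroups, zero-marginal tables,
no discordant pairs) return explicit markers or conventions rather
than errors where a downstream analysis can proceed.

## Limitations

* Two sites only: bimanual grasps and more-than-two-effector
  competition are out of scope; `both` records are handled by the
  statistics layer but never produced by the simulator.
* The model makes no attempt to capture reaction times or the
  within-trial time course of real reaches; only the end-state
  selection is read out.
* Parameters are fixed per age group; there is no fitting machinery
  for estimating $c$ or $n$ from new behavioral records.
* The published parameterization reproduces the control condition
  and the training columns; the test-condition neutral proportions
  are reproduced only under the leaky-memory sensitivity variant, as
  discussed above.
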