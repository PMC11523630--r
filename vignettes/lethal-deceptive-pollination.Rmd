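---
title: "Modelling lethal deceptive pollination: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lethal deceptive pollination: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arisaemasim)
```

## The system and its assumptions

The package models a deceptive trap-flower plant (an *Arisaema*-type
sequential hermaphrodite) and its specialist pollinator, a fungus gnat
of which only males are attracted. The biological assumptions baked
into the equations are:

* One plant individual is one inflorescence ("flower scale").
* The plant has three stages: juvenile `X_J`, adult male `X_M`, adult
  female `X_F`. Juveniles mature to male (`g_JM`, a *net* rate that
  absorbs occasional regression of males back to the juvenile stage),
  males change sex to female (`g_MF`), and females revert to male after
  successful reproduction, so the reversal flux is proportional to
  pollination success (`g_FM * Phi_X`).
* Juveniles are produced vegetatively by both adult sexes
  (`r_VM`, `r_VF`) and sexually by pollinated females (`r_P * Phi_X`).
  Juveniles themselves produce nothing. Recruitment is limited by open
  space: all juvenile production is multiplied by
  `1 - (X_J + X_M + X_F) / K_X`.
* Male gnats choose visit targets among male plants, female plants and
  female gnats in proportion to attractiveness-weighted abundance; a
  female-plant visit is fatal (no exit hole). A male makes at most `N`
  visits in its lifetime.
* Insect recruitment comes from mated females at rate `f`, sex ratio
  `s : (1 - s)` at birth, limited by brood-site capacity `K_Y`. Male
  gnats carry the extra mortality `q * P`, where `P` is the lifetime
  probability of being trapped and `q` converts it to a per-unit-time
  rate.
* Pollination and mating success saturate (Holling type II) with
  half-saturation constants `A_X` and `A_Y`.

Time is dimensionless throughout; the protocol horizon `t = 50000` is a
convergence convention, not calendar time.

## Lifetime visit statistics

Conditional on the per-visit probabilities `(p_M, p_F, p_Y)`, the three
lifetime expectations are defined by sums over visit-sequence
compositions and are implemented twice on purpose:

* `visit_stats_combinatorial()` evaluates the double sums literally,
  with binomial coefficients computed exactly before any floating
  multiplication (`choose()` is exact for the `N <= 20` range used
  here, which avoids cancellation).
* `visit_stats_closed_form()` uses the binomial-theorem simplification
  (with `x = 1 - p_F` and `S = sum_{j=1}^{N-1} j x^(j-1)`):
  `Q1 = p_F p_M S`, `Q2 = p_F p_Y S + N p_Y x^(N-1)`,
  `P = 1 - x^N`. This is the form the ODE right-hand side calls.

The printed series for the trap probability, taken at face value, has a
`(1 - p_F)^(k-1)` term starting at `k = 0`, which is singular. We read
it as the standard geometric sum `P = sum_{k=0}^{N-1} p_F (1-p_F)^k =
1 - (1-p_F)^N`, the probability that at least one of `N` visits hits a
female plant — consistent with its stated meaning and confirmed by the
Monte Carlo oracle. The second `Q2` sum runs over `k = 0..N` (all `N`
visits, no female plant hit) exactly as printed.

Three degenerate-input conventions:

* **Empty world.** If `a_M X_M + a_F X_F + Y_F = 0` there is nothing to
  visit; `(p_M, p_F, p_Y) = (0, 0, 0)` and `Q1 = Q2 = P = 0`, avoiding
  0/0.
* **Success fractions.** `Phi = v / (A + v)` with `v = Y_M Q` is set to
  0 whenever `v = 0`, including the doubly degenerate `A = 0` case.
* **`N` is a strict integer**; fractional values are rejected rather
  than rounded.

### The Monte Carlo oracle

`simulate_visit_sequences()` is an individual-based re-implementation
used only for validation: each trial draws up to `N` categorical visit
events. In lethal mode the sequence truncates at the first female-plant
visit. In the optional non-lethal mode (trap flowers that release their
visitors) all `N` visits happen; we count male-plant visits before the
first female-plant visit as the pollen-carrying ones — i.e. death is
removed but pollen is still delivered once, at the first female-plant
visit — and all female-insect visits as copulations. If a sequence
contains no female-plant visit its `Q1` contribution is zero (no
pollination occurred). That accounting is a package convention for the
non-lethal variant; alternative conventions (pollen replenished at
every male-plant visit) would raise `Q1` but change nothing in the
lethal model, which is the one the dynamics use.

The oracle seeds a local RNG and restores the caller's `.Random.seed`,
so estimates are bit-reproducible and side-effect free. The trap
indicator is exactly Bernoulli, so where a z-test against the analytic
`P` is wanted at extreme probabilities the exact standard error
`sqrt(P (1 - P) / n)` should replace the degenerate sample estimate.

## Static compositions for the behaviour curves

The behaviour-response curves (`behaviour_response()`) evaluate
`(Q1, Q2, P)` over a frozen community rather than a dynamic one. Female
gnats sit at `Y_F = K_Y / 2`. Total *adult* plant abundance is fixed at
`K_X / 2` and split by the plant male ratio; juveniles are excluded
because they are not visit targets. The plant total is not dictated by
the protocol anywhere, so we chose the value symmetric with the insect
convention; the qualitative shapes (monotone responses to
attractiveness; unimodal `Q1` against the male ratio, peaking near
0.67 at attractiveness 0.4 and `N = 10`) are insensitive to this
choice over at least `[K_X/4, K_X]`, which the test suite probes. The
argmax of `Q1` over a grid is reported with a smallest-value tie-break
on a 0.01 grid step.

## Numerical integration

* **Solver.** `deSolve::ode()` with `lsoda` (stiff-capable, adaptive),
  `rtol = 1e-8`, `atol = 1e-10`. Halving the tolerances changes the
  window-averaged abundances of the default run by less than 1e-4
  relative (a test asserts this self-convergence).
* **Non-negativity.** The right-hand side clips its state argument at
  zero so adaptive steps cannot probe negative abundances; saved output
  is clipped too (clips are bounded by `atol`).
* **Extinction clamping.** The protocol's threshold 0.001 is applied
  *during* integration: a root function watches total plant and total
  insect abundance, and an event zeroes the group that touches the
  threshold, recording the time. Once zeroed a group stays at zero (all
  its source terms are proportional to its own abundance). This
  prevents biologically meaningless rebounds from abundances of order
  1e-10 and makes the alternative-stable-state structure reproducible.
  Classification re-applies the same threshold to the window means, so
  a population that merely grazes the threshold late in the run is
  still classified consistently.
* **Window averaging.** Steady-state summaries are trapezoid
  time-averages over the final fraction (default 10%) of the run, with
  linearly interpolated window endpoints. Output is saved on a uniform
  grid of 2001 points by default — dense enough that quadrature error
  is negligible against the solver tolerances for these smooth,
  equilibrium-approaching trajectories.
* **Sex ratios** are ratios of window means (not means of ratios):
  stable when one sex is nearly absent, and consistent with reporting
  long-term average abundances. When both sexes' means are below 1e-12
  the ratio is reported as `NA`, never 0/0.

## Scenarios, sweeps and problem sizes

The two presets mirror the empirical dichotomy among the four field
species: `"first"` (no cormlets, slow sex change:
`r_VM = r_VF = 0`, `g_MF = 0.005`) and `"second"` (cormlets present,
faster sex change: `r_VM = r_VF = 0.02`, `g_MF = 0.01`). The remaining
defaults are the calibrated table values (`r_P = 1`, `K_X = K_Y = 15`,
`g_JM = 0.05`, `g_FM = 0.01`, `d_J = 0.015`, `d_M = d_F = 0.01`,
`s = 0.5`, `f = 2`, `d_Y = 0.1`, `A_X = 1`, `A_Y = 10`, `q = 0.5`,
`N = 10`); the package default for the "varied" parameters is the
second preset with `a_M = a_F = 0.4`.

Sweep axes accept the linked names `r_V` and `a`, which always set both
members of the pair — sweeps never explore asymmetric vegetative rates
or attractiveness, matching how the scenarios are defined. Published
figure axes do not state their grid resolution; we default to 21 x 21
for maps (a config knob) and run the test-suite maps at 9 x 9 over
`g_MF, r_V` in `[0, 0.05]`, which resolves every regime the full-size
maps show while keeping a map under 20 s on one core. When a map spans
`r_V` against `g_MF` the analytic persistence boundary `r*` is attached;
note that with `d_M = d_F` the boundary is flat in `g_MF`
(`r* = 0.013` at the defaults), because faster sex change trades male
cormlet production for female cormlet production at equal lifetime
rates.

## What the simulator does and does not emulate

The model is deterministic ODE dynamics: it captures mean-field
coexistence structure, alternative stable states, and sex-ratio biases,
but has no demographic stochasticity, no environmental fluctuation, no
individual variation, no spatial structure and no evolution of
attractiveness or avoidance behaviour. Tests passing on this model
therefore say nothing about extinction risk from small-population
noise, or about rescue via recolonisation — both flagged as open
questions for the real system. The extinction threshold is the proxy
for demographic stochasticity at low abundance.

## Known limitations and honest discrepancies

* At an interior equilibrium the female-plant balance forces
  `X_M / X_F = (g_FM Phi_X + d_F) / g_MF`. With the default
  `g_FM = d_F = 0.01` and the second preset's `g_MF = 0.01` this ratio
  cannot exceed 2 (since `Phi_X <= 1`), so the plant male ratio is
  capped at 2/3 in that scenario; the protocol run at attractiveness
  0.4 computes ~0.606 (see `scripts/acceptance.R` output). A
  calibration target of 0.70 +/- 0.05 for this scenario is therefore
  analytically unreachable; the first preset, whose slower sex change
  relaxes the cap, reaches ~0.77 where it coexists.
* `lsoda`'s root finding locates threshold crossings to solver
  precision, but a trajectory that approaches the threshold
  tangentially without crossing is not clamped; classification at the
  window means catches these.
* The non-lethal oracle mode encodes one defensible visit-accounting
  convention (documented above), not a claim about any particular
  published variant.
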