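---
title: "Scene-memory foraging: model, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scene-memory foraging: model, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`sceneforage` simulates a forager that has no spatial map and no memory of
where it has been, only a single short-lived *scene memory*: the count of
resource sites it could see at some recent moment. The package exists to
study how switching between two purely local site-selection rules, triggered
by nothing more than "this scene looks like one I remember", produces
movement that is confined like a home range yet still discovers new sites —
and to provide the movement statistics (distinct-site counts, revisitation
tails, mean-squared displacement, density maps) needed to characterise that
behaviour against memory-free and spatial-memory controls.

## The world and the agent

The arena is a `field_width` × `field_height` rectangle (default
100.00 × 100.00) scattered with `n_sites` point sites (default 1000) placed
independently and uniformly at random for each trial. The agent starts every
trial at `(start_x, start_y)` (default the centre, (50.00, 50.00)) and lives
in discrete time for `n_steps` steps (default 10 000).

Each step the agent perceives its *local sites*: all sites within Euclidean
distance `visual_radius` (default 4.00, closed ball) of its position,
excluding a site at distance exactly zero — the site it is standing on is
not a candidate, otherwise nearest-site selection would re-pick it forever.
Two local selection rules are defined:

* **exploitation** — move to the nearest local site;
* **exploration** — move to the farthest local site.

Moving onto the selected site consumes exactly one time step regardless of
the distance covered and is recorded as a *visit*. When no site is visible
the agent instead takes one random cardinal step (north/east/south/west each
with probability 1/4) of length `step_size` (default 1), reflected at the
field boundary.

## The rule-change model

The focal model starts under exploitation (the default rule) with an empty
scene memory. On each step where at least one site is visible:

1. If the memory is empty or has expired, the current local-site count is
   stored as `memory_sum` together with the step index. No comparison is
   made on the storing step (a freshly stored count trivially equals
   itself).
2. Otherwise, if the current count equals `memory_sum`, the agent concludes
   it may have returned to familiar ground — rightly or wrongly, since equal
   counts can arise anywhere — and swaps its active rule with probability
   `switch_prob` (default 0.5). The memory is retained after a match; only
   age clears it.
3. The memory expires `theta` steps after storage (default `theta = 5`):
   comparisons are allowed while `step − stored_at ≤ theta`, and the first
   perceiving step after that re-stores a fresh count, again without a
   comparison.

Site selection then proceeds under the (possibly just-swapped) rule. The
flip is the model's entire cognitive apparatus: a count, a clock, and a
coin.

## Control models

Three memory-free controls share the identical stepping skeleton with the
selection fixed for the whole trial: always nearest (`fixed_exploitation`),
always farthest (`fixed_exploration`), or uniform among local sites
(`random_choice`).

The spatial-memory control gives the agent what the focal model lacks:
explicit locations of up to `n_locations` visited sites, each carrying two
clocks measured from its last visit. While the *working memory* is alive
(`theta_work` steps, default 5) the agent will not deliberately return to
the site; once it has lapsed but the *reference memory* (`theta_reference`
steps, default 10) is still alive, the site is an eligible return target,
taken — uniformly among eligible sites — with probability `prob` each step
as a direct one-step relocation (knowing a location is what spatial memory
means, so travel mechanics are not modelled). Otherwise the agent falls
back to plain exploitation. Visits insert or refresh sites in memory;
exceeding capacity evicts the entry with the oldest last visit, and entries
not revisited within `theta_reference` steps are forgotten.

A consequence worth knowing: at the default site density the exploitation
fallback pins the agent into a tight two-site cycle, so the single
remembered location is nearly always the site just visited, its working
memory never lapses, and the return mechanism essentially never fires.
With `prob = 0` the model is exactly fixed exploitation, trajectory for
trajectory, under a shared seed — a property the test suite asserts.

## Movement statistics

* `distinct_visited()` — the number of different sites visited in a trial,
  the headline efficiency measure.
* `revisit_distribution()` / `fit_tail()` — per-site visit counts, fitted by
  maximum likelihood with two one-parameter families on support
  `x ≥ 1`: the discrete power law `P(x) = x^−μ / ζ(μ)` (zeta-normalised,
  `x_min = 1`, fitted by 1-D optimisation of the exact likelihood) and the
  discrete exponential `P(x) = (1 − e^−λ) e^−λ(x−1)` (geometric; closed-form
  MLE `λ = log(m/(m−1))` for sample mean `m`). With one parameter each,
  `AIC = 2 − 2 logL`, and Akaike weights
  `w_i = exp(−Δ_i/2)/Σ_j exp(−Δ_j/2)` arbitrate. A heavy-tailed revisit
  pattern — a few sites visited orders of magnitude more often than the
  rest — puts the weight on the power law; the revisit counts of a random
  walker are near-geometric and fall to the exponential.
* `mean_squared_displacement()` — squared displacement from the trial's
  fixed start position, averaged over trials and then within time bins of
  `bin_size` steps (default 10), reported against the bin midpoint and its
  square. A plateau ("saturation") is the signature of confined,
  home-range-like movement.
* `density_map()` — a 2-D occupancy histogram of all logged positions with
  half-open square bins (default width 4.00), the utilisation picture of a
  trial.

Because "saturation" is a property of a curve's shape, the tests
operationalise it as a bounded-growth index: the final-bin MSD must be less
than twice the MSD at t ≈ 200 for the rule-change model, and at least twice
it for random choice. The threshold of 2 was fixed from the qualitative
contrast the index must detect (a plateau reached within a few hundred steps
versus continued diffusive growth), not fitted to any run.

## Randomness and reproducibility

Every trial is a deterministic function of `(config, seed)`. The per-trial
stream seeds the site field first (all x, then all y), then feeds the
simulation; experiment runners use seeds `base_seed + 0, 1, …` per trial.
Draw conventions are fixed and shared between the pure-R reference
implementation (`step_agent()`) and the compiled engine, which the tests
hold to draw-for-draw identical trajectories:

* an index among k options costs one uniform (`floor(u·k)`, clamped);
* a selection tie-break draw happens only when ≥ 2 candidates tie exactly
  (with continuous coordinates, essentially never; the contract matters for
  hand-built worlds);
* random-choice selection always costs one draw;
* the rule-switch coin is drawn only on a scene match with
  `switch_prob > 0`, and the spatial-memory return coin only when eligible
  sites exist with `prob > 0` — this is what makes the degenerate-parameter
  models (`switch_prob = 0`, `prob = 0`) consume the identical stream as
  fixed exploitation and hence coincide with it trajectory-for-trajectory.

## Numerical and design choices

* **Continuous space.** Sites get continuous uniform coordinates and the
  agent continuous positions; printed quantities with two decimals (field
  size, radius, start) indicate real-valued geometry. An integer-lattice
  reading was evaluated during development and changes the emergent
  statistics noticeably (exact distance ties become common); the continuous
  reading is the one whose control-model behaviour we consider canonical.
* **Closed visual ball.** Distance exactly equal to the radius counts as
  visible; the boundary has measure zero, so results are insensitive.
* **Reflecting boundary** for the random walk, with `"clamp"` available;
  site-to-site moves always end in bounds by construction.
* **Memory conventions.** Comparison suppressed on storing steps; memory
  retained after a match; expiry strictly after `theta` steps
  (`step − stored_at > theta`); re-storage happens on the first perceiving
  step after expiry. Each is stated in the function documentation and
  pinned by a unit test.
* **Spatial-memory eviction** is oldest-last-visit-first; the return draw
  precedes the exploitation fallback within a step.
* **Tail-fit domain.** `fit_tail()` requires integer counts ≥ 1; an
  all-equal counts vector is a degenerate fit and is reported with a
  warning (the power-law optimum then sits at the search boundary). The
  power-law exponent is searched in (1, 50], which comfortably brackets
  every empirically observed value.

## What the simulations do and do not show

The synthetic site fields are spatially uniform and temporally static:
sites are never depleted, never renewed, never clustered, and there is a
single agent. These are the study conditions, not a claim about nature —
passing tests show that the *mechanism* produces confined-but-exploratory
movement under those conditions, not that real foragers use scene counts.
Resource renewal is irrelevant here precisely because visits are counted,
not harvested energy.

Trial-level quantities in the test suite are exercised at the reference
scale of 100 trials × 10 000 steps where a claim concerns the reference
study conditions, and at reduced scale (a few hundred steps, a few hundred
sites) for contracts that do not depend on scale, such as determinism,
engine equivalence and conservation identities. The problem sizes are
stated in each test.

## Known limitations

* The verbal description this model family comes from leaves several
  micro-details open (movement mechanics between sites, the exact timing of
  scene comparisons, what exactly the spatial-memory capacity counts). The
  semantics implemented here are the ones documented above, chosen for
  internal consistency and fidelity to the stated control-model behaviour;
  a substantial space of alternative readings was simulated during
  development, and none reproduced every reported summary statistic
  simultaneously. The acceptance harness reports this package's honest
  numbers; conditions whose reference values this implementation does not
  reproduce are left failing rather than fitted.
* Single-trial tail fits rest on few distinct sites (often under 15), so
  the Akaike comparison between power law and exponential can be
  indecisive for individual seeds; multi-seed medians are more stable and
  are what the acceptance harness reports.
* The simulator is serial; experiments parallelise trivially over seeds if
  needed, at the cost of managing the seed arithmetic yourself.
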