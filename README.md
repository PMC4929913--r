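# sceneforage

Agent-based simulation of a forager that builds a weak home range without
any spatial memory.

Many home-range models assume the animal remembers *where* it has been.
`sceneforage` implements the opposite extreme: an agent on a bounded field
of point resource sites that remembers only one number — the count of sites
it could see at some recent moment (a *scene memory*, kept for `θ` steps).
Each step it moves to a site chosen by one of two local rules,
**exploitation** (nearest visible site) or **exploration** (farthest visible
site), and whenever the currently visible count equals the remembered one it
suspects it has looped back onto familiar ground and swaps rules with
probability 0.5. Out of that single count, a clock and a coin comes movement
that is confined and revisitation-heavy yet keeps discovering new sites —
an emergent weak home range.

The package provides:

* the rule-change model plus four controls: fixed exploitation, fixed
  exploration, random choice, and a spatial working/reference-memory agent
  (`run_trial()`, `run_control_trial()`, `run_spatial_memory_trial()`,
  single-step `step_agent()` for hand-traceable worlds);
* movement statistics: distinct-site counts, per-site revisitation
  distributions with discrete power-law vs exponential maximum-likelihood
  fits arbitrated by Akaike weights (`fit_tail()`), mean-squared
  displacement curves (`mean_squared_displacement()`) and trajectory
  density maps (`density_map()`);
* seeded Monte-Carlo experiment runners with self-describing summary
  tables, manifests and byte-reproducible outputs (`run_experiment()`,
  `compare_models()`), and a thin command-line interface
  (`inst/cli/sceneforage`) with `run` / `sweep` / `analyze` / `compare`
  subcommands.

The revisitation tail is compared between
`P(x) = x^(−μ) / ζ(μ)` (discrete power law, `x_min = 1`) and
`P(x) = (1 − e^(−λ)) e^(−λ(x−1))` (discrete exponential), each fitted by
maximum likelihood; `AIC = 2 − 2 log L` and Akaike weights
`w_i = exp(−Δ_i/2) / Σ_j exp(−Δ_j/2)` decide which family carries the tail.

## A worked example

```r
library(sceneforage)

cfg <- sim_config()        # 100x100 field, 1000 sites, radius 4, theta 5
log <- run_trial(cfg, seed = 1)
log
#> Visit log: model 'rule_change', seed 1, 10000 steps
#>   10000 visit events over 5 distinct sites; 1689 rule switches, final rule 'exploration'

rd <- revisit_distribution(log)
rd
#>   site_id n_visits
#> 1     123        5
#> 2     146     4995
#> 3     258        5
#> 4     337     2507
#> 5     959     2488

fit_tail(rd$n_visits)
#> Tail fits on 5 counts (x_min = 1):
#>   power law:   mu = 1.166,  logL = -41.37, AIC = 84.74, weight = 0.836
#>   exponential: lambda = 0.001, logL = -43.00, AIC = 88.01, weight = 0.164
```

The agent spent 10 000 steps almost entirely on a handful of sites — a few
visited thousands of times — while occasionally breaking away: the
archetypal weak home range. The heavy-tailed visit counts prefer the power
law by Akaike weight (0.836 here); a random-choice agent's counts prefer
the exponential instead, with weight near 1.

Experiments aggregate trials:

```r
s <- run_experiment("rule_change", n_trials = 100, base_seed = 1)
mean(s$distinct_visited)
#> [1] 6.2
compare_models(s, run_experiment("fixed_exploitation", n_trials = 100, base_seed = 1))
#>       model_a            model_b mean_a mean_b mean_diff statistic      p_value
#> 1 rule_change fixed_exploitation    6.2   2.62      3.58      9310 4.884029e-27
#>   direction
#> 1 a_greater
```

## Command line

```sh
inst/cli/sceneforage run    --model rule_change --n-trials 100 --seed 1 --out-dir out/rc
inst/cli/sceneforage sweep  --model rule_change --param theta --values 5,10,20 --out-dir out/theta
inst/cli/sceneforage analyze --model rule_change --seed 1 --out-dir out/one
inst/cli/sceneforage compare --summary-a out/rc/summary.csv --summary-b out/fx/summary.csv
```

Flags mirror the `sim_config()` / `spatial_memory_config()` field names; a
YAML config file can supply any of them, with explicit flags taking
precedence.
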