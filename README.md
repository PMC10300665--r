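# rolesim

An agent-based model of occupational self-segregation by group "type".
A population of 1000 agents, half of each of two arbitrary types, chooses
among 60 roles in a scarcity-priced economy over 400 timesteps. Agents
combine three sources of information: globally shared **priors** about
group differences in competence, **social counts** of living agents of each
type who perform or have abandoned each role, and perfect knowledge of
their own ability in roles they have personally tried. The package exists
to separate the segregation produced by *beliefs about* group differences
from the segregation produced by *actual* differences, and to compare both
against the "optimal" sorting of perfectly informed agents.

It is aimed at researchers in cultural evolution and social learning who
want a fast, fully reproducible reimplementation of this class of model:
seeded replicate grids, a compiled core (~0.2 s per full-scale replicate),
a plain-R reference implementation of the stepping rule, and a test suite
that checks the belief machinery against brute-force Bayes.

## The model in brief

* **Payoff** of agent *i* performing role *r*: ability × price,
  `a_ir * p_r`, with scarcity pricing `p_r = (N/R) / (n_r + 1)` where `n_r`
  is the number of living agents currently performing *r* (prices update
  live within a timestep).
* **True abilities** `a_ir ~ N(100, 20)`; depending on the state of reality
  (models 1–6), 20% + 20% of roles truly favour one type with ability
  offsets ±15 (*d* = 1.5) or ±4 (*d* = 0.4), possibly vanishing for agents
  created after timestep 40, possibly with forced exploration of ≥ 4 or
  ≥ 10 roles before settling.
* **Beliefs**: a shared prior (proportion *q* of roles expected to favour
  each type, expected effect size *s* in sd units) combines with per-role
  continue/abandon counts through a three-hypothesis Bayes rule into
  `(A0, A1, An)`, the probabilities the role favours type 0, type 1 or
  neither; an untried role is then worth
  `p_r * (100 + s*20*(A_own − A_other))`.
* **Decisions**: agents take the highest-valued candidate role (ties
  uniform at random), adopt it as occupation iff its realized payoff
  strictly exceeds the estimated payoff of further search, and abandon an
  occupation when its payoff drops below a fraction θ ∈ {1, 0.9, 0.75} of
  that search value.
* **Outcome**: the segregation index
  `S = 2 * Σ_r n_r |n0_r/n_r − 1/2| / Σ_r n_r`, from 0 (every role 50:50)
  to 1 (every role single-type).

See the vignette (`vignettes/occupational-segregation-model.Rmd`) for the
full specification, the likelihood model behind the belief update, and the
design decisions taken where the verbal model description is open.

## Worked example

```r
library(rolesim)

# one replicate: no true differences, strong priors, high inertia
cfg <- world_config(model_id = 3, priors = "many-large", theta = 0.75,
                    seed = 7)
res <- run_simulation(cfg)
tail(res$segregation, 1)
#> [1] 0.6094553

# the same reality with egalitarian priors
res0 <- run_simulation(world_config(model_id = 3, priors = "none",
                                    theta = 0.75, seed = 7))
tail(res0$segregation, 1)
#> [1] 0.1978836
```

Although no role truly favours either type in model 3, agents who merely
*believe* that many large differences exist end up about three times more
segregated (0.61) than egalitarian-prior agents (0.20), whose outcome
matches the granularity floor of random 50:50 assignment at ~17 agents per
role.

```r
# perfect-knowledge baselines: the "optimal" segregation per reality
baseline_suite(replicates = 10, base_seed = 1)
#>    model1    model2    model3
#> 0.5287721 0.2916580 0.2044403
```

Omniscient agents self-sort to ≈ 0.53 under large true differences, ≈ 0.29
under small ones, and ≈ 0.20 with none. Replicated grids over models ×
priors × thresholds come from `run_grid()` / `experiment_grid()` and are
written as tidy CSV; a thin command-line wrapper is installed at
`inst/cli/rolesim` (`rolesim run ...`, `rolesim grid --config grid.yaml`,
`rolesim baselines`).

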