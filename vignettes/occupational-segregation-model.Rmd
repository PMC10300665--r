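---
title: "An agent-based model of occupational segregation by group type"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of occupational segregation by group type}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rolesim)
```

## The question the model asks

Workforces in industrialized societies remain strongly segregated by gender
even where formal barriers have largely disappeared. One candidate
explanation is social learning: if people hold a shared belief that group
differences in competence *may* exist, then observing who currently performs
and who has abandoned each occupation becomes evidence about which
occupations "suit" one's own group — and acting on that evidence regenerates
the very pattern being observed. `rolesim` implements a minimal agent-based
model of this feedback loop, so that the segregation produced by *beliefs
about* group differences can be compared against the segregation produced by
*actual* group differences, and against the "optimal" sorting of omniscient
agents.

## The model

A population of `N = 1000` agents, half of each of two arbitrary types
(0 and 1), lives through `T = 400` discrete timesteps. Each timestep every
agent acts once, in a fresh uniform-random order. When it acts, an agent
either dies with probability 0.05 — being replaced by a naive agent of the
same type, which starts acting the following step — or performs one of
`R = 60` roles.

**Economy.** Performing role $r$ yields payoff $a_{ir}\,p_r$, where $a_{ir}$
is the agent's true ability in the role and $p_r$ is the price of the role's
goods. Prices reflect scarcity: with $n_r$ living agents currently
performing $r$,

$$p_r = \frac{N/R}{n_r + 1},$$

so crowded roles pay less and empty roles remain finitely and attractively
priced. Occupancy — and with it every price — updates live as agents act
within a timestep, which is what makes the randomized acting order
consequential. All agent decisions compare payoffs that carry the same price
scale, so behaviour is invariant under a global price rescale (a property
the test suite asserts). The acting agent is removed from the occupancy
tally while it decides, so every price it sees, including that of its own
role, is computed net of itself; payoffs are credited at the pre-joining
price.

**True abilities.** $a_{ir} \sim \mathcal N(100, 20)$ independently across
agents and roles. Six states of reality modify these draws. In model 1,
$\lfloor 0.2R \rfloor$ roles favour each type: the favoured type gets $+15$
and the other $-15$ in those roles, a between-type effect size of
$d = 30/20 = 1.5$. Model 2 is identical with offsets $\pm 4$ ($d = 0.4$).
Model 3 applies no offsets. Models 4–6 behave like model 1 except that
agents created after timestep 40 receive no offsets (differences "vanish"
for later cohorts); models 5 and 6 additionally force exploration (below).
`cohens_d_audit()` verifies the realized effect sizes empirically.

**Beliefs.** Agents share a population-wide prior with two components: the
expected proportion $q \in \{0, 0.1, 0.4\}$ of roles favouring each type,
and the expected favour size $s \in \{0.2, 0.5\}$ in ability standard
deviations. Five presets (`none`, `few-small`, `few-large`, `many-small`,
`many-large`) cover the grid; `none` is an *egalitarian certainty* ($q=0$),
not an absence of opinion. For each role agents observe, over living agents
only, how many of each type currently continue in it and how many tried and
abandoned it. A three-hypothesis Bayes rule (favours type 0 / favours
type 1 / neutral, prior masses $q, q, 1-2q$) converts those counts into a
posterior triple $(A_0, A_1, A_n)$, and an untried role is valued at

$$E = p_r\big(100 + s\,\sigma\,(A_\text{own} - A_\text{other})\big).$$

**The likelihood model.** How exactly the counts should enter the belief
update is a genuine modelling choice; the package adopts the simplest
generative story consistent with the verbal mechanism above: each
observed try-outcome is a Bernoulli continue-vs-abandon trial with
continuation probability 0.5 under neutrality, and $0.5 \pm \delta$
(favoured/other type) under a favour hypothesis, with $\delta = s/2$.
Binomial coefficients cancel in the normalization; computation is done in
log space with exponents aggregated so that the posterior is exactly
equivariant under a type-label swap. One consequence worth knowing: with
population-scale counts this likelihood saturates. A few hundred
observations drive $(A_0, A_1, A_n)$ to near-certainty for *any* nonzero
$q$, so at high-inertia thresholds the final segregation level responds
only weakly to which nonzero preset is in force, and the payoff-gap
amplification is monotone in $s$ only while the evidence is one-sided
(sharper expected effects make near-balanced evidence count *for* the
neutral hypothesis). Both regimes are characterized in the test suite.

**Decisions.** An unoccupied agent picks the candidate role with the highest
value — known ability times price for roles it has tried, the posterior
expectation otherwise — breaking exact ties (relative tolerance $10^{-9}$)
uniformly at random. Having performed a role once it knows its true ability
there forever. It adopts the role as its occupation iff the realized payoff
strictly exceeds its *threshold*: the estimated payoff of further search,
i.e. the best expectation among still-untried roles (or the best known
alternative once everything has been tried). An occupied agent keeps
performing its occupation until its realized payoff drops below $\theta$
times that same search value, with $\theta \in \{1.0, 0.9, 0.75\}$; lower
$\theta$ models inertia such as retraining costs. Under forced exploration
(models 5 and 6) agents must try at least 4 or 10 distinct roles before any
adoption, and candidates are restricted to untried roles until then.

**Perfect knowledge.** As a baseline, agents can instead be given their true
ability in every role (`priors = "perfect"`), so they sort by actual
comparative advantage. These runs (at $\theta = 1$, frictionless movement)
define the "optimal" segregation level for each state of reality: about
0.51 under large true differences, 0.28 under small ones, and 0.19 with
none — the latter being pure binomial granularity, since with fewer than 20
agents per role even random 50:50 assignment deviates noticeably from an
even split.

**Outcome.** The segregation index is twice the occupancy-weighted mean
absolute deviation of role type-ratios from 50:50, computed over occupied
roles at the end of each step; explorers count towards the role they tried
that step, while agents created during the step have not yet performed and
count nowhere (so end-of-step occupancy totals $N$ minus that step's
replacements, about 5%).

## Reproducible experiments

`run_grid()` crosses models, priors and thresholds, with per-condition RNG
streams derived by hashing (condition, replicate, base seed), so enlarging
a grid never perturbs existing cells. A single replicate at the standard
scale (1000 agents × 400 steps) runs in roughly a second thanks to the
compiled core; the stepping rule also exists as a plain-R reference
(`step_agent()`) that the tests verify against the engine state-for-state
in a deterministic regime (no death, fixed acting order, tie-free values).

```{r baselines, eval = FALSE}
baseline_suite(replicates = 10, base_seed = 1)
#>    model1    model2    model3
#> 0.5287721 0.2916580 0.2044403
```

The experiment grids in the test suite use 10 replicates per condition — a
scale at which condition means are stable to roughly ±0.01–0.03 — rather
than the 100 used for publication-grade figures; `run_grid()` takes any
replicate count.

## Design choices where the model is genuinely open

* **Price function.** The model requires only that price fall with
  occupancy; the $(N/R)/(n_r+1)$ form was chosen for positivity,
  monotonicity and a price scale of ~1 at uniform occupancy, and is
  validated behaviourally by the perfect-knowledge baselines rather than
  by formula identity.
* **Adoption vs abandonment.** The threshold fraction $\theta$ applies only
  to abandoning an occupation; adoption always requires strictly exceeding
  the full search value. At the adoption decision the just-tried role is
  already "tried", so the search value is taken over the remaining untried
  roles (otherwise an agent could never adopt its last untried role).
* **Replacement.** Dying consumes the agent's action; its replacement is
  naive, of the same type, and begins acting the next step. The population
  and the 500/500 type split are therefore conserved exactly.
* **Social counts.** Each living agent contributes at most one mark
  (continuing *or* abandoned) per role; all its marks vanish at death. An
  agent's own marks are included in the counts it sees, harmlessly: belief
  inference is only ever applied to roles the agent has never tried, where
  it has no marks.
* **Type split.** 500/500, implied by same-type replacement plus symmetry
  of every reported condition. `world_config()` therefore requires an even
  population size.
* **20% of roles.** Implemented as $\lfloor 0.2R \rfloor$ per side — exact
  at $R = 60$.

## What the synthetic worlds do and do not show

All inputs are generated by the model itself; there is no empirical data.
The generator reproduces the *structure* of the modelled world — two equal
types, independent Normal abilities, categorical favour effects of fixed
size, global observability of living agents' histories — and none of the
things real labour markets add: persistent cultural records of the dead,
media and prestige effects, individual variation in priors or social-
learning reliance, more than two categories, costs of switching beyond the
inertia fraction. Passing tests therefore validate the mechanism under its
own assumptions, not any quantitative claim about real workforces.

## Known limitations

* The belief likelihood is one defensible choice (see above); alternative
  plausible formulations that keep posteriors soft at large counts would
  grade the prior presets more finely at high inertia.
* With $\theta = 1$ and perfect knowledge there is persistent low-level
  churn (an agent abandons whenever any untried role looks better); the
  segregation index is insensitive to it, but occupation tenure statistics
  would not be.
* The segregation index is reported for every timestep including the first
  few, where most agents are still exploring and the index mostly reflects
  price-chasing noise.
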