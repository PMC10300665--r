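#' Prior regimes over group differences
#'
#' Agents share a population-wide prior over how many roles truly favour one
#' type and how large any favour effect is. The prior has two components:
#' `q`, the expected proportion of roles favouring *each* type (so a fraction
#' `2q` of roles is expected to differ at all), and `s`, the expected size of
#' the favour effect relative to neutral, in units of the population ability
#' standard deviation. Five presets are provided:
#'
#' | preset | name         | q    | s    |
#' |--------|--------------|------|------|
#' | 0      | `none`       | 0    | --   |
#' | 1      | `few-small`  | 0.1  | 0.2  |
#' | 2      | `few-large`  | 0.1  | 0.5  |
#' | 3      | `many-small` | 0.4  | 0.2  |
#' | 4      | `many-large` | 0.4  | 0.5  |
#'
#' Preset 0 is an *egalitarian* prior, not an absent one: agents are certain
#' no role favours either type and consequently ignore type-specific social
#' information. Because `s` is coded relative to neutral (it is added for the
#' favoured type and subtracted for the other), the implied between-type gap
#' under a favour hypothesis is `2 * s` standard deviations.
#'
#' In belief updating, `s` also sets the discriminability of social evidence:
#' under a "role favours type t" hypothesis, type-t agents are assumed to
#' continue in the role with probability `0.5 + s/2` and the other type with
#' `0.5 - s/2` (capped so probabilities stay inside (0, 1)).
#'
#' @param preset integer 0-4 or one of `"none"`, `"few-small"`, `"few-large"`,
#'   `"many-small"`, `"many-large"`.
#' @return An object of class `role_priors`: list with `preset`, `label`,
#'   `q`, `s` and `delta` (the continuation-probability offset `s/2`).
#' @examples
#' priors_preset(4)
#' priors_preset("few-small")$q
#' @export
priors_preset <- function(preset) {
  labels <- c("none", "few-small", "few-large", "many-small", "many-large")
  if (is.character(preset)) {
    if (grepl("^[0-9]+$", preset)) {
      preset <- as.integer(preset)  # "0".."4", e.g. from a mixed vector
    } else {
      idx <- match(preset, labels)
      if (is.na(idx)) stop("unknown priors preset: ", preset, call. = FALSE)
      preset <- idx - 1L
    }
  }
  preset <- as.integer(preset)
  if (is.na(preset) || preset < 0L || preset > 4L) {
    stop("priors preset must be 0..4 or a preset name", call. = FALSE)
  }
  q <- c(0, 0.1, 0.1, 0.4, 0.4)[preset + 1L]
  s <- c(0, 0.2, 0.5, 0.2, 0.5)[preset + 1L]
  stopifnot(2 * q <= 1)
  delta <- min(s / 2, 0.45)  # cap keeps Bernoulli probabilities inside (0,1)
  structure(
    list(preset = preset, label = labels[preset + 1L], q = q, s = s,
         delta = delta),
    class = "role_priors"
  )
}

#' @export
print.role_priors <- function(x, ...) {
  cat(sprintf("<role_priors> preset %d (%s): q = %.2f, s = %.2f\n",
              x$preset, x$label, x$q, x$s))
  invisible(x)
}

#' Simulation configuration
#'
#' Collects every parameter of one simulation replicate. Defaults are the
#' standard study conditions: 1000 agents (500 per type), 60 roles, 400
#' timesteps, 5% death-and-replacement per agent-timestep, abilities drawn
#' from Normal(100, 20).
#'
#' @param model_id state of reality, 1-6:
#'   1 large true differences (ability offset +/-15, d = 1.5, in 20% + 20%
#'   of roles); 2 small true differences (offset +/-4, d = 0.4); 3 no
#'   differences; 4 as model 1 but agents created after `vanish_step` have
#'   no offsets; 5 and 6 as model 4 plus forced exploration of at least 4
#'   (model 5) or 10 (model 6) roles before an occupation may be adopted.
#' @param priors a [priors_preset()] object, a preset id/name, or `"perfect"`
#'   for the perfect-knowledge baseline condition in which agents know their
#'   own true ability in every role and ignore priors and social counts.
#' @param theta switching threshold in (0, 1]: an agent abandons its
#'   occupation when its realized payoff drops below `theta` times the
#'   estimated payoff of further search. Lower values mean more inertia.
#' @param n_agents population size (even; conserved by same-type replacement).
#' @param n_roles number of roles.
#' @param n_steps number of timesteps.
#' @param death_rate per agent-timestep probability of death-and-replacement.
#' @param ability_mean,ability_sd parameters of the base ability distribution.
#' @param forced_min_roles minimum distinct roles an agent must try before it
#'   can adopt an occupation. Defaults to 4 for model 5, 10 for model 6,
#'   0 otherwise.
#' @param vanish_step timestep after which newly created agents receive no
#'   ability offsets (models 4-6 only).
#' @param seed integer seed driving every source of randomness in the
#'   replicate (ability draws, acting order, death, tie-breaks).
#' @param price_scale multiplier applied to all prices; decisions are scale
#'   invariant so this never changes trajectories (exposed for testing that
#'   very property).
#' @param tie_tol relative tolerance under which candidate payoffs count as
#'   tied (ties are broken uniformly at random).
#' @return An object of class `world_config` (a validated list).
#' @examples
#' cfg <- world_config(model_id = 3, priors = "none", theta = 1, seed = 1)
#' cfg$n_agents
#' @export
world_config <- function(model_id = 3L,
                         priors = "none",
                         theta = 1.0,
                         n_agents = 1000L,
                         n_roles = 60L,
                         n_steps = 400L,
                         death_rate = 0.05,
                         ability_mean = 100,
                         ability_sd = 20,
                         forced_min_roles = NULL,
                         vanish_step = 40L,
                         seed = 1L,
                         price_scale = 1,
                         tie_tol = 1e-9) {
  model_id <- as.integer(model_id)
  if (is.na(model_id) || model_id < 1L || model_id > 6L) {
    stop("model_id must be in 1..6", call. = FALSE)
  }
  perfect <- FALSE
  if (identical(priors, "perfect")) {
    perfect <- TRUE
    priors <- priors_preset(0L)
  } else if (!inherits(priors, "role_priors")) {
    priors <- priors_preset(priors)
  }
  if (is.null(forced_min_roles)) {
    forced_min_roles <- c(0L, 0L, 0L, 0L, 4L, 10L)[model_id]
  }
  forced_min_roles <- as.integer(forced_min_roles)
  n_agents <- as.integer(n_agents)
  n_roles <- as.integer(n_roles)
  n_steps <- as.integer(n_steps)
  stopifnot(
    n_agents >= 2L, n_agents %% 2L == 0L,
    n_roles >= 2L, n_steps >= 0L,
    death_rate >= 0, death_rate < 1,
    ability_sd > 0, ability_mean > 0,
    theta > 0, theta <= 1,
    forced_min_roles >= 0L, forced_min_roles < n_roles,
    price_scale > 0, tie_tol >= 0
  )
  if (model_id != 3L && n_roles < 5L) {
    stop("models with true differences need n_roles >= 5 (20% of roles must round to >= 1)",
         call. = FALSE)
  }
  structure(
    list(model_id = model_id, priors = priors, perfect_knowledge = perfect,
         theta = theta, n_agents = n_agents, n_roles = n_roles,
         n_steps = n_steps, death_rate = death_rate,
         ability_mean = ability_mean, ability_sd = ability_sd,
         forced_min_roles = forced_min_roles,
         vanish_step = as.integer(vanish_step),
         seed = as.integer(seed), price_scale = price_scale,
         tie_tol = tie_tol),
    class = "world_config"
  )
}

#' @export
print.world_config <- function(x, ...) {
  cat(sprintf(
    "<world_config> model %d | %s | theta %.2f | %d agents x %d roles x %d steps | seed %d\n",
    x$model_id,
    if (x$perfect_knowledge) "perfect knowledge" else x$priors$label,
    x$theta, x$n_agents, x$n_roles, x$n_steps, x$seed))
  invisible(x)
}
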