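# Internal: advance the world n_steps using the compiled engine. Mutates
# `world` in place and returns the per-step segregation series. `order`
# (1-based agent indices) fixes the acting order of the FIRST step only, a
# hook for deterministic tests; all other steps use a fresh uniform-random
# permutation, as does the first when order is NULL.
run_engine <- function(world, n_steps, order = NULL) {
  cfg <- world$config
  to0 <- function(x) {
    x <- as.integer(x)
    x[is.na(x)] <- 0L
    x - 1L  # NA -> -1 sentinel
  }
  fav <- world$effects$favoured
  fav[is.na(fav)] <- -1L
  engine_cfg <- list(
    death_rate = cfg$death_rate, theta = cfg$theta,
    forced_min_roles = cfg$forced_min_roles,
    perfect = cfg$perfect_knowledge,
    q = cfg$priors$q, s = cfg$priors$s, delta = cfg$priors$delta,
    mu = cfg$ability_mean, sigma = cfg$ability_sd,
    tie_tol = cfg$tie_tol, price_scale = cfg$price_scale,
    model_id = cfg$model_id, vanish_step = cfg$vanish_step
  )
  res <- sim_steps_cpp(
    world$type, world$created_at, world$ability,
    matrix(as.integer(world$status), nrow = cfg$n_agents),
    to0(world$occupation), to0(world$performing),
    as.integer(fav), as.numeric(world$effects$offset),
    engine_cfg, as.integer(n_steps), world$step,
    if (is.null(order)) NULL else as.integer(order) - 1L
  )
  from0 <- function(x) {
    x <- x + 1L
    x[x == 0L] <- NA_integer_
    x
  }
  world$ability <- res$ability
  world$status <- res$status
  world$occupation <- from0(res$occupation)
  world$performing <- from0(res$performing)
  world$created_at <- res$created_at
  world$step <- world$step + as.integer(n_steps)
  res$segregation
}

#' Advance the world by one timestep
#'
#' Draws a fresh uniform-random permutation of the living agents and lets
#' each act in turn (see [step_agent()] for the per-agent rule), with
#' occupancy counts -- and therefore prices -- updating live as agents act.
#' The end-of-step segregation index is returned and the world is mutated in
#' place.
#'
#' @param world a `role_world` (mutated in place).
#' @param order optional integer vector of agent indices fixing the acting
#'   order (test hook); default `NULL` draws a random permutation.
#' @return The segregation index of the end-of-step occupancy (may be `NA`
#'   if no agent performed a role).
#' @examples
#' w <- init_world(world_config(model_id = 3, n_agents = 20, n_roles = 6,
#'                              n_steps = 5))
#' step_world(w)
#' @export
step_world <- function(world, order = NULL) {
  if (!is.null(order)) {
    stopifnot(length(order) == world$config$n_agents,
              setequal(order, seq_len(world$config$n_agents)))
  }
  run_engine(world, 1L, order)
}

#' Run one full simulation replicate
#'
#' Initializes the world from `config` (seeding the RNG from `config$seed`)
#' and advances it `config$n_steps` timesteps, recording the segregation
#' index after every step. In perfect-knowledge mode agents evaluate every
#' role at their own true ability times price instead of the posterior
#' expectation; in models 4-6 agents created after `vanish_step` receive no
#' true ability offsets.
#'
#' @param config a [world_config()].
#' @return An object of class `role_sim_result`: list with `segregation`
#'   (numeric, length `n_steps`), `occupancy` (final role x type table),
#'   `effects` (the replicate's true role-effect table), `config`, and
#'   `world` (the final state).
#' @examples
#' res <- run_simulation(world_config(model_id = 3, n_agents = 50,
#'                                    n_roles = 8, n_steps = 20, seed = 2))
#' tail(res$segregation, 1)
#' @export
run_simulation <- function(config) {
  world <- init_world(config)
  seg <- if (config$n_steps > 0L) run_engine(world, config$n_steps) else numeric(0)
  structure(
    list(segregation = seg, occupancy = occupancy_table(world),
         effects = world$effects, config = config, world = world),
    class = "role_sim_result"
  )
}

#' @export
print.role_sim_result <- function(x, ...) {
  fin <- if (length(x$segregation)) signif(x$segregation[length(x$segregation)], 3)
         else NA
  cat(sprintf("<role_sim_result> model %d | %s | theta %.2f | %d steps | final segregation %s\n",
              x$config$model_id,
              if (x$config$perfect_knowledge) "perfect knowledge"
              else x$config$priors$label,
              x$config$theta, length(x$segregation), fin))
  invisible(x)
}

# Search value used at the adoption decision: the just-performed role counts
# as tried, and the all-tried fallback must exclude it (it is the candidate
# occupation, not an alternative).
search_value_excluding <- function(world, agent, exclude_role) {
  vals <- role_values(world, agent)
  untried <- world$status[agent, ] == ROLE_UNTRIED
  if (any(untried)) return(max(vals[untried]))
  if (!is.na(exclude_role)) vals[exclude_role] <- -Inf
  max(vals)
}

#' Let a single agent act (reference implementation)
#'
#' One agent's action within a timestep, mirroring the compiled engine rule
#' for rule: with probability `death_rate` the agent dies and is replaced in
#' place by a naive same-type agent (created at `t`, fresh ability draws,
#' empty history) that begins acting next step; the dead agent's occupancy
#' and social-count contributions vanish with it. Otherwise the agent is
#' removed from occupancy while it decides (all prices it sees exclude
#' itself): an occupied agent keeps performing its occupation unless
#' [should_abandon()] fires, in which case the occupation is marked
#' abandoned; an unoccupied agent picks [choose_role()], performs the role,
#' learns its true ability there, and adopts it as occupation iff the
#' realized payoff strictly exceeds the estimated payoff of further search
#' and it has tried at least `forced_min_roles` roles -- otherwise the role
#' is marked abandoned.
#'
#' This R implementation is the readable reference; [step_world()] and
#' [run_simulation()] use the compiled equivalent.
#'
#' @param world a `role_world` (mutated in place).
#' @param agent agent index.
#' @param t the current timestep index (defaults to the step in progress).
#' @return Invisibly, a list describing what happened: `event` (one of
#'   `"death"`, `"stay"`, `"explore"`), `role`, `payoff`, `adopted`,
#'   `abandoned`.
#' @export
step_agent <- function(world, agent, t = world$step + 1L) {
  cfg <- world$config
  if (cfg$death_rate > 0 && stats::runif(1) < cfg$death_rate) {
    world$performing[agent] <- NA_integer_
    world$status[agent, ] <- ROLE_UNTRIED
    world$occupation[agent] <- NA_integer_
    world$created_at[agent] <- as.integer(t)
    world$ability[agent, ] <- draw_abilities(world$type[agent], t,
                                             world$effects, cfg)
    return(invisible(list(event = "death", role = NA_integer_,
                          payoff = NA_real_, adopted = FALSE,
                          abandoned = FALSE)))
  }
  world$performing[agent] <- NA_integer_
  abandoned <- FALSE
  occ <- world$occupation[agent]
  if (!is.na(occ)) {
    if (!should_abandon(world, agent)) {
      price <- role_prices(world)[occ]
      world$performing[agent] <- occ
      return(invisible(list(event = "stay", role = occ,
                            payoff = realized_payoff(world$ability[agent, occ], price),
                            adopted = FALSE, abandoned = FALSE)))
    }
    world$status[agent, occ] <- ROLE_ABANDONED
    world$occupation[agent] <- NA_integer_
    abandoned <- TRUE
  }
  r <- choose_role(world, agent)
  payoff <- realized_payoff(world$ability[agent, r], role_prices(world)[r])
  if (world$status[agent, r] == ROLE_UNTRIED) {
    world$status[agent, r] <- ROLE_ABANDONED  # provisional: tried, not adopted
  }
  tried_n <- sum(world$status[agent, ] != ROLE_UNTRIED)
  threshold <- search_value_excluding(world, agent, r)
  adopted <- payoff > threshold && tried_n >= cfg$forced_min_roles
  if (adopted) {
    world$status[agent, r] <- ROLE_CONTINUING
    world$occupation[agent] <- r
  }
  world$performing[agent] <- r
  invisible(list(event = "explore", role = r, payoff = payoff,
                 adopted = adopted, abandoned = abandoned))
}
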