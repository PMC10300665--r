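# World state is an environment (reference semantics: stepping mutates in
# place). Fields:
#   config     world_config
#   effects    role-effect table (make_role_effects)
#   type       integer N, 0/1
#   created_at integer N, creation timestep
#   ability    N x R numeric, true abilities
#   status     N x R integer: 0 untried, 1 tried-and-abandoned, 2 continuing
#   occupation integer N, settled role id (1..R) or NA
#   performing integer N, role performed in the current/most recent step or NA
#   step       completed timesteps

ROLE_UNTRIED <- 0L
ROLE_ABANDONED <- 1L
ROLE_CONTINUING <- 2L

#' Initialize a simulation world
#'
#' Creates the population at timestep 0: `n_agents` naive agents (half of
#' each type), true role effects drawn for this replicate, per-agent true
#' abilities realized eagerly, no occupations, empty social counts, and
#' prices at their empty-occupancy values. Seeds the RNG from
#' `config$seed`, so two calls with the same config produce identical
#' worlds and (together with [step_world()]/[run_simulation()]) identical
#' trajectories.
#'
#' @param config a [world_config()].
#' @return A `role_world` environment; see [world_state()] for a snapshot.
#' @examples
#' w <- init_world(world_config(model_id = 3, n_agents = 20, n_roles = 6))
#' table(w$type)
#' @export
init_world <- function(config) {
  if (!inherits(config, "world_config")) stop("config must be a world_config", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_agents
  r <- config$n_roles
  effects <- make_role_effects(config$model_id, r)
  type <- rep(c(0L, 1L), each = n %/% 2L)
  ability <- matrix(0, n, r)
  for (tp in c(0L, 1L)) {
    idx <- which(type == tp)
    ability[idx, ] <- draw_ability_matrix(length(idx), tp, 0L, effects, config)
  }
  w <- new.env(parent = emptyenv())
  w$config <- config
  w$effects <- effects
  w$type <- type
  w$created_at <- rep(0L, n)
  w$ability <- ability
  w$status <- matrix(ROLE_UNTRIED, n, r)
  w$occupation <- rep(NA_integer_, n)
  w$performing <- rep(NA_integer_, n)
  w$step <- 0L
  class(w) <- c("role_world", "environment")
  w
}

#' @export
print.role_world <- function(x, ...) {
  cat(sprintf("<role_world> t = %d | %d agents x %d roles | model %d | %s\n",
              x$step, x$config$n_agents, x$config$n_roles,
              x$config$model_id,
              if (x$config$perfect_knowledge) "perfect knowledge"
              else x$config$priors$label))
  invisible(x)
}

#' Role occupancy (living performers per role)
#'
#' Number of living agents currently performing each role, the quantity that
#' drives scarcity pricing. Explorers count towards the role they performed
#' in the current step; agents created this step have not yet performed and
#' count nowhere.
#'
#' @param world a `role_world`.
#' @param exclude optional agent index to leave out (used when evaluating
#'   prices from the acting agent's point of view).
#' @return Integer vector of length `n_roles`.
#' @export
role_occupancy <- function(world, exclude = NULL) {
  perf <- world$performing
  if (!is.null(exclude)) perf <- perf[-exclude]
  tabulate(perf, nbins = world$config$n_roles)
}

#' Current role prices
#'
#' Applies [compute_price()] to the current occupancy.
#'
#' @inheritParams role_occupancy
#' @return Numeric vector of prices, length `n_roles`.
#' @export
role_prices <- function(world, exclude = NULL) {
  compute_price(role_occupancy(world, exclude), world$config)
}

#' Social counts of living agents per role and type
#'
#' For every role and each type, the number of living agents of that type
#' currently continuing in the role (it is their occupation) and the number
#' who tried it and abandoned it. Dead agents contribute nothing: their
#' records vanish with them, so the counts always describe the living
#' population only.
#'
#' @param world a `role_world`.
#' @return A data.frame with one row per role: `role`, `continuing0`,
#'   `abandoned0`, `continuing1`, `abandoned1`.
#' @export
social_counts <- function(world) {
  t0 <- world$type == 0L
  data.frame(
    role = seq_len(world$config$n_roles),
    continuing0 = colSums(world$status[t0, , drop = FALSE] == ROLE_CONTINUING),
    abandoned0 = colSums(world$status[t0, , drop = FALSE] == ROLE_ABANDONED),
    continuing1 = colSums(world$status[!t0, , drop = FALSE] == ROLE_CONTINUING),
    abandoned1 = colSums(world$status[!t0, , drop = FALSE] == ROLE_ABANDONED)
  )
}

#' End-of-step occupancy table by role and type
#'
#' Counts, for each role, the agents of each type that performed it in the
#' most recent timestep (settled occupants and explorers alike). This is the
#' table the segregation index is computed from.
#'
#' @param world a `role_world`.
#' @return Integer matrix `n_roles` x 2 with columns `n0`, `n1`.
#' @export
occupancy_table <- function(world) {
  r <- world$config$n_roles
  out <- cbind(
    n0 = tabulate(world$performing[world$type == 0L], nbins = r),
    n1 = tabulate(world$performing[world$type == 1L], nbins = r)
  )
  rownames(out) <- NULL
  out
}

#' Snapshot of world state
#'
#' Returns a plain-list copy of the mutable world fields, convenient for
#' asserting invariants before/after stepping.
#'
#' @param world a `role_world`.
#' @return List of copies of `type`, `created_at`, `ability`, `status`,
#'   `occupation`, `performing`, `step`.
#' @export
world_state <- function(world) {
  list(type = world$type, created_at = world$created_at,
       ability = world$ability, status = world$status,
       occupation = world$occupation, performing = world$performing,
       step = world$step)
}

# Internal consistency audit; stops with a message if any structural
# invariant is violated. Used heavily by tests on small worlds.
audit_world <- function(world) {
  cfg <- world$config
  n <- cfg$n_agents
  stopifnot(
    length(world$type) == n,
    all(world$type %in% c(0L, 1L)),
    sum(world$type == 0L) == n %/% 2L,
    all(world$status %in% c(ROLE_UNTRIED, ROLE_ABANDONED, ROLE_CONTINUING))
  )
  occ <- world$occupation
  has_occ <- !is.na(occ)
  # occupation must be marked continuing, and be the unique continuing role
  cont_per_agent <- rowSums(world$status == ROLE_CONTINUING)
  stopifnot(all(cont_per_agent[has_occ] == 1L), all(cont_per_agent[!has_occ] == 0L))
  if (any(has_occ)) {
    stopifnot(all(world$status[cbind(which(has_occ), occ[has_occ])] == ROLE_CONTINUING))
  }
  # an occupied agent performs its occupation
  stopifnot(all(world$performing[has_occ] == occ[has_occ]))
  # performing roles are tried (explorers learn the role they perform)
  perf <- world$performing
  has_perf <- !is.na(perf)
  stopifnot(all(world$status[cbind(which(has_perf), perf[has_perf])] != ROLE_UNTRIED))
  # forced exploration: no occupation before trying E distinct roles
  tried_n <- rowSums(world$status != ROLE_UNTRIED)
  stopifnot(all(tried_n[has_occ] >= cfg$forced_min_roles))
  # social counts attribute exactly to living agents
  sc <- social_counts(world)
  stopifnot(all(sc$continuing0 + sc$continuing1 == tabulate(occ, nbins = cfg$n_roles)))
  invisible(TRUE)
}
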