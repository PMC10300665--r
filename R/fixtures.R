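#' Build a miniature deterministic world for tests
#'
#' Constructs a small, fully initialized world in milliseconds, optionally
#' with a hand-set ability matrix (bypassing the Normal draw, so decisions
#' can be made deterministic) and/or explicit social counts (realized by
#' assigning continuing/abandoned histories to agents, so every count is
#' attributable to a living agent and the full simulation invariants hold).
#' Worlds built this way are synthetic test scaffolding, not draws from the
#' study conditions.
#'
#' @param n_agents population size (even, <= 50).
#' @param n_roles number of roles (<= 8).
#' @param abilities optional `n_agents x n_roles` matrix of true abilities
#'   (positive); if omitted, abilities are drawn from the configured Normal.
#' @param counts optional data.frame with columns `role`, `continuing0`,
#'   `abandoned0`, `continuing1`, `abandoned1` to realize as agent
#'   histories. Continuing counts per type must fit within the population
#'   (an agent continues at most one role).
#' @param model_id,priors,theta,death_rate,forced_min_roles,seed,n_steps
#'   passed to [world_config()].
#' @return A `role_world`.
#' @examples
#' w <- make_mini_world(n_agents = 4, n_roles = 2,
#'                      abilities = matrix(c(120, 80, 120, 80,
#'                                           80, 120, 80, 120), 4, 2))
#' step_world(w, order = 1:4)
#' @export
make_mini_world <- function(n_agents = 4L, n_roles = 2L, abilities = NULL,
                            counts = NULL, model_id = 3L, priors = "none",
                            theta = 1.0, death_rate = 0, forced_min_roles = 0L,
                            seed = 1L, n_steps = 10L) {
  n_agents <- as.integer(n_agents)
  n_roles <- as.integer(n_roles)
  if (n_agents > 50L || n_roles > 8L) {
    stop("mini worlds are capped at 50 agents and 8 roles", call. = FALSE)
  }
  cfg <- world_config(model_id = model_id, priors = priors, theta = theta,
                      n_agents = n_agents, n_roles = n_roles,
                      n_steps = n_steps, death_rate = death_rate,
                      forced_min_roles = forced_min_roles, seed = seed)
  world <- init_world(cfg)
  if (!is.null(abilities)) {
    abilities <- as.matrix(abilities)
    if (!all(dim(abilities) == c(n_agents, n_roles))) {
      stop("abilities must be n_agents x n_roles", call. = FALSE)
    }
    if (any(abilities <= 0)) stop("abilities must be positive", call. = FALSE)
    world$ability <- abilities
  }
  if (!is.null(counts)) realize_counts(world, counts)
  audit_world(world)
  world
}

# Assign tried/occupation histories so that social_counts(world) reproduces
# the requested table. Continuing agents also perform their role (so the
# occupancy invariant holds); abandoned marks are spread over agents that do
# not already have that role continuing.
realize_counts <- function(world, counts) {
  cfg <- world$config
  stopifnot(all(c("role", "continuing0", "abandoned0", "continuing1",
                  "abandoned1") %in% names(counts)))
  for (tp in c(0L, 1L)) {
    pool <- which(world$type == tp)
    cont <- counts[[paste0("continuing", tp)]]
    if (sum(cont) > length(pool)) {
      stop("continuing counts exceed agents of type ", tp, call. = FALSE)
    }
    free <- pool
    for (k in seq_len(nrow(counts))) {
      r <- counts$role[k]
      nc <- cont[k]
      if (nc > 0) {
        take <- free[seq_len(nc)]
        free <- free[-seq_len(nc)]
        world$status[take, r] <- ROLE_CONTINUING
        world$occupation[take] <- r
        world$performing[take] <- r
      }
    }
    for (k in seq_len(nrow(counts))) {
      r <- counts$role[k]
      na_ <- counts[[paste0("abandoned", tp)]][k]
      if (na_ > 0) {
        eligible <- pool[world$status[pool, r] == ROLE_UNTRIED]
        if (length(eligible) < na_) {
          stop("abandoned counts exceed agents of type ", tp,
               " available for role ", r, call. = FALSE)
        }
        world$status[eligible[seq_len(na_)], r] <- ROLE_ABANDONED
      }
    }
  }
  invisible(world)
}
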