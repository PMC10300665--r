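#' True role effects for a state of reality
#'
#' Draws which roles truly favour which type, and by how much, for one
#' simulation replicate. In models with real differences (1, 2, and 4-6),
#' `floor(0.2 * n_roles)` roles favour type 0 and the same number favour
#' type 1, chosen uniformly at random without replacement; all remaining
#' roles are neutral. The ability offset is 15 units for the large-difference
#' models (1, 4, 5, 6; with sd 20 the implied between-type effect size is
#' d = 30/20 = 1.5) and 4 units for model 2 (d = 8/20 = 0.4). Model 3 leaves
#' every role neutral.
#'
#' @param model_id state of reality, 1..6.
#' @param n_roles number of roles (>= 5 for models with differences).
#' @return A data.frame with one row per role and columns `role` (1-based
#'   id), `favoured` (0, 1 or `NA` for neutral) and `offset` (ability units,
#'   0 for neutral roles).
#' @examples
#' set.seed(1)
#' eff <- make_role_effects(1, 60)
#' table(eff$favoured, useNA = "ifany")
#' @export
make_role_effects <- function(model_id, n_roles) {
  model_id <- as.integer(model_id)
  if (is.na(model_id) || model_id < 1L || model_id > 6L) {
    stop("unknown model_id: must be 1..6", call. = FALSE)
  }
  n_roles <- as.integer(n_roles)
  favoured <- rep(NA_integer_, n_roles)
  offset <- rep(0, n_roles)
  if (model_id != 3L) {
    if (n_roles < 5L) stop("n_roles must be >= 5 when differences exist", call. = FALSE)
    k <- floor(0.2 * n_roles)
    picked <- sample.int(n_roles, 2L * k)
    favoured[picked[seq_len(k)]] <- 0L
    favoured[picked[k + seq_len(k)]] <- 1L
    offset[picked] <- if (model_id == 2L) 4 else 15
  }
  data.frame(role = seq_len(n_roles), favoured = favoured, offset = offset)
}

# Vectorised ability draws for n same-type agents created at the same step.
# Returns an n x n_roles matrix. Offsets vanish for agents created after
# vanish_step in models 4-6.
draw_ability_matrix <- function(n, owner_type, created_at, effects, config) {
  n_roles <- nrow(effects)
  base <- matrix(
    rnorm(n * n_roles, config$ability_mean, config$ability_sd),
    nrow = n, ncol = n_roles
  )
  off <- ability_offsets(owner_type, created_at, effects, config)
  sweep(base, 2L, off, `+`)
}

# Per-role offset vector for one (type, creation time) combination.
ability_offsets <- function(owner_type, created_at, effects, config) {
  vanished <- config$model_id >= 4L && created_at > config$vanish_step
  if (vanished) return(rep(0, nrow(effects)))
  sgn <- ifelse(is.na(effects$favoured), 0,
                ifelse(effects$favoured == owner_type, 1, -1))
  sgn * effects$offset
}

#' Draw an agent's true abilities across all roles
#'
#' Base abilities are independent Normal(`ability_mean`, `ability_sd`) draws,
#' one per role. Where a role truly favours a type, the offset is added for
#' agents of the favoured type and subtracted for the other type. In models
#' 4-6, agents created after `vanish_step` receive no offsets at all
#' (differences "vanish" for later cohorts).
#'
#' @param owner_type agent type, 0 or 1.
#' @param created_at timestep at which the agent is created.
#' @param effects role-effect table from [make_role_effects()].
#' @param config a [world_config()] (supplies model id, ability distribution
#'   and `vanish_step`).
#' @return Numeric vector of true abilities, one per role.
#' @examples
#' cfg <- world_config(model_id = 1, seed = 1)
#' set.seed(1)
#' eff <- make_role_effects(1, cfg$n_roles)
#' a <- draw_abilities(0, created_at = 0, effects = eff, config = cfg)
#' length(a)
#' @export
draw_abilities <- function(owner_type, created_at, effects, config) {
  stopifnot(owner_type %in% c(0L, 1L), nrow(effects) == config$n_roles)
  drop(draw_ability_matrix(1L, owner_type, created_at, effects, config))
}

#' Empirical effect-size audit of the ability generator
#'
#' Draws `n_samples` agents of each type under the given state of reality and
#' measures the realized Cohen's d between types, separately for roles that
#' truly favour a type (sign-aligned so the favoured type is the first group)
#' and for neutral roles. With offset `D` and sd `sigma`, d converges to
#' `2 * D / sigma`: 1.5 for the large-difference models and 0.4 for model 2.
#'
#' @param model_id state of reality, 1..6.
#' @param n_samples agents drawn per type.
#' @param n_roles number of roles in the audited world.
#' @param config optional [world_config()]; defaults to the standard
#'   conditions for `model_id`.
#' @return List with `d_favoured` and `d_neutral` (mean per-role Cohen's d
#'   within each role class; `NA` if the class is empty) plus the per-role
#'   values `per_role` (data.frame).
#' @examples
#' set.seed(1)
#' cohens_d_audit(3, n_samples = 2000)$d_neutral
#' @export
cohens_d_audit <- function(model_id, n_samples, n_roles = 60L, config = NULL) {
  if (is.null(config)) {
    config <- world_config(model_id = model_id, n_roles = n_roles, seed = 0L)
  }
  effects <- make_role_effects(model_id, config$n_roles)
  a0 <- draw_ability_matrix(n_samples, 0L, 0L, effects, config)
  a1 <- draw_ability_matrix(n_samples, 1L, 0L, effects, config)
  m0 <- colMeans(a0); m1 <- colMeans(a1)
  v0 <- apply(a0, 2L, stats::var); v1 <- apply(a1, 2L, stats::var)
  pooled <- sqrt((v0 + v1) / 2)
  d <- (m0 - m1) / pooled
  # sign-align so the favoured type is always the first group
  sgn <- ifelse(is.na(effects$favoured), 1, ifelse(effects$favoured == 0L, 1, -1))
  d_aligned <- d * sgn
  fav <- !is.na(effects$favoured)
  list(
    d_favoured = if (any(fav)) mean(d_aligned[fav]) else NA_real_,
    d_neutral = if (any(!fav)) mean(d_aligned[!fav]) else NA_real_,
    per_role = data.frame(role = effects$role, favoured = effects$favoured,
                          d = d, d_aligned = d_aligned)
  )
}
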