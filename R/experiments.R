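#' Define an experiment grid
#'
#' The cross of states of reality, prior regimes and switching thresholds,
#' each run for `replicates` seeded replicates.
#'
#' @param models integer vector, subset of 1..6.
#' @param priors vector of preset ids (0..4), preset names, and/or
#'   `"perfect"`.
#' @param thetas numeric vector of switching thresholds in (0, 1].
#' @param replicates replicates per condition (>= 1).
#' @param base_seed base seed; each (condition, replicate) derives an
#'   independent RNG stream from it, so adding conditions or replicates
#'   never perturbs existing ones.
#' @return An object of class `experiment_grid`.
#' @examples
#' experiment_grid(models = 3, priors = c("none", "many-large"),
#'                 thetas = 0.75, replicates = 2)
#' @export
experiment_grid <- function(models = 1:6,
                            priors = c("none", "few-small", "few-large",
                                       "many-small", "many-large"),
                            thetas = c(1.0, 0.9, 0.75),
                            replicates = 10L,
                            base_seed = 1L) {
  models <- as.integer(models)
  if (length(models) == 0L || any(is.na(models)) || any(models < 1L | models > 6L)) {
    stop("models must be a non-empty subset of 1..6", call. = FALSE)
  }
  priors <- vapply(priors, function(p) {
    if (identical(p, "perfect")) "perfect" else priors_preset(p)$label
  }, character(1), USE.NAMES = FALSE)
  if (length(thetas) == 0L || any(thetas <= 0 | thetas > 1)) {
    stop("thetas must be a non-empty subset of (0, 1]", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L)
  structure(
    list(models = models, priors = unique(priors), thetas = thetas,
         replicates = replicates, base_seed = as.integer(base_seed)),
    class = "experiment_grid"
  )
}

# Deterministic seed for one (condition, replicate) cell: a small
# multiplicative mixing hash, kept below 2^31 so it is a valid R integer.
condition_seed <- function(base_seed, model, priors_label, theta, replicate) {
  m <- 2147483629  # largest prime < 2^31
  h <- (as.numeric(base_seed) %% m)
  mix <- function(h, x) (h * 69069 + as.numeric(x) + 1) %% m
  h <- mix(h, model)
  for (ch in utf8ToInt(priors_label)) h <- mix(h, ch)
  h <- mix(h, round(theta * 10000))
  h <- mix(h, replicate)
  as.integer(h %% 2147483587 + 1)
}

#' Run an experiment grid
#'
#' Runs every (model, priors, theta) condition for the grid's number of
#' replicates and returns a tidy per-timestep table. Deterministic given
#' `base_seed`; conditions use independent derived seeds.
#'
#' @param grid an [experiment_grid()].
#' @param ... overrides passed to [world_config()] (e.g. `n_agents`,
#'   `n_roles`, `n_steps` for scaled-down runs).
#' @param progress print one line per condition as it completes.
#' @return A tibble with columns `model`, `priors`, `theta`, `replicate`,
#'   `timestep`, `segregation`.
#' @examples
#' g <- experiment_grid(models = 3, priors = "none", thetas = 1,
#'                      replicates = 2)
#' tab <- run_grid(g, n_agents = 50, n_roles = 8, n_steps = 10)
#' nrow(tab)  # 2 replicates x 10 timesteps
#' @export
run_grid <- function(grid, ..., progress = FALSE) {
  stopifnot(inherits(grid, "experiment_grid"))
  out <- list()
  for (m in grid$models) {
    for (p in grid$priors) {
      for (th in grid$thetas) {
        rows <- lapply(seq_len(grid$replicates), function(rep) {
          seed <- condition_seed(grid$base_seed, m, p, th, rep)
          cfg <- world_config(model_id = m, priors = p, theta = th,
                              seed = seed, ...)
          tidy_segregation(run_simulation(cfg), replicate = rep)
        })
        out[[length(out) + 1L]] <- do.call(rbind, rows)
        if (progress) {
          message(sprintf("model %d | %s | theta %.2f done", m, p, th))
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Perfect-knowledge segregation baselines
#'
#' Mean final-timestep segregation of perfect-knowledge agents under the
#' three static states of reality: model 1 (large true differences),
#' model 2 (small) and model 3 (none). These define the "optimal" level of
#' segregation an omniscient population self-sorts to, the yardstick the
#' belief-driven conditions are compared against. Runs use theta = 1
#' (frictionless movement).
#'
#' @param replicates replicates per model (>= 5).
#' @param base_seed base seed for the derived replicate streams.
#' @param ... overrides passed to [world_config()].
#' @return Named numeric vector `c(model1 = ..., model2 = ..., model3 = ...)`
#'   with attribute `"final"` holding the per-replicate final values
#'   (a 3-column matrix).
#' @examples
#' baseline_suite(replicates = 5, base_seed = 1, n_agents = 100,
#'                n_roles = 10, n_steps = 30)
#' @export
baseline_suite <- function(replicates = 10L, base_seed = 1L, ...) {
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 5L)
  finals <- sapply(1:3, function(m) {
    vapply(seq_len(replicates), function(rep) {
      seed <- condition_seed(base_seed, m, "perfect", 1.0, rep)
      cfg <- world_config(model_id = m, priors = "perfect", theta = 1.0,
                          seed = seed, ...)
      res <- run_simulation(cfg)
      res$segregation[length(res$segregation)]
    }, numeric(1))
  })
  colnames(finals) <- c("model1", "model2", "model3")
  structure(colMeans(finals), final = finals)
}
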