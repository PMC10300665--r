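#' Segregation index of an occupancy table
#'
#' Twice the occupancy-weighted mean, over occupied roles, of each role's
#' absolute deviation from a 50:50 type ratio:
#' `S = 2 * sum(n_r * |n0_r / n_r - 0.5|) / sum(n_r)` with `n_r = n0_r + n1_r`,
#' summing over roles with `n_r > 0`. `S = 0` when every occupied role is
#' split exactly 50:50 and `S = 1` when every role is performed by one type
#' only. Empty roles carry zero weight (their type ratio is undefined).
#'
#' @param occupancy matrix or data.frame with one row per role and two
#'   columns of non-negative counts (type 0, type 1).
#' @return The index in `[0, 1]`, or `NA` if every role is empty.
#' @examples
#' segregation_index(cbind(c(3, 1), c(1, 1)))  # 1/3
#' segregation_index(cbind(c(10, 0), c(0, 10)))  # fully segregated: 1
#' @export
segregation_index <- function(occupancy) {
  occupancy <- as.matrix(occupancy)
  stopifnot(ncol(occupancy) == 2L, all(occupancy >= 0))
  tot <- rowSums(occupancy)
  keep <- tot > 0
  if (!any(keep)) return(NA_real_)
  dev <- abs(occupancy[keep, 1L] / tot[keep] - 0.5)
  2 * sum(tot[keep] * dev) / sum(tot[keep])
}

#' Summarize replicate simulation runs
#'
#' Averages the segregation series across replicates and summarizes the
#' distribution of final-timestep values.
#'
#' @param results list of `role_sim_result` objects (equal series lengths).
#' @return List with `mean_series` (numeric), `final` (numeric vector of
#'   final values, one per replicate), and `final_summary` (named vector:
#'   mean, sd, and the 2.5%, 25%, 50%, 75%, 97.5% quantiles).
#' @examples
#' cfg <- function(seed) world_config(model_id = 3, n_agents = 50,
#'                                    n_roles = 8, n_steps = 10, seed = seed)
#' runs <- lapply(1:3, function(s) run_simulation(cfg(s)))
#' summarize_runs(runs)$final_summary[["mean"]]
#' @export
summarize_runs <- function(results) {
  stopifnot(length(results) >= 1L)
  series <- lapply(results, function(r) r$segregation)
  len <- vapply(series, length, integer(1))
  if (length(unique(len)) != 1L) {
    stop("all runs must have the same number of recorded timesteps", call. = FALSE)
  }
  mat <- do.call(cbind, series)
  final <- if (len[1L] > 0L) mat[len[1L], ] else numeric(0)
  qs <- if (length(final)) quantile(final, c(0.025, 0.25, 0.5, 0.75, 0.975))
        else rep(NA_real_, 5L)
  list(
    mean_series = if (len[1L] > 0L) rowMeans(mat) else numeric(0),
    final = final,
    final_summary = c(mean = mean(final), sd = sd(final), qs)
  )
}

#' Tidy per-timestep segregation table for one run
#'
#' @param result a `role_sim_result`.
#' @param replicate replicate id recorded in the table.
#' @return A tibble with columns `model`, `priors`, `theta`, `replicate`,
#'   `timestep`, `segregation`.
#' @export
tidy_segregation <- function(result, replicate = 1L) {
  cfg <- result$config
  tibble::tibble(
    model = cfg$model_id,
    priors = if (cfg$perfect_knowledge) "perfect" else cfg$priors$label,
    theta = cfg$theta,
    replicate = as.integer(replicate),
    timestep = seq_along(result$segregation),
    segregation = result$segregation
  )
}

#' Write a tidy segregation table to CSV
#'
#' @param tbl a table as produced by [tidy_segregation()] or [run_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_segregation_csv <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run's provenance log (JSON lines)
#'
#' One JSON object per line: the configuration (with the priors flattened),
#' the seed, and the replicate's true role-effect table, enough to reproduce
#' the run exactly.
#'
#' @param result a `role_sim_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(result, path) {
  cfg <- result$config
  flat <- cfg[setdiff(names(cfg), "priors")]
  flat$priors_preset <- cfg$priors$preset
  flat$priors_q <- cfg$priors$q
  flat$priors_s <- cfg$priors$s
  lines <- c(
    jsonlite::toJSON(list(record = "config", config = flat), auto_unbox = TRUE),
    jsonlite::toJSON(list(record = "role_effects",
                          effects = result$effects), auto_unbox = TRUE,
                     na = "null")
  )
  writeLines(lines, path)
  invisible(path)
}
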