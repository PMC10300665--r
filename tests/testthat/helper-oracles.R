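# Independent oracles, deliberately written as plain explicit computations
# (no log-space tricks, no vectorisation, no reuse of package internals).

# Three-hypothesis Bayes rule for one role's social counts, as a literal
# prior-times-likelihood sum. delta is the continuation-probability offset.
oracle_posterior <- function(c0, a0, c1, a1, q, delta) {
  bern <- function(p_cont0, p_cont1) {
    p_cont0^c0 * (1 - p_cont0)^a0 * p_cont1^c1 * (1 - p_cont1)^a1
  }
  w0 <- q * bern(0.5 + delta, 0.5 - delta)        # favours type 0
  w1 <- q * bern(0.5 - delta, 0.5 + delta)        # favours type 1
  wn <- (1 - 2 * q) * bern(0.5, 0.5)              # neutral
  tot <- w0 + w1 + wn
  c(A0 = w0 / tot, A1 = w1 / tot, An = wn / tot)
}

# Naive two-pass reference for the segregation index.
oracle_segregation <- function(occ) {
  total <- 0
  for (r in seq_len(nrow(occ))) total <- total + occ[r, 1] + occ[r, 2]
  if (total == 0) return(NA_real_)
  acc <- 0
  for (r in seq_len(nrow(occ))) {
    nr <- occ[r, 1] + occ[r, 2]
    if (nr > 0) acc <- acc + nr * abs(occ[r, 1] / nr - 0.5)
  }
  2 * acc / total
}

# Final-timestep segregation for `reps` seeded replicates of one condition,
# using the same per-condition seed streams as run_grid().
final_segs <- function(model, priors, theta, reps = 10, base_seed = 1, ...) {
  vapply(seq_len(reps), function(rep) {
    seed <- rolesim:::condition_seed(base_seed, model,
                                     if (identical(priors, "perfect")) "perfect"
                                     else priors_preset(priors)$label,
                                     theta, rep)
    cfg <- world_config(model_id = model, priors = priors, theta = theta,
                        seed = seed, ...)
    res <- run_simulation(cfg)
    res$segregation[length(res$segregation)]
  }, numeric(1))
}

random_counts <- function(n, max_count = 50) {
  data.frame(
    continuing0 = sample.int(max_count + 1L, n, replace = TRUE) - 1L,
    abandoned0 = sample.int(max_count + 1L, n, replace = TRUE) - 1L,
    continuing1 = sample.int(max_count + 1L, n, replace = TRUE) - 1L,
    abandoned1 = sample.int(max_count + 1L, n, replace = TRUE) - 1L
  )
}
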