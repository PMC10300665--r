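test_that("init_world builds a balanced naive population deterministically", {
  cfg <- world_config(model_id = 1, n_agents = 100, n_roles = 10, seed = 4)
  w <- init_world(cfg)
  expect_equal(sum(w$type == 0L), 50)
  expect_equal(sum(w$type == 1L), 50)
  expect_true(all(w$status == 0L))
  expect_true(all(is.na(w$occupation)))
  expect_true(all(is.na(w$performing)))
  expect_equal(w$step, 0L)
  expect_true(all(role_prices(w) == compute_price(0, cfg)))
  w2 <- init_world(cfg)
  expect_identical(w$ability, w2$ability)
  expect_identical(w$effects, w2$effects)
})

test_that("equal seeds give identical trajectories", {
  cfg <- world_config(model_id = 4, priors = "few-large", theta = 0.9,
                      n_agents = 100, n_roles = 10, n_steps = 30, seed = 99)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$segregation, b$segregation)
  expect_identical(a$occupancy, b$occupancy)
  expect_length(a$segregation, 30)
  expect_true(all(a$segregation >= 0 & a$segregation <= 1))
})

test_that("a zero-step simulation is a valid degenerate result", {
  res <- run_simulation(world_config(n_agents = 20, n_roles = 6, n_steps = 0))
  expect_identical(res$segregation, numeric(0))
  expect_equal(sum(res$occupancy), 0)
})

test_that("population, type split and count attribution hold at every step", {
  cfg <- world_config(model_id = 5, priors = "many-small", theta = 0.9,
                      n_agents = 40, n_roles = 8, n_steps = 25,
                      death_rate = 0.2, forced_min_roles = 3, seed = 17)
  w <- init_world(cfg)
  for (t in 1:25) {
    step_world(w)
    expect_silent(rolesim:::audit_world(w))
    # end-of-step occupancy covers everyone except this step's replacements
    expect_equal(sum(occupancy_table(w)), cfg$n_agents - sum(w$created_at == t))
    expect_true(all(w$created_at[!is.na(w$performing)] < t + 1L))
  }
  # high churn must actually have replaced people for this to mean much
  expect_gt(sum(w$created_at > 0), 0)
})

test_that("dead agents vanish from social counts and occupancy", {
  cnt <- data.frame(role = 1:2, continuing0 = c(4, 0), abandoned0 = c(2, 3),
                    continuing1 = c(0, 4), abandoned1 = c(3, 2))
  w <- make_mini_world(n_agents = 20, n_roles = 2, counts = cnt,
                       priors = "many-large")
  w$config$death_rate <- 1  # everyone dies this step
  t_before <- w$step
  step_world(w)
  sc <- social_counts(w)
  expect_true(all(sc[, -1] == 0))
  expect_true(all(is.na(w$performing)))
  expect_true(all(is.na(w$occupation)))
  expect_true(all(w$created_at == t_before + 1L))
  expect_true(all(role_occupancy(w) == 0))
})

test_that("forced exploration visits distinct roles before any adoption", {
  w <- make_mini_world(n_agents = 10, n_roles = 6, forced_min_roles = 3,
                       priors = "none", n_steps = 8)
  for (t in 1:2) {
    step_world(w)
    expect_true(all(is.na(w$occupation)))
    # each agent has tried exactly t distinct roles so far
    expect_true(all(rowSums(w$status != 0L) == t))
  }
  for (t in 3:8) step_world(w)
  expect_silent(rolesim:::audit_world(w))
  settled <- !is.na(w$occupation)
  expect_true(all(rowSums(w$status[settled, , drop = FALSE] != 0L) >= 3))
})

test_that("compiled engine matches the R reference step-for-step", {
  # deterministic regime: no death, explicit acting order, asymmetric social
  # counts and continuous abilities so no decision is ever tied
  cnt <- data.frame(role = 1:4,
                    continuing0 = c(5, 0, 1, 0), abandoned0 = c(1, 3, 0, 2),
                    continuing1 = c(0, 4, 0, 2), abandoned1 = c(2, 0, 3, 1))
  build <- function() {
    w <- make_mini_world(n_agents = 20, n_roles = 4, counts = cnt,
                         priors = "many-large", theta = 0.9, seed = 3)
    set.seed(31)
    w$ability <- matrix(rnorm(20 * 4, 100, 20), 20, 4)
    w$ability <- abs(w$ability) + 1
    w
  }
  we <- build()
  wr <- build()
  set.seed(50)
  orders <- replicate(6, sample.int(20), simplify = FALSE)
  for (k in 1:6) {
    seg <- step_world(we, order = orders[[k]])
    for (i in orders[[k]]) step_agent(wr, i)
    wr$step <- wr$step + 1L
    expect_identical(we$occupation, wr$occupation)
    expect_identical(we$performing, wr$performing)
    expect_identical(we$status, wr$status)
    expect_equal(we$ability, wr$ability)
    expect_equal(seg, segregation_index(occupancy_table(wr)))
  }
})

test_that("perfect-knowledge engine matches the R reference", {
  build <- function() {
    w <- make_mini_world(n_agents = 12, n_roles = 5, priors = "perfect",
                         theta = 1.0, seed = 8)
    set.seed(77)
    w$ability <- matrix(abs(rnorm(12 * 5, 100, 20)) + 1, 12, 5)
    w
  }
  we <- build()
  wr <- build()
  for (k in 1:5) {
    ord <- seq_len(12)
    step_world(we, order = ord)
    for (i in ord) step_agent(wr, i)
    wr$step <- wr$step + 1L
    expect_identical(we$occupation, wr$occupation)
    expect_identical(we$status, wr$status)
  }
  # a settled perfect-knowledge agent keeps its role while payoff holds up
  expect_gt(sum(!is.na(we$occupation)), 0)
})

test_that("an agent above threshold keeps its occupation across steps", {
  # two strong specialists per role: they settle immediately and never move
  ab <- matrix(c(200, 50, 200, 50, 50, 200, 50, 200), 4, 2, byrow = TRUE)
  w <- make_mini_world(n_agents = 4, n_roles = 2, abilities = ab,
                       priors = "perfect")
  for (k in 1:5) step_world(w, order = 1:4)
  expect_identical(w$occupation, c(1L, 1L, 2L, 2L))
  expect_identical(w$performing, w$occupation)
})

test_that("the no-differences egalitarian world is stationary by late steps", {
  drift <- vapply(1:10, function(seed) {
    res <- run_simulation(world_config(model_id = 3, priors = "none",
                                       theta = 1.0, seed = seed))
    abs(mean(res$segregation[300:400]) - mean(res$segregation[200:300]))
  }, numeric(1))
  expect_lt(mean(drift), 0.03)
  expect_true(all(drift < 0.05))
})
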