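test_that("posterior matches brute-force Bayes on the worked example", {
  pr <- priors_preset(4)  # q = 0.4, s = 0.5, delta = 0.25
  post <- posterior_role_favour(
    list(continuing0 = 8, abandoned0 = 2, continuing1 = 2, abandoned1 = 8), pr)
  oracle <- oracle_posterior(8, 2, 2, 8, q = 0.4, delta = 0.25)
  expect_equal(as.numeric(post), as.numeric(oracle), tolerance = 1e-12)
  expect_gt(post[, "A0"], post[, "An"])
  expect_gt(post[, "An"], post[, "A1"])
})

test_that("posterior agrees with the brute-force oracle on random counts", {
  set.seed(101)
  for (preset in 1:4) {
    pr <- priors_preset(preset)
    cnt <- random_counts(250)
    post <- posterior_role_favour(cnt, pr)
    for (k in seq_len(nrow(cnt))) {
      oracle <- oracle_posterior(cnt$continuing0[k], cnt$abandoned0[k],
                                 cnt$continuing1[k], cnt$abandoned1[k],
                                 q = pr$q, delta = pr$delta)
      expect_equal(as.numeric(post[k, ]), as.numeric(oracle),
                   tolerance = 1e-10)
    }
  }
})

test_that("posterior triples are normalized probabilities", {
  set.seed(7)
  cnt <- random_counts(10000, max_count = 400)
  for (preset in 0:4) {
    post <- posterior_role_favour(cnt, priors_preset(preset))
    expect_true(all(abs(rowSums(post) - 1) < 1e-12))
    expect_true(all(post >= 0 & post <= 1))
  }
})

test_that("egalitarian priors ignore social information", {
  set.seed(8)
  cnt <- random_counts(50)
  post <- posterior_role_favour(cnt, priors_preset(0))
  expect_true(all(post[, "A0"] == 0 & post[, "A1"] == 0 & post[, "An"] == 1))
})

test_that("posterior is equivariant under swapping the type labels", {
  set.seed(9)
  cnt <- random_counts(200)
  swapped <- data.frame(continuing0 = cnt$continuing1,
                        abandoned0 = cnt$abandoned1,
                        continuing1 = cnt$continuing0,
                        abandoned1 = cnt$abandoned0)
  for (preset in 1:4) {
    a <- posterior_role_favour(cnt, priors_preset(preset))
    b <- posterior_role_favour(swapped, priors_preset(preset))
    expect_identical(a[, "A0"], b[, "A1"])
    expect_identical(a[, "A1"], b[, "A0"])
    expect_identical(a[, "An"], b[, "An"])
  }
  # symmetric counts give A0 == A1
  sym <- data.frame(continuing0 = 5, abandoned0 = 3, continuing1 = 5,
                    abandoned1 = 3)
  p <- posterior_role_favour(sym, priors_preset(4))
  expect_equal(unname(p[, "A0"]), unname(p[, "A1"]))
})

test_that("more one-sided evidence gives a more one-sided posterior", {
  pr <- priors_preset(2)
  a0_track <- vapply(0:30, function(c0) {
    posterior_role_favour(list(continuing0 = c0, abandoned0 = 2,
                               continuing1 = 4, abandoned1 = 6), pr)[, "A0"]
  }, numeric(1))
  expect_true(all(diff(a0_track) >= 0))
})

test_that("stronger priors amplify the payoff gap between types", {
  cfg <- world_config()
  set.seed(10)
  gap <- function(cnt, preset) {
    pr <- priors_preset(preset)
    post <- posterior_role_favour(cnt, pr)
    abs(expected_payoff(0L, post, pr, 1, cfg) -
          expected_payoff(1L, post, pr, 1, cfg))
  }
  tol <- 1e-12
  # expecting more differing roles (q) amplifies the gap for any counts
  cnt <- random_counts(200)
  g <- sapply(0:4, function(p) gap(cnt, p))
  expect_true(all(g[, 1] <= tol))                 # egalitarian: no gap
  expect_true(all(g[, 4] >= g[, 2] - tol))        # q up at fixed s (1 -> 3)
  expect_true(all(g[, 5] >= g[, 3] - tol))        # q up at fixed s (2 -> 4)
  # expecting larger differences (s) amplifies the gap when the evidence is
  # consistent (one-sided); near-balanced counts at a sharper expected
  # effect instead push mass onto the neutral hypothesis
  oneside <- data.frame(continuing0 = sample(0:60, 200, replace = TRUE),
                        abandoned0 = 0,
                        continuing1 = 0,
                        abandoned1 = sample(0:60, 200, replace = TRUE))
  h <- sapply(0:4, function(p) gap(oneside, p))
  expect_true(all(h[, 3] >= h[, 2] - tol))        # s up at fixed q (1 -> 2)
  expect_true(all(h[, 5] >= h[, 4] - tol))        # s up at fixed q (3 -> 4)
})

test_that("expected payoff combines posterior, prior size and price", {
  cfg <- world_config()
  pr2 <- priors_preset(2)  # s = 0.5
  expect_equal(expected_payoff(0L, c(0, 0, 1), pr2, 1, cfg), 100)
  expect_equal(expected_payoff(1L, c(0, 0, 1), pr2, 3, cfg), 300)
  expect_equal(expected_payoff(0L, c(1, 0, 0), pr2, 1, cfg), 110)
  expect_equal(expected_payoff(1L, c(1, 0, 0), pr2, 1, cfg), 90)
  # monotone in own-favour mass
  post <- matrix(c(0.7, 0.1, 0.2), ncol = 3)
  expect_gt(expected_payoff(0L, post, pr2, 1, cfg),
            expected_payoff(1L, post, pr2, 1, cfg))
})

test_that("choose_role is a uniform draw among exactly tied roles", {
  w <- make_mini_world(n_agents = 4, n_roles = 8, priors = "none")
  set.seed(12)
  draws <- replicate(4000, choose_role(w, 1L))
  counts <- tabulate(draws, nbins = 8)
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("choose_role prefers the role dominated by the agent's own type", {
  cnt <- data.frame(role = 1:2, continuing0 = c(10, 0), abandoned0 = c(0, 0),
                    continuing1 = c(0, 10), abandoned1 = c(0, 0))
  w <- make_mini_world(n_agents = 24, n_roles = 2, counts = cnt,
                       priors = "many-large")
  agent0 <- which(w$type == 0L & is.na(w$occupation))[1]
  agent1 <- which(w$type == 1L & is.na(w$occupation))[1]
  # equal occupancy -> equal prices; only the social counts differ
  expect_equal(length(unique(role_prices(w, exclude = agent0))), 1L)
  expect_equal(choose_role(w, agent0), 1L)
  expect_equal(choose_role(w, agent1), 2L)
})

test_that("abandonment triggers exactly when payoff drops below theta x search value", {
  # one settled agent with ability 80 in its occupation; every alternative is
  # untried with egalitarian expectation 100 x price, all prices equal
  w <- make_mini_world(n_agents = 4, n_roles = 4, priors = "none",
                       abilities = matrix(80, 4, 4))
  w$status[1, 1] <- 2L
  w$occupation[1] <- 1L
  w$performing[1] <- 1L
  expect_false(should_abandon(w, 1L, theta = 0.75))   # 80 >= 75
  expect_true(should_abandon(w, 1L, theta = 0.9))     # 80 < 90
  expect_true(should_abandon(w, 1L, theta = 1.0))
  # boundary: payoff exactly equal to threshold does not trigger
  w$ability[1, 1] <- 100
  expect_false(should_abandon(w, 1L, theta = 1.0))
  # nesting: abandoning at lower theta implies abandoning at higher theta
  set.seed(13)
  for (k in 1:20) {
    w$ability[1, 1] <- runif(1, 60, 140)
    dec <- sapply(c(0.75, 0.9, 1.0), function(th) should_abandon(w, 1L, th))
    expect_true(all(diff(dec) >= 0))
  }
})

test_that("search value is the best untried expectation, with tried fallback", {
  w <- make_mini_world(n_agents = 4, n_roles = 4, priors = "perfect",
                       abilities = matrix(c(50, 90, 110, 70), 4, 4,
                                          byrow = TRUE))
  # agent 1, nothing tried: best over untried = 110 * price (all prices equal)
  p <- role_prices(w, exclude = 1L)[1]
  expect_equal(search_value(w, 1L), 110 * p)
  # marking the best role tried weakly decreases the search value
  w$status[1, 3] <- 1L
  expect_lte(search_value(w, 1L), 110 * p)
  expect_equal(search_value(w, 1L), 90 * p)
  # all tried: best known alternative to the current occupation
  w$status[1, ] <- 1L
  w$status[1, 2] <- 2L
  w$occupation[1] <- 2L
  w$performing[1] <- 2L
  expect_equal(search_value(w, 1L), 110 * role_prices(w, exclude = 1L)[3])
})
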