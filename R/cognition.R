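#' Posterior probability that a role favours each type
#'
#' Combines the shared priors with the social counts for a role to infer how
#' likely the role is to truly favour type 0, type 1, or neither. The three
#' hypotheses have prior mass `q`, `q` and `1 - 2q`. Each observed
#' try-outcome among living agents is treated as a Bernoulli
#' "continue vs abandon" trial: under the neutral hypothesis both types
#' continue with probability 0.5; under "favours type t" the favoured type
#' continues with probability `0.5 + delta` and the other type with
#' `0.5 - delta`, where `delta = s/2` is derived from the prior effect size.
#' The posterior is the normalized prior-times-likelihood triple (binomial
#' coefficients cancel). Computation is done in log space, so large counts
#' are safe.
#'
#' With an egalitarian prior (`q = 0`) the posterior is (0, 0, 1) for any
#' counts: such agents ignore type-specific social information entirely.
#'
#' @param counts a data.frame (or list) with numeric fields `continuing0`,
#'   `abandoned0`, `continuing1`, `abandoned1`; vectorised over rows/roles.
#' @param priors a [priors_preset()] object.
#' @return Numeric matrix with one row per role and columns `A0`, `A1`, `An`
#'   summing to 1.
#' @examples
#' pr <- priors_preset(4)
#' posterior_role_favour(
#'   list(continuing0 = 8, abandoned0 = 2, continuing1 = 2, abandoned1 = 8), pr)
#' @export
posterior_role_favour <- function(counts, priors) {
  c0 <- as.numeric(counts$continuing0); a0 <- as.numeric(counts$abandoned0)
  c1 <- as.numeric(counts$continuing1); a1 <- as.numeric(counts$abandoned1)
  stopifnot(length(c0) == length(a0), length(c0) == length(c1),
            length(c0) == length(a1), all(c(c0, a0, c1, a1) >= 0))
  n <- length(c0)
  q <- priors$q
  if (q == 0) {
    out <- matrix(rep(c(0, 0, 1), each = n), n, 3L)
    colnames(out) <- c("A0", "A1", "An")
    return(out)
  }
  d <- priors$delta
  lp <- log(0.5 + d); lm <- log(0.5 - d); ln <- log(0.5)
  # aggregated exponents: kp outcomes support "favours 0", km support
  # "favours 1" (this form is exactly symmetric under a type-label swap)
  kp <- c0 + a1
  km <- a0 + c1
  ll0 <- kp * lp + km * lm                       # favours type 0
  ll1 <- km * lp + kp * lm                       # favours type 1
  lln <- (kp + km) * ln                          # neutral
  lw <- cbind(log(q) + ll0, log(q) + ll1, log1p(-2 * q) + lln)
  m <- apply(lw, 1L, max)
  w <- exp(lw - m)
  out <- w / rowSums(w)
  colnames(out) <- c("A0", "A1", "An")
  out
}

#' Expected payoff of an untried role
#'
#' An agent's payoff expectation for a role it has never performed: the
#' posterior-weighted mean ability, shifted up by `s` standard deviations if
#' the role favours the agent's own type and down by `s` if it favours the
#' other, multiplied by the current price. Writing `A_own` and `A_other` for
#' the posterior mass on the own-favour and other-favour hypotheses,
#' `E = price * (mu + s * sigma * (A_own - A_other))`.
#'
#' @param agent_type 0 or 1.
#' @param posterior matrix from [posterior_role_favour()] (or a length-3
#'   vector `A0, A1, An`); vectorised over rows.
#' @param priors a [priors_preset()] object (supplies `s`).
#' @param price role price(s), > 0.
#' @param config a [world_config()] (supplies `ability_mean`, `ability_sd`).
#' @return Numeric payoff estimate(s).
#' @examples
#' cfg <- world_config()
#' expected_payoff(0, c(1, 0, 0), priors_preset(2), price = 1, config = cfg)
#' @export
expected_payoff <- function(agent_type, posterior, priors, price, config) {
  if (is.null(dim(posterior))) posterior <- matrix(posterior, ncol = 3L)
  stopifnot(agent_type %in% c(0L, 1L), all(price > 0))
  a_own <- posterior[, 1L + agent_type]
  a_other <- posterior[, 2L - agent_type]
  price * (config$ability_mean + priors$s * config$ability_sd * (a_own - a_other))
}

# Value vector the agent assigns to every role at current prices/counts:
# tried roles at known ability x price, untried roles at the posterior
# expectation (perfect-knowledge agents use known ability everywhere).
# Prices exclude the acting agent's own occupancy contribution.
role_values <- function(world, agent) {
  cfg <- world$config
  prices <- role_prices(world, exclude = agent)
  vals <- world$ability[agent, ] * prices
  if (!cfg$perfect_knowledge) {
    untried <- world$status[agent, ] == ROLE_UNTRIED
    if (any(untried)) {
      sc <- social_counts(world)[untried, , drop = FALSE]
      post <- posterior_role_favour(sc, cfg$priors)
      vals[untried] <- expected_payoff(world$type[agent], post, cfg$priors,
                                       prices[untried], cfg)
    }
  }
  vals
}

#' Estimated payoff of further search
#'
#' The value an agent places on abandoning its current situation and
#' searching: the maximum expected payoff across roles it has not yet tried,
#' at current prices and social counts (perfect-knowledge agents use their
#' known ability instead of a posterior expectation). If every role has been
#' tried, the best known alternative is used: the maximum of ability times
#' price over all roles other than the current occupation.
#'
#' This quantity is the agent's threshold: occupations are adopted when the
#' realized payoff exceeds it, and abandoned when the realized payoff drops
#' below a fraction `theta` of it.
#'
#' @param world a `role_world`.
#' @param agent agent index.
#' @return A single payoff estimate.
#' @export
search_value <- function(world, agent) {
  vals <- role_values(world, agent)
  untried <- world$status[agent, ] == ROLE_UNTRIED
  if (any(untried)) return(max(vals[untried]))
  occ <- world$occupation[agent]
  if (!is.na(occ)) vals[occ] <- -Inf
  max(vals)
}

#' Choose the role with the highest expected payoff
#'
#' Candidate roles are valued at known ability times price when tried and at
#' the posterior payoff expectation when untried; the argmax is returned,
#' with exact ties (relative tolerance `config$tie_tol`) broken uniformly at
#' random. While an agent is under forced exploration (fewer than
#' `forced_min_roles` roles tried), candidates are restricted to untried
#' roles.
#'
#' @param world a `role_world`.
#' @param agent agent index.
#' @return A role id (1-based).
#' @export
choose_role <- function(world, agent) {
  cfg <- world$config
  vals <- role_values(world, agent)
  tried_n <- sum(world$status[agent, ] != ROLE_UNTRIED)
  if (tried_n < cfg$forced_min_roles) {
    vals[world$status[agent, ] != ROLE_UNTRIED] <- -Inf
  }
  best <- max(vals)
  if (!is.finite(best)) stop("no candidate roles available", call. = FALSE)
  cand <- which(vals >= best - cfg$tie_tol * abs(best))
  if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
}

#' Should an occupied agent abandon its occupation?
#'
#' `TRUE` iff the agent's current realized payoff (known ability times the
#' current price of its occupation) is strictly below `theta` times the
#' estimated payoff of further search ([search_value()]). `theta = 1` means
#' agents move whenever anything looks better; lower values model inertia
#' (costs of retraining etc.).
#'
#' @param world a `role_world`.
#' @param agent agent index; must have an occupation.
#' @param theta threshold fraction in (0, 1]; defaults to the world's
#'   configured value.
#' @return Logical scalar.
#' @export
should_abandon <- function(world, agent, theta = world$config$theta) {
  occ <- world$occupation[agent]
  if (is.na(occ)) stop("agent has no occupation", call. = FALSE)
  price <- role_prices(world, exclude = agent)[occ]
  payoff <- realized_payoff(world$ability[agent, occ], price)
  payoff < theta * search_value(world, agent)
}
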