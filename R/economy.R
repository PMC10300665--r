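#' Scarcity price of a role
#'
#' Goods are priced by scarcity: the fewer living agents currently perform a
#' role, the more its output is worth, which pushes the population towards a
#' division of labour. The price is
#' `price_scale * (n_agents / n_roles) / (n_performing + 1)`:
#' strictly positive (empty roles stay finite and attractive), strictly
#' decreasing in occupancy, and normalised so that uniform occupancy gives a
#' price of about `price_scale`.
#'
#' @param n_performing number of living agents currently performing the role
#'   (vectorised).
#' @param config a [world_config()].
#' @return Numeric price(s), same length as `n_performing`.
#' @examples
#' cfg <- world_config()
#' compute_price(0, cfg)            # empty role: 1000/60
#' compute_price(c(5, 20), cfg)     # scarcer role is pricier
#' @export
compute_price <- function(n_performing, config) {
  stopifnot(all(n_performing >= 0))
  config$price_scale * (config$n_agents / config$n_roles) / (n_performing + 1)
}

#' Realized payoff of performing a role
#'
#' An agent's payoff is its true ability in the role multiplied by the price
#' of the role's goods at the moment it acts.
#'
#' @param ability true ability (ability units); vectorised.
#' @param price role price (> 0); vectorised.
#' @return `ability * price`.
#' @examples
#' realized_payoff(115, 2)
#' @export
realized_payoff <- function(ability, price) {
  stopifnot(all(price > 0))
  ability * price
}
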