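# Shared fixtures: the classic utility/weighting parameter set with the
# per-condition (V, c) fits, and the fitted opponent belief.

tk_continuous <- function(...) prospect_params(c = 2.1, V = 1.27, ...)
tk_discrete <- function(...) prospect_params(c = 0.3, V = 1.43, ...)
fitted_belief <- function() opponent_belief(mu = 2.01, sigma = 0.97)

clock_cont <- function(start = 100) price_clock(start, duration = 5, dt = 0.05)
clock_disc <- function(start = 100) price_clock(start, duration = 5, dt = 0.5)

# a small grid of valid parameter sets for property loops
param_grid <- function() {
  list(
    tk_continuous(),
    tk_discrete(),
    prospect_params(alpha = 0.7, beta = 0.95, lambda = 1.5, gamma = 0.5,
                    delta = 0.9, c = 1, V = 2),
    prospect_params(gamma = 1, delta = 1, c = 0.1, V = 1.1),
    tk_continuous(value_anchor = "current_price"),
    tk_discrete(wait_exponent = "gamma")
  )
}
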