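#' Decision parameters of the prospect-theory bidder
#'
#' The agent's single-step choice between "bid now" and "wait one step"
#' combines a reference-dependent power utility (exponents `alpha` on gains,
#' `beta` on losses, loss aversion `lambda`), inverse-S probability weighting
#' with separate curvature for gain prospects (`gamma`) and loss prospects
#' (`delta`), a softmax sensitivity `c`, and a perceived-value multiplier `V`
#' converting the auction's price scale into the item's worth to the bidder.
#'
#' Utility and weighting exponents default to the classic cumulative
#' prospect-theory estimates (alpha = beta = 0.88, lambda = 2.25,
#' gamma = 0.61, delta = 0.69). `c` and `V` have no universal defaults; the
#' fitted per-condition values used in the reproduction configurations are
#' `V = 1.27, c = 2.1` (continuous clock) and `V = 1.43, c = 0.3` (discrete).
#'
#' @param alpha,beta Utility exponents for gains/losses, in (0, 1].
#' @param lambda Loss-aversion coefficient, >= 1.
#' @param gamma,delta Weighting exponents for gain/loss prospects, in
#'   (0.28, 1] (the regime where the weighting function is monotone).
#' @param c Softmax sensitivity, >= 0; 0 gives random 50/50 choice.
#' @param V Perceived-value multiplier, > 0.
#' @param value_anchor What `V` multiplies to give the perceived dollar value
#'   `P` of the stock: `"start_price"` (P = V * C(0), the default) or
#'   `"current_price"` (P = V * C(t)).
#' @param softmax_sign `"corrected"` (probability increases with an option's
#'   utility, the default) or `"as_printed"` (sign-flipped audit variant).
#' @param wait_exponent Which weighting exponent applies to the wait
#'   prospect: `"by_sign"` (gamma when its net utility is >= 0, delta
#'   otherwise; default), `"gamma"`, or `"delta"`.
#' @return An object of class `prospect_params`.
#' @seealso [pt_utility()], [pt_weight()], [bid_probability()]
#' @export
prospect_params <- function(alpha = 0.88, beta = 0.88, lambda = 2.25,
                            gamma = 0.61, delta = 0.69, c = 2.1, V = 1.27,
                            value_anchor = c("start_price", "current_price"),
                            softmax_sign = c("corrected", "as_printed"),
                            wait_exponent = c("by_sign", "gamma", "delta")) {
  value_anchor <- match.arg(value_anchor)
  softmax_sign <- match.arg(softmax_sign)
  wait_exponent <- match.arg(wait_exponent)
  stopifnot(alpha > 0, alpha <= 1, beta > 0, beta <= 1, lambda >= 1,
            gamma > 0.28, gamma <= 1, delta > 0.28, delta <= 1,
            c >= 0, V > 0)
  structure(
    list(alpha = alpha, beta = beta, lambda = lambda, gamma = gamma,
         delta = delta, c = c, V = V, value_anchor = value_anchor,
         softmax_sign = softmax_sign, wait_exponent = wait_exponent),
    class = "prospect_params"
  )
}

#' @export
print.prospect_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<prospect_params> alpha=%.3g beta=%.3g lambda=%.3g gamma=%.3g ",
    "delta=%.3g c=%.3g V=%.3g\n  anchor=%s softmax=%s wait_exponent=%s\n"),
    x$alpha, x$beta, x$lambda, x$gamma, x$delta, x$c, x$V,
    x$value_anchor, x$softmax_sign, x$wait_exponent))
  invisible(x)
}

#' Believed bid-time distribution of the competitors
#'
#' Each player assumes the other players' bid times are normally distributed,
#' N(mu, sigma), truncated to the auction window `[0, duration]` and
#' renormalised (bids outside the auction are impossible). The fitted values
#' from the laboratory data are mu = 2.01 s, sigma = 0.97 s, with 2
#' opponents in a three-player group.
#'
#' @param mu Mean believed bid time, seconds.
#' @param sigma SD of believed bid time, seconds; > 0.
#' @param n_opponents Number of competitors (default 2).
#' @return An object of class `opponent_belief`.
#' @export
opponent_belief <- function(mu = 2.01, sigma = 0.97, n_opponents = 2L) {
  stopifnot(is.numeric(mu), sigma > 0, n_opponents >= 1)
  structure(list(mu = mu, sigma = sigma, n_opponents = as.integer(n_opponents)),
            class = "opponent_belief")
}

#' Truncated-normal CDF of a believed bid time
#'
#' @param belief An [opponent_belief()].
#' @param duration Auction duration in seconds; the normal is truncated to
#'   `[0, duration]`.
#' @return A vectorised CDF function `F(t)` with `F(t) = 0` for `t <= 0` and
#'   `F(t) = 1` for `t >= duration`.
#' @export
belief_cdf <- function(belief, duration = 5) {
  stopifnot(inherits(belief, "opponent_belief"), duration > 0)
  lo <- stats::pnorm(0, belief$mu, belief$sigma)
  hi <- stats::pnorm(duration, belief$mu, belief$sigma)
  if (hi <= lo) stop("belief has no mass inside the auction window", call. = FALSE)
  function(t) {
    t <- pmin(pmax(t, 0), duration)
    (stats::pnorm(t, belief$mu, belief$sigma) - lo) / (hi - lo)
  }
}

#' Prospect-theory value function
#'
#' Power utility with a kink at the zero-dollar reference point:
#' `x^alpha` for gains, `-lambda * (-x)^beta` for losses, 0 at 0.
#'
#' @param x Signed dollar amount(s); gains positive, losses negative.
#' @param params A [prospect_params()].
#' @return Utility in utils (vectorised).
#' @export
pt_utility <- function(x, params) {
  stopifnot(inherits(params, "prospect_params"), all(is.finite(x)))
  out <- numeric(length(x))
  pos <- x > 0
  neg <- x < 0
  out[pos] <- x[pos]^params$alpha
  out[neg] <- -params$lambda * (-x[neg])^params$beta
  out
}

#' Inverse-S probability weighting function
#'
#' The canonical two-parameter form
#' `w(p) = p^e / (p^e + (1 - p)^e)^(1/e)`, applied with exponent
#' `e = gamma` for gain prospects and `e = delta` for loss prospects. For
#' `e < 1` it overweights small probabilities and underweights large ones
#' (inverse-S); `e = 1` is the identity. Exact at the endpoints:
#' `w(0) = 0`, `w(1) = 1`.
#'
#' @param p Probability vector in \[0, 1\].
#' @param exponent Curvature exponent in the monotone regime (0.28, 1].
#' @return Decision weight(s) in \[0, 1\].
#' @export
pt_weight <- function(p, exponent) {
  stopifnot(is.numeric(exponent), length(exponent) %in% c(1L, length(p)),
            all(exponent > 0.28), all(exponent <= 1))
  if (any(p < 0 | p > 1 | !is.finite(p)))
    stop("`p` must lie in [0, 1]", call. = FALSE)
  w <- p^exponent / (p^exponent + (1 - p)^exponent)^(1 / exponent)
  w[p == 0] <- 0
  w[p == 1] <- 1
  w
}

#' Probability that at least one competitor bids in the next window
#'
#' With `q = F(t + dt) - F(t)` the believed chance that one given competitor
#' bids in `(t, t + dt]`, the chance that *any* of `n_opponents` independent
#' competitors does is `r = 1 - (1 - q)^n_opponents`.
#'
#' @param F A CDF function (e.g. from [belief_cdf()]), non-decreasing.
#' @param t Window start time(s), seconds.
#' @param dt Window width, seconds; > 0.
#' @param n_opponents Number of competitors.
#' @return Hazard probability/ies `r` in \[0, 1\].
#' @export
competitor_hazard <- function(F, t, dt, n_opponents = 2L) {
  stopifnot(is.function(F), dt > 0, n_opponents >= 1)
  q <- F(t + dt) - F(t)
  if (any(q < -1e-12))
    stop("`F` is decreasing over the window; not a valid CDF", call. = FALSE)
  q <- pmin(pmax(q, 0), 1)
  1 - (1 - q)^n_opponents
}

#' Net utility of bidding immediately
#'
#' Bidding now is riskless: the player gains the stock, perceived value `P`,
#' and pays the current asking price, so the net utility is
#' `U(P) + U(-cost)`.
#'
#' @param P Perceived dollar value of the stock.
#' @param cost Current asking price, dollars, >= 0.
#' @param params A [prospect_params()].
#' @return Net utility (vectorised).
#' @export
net_utility_now <- function(P, cost, params) {
  stopifnot(all(cost >= 0))
  pt_utility(P, params) + pt_utility(-cost, params)
}

#' Weighted net utility of waiting one step
#'
#' Waiting promises the same stock at the lower next-step price but succeeds
#' only if no competitor bids first (probability `1 - r`): the weighted
#' utility is `w(1 - r) * (U(P) + U(-cost_next))`, the losing branch carrying
#' zero gain and zero loss. The weighting exponent is chosen by the sign of
#' the bracketed net utility (gamma if >= 0, delta otherwise) unless fixed
#' via `params$wait_exponent`.
#'
#' @param P Perceived dollar value of the stock.
#' @param cost_next Asking price after the next decrement, dollars.
#' @param r Competitor hazard over the coming window, in \[0, 1\].
#' @param params A [prospect_params()].
#' @return Weighted net utility (vectorised).
#' @export
net_utility_wait <- function(P, cost_next, r, params) {
  if (any(r < 0 | r > 1)) stop("`r` must lie in [0, 1]", call. = FALSE)
  bracket <- pt_utility(P, params) + pt_utility(-cost_next, params)
  e <- switch(params$wait_exponent,
              gamma = rep(params$gamma, length(bracket)),
              delta = rep(params$delta, length(bracket)),
              by_sign = ifelse(bracket >= 0, params$gamma, params$delta))
  pt_weight(rep_len(1 - r, length(bracket)), e) * bracket
}

#' Softmax probability of bidding now
#'
#' Converts the two weighted utilities into a choice probability,
#' `Pr(bid now) = exp(c u_now) / (exp(c u_now) + exp(c u_wait))`, computed in
#' a numerically stable logistic form. `c = 0` yields 0.5 regardless of the
#' utilities; large `c` makes the higher-utility option near-certain. The
#' `"as_printed"` sign variant negates the exponent.
#'
#' @param u_now,u_wait Net utilities of bidding now / waiting (vectorised).
#' @param params A [prospect_params()] (supplies `c` and the sign
#'   convention).
#' @return Probability/ies of bidding now; complements sum to 1 exactly.
#' @export
bid_probability <- function(u_now, u_wait, params) {
  stopifnot(all(is.finite(u_now)), all(is.finite(u_wait)))
  sgn <- if (params$softmax_sign == "corrected") 1 else -1
  z <- sgn * params$c * (u_now - u_wait)
  # evaluate on the tail side so Pr(now) + Pr(wait) is exactly 1
  q <- stats::plogis(-abs(z))
  ifelse(z >= 0, 1 - q, q)
}
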