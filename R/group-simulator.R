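#' Per-step bid-time distribution of a single agent
#'
#' Walks the price clock step by step. At step k (time `t_k = k * dt`, price
#' already decremented) the agent compares bidding now at `C(t_k)` against
#' waiting for `C(t_k + dt)` at the risk of a competitor bid in
#' `(t_k, t_k + dt]`; the softmax choice probability is the discrete-time
#' hazard `h_k`. Standard transformations give the bid-step density
#' `g_k = h_k * prod_{j<k}(1 - h_j)`, the CDF `G_k = sum_{j<=k} g_j`, and the
#' survival mass `1 - G_K` of never bidding (the clock reaching $0 unbid).
#'
#' At the final step the clock has reached $0 and the believed competitor
#' distribution (truncated to the auction window) has no remaining mass, so
#' "wait" degenerates to the same zero-cost prospect as "bid".
#'
#' @param params A [prospect_params()].
#' @param belief An [opponent_belief()].
#' @param clock A [price_clock()].
#' @return An object of class `bid_distribution`: list with `hazards`,
#'   `density`, `cdf`, `survival_final`, `times`, and the inputs.
#' @export
bid_time_distribution <- function(params, belief, clock) {
  stopifnot(inherits(params, "prospect_params"),
            inherits(belief, "opponent_belief"),
            inherits(clock, "price_clock"))
  n <- clock$n_steps
  k <- seq_len(n)
  t_k <- k * clock$dt
  cost_now <- price_at(clock, k)
  cost_next <- c(cost_now[-1], 0)

  F <- belief_cdf(belief, clock$duration)
  r <- competitor_hazard(F, t_k, clock$dt, belief$n_opponents)

  P <- switch(params$value_anchor,
              start_price = rep(params$V * clock$start_price, n),
              current_price = params$V * cost_now)

  u_now <- net_utility_now(P, cost_now, params)
  u_wait <- net_utility_wait(P, cost_next, r, params)
  if (any(!is.finite(u_now)) || any(!is.finite(u_wait)))
    stop(sprintf("non-finite utility at step %d",
                 which(!is.finite(u_now) | !is.finite(u_wait))[1]), call. = FALSE)
  h <- bid_probability(u_now, u_wait, params)

  surv_before <- cumprod(c(1, 1 - h))[seq_len(n)]  # prob still waiting before step k
  g <- h * surv_before
  G <- cumsum(g)
  structure(
    list(hazards = h, density = g, cdf = G,
         survival_final = prod(1 - h), times = t_k,
         params = params, belief = belief, clock = clock),
    class = "bid_distribution"
  )
}

#' @export
print.bid_distribution <- function(x, ...) {
  cat(sprintf("<bid_distribution> %d steps; P(bid) = %.3f, P(never) = %.3f\n",
              length(x$hazards), x$cdf[length(x$cdf)], x$survival_final))
  invisible(x)
}

#' CDF of the earliest bid among concurrent players
#'
#' The winning bid is the minimum of the players' independent bid times;
#' its CDF is `1 - (1 - G(t))^n_players` pointwise.
#'
#' @param G A numeric CDF vector, or a `bid_distribution` (its `cdf` is
#'   used).
#' @param n_players Number of concurrent players (default 3).
#' @return Numeric vector, the group-minimum CDF.
#' @export
winning_time_cdf <- function(G, n_players = 3L) {
  if (inherits(G, "bid_distribution")) G <- G$cdf
  stopifnot(is.numeric(G), all(G >= 0 & G <= 1), n_players >= 1)
  if (any(diff(G) < -1e-12)) stop("`G` must be non-decreasing", call. = FALSE)
  1 - (1 - G)^n_players
}

# Draw one bid step per player from (density, survival); n + 1 encodes "never".
draw_bid_steps <- function(dist, n_players) {
  n <- length(dist$density)
  prob <- c(dist$density, dist$survival_final)
  # guard tiny negative rounding
  prob[prob < 0] <- 0
  sample.int(n + 1L, n_players, replace = TRUE, prob = prob)
}

#' Monte-Carlo simulation of three-player Dutch auctions
#'
#' For each auction a start price is drawn, every player's bid step is drawn
#' independently from their per-step hazard process (each active player bids
#' at step k with probability `h_k`), and the earliest bidder wins at the
#' current clock price; simultaneous bids are broken uniformly at random.
#' Auctions in which no player bids before the clock reaches $0 are retained
#' as censored records (`winner = NA`).
#'
#' @param n_auctions Number of auctions to simulate.
#' @param params A [prospect_params()] shared by all players, or a list of
#'   one per player.
#' @param belief An [opponent_belief()].
#' @param dt Clock step in seconds (0.05 continuous, 0.5 discrete).
#' @param start_price_range Uniform start-price interval (model study
#'   default $80--$120).
#' @param duration Auction length, seconds.
#' @param n_players Players per auction (default 3).
#' @param unit_mode,unit_range Passed to [sample_unit_quantity()].
#' @param condition Label stored in the output (defaults to
#'   `"continuous"`/`"discrete"` by `dt`).
#' @param seed Optional integer; if given, `set.seed(seed)` is called first.
#' @return A data.frame of class `auction_outcomes` with columns
#'   `auction_id`, `condition`, `start_price`, `unit_quantity`,
#'   `winning_step`, `winning_price`, `winner`, `n_tied` (NA step/price/
#'   winner for censored auctions).
#' @examples
#' out <- simulate_auctions(50, prospect_params(c = 2.1, V = 1.27),
#'                          opponent_belief(), dt = 0.05, seed = 1)
#' summarize_simulation(out)
#' @export
simulate_auctions <- function(n_auctions, params, belief, dt,
                              start_price_range = c(80, 120), duration = 5,
                              n_players = 3L, unit_mode = "fixed",
                              unit_range = c(50L, 150L),
                              condition = NULL, seed = NULL) {
  stopifnot(n_auctions >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(params, "prospect_params")) {
    params <- rep(list(params), n_players)
  }
  stopifnot(length(params) == n_players,
            all(vapply(params, inherits, TRUE, "prospect_params")))
  if (is.null(condition))
    condition <- if (dt <= 0.1) "continuous" else "discrete"
  homogeneous <- length(unique(vapply(params, function(p)
    paste(unlist(p), collapse = "|"), character(1)))) == 1L

  start_price <- sample_start_price(n_auctions, start_price_range)
  units <- sample_unit_quantity(n_auctions, unit_mode, unit_range)
  n_steps <- round(duration / dt)

  winning_step <- rep(NA_integer_, n_auctions)
  winning_price <- rep(NA_real_, n_auctions)
  winner <- rep(NA_integer_, n_auctions)
  n_tied <- rep(1L, n_auctions)

  for (i in seq_len(n_auctions)) {
    cl <- price_clock(start_price[i], duration, dt)
    if (homogeneous) {
      dist <- bid_time_distribution(params[[1]], belief, cl)
      steps <- draw_bid_steps(dist, n_players)
    } else {
      steps <- vapply(params, function(p)
        draw_bid_steps(bid_time_distribution(p, belief, cl), 1L), integer(1))
    }
    m <- min(steps)
    if (m <= n_steps) {
      tied <- which(steps == m)
      winning_step[i] <- m
      winning_price[i] <- price_at(cl, m)
      winner[i] <- if (length(tied) == 1L) tied else sample(tied, 1L)
      n_tied[i] <- length(tied)
    } else {
      n_tied[i] <- 0L
    }
  }

  structure(
    data.frame(auction_id = seq_len(n_auctions), condition = condition,
               start_price = start_price, unit_quantity = units,
               winning_step = winning_step, winning_price = winning_price,
               winner = winner, n_tied = n_tied,
               stringsAsFactors = FALSE),
    class = c("auction_outcomes", "data.frame")
  )
}

#' Summary of simulated auction outcomes
#'
#' Mean and SD of the winning price and winning step per condition, counting
#' censored (no-bid) auctions separately; censored records are excluded from
#' the moments.
#'
#' @param outcomes An `auction_outcomes` data.frame from
#'   [simulate_auctions()].
#' @return A data.frame with one row per condition: `condition`, `n`,
#'   `n_decided`, `n_censored`, `mean_price`, `sd_price`, `mean_step`,
#'   `sd_step`.
#' @export
summarize_simulation <- function(outcomes) {
  stopifnot(is.data.frame(outcomes),
            all(c("condition", "winning_price", "winning_step") %in% names(outcomes)))
  decided <- !is.na(outcomes$winning_price)
  if (!any(decided))
    stop("no decided auctions: every record is censored", call. = FALSE)
  parts <- split(outcomes, outcomes$condition)
  out <- do.call(rbind, lapply(parts, function(d) {
    dd <- d[!is.na(d$winning_price), , drop = FALSE]
    data.frame(condition = d$condition[1], n = nrow(d), n_decided = nrow(dd),
               n_censored = nrow(d) - nrow(dd),
               mean_price = mean(dd$winning_price),
               sd_price = stats::sd(dd$winning_price),
               mean_step = mean(dd$winning_step),
               sd_step = stats::sd(dd$winning_step),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
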