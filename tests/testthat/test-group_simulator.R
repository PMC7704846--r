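test_that("a zero-sensitivity agent is a per-step coin flip", {
  d <- bid_time_distribution(prospect_params(c = 0, V = 1.27),
                             fitted_belief(), clock_disc())
  expect_equal(d$hazards, rep(0.5, 10))
  expect_equal(d$cdf, 1 - 0.5^(1:10))
  expect_equal(d$survival_final, 0.5^10)
})

test_that("hazard -> density/CDF transformations close to total mass one", {
  bel <- fitted_belief()
  for (par in param_grid()) {
    for (cl in list(clock_cont(93.7), clock_disc(118))) {
      d <- bid_time_distribution(par, bel, cl)
      expect_true(all(d$hazards >= 0 & d$hazards <= 1))
      expect_true(all(d$density >= 0))
      expect_true(all(diff(d$cdf) >= -1e-12))
      expect_equal(d$density,
                   d$hazards * cumprod(c(1, 1 - d$hazards))[seq_along(d$hazards)])
      expect_lt(abs(sum(d$density) + d$survival_final - 1), 1e-12)
      expect_lt(abs(d$cdf[length(d$cdf)] + d$survival_final - 1), 1e-12)
    }
  }
})

test_that("density matches a direct sequential simulation of single agents", {
  # independent oracle: walk the clock step by step, flipping a Bernoulli
  # coin with the step hazard, for many agents
  d <- bid_time_distribution(tk_discrete(), fitted_belief(), clock_disc())
  n_agents <- 2e4
  set.seed(101)
  steps <- rep(NA_integer_, n_agents)
  for (a in seq_len(n_agents)) {
    for (k in seq_along(d$hazards)) {
      if (runif(1) < d$hazards[k]) { steps[a] <- k; break }
    }
  }
  emp_cdf <- vapply(seq_along(d$hazards),
                    function(k) mean(!is.na(steps) & steps <= k), numeric(1))
  expect_lt(max(abs(emp_cdf - d$cdf)), 3 * 0.5 / sqrt(n_agents) * 2)
  expect_lt(abs(mean(is.na(steps)) - d$survival_final), 0.01)
})

test_that("group-minimum CDF follows 1 - (1 - G)^n", {
  expect_equal(winning_time_cdf(c(0, 1), 3), c(0, 1))
  expect_equal(winning_time_cdf(0.5, 3), 0.875)
  G <- c(0.1, 0.25, 0.6, 0.9, 1)
  expect_equal(winning_time_cdf(G, 2), 1 - (1 - G)^2)
  expect_error(winning_time_cdf(c(0.5, 0.3), 3), "non-decreasing")

  # brute-force oracle: empirical minimum of 3 independent draws
  d <- bid_time_distribution(tk_discrete(), fitted_belief(), clock_disc())
  set.seed(77)
  n_rep <- 1e5
  draws <- matrix(sample.int(11, 3 * n_rep, replace = TRUE,
                             prob = c(d$density, d$survival_final)),
                  nrow = 3)
  mins <- apply(draws, 2, min)
  emp <- vapply(1:10, function(k) mean(mins <= k), numeric(1))
  expect_lt(max(abs(emp - winning_time_cdf(d, 3))), 0.005)
})

test_that("simulated auctions respect the clock and symmetric win shares", {
  sim <- simulate_auctions(3000, tk_discrete(), fitted_belief(), dt = 0.5,
                           seed = 5)
  dec <- sim[!is.na(sim$winning_price), ]
  expect_gt(nrow(dec), 2500)
  # winning price is the clock price at the winning step
  expect_equal(dec$winning_price,
               dec$start_price * (1 - dec$winning_step / 10))
  expect_true(all(dec$winner %in% 1:3))
  expect_true(all(dec$n_tied >= 1))
  expect_true(all(sim$n_tied[is.na(sim$winning_price)] == 0L))
  # symmetric players win ~ 1/3 each
  shares <- tabulate(dec$winner, 3) / nrow(dec)
  se <- sqrt(1 / 3 * 2 / 3 / nrow(dec))
  expect_true(all(abs(shares - 1 / 3) < 3 * se))
})

test_that("censored auctions are retained with empty outcome fields", {
  # low perceived value + current-price anchor: agents only flip the fair
  # coin at the terminal $0 step, so ~ (1/2)^3 of auctions end unbid
  par <- prospect_params(c = 30, V = 0.5, value_anchor = "current_price")
  sim <- simulate_auctions(400, par, fitted_belief(), dt = 0.5, seed = 8)
  cens <- is.na(sim$winning_price)
  expect_gt(sum(cens), 10)
  expect_true(all(is.na(sim$winning_step[cens])))
  expect_true(all(is.na(sim$winner[cens])))
  s <- summarize_simulation(sim)
  expect_identical(s$n_decided + s$n_censored, s$n)
  expect_identical(s$n_censored, sum(cens))
})

test_that("simulation summary aggregates decided auctions only", {
  out <- data.frame(condition = "discrete",
                    winning_price = c(40, 60, NA),
                    winning_step = c(4, 6, NA))
  s <- summarize_simulation(out)
  expect_equal(s$mean_price, 50)
  expect_equal(s$sd_price, sqrt(200))
  expect_identical(s$n_censored, 1L)

  one <- data.frame(condition = "x", winning_price = 42.5, winning_step = 3)
  expect_equal(summarize_simulation(one)$mean_price, 42.5)

  allc <- data.frame(condition = "x", winning_price = NA_real_,
                     winning_step = NA_integer_)
  expect_error(summarize_simulation(allc), "censored")
})

test_that("summary means are stable across seeds", {
  m <- vapply(1:4, function(s) {
    sim <- simulate_auctions(1000, tk_discrete(), fitted_belief(), dt = 0.5,
                             seed = s)
    summarize_simulation(sim)$mean_price
  }, numeric(1))
  # winning-price SD ~ 9, so SE of a 1000-auction mean ~ 0.3
  expect_lt(max(m) - min(m), 2 * 4 * 0.3)
  expect_true(all(m > 40 & m < 70))
})

test_that("higher sensitivity c shifts winning steps earlier when bidding pays early", {
  # V = 3 makes bidding-now the better option from the first step on the
  # discrete clock, so sharper softmax concentrates bids earlier
  bel <- fitted_belief()
  cl <- clock_disc(100)
  d1 <- bid_time_distribution(prospect_params(c = 0.3, V = 3), bel, cl)
  expect_gt(d1$hazards[1], 0.5)  # premise: u_now > u_wait early
  G_by_c <- sapply(c(0.3, 1, 3, 10), function(cc) {
    winning_time_cdf(bid_time_distribution(prospect_params(c = cc, V = 3),
                                           bel, cl), 3)
  })
  # first-order stochastic dominance across the c grid
  for (j in seq_len(ncol(G_by_c) - 1))
    expect_true(all(G_by_c[, j + 1] >= G_by_c[, j] - 1e-12))
})

test_that("heterogeneous player parameters are honoured", {
  eager <- prospect_params(c = 5, V = 1.8)
  shy <- prospect_params(c = 5, V = 1.05)
  sim <- simulate_auctions(300, list(eager, shy, shy), fitted_belief(),
                           dt = 0.5, seed = 12)
  dec <- sim[!is.na(sim$winner), ]
  # the high-valuation player bids earlier, so wins far more than 1/3
  expect_gt(mean(dec$winner == 1), 0.5)
})
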