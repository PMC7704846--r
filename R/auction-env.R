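#' Descending price clock for a Dutch auction
#'
#' A Dutch auction opens at a start price that falls linearly to $0 over a
#' fixed duration. The clock advances in steps of `dt` seconds; after the
#' k-th step the asking price is `start_price * (1 - k / n_steps)`. The two
#' laboratory step rates are `dt = 0.05` s ("continuous", 100 decrements over
#' 5 s) and `dt = 0.5` s ("discrete", 10 decrements over 5 s).
#'
#' @param start_price Opening price in dollars; must be positive.
#' @param duration Auction length in seconds (default 5).
#' @param dt Seconds between price decrements; `duration / dt` must be a
#'   whole number of steps.
#' @return An object of class `price_clock` with fields `start_price`,
#'   `duration`, `dt` and `n_steps`.
#' @examples
#' cl <- price_clock(100, dt = 0.5)
#' price_at(cl, 5)   # $50 at the midpoint
#' price_at(cl, 10)  # exhausted to $0
#' @export
price_clock <- function(start_price, duration = 5, dt = 0.5) {
  stopifnot(is.numeric(start_price), length(start_price) == 1L, start_price > 0,
            is.numeric(duration), duration > 0, is.numeric(dt), dt > 0)
  n_steps <- round(duration / dt)
  if (abs(n_steps - duration / dt) > 1e-9 || n_steps < 1)
    stop("`duration` must be a whole number of `dt` steps", call. = FALSE)
  structure(
    list(start_price = start_price, duration = duration, dt = dt,
         n_steps = as.integer(n_steps)),
    class = "price_clock"
  )
}

#' @export
print.price_clock <- function(x, ...) {
  cat(sprintf("<price_clock> $%.2f -> $0 over %gs in %d steps of %gs\n",
              x$start_price, x$duration, x$n_steps, x$dt))
  invisible(x)
}

#' Asking price after a given clock step
#'
#' The price is evaluated *after* the step's decrement, so the first decision
#' of the auction is taken at `start_price * (1 - 1/n_steps)` and the final
#' step always reaches exactly $0.
#'
#' @param clock A [price_clock()].
#' @param step_index 1-based step index (vectorised); each element must lie
#'   in `1..n_steps`.
#' @return Price(s) in dollars.
#' @export
price_at <- function(clock, step_index) {
  stopifnot(inherits(clock, "price_clock"))
  if (length(step_index) == 0L) return(numeric(0))
  if (any(step_index != round(step_index)))
    stop("`step_index` must be whole numbers", call. = FALSE)
  if (any(step_index < 1L | step_index > clock$n_steps))
    stop(sprintf("`step_index` out of range 1..%d", clock$n_steps), call. = FALSE)
  clock$start_price * (1 - step_index / clock$n_steps)
}

#' Draw auction start prices
#'
#' Start prices are sampled uniformly on a dollar interval: $50--$150 in the
#' laboratory experiments, $80--$120 in the model-simulation study. Draws are
#' continuous (real-valued dollars); rounding to cents happens only at I/O.
#' Seed R's RNG (`set.seed()`) beforehand for reproducibility.
#'
#' @param n Number of draws.
#' @param range Length-2 numeric, `c(low, high)` with `low < high`.
#' @return Numeric vector of start prices.
#' @export
sample_start_price <- function(n, range = c(50, 150)) {
  stopifnot(length(range) == 2L, is.numeric(range), range[1] < range[2], n >= 0)
  stats::runif(n, range[1], range[2])
}

#' Draw per-auction unit quantities
#'
#' The stock on offer is either fixed at 100 units (fixed-unit experiment) or
#' an integer drawn uniformly from 50..150 (variable-unit experiment).
#'
#' @param n Number of draws.
#' @param mode `"fixed"` or `"uniform"`.
#' @param range Inclusive integer bounds for `"uniform"` mode.
#' @param fixed Quantity returned in `"fixed"` mode.
#' @return Integer vector of unit quantities.
#' @export
sample_unit_quantity <- function(n, mode = c("fixed", "uniform"),
                                 range = c(50L, 150L), fixed = 100L) {
  mode <- match.arg(mode)
  if (mode == "fixed") return(rep(as.integer(fixed), n))
  stopifnot(length(range) == 2L, range[1] < range[2])
  as.integer(sample(seq.int(range[1], range[2]), n, replace = TRUE))
}

#' Normalise discrete-condition winning steps
#'
#' The discrete clock has 10 steps against the continuous clock's 100; for
#' cross-condition comparison discrete steps are rescaled by multiplication
#' by 11, mapping 1..10 onto 11..110. This is an I/O-level transform used in
#' the analyses only; it never enters the decision model.
#'
#' @param step Integer step(s) in 1..10.
#' @return `step * 11`.
#' @export
normalize_discrete_step <- function(step) {
  if (length(step) && (any(step != round(step)) || any(step < 1 | step > 10)))
    stop("`step` must be whole numbers in 1..10", call. = FALSE)
  as.integer(step) * 11L
}

#' Experiment design for the three-player auction platform
#'
#' Captures the session structure of the laboratory studies: 11 three-person
#' groups play 1 practice block plus 5 testing blocks of 12 trials in each of
#' two step-rate conditions, with a $250 budget and a 500-unit warehouse per
#' player refreshed each block.
#'
#' @param n_groups Number of three-person groups (default 11).
#' @param players_per_group Players per group (default 3).
#' @param n_blocks Testing blocks per condition (default 5); one practice
#'   block (block 0) is always prepended by the generator.
#' @param trials_per_block Auctions per block (default 12).
#' @param start_price_range Uniform start-price interval in dollars.
#' @param unit_mode `"fixed"` (100 units each trial) or `"uniform"`
#'   (integer 50--150 per trial).
#' @param budget Hypothetical funds per player per block, dollars.
#' @param warehouse_capacity Warehouse size in units; a full player can no
#'   longer win.
#' @param duration,dt_continuous,dt_discrete Clock timing in seconds.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_groups = 11L, players_per_group = 3L,
                              n_blocks = 5L, trials_per_block = 12L,
                              start_price_range = c(50, 150),
                              unit_mode = c("fixed", "uniform"),
                              budget = 250, warehouse_capacity = 500L,
                              duration = 5, dt_continuous = 0.05,
                              dt_discrete = 0.5) {
  unit_mode <- match.arg(unit_mode)
  stopifnot(n_groups >= 1, players_per_group >= 1, n_blocks >= 1,
            trials_per_block >= 1, start_price_range[1] < start_price_range[2],
            budget > 0, warehouse_capacity > 0)
  structure(
    list(n_groups = as.integer(n_groups),
         players_per_group = as.integer(players_per_group),
         n_blocks = as.integer(n_blocks),
         trials_per_block = as.integer(trials_per_block),
         start_price_range = as.numeric(start_price_range),
         unit_mode = unit_mode, budget = budget,
         warehouse_capacity = as.integer(warehouse_capacity),
         duration = duration, dt_continuous = dt_continuous,
         dt_discrete = dt_discrete),
    class = "experiment_design"
  )
}
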