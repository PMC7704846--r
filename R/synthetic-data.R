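#' @title Synthetic trial logs in the laboratory platform format
#' @description Generates experiment-shaped trial records (groups x
#'   conditions x blocks x trials) by driving the group simulator with
#'   per-condition model parameters, applies the platform's budget and
#'   warehouse bookkeeping, and reads/writes the CSV dialect.
#' @name dutchpt-synthetic
NULL

trial_columns <- c("group_id", "player_pseudonym", "block", "trial",
                   "condition", "start_price", "unit_quantity",
                   "winning_step", "winning_step_norm", "winning_price",
                   "winner_id", "remaining_funds", "warehouse_fill")

pseudonym_pool <- c("falcon", "otter", "heron", "lynx", "ibis", "marten",
                    "osprey", "badger", "curlew", "stoat", "plover", "vole")

# deterministic pseudonym from (group, seat, seed)
make_pseudonym <- function(group, seat, seed) {
  idx <- (group * 7L + seat * 3L + (seed %% 97L)) %% length(pseudonym_pool) + 1L
  sprintf("%s-%02d%d", pseudonym_pool[idx], group, seat)
}

#' Generate a synthetic experiment's trial log
#'
#' Emulates one full laboratory experiment: each of `design$n_groups`
#' three-player groups completes 1 practice block (block 0) plus
#' `design$n_blocks` testing blocks of `design$trials_per_block` auctions in
#' each step-rate condition. Per-trial start prices and unit quantities
#' follow the design; bid steps come from the prospect-theory group
#' simulator with per-condition parameters. Budget and warehouse bookkeeping
#' is applied post hoc (it never enters the agents' decisions): each
#' player's funds and warehouse refresh at the start of every block, the
#' winner pays the winning price and stores the units, and a player whose
#' warehouse is full can no longer win.
#'
#' @param design An [experiment_design()].
#' @param params_continuous,params_discrete [prospect_params()] for the two
#'   step-rate conditions (defaults: the per-condition fits V = 1.27,
#'   c = 2.1 and V = 1.43, c = 0.3).
#' @param belief An [opponent_belief()].
#' @param seed Integer seed; the record stream is a pure function of
#'   (design, parameters, seed).
#' @param capacity_stops_winning If `TRUE` (default) a player at warehouse
#'   capacity is excluded from winning further auctions in the block.
#' @return A data.frame of `TrialRecord` rows (columns
#'   `r paste(trial_columns, collapse = ", ")`). Censored trials keep NA in
#'   the winner-dependent fields. `winning_step_norm` applies the x11
#'   normalisation in the discrete condition only.
#' @export
generate_experiment <- function(design = experiment_design(),
                                params_continuous = prospect_params(c = 2.1, V = 1.27),
                                params_discrete = prospect_params(c = 0.3, V = 1.43),
                                belief = opponent_belief(),
                                seed = 1L,
                                capacity_stops_winning = TRUE) {
  stopifnot(inherits(design, "experiment_design"))
  set.seed(seed)
  conds <- list(continuous = list(dt = design$dt_continuous, par = params_continuous),
                discrete = list(dt = design$dt_discrete, par = params_discrete))
  rows <- vector("list", 0L)
  for (grp in seq_len(design$n_groups)) {
    pseud <- vapply(seq_len(design$players_per_group),
                    function(s) make_pseudonym(grp, s, seed), character(1))
    for (cond in names(conds)) {
      dt <- conds[[cond]]$dt
      par <- conds[[cond]]$par
      n_steps <- round(design$duration / dt)
      for (blk in 0:design$n_blocks) {           # block 0 = practice
        funds <- rep(design$budget, design$players_per_group)
        fill <- rep(0L, design$players_per_group)
        for (trl in seq_len(design$trials_per_block)) {
          S <- sample_start_price(1, design$start_price_range)
          units <- sample_unit_quantity(1, design$unit_mode)
          cl <- price_clock(S, design$duration, dt)
          dist <- bid_time_distribution(par, belief, cl)
          steps <- draw_bid_steps(dist, design$players_per_group)
          eligible <- if (capacity_stops_winning)
            fill < design$warehouse_capacity else rep(TRUE, length(steps))
          steps[!eligible] <- n_steps + 1L
          m <- min(steps)
          if (m <= n_steps) {
            tied <- which(steps == m)
            w <- if (length(tied) == 1L) tied else sample(tied, 1L)
            price <- price_at(cl, m)
            funds[w] <- funds[w] - price
            fill[w] <- min(fill[w] + units, design$warehouse_capacity)
            rows[[length(rows) + 1L]] <- data.frame(
              group_id = grp, player_pseudonym = pseud[w], block = blk,
              trial = trl, condition = cond, start_price = S,
              unit_quantity = units, winning_step = m,
              winning_step_norm = if (cond == "discrete")
                normalize_discrete_step(m) else m,
              winning_price = price, winner_id = w,
              remaining_funds = funds[w], warehouse_fill = fill[w],
              stringsAsFactors = FALSE)
          } else {
            rows[[length(rows) + 1L]] <- data.frame(
              group_id = grp, player_pseudonym = NA_character_, block = blk,
              trial = trl, condition = cond, start_price = S,
              unit_quantity = units, winning_step = NA_integer_,
              winning_step_norm = NA_integer_, winning_price = NA_real_,
              winner_id = NA_integer_, remaining_funds = NA_real_,
              warehouse_fill = NA_integer_, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a trial log to CSV (with run manifest)
#'
#' Comma-separated, header row, `.` decimal separator, UTF-8. Dollar and
#' step fields are written at full double precision so that
#' `read_trials(write_trials(...))` is an identity. A JSON sidecar manifest
#' (`<path>.manifest.json`) records the run timestamp, seed and config hash
#' when provided.
#'
#' @param records Trial-record data.frame (see [generate_experiment()]).
#' @param path Output CSV path.
#' @param seed,config Optional provenance stored in the sidecar manifest.
#' @return `path`, invisibly.
#' @export
write_trials <- function(records, path, seed = NULL, config = NULL) {
  stopifnot(is.data.frame(records), all(trial_columns %in% names(records)))
  rec <- records[, trial_columns]
  num <- vapply(rec, is.double, logical(1))
  rec[num] <- lapply(rec[num], function(x) sprintf("%.12g", x))
  rec[rec == "NA"] <- NA
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE, na = "")
  write_manifest(paste0(path, ".manifest.json"), command = "write_trials",
                 seed = seed, config = config, outputs = path)
  invisible(path)
}

#' Read a trial log CSV
#'
#' Validates the column set and field types, rejecting malformed rows with
#' their line numbers, and warns when a stored winning price disagrees with
#' the price implied by the clock and the stored winning step. Practice
#' blocks (block 0) are dropped by default, mirroring their exclusion from
#' analysis.
#'
#' @param path CSV path in the dialect of [write_trials()].
#' @param drop_practice Drop block-0 records (default TRUE).
#' @param duration,dt_continuous,dt_discrete Clock timing used for the
#'   winning-price consistency check.
#' @param column_map Optional named character vector mapping this package's
#'   column names to the names found in the file, to adapt foreign layouts.
#' @return Trial-record data.frame.
#' @export
read_trials <- function(path, drop_practice = TRUE, duration = 5,
                        dt_continuous = 0.05, dt_discrete = 0.5,
                        column_map = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  if (!is.null(column_map)) {
    hit <- match(unname(column_map), names(raw))
    if (anyNA(hit)) stop("column_map names absent from file: ",
                         paste(column_map[is.na(hit)], collapse = ", "),
                         call. = FALSE)
    names(raw)[hit] <- names(column_map)
  }
  missing_cols <- setdiff(trial_columns, names(raw))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  raw <- raw[, trial_columns]
  if (nrow(raw) == 0L) {
    out <- raw
    num_cols <- setdiff(trial_columns, c("player_pseudonym", "condition"))
    out[num_cols] <- lapply(out[num_cols], as.numeric)
    return(out)
  }

  parse_num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data line %d: '%s'",
                   col, bad[1], raw[[col]][bad[1]]), call. = FALSE)
    v
  }
  out <- data.frame(
    group_id = as.integer(parse_num("group_id")),
    player_pseudonym = raw$player_pseudonym,
    block = as.integer(parse_num("block")),
    trial = as.integer(parse_num("trial")),
    condition = raw$condition,
    start_price = parse_num("start_price"),
    unit_quantity = as.integer(parse_num("unit_quantity")),
    winning_step = as.integer(parse_num("winning_step")),
    winning_step_norm = as.integer(parse_num("winning_step_norm")),
    winning_price = parse_num("winning_price"),
    winner_id = as.integer(parse_num("winner_id")),
    remaining_funds = parse_num("remaining_funds"),
    warehouse_fill = as.integer(parse_num("warehouse_fill")),
    stringsAsFactors = FALSE)
  bad_cond <- which(!out$condition %in% c("continuous", "discrete"))
  if (length(bad_cond))
    stop(sprintf("unknown condition at data line %d: '%s'",
                 bad_cond[1], out$condition[bad_cond[1]]), call. = FALSE)

  decided <- !is.na(out$winning_step)
  if (any(decided)) {
    dt <- ifelse(out$condition == "continuous", dt_continuous, dt_discrete)
    n_steps <- round(duration / dt)
    implied <- out$start_price * (1 - out$winning_step / n_steps)
    off <- decided & abs(out$winning_price - implied) > 1e-6 * pmax(out$start_price, 1)
    if (any(off))
      warning(sprintf("%d record(s) with winning_price inconsistent with the price clock (first at data line %d)",
                      sum(off), which(off)[1]), call. = FALSE)
  }
  if (drop_practice) out <- out[out$block != 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}
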