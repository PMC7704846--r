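#' Analyse a trial log the way the laboratory data were analysed
#'
#' Runs, per step-rate condition: the winning price vs (normalised) winning
#' step correlation, the start price vs winning price correlation, and the
#' low/high start-price two-sample comparison (pooled t with JZS Bayes
#' factor). Across conditions it adds the paired continuous-vs-discrete
#' price comparison (normality-checked t / signed-rank) and the routine
#' group and block summaries (one-way group ANOVA per condition and the
#' Greenhouse-Geisser-corrected block ANOVA).
#'
#' @param records Trial-record data.frame (practice block already removed),
#'   or an `auction_outcomes` data.frame (then only per-condition analyses
#'   that apply are run).
#' @param split_threshold Start-price cut for the low/high bins (default
#'   $100).
#' @return A nested list report, JSON-serialisable: one entry per condition
#'   with `price_step_corr`, `start_bid_corr`, `lowhigh_t`, plus
#'   `condition_comparison` and (for trial logs) `group_anova`,
#'   `block_anova`.
#' @export
analyze_trials <- function(records, split_threshold = 100) {
  stopifnot(is.data.frame(records),
            all(c("condition", "start_price", "winning_price") %in% names(records)))
  step_col <- if ("winning_step_norm" %in% names(records))
    "winning_step_norm" else "winning_step"
  report <- list()
  for (cond in sort(unique(records$condition))) {
    d <- records[records$condition == cond & !is.na(records$winning_price), ,
                 drop = FALSE]
    bins <- split_by_start_price(d, split_threshold)
    report[[cond]] <- list(
      n_decided = nrow(d),
      price_step_corr = unclass(correlate(d$winning_price, d[[step_col]])),
      start_bid_corr = unclass(correlate(d$start_price, d$winning_price)),
      lowhigh_t = unclass(two_sample_t(bins$low, bins$high))
    )
  }

  is_log <- all(c("group_id", "block", "trial") %in% names(records))
  if (is_log && length(unique(records$condition)) == 2L) {
    # pair trials by (group, block, trial) across conditions
    key <- interaction(records$group_id, records$block, records$trial)
    cont <- records[records$condition == "continuous", ]
    disc <- records[records$condition == "discrete", ]
    kc <- paste(cont$group_id, cont$block, cont$trial)
    kd <- paste(disc$group_id, disc$block, disc$trial)
    common <- intersect(kc, kd)
    a <- cont$winning_price[match(common, kc)]
    b <- disc$winning_price[match(common, kd)]
    keep <- !is.na(a) & !is.na(b)
    if (sum(keep) >= 3)
      report$condition_comparison <-
        unclass(compare_paired_conditions(a[keep], b[keep], method = "auto"))
    for (cond in c("continuous", "discrete")) {
      d <- records[records$condition == cond & !is.na(records$winning_price), ]
      if (length(unique(d$group_id)) >= 2) {
        av <- stats::oneway.test(winning_price ~ factor(group_id), data = d,
                                 var.equal = TRUE)
        report[[cond]]$group_anova <- list(F = unname(av$statistic),
                                           df = unname(av$parameter),
                                           p_value = av$p.value)
      }
      blk <- tapply(d$winning_price, list(d$group_id, d$block), mean)
      if (!anyNA(blk) && ncol(blk) >= 2 && nrow(blk) >= 2)
        report[[cond]]$block_anova <- rm_anova_gg(blk)
    }
  }
  report
}

#' Reproduce the model-simulation study
#'
#' Simulates 1000 three-player fixed-unit auctions per step-rate condition
#' under the fitted configuration (start prices U($80, $120), 5 s clock,
#' classic utility/weighting parameters, belief N(2.01, 0.97); continuous
#' V = 1.27, c = 2.1, dt = 0.05; discrete V = 1.43, c = 0.3, dt = 0.5),
#' then runs the start-price analyses on the simulated winning bids:
#' start-price/winning-bid Pearson correlation and the low ($80--100) vs
#' high ($100--120) pooled two-sample t with its JZS Bayes factor, per
#' condition.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_auctions Auctions per condition (study value 1000).
#' @param out_dir Optional directory; when given, writes `report.json`, the
#'   per-condition simulation CSVs, diagnostic figures (winning-bid
#'   histogram, ECDF, start-price scatter) and a run manifest.
#' @return The report: per condition `start_bid_corr`, `lowhigh_t`,
#'   `summary`, plus the simulated outcomes in `$simulations`.
#' @examples
#' rep <- reproduce_model_study(seed = 1, n_auctions = 200)
#' rep$continuous$start_bid_corr$estimate
#' @export
reproduce_model_study <- function(seed = 1L, n_auctions = 1000L,
                                  out_dir = NULL) {
  set.seed(seed)
  report <- list(seed = seed, n_auctions = n_auctions)
  sims <- list()
  for (cond in c("continuous", "discrete")) {
    cfg <- default_config(cond)
    sim <- simulate_auctions(
      n_auctions, config_params(cfg), config_belief(cfg), dt = cfg$dt_s,
      start_price_range = c(cfg$start_price_low, cfg$start_price_high),
      duration = cfg$duration_s, condition = cond)
    d <- sim[!is.na(sim$winning_price), ]
    bins <- split_by_start_price(d, threshold = 100)
    report[[cond]] <- list(
      n_decided = nrow(d),
      start_bid_corr = unclass(correlate(d$start_price, d$winning_price)),
      lowhigh_t = unclass(two_sample_t(bins$low, bins$high)),
      summary = summarize_simulation(sim)
    )
    sims[[cond]] <- sim
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cond in names(sims))
      utils::write.csv(sims[[cond]],
                       file.path(out_dir, paste0("sim_", cond, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(report[setdiff(names(report), "simulations")],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    plot_model_study(sims, file.path(out_dir, "figures.pdf"))
    write_manifest(file.path(out_dir, "manifest.json"),
                   command = "reproduce_model_study", seed = seed,
                   config = list(n_auctions = n_auctions),
                   outputs = file.path(out_dir, c("report.json", "figures.pdf")))
  }
  report$simulations <- sims
  invisible(report)
}

# winning-bid histogram, ECDF, and start-price scatter per condition
plot_model_study <- function(sims, path) {
  grDevices::pdf(path, width = 9, height = 6)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 3))
  for (cond in names(sims)) {
    d <- sims[[cond]][!is.na(sims[[cond]]$winning_price), ]
    graphics::hist(d$winning_price, breaks = 30, main = cond,
                   xlab = "winning bid ($)")
    graphics::plot(ecdf_step(d$winning_price), main = paste(cond, "ECDF"),
                   xlab = "winning bid ($)")
    graphics::plot(d$start_price, d$winning_price, pch = 16,
                   cex = 0.4, main = paste(cond, "start vs bid"),
                   xlab = "start price ($)", ylab = "winning bid ($)")
  }
  invisible(path)
}

#' Reproduce the synthetic-experiment pipeline
#'
#' Generates a full synthetic experiment trial log ([generate_experiment()])
#' and pushes it through [analyze_trials()], exercising the complete
#' analysis path without any external download.
#'
#' @param seed Integer seed.
#' @param design An [experiment_design()] (fixed-unit by default).
#' @param out_dir Optional directory for `trials.csv`, `report.json` and a
#'   manifest.
#' @return List with `records` and `report`.
#' @export
reproduce_synthetic_study <- function(seed = 1L,
                                      design = experiment_design(),
                                      out_dir = NULL) {
  records <- generate_experiment(design, seed = seed)
  testing <- records[records$block != 0L, , drop = FALSE]
  report <- analyze_trials(testing)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(records, file.path(out_dir, "trials.csv"), seed = seed)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    write_manifest(file.path(out_dir, "manifest.json"),
                   command = "reproduce_synthetic_study", seed = seed,
                   outputs = file.path(out_dir, c("trials.csv", "report.json")))
  }
  invisible(list(records = records, report = report))
}
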