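#' @title Analysis toolkit for auction trial data
#' @description Correlations, start-price binning, pooled and paired
#'   comparisons, and default-prior Bayes factors, packaged as the analyses
#'   run on both the laboratory trial logs and model-simulated auctions.
#' @name dutchpt-stats
NULL

new_stat_result <- function(method, estimate, statistic, df, p_value,
                            bf10 = NA_real_, extra = list()) {
  structure(
    c(list(method = method, estimate = estimate, statistic = statistic,
           df = df, p_value = p_value, bf10 = bf10,
           log_bf10 = if (is.na(bf10)) NA_real_ else log(bf10)),
      extra),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s\n  estimate = %.4g, statistic = %.4g, df = %s, p = %.4g",
              x$method, x$estimate, x$statistic,
              paste(signif(x$df, 6), collapse = ","), x$p_value))
  if (!is.na(x$bf10)) cat(sprintf(", BF10 = %.4g (ln %.4g)", x$bf10, x$log_bf10))
  cat("\n")
  invisible(x)
}

#' Pearson correlation with t-based test
#'
#' @param x,y Equal-length numeric vectors, n >= 3, finite, each with
#'   positive variance.
#' @return A `stat_result` with `estimate` r, `statistic` t,
#'   `df = n - 2`, `p_value`, and `r_squared`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: an input has zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  new_stat_result("Pearson correlation",
                  estimate = unname(ct$estimate),
                  statistic = unname(ct$statistic),
                  df = unname(ct$parameter), p_value = ct$p.value,
                  extra = list(r_squared = unname(ct$estimate)^2,
                               n = length(x)))
}

#' Split winning prices into low/high start-price bins
#'
#' Partitions decided records at a start-price threshold; a boundary start
#' price exactly at the threshold is assigned to the high bin. Records with
#' a censored winning price are dropped.
#'
#' @param records A data.frame carrying `start_price` and `winning_price`
#'   (e.g. from [simulate_auctions()] or [read_trials()]).
#' @param threshold Dollar cut point (default 100, giving $50--100 vs
#'   $100--150 in the experiments and $80--100 vs $100--120 in the model
#'   study).
#' @return `list(low = , high = )` of winning-price vectors; warns if a bin
#'   is empty.
#' @export
split_by_start_price <- function(records, threshold = 100) {
  stopifnot(is.data.frame(records),
            all(c("start_price", "winning_price") %in% names(records)))
  d <- records[!is.na(records$winning_price), , drop = FALSE]
  out <- list(low = d$winning_price[d$start_price < threshold],
              high = d$winning_price[d$start_price >= threshold])
  if (length(out$low) == 0L || length(out$high) == 0L)
    warning("empty start-price bin", call. = FALSE)
  out
}

#' Pooled-variance two-sample t test with default Bayes factor
#'
#' Student's t with pooled variance and `df = n_a + n_b - 2`, plus the
#' default JZS Bayes factor from [jzs_bf_ttest()]. The estimate is
#' `mean(a) - mean(b)`, so comparing a low against a high bin yields a
#' negative t when the high bin wins at higher prices.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return A `stat_result` with `estimate`, `statistic` t, `df`, `p_value`,
#'   `bf10`, `log_bf10`.
#' @export
two_sample_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2, all(is.finite(a)), all(is.finite(b)))
  if (stats::sd(c(a, b)) == 0)
    stop("degenerate samples: zero pooled variance", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  bf <- jzs_bf_ttest(unname(tt$statistic), n1 = length(a), n2 = length(b))
  new_stat_result("Two-sample t (pooled variance)",
                  estimate = mean(a) - mean(b),
                  statistic = unname(tt$statistic),
                  df = unname(tt$parameter), p_value = tt$p.value,
                  bf10 = bf$bf10,
                  extra = list(n1 = length(a), n2 = length(b)))
}

#' Default JZS Bayes factor for a t statistic
#'
#' The Jeffreys-Zellner-Siow default Bayesian t test: a Cauchy prior with
#' scale `sqrt(2)/2` on the standardised effect size under H1 against a
#' point null. The Bayes factor is computed by numerical integration of the
#' scale-mixture representation (the Cauchy as a normal mixed over an
#' inverse-gamma(1/2, scale^2/2) variance), on the log scale so that values
#' like `exp(100)` are exact. Invariant to the sign of `t`.
#'
#' Supply `n1` and `n2` for a two-sample design (effective sample size
#' `n1 n2 / (n1 + n2)`, `df = n1 + n2 - 2`) or only `n1` for a one-sample /
#' paired design (`df = n1 - 1`).
#'
#' @param t Observed t statistic.
#' @param n1,n2 Group sizes; `n2 = NULL` selects the one-sample form.
#' @param scale Cauchy prior scale (default `sqrt(2)/2`).
#' @return `list(bf10 = , log_bf10 = )`, with `bf10 = exp(log_bf10)`
#'   (`Inf` when out of double range; `log_bf10` is always finite).
#' @examples
#' jzs_bf_ttest(4.85, 330, 330)$bf10      # ~7.3e3
#' jzs_bf_ttest(15.706, 330, 330)$log_bf10  # ~101
#' @export
jzs_bf_ttest <- function(t, n1, n2 = NULL, scale = sqrt(2) / 2) {
  stopifnot(is.finite(t), n1 >= 2, is.null(n2) || n2 >= 2, scale > 0)
  if (is.null(n2)) {
    N <- n1
    nu <- n1 - 1
  } else {
    N <- n1 * n2 / (n1 + n2)
    nu <- n1 + n2 - 2
  }
  t2 <- t^2
  # log of [marginal likelihood under H1 given g] / [null likelihood],
  # integrated over z = log(g) against the inverse-gamma(1/2, scale^2/2) prior
  log_integrand <- function(z) {
    g <- exp(z)
    v <- -0.5 * log1p(N * g) -
      (nu + 1) / 2 * (log1p(t2 / (nu * (1 + N * g))) - log1p(t2 / nu)) +
      log(scale) - 0.5 * log(2 * pi) - 0.5 * z - scale^2 / (2 * g)
    v[!is.finite(v)] <- -Inf
    v
  }
  grid <- seq(-25, 25, length.out = 2001)
  M <- max(log_integrand(grid))
  I <- tryCatch(
    stats::integrate(function(z) {
      y <- exp(log_integrand(z) - M)
      y[!is.finite(y)] <- 0
      y
    }, -35, 35, rel.tol = 1e-10, subdivisions = 500L),
    error = function(e) stop("JZS integration failed: ", conditionMessage(e),
                             sprintf(" (t=%g, N=%g, nu=%g)", t, N, nu),
                             call. = FALSE)
  )
  log_bf10 <- M + log(I$value)
  list(bf10 = exp(log_bf10), log_bf10 = log_bf10)
}

#' Paired comparison of two conditions
#'
#' Paired Student t or Wilcoxon signed-rank comparison of two equal-length
#' paired vectors. With `method = "auto"` a Shapiro-Wilk normality check on
#' the pair differences selects the test (t if p >= .05, signed-rank
#' otherwise), mirroring the assumption-checking convention of the analyses;
#' the Shapiro result is reported either way.
#'
#' @param a,b Paired numeric vectors, equal length >= 3.
#' @param method `"auto"`, `"t"`, or `"wilcoxon"`.
#' @return A `stat_result`; for the t route `bf10` is the one-sample JZS
#'   Bayes factor on the differences, for the signed-rank route `bf10` is
#'   NA. Extra fields: `shapiro_w`, `shapiro_p`, `n`.
#' @export
compare_paired_conditions <- function(a, b, method = c("auto", "t", "wilcoxon")) {
  method <- match.arg(method)
  stopifnot(length(a) == length(b), length(a) >= 3,
            all(is.finite(a)), all(is.finite(b)))
  d <- a - b
  if (all(d == 0)) stop("degenerate pairs: all differences are zero", call. = FALSE)
  sw <- if (stats::sd(d) > 0 && length(d) >= 3 && length(d) <= 5000)
    stats::shapiro.test(d) else list(statistic = NA_real_, p.value = NA_real_)
  if (method == "auto")
    method <- if (!is.na(sw$p.value) && sw$p.value < 0.05) "wilcoxon" else "t"
  extra <- list(shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
                n = length(a))
  if (method == "t") {
    tt <- stats::t.test(a, b, paired = TRUE)
    bf <- jzs_bf_ttest(unname(tt$statistic), n1 = length(a))
    new_stat_result("Paired t", estimate = mean(d),
                    statistic = unname(tt$statistic),
                    df = unname(tt$parameter), p_value = tt$p.value,
                    bf10 = bf$bf10, extra = extra)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    new_stat_result("Wilcoxon signed rank", estimate = stats::median(d),
                    statistic = unname(wt$statistic),
                    df = NA_real_, p_value = wt$p.value, extra = extra)
  }
}

#' Right-continuous empirical CDF
#'
#' Thin wrapper over [stats::ecdf()] kept for a stable analysis surface;
#' `ecdf_step(v)(max(v))` is exactly 1.
#'
#' @param values Numeric sample, n >= 1.
#' @return A step function of class `ecdf`.
#' @export
ecdf_step <- function(values) {
  stopifnot(length(values) >= 1, all(is.finite(values)))
  stats::ecdf(values)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' A convenience wrapper for the routine block/condition ANOVAs of the
#' analysis pipeline: subjects x levels in wide form, sphericity epsilon by
#' the Greenhouse-Geisser formula from the within-subject covariance matrix,
#' and the corrected F test reported alongside the uncorrected one. Not an
#' acceptance-bearing computation.
#'
#' @param wide Numeric matrix or data.frame, rows = subjects, columns =
#'   within-subject levels (>= 2), no missing values.
#' @return A list with `F`, `df`, `p_value` (uncorrected), `epsilon`,
#'   `df_gg`, `p_gg`.
#' @export
rm_anova_gg <- function(wide) {
  wide <- as.matrix(wide)
  stopifnot(is.numeric(wide), nrow(wide) >= 2, ncol(wide) >= 2,
            !anyNA(wide))
  n <- nrow(wide); k <- ncol(wide)
  subj_mean <- rowMeans(wide); lvl_mean <- colMeans(wide); gm <- mean(wide)
  ss_lvl <- n * sum((lvl_mean - gm)^2)
  ss_err <- sum((wide - outer(subj_mean, rep(1, k)) -
                   outer(rep(1, n), lvl_mean) + gm)^2)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  Fv <- (ss_lvl / df1) / (ss_err / df2)
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  # Greenhouse-Geisser epsilon from the sample covariance of the levels
  S <- stats::cov(wide)
  dbar <- mean(diag(S)); sbar <- mean(S)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * sbar^2)
  eps <- num / den
  eps <- min(max(eps, 1 / (k - 1)), 1)
  df_gg <- c(df1 * eps, df2 * eps)
  list(F = Fv, df = c(df1, df2), p_value = p, epsilon = eps,
       df_gg = df_gg,
       p_gg = stats::pf(Fv, df_gg[1], df_gg[2], lower.tail = FALSE))
}
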