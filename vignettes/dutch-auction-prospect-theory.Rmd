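---
title: "A dynamic prospect-theory model of Dutch-auction bidding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic prospect-theory model of Dutch-auction bidding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dutchpt)
```

## The decision problem

In a Dutch auction the asking price `C(t)` starts high and falls linearly to
$0 over a fixed interval (here 5 s), and the first bid wins at the current
price. A bidder faces a sequence of binary choices, one per clock step of
width `dt`: *bid now* — a riskless prospect, winning the stock (perceived
dollar value `P`) at the current price — or *wait one step* — the same
stock at a lower price, but only if none of the competitors bids first.

`dutchpt` operationalises this trade-off with cumulative prospect theory:

* **Utility.** `U(x) = x^alpha` for gains, `-lambda * (-x)^beta` for
  losses, all prospects evaluated as changes from a zero-dollar reference
  point. Defaults are the classic estimates `alpha = beta = 0.88`,
  `lambda = 2.25`.
* **Probability weighting.** The two-parameter inverse-S form
  `w(p) = p^e / (p^e + (1-p)^e)^(1/e)`, with `e = gamma = 0.61` for gain
  prospects and `e = delta = 0.69` for loss prospects.
* **Competitor risk.** Each player believes the others' bid times are
  `N(mu, sigma)` (fitted values `mu = 2.01` s, `sigma = 0.97` s), truncated
  to the auction window and renormalised. The chance that at least one of
  `n` opponents bids in the next window is `r = 1 - (1 - q)^n` with
  `q = F(t + dt) - F(t)`.
* **Choice.** With `u_now = U(P) + U(-C(t))` and
  `u_wait = w(1 - r) * (U(P) + U(-C(t + dt)))`, the per-step probability of
  bidding is the softmax
  `Pr(bid) = exp(c u_now) / (exp(c u_now) + exp(c u_wait))`.

The per-step bid probabilities form a discrete-time hazard; standard
transformations give the bid-step density `g`, CDF `G`, and the group
winning-time CDF `1 - (1 - G)^3` for three concurrent players
(`bid_time_distribution()`, `winning_time_cdf()`).

## Parameters that matter

| parameter | meaning | unit | default |
|---|---|---|---|
| `alpha`, `beta` | utility curvature (gains/losses) | — | 0.88 |
| `lambda` | loss aversion | — | 2.25 |
| `gamma`, `delta` | weighting curvature (gains/losses) | — | 0.61 / 0.69 |
| `c` | softmax sensitivity | 1/utils | 2.1 (continuous), 0.3 (discrete) |
| `V` | perceived-value multiplier | — | 1.27 (continuous), 1.43 (discrete) |
| `mu`, `sigma` | believed competitor bid time | s | 2.01, 0.97 |
| `dt` | clock step | s | 0.05 (continuous), 0.5 (discrete) |

`c` and `V` are the only condition-specific fits: the discrete clock's
large price jumps go with a lower sensitivity and a higher perceived value.

## Design choices where the design was open

**Perceived value anchor.** `V` is a dimensionless multiplier and must be
anchored to a dollar scale. Anchoring to the *current* price
(`P = V * C(t)`) makes the bid-now bracket `C(t)^0.88 (V^0.88 - lambda)`,
which is negative at every price for any plausible `V < lambda^(1/alpha)
(~2.5)`: bidding never becomes attractive, winning bids collapse toward $0,
and the start-price/winning-bid correlation comes out *negative* — the
opposite of both the laboratory data and the model-simulation results.
Anchoring to the *start* price (`P = V * C(0)`) makes bidding now
profitable once the price falls below `(V^alpha / lambda)^(1/beta) * C(0)`
(about `0.51 * C(0)` at `V = 1.27`), reproducing winning bids around
$50 for $100 start prices, the positive start-price correlations, and the
low/high-bin t statistics. `value_anchor = "start_price"` is therefore the
default; `"current_price"` is retained as an explicit option.

**Softmax sign and the weighting formula.** The package uses the
positive-exponent softmax (choice probability increases in an option's
utility, which is what a *sensitivity* `c` means) and the canonical
two-parameter weighting form; a `softmax_sign = "as_printed"` variant that
negates the exponent is kept for auditability.

**Wait-prospect cost and exponent.** Waiting is evaluated at the *next*
price `C(t + dt)` (that is the point of waiting). Which weighting exponent
applies to the wait prospect is genuinely underdetermined; the default
applies `gamma` when the bracketed net utility is a net gain and `delta`
when it is a net loss (`wait_exponent = "by_sign"`), with fixed-exponent
variants available.

**Final step.** At the last step the clock has reached $0 and the truncated
belief has no mass left, so the wait prospect degenerates to the same
zero-cost prospect as bidding; under the corrected softmax the last
decision is a fair coin, and auctions can end unbid. Such auctions are kept
as censored records, mirroring the platform rule that a trial ends when the
price bar reaches $0.

**Ties.** Simultaneous bids within a step are broken uniformly at random
and the number of tied bidders is recorded.

## The simulator and the synthetic experiment

`simulate_auctions()` draws each player's bid step independently from the
hazard process (distributionally identical to flipping the per-step
Bernoulli coins) and the earliest bidder wins at the clock price. The
model-study configuration — 1000 three-player fixed-unit auctions per
step-rate condition, start prices uniform on $80–$120 — is packaged as
`reproduce_model_study()`.

`generate_experiment()` emulates the laboratory platform's session
structure: 11 three-person groups, both step-rate conditions, 1 practice
block (block 0, excluded from analysis on read) plus 5 testing blocks of 12
trials, start prices uniform on $50–$150, stock fixed at 100 units or
integer-uniform on 50–150. Budget ($250) and warehouse (500 units)
bookkeeping is applied *post hoc*, because the decision model contains no
budget term: funds fall by winning bids, stock accumulates, and a player at
capacity stops winning (the platform disables their bidding). What the
generator deliberately does **not** emulate: reaction-time noise,
inter-trial delays, within-session learning (the laboratory data showed no
block effects), or UI events. A green analysis-pipeline test on synthetic
logs therefore establishes that the pipeline computes the right statistics
on data with the right format and coarse structure — not that the model
fits any particular human dataset.

## Statistics

The analysis pipeline mirrors the laboratory analyses: Pearson correlations
(price vs step, start price vs winning bid), low/high start-price binning
at $100 (the boundary going to the high bin — with continuous prices the
choice is measure-zero, but a rule must exist), pooled-variance two-sample
t tests (all reported degrees of freedom equal `n1 + n2 - 2`), paired
t/Wilcoxon comparisons with a Shapiro–Wilk normality pre-check, and
Greenhouse–Geisser-corrected repeated-measures ANOVAs as routine wrappers.

Bayes factors are the default Jeffreys–Zellner–Siow t-test: a Cauchy prior
with scale `sqrt(2)/2` on the standardised effect under H1. `jzs_bf_ttest()`
integrates the scale-mixture representation numerically on the log scale
(substituting `z = log g` makes the integrand smooth and unimodal; the peak
is factored out before quadrature), so `ln BF` values near 100 are computed
without overflow. Reported `Log(BF10)` values are natural logs — this
convention was confirmed against the printed t/BF pairs before freezing.

## Numerical notes

* The softmax is evaluated on the tail side of the logistic so that
  `Pr(now) + Pr(wait) = 1` holds exactly in floating point.
* The hazard-to-density identity `sum(g) + S = 1` holds to 1e-12 by
  construction (cumulative products, no subtraction of near-equal terms).
* Start prices are continuous dollars; rounding happens only at I/O
  (trial CSVs store 12 significant digits, which round-trips through
  `read_trials()` to ~1e-12 relative error).
* Degenerate inputs error loudly: zero-variance correlations, all-zero
  paired differences, all-censored summaries, decreasing CDFs.

## Known limitations

* The reproduction targets for the model study are stochastic: at the
  stated 1000-auction scale the start-price correlation has a seed SD of
  about 0.03–0.04, and the printed values are themselves single Monte-Carlo
  draws. Replications centre near r = 0.53 (continuous) and r = 0.39
  (discrete) against printed 0.574 and 0.417.
* Parameters are taken as given (the classic utility/weighting set plus the
  per-condition `(V, c)` fits); no maximum-likelihood fitting to trial data
  is provided.
* The laboratory experiments' *empirical* statistics are reproducible only
  from the archived data deposit, which the package does not download; the
  synthetic generator covers the pipeline instead.
* Belief updating across trials, reference-point shifts, and
  budget-constrained bidding are out of scope (the narrowed $80–$120
  simulation range needed by the model hints at a reference-point effect
  the framework does not capture).
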