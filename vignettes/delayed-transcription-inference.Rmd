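---
title: "Inferring the promoter open-complex delay from RNA count time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the promoter open-complex delay from RNA count time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delaygene)
```

## The model

delaygene simulates single-gene transcription in a prokaryote with two
reactions. Initiation fires at stochastic rate $k_t$ while the promoter
`Pro` is free; firing consumes the promoter, which returns after a
*constant* delay $\tau_1$ — the promoter open complex formation, during
which the promoter is occupied and cannot initiate again — and the finished
`RNA` molecule appears after a *Gaussian* completion delay
$\tau_2 \sim N(\mu_2, \sigma_2^2)$ covering open complex formation,
elongation and termination. Each RNA degrades at rate $k_d$:

$$
\mathrm{Pro} \xrightarrow{\;k_t\;} \mathrm{Pro}(\tau_1) + \mathrm{RNA}(\tau_2),
\qquad
\mathrm{RNA} \xrightarrow{\;k_d\;} \varnothing .
$$

RNA polymerase is not represented explicitly; that is adequate while its
abundance is roughly constant, as in exponentially growing *E. coli*.
Defaults describe a lac-promoter-like gene: $\tau_1 = 40$ s,
$\mu_2 = 102$ s (40 s open complex + ~60 s elongation + termination),
$\sigma_2 = 14$ s, $k_d = 1/600\,\mathrm{s}^{-1}$ (10 min mean lifetime),
and $k_t = 0.05\,\mathrm{s}^{-1}$. Each initiation cycle is an exponential
wait of mean $1/k_t$ plus the occupied period $\tau_1$, so completed RNA
appear at rate $1/(1/k_t + \tau_1) = 1/60\,\mathrm{s}^{-1}$ and the
stationary mean level is

$$
\bar{x} = \frac{1/k_d}{1/k_t + \tau_1} = 10 .
$$

This renewal-reward identity (`analytic_stationary_mean()`) is used
throughout the test suite as an oracle that is independent of the
simulator.

On $k_t$: the effective cycle of 60 s corresponds to roughly 40 RNA
polymerases competing for a lac-affinity start site. The package exposes it
as an ordinary parameter of `transcription_params()`.

## Exact simulation with delays

Reactions whose products appear later than their firing time are outside
the scope of the plain Gillespie algorithm, so the simulator keeps a
*waitlist* of (absolute release time, species, count) entries. Each step
draws the next reaction the usual way — waiting time $\sim$
Exp($\sum_j a_j$), channel $j$ with probability $a_j / \sum a_j$, where the
propensity $a_j$ is the rate constant times the number of distinct
reactant combinations — and races it against the earliest waitlist release:
the earlier of the two happens, and a release discards the drawn reaction
(it is regenerated on the next step). Numerical conventions, chosen once
and kept:

* ties between a reaction and a release go to the reaction; equal release
  times leave the waitlist in insertion order;
* Gaussian delay draws that come out negative are redrawn rather than
  clamped (at the default $\mu_2/\sigma_2$ this is a $\sim 10^{-13}$
  event, but redrawing keeps the delay law clean for any parameters);
* events strictly beyond the simulation horizon are never applied, and
  pending waitlist entries die with the run.

The inner loop is compiled (Rcpp); a pure-R stepper with the identical
random-number call sequence (`step_dssa()`) exists so the two
implementations can be compared event for event in the tests.

## From trajectories to data

Each simulated cell runs 6000 s; the RNA count is read at 30 s intervals
over the last 3000 s (samples at 3000, 3030, ..., 5970 s — 100 points
spanning 2970 s). A sample at time $s$ reports the count after all events
at times $\le s$. The 30 s interval matches the current resolution of
single-molecule RNA counting in living cells; the 3000 s burn-in is ~5 RNA
lifetimes, and `run_experiment()` logs a first-half/second-half window-mean
diagnostic rather than enforcing stationarity. Measurement error, when
requested, is independent additive Gaussian noise of sd 0.5 per point with
negative values zeroed; noisy values re-enter the integer state space by
rounding half-up, which is unbiased for symmetric noise (the mapping is a
package choice; flooring would bias counts down by half a molecule).

## The Markov chain approximation

The sampled process $x_1, x_2, \ldots$ (one value per 30 s) is
approximated as a time-homogeneous Markov chain on states $0..K$ with
stationary law $\pi$ and transition matrix $P$, both estimated by
simulating the model at a candidate delay and counting: $\pi$ from the
marginal sample counts, row $x$ of $P$ from the next states observed after
$x$. Pairs never span two cells. $K$ is the largest observed state plus
one. The log-likelihood of observed series is then

$$
\ell = \sum_{\text{series}} \Big[ \log \pi(x_1)
     + \sum_{t=2}^{T} \log P(x_{t-1}, x_t) \Big],
$$

independent cells adding. Observed states above $K$ are clipped to $K$
(with a logged count) since the state space is data-driven.

Two guards keep $\ell$ finite and the estimate stable:

* **Smearing.** Counts are convolved with a 3-point kernel
  $(w, 1 - 2w, w)$ before normalization, bridging single-state gaps that
  finite sampling leaves near the edges of the visited range. Mass pushed
  below state 0 stays at 0; the state space grows by one at the top so
  nothing is lost. Smearing trades variance for bias: it over-disperses
  the transition rows, and since candidates with *longer* delays produce
  fewer arrivals per interval (narrower rows), a heavy kernel makes long
  delays look spuriously good. In a direct probe at the default budget
  (6e5-pair chains against 2000-cell data generated at $\tau_1 = 40$), the
  log-likelihood argmax shifted $+10$ s at $w = 0.25$, $+4$ s at
  $w = 0.10$, $+2$ s at $w = 0.05$ and was unbiased at $w = 0.02$; the
  default is therefore $w = 0.02$, configurable via `smear_kernel()`.
* **Flooring.** After smearing, remaining zeros are floored at
  $1/(n_{\text{samples}} + K + 1)$ — about one pseudo-count — and each
  vector renormalized with the floored entries held fixed. Rows for states
  never visited fall back to $\pi$.

The analytic 30 s transition law of the zero-delay model (binomial
survivors plus Poisson arrivals, `analytic_chain_no_delay()`) provides an
exact oracle for the whole estimation path.

## Scanning, fitting, summarizing

Candidate delays run from 0 to the upper bound obtained by dividing the
mean RNA lifetime by the mean RNA level — 60 s at the true parameters.
`run_experiment()` fixes the range at [0, 60]; `infer_tau()` can instead
plug in the observed data mean when the true parameters are unknown. The
default grid is 13 equally spaced points. Each candidate $\tau$ is
simulated with $\tau_1 = \tau$ and $\mu_2 = \tau + 62$, preserving the
decomposition of the 102 s completion delay (holding $\mu_2$ fixed is
available by flag; at steady state the two differ only by a time shift of
production events, which the stationary law cannot see). Chains for
different candidates use disjoint derived seeds, and the data's seed
substream is disjoint from every chain substream.

Because $\pi$ and $P$ are sampled, $\ell(\tau)$ is nonsmooth; a quadratic
is least-squares fitted to the grid points, giving a likelihood
proportional to a truncated normal on the candidate range, which a flat
prior turns into a posterior by normalization (numerically, at $10^{-3}$ s
resolution; the expected value agrees with the closed-form truncated-normal
mean to $10^{-6}$ in the tests). The reported summaries are the clipped
vertex (maximum likelihood) and the truncated mean (expected value). A
non-concave fit is flagged and falls back to the grid argmax with a
warning rather than failing.

## What the defaults reproduce, and known limitations

With 2e5 pairs per candidate chain and the 13-point grid, full experiments
at 10/100/1000 cells (noiseless and noisy) run in well under a minute each
on one core. Replicated experiments in the test suite show expected values
concentrated near 38–39 s at every sample size for data generated at
$\tau_1 = 40$, mean absolute error decreasing from 10 to 100 cells and
then saturating at the fit-anchor bias described below (so the 100- and
1000-cell errors are statistically indistinguishable, and the suite checks
for "no significant increase" rather than a strict decrease), the
candidate $\tau = 40$ dominating $\tau = 0$ and $\tau = 60$ in every
1000-cell scan, and sd-0.5 noise moving matched-seed estimates by well
under 5 s.

Three caveats a user should know:

* The log-likelihood is strongly asymmetric over the candidate range:
  delays below ~20 s imply a 2–3× higher stationary mean and are rejected
  by thousands of log units. An OLS parabola over the full grid is anchored
  by that steep left arm, which pulls the vertex a little below the truth
  (the ~1.5 s downward bias seen above) and makes the fitted curvature —
  hence the posterior width — reflect the global shape of the scan rather
  than local uncertainty. The posterior is best read as a point estimate
  with a stylized width.
* The chain uses one previous sample only. The delayed process has memory
  (a fired-but-unfinished transcript is invisible to the state), so this
  is an approximation; it is what makes the method cheap.
* The generator emulates the model's own world: constant polymerase
  availability, a single gene, perfectly synchronous 30 s sampling, and
  i.i.d. Gaussian measurement error. Passing tests say nothing about
  regulation, bursting from other mechanisms, cell division, or detection
  losses in real single-molecule data.

## Problem sizes used in the checks

The automated checks use 2e5 pairs per candidate chain; 20 replicate
pipelines at 10 cells and 10 at 100/1000 cells; 1e5 near-independent
samples (spaced 1800 s) for the stationary-law comparison; and 1e6 pairs
for the transition-law comparison, where rows are compared for states with
stationary probability at least 0.04 — rarer rows receive too few visits
for a total-variation comparison at the stated precision to be meaningful.
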