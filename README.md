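# delaygene

Stochastic simulation and inference for single-gene transcription with
time-delayed reactions.

In prokaryotes, transcription initiation is not instantaneous: after an RNA
polymerase commits to a promoter, the promoter is occupied for tens of
seconds while the open complex forms, and the finished transcript appears
only after elongation and termination. These delays shape the fluctuations
of RNA numbers in single cells, and with single-molecule RNA counting now
feasible at ~30 s resolution, they are in principle measurable from time
series. `delaygene` is for researchers who want to (a) simulate such
delayed gene-expression kinetics exactly and (b) infer the duration of the
promoter open complex formation from sampled RNA-count series.

## The model and the method

The transcription model is two reactions. Initiation fires at stochastic
rate $k_t$ while the promoter is free; firing consumes the promoter, which
returns after a constant delay $\tau_1$ (open complex formation), and the
RNA appears after a Gaussian delay $\tau_2 \sim N(102, 14^2)$ s; each RNA
degrades at rate $k_d = 1/600\ \mathrm{s}^{-1}$:

$$\mathrm{Pro} \xrightarrow{k_t} \mathrm{Pro}(\tau_1) + \mathrm{RNA}(\tau_2),
\qquad \mathrm{RNA} \xrightarrow{k_d} \varnothing$$

Simulation uses the delayed stochastic simulation algorithm: the classic
Gillespie step (exponential waiting time, propensity-weighted channel
choice) races against a *waitlist* of pending delayed products, whichever
is earlier happening first. The compiled core simulates tens of thousands
of cells per minute.

Inference approximates the 30-s-sampled RNA count process as a
time-homogeneous Markov chain: for each candidate delay $\tau$, a
stationary distribution $\pi_\tau$ and transition matrix $P_\tau$ are
estimated from simulations at that candidate (with light kernel smearing
and a probability floor), and the data's log-likelihood

$$\ell(\tau) = \sum_{\text{cells}} \Big[\log \pi_\tau(x_1) +
\sum_{t=2}^{T} \log P_\tau(x_{t-1}, x_t)\Big]$$

is evaluated on a grid of candidates spanning $[0, \tau_{\max}]$, where
$\tau_{\max}$ is the mean RNA lifetime over the mean RNA level (60 s at
the defaults). A quadratic fit to the grid log-likelihoods, exponentiated
and normalized, yields a truncated-normal posterior whose mode and mean
are the reported estimates. An additive Gaussian measurement-error model
(sd 0.5, negatives zeroed, rounded back to integers) lets you test
robustness to realistic counting noise.

See `vignette("delayed-transcription-inference")` for assumptions,
numerical conventions and limitations.

## Worked example

```r
library(delaygene)

params <- transcription_params()
params
#> Transcription parameters: k_t = 0.05 /s, tau1 = 40 s, tau2 ~ N(102, 14) s, k_d = 0.00166667 /s
analytic_stationary_mean(params)
#> [1] 10

series <- simulate_cells(100, params, seed = derive_seed(1, "data"))
mean(series)
#> [1] 9.9895

post <- infer_tau(series, infer_config(tau_max = 60, n_pairs = 2e5),
                  seed = derive_seed(1, "chains"))
post
#> Posterior over the open-complex delay on [0, 60] s
#>   maximum likelihood: 38.4 s
#>   expected value:     38.4 s
```

The 100 simulated cells average 9.99 RNA, matching the renewal-theory
stationary mean $(1/k_d)/(1/k_t+\tau_1) = 10$. The inferred open-complex
delay (posterior mean 38.4 s) recovers the true 40 s to within the
method's resolution; the scan behind it shows why the answer is
well-identified — candidates that imply the wrong stationary mean are
rejected by thousands of log units:

```r
round(cbind(tau = post$grid, loglik = post$logliks))[c(1, 5, 9, 13), ]
#>      tau loglik
#> [1,]   0 -88314
#> [2,]  20 -13575
#> [3,]  40 -12474
#> [4,]  60 -12933
```

`run_experiment()` packages the full pipeline (simulate, optionally add
noise, infer, write CSV/JSON/plot outputs), and `reproduce_figure(k, ...)`
reruns the reference study's figure designs (six example traces; posterior
plots for 10/100/1000 cells, noiseless and noisy). A thin command-line
front end lives at `inst/cli/delaygene`
(`Rscript <path> simulate --cells 100 --seed 1 --out out/`).

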