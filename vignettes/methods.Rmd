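---
title: "Methods: brain-state dynamics and network temporal variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-state dynamics and network temporal variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statedyn)
```

`statedyn` implements a complete analysis chain for resting-state brain
dynamics: a Gaussian hidden Markov model (HMM) over parcellated BOLD
network time series, per-subject dynamics metrics, windowed
functional-connectivity (FC) temporal variability, and covariate-adjusted
association testing against a continuous symptom score. It also ships a
synthetic cohort generator with *planted* effects, used throughout the test
suite to validate that the analysis recovers known ground truth.

## 1. Data model and preprocessing

The unit of data is a `parcellated_ts`: a $T \times N$ numeric matrix of
BOLD time series, one column per channel (parcel or network), with a
subject identifier. Channels are assigned to $M$ networks by a
`network_map`; the default map has $M = 17$ networks. Phenotypes carry the
symptom `score`, covariates `sex`, `age`, `mean_fd` (mean framewise
displacement), and subjects with `mean_fd` above 0.2 mm are excluded.

Before HMM fitting, channel time series are averaged within each network
(`network_average`) and each subject's network series are z-scored
(`standardize_and_concatenate`) so that the state means are expressed in
within-subject standard-deviation units and amplitude differences between
subjects do not drive state assignment. Fitting the HMM on network averages
rather than full parcel series keeps the observation dimension small
relative to the number of time points, which makes the state covariance
estimates well conditioned at single-run lengths.

## 2. Hidden Markov model

For subject $s$ with standardized network series
$y_t^{(s)} \in \mathbb{R}^M$, the model assumes a latent chain
$z_t \in \{1,\dots,K\}$ with initial distribution $\pi$, transition matrix
$A$, and Gaussian emissions

$$ y_t \mid z_t = k \;\sim\; \mathcal{N}(\mu_k, \Sigma_k). $$

Parameters are shared across subjects: all runs are concatenated and the
chain is *reset* at every subject boundary (each subject contributes an
independent chain with the same $(\pi, A, \mu, \Sigma)$). Estimation is
maximum-likelihood EM (Baum–Welch) with a scaled forward–backward pass and
a log-space Viterbi decoder, both implemented in C++. Restarts are
initialized from k-means partitions and the restart with the highest final
log-likelihood is kept. This is a maximum-likelihood stand-in for
variational Bayesian HMM implementations: model-selection by final
log-likelihood across restarts plays the role that free energy plays there.
The default is $K = 8$ states with 10 restarts.

If a state loses effectively all responsibility during EM it is re-seeded
from the data rather than left empty, and covariance updates carry a small
diagonal regularizer to keep them positive definite.

```{r fit-example}
co <- simulate_cohort(cohort_config(n_subjects = 20, n_states = 3,
                                    mean_separation = 4,
                                    b_sr = 0, b_var = 0, delta_max = 0),
                      seed = 7)
netts <- lapply(co$timeseries, network_average, map = co$network_map)
cc <- standardize_and_concatenate(netts)
fit <- fit_hmm(cc, K = 3, n_restarts = 3, seed = 2)
round(fit$trans, 3)
```

### Dynamics metrics

From the Viterbi path of each subject (`dynamics_metrics`):

- **Fractional occupancy** $\mathrm{FO}_k$ — fraction of volumes assigned
  to state $k$;
- **MaxFO** $= \max_k \mathrm{FO}_k$ — dominance of the single most
  visited state;
- **Switching rate** $\mathrm{SR}$ — number of state transitions divided
  by $T$.

Hard-path (Viterbi) occupancies are the default because they pair naturally
with the switch count; posterior-weighted FO
($\frac{1}{T}\sum_t \gamma_t(k)$) is available via `posterior_fo = TRUE`.

### State profiles

For interpretation, each state gets (`state_profile`): its **relative mean
activation** $\mu_k - \bar\mu$, where $\bar\mu$ is the FO-weighted grand
mean across states; its FC matrix $\mathrm{cov2cor}(\Sigma_k)$; and the top
5% strongest positive FC edges (`top_positive_fc`), the conventional sparse
summary of a state's connectivity fingerprint.

## 3. Temporal variability of windowed FC

Each subject's (parcel-level) time series is cut into non-overlapping
windows of length $l$; the remainder is dropped. For every window the
Pearson FC pattern of interest is vectorized:

- **within-network** variability of network $m$ uses the
  $\binom{n_m}{2}$ unique off-diagonal entries among its channels;
- **between-network** variability of pair $(m, m')$ uses the full
  $n_m \times n_{m'}$ cross-block.

For a window length $l$ with $W$ windows, the statistic is

$$ V_l \;=\; 1 - \binom{W}{2}^{-1} \sum_{a < b}
   \mathrm{corr}\!\left(\mathrm{vec}(C_a), \mathrm{vec}(C_b)\right), $$

and the reported value is the mean of $V_l$ over
$l \in \{20, 22, \dots, 40\}$, giving $V \in [0, 2]$: 0 when every window
shows the same FC pattern, 1 when patterns are uncorrelated, 2 when they
are exactly anticorrelated. An optional Fisher $z$ transform of the window
FC entries is available (`fisher = TRUE`) but off by default, matching the
plain-correlation definition above. With $M = 17$ networks this yields 17
within-network and $\binom{17}{2} = 136$ between-network features per
subject.

## 4. Association testing

Every dynamics and variability feature is tested against the symptom score
by **partial correlation** adjusted for sex, age, and mean FD: both the
feature and the score are OLS-residualized on the covariates, the Pearson
correlation $r$ of the residuals is computed, and
$t = r\sqrt{\mathrm{df}/(1 - r^2)}$ with $\mathrm{df} = n - 2 - c$ gives a
two-sided p-value. Benjamini–Hochberg FDR correction is applied **within
feature family** — state FOs ($K$ tests), within-network variability (17),
between-network variability (136) — while the two global HMM metrics
(MaxFO, SR) are reported at their raw p-values, reflecting their status as
two primary planned comparisons. `network_contribution` then ranks networks
by the cumulative $|r|$ of their significant between-network pairs.

## 5. The synthetic cohort generator

`simulate_cohort` plants subject-level effects so the full pipeline can be
validated end to end. Per subject $s$: stickiness
$\theta_s \sim U(0.80, 0.98)$ sets the transition matrix (diagonal
$\theta_s$, off-diagonal uniform), a state path of $T = 242$ volumes is
drawn, and BOLD is emitted from state-dependent Gaussians built from a
factor model — one shared global factor (loading $\gamma$, cross-network
structure), one factor per network (within-network structure), and
idiosyncratic noise, with per-state mean shifts of fixed pairwise
separation and per-state sign flips of network loadings so states differ in
FC, not just mean. The symptom score is

$$ \mathrm{score}_s = b_{\mathrm{SR}} \cdot \tilde{\mathrm{SR}}_s
   + b_{V} \cdot \tilde\delta_s + \varepsilon_s, $$

coupling it positively to the subject's true switching rate (which also
induces the negative MaxFO association, since stickier chains have both
lower SR and higher MaxFO) and to a **drift amplitude**
$\delta_s \in [0, \delta_{\max}]$ that controls genuine time-varying FC.

### Why the drift design is what it is

Planting detectable FC drift against the pattern-correlation statistic $V$
is not trivial; three natural designs provably do nothing, and the test
suite's design avoids all three:

1. *Uniform modulation of a block is invisible.* Scaling all channels of a
   network by a common $g(t)$ scales the whole window FC block by a common
   factor; Pearson pattern correlation is affine-invariant, so $V$ is
   unchanged.
2. *Injected structure proportional to the baseline pattern is invisible.*
   Adding a time-varying component whose cross-block signature is
   proportional to the existing one only rescales the pattern — again
   invisible to $V$.
3. *Common-frequency sinusoidal loadings lower $V$.* If channels share one
   modulation frequency, the product of two loadings contains a stable
   $\cos(\psi_i - \psi_j)$ term that adds *stable* structure and reduces
   pattern variability.

The generator therefore uses per-channel *distinct* phases and, for
between-network drift, channel-specific slow frequencies (2–7 cycles per
run) on a shared latent factor, so cross-channel products oscillate at
difference frequencies and no stable term survives. Two further choices
give the between-network features headroom to move: the global factor
loading is strong (`cross_scale = 0.85`), so baseline cross-network
patterns sit well above the noise floor of short-window FC estimates (with
weak cross-structure, between-network $V$ saturates near 1 for everyone and
no drift can raise it); and the drift-target channels are excluded from the
per-state sign flips, which would otherwise scramble the very cross-block
structure the drift has to modulate. These parameters were calibrated
against the generator's own diagnostics (window-FC coupling of $V$ to
$\delta$) before the acceptance checks were written, not tuned to them.

What the generator does *not* emulate: hemodynamic convolution, scanner
autocorrelation, spatial parcel geometry, or realistic motion artifacts.
Covariates (sex, age, mean FD) are drawn independently of the score, so
they act as pure noise dimensions for the partial correlation.

### Validation-scale choices

Several validation settings are scaled to the package's test-time budget,
as the package's own choice:

- Planted-effect recovery replicates use cohorts of 300 subjects with
  ground-truth state paths supplied to `dynamics_metrics` directly, rather
  than refitting the HMM inside each of the 20 replicates; HMM recovery
  itself is validated separately (decoded-path accuracy and transition
  matrix error on planted cohorts), so the replicate loop isolates the
  statistical pipeline from EM runtime.
- Recovery tests use 2–5 EM restarts and relaxed tolerances where the
  planted separation makes the likelihood surface easy; the analysis
  default remains 10 restarts at `tol = 1e-6`.

## 6. Pipeline

`run_pipeline` chains the stages `simulate` → `fit-hmm` → `profiles` →
`variability` → `associate`, writing each stage's outputs (cohort TSVs,
`model.json`, `metrics.tsv`, `variability.tsv`, `associations.tsv`,
`contributions.tsv`, `metadata.json`) into a run directory so single stages
can be re-run from cached intermediates. Stage seeds are derived
deterministically from one master seed. A command-line front end is
installed at `system.file("scripts", "statedyn.R", package = "statedyn")`.

```{r pipeline-example}
out <- file.path(tempdir(), "demo_run")
cfg <- run_config(simulate = cohort_config(n_subjects = 30, n_states = 3,
                                           mean_separation = 4),
                  n_states = 3, n_restarts = 2, seed = 11, max_iter = 40,
                  tol = 1e-5)
res <- suppressWarnings(run_pipeline(cfg, out))
head(res$associations[order(res$associations$p), c("feature", "r", "p", "p_fdr")])
```
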