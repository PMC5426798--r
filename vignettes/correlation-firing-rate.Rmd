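---
title: "When do spike-count correlations increase with firing rate?"
author: "eicorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{When do spike-count correlations increase with firing rate?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
library(eicorr)
```

## The question

Pairwise spike-count correlations in cortex are often reported to grow
with the firing rates of the pair, a structure with real consequences
for population coding.  In feedforward circuits the effect is understood
through a susceptibility argument: cells transfer common input
fluctuations to their outputs with a gain that depends on their
operating point, so pairs of high-rate cells inherit more correlation
from the same shared input.  `eicorr` implements the full computational
apparatus for asking when this relationship emerges in *recurrent*
excitatory–inhibitory networks, where shared input is generated
internally by overlapping projections rather than delivered externally.

The package has five coupled layers:

1. a **synthetic network generator** (conductance-based LIF cells with
   heterogeneous thresholds, fixed in-degree or Erdős–Rényi graphs);
2. a compiled **Euler–Maruyama simulator** for Monte-Carlo spike
   statistics;
3. a **threshold-integration engine** solving the Fokker–Planck
   boundary-value problems of each cell: stationary rate, baseline
   spike-train spectrum, and the susceptibility of the rate to
   modulations of mean conductances, conductance variances and current;
4. a network **linear-response** layer predicting the full
   cross-spectral matrix and windowed spike-count correlations, with a
   **graph-motif decomposition** of the prediction;
5. **correlation-susceptibility** reductions and a **shifted rank-one
   approximation** of the correlation matrix.

## Model

Each cell `i` follows, below its threshold `theta_i`,

$$\tau_m \dot v_i = -v_i - g_{E,i}(t)\,(v_i - E_E) - g_{I,i}(t)\,(v_i - E_I)
  + \sigma_i \sqrt{\tau_m}\,\xi_i(t),$$

with a spike and reset to 0 (after a refractory period `tau_ref`) on
crossing `theta_i`.  Conductances are second-order alpha kinetics: each
presynaptic spike kicks an auxiliary variable by the edge amplitude
`alpha_X W_YX / N_YX` (raw weight divided by in-degree), which relaxes
through a rise/decay cascade.  Voltages are in scaled units (rest 0,
reference threshold 1).

Key defaults (all exposed in `ei_network_config()` /
`synapse_constants()`):

| parameter | E | I | units |
|---|---|---|---|
| `tau_r` / `tau_d` | 1 / 5 | 2 / 10 | ms |
| `alpha` | 1 | 2 | – |
| reversal | +6.5 | −0.5 | scaled voltage |
| `tau_m`, `tau_ref` | 20, 2 | 20, 2 | ms |

Two regime presets differ only in recurrent excitation and background
noise: the *asynchronous* regime (`W_EE = 0.5`, `W_IE = 5`) and the
*strong asynchronous* regime (`W_EE = 9`, `W_IE = 8`), both with
`W_EI = 10`, `W_II = 5`, connection fractions 40% (E→E), 35% (I→E), 20%
(E→I), 40% (I→I), and 80 E + 20 I cells, so each E cell receives exactly
32 excitatory and 7 inhibitory inputs.

**A note on the noise magnitudes.**  The source table for the
background-noise strengths is typeset ambiguously ("2/2", "1.5/2", …).
We adopt the reading `sigma = x / sqrt(2)` (a radical lost in
typesetting): under the alternative plain-fraction reading the network's
excitatory population fires at 1–3 Hz, inconsistent with the ~10 Hz
population means the same source reports, while under ours both the
simulator and the theory reproduce those means to within a few percent.
The values remain explicit config fields (`sigma` in
`ei_network_config()`) so either reading can be imposed.

Heterogeneity enters through thresholds: `log(theta) ~
Normal(-s^2/2, s^2)` truncated to `[0.7, 1.4]`, with `s = 0.2`, so the
untruncated mean is exactly 1; the homogeneous control sets every
threshold to 1.  Thresholds are drawn by rejection sampling (exact; the
acceptance rate, about 95% at `s = 0.2`, is recorded as an attribute).

```{r network}
net <- ei_network("asynchronous", heterogeneous = TRUE, rng_seed = 1)
net
```

## Diffusion mapping and threshold integration

For the theory, each conductance input is split into mean and
fluctuation.  Poisson input at rate `nu` through an alpha synapse gives
conductance mean `amp * nu * tau_r` and variance
`amp^2 nu tau_r^2 / (2 (tau_r + tau_d))`
(`conductance_moments()`); the fluctuations become white multiplicative
noise, yielding an effective drift `-g0 (v - mu)` with
`g0 = 1 + gE + gI`, `mu = (gE E_E + gI E_I)/g0`, and a
voltage-dependent diffusion

$$D(v) = \frac{\sigma_E^2 (v-E_E)^2 + \sigma_I^2 (v-E_I)^2 +
  \sigma^2 \tau_m}{2\tau_m^2}.$$

`steady_rate()` solves the stationary Fokker–Planck problem for this
equation by threshold integration: the flux is integrated downward from
the absorbing boundary at `theta`, reinjected at the reset, and the rate
follows from normalization with the refractory correction
`1/(1/nu0 + tau_ref)`.  `cell_spectra()` adds, per frequency, the
first-passage-time density transform (the spike train is a renewal
process, giving the baseline power spectrum in closed form from that
transform) and the complex susceptibilities `A(omega)` of the rate to
each of `<gE>`, `<gI>`, `sigma_E^2`, `sigma_I^2` and the effective
potential `mu`.

Numerical choices, all validated in the test suite:

* voltage grid of 2048 points with the reset exactly on a node; the
  lower bound extends to `min(-1, mu - 8 sd)` so no stationary mass is
  truncated (with the operating points of these networks, a fixed floor
  at −1 would cut real probability);
* `omega = 0` is never obtained as a numerical limit: the
  zero-frequency susceptibility is the exact linearization of the
  stationary sweep, and the zero-frequency spectrum uses the first two
  first-passage moments from the backward equations
  (`C0(0) = nu CV^2`);
* refractoriness delays reinjected flux by `exp(-i omega tau_ref)` in
  the spectral problems;
* against the classical current-noise LIF (constant `D`) the solver
  matches the closed-form first-passage rate to ~`1e-6` relative, and
  `A(0)` matches centered finite differences to better than 1%.

The network rate fixed point (`self_consistent_rates()`) accumulates
each cell's presynaptic rates over the *actual* adjacency (per edge, not
mean field), maps them to conductance moments and solves the damped
Picard iteration `nu <- 0.5 nu + 0.5 f(nu)` to a relative tolerance of
`1e-6` (at most 500 iterations), seeded from the uncoupled rates.  For
the asynchronous heterogeneous network this lands within ~2% of the
Monte-Carlo rates; in the strong asynchronous regime the theory
underestimates rates by 15–20% (burst dynamics are beyond a
linearization around stationarity), which is a known limitation.

```{r rates}
rates <- self_consistent_rates(net)
head(rates, 3)
mean(rates$rate_hz[rates$type == "E"])
```

## Linear response and windowed correlations

`linear_response()` evaluates spectra and susceptibilities for every
cell at the self-consistent operating point.  The interaction matrix at
frequency `f` combines, for an excitatory source `j` of target `i`,

$$K_{ij} = \big(A_{\langle g_E\rangle,i} \tilde J_{ij}
  + A_{\sigma_E^2,i} \tilde L_{ij}\big) \tilde F_E(f),$$

(and the inhibitory analogue), where `J` is the mean-conductance gain of
the edge per unit presynaptic rate (`amp * tau_r`), `L = J * amp/2 *
tau_r/(tau_r + tau_d)` is its conductance-variance counterpart — the
exact ratio of the variance and mean gains of the alpha synapse — and
`F` is the unit-area synaptic filter transform.  Inhibition enters
through the sign of `A_<gI>` (negative), with all weights nonnegative.
The predicted cross-spectrum is the standard linear-response sandwich
`(I - K)^{-1} C^0 (I - K^*)^{-1}`, Hermitian and positive semidefinite
by construction.

Spike-count covariances over a window `T` follow by integrating the
cross-spectrum against the triangular-kernel window,
`Cov_T = \int C(f) (\sin(\pi f T)/(\pi f))^2 df`, on a uniform grid
(default 0–1000 Hz in 0.5 Hz steps; susceptibilities are
spline-interpolated from the 61-point logarithmic solver grid, which a
test verifies against direct solves).  The white high-frequency floor of
the spectrum diagonal is integrated analytically, so the quadrature only
carries the decaying part.  `T = Inf` returns the zero-frequency
correlations directly.  The step `df` must stay well below `1/T`; for
very long windows use a finer grid or the `Inf` mode.

```{r lr, eval = FALSE}
lr <- linear_response(net)
lc <- lr_correlations(lr, windows = c(5, 100, Inf))
glance(lc) # R^2 of rho vs sqrt(nu_i nu_j) per window
autoplot(lc)
```

## Motif decomposition

Because the spectral radius of `K(0)` is below 1 in both regimes
(~0.39 and ~0.46), the matrix inverse expands in powers of `K`: the
order-`n` piece `P^n = sum_l K^(n-l) C0 (K^*)^l` collects all undirected
paths of length `n` between a pair, and its normalization by the total
spectrum diagonal decomposes the long-window correlation coefficient
exactly (the test suite verifies geometric convergence at rate
`rho(K)` and recovery of the full correlation to `1e-6` when summed to
order 40).  At second order the contribution splits *exactly* (an
entrywise partition over the intermediate index) into E/I chains
(`K^2 C0` and transpose) and E/I common input (`K C0 K^*`).

In both regimes inhibitory common input dominates: regressing the total
second-order contribution on the I-common term across distinct E-E
pairs yields R² above 0.8, while every other motif stays far behind.
In the asynchronous regime the second order is a near-perfect predictor
of the total correlation (R² ≈ 0.97); the fraction-of-total measure is
meaningful only when totals are positive, so `motif_regression_stats()`
refuses it when more than 5% of pairs have nonpositive totals (the
asynchronous case, where orders alternate in sign) and otherwise drops
the few nonpositive pairs with a message.

```{r motifs, eval = FALSE}
md <- motif_decomposition(lr)
motif_regression_stats(md)
common_input_grouping(md)
```

## Correlation susceptibility

For long windows the correlation inherited from shared input
factorizes through the single-cell quantity

$$S_i = \frac{A_{\langle g_I\rangle, i}(0)}{\sqrt{\nu_i}},$$

whose pairwise product equals
`A_i(0) A_j(0) / sqrt(C_ii(0) C_jj(0))` under the Poisson-variance
assumption `C_ii(0) = nu_i` (the square root in the definition is forced
by that factorization; `pair_susceptibility()` computes the pair form
with the full predicted spectra instead of the Poisson assumption).
`S_i` is negative — stronger inhibition lowers the rate — so pair
correlations grow with rate exactly when `|S|` does.

`single_cell_susceptibility()` walks the reductions: the full
six-parameter evaluation; nuisance parameters (`sigma_I`, `<gE>`,
`sigma_E`, `sigma`) replaced by E-population means (a choice: the
analysis concerns E-E pairs); additionally averaging `<gI>` so only
`theta` varies (the one-dimensional path the threshold-heterogeneous
network actually takes); and the alternative path at `theta = 1`
sweeping `<gI>` (rate diversity generated by inhibition instead of
excitability).  The two paths behave differently — along the threshold
path `|S|` falls with rate above roughly 5 Hz (correlations decrease),
along the inhibition path it rises up to roughly 15 Hz (correlations
increase) — which is the central mechanistic point: *how* rate diversity
is generated decides the correlation–rate relationship.
`rate_surface()` evaluates the reduced rate and susceptibility on a
`(<gI>, theta)` grid with both paths overlaid.

## Low-rank structure

If correlations follow `rho_ij = c S(nu_i) S(nu_j)` the off-diagonal
correlation matrix is rank one.  `rank_one_approx()` fits
`C ≈ lambda I + (sigma_1 - lambda) u_1 u_1^T` with the closed-form
shift

$$\lambda = \lambda_1 - \frac{\sum_{j>1} (\lambda_1-\lambda_j)^2}
  {\sum_{j>1} (\lambda_1-\lambda_j)},$$

which maximizes the Frobenius fraction captured by the leading
direction (verified against a brute-force grid search; exact on planted
diagonal-plus-rank-one matrices; equivariant under `C + mu I`).  The
leading vector's sign is fixed so its rate-weighted mean is
nonnegative.  Applied to the E-E correlation matrix at `T = 100` ms
(`ee_correlation_matrix()` orders cells by decreasing rate), the
approximation tracks the measured correlations in the strong
asynchronous regime and aligns `u_1` with firing rate, while in the
asynchronous regime it compresses everything into a narrow band near
zero — low-rank structure is a fingerprint of the correlation–rate
relationship.

## Monte-Carlo design and problem sizes

The simulator integrates at `dt = 0.01` ms (well below every time
constant; halving `dt` moves population rates by under 2%), holds
spiking cells for `ceil(tau_ref/dt)` steps while synapses keep evolving,
and detects crossings at step boundaries.  Spike counts are accumulated
directly into bins (1 ms by default; analyses re-bin by summation), and
each realization is independently initialized and equilibrated (1000 ms
discarded).  We verified that one long realization and many short
independently-equilibrated realizations give statistically
indistinguishable rates, Fano factors and correlations, so the package
defaults to few long realizations, which halves the equilibration
overhead.  The RNG is a self-contained counter-seeded xoshiro256++
stream, so a seed reproduces spike trains bitwise regardless of R's RNG
state.

Sampling scales used by the bundled acceptance script (chosen as a
desk-scale budget on which the headline statistics are stable):
400–800 s of simulated time per network seed, with every statistic of
a single random realization averaged over several independent network
seeds (the correlation-rate R² varies by ±20% across realizations at
`N = 100`).  Per-pair Pearson coefficients converge slowly, which
biases the raw regression R² downward at finite time;
`corr_rate_r2()` removes that attenuation by split-half
(Spearman–Brown) reliability correction, estimating the infinite-data
value, and both the acceptance script and the tests report the
corrected statistic.

What the generator does *not* emulate: synaptic delays and axonal
conduction, distance-dependent connectivity, plasticity, colored
background noise, and stimulus drive.  Passing tests therefore
demonstrate internal consistency of the theory and simulator under the
stated model, not fidelity to any particular biological dataset.

## Known limitations

* Linear response underestimates strong-asynchronous rates (15–20%) and
  mean correlations; its *relative* structure (which pairs are more
  correlated, and why) remains accurate, which is what the motif and
  susceptibility analyses use.
* Poisson-likeness is window-dependent: Fano factors sit in 0.9–1.1
  across the whole population at a 20 ms count window in both regimes,
  but at `T = 100` ms the fastest (low-threshold, high-rate) inhibitory
  cells drift up to ~1.2–1.3 — long-timescale dispersion that the
  renewal baseline cannot produce; at `T = 5` ms all Fano factors sit
  just below 1.
* The fraction-of-total motif measure is undefined for sign-alternating
  regimes (refused, see above).
* The threshold-integration engine assumes white conductance
  fluctuations; synaptic filtering enters the network theory through
  the interaction matrix, not the single-cell baseline.
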