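# eicorr

**When do pairwise spike-count correlations increase with firing rate in
recurrent E/I networks?**

`eicorr` is an R package for computational neuroscientists studying
correlated variability in recurrently coupled excitatory–inhibitory
networks of conductance-based leaky integrate-and-fire (LIF) neurons.
It provides, as one composable toolchain:

* a **synthetic network generator** — fixed in-degree or Erdős–Rényi
  E/I graphs (80 E + 20 I by default), second-order alpha conductance
  synapses, and lognormally heterogeneous spiking thresholds
  (`log θ ~ N(−s²/2, s²)` truncated to `[0.7, 1.4]`, `s = 0.2`), with
  two firing-regime presets: *asynchronous* (weak recurrent excitation,
  flat population spectra) and *strong asynchronous* (stronger
  `W_EE`, `W_IE`; occasional partial-population bursts);
* a compiled **Euler–Maruyama Monte-Carlo simulator**
  (`dt = 0.01` ms) with windowed spike-count statistics (rates, Fano
  factors, pairwise Pearson correlations `ρ_T`, population power
  spectra);
* a **threshold-integration engine** (Fokker–Planck boundary-value
  solver with multiplicative, voltage-dependent diffusion) for each
  cell's stationary rate, baseline spike-train spectrum `C⁰(ω)` and the
  susceptibilities `A(ω)` of its rate to modulations of `⟨g_E⟩`,
  `⟨g_I⟩`, `σ_E²`, `σ_I²` and the effective current;
* a **linear-response** layer assembling the interaction matrix
  `K̃(ω)` and the predicted cross-spectral matrix
  `C̃(ω) = (I−K̃)⁻¹ C̃⁰ (I−K̃*)⁻¹`, with windowed covariances via the
  triangular spectral kernel;
* a **motif decomposition** `C̃ = Σₙ P̃ⁿ`,
  `P̃ⁿ = Σₗ K̃ⁿ⁻ˡ C̃⁰ (K̃*)ˡ`, splitting correlations by path order and,
  at second order, by motif type (E/I chains vs E/I common input);
* **correlation susceptibility** analysis
  (`S_ij = A_i(0)A_j(0)/√(C̃_ii C̃_jj)`, single-cell reductions over the
  `(⟨g_I⟩, θ)` plane) explaining *when* correlations track rates; and
* a **shifted rank-one approximation**
  `C_T ≈ λI + (σ₁−λ)u₁u₁ᵀ`, with the closed-form optimal shift
  `λ = λ₁ − Σ_{j>1}(λ₁−λ_j)²/Σ_{j>1}(λ₁−λ_j)`, linking the
  correlation–rate relationship to low-dimensional structure.

The headline phenomenon: with weak recurrent excitation, E-E
correlations show *no* relationship with the pair's geometric-mean rate
`√(ν_i ν_j)`; with strong excitation a clear positive relationship
appears, carried mainly by shared inhibitory input, and the correlation
matrix becomes effectively diagonal-plus-rank-one with the leading
vector aligned to firing rate.

## Worked example

```r
library(eicorr)

net <- ei_network("strong_asynchronous", heterogeneous = TRUE, rng_seed = 1)
net
#> <ei_network> strong_asynchronous regime, 80 E + 20 I cells, 3600 edges (fixed_in_degree)
#>   thresholds: heterogeneous (s_theta = 0.2, range 0.703-1.382)

lr <- linear_response(net)   # self-consistent rates + per-cell spectra
lr
#> <ei_lr> 100 cells, 62 frequencies; mean rates E 5.60 Hz, I 35.93 Hz
#>   spectral radius of K(0): 0.433

lc <- lr_correlations(lr, windows = c(5, 100, Inf))
glance(lc)
#> # A tibble: 3 × 4
#>   window r_squared    slope mean_rho_EE
#>   <chr>      <dbl>    <dbl>       <dbl>
#> 1 5          0.377 0.000558     0.00613
#> 2 100        0.289 0.00324      0.0345
#> 3 Inf        0.261 0.00343      0.0363
```

The `r_squared` column is the OLS R² of predicted E-E correlation
against `√(ν_i ν_j)`: in this strong-asynchronous realization,
geometric-mean rate explains ~38% of the variability of 5-ms
correlations (it is below 0.02 in the asynchronous regime).  The motif
decomposition shows which paths carry the correlation:

```r
motif_regression_stats(motif_decomposition(lr))
#> # A tibble: 10 × 3
#>    term     order r_squared
#>  1 R1           1    0.550
#>  2 R2           2    0.454
#>  3 R3           3    0.383
#>  ...
#> 10 common_I     2    0.868
```

— inhibitory common input (`common_I`) predicts the total second-order
contribution with R² ≈ 0.87, an order of magnitude above any other
motif type.  Finally the correlation matrix is well approximated as
diagonal plus rank one, with leading weights ordered by rate:

```r
Cee <- ee_correlation_matrix(lc$rho[["100"]], lr$rates)
lrk <- rank_one_approx(Cee, rates = attr(Cee, "rates"))
lrk
#> <ei_lowrank> lambda = 0.9600, sigma1 = 3.8213, Frobenius fraction 0.894
approximation_quality(Cee, lrk, attr(Cee, "rates"))$u1_rate_spearman
#> [1] 0.905
```

Monte-Carlo counterparts of all of these come from
`simulate_network()` + `spike_count_stats()`; see the vignette
(`vignettes/correlation-firing-rate.Rmd`) for the model, the numerical
choices and their validation.

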