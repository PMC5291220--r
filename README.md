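# tempomem

Characterizing nonlinear time series — chaotic maps and flows, noise
processes, physiological recordings — through the *temporal networks* they
induce. A trajectory in phase space is coarse-grained over an equal-size
grid; every sampling step then stamps one directed, time-labelled edge
between the cells it connects. Two analyses are built on this lossless,
one-to-one representation:

* **Memory entropy.** For each memory order τ, the observed τ-step paths
  form the nodes of a consecutive memory network; its entropy growth rate

  H(τ) = − Σ_a π_a Σ_b T_ab ln T_ab,  T_ab = w(a,b) / Σ_b′ w(a,b′)

  (nats, empirical stationary weights π) measures how uncertain the next
  jump is given τ+1 cells of history. White noise collapses to H ≈ 0
  within two or three scales, an AR(3) process within about six, periodic
  signals sit at H ≡ 0, and chaotic signals decay *exponentially*,
  H(τ) ∝ exp(−ρτ). The decay rate ρ — the **memory exponent** — is fitted
  over the automatically located scaling window and tracks the largest
  Lyapunov exponent, which makes it a practical detector of bifurcations
  and periodic windows.

* **Betweenness preference.** Per node v, the count matrix
  B^v[ω₁, ω₂] = #{t : (ω₁, v; t), (v, ω₂; t+1)} of two-step
  time-respecting paths through v is summarized by its mutual information
  I^v (bits). I^v = 0 means v forwards flows independently of their
  origin (always true for periodic series); high-I^v cells mark
  preferential routing in phase space.

The package ships seed-reproducible generators for every benchmark
(logistic, Hénon, Ikeda, Rössler via fixed-step RK4, AR(3), white and 1/f
noise, plus SNR-controlled observational noise), the full pipeline from
series to exponent, the logistic-map bifurcation experiment with an
analytic Lyapunov reference, and a thin command-line front end.

## Worked example

```r
library(tempomem)

series <- gen_logistic(20000, mu = 4, n_transient = 4000, seed = 42)
fit <- memory_exponent(series, m = 2, l = 1, n_cells = 900)
fit
#> <tm_memory_fit> rho = 0.6062 (R^2 = 1.000, tau in [9, 13])
head(attr(fit, "profile"), 8)
#>   tau         H n_nodes
#> 1   0 0.8273855      88
#> 2   1 0.7416024     204
#> 3   2 0.7087625     435
#> 4   3 0.6837538     894
#> 5   4 0.6502119    1790
#> 6   5 0.5924166    3424
#> 7   6 0.4992667    6051
#> 8   7 0.3763192    9491
```

The fully chaotic logistic map (embedded with m = 2, l = 1 on a 30×30
grid) yields ρ ≈ 0.61 with an essentially perfect log-linear fit over the
scaling window τ = 9..13 — on the scale of its Lyapunov exponent
ln 2 ≈ 0.693. The profile also shows the flat, well-sampled head
(τ ≲ 6) that precedes the finite-sample scaling regime; the methods
vignette explains why the exponent lives in the latter.

Betweenness preference over the same network:

```r
traj <- delay_embed(as.matrix(series)[, 1], 2, 1)
gt <- temporal_network(symbolize(traj, fit_grid(traj, n_cells = 900)))
bp <- bp_distribution(gt)
sprintf("nodes scored: %d; share with I = 0: %.2f; max I = %.2f bits",
        nrow(bp), mean(bp$I < 1e-12), max(bp$I))
#> "nodes scored: 88; share with I = 0: 0.27; max I = 0.95 bits"
```

A heterogeneous distribution with a sizable spike at I = 0 and a few
high-I cells — the chaotic signature, versus I ≡ 0 for any periodic
series.

Command line (same pipeline, TSV in/out):

```sh
Rscript inst/cli/tempomem.R generate --system logistic --n 20000 --transient 4000 --seed 42 -o series.csv
Rscript inst/cli/tempomem.R entropy series.csv --m 2 --l 1 --cells 900 -o profile.tsv
Rscript inst/cli/tempomem.R rho profile.tsv
Rscript inst/cli/tempomem.R bifurcation --d-mu 0.005 --seed 1 -o scan.tsv
```

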