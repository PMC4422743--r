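# saxsens

Ensemble deconvolution of protein (un)folding from solution X-ray
scattering.

## The problem

Near its thermal midpoint a small protein is a mixture of interconverting
species — native molecules, partially (un)folded intermediates, and
denatured chains. A solution S/WAXS measurement sees only the
population-weighted average intensity of that mixture. `saxsens` is for
structural biologists and biophysicists who want to invert that average:
given a pool of candidate conformers (MD snapshots, NMR models, or the
package's own synthetic generator) and an experimental curve
*I*(*q*) over 0.01 < *q* < 0.7 Å⁻¹, it finds a small weighted
sub-ensemble whose average scattering reproduces the measurement,
tracks how the native / intermediate / unfolded populations shift with
temperature, and cross-validates the result against NMR observables that
were never used in the fit.

## The method

Single-conformer profiles come from the Debye equation with dummy-atom
excluded-volume solvent correction,

    I(q) = Σᵢ Σⱼ gᵢ(q) gⱼ(q) sin(q dᵢⱼ)/(q dᵢⱼ),
    gᵢ(q) = fᵢ(q) − ρₛ Vᵢ exp(−π Vᵢ^{2/3} q²),

with bulk density ρₛ = 0.340 e/Å³ and zero shell contrast by default.
An ensemble is a fixed-capacity multiset of pool indices (capacity
L = 20; a conformer's weight is its multiplicity / L). A genetic
algorithm — 20 elites per generation, 20 crossover + 40 mutation
offspring, survival of the best distinct multisets — minimizes the
squared log-intensity difference over the 0.07–0.7 Å⁻¹ window after a
closed-form scale,

    χ² = Σ_q [ln I_exp(q) − ln c − ln Ī_model(q)]².

Independent repeats give per-structure weights as mean ± sd of gene
fractions. Around the core estimator the package provides GROMOS-style
(Daura) RMSD clustering for pool reduction, Guinier fits, Rg-based
N/I/U population tables, RDC back-calculation with SVD-fitted alignment
tensors and sliding-window Cornilescu Q-factor maps, power-averaged NOE
violation counting (d̄ = ((1/N) Σ dᵢ⁻³)^(−1/3)), and a synthetic-data
generator (three-helix-bundle conformers with controlled unfolding) that
gives every stage a known ground truth.

## Worked example

Generate a 24-conformer pool at three unfolding levels, simulate a
mixture experiment (60% native / 30% intermediate / 10% unfolded with 1%
noise), and deconvolute it:

```r
library(saxsens)

pool <- generate_pool(levels = data.frame(u = c(0, 0.1, 1),
                                          undock = c(FALSE, TRUE, FALSE),
                                          count = c(8, 8, 8)),
                      seed = 1)
q  <- default_q_grid()
P  <- sapply(pool, function(s) debye_profile(s, q = q)$intensity)
rg <- sapply(pool, radius_of_gyration)

w <- numeric(24); w[c(2, 12, 20)] <- c(0.6, 0.3, 0.1)
expt <- synth_experiment(P, w, noise_model(0.01), seed = 2, q = q)

fit <- ensemble_fit(P, expt,
                    ga_config(iterations = 1000, repeats = 10, seed = 3),
                    pool_rg = rg)
print(fit)
```

```
<ensemble_fit> pool 24, capacity 20, 10 repeats
  best score 0.01691 (repeat 1), median 0.01691
  top structures by mean weight:
    #2: 0.600 +/- 0.000 (Rg 13.4 A)
    #12: 0.300 +/- 0.000 (Rg 26.5 A)
    #20: 0.100 +/- 0.000 (Rg 22.6 A)
```

Every repeat recovered the planted composition exactly: structure #2 (a
compact native conformer, Rg 13.4 Å) carries weight 0.600, the undocked
conformer #12 carries 0.300, the unfolded #20 carries 0.100, and the
best score ≈ 0.017 is the noise floor (the expected value is
(m−1)σ² ≈ 0.0126 for m = 127 grid points at σ = 0.01, and individual
realizations scatter around it). Classifying the weights by radius of
gyration — this undocked conformer happens to be extended (Rg 26.5 Å),
so by size it falls in the unfolded group:

```r
classify_by_rg(fit$weights, rg, rg_boundaries())
```

```
  condition fraction_N fraction_I fraction_U sd_N sd_I sd_U
1        NA        0.6          0        0.4    0    0    0
```

`run_pipeline()` chains the full workflow (pool → profiles → clustering →
per-condition GA fits → population table → NMR validation) from a single
config list or YAML file and writes TSV/JSON outputs plus a manifest; see
`?run_pipeline` and the methods vignette
(`vignettes/ensemble-deconvolution.Rmd`) for the model, parameter and
design details.

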