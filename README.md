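# edrconnectome

Generative models and comparison statistics for interareal cortical
networks built on the **exponential distance rule** (EDR): the empirical law
that the number of axonal projections of length *d* decays as
*p(d) = λ e^(−λd)*. The package is for computational neuroanatomists and
network scientists who want to ask how much of a connectome's binary and
weighted structure follows from a single decay rate plus cortical geometry,
and to compare brains of very different sizes on a common spatial template.

## What it implements

- **EDR / CDR random connectomes** over a fixed interareal distance matrix
  (`sample_edr()`, `sample_cdr()`): lengths drawn from the exponential law,
  pairs chosen within distance bins, randomly oriented unit connections
  accumulated into weights until a target binary density is reached. The CDR
  (constant distance rule) is the distance-blind null.
- **Decay-rate estimation** (`fit_decay()`): log-linear or Poisson-GLM fits
  of binned projection-length counts, at white-matter (0.5 mm bins) or local
  gray-matter scale (fit range up to 0.9 mm).
- **Model fitting by parameter matching** (`parameter_match()`): λ chosen to
  minimize |P(G_exp) − ⟨P(λ)⟩| over model ensembles, for P ∈ {M1, M2,
  3-motif profile, clique profile, second eigenvalue of AAᵀ}.
- **Comparison statistics**: directed 3-node motif census over the 16
  isomorphism classes with degree-preserving rewiring nulls and log
  residuals; clique census on the bidirectional skeleton; clique-union core
  extraction with block densities and a chance-likelihood formula;
  chance-corrected in-link similarity profiles versus distance with EDR
  ensemble envelopes; total wire length Λ = Σ A·D with yoked-permutation
  nulls and simulated-annealing placement optimization.
- **Common adimensional template** (`rescale_adimensional()`): distances
  divided by the species mean ⟨d⟩, so that γ = λ⟨d⟩ compares decay regimes
  across brains (γ ≈ 3.5 mouse-like, γ ≈ 5 macaque-like).
- **Synthetic species with known ground truth** (`make_species()`,
  `mouse_like_species()`, `macaque_like_species()`): jittered-grid areas on
  an elliptical sheet, Euclidean distances, one EDR realization, and an
  axon-length sample — a complete, serializable stand-in for the (non
  machine-readable) empirical datasets.

## Worked example

```r
library(edrconnectome)

mouse <- mouse_like_species(seed = 1001)   # 33 areas, <d> = 4.54 mm, rho = 0.68
distance_stats(mouse$D)
#> distance stats over 528 pairs: <d> = 4.54, d_max = 10.12, d_max/<d> = 2.23

fit_decay(lengths = sample_axon_lengths(0.78, 2e6, d_max = 10.1, seed = 421),
          binwidth = 0.5)
#> decay rate 0.7801 (95% CI 0.7775-0.7827), loglinear fit over 20 bins of width 0.5

pm <- parameter_match(sample_edr(mouse$D, 0.8, density = 0.68, seed = 31),
                      mouse$D, measures = c("M1", "M2", "motifs", "cliques"),
                      lambda_grid = seq(0.6, 1.0, by = 0.05),
                      n_ensemble = 200, seed = 32)
sapply(pm, function(r) r$lambda_hat)
#>      M1      M2  motifs cliques
#>    0.85    0.85    0.85    0.80
```

The fitted rates cluster within 0.05 mm⁻¹ of the planted 0.8 mm⁻¹: the EDR
statistics of one realization pin down the decay rate that generated it.
The `analysis/` directory contains six numbered drivers that run the whole
workflow (species synthesis → decay fits → parameter matching → motifs and
core → similarity on the adimensional template → wiring economy) and write
plain-text tables under `results/`.

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance quantity from
scratch — it draws two million projection lengths from the generating
truncated exponential law (rate 0.78 mm⁻¹, cutoff 10.1 mm), bins them at
0.5 mm, fits the decay with the package's estimator, and writes the result
as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/edr-comparative-connectomics.Rmd`) explains
the model and its assumptions, every tunable default with units, what the
synthetic species do and do not emulate, and the numerical conventions.
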