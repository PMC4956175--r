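---
title: "Comparative connectomics with the exponential distance rule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative connectomics with the exponential distance rule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edrconnectome)
```

## The model

Interareal cortical networks are directed, weighted and spatially embedded.
Tract-tracing surveys in both rodents and primates show that the number of
axons of length $d$ falls off exponentially,

$$p(d) = \lambda e^{-\lambda d},$$

the *exponential distance rule* (EDR), with a species-specific decay rate
$\lambda$ (about 0.78 mm$^{-1}$ in the mouse white matter, about
0.19 mm$^{-1}$ in the macaque). Combined with the geometry of the cortical
sheet — summarized by the matrix $D = \{d_{ij}\}$ of distances between area
barycenters and its unimodal distribution $q(d)$ — this single empirical law
turns out to constrain much of the binary and weighted structure of the
interareal graph.

`sample_edr()` implements the associated maximum-entropy-style generative
model. Each iteration draws a connection length from $p(d)$, locates its
distance bin, picks uniformly an unordered area pair whose separation falls
in that bin, and inserts a unit connection with a fair-coin orientation.
Repeated hits on the same ordered pair accumulate weight — which is how the
model produces its heavy, roughly log-normal weight distribution — and the
process stops exactly when the number of distinct ordered connected pairs
reaches the target, so the realized binary density always equals the
requested one. Draws falling beyond the largest distance or into bins that
contain no pairs are rejected and redrawn, which preserves the conditional
exponential law on the populated bins.

The *constant distance rule* (CDR) null, `sample_cdr()`, inserts each unit
connection on an unordered pair chosen uniformly among **all** pairs: the
distance-blind limit. A subtlety worth recording: the $\lambda \to 0$ limit
of the binned EDR algorithm weights *bins* uniformly, while the CDR weights
*pairs* uniformly. The two laws coincide exactly only when every bin holds
the same number of pairs (the regime in which the package tests their
equivalence); on a general geometry the CDR is the scientifically meaningful
null and is implemented by uniform pair choice, the definition used in the
comparisons.

## The common adimensional template

Brains of different sizes are compared after dividing all distances by the
species mean $\langle d \rangle$ (`rescale_adimensional()`), which maps both
a 10 mm mouse hemisphere and a 60 mm macaque hemisphere onto a template with
unit mean distance and maximum near 2.2. On this template the decay rate
becomes the adimensional

$$\gamma = \lambda \langle d \rangle,$$

about 3.5 for the mouse and 5 for the macaque: the larger brain lives in the
more strongly constrained regime.

## Fitting

Two routes to $\lambda$ are provided.

**Direct decay fitting** (`fit_decay()`): projection lengths (or pre-binned
neuron counts) are binned at a fixed width (0.5 mm at white-matter scale) and
the log counts regressed on the bin centers, or the counts fitted by a
Poisson GLM with log link. For equal-width bins the expected log count is
exactly linear in the bin center, so the slope estimates $-\lambda$ without
binning bias. One numerical choice matters: when a raw sample is truncated
*inside* the top bin (e.g. lengths up to 10.1 mm binned at 0.5 mm), that bin
is underfilled and sits at the point of highest leverage; `fit_decay()`
therefore drops an incomplete top bin. Confidence intervals are normal
approximations on the slope — the convention is not dictated by anything
deeper, and the reduced-sample recovery tests treat the published interval
(0.72, 0.83) as the acceptance band. The local gray-matter variant is the
same machinery restricted to short distances (`fit_range = c(0, 0.9)` mm).

**Parameter matching** (`parameter_match()`): for a data network
$G_{\mathrm{exp}}$ and a network statistic $P$, ensembles of EDR graphs at
the data's density are generated over a grid of $\lambda$ and the fitted
$\lambda_P$ minimizes $|P(G_{\mathrm{exp}}) - \langle P(\lambda)\rangle|$.
Scalar statistics ($M_1$, $M_2$, second eigenvalue of $AA^T$) are compared
directly; profile statistics (motif and clique counts) through the RMS of
log-ratios against the ensemble-mean counts, with size classes where either
count is zero dropped (and the number dropped reported — the handling of
zeros is a package choice). Grid minimization is used deliberately: the
objective is a noisy ensemble average, and a grid with a stated step is
reproducible where a continuous optimizer on noise is not. The default
ensemble is 1000 per grid point; tests and the analysis scripts use 60–200
with correspondingly widened tolerances.

## Comparison statistics

*Motifs.* Every node triple induces one of 16 directed isomorphism classes
(`motif_census()`), numbered by the package's documented canonical table —
ascending arc count, mutual-pair classes first — which places the lone
bidirectional pair at class 3 and the oriented 3-cycle at class 10; the
order coincides with the standard triad census, which serves as an
independent oracle in the tests. Profiles are judged against a
degree-preserving rewiring null (`rewire_degree_preserving()`, double-edge
swaps with rejection, default $10M$ attempts) through logarithmic residuals
$\ln(m_{\mathrm{data}}/\langle m_{\mathrm{null}}\rangle)$ with 95% bands
from the null percentiles; classes with a zero null mean are flagged, not
computed, and a zero lower percentile is floored at half a count before
taking logs.

*Cliques and core.* Cliques live on the bidirectional skeleton (an
undirected edge requires links in **both** directions — a 12-area set with a
single missing directed link yields two 11-cliques, not a 12-clique). All
cliques of every size are counted, not only maximal ones; the core is the
union of all maximum cliques, ties included, and block link counts and
densities follow. The chance likelihood of such a core under an equally
dense random graph (`core_likelihood()`) is evaluated in log space; note
that evaluating the printed formula with the printed mouse inputs gives
$\sim 7 \times 10^{-12}$, not the published $2.07 \times 10^{-12}$ — the
package implements the formula as stated and documents the discrepancy
rather than resolving an unstated convention.

*Similarity.* The in-link similarity of target areas $x,y$ counts the
sources from which both or neither receive input, corrected by the
expectation for independent random in-links of the same degrees:
$S = n/N - [(k_x/N)(k_y/N) + (1-k_x/N)(1-k_y/N)]$. All $N$ areas count as
potential sources, including $x$ and $y$ themselves (the convention forced
by the bound $n \le N$; absent self-connections contribute "neither"
agreements). The index is symmetric, bounded by 1 in magnitude, and averages
to zero on Erdős–Rényi graphs. `ensemble_similarity_density()` pools pair
clouds over an EDR ensemble (300 networks by convention) and smooths them
with `MASS::kde2d` under a Silverman-style bandwidth — the smoothing is
presentation, not inference.

*Wiring.* Total wire length $\Lambda = \sum_{ij} A_{ij} D_{ij}$ is judged
against a yoked-permutation null (rows and columns of $A$ permuted together,
leaving all topology intact) and against simulated annealing over area
placements (swap moves, Metropolis acceptance, geometric cooling, defaults
$T_0 = \Lambda/100$, factor 0.999, $10^5$ steps — the schedule is a package
default, stated because no canonical one exists). Two genuinely different
behaviors emerge and are worth stating precisely: EDR networks are already
nearly wire-optimal (annealing shaves a fraction of a percent), while CDR
networks, whose placement carries no distance information, leave several
percent on the table. An earlier draft of the test plan expected the CDR
reduction to be near zero; measurement shows the opposite, for the reason
just given, and the tests assert the measured, explainable contrast.

## The synthetic species

No machine-readable empirical matrices ship with the package, so synthetic
species (`make_species()`) stand in, with every generator default a stated
condition rather than a tunable: 33 areas; mean interareal distance 4.54 mm
(mouse-like) or 26.35 mm (macaque-like); decay rates 0.78 and
0.188 mm$^{-1}$; densities 0.68 and 0.66. Geometry is a jittered grid
clipped to an elliptical sheet: uniform rectangles cannot reach the
empirical $d_{\max}/\langle d \rangle \approx 2.2$ (any rectangle gives
$\gtrsim 2.7$), while a disc lands there naturally. A radial `spread` knob
pushes areas toward the rim to mimic the more peaked distance distribution
of a folded cortex; it was calibrated once against the published ratios
(2.22 mouse, 2.21 macaque) and is not revisited. Axon-length samples are
drawn from the realized edge lengths with multiplicity, so decay-rate
recovery exercises the same pathway as binning labeled neurons.

What a green test on these fixtures does **not** establish: anything about
the real matrices' particular values (the published $\lambda$-range
0.78–0.93 from data fits, the 12%/5% annealing reductions, the 0.608
variance ratio of normalized distance distributions). Those depend on the
actual empirical geometry and connectivity and are deliberately outside the
test surface; the fixtures establish that the estimators recover known
ground truth and that the model reproduces the *qualitative* empirical
behaviors (motif residual structure, similarity–distance decay, wire
economy).

## Numerical conventions and degenerate inputs

- Histogram bins are left-closed, right-open, with the top edge closed so
  the maximum is counted; sampler bin width defaults to $d_{\max}/25$
  (about 0.4 mm at mouse scale, a few mm at macaque scale).
- The permutation variance-ratio test includes the observed ratio in the
  permutation distribution (minimum attainable $p = 1/(n_{\mathrm{perm}}+1)$)
  and defines "more extreme" two-sidedly as below $\min(r, 1/r)$ or above
  $\max(r, 1/r)$, which reduces to the published one-sided phrasing when
  $r < 1$.
- Degenerate cases error early and loudly: non-symmetric or non-positive
  distance matrices, zero-variance samples, all-zero histograms, empty
  common support in log-ratio comparisons, saturated target densities.
  Perfect separation in the connection-probability GLM is flagged, with no
  estimates returned.
- All stochastic entry points take a `seed`; ensemble routines derive child
  seeds from the master seed, so every reported number is reproducible
  bitwise.

## A worked run

```{r example, eval = FALSE}
mouse <- mouse_like_species(seed = 1001)
fit <- fit_decay(lengths = mouse$axon_lengths, binwidth = 0.5)
match <- parameter_match(mouse$connectome, mouse$D,
                         measures = c("M1", "M2", "motifs", "cliques"),
                         lambda_grid = seq(0.6, 1.0, by = 0.05),
                         n_ensemble = 200, seed = 7)
core <- extract_core(mouse$connectome)
```

The numbered scripts under `analysis/` run this workflow end to end —
species synthesis, decay fitting, parameter matching, motif/core analysis,
the adimensional similarity comparison, and wiring — writing plain-text
tables under `results/`.

## Known limitations

- The EDR is treated as isotropic and area-independent; per-target
  variability of real decay curves is observed biology the model
  intentionally averages over.
- Distances are exact inputs; no white-matter path or folded-surface
  geometry is computed.
- The clique census is exponential in the worst case; it is comfortable at
  $N \approx 33$ and the densities used here, not at hundreds of areas.
- The annealing optimizer is a baseline, not a state-of-the-art placement
  solver; it is used to measure slack, not to certify global optima (except
  on planted instances where the optimum is known).
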