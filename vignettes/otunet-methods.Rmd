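---
title: "Methods: depth-stratified soil microbiome analysis and co-occurrence networks"
author: "otunet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-stratified soil microbiome analysis and co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otunet)
```

# Scope

`otunet` implements the computational chain used to analyze 16S amplicon OTU
tables from depth-stratified fertilization experiments: three treatments
(unfertilized control CK, mineral fertilizer CF, mineral fertilizer plus
farmyard manure CFM) sampled at four depth layers (0–20, 20–40, 40–60,
60–90 cm) with three field replicates, 36 samples in all. The pipeline
starts at the OTU count table; read merging, quality filtering, OTU picking
and chimera removal are upstream of its scope. Analysis proceeds in four
stages: preprocessing, community ordination and tests, negative-binomial
differential abundance, and co-occurrence network inference. A synthetic
community generator with a machine-readable ground truth supports
validation of every stage.

# Preprocessing

OTUs whose count summed over *all* samples equals exactly 1 are removed
before rarefaction; this table-wide definition matches common practice
after pooled OTU picking, and per-sample singletons are deliberately kept
because Good's coverage needs them. Each sample is then rarefied to a fixed
depth (default 9500 reads) by a single multivariate hypergeometric draw —
one seed-controlled subsample per sample, not an average over repeated
rarefactions. Samples below the target depth are dropped with a logged
warning rather than padded. Good's coverage is $C = 1 - F_1/N$ with $F_1$
the per-sample singleton count and $N$ the sample total; it is computed on
the rarefied table by default (a flag selects pre-rarefaction counts — the
choice is not fixed by the protocol the pipeline follows, so both are
available). Rarefaction curves use the exact hypergeometric expectation

$$E[S_m] = \sum_i \left(1 - \binom{N - N_i}{m}\middle/\binom{N}{m}\right),$$

evaluated through `lchoose` so that large read totals cannot overflow.

# Ordination and community tests

Community dissimilarity is Bray–Curtis on Hellinger-transformed counts
($y_{ij} = \sqrt{n_{ij}/N_j}$). Pairing Hellinger with Bray–Curtis rather
than with the Euclidean distance is unusual but deliberate — it reproduces
the analysis protocol this package implements; a Euclidean-on-Hellinger
comparison is a one-line change for the user since both steps are exposed.

PCoA applies Gower double-centering to $-d^2/2$ and eigendecomposes;
coordinates use positive eigenvalues only, and negative eigenvalue mass is
reported without Lingoes/Cailliez correction (matching the default behavior
of the standard ordination tooling). ANOSIM uses mid-ranked
dissimilarities, $R = (\bar r_{between} - \bar r_{within})/(M/2)$ with
$M = n(n-1)/2$, and a one-sided permutation p-value with the add-one
convention $p = (1 + \#\{R^* \ge R\})/(1 + B)$; when $n! \le B$ the
permutation distribution is enumerated exhaustively and the exact tail is
returned instead. db-RDA regresses the positive-eigenvalue PCoA axes on the
standardized (z-scored, $n-1$ denominator) environmental matrix;
pseudo-$F = (\text{constrained}/q)/(\text{residual}/(n-q-1))$ is tested by
permuting environment rows. Per-variable goodness-of-fit follows the
vector-fitting convention — $R^2$ of each variable regressed on the first
two ordination axes (the plotted plane) with its own permutation test; when
a stratum has fewer samples than variables plus residual degrees of freedom
(the 9-sample topsoil stratum with 8 soil variables), the constrained model
is impossible for any implementation and the command-line pipeline reports
the vector fits alone. The Mantel statistic is the Pearson correlation of
upper-triangle dissimilarities with joint row/column permutation of the
second matrix, sharing the add-one/exhaustive conventions above. All
permutation tests default to 999 permutations.

# Differential abundance

The between-treatment test is a negative-binomial Wald test in the style of
the standard count-based differential abundance machinery, re-implemented
at desk scale with a simplified dispersion treatment:

* **Size factors** are median-of-ratios: the reference is the geometric
  mean profile over OTUs positive in every sample (falling back to OTUs
  positive in at least half the samples), and $s_j$ is the arithmetic
  median of count-to-reference ratios.
* **Dispersions** ($\alpha$ in $\mathrm{var} = \mu + \alpha\mu^2$) are
  per-OTU method-of-moments estimates from within-group variances of
  normalized counts, shrunk toward a robustly fitted $a_1/\mu + a_0$ trend
  by degrees-of-freedom weighting (prior weight 6 df, floor $10^{-8}$).
  This replaces the full empirical-Bayes MAP machinery on purpose: it keeps
  the estimator transparent and testable while preserving the intent —
  sharing information across OTUs. No independent filtering and no
  fold-change shrinkage are applied, because the downstream selection rule
  uses raw $\log_2$ fold changes.
* **The Wald test** fits $\mu_{ij} = s_j q_i 2^{\beta_i x_j}$ per OTU by
  IRLS with the dispersion held fixed, reports $\beta_i$ (log2 fold
  change), its standard error from the expected information, and the
  two-sided normal p-value. OTUs all-zero in both groups are flagged with
  $\beta = 0, p = 1$; non-convergent fits are flagged and never abort the
  table.

p-values are BH-adjusted within each contrast separately, and OTUs are
classified **enriched** ($\beta > 1$, $q < 0.1$) or **depleted**
($\beta < -1$, $q < 0.1$). For the subsoil contrasts the three deeper
layers are pooled as replicates (9 vs 9); depth-as-covariate modeling was
considered and deferred since the pooled design is what the topsoil/subsoil
split implies. The union of enriched and depleted OTUs across a stratum's
CF and CFM contrasts, each labeled with its source contrast(s), feeds the
network stage.

# Co-occurrence networks

Spearman correlations are computed as Pearson correlations of mid-ranked
abundance rows, with two-sided p-values from the t approximation
$t = r\sqrt{(n-2)/(1-r^2)}$ (a permutation option would be a drop-in; the
t approximation is the default because the network stage operates on 27–36
samples where it is accurate). BH adjustment runs over the full upper
triangle of the selected-OTU matrix — the set of tests actually performed
per network.

The correlation cutoff is chosen automatically by random-matrix-theory
scanning. For each candidate $t$ on a grid (default 0.30–0.95, step 0.01),
entries with $|\rho| < t$ are zeroed and the eigenvalue spectrum of the
resulting matrix is examined: near-degenerate eigenvalues are removed
(isolated nodes pile up identical eigenvalues), the spectrum is unfolded
with a monotone cubic (Hyman) spline over roughly $n/10$ knots of the
empirical spectral CDF, and nearest-neighbour spacings are histogrammed in
bins of width 0.1 on $[0, 3]$, pooling adjacent bins to expected counts of
at least 5 so the chi-square approximation stays valid on small spectra.
Uncorrelated (modular) spectra show Poisson spacings $P(s) = e^{-s}$; dense
random spectra show Wigner–Dyson repulsion
$P(s) = \frac{\pi}{2} s\, e^{-\pi s^2/4}$. A grid point is
Poisson-consistent when the Poisson chi-square test passes at 0.05 *or* the
histogram is strictly closer (chi-square per degree of freedom) to the
Poisson law than to the Wigner–Dyson law; the chosen threshold is the
smallest consistent point whose successor is also consistent. The relative
Poisson-vs-Wigner comparison matters: on spectra of a few dozen
eigenvalues, the absolute goodness-of-fit test over-rejects (block
structure leaves residual repulsion inside each block's bulk), which would
occasionally push the scan past the true within-module correlation level.
If no stable point exists the normalized chi-square minimizer is used, with
a warning. All knobs (grid, pass level) are exposed in the configuration.

Edges join OTU pairs with $|\rho| \ge t$ and BH-adjusted correlation
$q < 0.001$; self-connections are removed, isolated nodes are retained but
flagged, and edge signs are kept as attributes. Modularity and centralities
operate on the sign-ignored unweighted graph: exact betweenness by Brandes'
algorithm (unnormalized, each unordered pair counted once, equal splitting
over shortest paths), and module detection by Clauset–Newman–Moore greedy
modularity maximization with deterministic lexicographic tie-breaking.
Modules with at least 4 nodes are reported; smaller communities stay in the
raw partition. Keystones are ranked by betweenness, ties broken by degree
then OTU id. Each module's source composition counts members per selecting
contrast, and module–environment association is a Mantel test between the
Bray–Curtis dissimilarity on the module's counts and the Euclidean distance
of each standardized soil variable, BH-adjusted across variables within a
module.

# The synthetic community generator

`generate_dataset()` emulates the post-OTU-picking state of the 36-sample
design. Counts are drawn $\mathrm{NB}(\mu_{ij}, \alpha_i)$ with

$$\log_2 \mu_{ij} = b_i + \beta_i x_{t(j)} + \delta_i\,\ell(j)
  + \lambda f_{m(j)} + \varepsilon_{ij},$$

where $b_i$ is a baseline log2 relative mass (background OTUs uniform on
[0, 6.5], planted OTUs on [5.5, 6.5] so planted effects act on
well-observed counts of roughly 50–120 reads after rarefaction), $\beta_i$
a planted treatment fold change ($|\beta| = 2$ by default), $\delta_i$ a
monotone depth slope on a random 20% of background OTUs (0.3–0.8 log2 per
layer, giving ordination and ANOSIM a true depth signal), and $f_m$ a
standard-normal latent factor shared by module $m$'s members. Relative
masses are normalized within each sample and scaled by a library size drawn
from 15 000–30 000 before NB sampling, so the data are compositional like
real amplicon counts. Module $m$'s environmental covariate is
$f_m + \mathcal N(0, 0.5)$, mapped onto SOC for the first module and Olsen
P for the second; the remaining soil variables carry depth trends plus
noise at realistic scales.

Two calibration choices were made once, at design time, and are worth
recording. First, module members also carry planted treatment fold changes
(odd-numbered modules enriched under CFM, even-numbered under CF and CFM):
the network stage consumes *differentially abundant* OTUs only, so modules
that were invisible to the selection rule could never appear in any
network. Second, the latent amplitude and the residual dispersion of module
members trade off against each other: the latent factor is genuine
between-sample variance, so the dispersion estimator absorbs it and large
amplitudes destroy Wald power, while small amplitudes leave within-module
correlations undetectable at $q < 0.001$. The defaults
(`module_latent_sd = 0.8`, `module_latent_correlation = 0.9`,
`module_dispersion = 0.05`) place realized within-module Spearman
correlations near 0.75 and planted fold-change recovery power above 90% on
the pooled subsoil contrast — a regime in which both ends of the pipeline
have something real to find, which is what a validation dataset is for.

`simulate_correlated_blocks()` generates Gaussian profiles with exact
planted correlation blocks (shared factors), optional weak between-block
correlation, and an optional bridge variable loading on two block factors.
It validates the RMT scan (blocks must survive thresholding as connected
components) and keystone ranking (the bridge must carry maximal
betweenness). The bridge is planted at the correlation level rather than in
the count generator because the ground-truth contract guarantees that no
OTU belongs to two modules.

What the generator does *not* emulate: taxon-realistic rank-abundance
shapes (taxonomy is a fixed mock lineage list assigned round-robin, present
only to exercise joins and reporting), sequencing-error or chimera
artifacts, phylogenetic correlation among OTUs, and environmental
confounding between treatment and depth. Passing the validation suite
therefore demonstrates that the *algorithms* recover known structure under
the stated statistical model, not that any biological conclusion from real
data is correct.

# Numerical and convention choices

* Permutation p-values use the add-one convention everywhere, never return
  0, and switch to exhaustive enumeration when $n! \le B$.
* Ties are mid-ranked everywhere (ANOSIM, Spearman).
* The BH family is per contrast for differential abundance, the full
  upper triangle per network for correlations, and per module for
  module–environment tests.
* IRLS runs at most 50 iterations to $10^{-10}$, coefficients clamped to
  $\pm 50$ on the natural-log scale; hitting the clamp marks the OTU
  non-convergent rather than reporting a pseudo-infinite fold change.
* Degenerate inputs are defined outcomes, not crashes: all-zero OTUs and
  samples, constant dissimilarities (Mantel $r$ reported as 0 with a
  warning), edgeless networks ($Q = 0$, singleton partition), identity
  correlation matrices in the RMT scan.
* Writers emit 6 significant digits for reals and scientific notation for
  p-values, making identical runs byte-identical.

# Validation problem sizes

The test suite validates against independent oracles at sizes where the
oracles are exact: exhaustive permutation enumeration at 5–6 samples,
all-shortest-path betweenness enumeration on graphs of up to 8 nodes, and
hand-derived closed forms. Statistical calibration uses 500 replicates for
the Mantel and db-RDA permutation-p uniformity checks (12 samples, 99
permutations each) and four null generator datasets (2000 Wald tests) for
the type-I error check. Parameter recovery runs the full pipeline on 20
generator seeds at the default scale (500 OTUs, 36 samples) and 20
planted-block replicates for the RMT and keystone checks. These sizes give
the binomial and Kolmogorov–Smirnov bounds used in the assertions
meaningful power while keeping the whole suite comfortably under a minute
of computation.

# Known limitations

* The dispersion shrinkage is deliberately simpler than the full
  empirical-Bayes treatment; at very small replication (3 vs 3) its Wald
  test is mildly conservative at low counts.
* RMT threshold selection needs a spectrum to work with: below 20 selected
  OTUs the scan refuses and asks for a manual threshold, and on spectra of
  a few dozen eigenvalues the chosen threshold tends to sit at the lower
  end of the grid.
* PCoA negative eigenvalues are reported, not corrected; coordinates span
  positive axes only.
* Signed-modularity variants are not implemented; edge signs are
  attributes, and community structure is computed on topology alone.
* The Spearman p-values use the t approximation; an exact permutation
  alternative is not currently wired into the network stage.
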