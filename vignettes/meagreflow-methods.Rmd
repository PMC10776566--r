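---
title: "Methods behind meagreflow: larval drift, population genetics and telemetry"
author: "meagreflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind meagreflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`meagreflow` assembles the three computational legs commonly combined in
marine population-connectivity studies of coastal fishes such as the Atlantic
meagre: (i) a Lagrangian biophysical model of passive larval drift over
gridded ocean currents, summarised as dispersal-distance statistics and
pairwise oceanographic-connectivity matrices; (ii) population-genetic
analyses of biallelic SNP panels and mitochondrial control-region sequences;
and (iii) telemetry track summaries for adult movement. Every input can be
generated synthetically with seeded reproducibility, so the full pipeline is
testable end to end without external data. This vignette records the models,
the tunable parameters, the numerical conventions, and the design choices
made where the methodology left the details open.

# Synthetic data: what it emulates and what it does not

The fixture generators mirror the *structure* of the real inputs, not their
content.

* **Velocity fields** are daily u/v grids at 0.08° (the resolution of the
  HYCOM-class reanalyses used for this kind of work), with a land mask from
  polygons. Analytic kinds (`zero`, `uniform`, `double_gyre`,
  `solid_rotation`) have closed-form node values and exist chiefly so the
  advection code can be verified against physics; `random_smooth` is a
  seeded sum of low-order Fourier modes giving a smoothly varying,
  divergence-unconstrained flow. None of these emulates real mesoscale
  ocean dynamics; conclusions about a real coastline require real forcing.
* **Genotypes** follow the Balding–Nichols model: per locus an ancestral
  minor-allele frequency $p$ is drawn uniformly from a configurable range,
  each subpopulation's frequency from
  $\mathrm{Beta}\!\big(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$
  (so $E[p_k]=p$ and $\mathrm{Var}[p_k]=F\,p(1-p)$, giving expected
  $F_{ST}=F$; $F=0$ is taken as the exact limit $p_k=p$), and genotypes as
  two binomial allele copies. Loci are unlinked and missingness is injected
  uniformly at random — there is no linkage disequilibrium, no allele-drop
  bias, and no coalescent history, so tests passing on these fixtures
  demonstrate estimator correctness, not robustness to real ascertainment.
* **Haplotype alignments** are built from a recorded mutation tree: each
  haplotype derives from a stated parent by one substitution at a site of
  its own, so every pairwise Hamming distance equals the tree-path length
  and the generator's graph is exact ground truth for network tests.
  Per-locality sample counts are produced by largest-remainder rounding of
  the requested frequencies, so small samples are deterministic.
* **Tracks** interpolate stated waypoints at stated times, with optional
  isotropic Gaussian positional noise (km). No behaviour or geolocation
  error model is implied.

One named RNG stream per fixture kind is derived from the master seed
(`derive_seed`), so adding a fixture never changes another fixture's draw.

# Larval drift model

Particles are passive 2-D surface drifters. Positions advance hourly (the
step is configurable) by forward Euler, converting velocities in m/s to
degrees with a spherical metric ($R = 6371$ km) and a cos-latitude
correction; a classical 4th-order Runge–Kutta integrator is available and
is what the convergence and solid-rotation rotation-return checks use,
since first-order integration is the documented default for production
parity with hourly positioning rather than an accuracy claim.

* **Interpolation.** Bilinear over the four surrounding grid nodes;
  land nodes are dropped from the stencil with weight renormalisation, and
  a fully-land stencil is the beaching signal. Daily fields are taken as
  piecewise-constant in time (the forcing is daily, positions hourly, and
  only spatial interpolation is part of the stated method); a query beyond
  the last day clamps to the final frame.
* **Fates.** The first event among: *settled* — the particle enters a
  settlement polygon; *beached* — all-land stencil; *lost_open_ocean* —
  exit from the grid; *expired* — reaching the maximum drift duration
  (default 30 days, a pelagic larval duration). Settlement is an *entry*
  event: a particle released inside its own site's settlement polygon does
  not settle until it has first left that polygon, which makes the
  zero-current field yield `expired` (not instant self-settlement) while
  still allowing genuine local retention. Settlement at the same hour as a
  would-be beaching resolves to settlement.
* **Settlement geometry.** Each site's settlement polygon defaults to its
  spawning polygon expanded radially by 10 km about its centroid — an
  operational reading of "the coastal area including a spawning location".
  The buffer is approximate (radial in local-metric km) and configurable.
* **Release design.** Spawning polygons are rasterised at ~3 km (the
  analysis scripts use 8 km to keep particle counts desk-sized) in a local
  equal-area approximation; cells whose centroid is on land are dropped,
  and a polygon smaller than one cell falls back to its centroid. Releases
  happen for every site, year, in-season day and cell,
  `release_per_day` particles each.
* **Statistics.** Dispersal distance is the great-circle
  (haversine, $R=6371$ km) distance from release to final position,
  whatever the fate; the 95th percentile uses the linear-interpolation
  (type-7) quantile. Connectivity $P_{ij}$ is the fraction of particles
  released at $i$ whose fate was settlement at $j$; rows of sites with
  zero releases are undefined (`NA`), never $0/0$.

# Nuclear SNP statistics

* **QC.** Loci are filtered in the fixed order call rate (default
  $\ge 0.95$) → pooled minor-allele frequency ($\ge 0.05$) →
  reproducibility; the order only affects per-criterion removal counts,
  not the surviving set, and both are reported. Individuals above a
  missingness ceiling are dropped first in the analysis scripts, with
  per-locality sample sizes reported.
* **Diversity.** Observed allele counts, observed heterozygosity, unbiased
  expected heterozygosity $2p(1-p)\cdot\frac{2n}{2n-1}$, and rarefied
  allelic richness by hypergeometric rarefaction
  $A_r = \sum_a \big[1 - \binom{N-N_a}{g}\big/\binom{N}{g}\big]$ to a
  common gene-copy count $g$.
* **HWE.** Levene's exact conditional distribution of the heterozygote
  count given the allele counts; the two-sided p sums all configurations
  no more probable than the observed one, and heterozygote deficiency is
  flagged from the one-sided tail. The implementation is verified against
  an independent recursive enumeration for every configuration with
  $2n \le 30$.
* **LD.** Genotypic association per locality by Fisher's exact test on the
  3×3 genotype table — a deliberate, documented approximation to the
  Markov-chain unphased exact test of GENEPOP-class software. Being an
  exact conditional test it is conservative at small counts; its measured
  type-I rate sits at or below the nominal level.
* **$F_{ST}$.** Weir–Cockerham (1984) variance components $a$, $b$, $c$
  per locus; the multilocus estimate is
  $\hat\theta = \sum_l a_l \big/ \sum_l (a_l+b_l+c_l)$ with loci
  monomorphic across the compared populations excluded and per-locus
  complete-case handling of missing genotypes. Pair-level significance is
  by permutation of individuals between the two localities with the
  $(1+\#\{\theta^*\ge\hat\theta\})/(1+N)$ convention (a permutation p is
  never exactly zero).
* **Standardised $F_{ST}$.** Hedrick-style:
  $\theta' = \theta / \theta_{max}$ with
  $\theta_{max} = (k-1)(1-H_S)/(k-1+H_S)$, where $H_S$ is the mean
  unbiased within-population gene diversity of the pair. The unstandardised
  $\theta$ is always reported alongside, since "standardised pairwise
  differentiation" admits more than one formula in the literature.
* **Isolation by distance.** Simple Mantel test: Pearson correlation of
  upper-triangle entries, simultaneous row/column permutation of one
  matrix, default 1000 permutations, $(1+\text{count})/(1+N)$ p. Geographic
  distances are Euclidean on equirectangular-projected coordinates by
  default (great-circle available); no coastline-following distance is
  implemented.
* **Outlier scan.** The reversible-jump MCMC machinery of Bayescan-class
  software is out of scope; its scientific role — flagging loci with
  unusually high or low differentiation — is filled by a permutation scan.
  Per locus, the multi-population $\theta_l$ is compared with the null
  built by shuffling locality labels (one shuffle per replicate, applied
  to all loci). The two-sided statistic is the absolute deviation of
  $\theta_l$ from the permutation-ensemble mean; because $\theta_l$ is
  discrete under label permutation (ties are common and the lower tail can
  be unreachable, which makes naive tail-doubling badly conservative), the
  comparison uses a seeded uniform tie-break, which restores an exactly
  uniform null p while keeping the $(1+\text{count})/(1+N)$ form.
  Benjamini–Hochberg q-values accompany the raw p-values.

# Mitochondrial DNA

* **Collapse.** Identical sequences share a haplotype, labelled in order
  of first appearance. Under the default policy a sequence with `N`/gap
  characters merges into the first haplotype matching at every resolved
  site (falling back to founding its own); a strict policy treating
  ambiguity codes as ordinary states is available. Hamming distances
  exclude ambiguous sites pairwise.
* **Diversity.** Nei's unbiased haplotype diversity
  $h = \frac{n}{n-1}(1-\sum_i p_i^2)$.
* **Haplotype $F_{ST}$.** $(H_T - H_S)/H_T$ with $H_S$ the
  sample-size-weighted mean of unbiased within-locality diversities and
  $H_T$ the unbiased diversity of the pooled sample; two localities fixed
  for the same haplotype give 0 by convention, and significance is by
  permuting samples between the pair (default 1000 permutations).
* **Median-joining network.** Starting from the observed haplotypes
  (restricted to variable sites), the algorithm repeatedly adds the
  majority-consensus (quasi-median) vector of a node triple that most
  reduces the minimum-spanning cost of the node set, with lexicographic
  tie-breaks; when no candidate helps, medians whose removal leaves the
  spanning cost unchanged are pruned, and the result is the minimum
  spanning *network* (all spanning edges tied within the `epsilon`
  tolerance, `epsilon = 0` default) over the final node set. Edge weights
  are mutation counts. On small panels the produced cost is verified
  against an exhaustive Steiner search; the greedy construction is not
  guaranteed optimal on arbitrary inputs.

# Clustering

* **Admixture model.** A Gibbs sampler with *independent*
  $\mathrm{Beta}(1,1)$ allele frequencies per cluster and
  $\mathrm{Dirichlet}(1,\dots,1)$ memberships — deliberately simpler than
  the correlated-frequencies F-model of STRUCTURE. The simplification
  preserves the scientific contract exercised here (cluster recovery at
  moderate divergence) at a fraction of the implementation risk, and is
  the package's documented divergence from that software. Each sweep
  samples allele-copy origins, then frequencies and memberships from their
  conjugate posteriors; the observed-data log-likelihood
  $\sum_{il}\log\mathrm{Binom}(x_{il}\mid 2, \sum_k q_{ik}p_{kl})$ is
  recorded every iteration and posterior means are accumulated after
  burn-in. Desk-scale defaults (2000 iterations, 500 burn-in; the analysis
  scripts use the same order of magnitude) replace the production-scale
  500k/200k settings of STRUCTURE-era workflows, which remain available
  through the arguments. Label switching across runs is resolved by greedy
  matching of Q columns, deterministically.
* **$\Delta K$.** Evanno's criterion over replicate runs:
  $\Delta K = |\bar L(K+1) - 2\bar L(K) + \bar L(K-1)| / \mathrm{sd}(L(K))$,
  defined for interior K, undefined where the replicate sd is zero. The
  replicate likelihood is the post-burn-in mean of the trace.
* **PCoA.** Classical metric scaling via Gower double-centring
  (`stats::cmdscale`); negative eigenvalues are reported, never silently
  dropped. The individual-level genetic distance is the allele-sharing
  distance (mean over non-missing loci of |dosage difference|/2).
* **DAPC.** Mean-imputed, centred dosages → principal components (the
  smallest set explaining ≥ 90% of variance, replacing the interactive
  choice of adegenet-class software) → linear discriminant analysis, with
  individual scores and posterior memberships.

# Telemetry

Great-circle leg distances (haversine, $R = 6371$ km) between consecutive
records, cumulative track length, maximum pairwise displacement, and the
maximum distance within any sliding 365-day window ("distance in a single
year" without assuming calendar years). Zone transitions classify each
record by containing polygon (non-overlap is validated; records outside all
zones are "offshore") and report consecutive-record zone changes.
Positions are consumed as given — geolocation modelling is out of scope —
with an optional per-record uncertainty carried through.

# Pipeline orchestration and determinism

`run_all()` executes fixtures → dispersal → SNP genetics → mtDNA →
clustering → telemetry from a single YAML configuration with a versioned
schema (unknown keys are rejected with itemised messages). Every stage's
seed derives deterministically from the master seed; stage failures are
recorded in the manifest and dependents are skipped. The manifest carries
stage status, output paths, md5 checksums, timings and the package version;
two runs with the same configuration and seed produce checksum-identical
outputs, which is the tested determinism contract (timings and timestamps
are excluded from it).

# Problem sizes and numerical conventions

The bundled analyses and tests run at desk scale by design: grids of a few
degrees at 0.08°, hundreds to ~1700 loci, tens of individuals per
locality, hundreds to ~2500 sampler iterations, 199–1000 permutations.
These sizes were chosen so the full suite exercises every code path in
minutes on one core while leaving estimator behaviour measurable (e.g.
$F_{ST}$ recovery to ±0.02 at 1000 loci). Scaling the same calls up to
production sizes changes nothing but wall-clock time.

Other conventions: permutation p-values are $(1+\text{count})/(1+N)$ with
recorded seeds; quantiles are type-7; distances spherical with
$R = 6371$ km; dosage is minor-allele count with `NA` for missing; all
tabular outputs are plain CSV/TSV/FASTA/GeoJSON/JSON and the velocity-field
interchange format is a documented long-format CSV of the gridded daily
values.

# Known limitations

Purely 2-D passive drift (no behaviour, mortality, vertical structure or
diffusion kicks); approximate radial polygon buffering rather than geodesic
buffering; the LD test approximates the unphased exact test; the admixture
model omits correlated allele frequencies and linkage; the median-joining
construction is greedy; synthetic fixtures carry none of the ascertainment
structure of real reduced-representation sequencing. Each of these is a
deliberate scope decision recorded above.
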