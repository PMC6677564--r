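---
title: "Methods: microsatellite diversity, structure and coalescent ABC in edgepop"
author: "edgepop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsatellite diversity, structure and coalescent ABC in edgepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`edgepop` analyses small microsatellite (SSR) panels and plastid spacer
alignments from species sampled as a handful of small populations — the
situation typical of narrowly endemic plants at the margin of their genus
range. It covers four stages: per-locus diversity statistics, population
structure (AMOVA, pairwise $F_{ST}$, DAPC), plastid haplotype/nucleotide
diversity, and a coalescent simulator under the generalized stepwise
mutation model (GSM) that drives approximate Bayesian computation (ABC)
over four single-population demographic scenarios. A synthetic-data
generator reproduces the shape of such studies so every stage can be tested
without external downloads.

# Data model

Alleles are stored as integer repeat counts. Fragment sizes in base pairs
are converted at ingest using each locus' motif length and a size offset
(estimated as the minimum observed size modulo the motif when not
supplied); off-lattice sizes are rounded to the nearest repeat unit with a
warning. The stepwise mutation machinery operates on repeat numbers, so
this is the natural internal unit. Missing genotypes are an explicit
sentinel (`NA` for both gene copies; half-calls are rejected) and are
excluded pairwise per locus from every statistic. GenePop (2- or 3-digit
coding auto-detected, allele `0` missing) and a documented csv layout
(`<locus>_1`, `<locus>_2` columns) are supported for genotypes; aligned
FASTA per region for sequences, with regions concatenated and treated as a
single locus thereafter.

# Diversity statistics and their conventions

* **Gene diversity** uses Nei's unbiased estimator
  $GD = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$ over $n$ gene copies —
  the probability that two copies drawn *without* replacement differ.
  Inside **PIC**
  ($1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$) and the null-allele
  estimators, the plug-in $H_e = 1 - \sum p_i^2$ is used instead, matching
  the conventions of the marker-characterization tools these statistics
  come from; both variants are exposed.
* **Allelic richness** is rarefied exactly:
  $AR(g) = \sum_i \left[1 - \binom{N - N_i}{g} / \binom{N}{g}\right]$,
  with the rarefaction size defaulting to the smallest per-population gene
  count in the data set.
* **$F_{IS}$** is the Weir–Cockerham variance-components estimator, summed
  over alleles and loci. Significance comes from re-pairing gene copies at
  random within populations; the two-sided p-value uses the
  $(k + 1)/(n + 1)$ permutation estimator throughout the package, which is
  never exactly zero.
* **Null alleles**: Chakraborty's $(H_e - H_o)/(H_e + H_o)$ and
  Brookfield's first estimator $(H_e - H_o)/(1 + H_e)$, reported as
  computed (negative values indicate heterozygote excess). Exact
  tool-specific maximum-likelihood variants exist elsewhere; small
  discrepancies against them are expected.
* **Hardy–Weinberg** testing is the conditional exact test on the genotype
  table given allele counts (Levene distribution). The state space is
  enumerated exactly when small (up to `enum_cap` tables, attempted for up
  to six alleles); otherwise the null is sampled by shuffling the $2n$
  gene copies and re-pairing them, which draws from the Levene
  distribution exactly. The p-value aggregates tables no more probable
  than the observed one. The deviation direction is reported from the sign
  of $H_e - H_o$.
* **Linkage disequilibrium** between locus pairs uses the log-likelihood
  ratio ($G$) on the two-locus genotype contingency table, with genotypes
  of one locus permuted among individuals within populations. Note that
  when nearly every individual carries a unique genotype the table is a
  permutation matrix and the statistic degenerates; the test is only
  informative when genotype classes repeat.

# AMOVA, pairwise $F_{ST}$ and DAPC

AMOVA partitions variation among and within populations at the gene-copy
level with the number-of-different-alleles (0/1) distance, giving an
$F_{ST}$-like fixation index (an allele-size flag would yield the
$R_{ST}$ analogue; the 0/1 distance is the default because small panels
rarely support size-based distances). Sums of squares decompose exactly
per locus; variance components are summed across loci and negative
components are retained as computed, so a pair of identical populations
yields a small negative estimate of order $-1/(n' - 1)$ rather than zero.
Significance permutes whole individuals across populations. Pairwise
$F_{ST}$ runs the same machinery per population pair, optionally
Bonferroni-adjusted.

DAPC encodes individuals as centred allele-dosage vectors (one column per
allele, dosage/2, missing values imputed at the column mean), retains
principal components (default: enough for 90% of variance, capped at a
third of the sample size), and applies linear discriminant analysis to
given groups or to clusters found by k-means over the PC scores.
Cluster number is selected by a spherical-Gaussian BIC,
$n \log(\mathrm{WSS}/n) + k\,d\,\log n$, whose per-cluster penalty scales
with the retained dimension $d$; on unstructured data it selects $k = 1$
and the result is flagged `no_structure`. Coordinates are defined up to
sign, as in any eigen-decomposition.

# The coalescent–GSM simulator

Four demographic scenarios are modelled as piecewise-constant diploid
effective sizes, backwards in time:

1. constant long-term size `Ne`;
2. a still-bottlenecked population: current `Ne2`, ancestral `Na2 > Ne2`,
   change at `t`;
3. a recent expansion: current `Ne3 > Na3` since `t`;
4. a transitory bottleneck: `Ne4` now, `Nb` between `t1 < t2`, ancestral
   `Na4`, with `Nb` below both.

Genealogies use the continuous-time coalescent (pairwise rate $1/2N$ per
generation within an epoch, exponential waiting times rescaled at epoch
boundaries); population sizes in the priors are far above the sample
sizes, where this approximation is standard. Mutations are Poisson along
branches; each mutation moves the allele by $\pm(1 + G)$ repeat units,
$G \sim \mathrm{Geometric}(P)$ on $\{0, 1, \dots\}$ with equiprobable
sign, so every mutation moves at least one unit and $P \to 1$ recovers the
single-step model.

Two implementation choices matter for throughput and are therefore stated
precisely:

* **Per-branch compound sampling.** The summed displacement of the $m$
  mutations on a branch is sampled in $O(1)$ draws:
  $m_\uparrow \sim \mathrm{Binomial}(m, 1/2)$ and the summed step sizes of
  each direction are $m_\cdot + \mathrm{NegBinomial}(m_\cdot, P)$. This is
  exactly the distribution of the event-by-event sum on an unbounded
  lattice (verified against an event-level simulation in the test suite)
  and removes the per-event cost, which is prohibitive when
  $\theta = 4N\mu$ reaches $10^3$–$10^4$ under the priors.
* **Boundary folding.** Allele ranges are enforced by folding (sawtooth
  reflection) of each node's value into the locus range before its
  descendant branches evolve, rather than by reflecting every mutation
  event. Reflection was preferred over truncation/clamping to avoid
  absorbing boundary states; a `boundary = "clamp"` flag restores
  clamping. Folding at nodes only, not events, is an approximation to the
  fully reflected walk; for ranges that are wide relative to the walk it
  is indistinguishable, and at stationarity the simulator reproduces the
  Ohta–Kimura equilibrium gene diversity
  $1 - 1/\sqrt{1 + 8N\mu}$ within Monte-Carlo error (tested at
  $\theta \in \{0.5, 2, 8\}$).

The root allele starts at the range midpoint (arbitrary but
stationary-friendly); tips are paired consecutively into diploids, which
equals random pairing by exchangeability. Identical seeds give identical
data sets.

# Priors

All demographic priors are uniform; times are in generations with a
one-year generation time. Defaults, chosen once for the biology the
package targets and fully user-configurable:

| parameter | default | rationale |
|---|---|---|
| current/bottleneck sizes (`Ne2`, `Na3`, `Nb`) | U(10, $10^4$) | species persisting as a few small patches |
| ancestral/expanded sizes (`Na2`, `Ne3`, `Ne4`, `Na4`) | U($10^4$, $5\times10^5$) | widespread pre-fragmentation populations |
| scenario-1 `Ne` | U(10, $5\times10^5$) | spans both regimes |
| event times (`t`, `t1`, `t2`) | U(10, $5\times10^4$) | from decade-scale to late-Quaternary events |
| mean mutation rate $\bar\mu$ | U($10^{-4}$, $10^{-2}$) | microsatellite range |
| per-locus $\mu$ | Gamma(shape 2, mean $\bar\mu$), truncated to [$10^{-5}$, $10^{-2}$] | hierarchical locus variation |
| per-locus GSM $P$ | U(0.1, 0.9) | values near 0 imply divergent step sizes; near 1, single-step |

Separating the size classes is what makes the bottleneck scenario
identifiable: if current and ancestral sizes shared one broad prior,
scenario 2 would contain near-constant histories and no data could
distinguish it from scenario 1. The split encodes the prior knowledge
that present-day populations are small while ancestral ones were not,
which is the hypothesis space the scenario set is meant to represent.

# ABC workflow

The four single-sample summary statistics are the panel means of: number
of alleles, unbiased gene diversity, allele-size variance over gene copies
(denominator $n$), and the Garza–Williamson ratio $M = k/(r + 1)$ with
$k$ alleles over a size range of $r$ repeat units. "Mean allele size
variance" is used (not mean allele size): a location statistic carries no
demographic signal under a symmetric mutation model, while the variance
and $M$ carry the bottleneck footprint.

Distances are Euclidean on statistics standardized by the reference
table's median and MAD; a statistic whose MAD is zero (possible under
heavy range saturation) falls back to its standard deviation and is
dropped only if that is zero too. Model choice reports both the direct
rejection estimate (class proportions among the `k_direct` nearest rows)
and multinomial logistic regression over the `k_logistic` nearest rows
with Epanechnikov weights, evaluated at the observation, with
delta-method 95% intervals from the fit's asymptotic covariance;
quasi-separated fits are refitted with a small weight decay and flagged.
At the published full scale these selection sizes are 500 and 40,000 of
$8\times10^6$ rows; scaled-down tables use the same proportions.

Parameter posteriors use local-linear regression adjustment: parameters
are logit-transformed to their prior bounds, regressed on the
standardized statistics over the `k_est` accepted rows with Epanechnikov
weights, shifted to the observed point and back-transformed. With a
zero regression signal the rejection posterior is returned unchanged.
Modes come from a weighted Gaussian kernel density (Silverman bandwidth);
intervals are weighted 5%/95% quantiles.

Scenario-choice confidence is measured by re-simulating pseudo-observed
data sets (pods) and re-running model choice. Pods can come from the
priors (the default, measuring global scenario separability) or from a
scenario's fitted posterior around the observation; restricting
posterior pods to the selected scenario gives the type-I-style
"confidence in the choice" error — the fraction of data sets like the
fitted one that would not re-select the same scenario. Posterior model
checking simulates from the fitted posterior and reports per-statistic
tail probabilities $P(\mathrm{sim} \le \mathrm{obs})$, flagging values
outside (0.025, 0.975).

# Synthetic data

`sim_island_genotypes()` draws ancestral allele frequencies per locus
from a Dirichlet, population frequencies from a Dirichlet concentrated
around them with per-population drift parameter $F$ (the Balding–Nichols
equilibrium of an island model), and genotypes with an inbreeding
coefficient fixed at the partial-selfing equilibrium $F_{IS} = s/(2-s)$
by duplicating a single draw with that probability. This is an
equilibrium shortcut rather than a generation-by-generation island
simulation: it gives direct control of the calibrated $F_{ST}$ band and
the analytic $F_{IS}$ target that the recovery tests score against. The
two profile generators fix the study shape: seven populations of 38
individuals with 10 of 12 loci polymorphic, drift calibrated to
$F_{ST} \approx 0.05$–0.1, no selfing, and a single plastid haplotype
over 471 + 650 bp; versus four populations of 81 individuals with 5 of 14
loci polymorphic, selfing 0.5 ($F_{IS} = 1/3$), one strongly diverged
population, and two plastid haplotypes at skewed frequencies over
445 + 746 bp.

What the generator does **not** emulate: genotyping artefacts (null
alleles, allele dropout, off-lattice sizes), linkage between loci,
isolation by distance, and mutation–drift disequilibrium within
populations (frequencies are drawn at equilibrium). Tests passing on
these data demonstrate estimator correctness under the stated model, not
robustness to those artefacts.

For the demographic-inference experiments the observed data sets are
simulated under the bottleneck scenario with GSM $P = 0.22$ and a fixed
per-locus mutation rate calibrated once per configuration
($3\times10^{-4}$ for the 10-locus/38-individual design,
$1\times10^{-4}$ for the 5-locus/81-individual design) so that the
simulated panels sit at the diversity scale such studies report (mean
alleles per locus near 4 and 8, respectively); the reference tables
integrate over the full hierarchical mutation prior.

# Numerical choices and degenerate inputs

* Permutation and Monte-Carlo p-values always use $(k+1)/(n+1)$.
* Haplotype ids are assigned in decreasing frequency, ties broken
  lexicographically; gap/`N` columns are excluded completely by default
  (pairwise handling available via `exclude_gaps = FALSE`).
* Monomorphic loci: HWE p = 1 with a "not testable" flag; $F_{IS}$
  undefined (`NA`); they are excluded from LD pairs.
* The logit transform clamps to $[\varepsilon, 1-\varepsilon]$,
  $\varepsilon = 10^{-6}$, to keep boundary draws finite.
* Reference-table builds, pipeline stages and the simulator are
  deterministic given their seeds; the pipeline derives independent
  per-stage streams from one master seed so toggling one stage does not
  shift another's randomness.
* Test and acceptance problem sizes are package choices: 200,000-row
  reference tables (50,000 per scenario) with proportionally scaled
  selection sizes, 50-pod error/coverage experiments, and 200-replicate
  equilibrium checks. These sizes keep every stochastic check within
  narrow Monte-Carlo error while remaining routine on a single CPU.

# Known limitations

* Single-population demographic scenarios only: no migration,
  multi-population models or recombination in the simulator.
* The AMOVA is two-level; hierarchical (region/population) designs are
  out of scope.
* The logistic model-choice CIs are asymptotic; with very small `k` they
  should be read qualitatively.
* Null-allele estimates are moment-based; likelihood-based tool variants
  will differ in the third decimal on small panels.
* The DAPC cluster search is a k-means/BIC heuristic; like all such
  criteria it is calibrated for well-separated spherical clusters in PC
  space.
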