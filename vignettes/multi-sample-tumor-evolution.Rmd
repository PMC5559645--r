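---
title: "Reconstructing multi-sample tumor evolution with phyloCCF"
author: "phyloCCF authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing multi-sample tumor evolution with phyloCCF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloCCF)
```

# The problem

When several tumor samples from one patient are sequenced — a primary breast
cancer and a later relapse or metastasis, say — the somatic mutations they
share and do not share encode the history of the disease. phyloCCF turns
per-sample variant read counts into that history in five steps: convert read
counts to cancer cell fractions (CCFs), cluster mutations jointly across
samples, order the clusters into a rooted phylogenetic tree, place
whole-genome duplication (WGD) on the molecular-time axis, and describe the
mutational processes and driver mutations active on each branch.

This vignette describes each model, its assumptions, the tunable parameters,
and the deliberate design choices, in that order. Everything quantitative
shown here is computed by the package's own functions at modest problem
sizes; the test suite and `scripts/acceptance.R` recompute the same
quantities independently.

# From read counts to cancer cell fractions

A mutation carried by a fraction $p$ of tumor cells (its CCF), on $m$ of the
$c$ DNA copies at its locus, in a sample of purity $\rho$, has expected
variant allele fraction

$$ f = \frac{\rho\, m\, p}{\rho\, c + 2(1-\rho)} . $$

The denominator counts all alleles at the locus: $c$ per tumor cell and two
per contaminating normal cell. `expectedVAF()` implements this and every
stage of the package goes through it, so purity and copy number enter all
models in exactly one place.

Multiplicity is not observable directly. `estimateMultiplicity()` assigns
$m$ by minimising $|X/n - f(\rho, c, m, 1)|$ over $m \in 1..c$ for
near-clonal mutations, and fixes $m = 1$ otherwise — a subclonal mutation
arises after any copy-number gain, on one copy. "Near-clonal" means the CCF
implied at $m = 1$ reaches 0.9 (`clonalCutoff`); below that there is no
evidence for extra copies and $m > 1$ would only inflate the CCF error.

Two QC rules exclude mutations whose absence or CCF cannot be interpreted
(`qcFilter()`): mutations in a region clonally deleted in any related sample
(loss, not clonal structure, could explain absence there), and mutations
falling outside every copy-number segment in at least one sample (undefined
$c$). Each exclusion carries a reason code, and the retained fraction is
reported; on the default synthetic cohorts it is around 95–97%.

# Multi-dimensional Dirichlet-process clustering

`dpCluster()` models the variant reads of mutation $i$ in sample $s$ as

$$ X_{is} \mid k \sim \mathrm{Binomial}\!\left(n_{is},\,
   f(\rho_s, c_{is}, m_{is}, p_{ks})\right), $$

independent across samples given the cluster $k$, with a Dirichlet-process
prior over the partition. The emission on raw read counts (rather than on
point CCF estimates) is what lets depth speak: a 5% VAF at depth 400 is
strong evidence, the same VAF at depth 12 is not.

Implementation choices, each of which was genuinely open:

* **Cluster CCFs on a grid.** Cluster parameters $p_{ks}$ live on a 0.01
  grid over $[0, 1.2]$, making their conditional posterior an exact
  discrete distribution (uniform prior). Values above 1 are allowed during
  sampling to absorb occasional multiplicity misestimates and truncated to
  1 for reporting and tree building.
* **Collapsed CRP scan with auxiliary components** (Neal's algorithm 8,
  3 auxiliaries) handles the non-conjugate emission; the concentration
  parameter has a Gamma(1,1) hyperprior resampled each sweep by the
  Escobar–West move. Defaults are 1,000 sweeps with 500 burn-in.
* **Partition summary.** Among the sampled partitions, the one maximising
  the posterior expected adjusted Rand index against the pairwise
  co-clustering matrix is reported (Fritsch–Ickstadt criterion) — a whole
  partition actually visited by the sampler, not an average that may
  correspond to no sample.
* **Order invariance.** A sequential CRP scan depends on row order, so
  mutations are canonically ordered by identifier before sampling; the same
  seed and data then give the same partition whatever the input order.
* **Small clusters.** Clusters below `minClusterSize` (1% of mutations,
  floor 5) are merged into their nearest neighbour in CCF space and the
  receiver flagged. Sub-percent clusters are almost always sampling debris
  at realistic depths; the flag preserves the audit trail.
* CCF posterior medians and 95% credible intervals per cluster and sample
  are read off the exact grid posterior given the final partition.

The Gibbs sampler is compiled code; all randomness flows through R's RNG so
`set.seed()` governs reproducibility end to end.

# Ordering clusters into a tree

Clusters constrain topology through the pigeonhole principle
(`buildTree()`): a cluster can only be ancestral to another if its CCF
dominates in *every* sample (within tolerance `tol`, default 0.05 CCF), and
the CCFs of sibling clusters cannot sum above their parent's in any sample.
The trunk is the unique cluster clonal everywhere (CCF $\geq 1 -$ `tol`).

Rather than heuristically picking one tree, the package enumerates every
parent assignment satisfying both constraints (cluster counts are small, so
this is exact and fast), ranks them by total nesting depth, returns the
deepest as primary and keeps the rest as ranked alternatives. Mutations are
assigned to the branch of their maximum posterior membership, with ties
going to the more ancestral cluster — the conservative choice, since it
avoids inventing heterogeneity the data do not demand. Mutual dominance
within tolerance is resolved by merging, with a warning.

Two branch statistics summarise primary/recurrence relationships:

* `divergenceFraction()` — the share of the primary tumor's molecular time
  elapsed when the recurrence-seeding lineage diverged: substitutions from
  the root to the divergence node over substitutions on the primary's
  root-to-tip lineage. Only substitutions in regions with identical copy
  number across samples should be counted (pass `cnConstantIds`), since
  deletions would otherwise shorten branches unequally. When the primary
  has several leaf lineages the *longest* is the denominator; the modal
  lineage is a defensible alternative, and using the longest makes the
  fraction conservative (never overstated).
* `recurrenceExcess()` — substitutions private to the recurrence minus
  those private to the primary, as a percentage of all substitutions in the
  primary; negative values mean the primary carried the larger private
  load.

Presence of a mutation in a sample is a hypothesis test, not a VAF
threshold: `presenceCall()` declares presence when
$P(\mathrm{Binomial}(n, e) \geq X) \leq 0.05$ at the conservative error
rate $e = 1/200$. An untyped site ($n = 0$) is NA — never "absent".
Structural variants are present where reconstructed or supported by at
least 4 split reads (`svPresence()`).

# Timing whole-genome duplication

On tetraploid segments, clonal mutations acquired *before* the duplication
sit on two copies ($m = 2$, expected VAF $\approx 2\times$ higher) and
those acquired *after* on one. `wgdEM()` fits the resulting binomial
mixture — early-clonal, late-clonal, and optionally subclonal states whose
CCFs are taken from the cluster solution rather than fitted free (they are
already estimated, and freeing them would let the mixture drift) — by EM:
posterior state probabilities by Bayes' formula, mixture weights as mean
posteriors, convergence at $\max|\Delta\pi| < 10^{-8}$ within 1,000
iterations, log-likelihood checked non-decreasing at every step. Ten random
restarts guard against local optima (the first start is uniform).

The relative duplication time is

$$ t = \frac{2\pi_e}{2\pi_e + \pi_l}, $$

because each pre-WGD time unit yields observable mutations on two copies.
Confidence intervals come from a percentile bootstrap: 100 resamples of the
mutations with replacement, refitting each (initialised at the full-data
estimate), taking the central 95% of the resampled $t$. The model is
defined for $c = 4$; other ploidies are rejected with a clear message
rather than silently extended. `timeWGD()` wraps the three steps and
requires at least 20 tetraploid trunk mutations.

# Refitting mutational signatures per branch

Branches with more than 20 mutations are summarised as 96-channel
trinucleotide spectra (pyrimidine-strand convention) and decomposed over a
consensus catalogue. For a 27-signature catalogue, all
$\sum_{k=1}^{7} \binom{27}{k} = 1{,}285{,}623$ subsets of up to seven
signatures are evaluated; each subset is fitted by non-negative least
squares (exposures in mutation counts) and scored by the Pearson
correlation $r$ between observed and reconstructed spectrum.

Model selection applies two rules: any solution in which a non-exempt
signature contributes under 2% of mutations or under 50 mutations is
discarded (signatures 1 and 5 are exempt, as continuously active endogenous
processes legitimately contribute trickles); among the survivors, the best
solution of each size enters a nested ladder in which a larger model is
preferred only if it improves $r$ by at least 0.02. The anchor of that
comparison is the best *accepted smaller* model — the ladder
interpretation — since the alternative (any smaller model) is not uniquely
defined. An audit trail records evaluation and discard counts and every
ladder decision. If no subset is admissible the best single-signature fit
is returned with a warning.

The search is exhaustive and exact in compiled code: because Pearson $r$
and the NNLS normal equations need only $A^\top A$, $A^\top y$ and column
sums, no candidate ever touches the 96-dimensional space, and the full
1.29M-subset search runs in seconds. An earlier design sketched
branch-and-bound pruning with an exact-mode fallback; exact enumeration at
this speed makes pruning complexity without benefit, so it was dropped.

NNLS itself is a design choice — the selection framework only requires
*some* exposure estimator — validated in the tests against a grid search on
the simplex for two-signature mixtures.

# The synthetic cohort generator

`simulatePatient()` exists so that every stage above can be tested by
parameter recovery against known truth. It emulates: a clone tree with
per-sample CCFs (validated for lineage monotonicity — a child's CCF can
never exceed its parent's in any sample, and the trunk is 1 everywhere);
purity per sample; Poisson depth (floor 1) around `depthMean`; binomial
variant reads at the expected VAF; whole-genome duplication, where trunk
mutations predate the duplication with probability $t/(2-t)$ so the
configured timing is recovered by construction; per-branch signature
mixtures, with each mutation drawing a generating signature and then a
channel; sequencing error as Binomial($n$, 0.005) reads wherever the true
VAF is zero, including dedicated null sites that exercise presence calling;
and copy-number pathology — a clonally deleted region in the last sample
and a segment gap in the first — that exercises the QC filter.

Default conditions describe the cohorts this analysis targets: two samples
(primary and relapse), mean depth 42 (whole-genome scale), purity at least
0.7 (histopathology-screened cellularity), a trunk-dominated tree (500
trunk / 150 + 150 private mutations in scaled-down form), error rate 1/200.
Where no empirical value exists — the distribution of subclone CCFs across
patients — the generator draws nothing silently: CCFs are stated
explicitly in the clone-tree specification, and the shipped default (0.6
and 0.7 private subclones) is an arbitrary but fixed choice.

What the generator does *not* emulate, and therefore what passing recovery
tests cannot show: mapping artifacts and strand bias, subclonal copy
number, kataegis and regional mutation-rate variation, overdispersed
(beta-binomial) read counts, or FFPE damage. Results on real cohorts depend
on upstream calling quality in ways the synthetic tests cannot probe.

The signature catalogue shipped for simulation,
`syntheticSignatureCatalog()`, is a deterministic synthetic stand-in — 27
sparse, well-separated probability columns — not the published consensus
signatures, which are an external input (`readSignatureCatalog()`) rather
than redistributed data.

# Driver annotation

`annotateDriver()` applies four oncogenicity categories in strict
precedence: (1) canonical hotspot mutations; (2) non-synonymous
substitutions or in-frame deletions at oncogene loci with at least 3 prior
somatic reports; (3) truncating, frameshift or essential-splice variants in
tumor suppressors, or tumor-suppressor hotspots with at least 2 reports;
(4) silent mutations at recurrent splice-site hotspots. The hotspot
database is an input table, not bundled. Copy-number drivers: amplification
above twice genome ploidy, homozygous deletion at copy number 0, and in
targeted data amplification at mean logR > 1 — flagged for manual review
rather than auto-called heterogeneous, the conservative stance. The
gene-level logR confidence interval is reported alongside but the call uses
the point estimate. Cohort enrichment uses two-sided Fisher exact tests
with Benjamini–Hochberg correction, significance at $q < 0.1$. Driver
timing between matched samples labels a gene early (identical mutation in
both), late (recurrence-only — requiring the primary site typed and absent
by the presence test, so coverage dropouts cannot masquerade as late
drivers) or both-different.

# Worked example

```{r example, eval = FALSE}
cfg <- pipelineConfig(
    simulate = TRUE,
    simulationArgs = list(depthMean = 80, nNullSites = 0,
                          purity = c(primary = 0.9, relapse = 0.85),
                          seed = 42),
    outputDir = "run42", maxSignatures = 4, seed = 42)
res <- runPipeline(cfg)
res$clusters          # CCFs, sizes, credible intervals
res$tree              # pigeonhole tree with branch assignments
divergenceFraction(res$tree, "primary", "relapse")
```

The pipeline writes `clusters.tsv`, `tree.nwk` (Newick, branch lengths =
substitution counts), `branch_stats.tsv`, `wgd_timing.json`,
`signatures.tsv` and a run log to the output directory, and re-running the
same configuration reproduces them byte for byte.

# Numerical choices and problem sizes

Tolerances that matter: EM convergence $10^{-8}$ on mixture weights;
catalogue columns must sum to 1 within $10^{-3}$ (then renormalised
exactly); CCF grid resolution 0.01; tree dominance tolerance 0.05 CCF;
membership ties broken toward the ancestral cluster at $10^{-9}$. Degenerate
inputs are handled explicitly: empty mutation sets round-trip as valid
empty files; all-zero spectra and empty indel sets are errors; WGD states
with numerically identical expected VAFs are collapsed with a warning;
zero cells in 2x2 tables get a Haldane 0.5 correction, flagged.

The test suite and acceptance script run their recovery studies at
deliberately moderate sizes — 500-mutation patients, 10–20 clustering
replicates, 20–60 timing replicates, 3,000-mutation spectra — chosen as the
smallest scales at which the statistical guarantees being asserted (90%
co-clustering accuracy, ±0.05 timing error, ±5% exposure recovery) are
comfortably identifiable.

# Known limitations

* The binomial emission ignores overdispersion; real data may need a
  beta-binomial, which would widen cluster credible intervals.
* Multiplicity estimation assumes integer $m$ on clonal copy number;
  subclonal copy number is consumed from the segment input but not modelled
  inside the clustering emission.
* WGD timing is defined for tetraploid regions only and assumes no
  post-duplication losses in the regions analysed.
* The tree enumeration is exact only because cluster counts per patient
  are small (2–6); it would need pruning beyond ~10 clusters.
* Signature refitting inherits the identifiability limits of its
  catalogue: strongly collinear signature columns cannot be separated at
  branch-scale mutation counts, whatever the search does.
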