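---
title: "Joint copy-number deconvolution across multiple tumor samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint copy-number deconvolution across multiple tumor samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonecna)
```

## The problem

A bulk tumor sample is a mixture of a diploid normal clone and one or more
tumor clones that differ by somatic copy-number aberrations (CNAs) and,
in a substantial fraction of tumors, a whole-genome duplication (WGD).
Sequencing reads measure two signals per genomic region and sample: the
read-depth ratio (RDR), the tumor read share of the region normalized by a
matched normal, and the mirrored B-allele frequency (BAF) of heterozygous
germline SNPs. Both are superpositions of the (unknown) integer
allele-specific copy numbers of the (unknown) clones, weighted by their
(unknown) proportions. `clonecna` deconvolves these mixtures *jointly*
across all samples of one patient.

Formally, with `m` genomic clusters, `n` clones (clone 1 the diploid
normal) and `k` samples, the model is

    F^A = A U,   F^B = B U

where `A`, `B` are `m x n` integer allele-specific copy-number matrices,
`U` is the `n x k` clone-proportion matrix (columns on the simplex), and
`F^A`, `F^B` are the allele-specific *fractional* copy numbers implied by
the scaled RDR/BAF. Inference minimizes the length-weighted L1 distance

    D = sum_s sum_p l_s ( |f^A_sp - (AU)_sp| + |f^B_sp - (BU)_sp| )

subject to a maximum total copy number (`a + b <= cmax`, default 12), a
minimum clone proportion (`u = 0` or `u >= umin`, default 0.03), and the
evolutionary one-sidedness constraint that no allele of a cluster is
amplified in one clone and deleted in another relative to the pivot
`theta` (1 without WGD, 2 with WGD).

## Pipeline stages and the choices behind them

### RDR and BAF (`bin_signals()`)

Bins default to 50 kb. RDR is the ratio of read shares, so it is invariant
to per-sample sequencing depth. BAF needs a phase decision per SNP (which
allele belongs to the bin's "B" side). A per-bin, per-sample two-component
binomial EM assigns phases (20 iterations from min-side initialization).
Two numerical points matter:

* the symmetric binomial mixture is *degenerate at 0.5*: on truly
  balanced data the EM settles slightly below 0.5 (the classic spurious
  optimum of symmetric mixtures). Each bin/cluster is therefore tested
  against the plain Binomial(0.5) null by a likelihood-ratio test (1%
  level) and snapped to 0.5 unless the mixture is clearly favored. This
  makes the estimator unbiased at balanced regions, which anchor
  detection depends on;
* at cluster level the phase must be *shared across samples*: a cluster's
  minor allele in one sample can be its major allele in another, and a
  single allele-assignment pair (A, B) can only represent that if the
  pooled BAF is allele-consistent. The cluster-level EM therefore pools
  each SNP's evidence across samples (one phase per SNP) and orients each
  cluster so its mean BAF is at most 0.5; individual samples may then
  exceed 0.5, and `f^B` may exceed `f^A` entry-wise in such samples.
  Without this, the true solution of a patient whose minor allele
  switches between samples is not representable (we observed the distance
  at the true solution an order of magnitude above the fitted one before
  making this change).

GC and mappability corrections are accepted as an optional multiplicative
per-bin vector but not estimated: count-level inputs are assumed
normalized, as real-data read processing is out of scope.

### Global clustering (`cluster_bins()`)

Bins are clustered in the joint `2k`-dimensional feature space (RDR and
BAF of every sample, z-scored per feature) with a truncated variational
Dirichlet-process Gaussian mixture (diagonal covariance, stick-breaking
truncation 50, concentration 0.01, 10 k-means-initialized restarts keeping
the best variational score). This is a *global* clustering along the
genome and across samples — not a segmentation — so distant regions with
the same clone-level state share statistical strength, and low-purity
samples borrow signal from high-purity ones. Clusters closer than
`tol_r = 0.08` (RDR) and `tol_baf = 0.04` (BAF) in every sample are merged
(closest pair first, re-pooled after each merge); clusters below 0.1% of
the genome are reassigned to the nearest centroid. The tolerances match
the centroid noise of 50 kb bins at ~30x coverage; they are user-tunable.

### Scaling to fractional copy numbers (`scaling_hypotheses()`)

RDR determines fractional copy numbers only up to a per-sample scale. The
scale is fixed by clonal anchor clusters:

* **no WGD** — the largest cluster balanced in every sample
  (|BAF - 0.5| <= `tol_baf`) is taken as diploid (1, 1), giving
  `f = 2 r / r_anchor`;
* **WGD** — the balanced anchor is (2, 2) and a second cluster with a
  fixed state in all tumor clones is required. Candidates must keep their
  RDR/BAF ordering relative to every other cluster in all samples (a
  clonal state preserves relative position) and are matched by least
  squares on BAF to the states reachable by one gain or loss before or
  after a WGD: (2,0), (2,1), (3,2), (4,2), (3,1), (4,3). Each candidate
  state gives a per-sample 2x2 linear system in the scale and the normal
  proportion; it must be non-singular (the identifiability condition
  `r_anchor (omega_z - 2) != r_z (omega_anchor - 2)`) and yield a normal
  proportion in [0, 1]. The largest feasible candidate wins, ties to the
  total copy number nearest 4. If no candidate survives, the WGD
  hypothesis is simply absent from model selection.

Both hypotheses are carried forward; choosing between them is deferred
until after factorization, which is the crux of separating "many
subclonal CNAs" from "one WGD".

### Factorization (`solve_cacf_cd()`, `solve_cacf_exact()`)

Coordinate descent alternates two *exact* block updates:

* **integer update** — for fixed `U` the objective separates by cluster;
  each cluster is minimized exactly by enumerating the one-sided tumor
  copy vectors per allele, with the `a + b <= cmax` coupling resolved by
  a box-minimum dynamic program over the copy grid (C++). Ties break
  toward states nearest `(theta, theta)`, then lexicographically —
  applied exactly for up to two tumor clones; with more clones the
  dynamic program returns the first optimum in a fixed enumeration
  order, which is still deterministic;
* **proportion update** — per sample, the weighted-L1 fit over the
  simplex with the semi-continuous constraint (`u = 0` or `>= umin`) is
  solved by branch and bound over the disjunction, each node a small
  linear program solved by a dense two-phase simplex with Bland's rule
  (C++). This equals support enumeration but prunes with LP bounds.

Both updates are exact minimizers, so `D` is non-increasing; iteration
stops when the decrease falls below 1e-6 or after 50 rounds. Because the
exact proportion LP dominates runtime, inner iterations use an exact
*pairwise* update (1-D mass transfers between clone pairs; each transfer
optimum is at a breakpoint of the convex piecewise-linear objective),
with the joint LP minimizer applied as a final polish.

The objective is rugged — basins in the purity direction are a few
percent wide at low purity and high copy number, and joint basins across
samples multiply — so the search layers several deterministic devices on
top of the random restarts (Dirichlet columns with random sparsity):
a purity ladder and a per-sample single-clone purity scan as
initializations; a hierarchical warm start from the solved `n - 1`
problem with each clone split in turn (the two-clone base is solved
globally by grid search on small instances); basin hopping over
per-sample normal/clone swaps and incumbent perturbations; and crossover
of per-sample proportion columns between the best distinct restarts
(stuck solutions typically misfit exactly one sample). On 50 random
noiseless instances (20 clusters, up to 4 clones, up to 3 samples) this
search recovers the true factorization in 49/50 cases at 20 random
restarts. After convergence, duplicate tumor clones are merged and
clones ordered by total proportion, so solutions are canonical and runs
reproducible bit-for-bit under a seed.

The exact reference solver enumerates all copy-number states jointly with
tumor purity discretized on a 0.01 grid (single tumor clone, up to two
samples, global optimum of the discretized problem), then polishes the
best grid basins with the same continuous block updates. The polish makes
the reference live in the same continuous solution space as coordinate
descent — without it, a grid optimum can sit measurably *above* what the
continuous LP reaches, and "oracle dominance" would be ill-posed.

### Model selection (`select_solution()`)

For each hypothesis the solver runs over `n = 2 .. n_max` (default 6).
Two facts shape the criterion. First, the residual distance of a correct
fit is not zero but sits at a *noise floor* set by counting statistics:
the binomial standard errors of each cluster's pooled read and SNP
counts, propagated through the RDR scaling and the allele split, predict
an expected distance `D_noise = sqrt(2/pi) sum l_s (s^A_sp + s^B_sp)`.
Second, because the minimum clone proportion (0.03) is comparable to
the relative noise of large clusters, clones beyond the true number act
as continuous nuisance parameters that keep "improving" `D` below the
floor — a naive elbow on relative improvements therefore overestimates
`n` and randomizes the WGD call. The criterion is thus:

* within a hypothesis, `n*` is the smallest `n` whose fit reaches the
  noise floor (`D(n) <= noise_floor x D_noise`, `noise_floor = 2` to
  absorb scaling bias and residual cluster impurity); if no `n` reaches
  it, fall back to an elbow on improvements relative to the baseline
  `D(2)` with threshold `tau` (default 0.05);
* across hypotheses, compare the noise-normalized distances
  `chi = D / D_noise`, which are scale-free (the WGD scaling doubles
  both `D` and `D_noise`). The WGD explanation is selected when any of
  three conditions holds, and the simpler no-WGD explanation stands
  otherwise:
    1. *structural evidence* — at least 2% of the genome sits in clonal
       clusters at odd total copy number under the WGD scaling
       (`wgd_odd_clonal_mass()`): single-copy events after a duplication
       produce these, while a doubled reading of a diploid genome cannot
       — together with a fit at least as good (or a smaller `n*` with a
       fit within 20%);
    2. *decisive fit* — `chi_w < 0.8 chi_n`: the margin exists because
       the finer post-WGD copy-number grid can always absorb slightly
       more noise;
    3. *dominance* — fewer clones at a fit at least as good, the
       "simplest solution" principle.

A genome whose post-WGD clonal events are few and whose pre-WGD states
all have even totals is *intrinsically ambiguous* — its no-WGD
interpretation fits the data equally well at the same clone count — and
is then called no-WGD by the simplicity rule; this bounds attainable
recall below 100% at these study conditions (with 2-3 samples per
patient, several simulated cohorts put it near 60-70%), consistent with
the imperfect recall reported for this class of methods. The selection
constants were fixed on a development cohort of simulated patients
disjoint from the packaged test cohorts.

## The simulator (`simulate_patient()`)

The generator emulates multi-sample bulk sequencing at the counts level.
Clone genomes accumulate events along a random phylogeny: per tumor
branch, 6 focal, 4 small, 3 medium, 2 arm and 1 whole-chromosome events,
each a single-copy gain or loss of one allele; at most one WGD, placed at
a random point of the trunk so it affects all tumor clones. Event sizes
(focal < 1 Mb, small 3-5 Mb, medium 10-20 Mb at full genome scale) scale
linearly with the configured genome size relative to 3 Gb, with a floor
of one bin, and breakpoints snap to the bin grid: a counts-level
simulator emulates segment-level CNAs at the granularity the method
consumes, and unaligned sub-bin breakpoints would only create mixed-state
bins that no integer assignment can fit — an artifact of the reduced
test genome (100 Mb) where event sizes approach the 50 kb bin, not a
feature of real data at 3 Gb.

Read counts respect genome-length differences between clones: the
expected read share of clone `i` is `u_i L_i / sum_j u_j L_j` with
`L_i = sum_s c_si l_s` — a WGD clone at equal cell proportion contributes
twice the reads of a diploid clone. Per-bin tumor counts are multinomial
with probabilities proportional to the mixture's genome content of the
bin; the matched normal is multinomial by bin length; SNP depths are
Poisson around the local mixed copy content with binomially split
alleles (SNP spacing 2 kb, haplotype of the alternate allele random).
Coverage defaults to 30x with nominal 100 bp reads.

Somatic mutations for the VAF module are placed on random tumor branches
on an allele with at least one copy; a mutation is "early" (precedes the
allele's subsequent amplifications, carrying the full allele copy number
in each descendant clone) or "late" (one copy) with probability 1/2.
This dichotomy matches the endpoint cases of per-event history tracking
without simulating per-event mutation timing, which the counts-level
generator does not attempt.

What the simulator does **not** model: GC and mappability bias,
replication timing, sequencing error in allele counts, subclonal or
multiple WGDs, phased haplotype blocks. Passing tests on this generator
therefore demonstrate correctness of the deconvolution machinery under
the stated generative model, not robustness to real-data artifacts.

## Mutation consistency (`assess_mutations()`)

For each somatic mutation, the observed VAF gets an equal-tailed 95%
credible interval from a Beta(1, 1)-prior binomial posterior,
`Beta(v + 1, T - v + 1)`. The attainable VAFs under the inferred solution
enumerate the mutated-copy assignments per tumor clone (0 to the allele
copy number, per allele side, normal fixed at 0, no homoplasy); the
mutation is *explained* if some attainable VAF falls in the interval.
Enumerations beyond 1e4 assignments are reduced to the deterministic
per-clone choices {0, 1, full}. Summary counts exclude mutations with
VAF < 0.2, which likely postdate the CNAs at their locus. Cancer cell
fractions use `CCF = VAF (mu c_T + 2(1 - mu)) / (m mu)` with the
multiplicity `m` the positive integer (up to the largest allele copy
number) bringing CCF closest to 1 subject to `CCF <= 1.1`, else the
smallest attainable CCF, clipped to [0, 1.5].

## Problem sizes used in the test suite

The packaged tests and the acceptance script run at reduced scale chosen
to exercise every code path at statistically meaningful coverage: 100 Mb
genomes (22 proportionally scaled autosomes) for cohort-level WGD
calling, 20-40 Mb genomes for module-level checks, 30x coverage, 2-4
clones and 2-3 samples per patient, and 16-patient cohorts. These are the
package's standing test conditions; the same code runs unchanged on
full-size genomes.

## Known limitations

* One clonal WGD at most; subclonal or repeated WGDs are out of scope.
* Allele assignment is per cluster; clusters are not phased against each
  other or against a reference panel.
* The WGD/no-WGD decision rests on clonal anchor clusters; a genome with
  no balanced clonal region in some sample aborts with "no balanced
  clonal cluster" rather than guessing.
* Small clusters near the merge tolerance can absorb each other; the
  subclonal-fraction statistic is correspondingly resolution-limited.
* The exact solver is exponential in clones and samples and guarded to
  single-tumor-clone, two-sample instances; it is a reference for tests,
  not a production path.
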