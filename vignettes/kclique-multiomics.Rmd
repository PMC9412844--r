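---
title: "K-clique communities in multi-omics correlation networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{K-clique communities in multi-omics correlation networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`kcliqueomics` integrates three omics blocks measured on stool samples from
a two-arm, two-timepoint nutritional intervention — microbial taxa relative
abundances, volatile-compound relative abundances and binned 1H NMR spectral
intensities — into per-group Spearman correlation threshold networks, and
characterises the groups through overlapping k-clique communities. This
vignette explains the model, the defaults and why they are set where they
are, what the synthetic cohort generator does and does not emulate, and the
numerical decisions a user may want to revisit.

## The network model

All features are placed on a common footing as columns of a samples ×
features table. For a group of subjects (see *Grouping* below) the package
computes the Spearman correlation matrix — rank correlation detects any
monotone relationship, linear or not, which is the right notion when a
microbial abundance and a metabolite intensity can be related through
saturating kinetics — and forms an undirected, unweighted graph with a link
wherever ρ exceeds the group's threshold, strictly. The adjacency is the
binary Nfeats × Nfeats matrix with zero diagonal; isolated features remain
as nodes so group networks always share one node set.

**Signed versus absolute thresholding.** The default is signed (ρ > t):
links represent co-occurrence, the reading under which "correlation greater
than t" is taken literally. Anti-correlations (competitive exclusion,
substrate depletion) are biologically meaningful too, so `mode = "absolute"`
(|ρ| > t) is a first-class option rather than the default.

**Grouping.** At baseline the intervention has not started, so the arms are
pooled and networks are built per sex with the softer default threshold
t = 0.5. At endpoint, networks are built per sex × arm with t = 0.7: the
per-group sample is roughly half the baseline one, and the significance of a
correlation degrades with n, so a harder threshold avoids representing
links a smaller sample cannot support. Both defaults are overridable per
group, and a `significance` policy resolves the threshold to the smallest
ρ with two-sided p < α under the t approximation
(t = ρ√((n−2)/(1−ρ²)), df = n−2), found by root-finding to 1e-9 and strictly
decreasing in n. For very small groups (n < 10) a seeded permutation
p-value (`spearman_perm_pvalue`) is available as a cross-check on the
approximation.

**Soft thresholding** is provided as a diagnostic
(`soft_threshold_power`): correlations are raised to candidate powers and
the scale-free fit index (R² of log10 frequency against log10 weighted
connectivity over connectivity bins) is tabulated; the smallest power
reaching the target R² (default 0.8) is reported. A power cannot resolve to
a binary adjacency, so the soft policy never enters hard network
construction — it answers "would a scale-free weighted network be a
reasonable model here?", not "where do I cut?".

## Preprocessing

- **Median relative-abundance filter** (default 0.5%, a deliberately hard
  cutoff yielding compact networks): a feature is removed when its median
  RA falls below the threshold. The default scope is `per_timepoint_union`
  — keep a feature passing at baseline *or* endpoint — because baseline and
  endpoint networks must share a node set to be comparable; intersection
  and pooled scopes are available. Medians with even counts are the mean of
  the two central order statistics.
- **Log transform**: abundances surviving the filter remain right-skewed,
  approximately log-normal; natural log brings them near normality. The
  base is irrelevant downstream (ranks are unchanged). Zeros are handled by
  a pseudocount defaulting to half the smallest positive value of the
  table; the transform refuses zeros with a zero pseudocount rather than
  producing -Inf silently.
- **PQN regional normalisation** of spectra uses the canonical two-step
  algorithm per region: each sample's region is first scaled to the batch's
  median region area (integral normalisation), then divided by the median
  quotient against the point-wise median reference spectrum. Running it per
  region (aromatic / hydroxylic / aliphatic; the ppm bounds are
  configuration, since they depend on solvent and excised regions) handles
  region-specific dilution. The two-step form makes the output exactly
  invariant to any per-sample, per-region rescaling up to one batch
  constant per region — a constant that cancels in rank correlations.
- **Binning** pools consecutive windows of `width` points (default 150, so
  a 60,000-point profile becomes 400 buckets) by their mean. A trailing
  partial window is pooled when it holds at least half a window, else
  dropped and logged. Width 1 is the identity.

## The two-step NMR reduction

Adjacent buckets of one signal and resonances of one molecule are nearly
collinear. Left alone they form a densely connected giant component of
spectral features that dominates every topological statistic. The reduction
removes that redundancy in two steps fitted once on all samples (so T0 and
Te share the reduced feature set):

1. **Selection.** One multinomial logistic objective with an L1 penalty
   over a log-spaced strength grid (default 10 points, 1e-3…1e3), features
   z-scored internally, stratified cross-validation (default 5 folds). The
   strength is chosen by the one-standard-error rule — the strongest
   penalty within one SE of the best mean accuracy — and, in addition, the
   fully penalised null model is returned unless the best accuracy beats
   the no-information rate (majority-class frequency) by at least three
   standard errors. Both guards exist for the same reason: CV accuracy
   differences of a few percent are noise, and without them uninformative
   labels (e.g. permuted ones) select weak penalties that keep dozens of
   buckets. With any real class signal the guards are inert. Coefficients
   below 1e-8 in absolute value for every class count as zero (numerical
   solvers rarely return exact zeros); a bucket is kept when any class
   coefficient survives. Multiclass handling is one multinomial objective,
   not one-vs-rest. Class labels are a user input; the pipeline default is
   arm × timepoint, the finest outcome structure the trial defines.
2. **Agglomeration and pooling.** Distance 1 − Pearson r (signed: strongly
   anti-correlated buckets are not the same molecule), average linkage —
   the natural partner of cophenetic pruning since a cluster's cophenetic
   diameter is its subtree height. The cut is the smallest merge height at
   which no singleton cluster remains, capped at 0.7 (intra-cluster
   correlation at least 0.3); if no singleton-free cut exists below the
   cap, the cap is used with a warning and the remaining singletons stand.
   Each cluster is pooled per sample by the median of its buckets, a
   robust summary that ignores one aberrant resonance.

Degenerate outcomes are handled explicitly: zero selected buckets drops the
NMR block with a warning; one selected bucket skips agglomeration.

## Clique percolation

Maximal cliques are enumerated by Bron–Kerbosch with pivoting (via igraph)
with a hard cap (default 1e6) that aborts on pathologically dense graphs.
Communities of order k are computed over maximal cliques of size ≥ k, two
being adjacent when they share at least k−1 nodes; each community is the
node union of a connected component of that clique adjacency. This is the
standard equivalent shortcut to percolating all k-cliques directly, and the
test suite verifies the equivalence against a brute-force definitional
oracle on hundreds of random graphs. k = 2 degenerates to connected
components restricted to non-isolated nodes; communities nest across k.
Community lists are returned in canonical sorted order so runs are
byte-reproducible.

Bridge nodes (membership ≥ 2) are the analytically interesting output:
features through which two otherwise separate correlation mechanisms
connect.

## Cross-group comparison

`compare_networks` bundles per-field topology deltas, edge-set Jaccard,
community matching and per-node membership shifts. Matching is greedy
maximum-Jaccard one-to-one (ties resolved by larger intersection, then
canonical order), with pairs below 0.5 Jaccard reported unmatched; greedy
was chosen over optimal assignment for transparency, and the tests compare
it against an exhaustive-assignment oracle on perturbed community sets. A
community's "extension" is operationalised as its node-set size and
"completeness" of a matched pair as the fraction of the partner's nodes
present; both are conventions of this package, since the underlying notions
have no unique formula.

## The synthetic cohort generator

The generator is the package's test bed: it produces data with exactly the
statistical structure the framework assumes, so every pipeline stage is
exercisable without any download.

The construction is a Gaussian latent-factor model pushed through
`exp(mu + sigma * z)`. Because Spearman correlation is invariant to
monotone marginal transforms, planted rank correlations are exact in
expectation while the observed marginals are log-normal, as relative
abundances filtered at 0.5% typically are. Taxa and VOC blocks are
renormalised to 100% per sample (compositional), NMR buckets stay positive
intensities. Each consortium has a factor; members load with
√rho_plant. NMR molecule blocks share a latent with intra-block correlation
0.95. Endpoint arm-A samples receive a latent shift (default 1 SD) on two
molecule blocks, giving the selection step a real outcome signal.

Defaults are frozen as the package's study conditions:

- 22 subjects per sex × arm cell (~90 completers, a realistic sub-study);
  end-to-end recovery checks raise this to 100 per group.
- Two consortia of 8 features (6 taxa + 2 VOCs) sharing one taxon.
- `rho_plant = 0.95`, `factor_cor = 0.52`, `rho_bridge = 0.845`,
  `noise_sd = 0.02`.

The bridge calibration deserves its arithmetic. A feature shared by two
consortia loads symmetrically on both factors, so its correlation to either
consortium's members is capped at √(rho_plant·(1+factor_cor)/2) —
positive-semidefiniteness, not a tuning choice. Meanwhile
cross-consortium member pairs correlate at rho_plant · factor_cor and must
stay well below the 0.7 edge threshold, or chance cross edges would merge
the two communities through triangles containing the bridge. Compositional
renormalisation and measurement noise attenuate realised Spearman values a
few hundredths below their latent targets, and at n = 100 the sampling
error of a Spearman coefficient is about 0.05 — with a noticeable
common-mode component across all edges of one node. Working through those
constraints: the cross-correlation budget (≤ ~0.5) bounds factor_cor at
~0.52 for rho_plant = 0.95, which caps the bridge at 0.845; placing the
bridge exactly at the cap has the welcome side effect of zeroing its
residual latent noise, so its edge failures decorrelate; and eight-member
consortia give the bridge seven chances per side to form the two edges it
needs to join a community. Each compositional block also carries one
dominant, low-variance feature (e.g. a taxon at mu = 5.5, sd = 0.05 on the
log scale) so the renormalisation denominator — and with it the induced
spurious correlation — stays nearly constant.

What the generator does **not** emulate: sequencing depth and zero
inflation, longitudinal within-subject correlation between T0 and Te
(timepoints are independent draws), taxon phylogeny, chemical-shift drift
and peak overlap, batch effects, or realistic spectra (cohorts are
generated at bucket level; spectrum-level operations are tested on
synthetic spectra built in the tests themselves). Passing tests therefore
demonstrate that the machinery is correct under its own assumptions, not
that those assumptions hold for any particular real dataset.

## Numerical choices and degenerate inputs

- Thresholding is strictly `>`; t = 1 gives an empty edge set (warned), not
  an error.
- Zero-variance features: correlations set to 0 with a warning in
  `spearman_matrix` (no link can form); hard error in agglomeration, where
  an undefined correlation cannot be worked around.
- Missing values block correlation with a hard error; `resolve_missing`
  offers explicit dropping. There is no silent imputation.
- Ranks use average ties; root-finding tolerance 1e-9; coefficient zero
  tolerance 1e-8; community and clique lists canonically sorted.
- Power-law fits are OLS of log10 count on log10 degree — the straight line
  on the log-log plot — not a maximum-likelihood tail exponent. Degree-0
  nodes are excluded from the fit (log 0) but kept in every other
  statistic; fewer than 3 usable points yields an absent fit with a
  warning, and both frequency- and probability-scaled intercepts are
  reported since only the intercept depends on that choice.
- One top-level pipeline seed fans out to per-stage seeds by stage-name
  hashing, so stages are independently reproducible; every resolved
  threshold, chosen penalty and cut height lands in the manifest.

## Problem sizes in the test suite

The suite validates percolation on 500 random graphs of up to 8 nodes for
k ∈ {2,3,4} against a brute-force oracle, threshold monotonicity and rank
invariance on 50 random 40-feature tables, agglomeration on 100 random
dendrograms plus 20 planted-block replicates, and end-to-end
planted-consortium recovery on 20 replicated cohorts at 100 subjects per
group. These sizes were chosen to exercise every code path with tight
statistical margins while keeping the default `testthat` run in the order
of a minute per file.

## Known limitations

- Thresholded correlation networks confound direct and indirect
  association; no conditional-independence (partial correlation) option is
  provided, by design.
- The statistical significance of *differences* between group networks is
  not assessed — the comparison module is descriptive, as a permutation
  scheme across subjects would need design decisions the framework leaves
  open.
- Clique enumeration is exponential in the worst case; the cap turns
  pathological inputs into a clear error rather than an unbounded
  computation. Dense networks (soft thresholds on many features) should be
  analysed at higher k or harder t.
- The signed default ignores anti-correlations; use `mode = "absolute"`
  when exclusion relationships matter.
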