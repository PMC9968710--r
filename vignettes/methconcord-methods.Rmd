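---
title: "Methods and design notes for methconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for methconcord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methconcord)
```

## What the pipeline estimates

The package asks, probe by probe, how well DNA methylation measured in an
accessible tissue (blood, saliva, buccal epithelium) tracks methylation in
brain tissue from the same subjects. Inputs are normalized beta values —
the methylated fraction per CpG per sample, in [0, 1] — on an EPIC-style
array, for a small surgical cohort (around 19 subjects).

Two complementary views are computed:

1. **Across-subject** (global): average each probe over subjects within a
   tissue, then Pearson-correlate the two mean vectors across probes.
   This is dominated by each probe's baseline methylation class
   (hypo/hyper), which is broadly conserved across tissues, so values are
   high (~0.9) and say little about individual differences.
2. **Within-subject, per CpG**: for one probe, correlate the 19 paired
   beta values across subjects between two tissues with Spearman's rho.
   This is the quantity a surrogate-tissue study actually needs: does
   *inter-individual variation* transfer across tissues at this CpG?

Only a minority of CpGs show transferable inter-individual signal; the
pipeline's job is to say which, with honest small-sample inference, and to
flag the probes where an apparent correlation is an artifact of genotype
or cell composition.

## Inference for the per-CpG correlation

With n = 19 subjects, asymptotic p-values deserve suspicion, and rank
correlation is used precisely because single outliers otherwise dominate.
The engine:

- computes rho on average ranks (ties share their mean rank), over
  pairwise-complete subjects, with a minimum of `min_n = 5` complete
  pairs (below that the probe is emitted with an NA rho and a reason
  code, never dropped silently);
- for n ≤ 8 with no ties, computes the two-sided p from the exhaustive
  n! permutation distribution of rho (exact, cached per n);
- otherwise uses the t approximation
  `t = rho * sqrt((n - 2) / (1 - rho^2))` with n − 2 degrees of freedom.
  Ties always take this route: the exact null assumes distinct ranks.

P-values are stored at full precision. Truncating tiny p-values to zero
(as correlation-database exports sometimes do) is a reporting artifact
and is deliberately not replicated.

Inverting the t approximation gives the smallest nominally significant
correlation, `critical_rho()`: at n = 19, alpha = 0.05 this is 0.456,
i.e. 0.46 at two decimals. Multiple testing uses the Benjamini–Hochberg
step-up, implemented directly (q = min over j ≥ i of m·p(j)/j, capped at
1) and verified against `stats::p.adjust` in the tests.

The per-8 exact and t-approximate routes agree within 0.02 for |rho| up
to 0.9 at n = 19 (checked against a 10^5-draw Monte-Carlo permutation in
the acceptance suite), so routing by n and ties does not create visible
seams in the output.

## Probe filters

Three filters run before any statistics, mirroring standard array
practice:

- **SNP proximity**: remove probes annotated with a SNP within 5 bp of
  the interrogated site, boundary inclusive ("within 5 bp" is read
  plainly as ≤ 5). An NA distance means "no SNP nearby" and is kept;
  probes missing from the annotation table altogether are kept and
  warned about — filters fail open on metadata gaps and closed only on
  measured unreliability.
- **Detection greedy-cut**: with detection p-values per measurement,
  iteratively remove whichever probe (row) or sample (column) has the
  highest fraction of entries above 0.01 until none remain. Ties prefer
  removing a probe over a sample — samples are precious in a 19-subject
  design — and among probes the lexicographically smallest id, making
  the procedure fully deterministic. The reference implementation of
  greedy-cut in array-QC toolkits optimizes an FPR-based objective whose
  exact stopping rule is not public; this simpler "remove until clean"
  variant is an explicit approximation, so published removal counts from
  real cohorts are not reproduction targets.
- **Context**: remove non-CpG-context probes.

Per-rule counts may overlap; the report reconciles raw counts, the unique
union, and survivors exactly.

## Cell-composition adjustment

Bulk methylation is a mixture over cell types with subject-varying
proportions, which manufactures cross-tissue correlation at any probe
whose methylation differs between cell types. Adjustment regresses each
probe's betas on fixed per-tissue covariates across subjects (OLS) and
keeps residual + probe mean:

- brain: neuron proportion;
- blood: B, NK, CD4T, CD8T, Mono — Neutro is dropped by column, because
  the six fractions sum to one and including all six is exactly collinear
  with the intercept (the model errors loudly, naming the collinear
  columns, if asked to do this);
- saliva / buccal: epithelial fraction.

Re-adding the probe mean keeps values on the interpretable beta scale;
downstream correlation is rank-based, so the constant shift is inert.
Whether the original databases re-added the mean or used raw residuals is
not documented; this choice is ours and is recorded here. Values are
clipped to [0, 1] afterwards (ranks essentially preserved), and probes
with fewer than 5 complete subjects pass through unadjusted, flagged.
On complete data the residuals are orthogonal to every covariate to
numerical precision (|cor| < 1e-10) and per-probe means are preserved —
both are acceptance-tested, as is idempotence.

## Variable CpGs

Most probes barely vary between people; correlating near-constant probes
mostly measures noise. A probe is *variable* when, after discarding
values strictly outside its [10th, 90th] percentile band (linear
interpolation quantiles, `type = 7`; values equal to a percentile are
retained), the remaining values still span at least 0.05 beta units
("at least 5%" is threshold-inclusive, applied with a 1e-12 tolerance so
binary rounding of, say, 0.15 − 0.10 cannot flip the class). Neither the
quantile estimator nor the boundary conventions are pinned down by the
definitions in the literature; both are explicit arguments. Cross-tissue
analyses may be restricted to probes variable in *all* tissues
(`intersect_variable()`).

## Genotype-driven multimodal probes

A probe sitting on an unannotated polymorphism produces beta values
clustered near 0.05 / 0.5 / 0.95 — genotype classes, not methylation.
Detection is per probe:

1. **1-D k-means, solved exactly.** In one dimension the optimal k-means
   partition consists of contiguous segments of the sorted values, so the
   global optimum is found by enumerating all `choose(n-1, k-1)` cut
   placements with prefix sums (trivial at n ≈ 19; quantile-seeded Lloyd
   remains as a documented fallback for large n). This is a deliberate
   deviation from plain Lloyd iteration: quantile-seeded Lloyd was
   measured to miss the global optimum on a substantial fraction of
   genotype-like fixtures (two seeds land in the majority cluster and the
   two distant minor clusters merge; Lloyd cannot escape), which would
   make the gap statistic's observed dispersion depend on luck. A
   dynamic-programming clusterer (`kmeans_1d_dp`) provides an
   algorithmically independent check; the two must agree on every test
   fixture.
2. **Gap statistic** over k = 1..3 with B = 50 uniform references over
   the observed range (the simplest reference; in 1-D no PCA rotation is
   needed), `Gap(k) = mean_b log W_k(ref_b) − log W_k(obs)`,
   `s_k = sd_b · sqrt(1 + 1/B)`, seeded and reproducible. Zero
   dispersions (duplicated values) are floored at 1e-12 before the log.
3. **Cluster number** by the one-standard-error rule against the global
   Gap maximum ("firstSEmax", as in `cluster::clusGap`): the smallest k
   with `Gap(k) ≥ max Gap − s_argmax`. The textbook stepwise rule
   (smallest k with `Gap(k) ≥ Gap(k+1) − s_{k+1}`) fails outright on
   symmetric three-cluster genotype data: Gap *dips* at k = 2, because a
   uniform reference gains more from a two-way split than three
   well-separated clusters do, so the stepwise scan stops at k = 1 and
   heterozygote-bearing probes go undetected. With the global-max
   variant, planted 2- and 3-cluster fixtures are recovered at ≥ 95%
   sensitivity with ≤ 5% false positives (acceptance-tested).
4. **Flag** iff chosen k ≥ 2, every pairwise center separation ≥ 0.2
   (genotype clusters are ~0.45 apart; methylation gradients are not),
   and every cluster holds ≥ 2 subjects. The thresholds used by the
   original database's filter are unpublished; these defaults mirror the
   genotype geometry and are configurable, so published flagged counts
   are not reproduction targets. Raising either gate can only unflag
   probes (tested monotonicity).

Under Hardy–Weinberg sampling at realistic allele frequencies, some
genotype probes are *realized* monomorphic or carry a singleton minor
cluster in a 19-subject draw; those are undetectable by design (and the
truth object records genotypes so tests can condition on detectability).

## Cross-database stability and mQTLs

Given a second database's per-CpG correlations for the same tissue pairs,
records are inner-joined on probe and pair after excluding undefined rho
on either side (the excluded count is reported), and each probe gets
`delta = |rho_A − rho_B|`. Probes with delta < 0.2 are *stable* — the
boundary 0.2 itself is unstable, following the strict "lesser than"
wording; the threshold is an argument. The per-pair
correlation-of-correlations and the 7-region Venn decomposition of the
three brain–peripheral stable sets reconcile exactly with set algebra.
mQTL annotation flags probes on a supplied list, applying the canonical
p < 1e-14 cutoff when the list carries p-values.

## The synthetic cohort: what it emulates, what it does not

`generate_cohort()` states a world and sticks to it. Defaults: 19
subjects, four tissues, 10^4 probes, 15% of probes with cross-tissue
correlated deviations at rho 0.7, 2% + 1% genotype probes at allele
frequency 0.3, 10% cell-composition-confounded probes, beta-scale noise
sd 0.03, 0.2% sporadic detection failures.

Construction, per probe and tissue, on the logit scale: a bimodal
baseline (each probe hypo- or hyper-methylated, Beta(2,8) / Beta(8,2)
modes) plus probe-specific tissue offsets (largest for brain, so tissues
separate genome-wide in MDS), plus — for planted probes — a shared
per-subject deviation with variance `rho/(1-rho)` times the noise
variance, giving latent Pearson correlation exactly `rho_true` between
any two tissues, plus independent noise (logit sd = 4 × `noise_sd`, the
inverse-logit slope at 0.5). The inverse logit is strictly monotone, so
Spearman statistics transfer from the latent scale unchanged; the
observed mean Spearman over planted probes lands slightly below
`rho_true` (the usual rank-correlation attenuation of a Gaussian copula,
about 0.68 for 0.7). Genotype probes overwrite the baseline with
subject-level Hardy–Weinberg genotypes mapped additively to
0.05/0.5/0.95 (k = 3) or dominantly collapsed to 0.05/0.95 (k = 2),
identical across a subject's tissues. Cell-confounded probes couple to
the tissue's leading proportion (neuron; CD4+CD8; epithelial), drawn
per-subject from Beta/Dirichlet-style distributions. The four planted
classes are disjoint, so "null probes" are genuinely null — a nontrivial
point, because with n = 19 the leading proportions of two tissues are
often sample-correlated by chance, and any probe coupled to both
inherits that correlation; that is precisely the confound the adjustment
stage removes, and it lives in its own truth class (`cell_probes`).

A single integer seed drives everything through deterministically derived
per-stage sub-streams; regeneration is bit-identical.

Not emulated: raw intensities, age/sex covariates, batch effects,
probe-type (I/II) chemistry differences, spatial chromosomal structure,
realistic LD between genotype probes. A green test on this world
establishes that the machinery is correct, calibrated, and recovers
planted structure at its stated tolerances — not that any particular
real-cohort number is reproduced. Headline numbers from real cohorts
(survivor counts like 825 637, nominal fractions like 19.0%) require the
original raw arrays and unpublished algorithm parameters and are
explicitly out of scope.

## Numerical conventions

- TSV dialect everywhere: tab-separated, UTF-8, '.' decimal, "NA"
  missing, header mandatory; matrices carry `probe_id` first.
- Betas clip to [0, 1] after any arithmetic that can leave the range.
- Zero-variance vectors yield NA statistics with reason codes, never
  errors, except where a result would be silently meaningless
  (across-subject correlation of a constant mean vector errors).
- MDS is classical Torgerson scaling via `stats::cmdscale` on Euclidean
  distances over complete-case probes; ancestry PCs are the top-k
  subject scores of the SVD of the probe-centered SNP-probe submatrix.
  Both are deterministic up to sign.
- Per-subject correlations use Pearson (the convention is not pinned
  down in the literature for this summary; rank correlation over 10^3+
  probes is nearly identical, and Pearson keeps the coupling statistic's
  t-test exact under normality).
- The CLI exits 0 on success, 2 on configuration errors, 3 on missing
  inputs, 4 on stage failures; `run` writes a log echoing seed and
  parameters.

## Known limitations

- The greedy-cut objective is a simplification of the FPR-curve-based
  original; on matrices with diffuse low-grade failures it removes more
  probes than a curve-based stopping rule would.
- Exact permutation inference stops at n = 8 (8! = 40 320 permutations);
  9 ≤ n ≤ 12 would be feasible with more memory but the t approximation
  is already within 0.02 there.
- The gap-statistic detector assumes genotype-like geometry (clusters
  ≥ 0.2 apart); mQTLs with small effect sizes present as ordinary
  variable CpGs and are only catchable via the mQTL list annotation.
- Cell-proportion estimation itself (reference-based deconvolution) is
  an input, not a feature; garbage proportions in, garbage adjustment
  out.
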