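---
title: "Prioritizing GWAS variants with a genomic Local Moran's Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing GWAS variants with a genomic Local Moran's Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moranprio)
```

## Motivation

Single-marker GWAS ranks variants by association p-value, which
penalizes low-frequency variants twice: their effect estimates are
noisy, and the multiple-testing threshold is unforgiving. Yet a true
low-frequency risk haplotype leaves a characteristic footprint that a
p-value cannot see — *several* SNPs tagging the same haplotype all show
elevated odds ratios, coherently. Local indicators of spatial
autocorrelation were designed for exactly this pattern-detection
problem in geography: find observations whose value agrees with a
weighted average of their neighbors. This package transplants that
idea to the genome, with linkage disequilibrium playing the role of
spatial proximity.

## The model

Let OR_i be the per-allele odds ratio for SNP *i*, referred to the
risk-increasing allele so that OR_i ≥ 1, and let

z_i = Φ⁻¹((rank_i − ½) / n)

be the rank-based inverse-normal transform of the ORs over all n
scored SNPs (mid-ranks for ties). The local score is

LMI_i = z_i · ( Σ_j z_j r²_ij ) / ( Σ_j r²_ij ),

with *j* running over the *neighborhood* of *i*: scored SNPs on the
same chromosome within ±500 kb whose panel minor-allele frequency is
within 0.05 of SNP *i*'s, weighted by panel r². The second factor is a
convex combination of the neighbors' z values, so

* LMI_i > 0 when the focal SNP and its LD neighborhood deviate in the
  same direction from the center of the OR distribution;
* LMI_i < 0 when they disagree (or the "neighborhood" is mere physical
  proximity without LD support);
* if every neighbor shares the focal z, LMI_i = z_i² exactly — a useful
  identity for testing.

Two exclusion rules follow the statistic: SNPs with negative LMI are
discarded, as are SNPs with non-negative LMI whose z lies in the bottom
half of the transformed OR distribution (they are "coherent" only in
being unremarkable). The prioritized set is the top fraction (default
0.5%) of the survivors by LMI.

## Tunable parameters

| Parameter | Default | Where | Why |
|---|---|---|---|
| `half_window_bp` | 500,000 bp | `neighbors_window`, `compute_lmi`, `credible_set`, `prune_independent` | the distance beyond which useful LD is rare in European-ancestry panels; boundary inclusive |
| `maf_tolerance` | 0.05 (absolute) | `compute_lmi` | neighbors are MAF-matched to maximize the chance that dosage correlation reflects a shared haplotype; the matching rule itself (absolute tolerance) is our choice, as only the intent is standard |
| `min_panel_maf` | 0.01 | `compute_lmi` | below 1% panel frequency r² estimates from a reference panel of realistic size are unstable; such SNPs are reported `estimable = FALSE`, never silently dropped |
| `fraction` | 0.005 | `select_top_fraction` | the top 0.5% of retained SNPs; the count uses `floor`, ties broken by smaller p then id |
| `min_maf`, `min_info` | 0.05 (strict >), 0.91 (≥) | `qc_filter` | common-variant analysis set; imputed records need a high info score |
| `prior_w` | 0.04 | `wakefield_bf`, `credible_set` | prior variance of the log OR (prior SD 0.2) — the standard weakly-informative choice for summary-statistic fine-mapping of binary traits |
| `r2_min` | 0.1 (strict >) | `credible_set` | region membership requires LD with the lead beyond background |
| `mass` | 0.99 | `credible_set` | cumulative posterior the reported set must reach |
| `r2_max` | 0.2 (strict <) | `prune_independent` | conventional independence threshold for clumping |
| `alpha` | 1e−5 | `bonferroni_filter` | Bonferroni-adjusted significance for interaction calls |
| `bin_size` | 40,000 bp | `read_interactions` | resolution of the interaction matrices the calls derive from |

## Numerical and convention choices

* **Inverse-normal transform.** The offset (rank − ½)/n keeps quantiles
  strictly inside (0, 1) for any n (n = 1 maps to z = 0); mid-ranks
  make the transform well-defined under ties. The transform is applied
  genome-wide, not per chromosome, so z values are comparable across
  chromosomes. Because the transform is monotone, the "bottom half"
  exclusion is identical whether judged on z or on raw OR; the boundary
  value (z equal to the median) is retained.
* **LD estimation.** r² is the squared Pearson correlation of dosage
  vectors over pairwise-complete individuals. Pairs with fewer than two
  complete individuals or zero variance have *undefined* LD: the weight
  is treated as absent rather than zero, and a SNP whose entire
  neighborhood is undefined is flagged not estimable (a zero weight-sum
  would otherwise divide by zero). The vectorized path uses the same
  scalar arithmetic as the pairwise primitive so that exact-zero
  correlations do not flip estimability through summation-order
  artifacts.
* **Neighbors outside the scored set** (present in the panel but
  without an association record) contribute nothing; they are excluded
  from both the numerator and the denominator rather than zeroing the
  weight.
* **Windows never span chromosomes**, and the simulator's default 2-Mb
  between-block gap guarantees distinct blocks cannot enter each
  other's windows.
* **Coordinates.** SNP positions are 1-based (VCF convention)
  throughout the panel and summary-statistic layers. BED/BEDPE inputs
  keep their native 0-based half-open intervals; a SNP overlaps an
  interaction bin when its position lies in [start, end), so a SNP
  exactly at a bin's end coordinate belongs to the next bin, matching
  the contiguous binning of interaction matrices.
* **Logistic fits** use IRLS (`glm.fit`) with log-likelihood tolerance
  1e−8 and at most 100 iterations. Quasi-complete separation is
  detected as |β̂| > 20 and reported as a flagged NA record — at desk
  scale a zero cell is data sparsity, not evidence.
* **Meta-analysis** is DerSimonian–Laird (delegated to `metafor`,
  method `"DL"`), the default of the standard tooling; a single study
  passes through with τ² = 0.
* **Permutation p-values** use the +1 correction in sampled mode, so p
  is never exactly zero; when C(n, k) ≤ 10,000 the null is enumerated
  exhaustively and the observed subset counts itself. "Better rank"
  means numerically smaller (rank 1 = largest LMI), and the one-tailed
  p counts null medians ≤ the observed one. The null sets are drawn
  from the supplied ranked list — the natural sampling frame given that
  the hit set is a subset of it.
* **Credible sets from nearby leads are reported separately**, not
  merged: merging rules introduce order dependence, and the consumer
  can deduplicate by membership overlap if desired.
* **Rank-sum tests** are exact (enumeration) only for pooled n ≤ 12
  without ties, otherwise normal-approximated with tie and continuity
  correction. For fully separated samples the approximation deviates
  from the exact tail by up to ~0.02 — a property of the approximation
  itself worth knowing when p-values near 0.05 matter.

## The simulator: what it emulates, and what it does not

`simulate_panel` generates each LD block from a small pool of founder
haplotypes: every individual draws two founders uniformly and each
allele copy then flips with a per-block mutation rate. This gives
exact, explainable LD — with no mutation every haplotype *is* a
founder, two complementary founders give r² = 1, and a mutation rate
of 0.5 erases LD — plus valid VCF output, which is why it was chosen
over multivariate-normal dosage thresholding. Phenotypes follow a
logistic model on planted causal dosages plus centered covariate
effects (age, sex, three-level region), so with no causal effects and
zero intercept the case fraction is ½ by symmetry.

`scenario_low_maf_cluster` encodes the study condition the method
targets: a 12-SNP cluster carried by a single risk founder haplotype at
frequency 0.04 (realized MAFs ≈ 0.02–0.05, within-block r² high), a
planted cluster odds ratio of 1.5, one common-variant hit (OR 1.35,
MAF 0.2–0.5) and 120 null SNPs, for 2,000 individuals. The cluster OR
of 1.5 at MAF 0.04 is deliberately *power-limited*: each member's
single-marker p-value is noisy and mid-table, while the LD-weighted
average over eleven coherent neighbors keeps the cluster at the top of
the LMI ranking. That contrast — not raw detection — is what the
scenario exists to measure.

What the generator does **not** emulate: recombination-map-driven LD
decay (LD is block-uniform), demographic structure and admixture,
genotyping error beyond symmetric allele flips, imputation uncertainty,
chromosome-scale LD, or genome-scale SNP counts. Tests passing on this
generator therefore demonstrate the statistic's *contracts and
comparative behavior* under controlled LD, not performance on real
consortium data.

## Problem sizes used by the test suite

The packaged checks run at sizes chosen to make their statistical
assertions sharp but cheap: 50 brute-force-oracle fixtures of 36 SNPs ×
40 individuals; 100 parameter-recovery replicates at n = 5,000; 200
calibration replicates of the permutation benchmark (B = 199, 80-SNP
lists); 50 scenario seeds for the low-MAF prioritization contrast. The
selection-arithmetic check uses the full 102,146-SNP scored-list size
directly, since it is pure rank arithmetic.

## Known limitations

* The statistic inherits the reference panel: SNPs absent from the
  panel or below 1% panel MAF are not estimable, and panel/study
  ancestry mismatch biases r² weights.
* MAF matching by absolute tolerance is asymmetric in effect across the
  frequency spectrum (0.05 is generous at MAF 0.4, strict at 0.02);
  alternatives (ratio or bin matching) fit behind the same interface.
* The exclusion rules assume risk-allele-referred ORs; applying them to
  signed betas would discard protective clusters by construction.
* Credible sets assume a single causal variant per region and a shared
  prior variance; multi-causal fine-mapping is out of scope.
* The chromatin layer consumes interaction *calls*; it performs no map
  construction, normalization or significance modeling of its own.
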