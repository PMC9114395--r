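---
title: "Methods: crypt phylogenomics from clonal read counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crypt phylogenomics from clonal read counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptphylo)
```

# Overview

`cryptphylo` analyses somatic variants called from laser-capture
microdissected intestinal crypts. Each crypt is a clonal unit: a somatic
variant carried by the crypt's founding stem cell lineage is present in
essentially every cell, so true somatic variants appear at a variant allele
fraction (VAF) near 0.5 in carrier crypts and near zero elsewhere. The
pipeline exploits this all-or-nothing structure end to end:

1. **Filtering** separates somatic variants from germline variants and
   sequencing artifacts using aggregate read counts.
2. **Phylogeny** reconstructs the lineage tree of the sampled crypts by
   maximum parsimony on binary presence/absence genotypes and places every
   variant on a branch by maximum likelihood.
3. **Spectra** classify mutations into the SBS96 trinucleotide scheme and the
   PCAWG/COSMIC ID83 indel scheme, per branch.
4. **Signatures** are extracted de novo (hierarchical Dirichlet process
   sampler or NMF), matched against a reference catalogue by EM
   deconvolution, and refit as per-branch exposures.
5. **Burden** converts branch placements into per-crypt mutation burdens and
   rates, compares cohorts with a linear mixed model, and annotates candidate
   driver mutations.

A synthetic cohort generator (`simulate_cohort()`) produces read counts with
complete ground truth for every stage, and is what the test suite and the
`analysis/` drivers run on.

# Filtering

## Quality predicates

`quality_filter()` applies per-kind caller annotations: SBS calls require
alignment score median (ASMD) >= 140 and zero clipped reads (CLPM == 0);
indel calls require Qual >= 300 and site depth >= 15. Missing annotation
columns either fail the variant or skip the rule (`on_missing`).

## Exact binomial germline test

A germline heterozygous variant is present in every crypt at VAF 0.5, so the
alt count aggregated over all copy-number-neutral crypts is Binomial(depth,
0.5). `binomial_germline_test()` computes the one-sided exact tail
P(X <= alt_sum); p-values are Benjamini-Hochberg adjusted across variants and
a variant is called germline when its adjusted value is *not* small
(q >= 1e-5 by default): somatic variants, present in a subset of crypts, sit
significantly *below* the 0.5 line.

One consequence is worth stating explicitly: a genuinely somatic variant
shared by nearly all sampled crypts (for example one on the branch separating
a single crypt from the other seven) has an aggregate VAF close to 0.5 and is
*correctly* indistinguishable from germline by this test. Such variants are
removed, and the corresponding near-trunk split of the tree can become
unresolvable from the filtered data. This is a property of the design, not of
the implementation; the test suite exercises tree recovery on uncontaminated
cohorts where no germline filter is needed, and filter behaviour separately.

## Beta-binomial overdispersion filter

Sequencing artifacts recur across crypts at low, variable VAF. For each
variant the beta-binomial overdispersion parameter rho is estimated by
maximum likelihood (`estimate_rho()`), plugging in the pooled mean
`mu = sum(alt)/sum(depth)` and parameterizing `alpha = mu(1-rho)/rho`,
`beta = (1-mu)(1-rho)/rho`. True clonal variants are bimodal across crypts
(VAF 0 or 0.5) and need large rho; artifacts scatter unimodally and fit small
rho. Variants with rho < 0.1 (SBS) or rho < 0.2 (indels) are dropped. The
MLE is verified against a 10,000-point grid search in the tests.

# Phylogeny

## Zygote-rooted parsimony

Genotypes are coded per crypt from VAF: 1 if VAF > 0.3, 0 if VAF < 0.1,
missing otherwise (`code_genotypes()`). The tree is rooted at the zygote,
which carries none of the somatic variants; the zygote sits *above* the most
recent common ancestor of the sampled crypts on a trunk edge, so a variant
present in every crypt costs one change (on the trunk), not two. Fitch
scoring (`fitch_score()`) implements exactly this model, and the search
(`search_mp_tree()`) enumerates all rooted resolved topologies — including
trunk insertions — up to 8 leaves ((2n-3)!! of them), or uses seeded stepwise
addition plus nearest-neighbour-interchange hill climbing with restarts for
larger trees. Ties are reported and broken deterministically by the
lexicographically smallest canonical form. `bootstrap_support()` resamples
characters with replacement.

The exhaustive enumeration is capped at 8 leaves (10,395 topologies at n = 8;
the double factorial grows by a factor of 2n-3 per leaf), which bounds the
exhaustive path to well under a second while covering every cohort size the
brute-force test oracles can also handle.

## Maximum-likelihood placement

Given the tree, each variant's log-likelihood on a candidate branch sums
Binomial(alt | depth, 0.5) over descendant crypts and
Binomial(alt | depth, 0.001) over the rest (`assign_variants_ml()`).
Candidates are every branch, the trunk ("root": present in all crypts), and
an artifact category (absent everywhere), which captures low-VAF variants
that fit no carrier set; the posterior is normalized under a uniform prior.
Indels are placed on the SBS-built tree (`assign_indels_to_sbs_tree()`):
normal crypts carry too few indels to support their own topology.

# Spectra

`sbs_channel()` strand-normalizes purine references by reverse complementing
ref, alt and trinucleotide context, yielding the 96 pyrimidine-centred
channels in COSMIC order. `id_channel()` implements the ID83 scheme: 1 bp
deletions/insertions at C/T homopolymers (run length encoded 0..5, where the
deletion field counts the tract *including* the deleted base minus one),
longer events at tandem repeats (repeat units 0..5, deletions counting the
deleted copy), and deletions with microhomology. Two conventions deserve
mention:

* For 1 bp events the homopolymer run is counted on **both** flanks. Strand
  normalization can reflect the tract to the 5' side of the event, where a
  3'-only count would miss it; homopolymer runs are strand-symmetric, so the
  two-sided count is the correct invariant. Multi-base repeat units are
  counted on the 3' flank only (left-alignment of calls is assumed).
* Microhomology is only assessed when the deleted motif has no adjacent full
  copy, as the longest prefix of the deleted sequence matching the start of
  the 3' flank or suffix matching the end of the 5' flank, capped at
  length-1.

`branch_spectra()` builds per-branch count matrices, excluding branches with
fewer than 100 classified mutations and subsampling branches above 2,500
(seeded, unbiased in expectation). `microsatellite_frameshift_flag()` marks
indels inside tracts of >= 5 repeat units.

# Signatures

## Hierarchical Dirichlet process backend

`hdp_extract()` runs a three-level Chinese-restaurant-franchise Gibbs sampler
(cohort -> patient -> branch), implemented in C++ with direct assignment,
explicit stick weights, and auxiliary-variable resampling of the
concentration parameters (Gamma(1, 1) priors). The chain is initialized from
a random partition into `init_k` (default 10) dishes; starting from a single
dish mixes poorly because new-dish moves are rare. Posterior samples are
summarized by matching each retained sample's dishes to a modal-K reference
sample by greedy cosine matching, accumulating counts, merging components
with cosine >= 0.9, and dropping components that never reach 1% exposure in
at least `min_sample` branches. Exposures are then refit by EM against the
final components.

## NMF backend and rank selection

`nmf_extract()` runs multiplicative-update KL-NMF over a rank range with
seeded restarts and selects the largest rank whose restarts agree: the
cosine-silhouette of matched components across restarts must exceed 0.8.

## Deconvolution, reconstitution, residuals

`em_deconvolute()` fits non-negative mixture weights of catalogue references
to each de novo component (EM, tolerance 1e-8 on the weight step).
`reconstitute()` keeps references with weight strictly above 0.15 (SBS; 0.2
recommended for indels) and accepts the component if the kept-reference
reconstruction has cosine > 0.9 with it. Components that fail are split into
their accepted references plus a **residual** signature
(`residual_signature()`): the renormalized positive part of the component
minus the kept references. A component that actually lies in the catalogue
span has no residual and raises an error (the floor, 1e-6 of total mass,
sits deliberately above the EM tolerance). `deconvolute_components()`
orchestrates this over all components and refits per-branch exposures
against the final signature set, zeroing exposures below 0.1.

# Burden

`burden_table()` sums each crypt's assigned variants along its root-to-leaf
path (including trunk variants) and divides by age for per-year rates;
`tissue_median_rates()` takes medians over survey crypts per tissue.
`lmm_lrt()` compares `burden ~ age + (1 | patient)` against the same model
plus a cohort term by likelihood ratio (both fit by maximum likelihood;
chi-squared with 1 df).

`simulate_burden_cohort()` offers two generator families. The `"gaussian"`
family matches the fitted model exactly (normal patient intercepts, normal
residuals) and is what the calibration tests use: a likelihood-ratio test is
only guaranteed its nominal type-I error under a correctly specified null,
so calibration must be assessed under the model's own family. The
`"poisson"` family (log-normal patient effects, Poisson counts) is the more
realistic generator used for power assessment.

`flag_drivers()` applies rules in priority order — known driver change,
truncating variant in a tumour suppressor, missense at an annotated hotspot —
never flags synonymous variants, and carries the microsatellite flag for
frameshifts in long tracts (such indels are frequent passengers under
mismatch-repair deficiency). `driver_summary()` reports crypt percentages
rounded half-up to one decimal.

# Scope and open questions

* The generator plants clonal, single-origin variants on a known tree
  (conflict-free by construction); it does not simulate copy-number change,
  contamination between crypts, or subclonal architecture beyond the
  artifact class.
* Exhaustive tree search is capped at 8 leaves; heuristic search has no cap
  but, like all hill climbers, has no optimality guarantee (it is validated
  against the exhaustive optimum on small instances).
* Per-crypt rates are computed per crypt and then medianed; a
  regression-slope estimate is a reasonable alternative the median does not
  capture.
* Burdens are uncorrected for calling sensitivity; a sensitivity divisor
  hook exists with default 1.
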