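# cryptphylo

Somatic phylogenomics of clonal epithelial crypts: from per-crypt variant
read counts to filtered somatic calls, crypt lineage trees, per-branch
mutational spectra and signatures, and mutation burden statistics.

Intestinal crypts are clonal: each is maintained by a small stem cell niche,
so a somatic mutation fixed in the founding lineage is carried by essentially
all cells of the crypt. In deep sequencing of a microdissected crypt, true
somatic variants therefore sit near VAF 0.5 in carrier crypts and near 0
elsewhere — an all-or-nothing signal that this package exploits at every
stage:

* **Filtering** — quality predicates; an exact one-sided binomial test
  against aggregate VAF 0.5 flags germline variants; a beta-binomial
  overdispersion (rho) MLE separates bimodal clonal variants from low-VAF
  recurrent artifacts (`filter_variants()`).
* **Phylogeny** — zygote-rooted maximum parsimony on binary VAF genotypes
  with exhaustive search up to 8 crypts and seeded stepwise+NNI search above,
  bootstrap supports, and maximum-likelihood placement of every variant on a
  branch, with trunk and artifact categories (`search_mp_tree()`,
  `assign_variants_ml()`).
* **Spectra** — SBS96 trinucleotide and PCAWG ID83 indel classification with
  strand normalization, repeat and microhomology logic, and per-branch
  spectrum matrices (`sbs_channel()`, `id_channel()`, `branch_spectra()`).
* **Signatures** — de novo extraction by a hierarchical Dirichlet process
  Gibbs sampler (C++) or by KL-NMF with silhouette rank selection; EM
  deconvolution against a reference catalogue with reconstitution thresholds
  and residual ("unknown") signature construction; per-branch exposure
  refitting (`hdp_extract()`, `nmf_extract()`, `deconvolute_components()`).
* **Burden** — per-crypt burdens as path sums over the tree, per-year rates,
  tissue medians, tumour/normal folds, a mixed-model cohort comparison
  (`lmm_lrt()`), and rule-based driver annotation (`flag_drivers()`).

A synthetic cohort generator (`simulate_cohort()`) emulates clonal crypt
sequencing — germline variants, recurrent artifacts, signature-driven somatic
mutations on a known tree, optional hypermutant crypts and tumour clades —
with ground truth for every stage.

## Worked example

An 8-crypt cohort at 30X with 2,000 germline variants, 500 artifacts and
signature-driven somatic mutations (planted rate 10 SBS and 0.4 indels per
year, age 50):

```r
library(cryptphylo)

cat_sbs <- synthetic_signatures(sbs96_labels(), 3, seed = 42)
cat_id  <- synthetic_signatures(id83_labels(), 2, seed = 43, prefix = "IDSIG")
cfg <- sim_config(n_crypts = 8, seed = 1,
                  signature_activities = c(SIG1 = 6, SIG2 = 3, SIG3 = 1),
                  id_signature_activities = c(IDSIG1 = 0.3, IDSIG2 = 0.1))
coh <- simulate_cohort(cfg, cat_sbs, cat_id, seed = 1)
nrow(coh$matrix$alt)
#> [1] 6555

flt <- filter_variants(coh$matrix)
table(flt$status)
#> artifact germline  somatic
#>      497     2006     4052

som <- cm_subset(coh$matrix, flt$id[flt$status == "somatic"])
sbs_ids <- som$variants$id[som$variants$kind == "SBS"]
g <- code_genotypes(cm_subset(som, sbs_ids))
mp <- search_mp_tree(g, mode = "heuristic", seed = 1, restarts = 3)
c(score = mp$score, n_optimal = mp$n_optimal,
  rf_to_truth = rf_distance(mp$tree, coh$truth$tree))
#>       score   n_optimal rf_to_truth
#>        3816           1           0

asg_sbs <- assign_variants_ml(mp$tree, cm_subset(som, sbs_ids))
asg_id <- assign_indels_to_sbs_tree(
  mp$tree, cm_subset(som, setdiff(som$variants$id, sbs_ids)))
bt <- burden_table(mp$tree, coh$matrix$samples, asg_sbs, asg_id)
tissue_median_rates(bt)
#>   group n sbs_rate id_rate
#> 1 colon 8    10.09    0.41
```

The recovered median rates (10.09 SBS and 0.41 indels per crypt per year)
match the planted 10 and 0.4 to within sampling noise, and the inferred tree
is identical to the simulated one.

## Analysis pipeline

Numbered drivers under `analysis/` chain the full workflow on a simulated
cohort and write tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R --seed 1 --outdir results/cohort
Rscript analysis/02_filter_variants.R --matrix results/cohort
Rscript analysis/03_build_tree.R --bootstrap 100 --seed 7
Rscript analysis/04_signatures.R --backend hdp   # or --backend nmf
Rscript analysis/05_burden.R --report results/burden_report.json
```

Each driver takes `--help`-style flags documented in its header comment
(matrix/tree locations, filter thresholds, bootstrap replicates, extraction
backend, catalogue path, driver gene lists).

## Reproduction

* **Unit and acceptance tests** (requires `testthat`):

  ```r
  testthat::test_dir("tests/testthat", package = "cryptphylo",
                     load_package = "installed")
  ```

  `tests/testthat/test-acceptance.R` holds the end-to-end guarantees: filter
  recovery on the default cohort, the overdispersion MLE against a grid
  oracle, parsimony scoring against brute-force enumeration on all 945
  rooted 6-leaf topologies, tree and placement recovery over 20 seeds,
  hand-built SBS/indel classification tables, planted-signature recovery by
  both backends, exact deconvolution and residual isolation, mixed-model
  calibration and power, and burden-rate and tumour-fold recovery.

* **Acceptance script** — one self-contained run that writes the headline
  quantities as JSON:

  ```sh
  Rscript scripts/acceptance.R --seed 1 --out acceptance.json
  ```

  With seed 1 this reports, among others: germline recovery 1.0, artifact
  removal 0.994, somatic retention 0.9985, Robinson–Foulds distance 0 to the
  true tree, placement accuracy 1.0 (SBS and indel), median rate 10.09 SBS
  per year against a planted 10, minimum signature-recovery cosine 0.994
  (NMF) / 0.992 (HDP), and a tumour/normal burden fold of 95.3 against a
  planted 100x construction.

* **Vignette** — `vignettes/methods.Rmd` documents the statistical methods,
  parameter defaults and their rationale, and the scope of the generator.
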