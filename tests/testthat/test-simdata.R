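test_that("simulate_tree returns the cherry on two crypts and errors below", {
  t <- simulate_tree(2, seed = 9)
  expect_equal(t$nleaf, 2L)
  expect_identical(ct_canonical(t), "(crypt01,crypt02);")
  expect_error(simulate_tree(1), "n_crypts")
})

test_that("simulate_tree on 8 crypts has the right shape and unit path sums", {
  t <- simulate_tree(8, seed = 1)
  expect_equal(t$nleaf, 8L)
  expect_equal(length(t$parent), 15L)        # 8 leaves + root + 6 internal
  expect_equal(sum(t$parent != 0L), 14L)     # 14 branches
  expect_true(all(t$frac[-9L] > 0))
  # root-to-leaf fraction sums are 1 for every leaf
  for (leaf in 1:8) {
    s <- 0; v <- leaf
    while (v != 9L) { s <- s + t$frac[v]; v <- t$parent[v] }
    expect_equal(s, 1)
  }
})

test_that("simulate_tree is deterministic under a fixed seed", {
  a <- simulate_tree(8, seed = 77)
  b <- simulate_tree(8, seed = 77)
  expect_identical(ct_canonical(a), ct_canonical(b))
  expect_identical(a$frac, b$frac)
})

test_that("a degenerate one-channel signature yields only that channel", {
  v <- rep(0, 96); names(v) <- sbs96_labels(); v["A[C>T]G"] <- 1
  cat1 <- signature_catalogue(matrix(v, ncol = 1,
                                     dimnames = list(sbs96_labels(), "ONLY")))
  cfg <- sim_config(n_crypts = 4, n_germline = 0L, n_artifact = 0L,
                    embryonic_mutation_count = 0L,
                    signature_activities = c(ONLY = 5))
  tree <- simulate_tree(4, seed = 2)
  dm <- draw_mutations(tree, cfg, cat1, seed = 2)
  expect_gt(nrow(dm$variants), 0)
  expect_true(all(dm$variants$channel == "A[C>T]G"))
  # the realized ref/alt/context re-classify to the same channel
  rederived <- sbs_channel(dm$variants$ref, dm$variants$alt,
                           dm$variants$context)
  expect_true(all(rederived == "A[C>T]G"))
})

test_that("zero activities produce zero somatic variants and empty truth", {
  cats <- test_catalogues()
  cfg <- sim_config(n_crypts = 4, n_germline = 5L, n_artifact = 5L,
                    embryonic_mutation_count = 0L,
                    signature_activities = c(SIG1 = 0, SIG2 = 0, SIG3 = 0))
  dm <- draw_mutations(simulate_tree(4, seed = 3), cfg, cats$sbs, seed = 3)
  expect_equal(sum(dm$variants$class == "somatic"), 0L)
  expect_length(dm$truth$branch_variants, 0L)
})

test_that("unknown signature names are a missing-reference error", {
  cats <- test_catalogues()
  cfg <- sim_config(n_crypts = 4, signature_activities = c(NOPE = 5))
  expect_error(draw_mutations(simulate_tree(4, seed = 4), cfg, cats$sbs,
                              seed = 4),
               "unknown signature")
})

test_that("large draws converge to the planted channel distribution", {
  cats <- test_catalogues()
  tree <- simulate_tree(2, seed = 5)
  # push ~10,000 mutations from SIG1 through one generator call
  cfg <- sim_config(n_crypts = 2, patient_age = 1000,
                    n_germline = 0L, n_artifact = 0L,
                    embryonic_mutation_count = 0L,
                    signature_activities = c(SIG1 = 10))
  dm <- draw_mutations(tree, cfg, cats$sbs, seed = 5)
  expect_gt(nrow(dm$variants), 5000)
  emp <- tabulate(match(dm$variants$channel, sbs96_labels()), nbins = 96)
  expect_gte(cosine(emp / sum(emp), cats$sbs$vectors[, "SIG1"]), 0.99)
})

test_that("zero sequencing error makes non-carrier cells exactly alt = 0", {
  cats <- test_catalogues()
  cfg <- default_test_config(seq_error = 0, n_germline = 0L, n_artifact = 0L,
                             patient_age = 10)
  tree <- simulate_tree(8, seed = 6)
  dm <- draw_mutations(tree, cfg, cats$sbs, seed = 6)
  reads <- sample_reads(dm$truth, cfg, seed = 6)
  leafsets <- cryptphylo:::ct_leafsets(tree)
  for (b in names(dm$truth$branch_variants)) {
    vs <- dm$truth$branch_variants[[b]]
    non_carriers <- setdiff(seq_len(8), leafsets[[as.integer(b)]])
    if (length(non_carriers)) {
      expect_true(all(reads$alt[vs, non_carriers] == 0L))
    }
  }
})

test_that("germline sites have mean VAF near one half", {
  cats <- test_catalogues()
  cfg <- sim_config(n_crypts = 8, n_germline = 100L, n_artifact = 0L,
                    embryonic_mutation_count = 0L,
                    signature_activities = c(SIG1 = 0.1), patient_age = 10)
  dm <- draw_mutations(simulate_tree(8, seed = 7), cfg, cats$sbs, seed = 7)
  reads <- sample_reads(dm$truth, cfg, seed = 7)
  g <- names(dm$truth$variant_class)[dm$truth$variant_class == "germline"]
  vaf <- rowSums(reads$alt[g, ]) / rowSums(reads$depth[g, ])
  expect_lt(abs(mean(vaf) - 0.5), 0.02)
  expect_true(all(abs(vaf - 0.5) < 0.2))
})

test_that("artifact sites mostly fail the overdispersion filter at 8 crypts", {
  cats <- test_catalogues()
  cfg <- sim_config(n_crypts = 8, n_germline = 0L, n_artifact = 200L,
                    embryonic_mutation_count = 0L,
                    signature_activities = c(SIG1 = 0.1), patient_age = 10)
  dm <- draw_mutations(simulate_tree(8, seed = 8), cfg, cats$sbs, seed = 8)
  reads <- sample_reads(dm$truth, cfg, seed = 8)
  a <- names(dm$truth$variant_class)[dm$truth$variant_class == "artifact"]
  rho <- vapply(a, function(v) estimate_rho(reads$alt[v, ], reads$depth[v, ]), 0)
  expect_gte(mean(rho < 0.1), 0.9)
})

test_that("generated variants re-classify to their generating channel", {
  cats <- test_catalogues()
  coh <- simulate_cohort(default_test_config(n_germline = 50L,
                                             n_artifact = 20L),
                         cats$sbs, cats$id, seed = 11)
  v <- coh$matrix$variants
  sbs <- v$kind == "SBS"
  expect_identical(sbs_channel(v$ref[sbs], v$alt[sbs], v$context[sbs]),
                   v$channel[sbs])
  expect_identical(id_channel(v$kind[!sbs], v$indel_seq[!sbs],
                              v$flank5[!sbs], v$flank3[!sbs]),
                   v$channel[!sbs])
})

test_that("simulate_cohort is deterministic and internally consistent", {
  cats <- test_catalogues()
  cfg <- default_test_config(n_germline = 30L, n_artifact = 10L,
                             patient_age = 10)
  a <- simulate_cohort(cfg, cats$sbs, cats$id, seed = 12)
  b <- simulate_cohort(cfg, cats$sbs, cats$id, seed = 12)
  expect_identical(a$matrix$alt, b$matrix$alt)
  expect_identical(a$matrix$variants, b$matrix$variants)
  # every somatic variant on exactly one branch; union = somatic set
  som <- names(a$truth$variant_class)[a$truth$variant_class == "somatic"]
  placed <- unlist(a$truth$branch_variants, use.names = FALSE)
  expect_setequal(placed, som)
  expect_equal(anyDuplicated(placed), 0L)
})

test_that("crypts are clonal: median somatic VAF above 0.3 in every crypt", {
  cats <- test_catalogues()
  coh <- simulate_cohort(default_test_config(), cats$sbs, cats$id, seed = 13)
  som <- names(coh$truth$variant_class)[coh$truth$variant_class == "somatic"]
  sm <- cm_subset(coh$matrix, som)
  for (s in sm$samples$id) {
    cs <- clonality_summary(sm, s, som)
    expect_true(cs$is_clonal)
    expect_gt(cs$median_vaf, 0.3)
  }
})

test_that("a tumour clade carries a hypermutated trunk shared by its crypts", {
  cats <- test_catalogues()
  cfg <- default_test_config(
    patient_age = 10,
    tumour_clade = list(n_crypts = 3, trunk_mutations = 800,
                        trunk_mix = c(SIG1 = 1), branch_mutations = 20))
  coh <- simulate_cohort(cfg, cats$sbs, cats$id, seed = 14)
  expect_equal(sum(coh$matrix$samples$crypt_type == "tumour"), 3L)
  tree <- coh$truth$tree
  sets <- cryptphylo:::ct_leafsets(tree)
  tum_leaves <- which(coh$matrix$samples[match(tree$labels,
                                               coh$matrix$samples$id),
                                         "crypt_type"] == "tumour")
  sizes <- vapply(names(coh$truth$branch_variants), function(b) {
    length(coh$truth$branch_variants[[b]])
  }, 0L)
  trunk <- names(which(vapply(names(sizes), function(b) {
    setequal(sets[[as.integer(b)]], tum_leaves)
  }, TRUE)))
  expect_length(trunk, 1L)
  expect_gt(sizes[trunk], 600)
})

test_that("write_cohort emits the full text bundle", {
  cats <- test_catalogues()
  coh <- simulate_cohort(default_test_config(n_germline = 10L,
                                             n_artifact = 5L,
                                             patient_age = 5),
                         cats$sbs, cats$id, seed = 15)
  dir <- tempfile()
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(
    dir, c("alt.tsv", "depth.tsv", "variants.tsv", "samples.tsv",
           "tree.nwk", "truth.json")))))
  nwk <- readLines(file.path(dir, "tree.nwk"))
  expect_silent(ape::read.tree(text = nwk))
  unlink(dir, recursive = TRUE)
})
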