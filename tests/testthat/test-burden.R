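# Fixed 4-leaf tree ((a,b),(c,d)); node 6 = {a,b}, node 7 = {c,d}.
burden_tree <- function() new_ctree(c(6L, 6L, 7L, 7L, 0L, 5L, 5L),
                                    c("a", "b", "c", "d"))

burden_samples <- function(age = 10) {
  data.frame(id = c("a", "b", "c", "d"), patient = "P1", tissue = "colon",
             crypt_type = "survey", age = age, cohort = "LS",
             stringsAsFactors = FALSE)
}

# Minimal assignment object: `branch` is a character node id or "root".
fake_assignment <- function(branches) {
  list(assignment = data.frame(id = paste0("v", seq_along(branches)),
                               branch = branches, loglik = 0, posterior = 1,
                               stringsAsFactors = FALSE))
}

test_that("burdens are root-to-leaf path sums including the trunk", {
  # 10 on the trunk (root), 5 private to a, 3 on the {a,b} branch
  asg <- fake_assignment(c(rep("root", 10), rep("1", 5), rep("6", 3)))
  bt <- burden_table(burden_tree(), burden_samples(), asg)
  expect_equal(bt$sbs_burden[bt$id == "a"], 18)
  expect_equal(bt$sbs_burden[bt$id == "b"], 13)
  expect_equal(bt$sbs_burden[bt$id == "c"], 10)
  expect_equal(bt$sbs_rate[bt$id == "a"], 1.8)
  expect_error(burden_table(burden_tree(),
                            transform(burden_samples(), age = NA), asg),
               "missing ages")
})

test_that("leaf burdens conserve the assigned variant total along paths", {
  set.seed(81)
  branches <- as.character(sample(c(1:4, 6:7), 200, replace = TRUE))
  asg <- fake_assignment(branches)
  bt <- burden_table(burden_tree(), burden_samples(), asg)
  tab <- table(factor(branches, levels = as.character(c(1:4, 6:7))))
  expect_equal(bt$sbs_burden[bt$id == "a"], unname(tab["1"] + tab["6"]))
  expect_equal(bt$sbs_burden[bt$id == "d"], unname(tab["4"] + tab["7"]))
})

test_that("tissue medians use survey crypts and are order invariant", {
  bt <- data.frame(id = letters[1:4], patient = "P1",
                   tissue = c("colon", "colon", "colon", "ileum"),
                   crypt_type = c("survey", "survey", "survey", "tumour"),
                   age = 10, cohort = "LS",
                   sbs_burden = c(500, 550, 600, 9999),
                   id_burden = c(20, 22, 24, 999),
                   stringsAsFactors = FALSE)
  bt$sbs_rate <- bt$sbs_burden / bt$age
  bt$id_rate <- bt$id_burden / bt$age
  m <- tissue_median_rates(bt)
  expect_equal(m$group, "colon")  # the tumour crypt is excluded
  expect_equal(m$sbs_rate, 55)
  m2 <- tissue_median_rates(bt[sample(4), ])
  expect_equal(m2, m)
  expect_warning(tissue_median_rates(bt, crypt_types = "mmrd"), "no crypts")
})

test_that("single-crypt groups report their own rate", {
  bt <- data.frame(id = "a", patient = "P1", tissue = "colon",
                   crypt_type = "survey", age = 10, cohort = "LS",
                   sbs_burden = 480, id_burden = 20, stringsAsFactors = FALSE)
  bt$sbs_rate <- 48; bt$id_rate <- 2
  expect_equal(tissue_median_rates(bt)$sbs_rate, 48)
})

test_that("the cohort LRT is near null on relabeled halves of one cohort", {
  bt <- simulate_burden_cohort(n_patients = c(20L, 0L), seed = 5,
                               family = "gaussian")
  # relabel half of the patients as the second cohort
  bt$cohort <- ifelse(as.integer(factor(bt$patient)) <= 10, "A", "B")
  res <- lmm_lrt(bt)
  expect_gte(res$statistic, 0)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_error(lmm_lrt(transform(bt, cohort = "A")), "both cohorts")
})

test_that("the cohort LRT detects a planted rate difference", {
  bt <- simulate_burden_cohort(rates = c(55, 165), seed = 6)
  res <- lmm_lrt(bt)
  expect_lt(res$p_value, 1e-4)
  expect_true("cohortB" %in% names(res$coefficients))
})

test_that("fold differences divide group medians with guardrails", {
  bt <- data.frame(id = letters[1:6], patient = "P1", tissue = "colon",
                   crypt_type = rep(c("survey", "tumour"), each = 3),
                   age = 10, cohort = "LS",
                   sbs_burden = c(400, 500, 600, 40000, 50000, 60000),
                   id_burden = c(10, 20, 30, 100, 200, 300),
                   stringsAsFactors = FALSE)
  bt$sbs_rate <- bt$sbs_burden / 10; bt$id_rate <- bt$id_burden / 10
  f <- fold_difference(bt)
  expect_equal(f$sbs_fold, 100)
  expect_equal(f$id_fold, 10)
  expect_equal(f$n_a, 3L)
  # identical groups give fold 1
  bt2 <- bt; bt2$sbs_burden <- 500; bt2$id_burden <- 20
  expect_equal(fold_difference(bt2)$sbs_fold, 1)
  expect_error(fold_difference(bt[bt$crypt_type == "survey", ]), "empty group")
  bt3 <- bt; bt3$sbs_burden[1:3] <- 0
  expect_error(fold_difference(bt3), "zero median")
})

test_that("driver rules fire in priority order and spare benign classes", {
  v <- data.frame(
    id = paste0("m", 1:7),
    sample = paste0("c", c(1, 1, 2, 3, 4, 5, 6)),
    gene = c("APC", "TP53", "KRAS", "KRAS", "APC", "BRAF", "APC"),
    change = c("R213*", "R175H", "G12V", "G13D", "T1556fs", "V600E", "A10A"),
    consequence = c("nonsense", "missense", "missense", "missense",
                    "frameshift", "synonymous", "synonymous"),
    indel_seq = c(NA, NA, NA, NA, "T", NA, NA),
    flank3 = c(NA, NA, NA, NA, "TTTTTGA", NA, NA),
    stringsAsFactors = FALSE
  )
  calls <- flag_drivers(
    v,
    known_list = c("TP53 R175H"),
    tsg_list = c("APC", "TP53"),
    hotspot_list = c("KRAS 12")
  )
  expect_setequal(calls$id, c("m1", "m2", "m3", "m5"))
  expect_identical(calls$rule_fired[calls$id == "m1"], "truncating-TSG")
  expect_identical(calls$rule_fired[calls$id == "m2"], "known")
  expect_identical(calls$rule_fired[calls$id == "m3"], "hotspot-missense")
  # the frameshift in a 6-unit poly-T tract carries the microsatellite flag
  expect_true(calls$microsatellite_flag[calls$id == "m5"])
  expect_false(any(calls$microsatellite_flag[calls$id != "m5"]))
  expect_error(flag_drivers(v[, c("id", "gene")]), "columns")
})

test_that("driver summary reproduces printed-percentage arithmetic", {
  calls <- data.frame(
    id = paste0("m", 1:33),
    sample = c(paste0("c", 1:23),                 # 23 crypts with one driver
               rep(paste0("d", 1:5), each = 2)),  # 5 crypts with two drivers
    gene = "APC", change = paste0("X", 1:33),
    stringsAsFactors = FALSE
  )
  s <- driver_summary(calls, n_crypts_total = 132)
  expect_equal(s$crypts_with_driver, 28)
  expect_equal(s$pct_with_driver, 21.2)
  expect_equal(s$pct_one_driver, 17.4)
  expect_equal(s$pct_two_drivers, 3.8)
  expect_equal(s$crypts_with_driver, s$crypts_one_driver + s$crypts_two_drivers)
  z <- driver_summary(calls[0, ], 132)
  expect_equal(z$pct_with_driver, 0)
  expect_error(driver_summary(calls, 0), "n_crypts_total")
})

test_that("burden rates recover the planted per-year rate end to end", {
  cats <- test_catalogues()
  coh <- simulate_cohort(default_test_config(), cats$sbs, cats$id, seed = 82)
  tree <- coh$truth$tree
  som <- names(coh$truth$variant_class)[coh$truth$variant_class == "somatic"]
  sm <- cm_subset(coh$matrix, som)
  sbs <- cm_subset(sm, sm$variants$id[sm$variants$kind == "SBS"])
  ids <- cm_subset(sm, sm$variants$id[sm$variants$kind != "SBS"])
  bt <- burden_table(tree, coh$matrix$samples,
                     assign_variants_ml(tree, sbs),
                     assign_indels_to_sbs_tree(tree, ids))
  planted <- sum(default_test_config()$signature_activities)
  rel_err <- abs(bt$sbs_rate - planted) / planted
  expect_lt(median(rel_err), 0.1)
})
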