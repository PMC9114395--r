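# A fixed 4-leaf tree: ((a,b),(c,d)). Nodes: leaves a=1 b=2 c=3 d=4, root=5,
# internal 6={a,b}, 7={c,d}.
tree_ab_cd <- function() new_ctree(c(6L, 6L, 7L, 7L, 0L, 5L, 5L),
                                   c("a", "b", "c", "d"))
# ((a,c),(b,d)): leaves a=1 c=2 b=3 d=4, node 6={a,c}, node 7={b,d}
tree_ac_bd <- function() new_ctree(c(6L, 6L, 7L, 7L, 0L, 5L, 5L),
                                   c("a", "c", "b", "d"))

test_that("code_genotypes applies strict VAF thresholds and handles zero depth", {
  alt <- matrix(c(12L, 2L, 6L, 9L, 0L), 5, 1,
                dimnames = list(paste0("v", 1:5), "s1"))
  depth <- matrix(c(30L, 30L, 30L, 30L, 0L), 5, 1, dimnames = dimnames(alt))
  cm <- count_matrix(alt, depth,
                     data.frame(id = paste0("v", 1:5),
                                stringsAsFactors = FALSE),
                     data.frame(id = "s1", patient = "P1", tissue = "colon",
                                crypt_type = "survey", age = 50,
                                stringsAsFactors = FALSE))
  g <- code_genotypes(cm)
  expect_identical(as.vector(g), c(1L, 0L, NA, NA, NA))
})

test_that("fitch_score counts single and double origins correctly", {
  g <- matrix(c(1L, 1L, 0L, 0L), 1, 4,
              dimnames = list("v1", c("a", "b", "c", "d")))
  expect_equal(fitch_score(tree_ab_cd(), g), 1L)
  # on the conflicting topology the same character needs two changes
  expect_equal(fitch_score(tree_ac_bd(), g), 2L)
  # fully ambiguous character costs nothing
  g2 <- matrix(NA_integer_, 1, 4, dimnames = dimnames(g))
  expect_equal(fitch_score(tree_ab_cd(), g2), 0L)
  # variant present in all leaves forces the root out of state 0: one change
  g3 <- matrix(1L, 1, 4, dimnames = dimnames(g))
  expect_equal(fitch_score(tree_ab_cd(), g3), 1L)
  expect_error(fitch_score(tree_ab_cd(), matrix(1L, 1, 2,
                                                dimnames = list("v", c("x", "y")))),
               "do not match")
})

test_that("fitch_score equals brute-force completion enumeration", {
  set.seed(41)
  labels <- letters[1:5]
  for (rep in 1:6) {
    tree <- random_topology(labels)
    g <- matrix(sample(c(0L, 1L, NA), 5 * 12, replace = TRUE,
                       prob = c(.45, .45, .1)),
                12, 5, dimnames = list(NULL, labels))
    expect_identical(fitch_score(tree, g, per_site = TRUE), oracle_fitch(tree, g))
  }
})

test_that("parsimony score is invariant to variant order and leaf relabeling", {
  set.seed(42)
  labels <- letters[1:6]
  tree <- random_topology(labels)
  g <- matrix(sample(c(0L, 1L, NA), 6 * 30, replace = TRUE), 30, 6,
              dimnames = list(NULL, labels))
  s <- fitch_score(tree, g)
  expect_equal(fitch_score(tree, g[sample(30), ]), s)
  expect_equal(fitch_score(tree, g[, sample(6)]), s)
})

test_that("exhaustive search recovers the generating topology from perfect characters", {
  # characters = indicators of the clades of a known 5-leaf tree
  true <- cryptphylo:::ct_renumber(
    c(0L, 1L, 1L, 2L, 2L, 4L, 4L, 6L, 6L), c(3L, 5L, 7L, 8L, 9L),
    c("a", "b", "c", "d", "e"))
  clades <- list(c("d", "e"), c("c", "d", "e"), c("b", "c", "d", "e"))
  g <- do.call(rbind, c(
    lapply(clades, function(cl) as.integer(c("a", "b", "c", "d", "e") %in% cl)),
    lapply(c("a", "b", "c", "d", "e"),
           function(l) as.integer(c("a", "b", "c", "d", "e") == l))
  ))
  g <- g[rep(seq_len(nrow(g)), 3), ]  # triplicate for signal
  colnames(g) <- c("a", "b", "c", "d", "e")
  res <- search_mp_tree(g, mode = "exhaustive")
  expect_identical(ct_canonical(res$tree), ct_canonical(true))
  # each of the 8 distinct characters fits with exactly one change
  expect_equal(res$score, 24L)
  expect_equal(res$n_optimal, 1L)

  heur <- search_mp_tree(g, mode = "heuristic", seed = 3, restarts = 3)
  expect_equal(heur$score, res$score)
  expect_identical(ct_canonical(heur$tree), ct_canonical(res$tree))
})

test_that("co-optimal trees are reported and the tie-break is deterministic", {
  g <- matrix(c(1L, 1L, 0L, 0L), 1, 4,
              dimnames = list("v1", c("a", "b", "c", "d")))
  res1 <- search_mp_tree(g, mode = "exhaustive")
  expect_gt(res1$n_optimal, 1L)
  res2 <- search_mp_tree(g, mode = "exhaustive")
  expect_identical(ct_canonical(res1$tree), ct_canonical(res2$tree))
  expect_identical(res1$optimal, res2$optimal)
  expect_error(search_mp_tree(g[, 1:2, drop = FALSE]), ">= 3")
  expect_error(search_mp_tree(matrix(0L, 1, 9,
                                     dimnames = list(NULL, letters[1:9])),
                              mode = "exhaustive"),
               "up to 8 leaves")
})

test_that("bootstrap supports are certain for heavily replicated perfect characters", {
  labels <- c("a", "b", "c", "d", "e")
  clades <- list(c("a", "b"), c("a", "b", "c"), c("d", "e"))
  g <- do.call(rbind, lapply(clades, function(cl) as.integer(labels %in% cl)))
  g <- g[rep(1:3, each = 100), ]
  colnames(g) <- labels
  res <- search_mp_tree(g, mode = "exhaustive")
  bs <- bootstrap_support(g, res$tree, n = 100, seed = 4)
  expect_length(bs, 3L)  # internal non-root nodes of a 5-leaf tree
  expect_true(all(bs == 100))
  expect_null(bootstrap_support(g, res$tree, n = 0))
})

test_that("ML placement puts private, shared and trunk variants where they belong", {
  tree <- tree_ab_cd()
  alt <- rbind(private_a = c(15L, 0L, 0L, 0L),
               cherry_ab = c(15L, 15L, 0L, 0L),
               trunk     = c(15L, 15L, 15L, 15L),
               nodepth   = c(0L, 0L, 0L, 0L))
  colnames(alt) <- c("a", "b", "c", "d")
  depth <- matrix(30L, 4, 4, dimnames = dimnames(alt))
  depth["nodepth", ] <- 0L
  cm <- count_matrix(alt, depth,
                     data.frame(id = rownames(alt), stringsAsFactors = FALSE),
                     data.frame(id = c("a", "b", "c", "d"), patient = "P1",
                                tissue = "colon", crypt_type = "survey",
                                age = 50, stringsAsFactors = FALSE))
  asg <- assign_variants_ml(tree, cm)
  a <- asg$assignment
  expect_identical(a$branch[a$id == "private_a"], "1")
  expect_gt(a$posterior[a$id == "private_a"], 0.99)
  expect_identical(a$branch[a$id == "cherry_ab"], "6")
  expect_identical(a$branch[a$id == "trunk"], "root")
  expect_true(is.na(a$branch[a$id == "nodepth"]))
  # conservation: branch lengths sum to the number of variants
  expect_equal(sum(asg$branch_lengths), nrow(alt))
})

test_that("low-VAF variants fall into the artifact category", {
  tree <- tree_ab_cd()
  # VAF ~0.07 in every crypt: below the presence/absence crossover (~0.10 at
  # err = 0.001), so no carrier set explains the reads better than none
  alt <- matrix(2L, 1, 4, dimnames = list("art", c("a", "b", "c", "d")))
  depth <- matrix(30L, 1, 4, dimnames = dimnames(alt))
  cm <- count_matrix(alt, depth,
                     data.frame(id = "art", stringsAsFactors = FALSE),
                     data.frame(id = c("a", "b", "c", "d"), patient = "P1",
                                tissue = "colon", crypt_type = "survey",
                                age = 50, stringsAsFactors = FALSE))
  asg <- assign_variants_ml(tree, cm)
  expect_true(is.na(asg$assignment$branch))
  expect_equal(asg$branch_lengths[["artifact"]], 1L)
})

test_that("indel assignment reuses the SBS tree and handles empty input", {
  tree <- tree_ab_cd()
  empty <- count_matrix(
    matrix(integer(0), 0, 4, dimnames = list(NULL, c("a", "b", "c", "d"))),
    matrix(integer(0), 0, 4, dimnames = list(NULL, c("a", "b", "c", "d"))),
    data.frame(id = character(0), stringsAsFactors = FALSE),
    data.frame(id = c("a", "b", "c", "d"), patient = "P1", tissue = "colon",
               crypt_type = "survey", age = 50, stringsAsFactors = FALSE))
  res <- assign_indels_to_sbs_tree(tree, empty)
  expect_equal(nrow(res$assignment), 0L)
})

test_that("heuristic search matches the exhaustive optimum on small instances", {
  set.seed(51)
  for (n in c(5, 6)) {
    labels <- letters[1:n]
    g <- matrix(sample(c(0L, 1L, NA), n * 20, replace = TRUE,
                       prob = c(.4, .4, .2)),
                20, n, dimnames = list(NULL, labels))
    ex <- search_mp_tree(g, mode = "exhaustive")
    he <- search_mp_tree(g, mode = "heuristic", seed = 6, restarts = 4)
    expect_gte(he$score, ex$score)  # heuristic can never beat the optimum
    expect_equal(he$score, ex$score)
  }
})
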