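# Crypt phylogenies: VAF-coded genotypes, maximum parsimony under a
# zygote-rooted Fitch criterion (missing data as {0,1}), bootstrap supports,
# and maximum-likelihood placement of variants on branches.

#' Code genotypes from VAFs
#'
#' VAF > `present` codes 1, VAF < `absent` codes 0, anything between (or a
#' zero-depth cell) is ambiguous (NA). Inequalities are strict on both sides.
#'
#' @param matrix A `count_matrix` (somatic variants only).
#' @param present,absent VAF thresholds (defaults 0.3 / 0.1).
#' @return Integer matrix (variants x samples) with entries 0, 1 or NA.
#' @export
code_genotypes <- function(matrix, present = 0.3, absent = 0.1) {
  vaf <- matrix$alt / matrix$depth
  g <- matrix(NA_integer_, nrow(vaf), ncol(vaf), dimnames = dimnames(vaf))
  g[!is.na(vaf) & matrix$depth > 0 & vaf > present] <- 1L
  g[!is.na(vaf) & matrix$depth > 0 & vaf < absent] <- 0L
  g
}

# Collapse genotype rows to unique site patterns with multiplicities.
compress_patterns <- function(genotypes) {
  key <- apply(genotypes, 1, function(r) paste(ifelse(is.na(r), "?", r), collapse = ""))
  u <- !duplicated(key)
  list(patterns = genotypes[u, , drop = FALSE],
       weights = as.vector(table(key)[key[u]]),
       key = key)
}

#' Zygote-rooted Fitch parsimony score
#'
#' Small-parsimony count of binary state changes per variant, with ambiguous
#' leaves treated as {0,1} and the root state set intersected with {0} (the
#' zygote carries no somatic variant; a root forced out of state 0 costs one
#' additional change).
#'
#' @param tree A `ctree` whose leaf labels match the genotype columns.
#' @param genotypes Integer matrix (variants x samples; 0/1/NA).
#' @param weights Optional per-variant multiplicities.
#' @param per_site Return the per-variant vector instead of the sum.
#' @return Integer parsimony score.
#' @export
fitch_score <- function(tree, genotypes, weights = NULL, per_site = FALSE) {
  if (!setequal(colnames(genotypes), tree$labels)) {
    stop("fitch_score: genotype columns do not match tree leaves")
  }
  g <- genotypes[, tree$labels, drop = FALSE]
  n <- tree$nleaf
  nchar_ <- nrow(g)
  if (nchar_ == 0L) return(if (per_site) integer(0) else 0L)
  sets <- vector("list", length(tree$parent))
  for (v in seq_len(n)) {
    x <- g[, v]
    sets[[v]] <- ifelse(is.na(x), 3L, x + 1L)
  }
  changes <- integer(nchar_)
  ch <- ct_children(tree)
  for (v in ct_postorder(tree)) {
    if (v <= n) next
    kids <- ch[[v]]
    sa <- sets[[kids[1]]]; sb <- sets[[kids[2]]]
    inter <- bitwAnd(sa, sb)
    disjoint <- inter == 0L
    changes <- changes + disjoint
    sets[[v]] <- ifelse(disjoint, bitwOr(sa, sb), inter)
  }
  root_set <- sets[[n + 1L]]
  changes <- changes + (bitwAnd(root_set, 1L) == 0L)
  if (!is.null(weights)) changes <- changes * weights
  if (per_site) changes else sum(changes)
}

# Attach a new leaf above node `at` of `tree`; the new leaf gets the given
# label. Returns a renumbered ctree.
attach_leaf <- function(tree, label, at) {
  m <- length(tree$parent)
  root <- tree$nleaf + 1L
  if (at == root) {
    # trunk insertion: the new internal node becomes the root
    parent_raw <- c(tree$parent, 0L, m + 1L)
  } else {
    parent_raw <- c(tree$parent, tree$parent[at], m + 1L)
  }
  parent_raw[at] <- m + 1L
  # raw root id stays tree's root; renumber needs raw leaf ids in label order
  new_labels <- c(tree$labels, label)
  leaves_raw <- c(seq_len(tree$nleaf), m + 2L)
  ct_renumber(parent_raw, leaves_raw, new_labels)
}

# All rooted NNI neighbours of a tree.
nni_neighbours <- function(tree) {
  n <- tree$nleaf
  root <- n + 1L
  ch <- ct_children(tree)
  out <- list()
  for (v in seq_along(tree$parent)) {
    if (v <= n || v == root) next  # internal non-root nodes only
    u <- tree$parent[v]
    c_other <- setdiff(ch[[u]], v)
    for (a in ch[[v]]) {
      p <- tree$parent
      p[c_other] <- v
      p[a] <- u
      out[[length(out) + 1L]] <- new_ctree(p, tree$labels)
    }
  }
  out
}

#' Maximum parsimony tree search
#'
#' Exhaustive mode enumerates all rooted resolved topologies (up to 8 leaves)
#' and returns the minimal-score set; heuristic mode uses seeded random-order
#' stepwise addition followed by nearest-neighbour-interchange hill climbing,
#' with restarts. Ties are broken by the lexicographically smallest canonical
#' Newick string.
#'
#' @param genotypes Integer genotype matrix (variants x samples).
#' @param mode "heuristic" or "exhaustive".
#' @param seed Integer seed (heuristic mode).
#' @param restarts Number of stepwise-addition restarts (heuristic).
#' @return list(tree, score, n_optimal, optimal) where `optimal` holds the
#'   canonical strings of the co-optimal trees found.
#' @export
search_mp_tree <- function(genotypes, mode = c("heuristic", "exhaustive"),
                           seed = 1L, restarts = 3L) {
  mode <- match.arg(mode)
  labels <- colnames(genotypes)
  if (length(labels) < 3L) stop("search_mp_tree: need >= 3 samples")
  cp <- compress_patterns(genotypes)
  score_of <- function(t) {
    fitch_score(t, cp$patterns[, t$labels, drop = FALSE], cp$weights)
  }

  if (mode == "exhaustive") {
    if (length(labels) > 8L) {
      stop("search_mp_tree: exhaustive mode supports up to 8 leaves")
    }
    trees <- all_topologies(labels)
    scores <- vapply(trees, score_of, 0L)
    best <- min(scores)
    opt <- trees[scores == best]
    canon <- vapply(opt, ct_canonical, "")
    o <- order(canon)
    return(list(tree = opt[[o[1]]], score = best,
                n_optimal = length(opt), optimal = sort(canon)))
  }

  set.seed(seed)
  best_score <- Inf
  best_trees <- list()
  for (r in seq_len(restarts)) {
    ord <- sample(labels)
    # stepwise addition from the 2-leaf tree (root is node 3)
    t <- new_ctree(c(3L, 3L, 0L), ord[1:2])
    for (lab in ord[-(1:2)]) {
      # every edge is a candidate, including the trunk above the root
      cand_nodes <- seq_along(t$parent)
      cands <- lapply(cand_nodes, function(v) attach_leaf(t, lab, v))
      sc <- vapply(cands, score_of, 0L)
      t <- cands[[which.min(sc)]]
    }
    # NNI hill climbing
    s <- score_of(t)
    repeat {
      nb <- nni_neighbours(t)
      sc <- vapply(nb, score_of, 0L)
      if (min(sc) < s) {
        s <- min(sc)
        t <- nb[[which.min(sc)]]
      } else break
    }
    if (s < best_score) {
      best_score <- s
      best_trees <- list(t)
    } else if (s == best_score) {
      best_trees <- c(best_trees, list(t))
      # keep co-optimal NNI-equal neighbours too
    }
    if (s == best_score) {
      nb <- nni_neighbours(t)
      sc <- vapply(nb, score_of, 0L)
      best_trees <- c(best_trees, nb[sc == best_score])
    }
  }
  canon <- vapply(best_trees, ct_canonical, "")
  keep <- !duplicated(canon)
  best_trees <- best_trees[keep]
  canon <- canon[keep]
  o <- order(canon)
  list(tree = best_trees[[o[1]]], score = as.integer(best_score),
       n_optimal = length(best_trees), optimal = sort(canon))
}

#' Bootstrap clade supports
#'
#' `n` replicates resample variants (genotype rows, ambiguity retained) with
#' replacement; each replicate is re-searched heuristically and supports are
#' the percentage of replicate trees containing each internal clade of the
#' chosen tree.
#'
#' @param genotypes Integer genotype matrix.
#' @param tree The chosen tree (a `ctree`).
#' @param n Number of replicates (default 1000).
#' @param seed Integer seed.
#' @param restarts Stepwise restarts per replicate.
#' @return Named numeric vector: support in [0, 100] per internal non-root
#'   node of `tree` (names are node ids); NULL if n = 0.
#' @export
bootstrap_support <- function(genotypes, tree, n = 1000L, seed = 1L,
                              restarts = 1L) {
  if (n <= 0L) return(NULL)
  set.seed(seed)
  nleaf <- tree$nleaf
  internal <- setdiff(seq(nleaf + 2L, length.out = max(0L, nleaf - 2L)),
                      integer(0))
  clades <- ct_clades(tree)
  hits <- stats::setNames(numeric(length(clades)), names(clades))
  names(hits) <- internal
  V <- nrow(genotypes)
  for (b in seq_len(n)) {
    idx <- sample.int(V, V, replace = TRUE)
    rep_seed <- sample.int(.Machine$integer.max, 1L)
    res <- search_mp_tree(genotypes[idx, , drop = FALSE], mode = "heuristic",
                          seed = rep_seed, restarts = restarts)
    rep_clades <- ct_clades(res$tree)
    hits <- hits + as.numeric(clades %in% rep_clades)
  }
  100 * hits / n
}

#' Maximum-likelihood placement of variants on branches
#'
#' For each variant and candidate branch, the log-likelihood sums
#' binomial(alt | depth, clonal_vaf) over crypts descending from the branch
#' and binomial(alt | depth, err) over the rest. Candidates are every branch,
#' the root (a trunk shared by all crypts) and an artifact category (err in
#' all crypts), which prevents contradictory variants from being forced onto
#' the tree. The posterior is the likelihood normalized under a uniform
#' branch prior.
#'
#' @param tree A `ctree` whose leaves match the matrix samples.
#' @param matrix A `count_matrix` of somatic variants.
#' @param clonal_vaf Expected carrier VAF (default 0.5).
#' @param err Expected non-carrier alt read fraction (default 0.001).
#' @return list(assignment = data.frame(id, branch, loglik, posterior),
#'   branch_lengths = named count vector per branch incl. "root" and
#'   "artifact").
#' @export
assign_variants_ml <- function(tree, matrix, clonal_vaf = 0.5, err = 0.001) {
  stopifnot(setequal(tree$labels, matrix$samples$id))
  alt <- matrix$alt[, tree$labels, drop = FALSE]
  depth <- matrix$depth[, tree$labels, drop = FALSE]
  V <- nrow(alt)
  l1 <- stats::dbinom(alt, depth, clonal_vaf, log = TRUE)
  l0 <- stats::dbinom(alt, depth, err, log = TRUE)
  d <- l1 - l0
  tot0 <- rowSums(l0)
  root <- tree$nleaf + 1L
  leafsets <- ct_leafsets(tree)
  cand <- c(seq_along(tree$parent)[-root], root)  # branches then root-trunk
  ll <- matrix(NA_real_, V, length(cand) + 1L,
               dimnames = list(rownames(alt), c(cand, "artifact")))
  for (j in seq_along(cand)) {
    ll[, j] <- tot0 + rowSums(d[, leafsets[[cand[j]]], drop = FALSE])
  }
  ll[, length(cand) + 1L] <- tot0

  nodepth <- rowSums(depth) == 0
  which_best <- max.col(ll, ties.method = "first")
  best_name <- colnames(ll)[which_best]
  post <- exp(ll - apply(ll, 1, max))
  post <- post / rowSums(post)
  posterior <- post[cbind(seq_len(V), which_best)]
  branch <- ifelse(best_name == "artifact", NA_character_,
                   ifelse(best_name == as.character(root), "root", best_name))
  branch[nodepth] <- NA_character_
  posterior[nodepth] <- NA_real_
  assignment <- data.frame(id = rownames(alt), branch = branch,
                           loglik = ll[cbind(seq_len(V), which_best)],
                           posterior = posterior,
                           stringsAsFactors = FALSE)
  lev <- c(as.character(cand[-length(cand)]), "root", "artifact")
  bl <- table(factor(ifelse(is.na(branch), "artifact", branch), levels = lev))
  list(assignment = assignment,
       branch_lengths = stats::setNames(as.integer(bl), lev))
}

#' Assign indels to the SBS-built tree
#'
#' Identical likelihood machinery as [assign_variants_ml()], run on the indel
#' count matrix against the fixed tree built from SBS genotypes (normal crypts
#' carry too few indels to support their own tree).
#'
#' @inheritParams assign_variants_ml
#' @param indel_matrix `count_matrix` of somatic indels (same samples).
#' @export
assign_indels_to_sbs_tree <- function(tree, indel_matrix, clonal_vaf = 0.5,
                                      err = 0.001) {
  if (nrow(indel_matrix$alt) == 0L) {
    return(list(assignment = data.frame(id = character(0), branch = character(0),
                                        loglik = numeric(0), posterior = numeric(0)),
                branch_lengths = NULL))
  }
  assign_variants_ml(tree, indel_matrix, clonal_vaf = clonal_vaf, err = err)
}
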