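# Rooted binary trees over crypt samples. Nodes are numbered in the ape
# convention: leaves 1..n, root n+1, internal nodes n+2..2n-1. A tree is a
# parent vector (0 at the root); the "branch" above node v is identified by v,
# so a tree with n leaves has 2n-2 branches.

#' Construct a rooted binary crypt tree
#'
#' @param parent Integer vector of length 2n-1; `parent[v]` is the parent node
#'   of `v`, 0 for the root (node n+1).
#' @param labels Character vector of n leaf labels (nodes 1..n).
#' @param frac Optional numeric vector of branch time-fractions per node
#'   (NA at the root).
#' @return An object of class `ctree`.
#' @export
new_ctree <- function(parent, labels, frac = NULL) {
  n <- length(labels)
  stopifnot(length(parent) == 2L * n - 1L, n >= 2L)
  root <- n + 1L
  if (parent[root] != 0L || any(parent[-root] < 1L)) {
    stop("new_ctree: root must be node n+1 with parent 0")
  }
  nd <- tabulate(parent[-root], nbins = 2L * n - 1L)
  if (any(nd[seq_len(n)] != 0L) || any(nd[(n + 1L):(2L * n - 1L)] != 2L)) {
    stop("new_ctree: tree must be binary with leaves 1..n")
  }
  t <- list(parent = as.integer(parent), nleaf = n, labels = labels,
            frac = frac)
  class(t) <- "ctree"
  t
}

#' @export
print.ctree <- function(x, ...) {
  cat("Rooted binary tree:", x$nleaf, "leaves (",
      paste(utils::head(x$labels, 5), collapse = ", "),
      if (x$nleaf > 5) "..." else "", ")\n")
  invisible(x)
}

ct_children <- function(tree) {
  ch <- vector("list", length(tree$parent))
  for (v in seq_along(tree$parent)) {
    p <- tree$parent[v]
    if (p > 0L) ch[[p]] <- c(ch[[p]], v)
  }
  ch
}

# Children-before-parent ordering of all nodes.
ct_postorder <- function(tree) {
  nn <- length(tree$parent)
  root <- tree$nleaf + 1L
  ch <- ct_children(tree)
  out <- integer(nn)
  k <- 0L
  stack <- c(root)
  visit <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    visit <- c(visit, v)
    stack <- c(stack, ch[[v]])
  }
  rev(visit)  # preorder reversed = valid postorder for this traversal
}

#' Leaf index sets per node
#'
#' @param tree A `ctree`.
#' @return List over all nodes; element v holds the leaf indices (1..nleaf,
#'   positions in `tree$labels`) under node v.
#' @export
ct_leafsets <- function(tree) {
  n <- tree$nleaf
  sets <- vector("list", length(tree$parent))
  for (v in seq_len(n)) sets[[v]] <- v
  for (v in ct_postorder(tree)) {
    if (v > n) {
      kids <- which(tree$parent == v)
      sets[[v]] <- sort(unlist(sets[kids]))
    }
  }
  sets
}

# Clade keys (comma-joined sorted leaf labels) for internal non-root nodes.
ct_clades <- function(tree) {
  n <- tree$nleaf
  sets <- ct_leafsets(tree)
  internal <- setdiff((n + 2L):(2L * n - 1L), integer(0))
  if (n == 2L) return(character(0))
  vapply(internal, function(v) {
    paste(sort(tree$labels[sets[[v]]]), collapse = ",")
  }, "")
}

#' Newick serialization of a crypt tree
#'
#' @param tree A `ctree`.
#' @param lengths Optional branch lengths per node (edge above the node).
#' @param node_labels Optional labels for internal nodes (e.g. bootstrap
#'   supports).
#' @return Newick string with trailing semicolon.
#' @export
ct_newick <- function(tree, lengths = NULL, node_labels = NULL) {
  ch <- ct_children(tree)
  rec <- function(v) {
    if (v <= tree$nleaf) {
      s <- tree$labels[v]
    } else {
      s <- paste0("(", paste(vapply(ch[[v]], rec, ""), collapse = ","), ")")
      if (!is.null(node_labels) && !is.na(node_labels[v])) {
        s <- paste0(s, node_labels[v])
      }
    }
    if (!is.null(lengths) && !is.na(lengths[v])) {
      s <- paste0(s, ":", format(lengths[v], digits = 12))
    }
    s
  }
  paste0(rec(tree$nleaf + 1L), ";")
}

# Canonical topology string: children sorted recursively by their own string.
# Used as the deterministic tie-break among equally parsimonious trees.
ct_canonical <- function(tree) {
  ch <- ct_children(tree)
  rec <- function(v) {
    if (v <= tree$nleaf) return(tree$labels[v])
    kids <- sort(vapply(ch[[v]], rec, ""))
    paste0("(", paste(kids, collapse = ","), ")")
  }
  paste0(rec(tree$nleaf + 1L), ";")
}

#' Convert to an ape "phylo" object
#'
#' @param tree A `ctree`.
#' @param lengths Optional branch lengths per node.
#' @return An [ape::as.phylo] compatible `phylo` object.
#' @export
ct_to_phylo <- function(tree, lengths = NULL) {
  n <- tree$nleaf
  nonroot <- setdiff(seq_along(tree$parent), n + 1L)
  edge <- cbind(tree$parent[nonroot], nonroot)
  ph <- list(edge = edge, tip.label = tree$labels, Nnode = n - 1L)
  if (!is.null(lengths)) ph$edge.length <- lengths[nonroot]
  class(ph) <- "phylo"
  ape::reorder.phylo(ph, "cladewise")
}

# Renumber an arbitrary parent map (temporary ids) into canonical numbering.
# `leaves` gives the temporary ids of the leaves in label order.
ct_renumber <- function(parent_raw, leaves, labels) {
  ids <- seq_along(parent_raw)
  root_raw <- ids[parent_raw == 0L]
  n <- length(leaves)
  internal_raw <- setdiff(ids, c(leaves, root_raw))
  map <- integer(length(parent_raw))
  map[leaves] <- seq_len(n)
  map[root_raw] <- n + 1L
  map[internal_raw] <- n + 1L + seq_along(internal_raw)
  parent <- integer(2L * n - 1L)
  for (v in ids) {
    parent[map[v]] <- if (parent_raw[v] == 0L) 0L else map[parent_raw[v]]
  }
  new_ctree(parent, labels)
}

#' Random resolved rooted topology
#'
#' Sequential leaf attachment using the current RNG state; every resolved
#' rooted shape is reachable. No branch fractions are set.
#'
#' @param labels Leaf labels (>= 2).
#' @return A `ctree`.
#' @export
random_topology <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 2L)
  # temporary ids: grow arrays
  parent_raw <- c(0L, 1L, 1L)  # root=1, leaves 2,3
  leaves <- c(2L, 3L)
  for (i in seq_len(n - 2L)) {
    v <- sample.int(length(parent_raw), 1L)  # any edge, incl. the trunk
    u <- length(parent_raw) + 1L          # new internal node splits edge above v
    w <- length(parent_raw) + 2L          # new leaf
    parent_raw <- c(parent_raw,
                    if (parent_raw[v] == 0L) 0L else parent_raw[v], u)
    parent_raw[v] <- u
    leaves <- c(leaves, w)
  }
  ct_renumber(parent_raw, leaves, labels)
}

#' All rooted resolved topologies
#'
#' Recursive leaf addition to every branch; there are (2n-3)!! rooted resolved
#' topologies, so enumeration is capped at 8 leaves.
#'
#' @param labels Leaf labels (2 to 8).
#' @return List of `ctree` objects.
#' @export
all_topologies <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 2L, n <= 8L)
  grow <- function(tlist, k) {
    if (k > n) return(tlist)
    out <- list()
    for (t in tlist) {
      m <- length(t$parent)  # raw representation: list(parent, leaves)
      for (v in seq_len(m)) {
        # insert on the edge above v; v may be the root (trunk insertion,
        # in which case the new internal node becomes the root)
        pr <- c(t$parent, if (t$parent[v] == 0L) 0L else t$parent[v], m + 1L)
        pr[v] <- m + 1L
        out[[length(out) + 1L]] <- list(parent = pr, leaves = c(t$leaves, m + 2L))
      }
    }
    grow(out, k + 1L)
  }
  raw <- grow(list(list(parent = c(0L, 1L, 1L), leaves = c(2L, 3L))), 3L)
  lapply(raw, function(t) ct_renumber(t$parent, t$leaves, labels))
}

#' Robinson-Foulds distance between rooted trees
#'
#' Symmetric difference of the internal (non-root) clade sets of two rooted
#' trees over the same leaves.
#'
#' @param t1,t2 `ctree` objects on identical leaf labels.
#' @return Non-negative integer; 0 iff the topologies agree.
#' @export
rf_distance <- function(t1, t2) {
  c1 <- ct_clades(t1)
  c2 <- ct_clades(t2)
  length(setdiff(c1, c2)) + length(setdiff(c2, c1))
}
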