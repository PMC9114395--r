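#!/usr/bin/env Rscript

# Build the maximum-parsimony crypt tree from somatic SBS genotypes, bootstrap
# its clades, and place SBS and indel variants on branches by maximum
# likelihood. Writes the annotated Newick tree (bootstrap supports as internal
# node labels, branch lengths = assigned SBS counts), the per-variant
# assignments and the per-branch variant lists.
#
# Usage: Rscript analysis/03_build_tree.R [--matrix results/cohort]
#          [--filtered results/filtered_variants.tsv] [--bootstrap 100]
#          [--seed 7] [--outdir results/tree]

suppressPackageStartupMessages(library(cryptphylo))

args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i)) default else args[i + 1L]
}
matrix_dir <- arg_val("--matrix", "results/cohort")
filtered <- arg_val("--filtered", "results/filtered_variants.tsv")
n_boot <- as.integer(arg_val("--bootstrap", "100"))
seed <- as.integer(arg_val("--seed", "7"))
outdir <- arg_val("--outdir", "results/tree")

cm <- read_count_matrix(matrix_dir)
flt <- utils::read.delim(filtered, stringsAsFactors = FALSE)
som <- cm_subset(cm, flt$id[flt$status == "somatic"])
sbs_ids <- som$variants$id[som$variants$kind == "SBS"]
id_ids <- setdiff(som$variants$id, sbs_ids)

g <- code_genotypes(cm_subset(som, sbs_ids))
mp <- search_mp_tree(g, mode = "heuristic", seed = seed, restarts = 3)
cat("parsimony score:", mp$score, "| co-optimal trees:", mp$n_optimal, "\n")

supports <- bootstrap_support(g, mp$tree, n = n_boot, seed = seed)
asg_sbs <- assign_variants_ml(mp$tree, cm_subset(som, sbs_ids))
asg_id <- assign_indels_to_sbs_tree(mp$tree, cm_subset(som, id_ids))

dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

node_labels <- rep(NA_character_, length(mp$tree$parent))
if (!is.null(supports)) {
  node_labels[as.integer(names(supports))] <- sprintf("%.0f", supports)
}
lengths <- numeric(length(mp$tree$parent))
bl <- asg_sbs$branch_lengths
branch_nodes <- setdiff(names(bl), c("root", "artifact"))
lengths[as.integer(branch_nodes)] <- bl[branch_nodes]
writeLines(ct_newick(mp$tree, lengths = lengths, node_labels = node_labels),
           file.path(outdir, "tree.nwk"))
# exact node numbering (the Newick round trip does not preserve it); branch
# ids in assignments.tsv refer to these node ids
utils::write.table(
  data.frame(node = seq_along(mp$tree$parent), parent = mp$tree$parent,
             label = c(mp$tree$labels,
                       rep(NA, length(mp$tree$parent) - mp$tree$nleaf))),
  file.path(outdir, "tree_nodes.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

assignments <- rbind(
  cbind(asg_sbs$assignment, kind = "SBS"),
  cbind(asg_id$assignment, kind = "ID")
)
utils::write.table(assignments, file.path(outdir, "assignments.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

branch_lists <- assignments[!is.na(assignments$branch),
                            c("branch", "id", "kind")]
branch_lists <- branch_lists[order(branch_lists$branch, branch_lists$id), ]
utils::write.table(branch_lists, file.path(outdir, "branch_variants.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", outdir, "\n")
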