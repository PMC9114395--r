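#!/usr/bin/env Rscript

# Per-crypt mutation burdens from branch assignments, tissue median rates,
# cohort comparison (when two cohorts are present), tumour/normal fold (when
# tumour crypts are present) and driver annotation (when gene lists are
# supplied). Writes the burden table and a JSON summary report.
#
# Usage: Rscript analysis/05_burden.R [--matrix results/cohort]
#          [--tree results/tree] [--assignments results/tree/assignments.tsv]
#          [--out results/burden_table.tsv] [--report results/burden_report.json]
#          [--drivers drivers.tsv] [--known known.txt] [--tsg tsg.txt]
#          [--hotspots hotspots.txt]

suppressPackageStartupMessages(library(cryptphylo))

args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i)) default else args[i + 1L]
}
matrix_dir <- arg_val("--matrix", "results/cohort")
tree_dir <- arg_val("--tree", "results/tree")
assignments_path <- arg_val("--assignments",
                            file.path(tree_dir, "assignments.tsv"))
out <- arg_val("--out", "results/burden_table.tsv")
report_path <- arg_val("--report", "results/burden_report.json")
drivers_path <- arg_val("--drivers", NA)

cm <- read_count_matrix(matrix_dir)
nodes <- utils::read.delim(file.path(tree_dir, "tree_nodes.tsv"),
                           stringsAsFactors = FALSE)
tree <- new_ctree(as.integer(nodes$parent[order(nodes$node)]),
                  nodes$label[!is.na(nodes$label)])
asg <- utils::read.delim(assignments_path, stringsAsFactors = FALSE)
asg$branch <- as.character(asg$branch)
split_asg <- function(kind) list(assignment = asg[asg$kind == kind, ])
bt <- burden_table(tree, cm$samples, split_asg("SBS"), split_asg("ID"))

dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
utils::write.table(bt, out, sep = "\t", quote = FALSE, row.names = FALSE)

report <- list(n_crypts = nrow(bt),
               median_rates = tissue_median_rates(bt))
if (any(bt$crypt_type == "tumour")) {
  report$tumour_normal_fold <- fold_difference(bt, group_a = "tumour",
                                               group_b = "survey")
}
if (length(unique(bt$cohort)) >= 2) {
  lrt <- suppressMessages(lmm_lrt(bt))
  report$cohort_lrt <- list(statistic = lrt$statistic, p_value = lrt$p_value)
}
if (!is.na(drivers_path)) {
  read_list <- function(flag) {
    p <- arg_val(flag, NA)
    if (is.na(p)) character(0) else readLines(p)
  }
  dv <- utils::read.delim(drivers_path, stringsAsFactors = FALSE)
  calls <- flag_drivers(dv, known_list = read_list("--known"),
                        tsg_list = read_list("--tsg"),
                        hotspot_list = read_list("--hotspots"))
  report$drivers <- driver_summary(calls, n_crypts_total = nrow(bt))
}

jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                     pretty = TRUE)
cat("wrote", out, "and", report_path, "\n")
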