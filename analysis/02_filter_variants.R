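#!/usr/bin/env Rscript

# Run the quality / germline / overdispersion filter stack over a cohort
# bundle and write the per-variant status table.
#
# Usage: Rscript analysis/02_filter_variants.R [--matrix results/cohort]
#          [--alpha 1e-5] [--rho-sbs 0.1] [--rho-indel 0.2]
#          [--out results/filtered_variants.tsv]

suppressPackageStartupMessages(library(cryptphylo))

args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i)) default else args[i + 1L]
}
matrix_dir <- arg_val("--matrix", "results/cohort")
alpha <- as.numeric(arg_val("--alpha", "1e-5"))
rho_sbs <- as.numeric(arg_val("--rho-sbs", "0.1"))
rho_indel <- as.numeric(arg_val("--rho-indel", "0.2"))
out <- arg_val("--out", "results/filtered_variants.tsv")

cm <- read_count_matrix(matrix_dir)
flt <- filter_variants(cm, alpha = alpha,
                       rho_thresholds = c(SBS = rho_sbs, indel = rho_indel))

dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
utils::write.table(flt, out, sep = "\t", quote = FALSE, row.names = FALSE)
cat("status counts:\n")
print(table(flt$status))
cat("wrote", out, "\n")
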