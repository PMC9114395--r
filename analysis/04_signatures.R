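#!/usr/bin/env Rscript

# Per-branch mutational spectra, de novo signature extraction (HDP or NMF
# backend), deconvolution against a reference catalogue with residual
# handling, and exposure refitting.
#
# Usage: Rscript analysis/04_signatures.R [--matrix results/cohort]
#          [--tree results/tree] [--backend hdp|nmf]
#          [--catalogue results/cohort/sbs_catalogue.tsv] [--seed 7]
#          [--outdir results/signatures]

suppressPackageStartupMessages(library(cryptphylo))

args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i)) default else args[i + 1L]
}
matrix_dir <- arg_val("--matrix", "results/cohort")
tree_dir <- arg_val("--tree", "results/tree")
backend <- arg_val("--backend", "hdp")
catalogue_path <- arg_val("--catalogue", "results/cohort/sbs_catalogue.tsv")
seed <- as.integer(arg_val("--seed", "7"))
outdir <- arg_val("--outdir", "results/signatures")
stopifnot(backend %in% c("hdp", "nmf"))

cm <- read_count_matrix(matrix_dir)
asg <- utils::read.delim(file.path(tree_dir, "assignments.tsv"),
                         stringsAsFactors = FALSE)
asg <- asg[asg$kind == "SBS" & !is.na(asg$branch), ]
v <- cm$variants[match(asg$id, cm$variants$id), ]
channel <- sbs_channel(v$ref, v$alt, v$context)
patient <- rep(cm$samples$patient[1], nrow(asg))

sp <- branch_spectra(channel, asg$branch, sbs96_labels(), seed = seed,
                     patient = patient)
if (length(sp$excluded)) {
  cat("branches below the spectrum floor:",
      paste(sp$excluded, collapse = ", "), "\n")
}

if (backend == "hdp") {
  ext <- hdp_extract(sp$counts, sp$patient, seed = seed)
} else {
  ext <- nmf_extract(sp$counts, k_range = 1:5, restarts = 10, seed = seed)
}
cat("backend:", backend, "| components:", ncol(ext$components), "\n")

catalogue <- read_signature_catalogue(catalogue_path, labels = sbs96_labels())
dec <- deconvolute_components(ext$components, catalogue, sp$counts,
                              component_exposures = ext$exposures)

dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
utils::write.table(
  data.frame(Type = rownames(sp$counts), sp$counts, check.names = FALSE),
  file.path(outdir, "branch_spectra.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(Type = sbs96_labels(), ext$components, check.names = FALSE),
  file.path(outdir, "components.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(Type = sbs96_labels(), dec$signatures, check.names = FALSE),
  file.path(outdir, "signatures.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(branch = rownames(dec$exposures$fractions),
             dec$exposures$fractions, check.names = FALSE),
  file.path(outdir, "exposures.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
cat("final signatures:", paste(colnames(dec$signatures), collapse = ", "), "\n")
cat("wrote", outdir, "\n")
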