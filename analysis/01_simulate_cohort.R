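#!/usr/bin/env Rscript

# Simulate a crypt cohort with ground truth and write it as a results bundle.
#
# Usage: Rscript analysis/01_simulate_cohort.R [--config cohort.json]
#          [--seed N] [--outdir results/cohort]
#
# The optional config file (JSON) may override any sim_config() argument;
# signature activities are given as named objects.

suppressPackageStartupMessages(library(cryptphylo))

args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i)) default else args[i + 1L]
}
seed <- as.integer(arg_val("--seed", "1"))
outdir <- arg_val("--outdir", "results/cohort")
config_path <- arg_val("--config", NA)

overrides <- list()
if (!is.na(config_path)) {
  overrides <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  for (nm in c("signature_activities", "id_signature_activities")) {
    if (!is.null(overrides[[nm]])) overrides[[nm]] <- unlist(overrides[[nm]])
  }
}
defaults <- list(n_crypts = 8, seed = seed,
                 signature_activities = c(SIG1 = 6, SIG2 = 3, SIG3 = 1),
                 id_signature_activities = c(IDSIG1 = 0.3, IDSIG2 = 0.1))
cfg <- do.call(sim_config, utils::modifyList(defaults, overrides))

cat_sbs <- synthetic_signatures(sbs96_labels(), 3, seed = 42)
cat_id <- synthetic_signatures(id83_labels(), 2, seed = 43, prefix = "IDSIG")
cohort <- simulate_cohort(cfg, cat_sbs, cat_id, seed = seed)
write_cohort(cohort, outdir)
write_signature_catalogue(cat_sbs, file.path(outdir, "sbs_catalogue.tsv"))
write_signature_catalogue(cat_id, file.path(outdir, "id_catalogue.tsv"))

cat("cohort:", nrow(cohort$matrix$alt), "variants x",
    ncol(cohort$matrix$alt), "crypts ->", outdir, "\n")
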