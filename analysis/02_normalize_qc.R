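#!/usr/bin/env Rscript
# Ortholog-restricted TPM normalization, square-root transform and
# sample-correlation QC, reading the files written by 01_simulate.R.
# Finding to verify: the dominant correlation split is non-pregnant vs
# pregnant, with mid- and late-gestation samples remaining highly similar.

library(cervcomp)

dat <- "results/data"
out <- "results"
design <- read_design(file.path(dat, "design.tsv"))
species <- unique(as.character(design$species))
orthomap <- read_ortholog_map(file.path(dat, "orthologs.tsv"), species)

for (sp in species) {
  cm <- read_count_table(file.path(dat, paste0("counts_", sp, ".tsv")),
                         file.path(dat, paste0("lengths_", sp, ".tsv")), sp)
  subset <- orthomap[[sp]][!is.na(orthomap[[sp]])]
  tpm <- compute_tpm(cm, gene_subset = subset)
  stopifnot(max(abs(colSums(tpm$values) - 1e6)) / 1e6 < 1e-9)
  sq <- sqrt_transform(tpm)
  corr <- sample_correlation(sq)
  flagged <- flag_poor_samples(corr, design[design$species == sp, ],
                               min_mean_r = 0.5)
  write_table(data.frame(sample = colnames(corr), round(corr, 4)),
              file.path(out, paste0("correlation_", sp, ".tsv")))

  st <- setNames(as.character(design$stage), design$sample)[colnames(corr)]
  offdiag <- function(a, b) {
    m <- corr[st == a, st == b, drop = FALSE]
    mean(m[m < 1])
  }
  cat(sprintf("%-11s NP-vs-pregnant r = %.3f | MG-vs-LG r = %.3f | flagged: %s\n",
              sp, mean(c(offdiag("NP", "MG"), offdiag("NP", "LG"))),
              offdiag("MG", "LG"),
              if (length(flagged)) paste(flagged, collapse = ",") else "none"))
}
cat("Correlation matrices written under", out, "\n")
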