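#!/usr/bin/env Rscript
# Within-species stage testing: one-way ANOVA over NP/MG/LG on sqrt-TPM,
# late-over-mid fold changes and direction calls on the TPM scale, no
# multiple-testing correction. Finding to verify: planted |log2FC| = 2
# effects are recalled with the correct direction in >= 80% of cases.

library(cervcomp)

bundle <- default_study_fixture(seed = 1)
design <- bundle$design
out <- "results"

de <- list()
for (sp in names(bundle$counts)) {
  subset <- bundle$orthomap[[sp]][!is.na(bundle$orthomap[[sp]])]
  tpm <- compute_tpm(bundle$counts[[sp]], gene_subset = subset)
  de[[sp]] <- de_table(tpm, design, test = "anova")
  write_table(de[[sp]], file.path(out, paste0("de_", sp, ".tsv")))
  cat(sprintf("%-11s %4d UP / %4d DOWN of %d orthologous genes\n", sp,
              sum(de[[sp]]$direction == "UP"),
              sum(de[[sp]]$direction == "DOWN"), nrow(de[[sp]])))
}

truth <- bundle$truth
planted <- truth[abs(truth$log2fc) == 2 &
                   truth$class %in% c("clade_down", "power_up", "power_down",
                                      "species_specific_up"), ]
de_all <- do.call(rbind, de)
dir <- de_all$direction[match(paste(planted$species, planted$gene),
                              paste(de_all$species, de_all$gene))]
want <- ifelse(planted$log2fc > 0, "UP", "DOWN")
cat(sprintf("Planted |log2FC|=2 direction recall: %.1f%% (%d effects)\n",
            100 * mean(dir == want), nrow(planted)))

gp <- de$guinea_pig
i <- match("guinea_pig_OG00002", gp$gene)
cat(sprintf("Receptor analogue (guinea pig): LG/MG fold change %.2f, ANOVA p %.2g -> %s\n",
            gp$fold_change[i], gp$p_value[i], gp$direction[i]))
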