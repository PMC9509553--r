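#!/usr/bin/env Rscript
# Stage 4: permutation Z-summary preservation of the baseline modules in the
# week-2 and week-6 networks of each outcome group, the differential
# preservation contrast, and the kME-shift ranking of genes losing module
# membership in remitters.

suppressPackageStartupMessages(library(tnfomics))

expr <- normalize_counts(read_counts("results/cohort/counts.tsv"))
design <- read_design("results/cohort/design.tsv")
mod_tab <- read.delim("results/network/modules.tsv")
dir.create("results/preservation", showWarnings = FALSE, recursive = TRUE)

x <- log2(expr$normalized + 1)
base_ids <- design$sample_id[design$assay == "rna" & design$timepoint == "baseline"]
genes <- mod_tab$gene_id
xb <- x[genes, base_ids]
modules <- module_eigengenes_and_kme(xb, setNames(mod_tab$module, mod_tab$gene_id))
modules$power <- 16L

rows <- list()
for (grp in c("remission", "non_remission")) for (tp in c("2w", "6w")) {
  smp <- design$sample_id[design$assay == "rna" & design$group == grp &
                            design$timepoint == tp]
  tab <- preservation_zsummary(modules, xb, x[genes, smp],
                               n_permutations = 100,
                               seed = 100 + nchar(grp) + nchar(tp))
  tab$condition <- grp; tab$timepoint <- tp
  rows[[paste(grp, tp)]] <- tab
}
pres <- do.call(rbind, rows)
rownames(pres) <- NULL
write.table(pres, "results/preservation/zsummary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ctr <- contrast_preservation(pres[pres$condition == "remission", ],
                             pres[pres$condition == "non_remission", ])
write.table(ctr, "results/preservation/contrast.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
flagged <- unique(ctr$module[ctr$flagged])
cat(sprintf("Modules disrupted specifically in remitters at week 2/6: %s.\n",
            paste(flagged, collapse = ", ")))

tests <- lapply(setNames(c("remission", "non_remission"),
                         c("remission", "non_remission")), function(grp) {
  smp <- design$sample_id[design$assay == "rna" & design$group == grp &
                            design$timepoint %in% c("2w", "6w")]
  x[genes, smp]
})
ks <- kme_shift(modules, xb, tests)
write.table(ks, "results/preservation/kme_shift.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
top <- ks[ks$module %in% flagged & ks$rank_in_module <= 5, ]
cat(sprintf("Largest kME losses in flagged modules: %s.\n",
            paste(head(top$gene_id, 10), collapse = ", ")))
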