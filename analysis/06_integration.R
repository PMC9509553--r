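#!/usr/bin/env Rscript
# Stage 6: cis integration of remission DMPs with remission DEGs - candidate
# pairs within +-5 kb of the TSS, Spearman correlation over matched samples,
# permutation FDR, sign classification, and module over-representation of
# DNAm-linked genes.

suppressPackageStartupMessages(library(tnfomics))

expr <- normalize_counts(read_counts("results/cohort/counts.tsv"))
meth <- filter_probes(read_betas("results/cohort/betas.tsv",
                                 "results/cohort/probe_annotation.tsv"))
design <- read_design("results/cohort/design.tsv")
annotation <- read_tss("results/cohort/genes.bed")
degs <- read.delim("results/de/deg_set_remission.tsv")$gene_id
dir.create("results/integration", showWarnings = FALSE, recursive = TRUE)

sig_probes <- unique(c(
  with(read.delim("results/methylation/dmp_remission_2w.tsv"),
       probe_id[significant]),
  with(read.delim("results/methylation/dmp_remission_6w.tsv"),
       probe_id[significant])))
cat(sprintf("%d remission DMPs (weeks 2 and 6 combined) enter the cis scan.\n",
            length(sig_probes)))

ann_p <- meth$annotation[meth$annotation$probe_id %in% sig_probes,
                         c("probe_id", "chrom", "pos")]
pairs <- map_cis_pairs(ann_p, degs, annotation, window_bp = 5000)
pairs <- correlate_pairs(expr, meth, pairs, design)
pairs <- permutation_fdr(pairs, expr, meth, design, n_permutations = 100,
                         seed = 601)
write.table(pairs, "results/integration/cis_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

signs <- classify_signs(pairs)
write.table(signs$pairs, "results/integration/sign_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d of %d candidate DMP-DEG pairs significant; %.1f%% follow the canonical negative correlation.\n",
            sum(pairs$significant, na.rm = TRUE), nrow(pairs),
            100 * signs$pairs$frac_negative))

mod_tab <- read.delim("results/network/modules.tsv")
modules <- structure(list(membership = setNames(mod_tab$module, mod_tab$gene_id)),
                     class = "module_set")
linked <- unique(pairs$gene_id[pairs$significant & !is.na(pairs$significant)])
enr <- module_overrepresentation(linked, modules)
write.table(enr, "results/integration/module_overrepresentation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("DNAm-linked genes: %d; module over-representation written for %d modules.\n",
            length(linked), nrow(enr)))
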