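#!/usr/bin/env Rscript
# Trains a self-organizing expression map on the synthetic transcriptome and
# summarizes its meta-genes: operon coherence (relative Shannon diversity and
# start-codon distances against permutation), expression variability, and
# regulon composition per unit.

library(colonyevo)

dir.create("results", showWarnings = FALSE)
seed <- 1

tx <- gen_transcriptome(synthesis_config(seed = seed))
normalized <- normalize_log(tx$counts, size_factors(tx$counts))
z <- t(scale(t(normalized)))
z <- z[apply(normalized, 1, sd) > 0, ]

som <- train_som(z, grid = c(10, 10), epochs = 50, seed = seed)
write.table(data.frame(gene = names(som$assignment),
                       unit = som$assignment),
            "results/som_assignments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cbind(unit = rownames(som$codebook),
                  as.data.frame(som$codebook)),
            "results/som_codebooks.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("SOM: %d x %d hexagonal grid, %d epochs; quantization error %.2f -> %.2f\n",
            som$h, som$w, som$epochs, som$qe[1], som$qe[length(som$qe)]))

ann <- tx$truth$annotation
rownames(ann) <- ann$gene_id
coh <- operon_coherence(som, stats::setNames(ann$operon_id, ann$gene_id),
                        ann, n_perm = 200, seed = seed)
write.table(coh$unit_diversity, "results/som_operon_diversity.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("operon coherence: same-operon co-assignment %.3f vs %.3f expected (permutation p = %.3g)\n",
            coh$coassignment$observed, mean(coh$coassignment$perm),
            coh$coassignment$p))
cat(sprintf("median within-unit same-strand start distance %.0f bp observed vs %.0f bp expected\n",
            median(c(coh$distances$observed$`+`, coh$distances$observed$`-`)),
            median(c(coh$distances$expected$`+`, coh$distances$expected$`-`))))

ms <- metagene_summaries(som, normalized, pca_profiles(normalized),
                         regulons = tx$truth$regulons)
write.table(ms$units, "results/som_metagene_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("meta-genes: %d occupied units, %d genes mapped\n",
            nrow(ms$units), length(som$assignment)))
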