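#!/usr/bin/env Rscript
# Stage 2: QC-filter the pool, log-normalize, select one-vs-rest marker
# genes, merge them into the signature union and average per type into
# the reference gene expression profile (RGEP).

source("analysis/00_config.R")

pool <- read_pool(file.path(OUT, "pool"))
qc <- qc_filter_cells(pool$counts,
                      qc_thresholds(CFG$min_genes, CFG$max_genes,
                                    CFG$min_umis, CFG$max_umis))
cat(sprintf("QC: kept %d of %d cells\n", sum(qc$kept), length(qc$kept)))

labels <- pool$labels[qc$kept]
norm <- normalize_sc(qc$counts)
markers <- find_markers(norm, labels,
                        marker_criteria(CFG$logfc_threshold, CFG$min_pct,
                                        CFG$max_adj_p))
write.table(markers, file.path(OUT, "markers.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("markers: %d genes across %d types (median %d per type)\n",
            length(unique(markers$gene)), length(unique(markers$type)),
            round(median(table(markers$type)))))

sig <- merge_signature_sets(split(markers$gene, markers$type),
                            universe = rownames(qc$counts))
rgep <- build_rgep(qc$counts, labels, sig, scale = CFG$rgep_scale)
write_rgep(rgep, file.path(OUT, "rgep.tsv"))
cat(sprintf("RGEP: %d signature genes x %d cell types (%s scale)\n",
            length(sig), length(rgep$cell_types), rgep$scale))
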