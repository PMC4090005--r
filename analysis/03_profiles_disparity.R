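#!/usr/bin/env Rscript
# Step 3: gene-anchored profiles and the within-species disparity analysis in
# the reference species. Produces average TSS/TTS metagene traces (raw and
# H3-normalized), nucleosome-level expression correlations, the
# log2(H3K9ac/H3K4me3) disparity sectors and their class enrichments.

library(chromdiverge)

ind <- "results/data"
trd <- "results/tracks"
out <- "results/disparity"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cs <- read.delim(file.path(ind, "chrom_sizes.tsv"))
chrom_sizes <- setNames(cs$size, cs$chrom)
genes <- read_genes(file.path(ind, "genes_A.tsv"))
nucs <- read_table(file.path(ind, "nucleosomes_A.tsv"), "nucleosomes")
classes <- read_table(file.path(ind, "classes.tsv"), "classes")

tr <- function(key) read_bedgraph(file.path(trd, paste0(key, ".bedGraph")),
                                  chrom_sizes, sample = key)
ac <- tr("H3K9ac_A"); me <- tr("H3K4me3_A"); h3 <- tr("H3_A")

# metagene traces, raw and H3-normalized
mat_ac <- gene_profile_matrix(ac, genes, tss_window())
mat_me <- gene_profile_matrix(me, genes, tss_window())
h3_sm <- smooth_track(log2_track(h3), 140)
mat_h3 <- gene_profile_matrix(h3_sm, genes, tss_window())
prof <- data.frame(bin = as.integer(colnames(mat_ac)),
                   H3K9ac = average_profile(mat_ac),
                   H3K4me3 = average_profile(mat_me),
                   H3 = average_profile(mat_h3),
                   H3K9ac_h3norm = colMeans(
                     gene_profile_matrix(log2_track(ac), genes, tss_window()) -
                       mat_h3, na.rm = TRUE),
                   H3K4me3_h3norm = colMeans(
                     gene_profile_matrix(log2_track(me), genes, tss_window()) -
                       mat_h3, na.rm = TRUE))
write.table(prof, file.path(out, "profiles_tss.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("H3K9ac peaks %+d bp and H3K4me3 %+d bp from the TSS (H3-normalized: %+d / %+d)",
                prof$bin[which.max(prof$H3K9ac)],
                prof$bin[which.max(prof$H3K4me3)],
                prof$bin[which.max(prof$H3K9ac_h3norm)],
                prof$bin[which.max(prof$H3K4me3_h3norm)]))

# nucleosome-level correlation with expression
rna <- read.delim(file.path(ind, "rna_A.tsv"))
counts <- as.matrix(rna[, -1]); rownames(counts) <- rna$gene_id
expr <- quantify_expression(counts, setNames(genes$length, genes$gene_id))
y <- setNames(expr$value, expr$gene_id)
nuc_cor <- sapply(list(H3K9ac = ac, H3K4me3 = me), function(track) {
  lev <- nucleosome_levels(track, nucs)
  m <- matrix(NA_real_, nrow(genes), 8,
              dimnames = list(genes$gene_id, as.character(c(-2L, -1L, 1:6))))
  m[cbind(match(lev$gene_id, rownames(m)),
          match(as.character(lev$index), colnames(m)))] <- lev$value
  positional_correlation(m, y)
})
write.table(data.frame(index = rownames(nuc_cor), nuc_cor),
            file.path(out, "nucleosome_expression_correlation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("expression correlation peaks: H3K9ac at %s, H3K4me3 at %s",
                rownames(nuc_cor)[which.max(nuc_cor[, 1])],
                rownames(nuc_cor)[which.max(nuc_cor[, 2])]))

# disparity ranking, sectors and enrichment
ac_sig <- region_means(ac, genes, region_def("peak_ac"))
me_sig <- region_means(me, genes, region_def("peak_me"))
disp <- disparity_ratios(ac_sig, me_sig, genes)
sector_size <- min(1200L, floor(sum(!is.na(disp$ratio)) / 3))
disp <- assign_sectors(disp, sector_size)
enr <- sector_enrichment(disp, classes)
write.table(disp, file.path(out, "disparity.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

conc <- concordance_fraction(disp)
top <- enr[order(enr$p_value), ][1:4, ]
message(sprintf("%.0f%% of genes concordant within +/-0.5 of the median ratio",
                conc))
message(paste(sprintf("  %s %s in %s (fe %.0f%%, p = %.1e)", top$class_name,
                      top$direction, top$sector, top$fe, top$p_value),
              collapse = "\n"))
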