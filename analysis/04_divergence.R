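#!/usr/bin/env Rscript
# Step 4: interspecies divergence. Pairs region signals and expression at
# orthologs, draws exceedance and consistency curves, classifies co-changes
# of the two marks and expression, and contrasts how each mark's divergence
# couples to expression divergence.

library(chromdiverge)

ind <- "results/data"
trd <- "results/tracks"
out <- "results/divergence"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cs <- read.delim(file.path(ind, "chrom_sizes.tsv"))
chrom_sizes <- setNames(cs$size, cs$chrom)
genes <- list(A = read_genes(file.path(ind, "genes_A.tsv")),
              B = read_genes(file.path(ind, "genes_B.tsv")))
omap <- read_table(file.path(ind, "orthologs.tsv"), "orthologs")

tr <- function(key) read_bedgraph(file.path(trd, paste0(key, ".bedGraph")),
                                  chrom_sizes, sample = key)
sig <- function(mark, sp)
  region_means(tr(paste(mark, sp, sep = "_")), genes[[sp]],
               region_def(if (mark == "H3K9ac") "peak_ac" else "peak_me"))

p_ac <- paired_region_signals(sig("H3K9ac", "A"), sig("H3K9ac", "B"), omap)
p_me <- paired_region_signals(sig("H3K4me3", "A"), sig("H3K4me3", "B"), omap)

expr <- lapply(c(A = "A", B = "B"), function(sp) {
  rna <- read.delim(file.path(ind, sprintf("rna_%s.tsv", sp)))
  counts <- as.matrix(rna[, -1]); rownames(counts) <- rna$gene_id
  e <- quantify_expression(counts, setNames(genes[[sp]]$length,
                                            genes[[sp]]$gene_id))
  data.frame(gene_id = e$gene_id, value = e$value, valid = TRUE)
})
p_expr <- paired_region_signals(expr$A, expr$B, omap)

common <- Reduce(intersect, list(p_ac$gene_id_a, p_me$gene_id_a,
                                 p_expr$gene_id_a))
d_ac <- p_ac$d[match(common, p_ac$gene_id_a)]
d_me <- p_me$d[match(common, p_me$gene_id_a)]
d_expr <- p_expr$d[match(common, p_expr$gene_id_a)]
message(sprintf("%d ortholog pairs with peak signals and expression in both species",
                length(common)))

grid <- seq(0, 2, by = 0.1)
exc <- rbind(cbind(divergence_exceedance(d_ac, grid), mark = "H3K9ac"),
             cbind(divergence_exceedance(d_me, grid), mark = "H3K4me3"),
             cbind(divergence_exceedance(d_expr, grid), mark = "expression"))
write.table(exc, file.path(out, "exceedance.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

pair_cls <- classify_change_pair(d_ac, d_me)
message(sprintf("H3K9ac vs H3K4me3 changes (threshold 0.4): %s",
                paste(sprintf("%s %.0f%%", names(pair_cls$proportions),
                              100 * pair_cls$proportions), collapse = ", ")))
message(sprintf("corr(d_ac, d_me) = %.2f", cor(d_ac, d_me)))

gated <- c(H3K9ac = threshold_gated_correlation(d_expr, d_ac),
           H3K4me3 = threshold_gated_correlation(d_expr, d_me))
cons <- rbind(cbind(consistency_vs_threshold(d_expr, d_ac), mark = "H3K9ac"),
              cbind(consistency_vs_threshold(d_expr, d_me), mark = "H3K4me3"))
n_ext <- min(1000L, floor(length(common) / 2))
enrc <- rbind(cbind(divergent_enrichment_curve(d_expr, d_ac, n_ext),
                    mark = "H3K9ac"),
              cbind(divergent_enrichment_curve(d_expr, d_me, n_ext),
                    mark = "H3K4me3"))
write.table(cons, file.path(out, "consistency.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(enrc, file.path(out, "enrichment_curve.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

triple <- triple_classification(d_ac, d_me, d_expr)
div_tab <- data.frame(gene_id_a = common,
                      d_ac = d_ac, d_me = d_me, d_expr = d_expr,
                      class_ac_me = as.character(pair_cls$labels),
                      triple = as.character(triple))
write.table(div_tab, file.path(out, "divergence.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("threshold-gated correlation with expression divergence: H3K4me3 r = %.2f, H3K9ac r = %.2f",
                gated[["H3K4me3"]], gated[["H3K9ac"]]))
cons1 <- cons[abs(cons$threshold - 1) < 1e-9, ]
message(sprintf("sign consistency with expression at a 2-fold modification threshold: H3K4me3 %.0f%%, H3K9ac %.0f%%",
                cons1$percent[cons1$mark == "H3K4me3"],
                cons1$percent[cons1$mark == "H3K9ac"]))
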