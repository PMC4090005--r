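#!/usr/bin/env Rscript
# Step 1: generate the two-species synthetic dataset and write every input
# file downstream steps consume. A moderate genome keeps the full workflow
# interactive; pass a different seed as the first CLI argument to revary it.

library(chromdiverge)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_genes = 800L, reads_per_sample = 8e5, rna_depth = 8e5,
                  seed = seed)
dat <- simulate_dataset(cfg)

write_genes(dat$genomes$species$A$genes, file.path(out, "genes_A.tsv"))
write_genes(dat$genomes$species$B$genes, file.path(out, "genes_B.tsv"))
write_table_kind(dat$genomes$species$A$nucleosomes,
                 file.path(out, "nucleosomes_A.tsv"), "nucleosomes")
write_table_kind(dat$genomes$species$B$nucleosomes,
                 file.path(out, "nucleosomes_B.tsv"), "nucleosomes")
write_table_kind(dat$genomes$orthologs, file.path(out, "orthologs.tsv"),
                 "orthologs")
write_table_kind(dat$genomes$classes, file.path(out, "classes.tsv"), "classes")
write_table_kind(dat$compendium, file.path(out, "compendium.tsv"),
                 "compendium")
write.table(data.frame(chrom = names(dat$genomes$chrom_sizes),
                       size = dat$genomes$chrom_sizes),
            file.path(out, "chrom_sizes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

for (sp in names(dat$reads)) {
  for (mark in names(dat$reads[[sp]])) {
    write_reads(dat$reads[[sp]][[mark]],
                file.path(out, sprintf("reads_%s_%s.bed", mark, sp)),
                read_length = cfg$read_length)
  }
  counts <- dat$rna[[sp]]
  write.table(data.frame(gene_id = rownames(counts), counts),
              file.path(out, sprintf("rna_%s.tsv", sp)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

message(sprintf("simulated %d genes x 2 species (%d ortholog pairs), %d ChIP samples at %g reads each",
                cfg$n_genes, nrow(dat$genomes$orthologs),
                sum(lengths(dat$reads)), cfg$reads_per_sample))
message("inputs written under ", out)
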