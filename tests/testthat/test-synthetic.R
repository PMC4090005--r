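test_that("generators are pure functions of the config seed", {
  cfg <- sim_config(n_genes = 10, seed = 7)
  expect_identical(generate_genomes(cfg), generate_genomes(cfg))
  cfg2 <- quick_config()
  d1 <- simulate_dataset(cfg2)
  d2 <- simulate_dataset(cfg2)
  expect_identical(d1$reads, d2$reads)
  expect_identical(d1$rna, d2$rna)
  expect_identical(d1$compendium, d2$compendium)
})

test_that("genome generation honors ortholog fraction and class exclusivity", {
  cfg <- sim_config(n_genes = 1000, seed = 2,
                    class_fractions = c(OPN = 0.3, DPN = 0.3, TATA = 0.2,
                                        essential = 0.2, responsive = 0.2,
                                        non_responsive = 0.2))
  g <- generate_genomes(cfg)
  expect_equal(nrow(g$orthologs), 900L)
  opn <- g$classes$gene_id[g$classes$class_name == "OPN"]
  dpn <- g$classes$gene_id[g$classes$class_name == "DPN"]
  expect_equal(length(opn), 300L)
  expect_equal(length(dpn), 300L)
  expect_length(intersect(opn, dpn), 0)
  # genes and their windows stay inside their slots
  ga <- g$species$A$genes
  expect_true(all(ga$tss >= 0 & ga$tss < g$chrom_sizes[ga$chrom]))
  expect_true(all(ga$tts >= 0 & ga$tts < g$chrom_sizes[ga$chrom]))
})

test_that("planted landscapes couple marks to expression as configured", {
  # no planted disparity, no nucleosome jitter: ac and me gene amplitudes
  # differ only by their fixed shapes -> near-perfect correlation
  cfg <- quick_config(disparity_effect = 0, nuc_noise_sd = 0,
                      minus1_ac_fraction = 0)
  l <- plant_landscapes(generate_genomes(cfg), cfg)
  ac <- log2(rowSums(l$A$intensity$H3K9ac))
  me <- log2(rowSums(l$A$intensity$H3K4me3))
  expect_gt(cor(ac, me), 0.999)

  # full methylation coupling and no independent mod divergence:
  # interspecies Delta-me equals Delta-expr exactly, per ortholog
  cfg <- quick_config(k4_expr_coupling = 1,
                      divergence_sd_mod = c(H3K9ac = 0, H3K4me3 = 0),
                      divergence_sd_expr = 0.5)
  g <- generate_genomes(cfg)
  l <- plant_landscapes(g, cfg)
  ia <- log2(l$A$intensity$H3K4me3[g$orthologs$gene_id_a, "2"])
  ib <- log2(l$B$intensity$H3K4me3[g$orthologs$gene_id_b, "2"])
  de <- l$A$expression[g$orthologs$gene_id_a] -
    l$B$expression[g$orthologs$gene_id_b]
  expect_equal(unname(ia - ib), unname(de), tolerance = 1e-12)
  expect_equal(l$truth$d_me, l$truth$d_expr, tolerance = 1e-12)

  # zero acetylation coupling: Delta-ac decorrelates from Delta-expr
  cfg <- sim_config(n_genes = 1000, k9_expr_coupling = 0, seed = 9)
  l <- plant_landscapes(generate_genomes(cfg), cfg)
  expect_lt(abs(cor(l$truth$d_ac, l$truth$d_expr)), 0.1)
})

test_that("ChIP read simulation samples fragments from nucleosome intensity", {
  cfg <- quick_config(fragment_length = 150)
  g <- generate_genomes(cfg)
  l <- plant_landscapes(g, cfg)
  # concentrate all intensity on one nucleosome of one gene
  l$A$intensity$H3K9ac[] <- 0
  gid <- g$species$A$genes$gene_id[1]
  l$A$intensity$H3K9ac[gid, "1"] <- 1
  reads <- simulate_chip_reads(l, g, "A", "H3K9ac", cfg, n_reads = 5000)
  nuc <- g$species$A$nucleosomes
  iv <- nuc[nuc$gene_id == gid & nuc$index == 1L, ]
  mid <- ifelse(reads$strand == "+", reads$pos + 75L, reads$pos - 74L)
  expect_true(all(mid >= iv$start & mid < iv$end))
  expect_true(all(reads$chrom == iv$chrom))
  # roughly half of the fragments emit a forward read
  expect_gt(mean(reads$strand == "+"), 0.45)
  expect_lt(mean(reads$strand == "+"), 0.55)

  l$A$intensity$H3K9ac[] <- 0
  expect_error(simulate_chip_reads(l, g, "A", "H3K9ac", cfg), "zero total")
})

test_that("forward and reverse first-base profiles are offset by the fragment length", {
  cfg <- sim_config(n_genes = 150, n_chroms = 1, fragment_length = 120,
                    reads_per_sample = 1e5, seed = 4)
  d <- simulate_dataset(cfg, chip_species = "A", h3_species = character(0))
  prof <- build_strand_profiles(d$reads$A$H3K9ac, d$genomes$chrom_sizes)
  ora <- oracle_shift_scan(prof$fwd, prof$rev, max_shift = 250)
  expect_lt(abs(ora$offset - 120), 5)
})

test_that("expression counts recover planted expression", {
  cfg <- quick_config()
  g <- generate_genomes(cfg)
  l <- plant_landscapes(g, cfg)
  l$A$expression[1] <- -Inf  # silenced gene
  counts <- simulate_expression_counts(l, g, "A", cfg, depth = 1e6)
  expect_equal(unname(counts[1, ]), c(0L, 0L))

  cfg2 <- sim_config(n_genes = 1000, seed = 8)
  g2 <- generate_genomes(cfg2)
  l2 <- plant_landscapes(g2, cfg2)
  counts2 <- simulate_expression_counts(l2, g2, "A", cfg2, depth = 1e6)
  est <- quantify_expression(counts2, setNames(g2$species$A$genes$length,
                                               g2$species$A$genes$gene_id))
  expect_gt(cor(est$value, l2$A$expression[est$gene_id]), 0.95)
})

test_that("compendium SDs separate responsive from non-responsive genes", {
  cfg <- sim_config(n_genes = 500, n_conditions = 200, seed = 6)
  g <- generate_genomes(cfg)
  l <- plant_landscapes(g, cfg)
  comp <- generate_compendium(l, g$classes, cfg)
  planted <- g$classes$gene_id[g$classes$class_name == "responsive"]
  cls <- responsiveness_classes(comp, n = length(planted))
  found <- cls$gene_id[cls$class_name == "responsive"]
  expect_gte(mean(planted %in% found), 0.95)
  expect_identical(comp, generate_compendium(l, g$classes, cfg))

  # a zero-variance gene has SD exactly 0
  comp[, 1] <- 5
  expect_equal(unname(apply(comp, 2, sd)[1]), 0)
})
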