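# Synthetic two-species generator. The generator is not a model of any real
# dataset: it plants the qualitative chromatin architecture the analysis is
# designed to detect (H3K9ac at the +1 nucleosome, an H3K4me3 plateau over
# +2/+3, promoter H3 dips, expression-coupled amplitudes, class-biased
# disparity, and expression-coupled interspecies divergence of H3K4me3 but not
# H3K9ac) so that every downstream stage is testable offline.

NUC_INDICES <- c(-2L, -1L, 1L, 2L, 3L, 4L, 5L, 6L)
MARKS <- c("H3K9ac", "H3K4me3", "H3")

#' Simulation configuration
#'
#' Defaults define the study conditions used throughout the package: a compact
#' yeast-like genome (one gene per 4 kb slot), 150 bp sonication fragments and
#' 40-base single-end reads, log2-normal expression, strong coupling of
#' interspecies H3K4me3 divergence to expression divergence
#' (`k4_expr_coupling = 0.8`) and weak coupling for H3K9ac
#' (`k9_expr_coupling = 0.1`), ~90\% shared orthologs, and moderate planted
#' disparity at OPN (extra acetylation) and DPN (extra methylation) genes.
#'
#' @param n_genes Number of genes per species.
#' @param n_chroms Number of chromosomes.
#' @param gene_spacing Slot width per gene, bp.
#' @param gene_length_range Uniform range for gene lengths, bp.
#' @param fragment_length Sonication fragment length, bp.
#' @param read_length Read length, bp.
#' @param reads_per_sample Single-end reads per ChIP sample.
#' @param rna_depth Total RNA-seq reads per replicate.
#' @param expression_mean,expression_log_sd Per-gene log2 expression
#'   distribution.
#' @param nuc_noise_sd Per-(gene, nucleosome) log2 jitter on mark intensities
#'   (shared between species at orthologs).
#' @param h3_noise_sd Log2 jitter on H3 occupancy.
#' @param minus1_ac_fraction Fraction of genes whose -1 nucleosome also carries
#'   elevated acetylation.
#' @param disparity_effect Log2 units added to H3K9ac intensity at OPN genes
#'   and to H3K4me3 at DPN genes (both species).
#' @param divergence_sd_expr SD of interspecies log2 expression shifts at
#'   orthologs.
#' @param k4_expr_coupling,k9_expr_coupling Weight in [0,1] with which the
#'   interspecies expression shift propagates into H3K4me3 / H3K9ac intensity.
#' @param divergence_sd_mod Named numeric (H3K9ac, H3K4me3): SD of
#'   expression-independent interspecies log2 modification shifts.
#' @param ortholog_fraction Fraction of genes with an ortholog.
#' @param class_fractions Named fractions for gene classes; OPN/DPN and
#'   responsive/non_responsive are drawn mutually exclusively.
#' @param n_conditions Conditions in the expression compendium.
#' @param responsive_sd,nonresponsive_sd Planted compendium SDs.
#' @param seed Integer master seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_chroms = 4L, gene_spacing = 4000L,
                       gene_length_range = c(500L, 2800L),
                       fragment_length = 150L, read_length = 40L,
                       reads_per_sample = 2e6, rna_depth = 2e6,
                       expression_mean = 3, expression_log_sd = 1.5,
                       nuc_noise_sd = 0.5, h3_noise_sd = 0.2,
                       minus1_ac_fraction = 0.3,
                       disparity_effect = 0.5,
                       divergence_sd_expr = 0.6,
                       k4_expr_coupling = 0.8, k9_expr_coupling = 0.1,
                       divergence_sd_mod = c(H3K9ac = 0.55, H3K4me3 = 0.35),
                       ortholog_fraction = 0.9,
                       class_fractions = c(OPN = 0.25, DPN = 0.25, TATA = 0.2,
                                           essential = 0.2, responsive = 0.2,
                                           non_responsive = 0.2),
                       n_conditions = 200L,
                       responsive_sd = 2.0, nonresponsive_sd = 0.2,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_genes, cfg$n_chroms, cfg$gene_spacing, cfg$fragment_length,
              cfg$read_length, cfg$reads_per_sample, cfg$rna_depth,
              cfg$n_conditions)
  if (any(counts <= 0)) stop("all counts in sim_config must be positive")
  if (cfg$k4_expr_coupling < 0 || cfg$k4_expr_coupling > 1 ||
      cfg$k9_expr_coupling < 0 || cfg$k9_expr_coupling > 1)
    stop("expression couplings must lie in [0, 1]")
  if (cfg$ortholog_fraction < 0 || cfg$ortholog_fraction > 1)
    stop("ortholog_fraction must lie in [0, 1]")
  if (any(cfg$class_fractions < 0 | cfg$class_fractions > 1))
    stop("class fractions must lie in [0, 1]")
  # genes plus promoter/terminator margins must fit inside a slot
  if (max(cfg$gene_length_range) > cfg$gene_spacing - 1050)
    stop("genes overlapping: gene_length_range too large for gene_spacing")
  if (!all(c("H3K9ac", "H3K4me3") %in% names(cfg$divergence_sd_mod)))
    stop("divergence_sd_mod must name H3K9ac and H3K4me3")
  structure(cfg, class = "sim_config")
}

# nucleosome interval in transcription-relative coordinates, half-open
nuc_rel_interval <- function(index, spacing = 165L, width = 147L) {
  rs <- ifelse(index > 0, (index - 1L) * spacing, index * spacing)
  cbind(start = rs, end = rs + width)
}

# map a transcription-relative half-open interval to genomic coordinates
rel_to_genomic <- function(tss, strand, rel_start, rel_end) {
  gstart <- ifelse(strand == "+", tss + rel_start, tss - rel_end + 1L)
  gend <- ifelse(strand == "+", tss + rel_end, tss - rel_start + 1L)
  cbind(start = as.integer(gstart), end = as.integer(gend))
}

#' Generate two species' gene architecture
#'
#' Produces annotation, nucleosome maps (indices -2..+6 tiled at 165 bp from
#' the TSS, 147 bp cores), a one-to-one ortholog map covering
#' `ortholog_fraction` of genes, and class tables (on species A ids; OPN/DPN
#' and responsive/non-responsive mutually exclusive). Orthologous genes share
#' coordinates and nucleosome layout; the species differ only in their planted
#' intensities (see [plant_landscapes()]).
#'
#' @param config A [sim_config()].
#' @return list(species = list(A, B), orthologs, classes, chrom_sizes).
#' @export
generate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  slots_per_chrom <- ceiling(n / config$n_chroms)
  chrom_names <- sprintf("chr%s", as.roman(seq_len(config$n_chroms)))
  chrom_sizes <- setNames(rep(slots_per_chrom * config$gene_spacing,
                              config$n_chroms), chrom_names)
  slot <- seq_len(n) - 1L
  chrom_i <- slot %/% slots_per_chrom + 1L
  slot_start <- (slot %% slots_per_chrom) * config$gene_spacing
  strand <- sample(c("+", "-"), n, replace = TRUE)
  len <- as.integer(round(runif(n, config$gene_length_range[1],
                                config$gene_length_range[2])))
  upstream_margin <- 600L
  tss <- ifelse(strand == "+", slot_start + upstream_margin,
                slot_start + config$gene_spacing - upstream_margin)
  tts <- ifelse(strand == "+", tss + len, tss - len)

  make_genes <- function(prefix) {
    data.frame(gene_id = sprintf("%s%05d", prefix, seq_len(n)),
               chrom = chrom_names[chrom_i], strand = strand,
               tss = as.integer(tss), tts = as.integer(tts),
               length = len, stringsAsFactors = FALSE)
  }
  genes_a <- make_genes("gA")
  genes_b <- make_genes("gB")

  make_nucs <- function(genes) {
    rel <- nuc_rel_interval(NUC_INDICES)
    out <- do.call(rbind, lapply(seq_along(NUC_INDICES), function(k) {
      g <- rel_to_genomic(genes$tss, genes$strand, rel[k, 1], rel[k, 2])
      data.frame(gene_id = genes$gene_id, index = NUC_INDICES[k],
                 chrom = genes$chrom, start = g[, 1], end = g[, 2],
                 stringsAsFactors = FALSE)
    }))
    out[order(out$gene_id, out$index), , drop = FALSE]
  }

  ortho_idx <- sort(sample.int(n, round(config$ortholog_fraction * n)))
  orthologs <- data.frame(gene_id_a = genes_a$gene_id[ortho_idx],
                          gene_id_b = genes_b$gene_id[ortho_idx],
                          stringsAsFactors = FALSE)

  fr <- config$class_fractions
  draw <- function(idx_pool, frac) sort(sample(idx_pool, round(frac * n)))
  opn <- draw(seq_len(n), fr[["OPN"]])
  dpn <- draw(setdiff(seq_len(n), opn), fr[["DPN"]])
  resp <- draw(seq_len(n), fr[["responsive"]])
  nonresp <- draw(setdiff(seq_len(n), resp), fr[["non_responsive"]])
  tata <- draw(seq_len(n), fr[["TATA"]])
  ess <- draw(seq_len(n), fr[["essential"]])
  classes <- rbind(
    data.frame(gene_id = genes_a$gene_id[opn], class_name = "OPN"),
    data.frame(gene_id = genes_a$gene_id[dpn], class_name = "DPN"),
    data.frame(gene_id = genes_a$gene_id[tata], class_name = "TATA"),
    data.frame(gene_id = genes_a$gene_id[ess], class_name = "essential"),
    data.frame(gene_id = genes_a$gene_id[resp], class_name = "responsive"),
    data.frame(gene_id = genes_a$gene_id[nonresp],
               class_name = "non_responsive"))

  list(species = list(A = list(genes = genes_a, nucleosomes = make_nucs(genes_a)),
                      B = list(genes = genes_b, nucleosomes = make_nucs(genes_b))),
       orthologs = orthologs, classes = classes, chrom_sizes = chrom_sizes)
}

mark_shape <- function(mark) {
  switch(mark,
    H3K9ac = c(0.05, 0.05, 1.00, 0.30, 0.15, 0.08, 0.05, 0.05),
    H3K4me3 = c(0.05, 0.08, 0.45, 1.00, 1.00, 0.60, 0.30, 0.15),
    H3 = c(0.70, 0.50, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00),
    stop("unknown mark ", mark))
}

#' Plant per-nucleosome modification landscapes for both species
#'
#' Mark intensities follow characteristic positional shapes (H3K9ac peaking at
#' the +1 nucleosome with a configurable fraction of genes also acetylated at
#' -1; an H3K4me3 plateau over +2/+3 decaying downstream; H3 occupancy dipping
#' at the promoter) and scale multiplicatively with `2^expression` for the two
#' marks. H3 occupancy is expression-independent: it is the occupancy control.
#' `disparity_effect` log2 units are added to H3K9ac at OPN genes and to
#' H3K4me3 at DPN genes in both species. Species B expression at orthologs is
#' species A expression plus Normal(0, `divergence_sd_expr`); the expression
#' shift propagates into H3K4me3 intensity with weight `k4_expr_coupling` and
#' into H3K9ac with weight `k9_expr_coupling`, on top of independent per-gene
#' modification shifts of SD `divergence_sd_mod`.
#'
#' @param genomes Output of [generate_genomes()].
#' @param config The same [sim_config()].
#' @return list(A, B, truth): per species, `expression` (named log2 vector) and
#'   `intensity` (list of genes x nucleosome-index matrices per mark); `truth`
#'   records the planted interspecies shifts per ortholog pair.
#' @export
plant_landscapes <- function(genomes, config) {
  set.seed(config$seed + 1L)
  n <- config$n_genes
  ids_a <- genomes$species$A$genes$gene_id
  ids_b <- genomes$species$B$genes$gene_id
  cls <- split(genomes$classes$gene_id, genomes$classes$class_name)

  expr_a <- setNames(rnorm(n, config$expression_mean, config$expression_log_sd),
                     ids_a)
  minus1 <- runif(n) < config$minus1_ac_fraction
  eps <- lapply(c(H3K9ac = "H3K9ac", H3K4me3 = "H3K4me3"), function(m)
    matrix(rnorm(n * length(NUC_INDICES), 0, config$nuc_noise_sd), n))
  eps$H3 <- matrix(rnorm(n * length(NUC_INDICES), 0, config$h3_noise_sd), n)

  base_log2 <- function(mark, expr, species_ids) {
    shape <- matrix(log2(mark_shape(mark)), n, length(NUC_INDICES), byrow = TRUE)
    if (mark == "H3K9ac") shape[minus1, 2] <- log2(0.6)
    w <- if (mark == "H3") 0 else 1
    m <- shape + w * matrix(expr, n, length(NUC_INDICES)) + eps[[mark]]
    if (mark == "H3K9ac") {
      hit <- species_ids %in% cls$OPN | species_ids %in% cls$OPN_b
      m[hit, ] <- m[hit, ] + config$disparity_effect
    }
    if (mark == "H3K4me3") {
      hit <- species_ids %in% cls$DPN | species_ids %in% cls$DPN_b
      m[hit, ] <- m[hit, ] + config$disparity_effect
    }
    m
  }

  # class membership translated to species B through the ortholog map
  pair_idx_a <- match(genomes$orthologs$gene_id_a, ids_a)
  pair_idx_b <- match(genomes$orthologs$gene_id_b, ids_b)
  in_class_b <- function(name) {
    idx <- pair_idx_b[genomes$orthologs$gene_id_a %in% cls[[name]]]
    ids_b[idx]
  }
  cls$OPN_b <- in_class_b("OPN")
  cls$DPN_b <- in_class_b("DPN")

  # interspecies shifts at orthologs; species-specific genes drawn fresh
  d_expr_pair <- rnorm(length(pair_idx_a), 0, config$divergence_sd_expr)
  d_mod <- list(
    H3K9ac = rnorm(length(pair_idx_a), 0, config$divergence_sd_mod[["H3K9ac"]]),
    H3K4me3 = rnorm(length(pair_idx_a), 0, config$divergence_sd_mod[["H3K4me3"]]))
  coupling <- c(H3K9ac = config$k9_expr_coupling,
                H3K4me3 = config$k4_expr_coupling, H3 = 0)

  expr_b <- setNames(rnorm(n, config$expression_mean, config$expression_log_sd),
                     ids_b)
  expr_b[pair_idx_b] <- expr_a[pair_idx_a] + d_expr_pair

  build_species <- function(which) {
    ids <- if (which == "A") ids_a else ids_b
    expr <- if (which == "A") expr_a else expr_b
    intensity <- lapply(setNames(MARKS, MARKS), function(mark) {
      m <- base_log2(mark, expr_a, ids)  # architecture anchored to species A
      if (which == "B" && mark != "H3") {
        shift <- numeric(n)
        shift[pair_idx_b] <- coupling[[mark]] * d_expr_pair + d_mod[[mark]]
        # species-specific genes: re-draw the expression-scaled component
        own <- setdiff(seq_len(n), pair_idx_b)
        shift[own] <- (expr_b[own] - expr_a[own])
        m <- m + matrix(shift, n, length(NUC_INDICES))
      }
      out <- 2^m
      dimnames(out) <- list(ids, as.character(NUC_INDICES))
      out
    })
    list(expression = setNames(expr, ids), intensity = intensity)
  }

  # truth differences follow the analysis orientation: species A - species B
  list(A = build_species("A"), B = build_species("B"),
       truth = data.frame(gene_id_a = genomes$orthologs$gene_id_a,
                          gene_id_b = genomes$orthologs$gene_id_b,
                          d_expr = -d_expr_pair,
                          d_ac = -(coupling[["H3K9ac"]] * d_expr_pair + d_mod$H3K9ac),
                          d_me = -(coupling[["H3K4me3"]] * d_expr_pair + d_mod$H3K4me3),
                          stringsAsFactors = FALSE))
}

#' Simulate stranded single-end ChIP-seq reads for one mark
#'
#' Fragment midpoints are sampled proportionally to nucleosome intensity
#' (uniform within the nucleosome interval); each fragment of length
#' `fragment_length` emits one read, forward at the fragment start or reverse
#' at the fragment end - 1, with probability 0.5 each.
#'
#' @param landscape Output of [plant_landscapes()].
#' @param genomes Output of [generate_genomes()].
#' @param species "A" or "B".
#' @param mark "H3K9ac", "H3K4me3" or "H3".
#' @param config The [sim_config()].
#' @param n_reads Number of reads (default `config$reads_per_sample`).
#' @param seed RNG seed (default derived from the config seed).
#' @return data.frame(chrom, pos, strand) of first-sequenced-base positions.
#' @export
simulate_chip_reads <- function(landscape, genomes, species, mark, config,
                                n_reads = config$reads_per_sample,
                                seed = config$seed + 10L) {
  set.seed(seed)
  nucs <- genomes$species[[species]]$nucleosomes
  intens <- landscape[[species]]$intensity[[mark]]
  w <- intens[cbind(match(nucs$gene_id, rownames(intens)),
                    match(as.character(nucs$index), colnames(intens)))]
  if (sum(w) <= 0) stop("zero total intensity for ", mark, " in species ", species)
  n_reads <- as.integer(n_reads)
  ridx <- sample.int(nrow(nucs), n_reads, replace = TRUE, prob = w)
  width <- nucs$end - nucs$start
  mid <- nucs$start[ridx] + floor(runif(n_reads) * width[ridx])
  fl <- config$fragment_length
  fstart <- mid - fl %/% 2L
  fend <- fstart + fl
  fwd <- runif(n_reads) < 0.5
  pos <- ifelse(fwd, fstart, fend - 1L)
  chrom <- nucs$chrom[ridx]
  csize <- genomes$chrom_sizes[chrom]
  keep <- pos >= 0 & pos < csize
  data.frame(chrom = chrom[keep], pos = as.integer(pos[keep]),
             strand = ifelse(fwd[keep], "+", "-"), stringsAsFactors = FALSE)
}

#' Simulate RNA-seq counts per gene and replicate
#'
#' Counts are Poisson with mean proportional to `gene_length * 2^expression`,
#' scaled so each replicate totals `depth` in expectation; replicates carry
#' independent noise.
#'
#' @param landscape Output of [plant_landscapes()].
#' @param genomes Output of [generate_genomes()].
#' @param species "A" or "B".
#' @param config The [sim_config()].
#' @param n_replicates Number of biological replicates.
#' @param depth Expected total reads per replicate.
#' @param seed RNG seed.
#' @return Integer matrix genes x replicates, rownames = gene ids.
#' @export
simulate_expression_counts <- function(landscape, genomes, species, config,
                                       n_replicates = 2L,
                                       depth = config$rna_depth,
                                       seed = config$seed + 20L) {
  set.seed(seed)
  genes <- genomes$species[[species]]$genes
  expr <- landscape[[species]]$expression[genes$gene_id]
  lambda <- genes$length * 2^expr
  lambda <- lambda / sum(lambda) * depth
  counts <- vapply(seq_len(n_replicates),
                   function(i) rpois(length(lambda), lambda), numeric(nrow(genes)))
  counts <- matrix(as.integer(counts), nrow = nrow(genes),
                   dimnames = list(genes$gene_id,
                                   sprintf("rep%d", seq_len(n_replicates))))
  counts
}

#' Generate a conditions x genes expression compendium
#'
#' Per-gene condition series centered on the gene's planted expression, with
#' planted SD `responsive_sd` for "responsive" genes, `nonresponsive_sd` for
#' "non_responsive" genes, and intermediate SDs (uniform 0.4-1.2) otherwise.
#'
#' @param landscape Output of [plant_landscapes()] (species A is used).
#' @param classes Class table with responsive/non_responsive rows.
#' @param config The [sim_config()].
#' @param seed RNG seed.
#' @return Numeric matrix conditions x genes.
#' @export
generate_compendium <- function(landscape, classes, config,
                                seed = config$seed + 30L) {
  set.seed(seed)
  expr <- landscape$A$expression
  ids <- names(expr)
  resp <- classes$gene_id[classes$class_name == "responsive"]
  nonresp <- classes$gene_id[classes$class_name == "non_responsive"]
  if (length(resp) == 0 || length(nonresp) == 0)
    stop("class table must contain responsive and non_responsive genes")
  sd_g <- runif(length(ids), 0.4, 1.2)
  sd_g[ids %in% resp] <- config$responsive_sd
  sd_g[ids %in% nonresp] <- config$nonresponsive_sd
  m <- matrix(rnorm(config$n_conditions * length(ids)),
              config$n_conditions, length(ids))
  m <- sweep(m, 2, sd_g, `*`)
  m <- sweep(m, 2, expr, `+`)
  dimnames(m) <- list(sprintf("c%04d", seq_len(config$n_conditions)), ids)
  m
}

#' Simulate a complete two-species dataset
#'
#' Convenience wrapper running [generate_genomes()], [plant_landscapes()],
#' ChIP read simulation for the requested marks and species, RNA-seq counts,
#' and the expression compendium, all deterministically from the config seed.
#'
#' @param config A [sim_config()].
#' @param chip_species Species to simulate ChIP reads for.
#' @param h3_species Species to simulate the H3 occupancy sample for (the
#'   two-species design here profiles H3 in the reference species only).
#' @return list(genomes, landscape, reads, rna, compendium). `reads` is a
#'   nested list `reads[[species]][[mark]]`.
#' @export
simulate_dataset <- function(config, chip_species = c("A", "B"),
                             h3_species = "A") {
  genomes <- generate_genomes(config)
  landscape <- plant_landscapes(genomes, config)
  reads <- list()
  k <- 0L
  for (sp in chip_species) {
    reads[[sp]] <- list()
    for (mark in c("H3K9ac", "H3K4me3")) {
      reads[[sp]][[mark]] <- simulate_chip_reads(
        landscape, genomes, sp, mark, config, seed = config$seed + 100L + k)
      k <- k + 1L
    }
  }
  for (sp in h3_species) {
    reads[[sp]][["H3"]] <- simulate_chip_reads(
      landscape, genomes, sp, "H3", config, seed = config$seed + 100L + k)
    k <- k + 1L
  }
  rna <- lapply(setNames(chip_species, chip_species), function(sp)
    simulate_expression_counts(landscape, genomes, sp, config,
                               seed = config$seed + 200L + match(sp, c("A", "B"))))
  compendium <- generate_compendium(landscape, genomes$classes, config)
  list(genomes = genomes, landscape = landscape, reads = reads, rna = rna,
       compendium = compendium)
}
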