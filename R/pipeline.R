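# Orchestration: simulate (or ingest) -> tracks -> metagene -> expression ->
# disparity -> divergence, from a single config, with per-stage logging and a
# machine-readable summary.

#' Pipeline configuration
#'
#' Bundles the simulation config with every analysis constant: 20-bp bins,
#' 140-base H3 smoothing, the 0.4 log2 change threshold, the 700-bp minimum
#' gene length, 1200-gene disparity sectors, 800/1000 divergent-set sizes and
#' the named region coordinates are all defaulted here so the standard
#' analysis is the default run.
#'
#' @param sim A [sim_config()].
#' @param pseudocount Pseudocount before log2.
#' @param smoothing_window H3 smoothing window, bp.
#' @param max_shift Strand-shift scan limit, bp.
#' @param sector_size Disparity sector size.
#' @param min_gene_length Minimum gene length for disparity ranking, bp.
#' @param change_threshold Significant-change threshold, log2.
#' @param concordance_cutoff Concordance half-width, log2.
#' @param n_extreme Divergent/non-divergent set size.
#' @param n_per_side Lowess-extracted set size.
#' @param lowess_span Lowess span.
#' @param threshold_grid Threshold grid for divergence curves.
#' @param write_inputs Write the simulated input tables to the output dir.
#' @param write_reads Also write simulated reads as BED (large; off by
#'   default).
#' @export
pipeline_config <- function(sim = sim_config(), pseudocount = 0.1,
                            smoothing_window = 140L, max_shift = 400L,
                            sector_size = 1200L, min_gene_length = 700L,
                            change_threshold = 0.4, concordance_cutoff = 0.5,
                            n_extreme = 1000L, n_per_side = 800L,
                            lowess_span = 0.3,
                            threshold_grid = seq(0, 2, by = 0.1),
                            write_inputs = TRUE, write_reads = FALSE) {
  cfg <- as.list(environment())
  thr <- c(cfg$sector_size, cfg$min_gene_length, cfg$change_threshold,
           cfg$concordance_cutoff, cfg$n_extreme, cfg$n_per_side)
  if (any(thr <= 0)) stop("pipeline thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

ppl_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full comparative-chromatin pipeline
#'
#' Simulates the two-species dataset, builds normalized coverage tracks with
#' estimated fragment lengths, extracts metagene and nucleosome-level
#' profiles (including H3-normalized versions for species A), quantifies
#' expression, computes the disparity sectors and class enrichments, and runs
#' all interspecies divergence analyses. Writes TSV artifacts, a summary JSON
#' and a markdown report under `out_dir`; returns the results invisibly.
#' Idempotent given the config seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @param verbose Log each stage with record counts.
#' @return (Invisibly) a list with all intermediate and final results.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pc <- config$pseudocount
  res <- list(config = config)

  # -- stage: simulate -------------------------------------------------------
  dat <- simulate_dataset(config$sim)
  genomes <- dat$genomes
  ppl_log(verbose, "simulate", "%d genes x 2 species, %d ortholog pairs",
          config$sim$n_genes, nrow(genomes$orthologs))
  if (config$write_inputs) {
    write_genes(genomes$species$A$genes, file.path(out_dir, "genes_A.tsv"))
    write_genes(genomes$species$B$genes, file.path(out_dir, "genes_B.tsv"))
    write_table_kind(genomes$species$A$nucleosomes,
                     file.path(out_dir, "nucleosomes_A.tsv"), "nucleosomes")
    write_table_kind(genomes$species$B$nucleosomes,
                     file.path(out_dir, "nucleosomes_B.tsv"), "nucleosomes")
    write_table_kind(genomes$orthologs, file.path(out_dir, "orthologs.tsv"),
                     "orthologs")
    write_table_kind(genomes$classes, file.path(out_dir, "classes.tsv"),
                     "classes")
    write_table_kind(dat$compendium, file.path(out_dir, "compendium.tsv"),
                     "compendium")
  }
  if (config$write_reads) {
    for (sp in names(dat$reads))
      for (mark in names(dat$reads[[sp]]))
        write_reads(dat$reads[[sp]][[mark]],
                    file.path(out_dir, sprintf("reads_%s_%s.bed", mark, sp)),
                    read_length = config$sim$read_length)
  }

  # -- stage: tracks ---------------------------------------------------------
  tracks <- list()
  frag <- list()
  for (sp in names(dat$reads)) {
    for (mark in names(dat$reads[[sp]])) {
      key <- paste(mark, sp, sep = "_")
      prof <- build_strand_profiles(dat$reads[[sp]][[mark]],
                                    genomes$chrom_sizes)
      est <- estimate_fragment_length(prof$fwd, prof$rev,
                                      max_shift = config$max_shift)
      tracks[[key]] <- merge_strands(prof$fwd, prof$rev, est$offset,
                                     sample = key)
      frag[[key]] <- data.frame(sample = key, fragment_length = est$offset,
                                strand_correlation = est$corr_at_offset)
      ppl_log(verbose, "tracks", "%s: fragment length %d (r=%.3f), %d reads",
              key, est$offset, est$corr_at_offset,
              nrow(dat$reads[[sp]][[mark]]))
    }
  }
  tracks <- normalize_to_lowest_total(tracks)
  res$fragment_lengths <- do.call(rbind, frag)
  write_tsv(res$fragment_lengths, file.path(out_dir, "fragment_lengths.tsv"))

  # -- stage: expression -----------------------------------------------------
  expr <- lapply(dat$rna, function(counts) {
    sp_genes <- genomes$species[[if (startsWith(rownames(counts)[1], "gA"))
      "A" else "B"]]$genes
    quantify_expression(counts, setNames(sp_genes$length, sp_genes$gene_id),
                        pseudocount = pc)
  })
  res$expression <- expr
  ppl_log(verbose, "expression", "quantified %d + %d genes",
          nrow(expr$A), nrow(expr$B))

  # -- stage: metagene (species A) ------------------------------------------
  genes_a <- genomes$species$A$genes
  mats <- list()
  for (mark in c("H3K9ac", "H3K4me3")) {
    key <- paste0(mark, "_A")
    mats[[paste0(mark, "_tss")]] <-
      gene_profile_matrix(tracks[[key]], genes_a, tss_window(), pc)
    mats[[paste0(mark, "_tts")]] <-
      gene_profile_matrix(tracks[[key]], genes_a, tts_window(), pc)
  }
  has_h3 <- "H3_A" %in% names(tracks)
  if (has_h3) {
    h3_sm <- smooth_track(log2_track(tracks$H3_A, pc),
                          config$smoothing_window)
    mats$H3_tss <- gene_profile_matrix(h3_sm, genes_a, tss_window())
    mats$H3_tts <- gene_profile_matrix(h3_sm, genes_a, tts_window())
    for (mark in c("H3K9ac", "H3K4me3")) {
      lg <- log2_track(tracks[[paste0(mark, "_A")]], pc)
      mats[[paste0(mark, "_h3norm_tss")]] <-
        gene_profile_matrix(lg, genes_a, tss_window()) - mats$H3_tss
    }
  }
  avg <- function(m) average_profile(m)
  prof_tss <- data.frame(bin = as.integer(colnames(mats$H3K9ac_tss)),
                         H3K9ac = avg(mats$H3K9ac_tss),
                         H3K4me3 = avg(mats$H3K4me3_tss))
  if (has_h3) {
    prof_tss$H3 <- avg(mats$H3_tss)
    prof_tss$H3K9ac_h3norm <- avg(mats$H3K9ac_h3norm_tss)
    prof_tss$H3K4me3_h3norm <- avg(mats$H3K4me3_h3norm_tss)
  }
  write_tsv(prof_tss, file.path(out_dir, "profiles_tss.tsv"))
  prof_tts <- data.frame(bin = as.integer(colnames(mats$H3K9ac_tts)),
                         H3K9ac = avg(mats$H3K9ac_tts),
                         H3K4me3 = avg(mats$H3K4me3_tts))
  write_tsv(prof_tts, file.path(out_dir, "profiles_tts.tsv"))
  res$profiles <- list(tss = prof_tss, tts = prof_tts)
  res$matrices <- mats
  ppl_log(verbose, "metagene", "TSS/TTS matrices for %d genes", nrow(genes_a))

  # nucleosome-level signals and their correlation with expression
  nuc_a <- genomes$species$A$nucleosomes
  expr_a <- setNames(expr$A$value, expr$A$gene_id)
  nuc_cor <- list()
  for (mark in c("H3K9ac", "H3K4me3")) {
    lev <- nucleosome_levels(tracks[[paste0(mark, "_A")]], nuc_a, pc)
    m <- matrix(NA_real_, nrow(genes_a), length(NUC_INDICES),
                dimnames = list(genes_a$gene_id, as.character(NUC_INDICES)))
    m[cbind(match(lev$gene_id, rownames(m)),
            match(as.character(lev$index), colnames(m)))] <- lev$value
    res[[paste0("nuc_levels_", mark)]] <- m
    nuc_cor[[mark]] <- positional_correlation(m, expr_a)
  }
  nuc_cor_df <- data.frame(index = NUC_INDICES,
                           H3K9ac = nuc_cor$H3K9ac,
                           H3K4me3 = nuc_cor$H3K4me3)
  write_tsv(nuc_cor_df, file.path(out_dir, "nucleosome_expression_correlation.tsv"))
  res$nucleosome_expression_correlation <- nuc_cor_df

  # -- stage: disparity (species A) -----------------------------------------
  rs <- function(track_key, region, genes)
    region_means(tracks[[track_key]], genes, region_def(region), pc)
  ac_peak_a <- rs("H3K9ac_A", "peak_ac", genes_a)
  me_peak_a <- rs("H3K4me3_A", "peak_me", genes_a)
  disp <- disparity_ratios(ac_peak_a, me_peak_a, genes_a,
                           config$min_gene_length)
  sec_size <- min(config$sector_size, floor(sum(!is.na(disp$ratio)) / 3))
  disp <- assign_sectors(disp, sec_size)
  enr <- sector_enrichment(disp, genomes$classes)
  gm <- group_mean_disparity(disp, genomes$classes)
  res$disparity <- disp
  res$enrichment <- enr
  res$group_means <- gm
  res$concordance <- concordance_fraction(disp, config$concordance_cutoff)
  write_tsv(disp, file.path(out_dir, "disparity.tsv"))
  write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  write_tsv(gm$means, file.path(out_dir, "group_means.tsv"))
  ppl_log(verbose, "disparity", "%d ranked genes, concordance %.1f%%",
          sum(!is.na(disp$ratio)), res$concordance)

  # -- stage: divergence -----------------------------------------------------
  genes_b <- genomes$species$B$genes
  omap <- genomes$orthologs
  ac_peak_b <- rs("H3K9ac_B", "peak_ac", genes_b)
  me_peak_b <- rs("H3K4me3_B", "peak_me", genes_b)
  p_ac <- paired_region_signals(ac_peak_a, ac_peak_b, omap)
  p_me <- paired_region_signals(me_peak_a, me_peak_b, omap)
  expr_tab <- function(sp) data.frame(gene_id = expr[[sp]]$gene_id,
                                      value = expr[[sp]]$value,
                                      valid = TRUE)
  p_expr <- paired_region_signals(expr_tab("A"), expr_tab("B"), omap)

  # divergence exceedance per mark and region
  exc <- list()
  for (mark in c("H3K9ac", "H3K4me3")) {
    for (reg in c("prom", if (mark == "H3K9ac") "peak_ac" else "peak_me",
                  "end")) {
      pa <- rs(paste0(mark, "_A"), reg, genes_a)
      pb <- rs(paste0(mark, "_B"), reg, genes_b)
      pr <- paired_region_signals(pa, pb, omap)
      cur <- divergence_exceedance(pr$d, config$threshold_grid)
      cur$mark <- mark
      cur$region <- if (reg %in% c("peak_ac", "peak_me")) "peak" else reg
      exc[[paste(mark, reg)]] <- cur
    }
  }
  exc <- do.call(rbind, exc)
  write_tsv(exc, file.path(out_dir, "exceedance.tsv"))
  res$exceedance <- exc

  # interspecies profile correlations (ortholog-aligned TSS matrices)
  prof_cor <- list()
  for (mark in c("H3K9ac", "H3K4me3")) {
    ma <- gene_profile_matrix(tracks[[paste0(mark, "_A")]], genes_a,
                              tss_window(), pc)
    mb <- gene_profile_matrix(tracks[[paste0(mark, "_B")]], genes_b,
                              tss_window(), pc)
    pc_ <- interspecies_profile_correlation(ma[omap$gene_id_a, , drop = FALSE],
                                            mb[omap$gene_id_b, , drop = FALSE])
    prof_cor[[mark]] <- pc_
  }
  ipc <- data.frame(bin = as.integer(names(prof_cor$H3K9ac$per_bin)),
                    H3K9ac = prof_cor$H3K9ac$per_bin,
                    H3K4me3 = prof_cor$H3K4me3$per_bin)
  write_tsv(ipc, file.path(out_dir, "interspecies_profile_correlation.tsv"))
  res$interspecies_profile_correlation <- ipc
  res$interspecies_overall_r <- c(H3K9ac = prof_cor$H3K9ac$overall,
                                  H3K4me3 = prof_cor$H3K4me3$overall)

  # merge the three difference vectors on common ortholog pairs
  common <- Reduce(intersect, list(p_ac$gene_id_a, p_me$gene_id_a,
                                   p_expr$gene_id_a))
  d_ac <- p_ac$d[match(common, p_ac$gene_id_a)]
  d_me <- p_me$d[match(common, p_me$gene_id_a)]
  d_expr <- p_expr$d[match(common, p_expr$gene_id_a)]
  ppl_log(verbose, "divergence", "%d ortholog pairs with all three signals",
          length(common))

  thr <- config$change_threshold
  mods <- classify_change_pair(d_ac, d_me, thr)
  ac_vs_expr <- classify_change_pair(d_expr, d_ac, thr)
  me_vs_expr <- classify_change_pair(d_expr, d_me, thr)
  triple <- triple_classification(d_ac, d_me, d_expr, thr)
  div_tab <- data.frame(
    gene_id_a = common,
    gene_id_b = p_ac$gene_id_b[match(common, p_ac$gene_id_a)],
    d_ac = d_ac, d_me = d_me, d_expr = d_expr,
    significant_ac = abs(d_ac) > thr, significant_me = abs(d_me) > thr,
    significant_expr = abs(d_expr) > thr,
    class_ac_me = as.character(mods$labels),
    class_expr_ac = as.character(ac_vs_expr$labels),
    class_expr_me = as.character(me_vs_expr$labels),
    triple = as.character(triple), stringsAsFactors = FALSE)
  write_tsv(div_tab, file.path(out_dir, "divergence.tsv"))
  res$divergence <- div_tab
  res$change_class_proportions <- list(ac_me = mods$proportions,
                                       expr_ac = ac_vs_expr$proportions,
                                       expr_me = me_vs_expr$proportions)

  gated <- c(H3K9ac = threshold_gated_correlation(d_expr, d_ac, thr),
             H3K4me3 = threshold_gated_correlation(d_expr, d_me, thr))
  cons <- rbind(cbind(consistency_vs_threshold(d_expr, d_ac, thr,
                                               config$threshold_grid),
                      mark = "H3K9ac"),
                cbind(consistency_vs_threshold(d_expr, d_me, thr,
                                               config$threshold_grid),
                      mark = "H3K4me3"))
  n_ext <- min(config$n_extreme, floor(length(common) / 2))
  enrc <- rbind(cbind(divergent_enrichment_curve(d_expr, d_ac, n_ext,
                                                 config$threshold_grid),
                      mark = "H3K9ac"),
                cbind(divergent_enrichment_curve(d_expr, d_me, n_ext,
                                                 config$threshold_grid),
                      mark = "H3K4me3"))
  write_tsv(cons, file.path(out_dir, "consistency.tsv"))
  write_tsv(enrc, file.path(out_dir, "enrichment_curve.tsv"))
  res$gated_correlation <- gated
  res$consistency <- cons
  res$enrichment_curve <- enrc

  # Lowess-divergent extraction and cross-mark overlap
  n_side <- min(config$n_per_side, floor(nrow(p_ac) / 2),
                floor(nrow(p_me) / 2))
  low_ac <- lowess_divergent_genes(p_ac$value_a, p_ac$value_b,
                                   p_ac$gene_id_a, n_side, config$lowess_span)
  low_me <- lowess_divergent_genes(p_me$value_a, p_me$value_b,
                                   p_me$gene_id_a, n_side, config$lowess_span)
  both_a_high <- hypergeom_enrichment(low_ac$set_a_high, low_me$set_a_high,
                                      union(p_ac$gene_id_a, p_me$gene_id_a))
  res$lowess <- list(ac = low_ac, me = low_me, overlap_a_high = both_a_high)

  # interspecies conservation of the disparity ratio
  disp_b <- disparity_ratios(ac_peak_b, me_peak_b, genes_b,
                             config$min_gene_length)
  ra <- disp$ratio[match(omap$gene_id_a, disp$gene_id)]
  rb <- disp_b$ratio[match(omap$gene_id_b, disp_b$gene_id)]
  okr <- !is.na(ra) & !is.na(rb)
  res$ratio_conservation_r <- cor(ra[okr], rb[okr])

  # -- stage: summary --------------------------------------------------------
  pick_p <- function(cl, sec) {
    row <- enr[enr$class_name == cl & enr$sector == sec, ]
    if (nrow(row) == 0) NA_real_ else row$p_value[1]
  }
  summary <- list(
    n_genes = config$sim$n_genes,
    n_ortholog_pairs = nrow(omap),
    n_divergence_pairs = length(common),
    fragment_lengths = as.list(setNames(res$fragment_lengths$fragment_length,
                                        res$fragment_lengths$sample)),
    strand_correlations = as.list(setNames(
      res$fragment_lengths$strand_correlation,
      res$fragment_lengths$sample)),
    concordance_percent = res$concordance,
    opn_high_ac_p = pick_p("OPN", "high_ac"),
    dpn_high_me_p = pick_p("DPN", "high_me"),
    interspecies_overall_r = as.list(res$interspecies_overall_r),
    ratio_conservation_r = res$ratio_conservation_r,
    r_dac_dme = cor(d_ac, d_me),
    change_class_proportions = lapply(res$change_class_proportions, as.list),
    gated_correlation = as.list(gated))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$summary <- summary
  make_report(out_dir)
  invisible(res)
}

#' Assemble a human-readable markdown report from pipeline outputs
#'
#' Walks the artifact files written by [run_pipeline()] and summarizes each
#' analysis; missing artifacts are listed as absent rather than failing.
#'
#' @param out_dir Pipeline output directory.
#' @return Path of the written `report.md`, invisibly.
#' @export
make_report <- function(out_dir) {
  lines <- c("# Comparative chromatin analysis report", "")
  have <- function(f) file.exists(file.path(out_dir, f))
  tsv <- function(f) read.delim(file.path(out_dir, f))
  section <- function(title, f, body) {
    if (have(f)) c(sprintf("## %s", title), "", body(), "")
    else c(sprintf("## %s", title), "", sprintf("*Artifact `%s` absent.*", f), "")
  }
  lines <- c(lines, section("Fragment lengths", "fragment_lengths.tsv", function() {
    d <- tsv("fragment_lengths.tsv")
    sprintf("- %s: %d bp (strand r = %.3f)", d$sample, d$fragment_length,
            d$strand_correlation)
  }))
  lines <- c(lines, section("Average TSS profiles", "profiles_tss.tsv", function() {
    d <- tsv("profiles_tss.tsv")
    c(sprintf("- H3K9ac peak at %+d bp from TSS", d$bin[which.max(d$H3K9ac)]),
      sprintf("- H3K4me3 peak at %+d bp from TSS", d$bin[which.max(d$H3K4me3)]))
  }))
  lines <- c(lines, section("Nucleosome-level expression correlation",
                            "nucleosome_expression_correlation.tsv", function() {
    d <- tsv("nucleosome_expression_correlation.tsv")
    c(sprintf("- H3K9ac correlation maximal at nucleosome %+d",
              d$index[which.max(d$H3K9ac)]),
      sprintf("- H3K4me3 correlation maximal at nucleosome %+d",
              d$index[which.max(d$H3K4me3)]))
  }))
  lines <- c(lines, section("Disparity sectors", "disparity.tsv", function() {
    d <- tsv("disparity.tsv")
    tab <- table(d$sector)
    sprintf("- %s: %d genes", names(tab), as.integer(tab))
  }))
  lines <- c(lines, section("Class enrichment", "enrichment.tsv", function() {
    d <- tsv("enrichment.tsv")
    top <- d[order(d$p_value), ][seq_len(min(6, nrow(d))), ]
    sprintf("- %s in %s: %s, fe %.0f%%, p = %.2e", top$class_name, top$sector,
            top$direction, top$fe, top$p_value)
  }))
  lines <- c(lines, section("Interspecies profile correlation",
                            "interspecies_profile_correlation.tsv", function() {
    d <- tsv("interspecies_profile_correlation.tsv")
    sprintf("- mean per-bin r: H3K9ac %.2f, H3K4me3 %.2f",
            mean(d$H3K9ac, na.rm = TRUE), mean(d$H3K4me3, na.rm = TRUE))
  }))
  lines <- c(lines, section("Divergence exceedance", "exceedance.tsv", function() {
    d <- tsv("exceedance.tsv")
    at1 <- d[abs(d$threshold - 1) < 1e-9, ]
    sprintf("- %s %s: %.1f%% of genes beyond 2-fold", at1$mark, at1$region,
            at1$percent)
  }))
  lines <- c(lines, section("Change classification and expression coupling",
                            "divergence.tsv", function() {
    d <- tsv("divergence.tsv")
    tab <- function(col) {
      t <- table(d[[col]])
      paste(sprintf("%s %.0f%%", names(t), 100 * as.numeric(t) / nrow(d)),
            collapse = ", ")
    }
    c(sprintf("- H3K9ac vs H3K4me3 changes: %s", tab("class_ac_me")),
      sprintf("- expression vs H3K9ac: %s", tab("class_expr_ac")),
      sprintf("- expression vs H3K4me3: %s", tab("class_expr_me")),
      sprintf("- triple classification: %s", tab("triple")))
  }))
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
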