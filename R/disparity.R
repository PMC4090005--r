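# The per-gene acetylation/methylation disparity statistic, ranked sectors,
# and hypergeometric gene-class enrichment.

#' Per-gene log2(H3K9ac / H3K4me3) disparity ratios
#'
#' Joins acetylation and methylation region signals; genes shorter than
#' `min_gene_length` or with either signal invalid are left unassigned with an
#' undefined ratio.
#'
#' @param ac,me Region-signal data.frames from [region_means()] or
#'   [nucleosome_levels()]-derived tables (gene_id, value, valid).
#' @param genes Gene annotation (for lengths).
#' @param min_gene_length Minimum gene length, bp (default 700).
#' @return data.frame(gene_id, ac, me, ratio, sector) with sector
#'   "unassigned" throughout (see [assign_sectors()]).
#' @export
disparity_ratios <- function(ac, me, genes, min_gene_length = 700L) {
  ids <- genes$gene_id
  a <- ac$value[match(ids, ac$gene_id)]
  m <- me$value[match(ids, me$gene_id)]
  av <- if ("valid" %in% names(ac)) ac$valid[match(ids, ac$gene_id)] else !is.na(a)
  mv <- if ("valid" %in% names(me)) me$valid[match(ids, me$gene_id)] else !is.na(m)
  ok <- !is.na(av) & !is.na(mv) & av & mv & genes$length >= min_gene_length
  ratio <- ifelse(ok, a - m, NA_real_)
  data.frame(gene_id = ids, ac = a, me = m, ratio = ratio,
             sector = "unassigned", stringsAsFactors = FALSE)
}

#' Rank genes by disparity ratio into three sectors
#'
#' Genes with a defined ratio are ranked (descending); the top `sector_size`
#' become `high_ac`, the bottom `sector_size` become `high_me`, and the
#' `sector_size` genes centered on the median rank become `mid`. Remaining
#' genes stay `unassigned`. Ties are broken by gene id, making the partition
#' invariant to input order.
#'
#' @param records Output of [disparity_ratios()].
#' @param sector_size Genes per sector (default 1200).
#' @export
assign_sectors <- function(records, sector_size = 1200L) {
  def <- which(!is.na(records$ratio))
  m <- length(def)
  if (m < 3L * sector_size)
    stop("too few genes with defined ratio (", m, ") for 3 sectors of ",
         sector_size)
  ord <- def[order(-records$ratio[def], records$gene_id[def])]
  sector <- records$sector
  sector[ord[seq_len(sector_size)]] <- "high_ac"
  sector[ord[(m - sector_size + 1L):m]] <- "high_me"
  mid_start <- floor((m - sector_size) / 2) + 1L
  sector[ord[mid_start:(mid_start + sector_size - 1L)]] <- "mid"
  records$sector <- sector
  records
}

#' Hypergeometric enrichment/depletion of a gene class in a sector
#'
#' One-sided hypergeometric test: enrichment `P[X >= k]`, depletion
#' `P[X <= k]` with `X ~ Hypergeometric(N, K, n)`. Fold enrichment is
#' expressed as percent deviation from the expected overlap `n K / N`.
#'
#' @param sector_genes Character vector (the drawn set).
#' @param class_genes Character vector (the marked set).
#' @param universe Character vector of all genes.
#' @return One-row data.frame with N, K, n, k, p_enrich, p_deplete, p_value,
#'   fe (percent), direction.
#' @export
hypergeom_enrichment <- function(sector_genes, class_genes, universe) {
  if (length(sector_genes) == 0 || length(class_genes) == 0)
    stop("empty sector or class")
  if (!all(sector_genes %in% universe) || !all(class_genes %in% universe))
    stop("sector and class must be subsets of the universe")
  N <- length(universe)
  K <- length(class_genes)
  n <- length(sector_genes)
  k <- length(intersect(sector_genes, class_genes))
  p_enrich <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_deplete <- phyper(k, K, N - K, n, lower.tail = TRUE)
  expected <- n * K / N
  fe <- 100 * (k / expected - 1)
  direction <- if (fe >= 0) "enriched" else "depleted"
  data.frame(N = N, K = K, n = n, k = k,
             p_enrich = p_enrich, p_deplete = p_deplete,
             p_value = if (fe >= 0) p_enrich else p_deplete,
             fe = fe, direction = direction, stringsAsFactors = FALSE)
}

#' Enrichment of every class in every sector
#'
#' @param records Sector-assigned disparity records.
#' @param classes Class table (gene_id, class_name).
#' @param sectors Sector names to test.
#' @return data.frame with one row per (class, sector).
#' @export
sector_enrichment <- function(records, classes,
                              sectors = c("high_ac", "mid", "high_me")) {
  universe <- records$gene_id[!is.na(records$ratio)]
  out <- list()
  for (cl in unique(classes$class_name)) {
    cg <- intersect(classes$gene_id[classes$class_name == cl], universe)
    if (length(cg) == 0) next
    for (sec in sectors) {
      sg <- records$gene_id[records$sector == sec]
      row <- hypergeom_enrichment(sg, cg, universe)
      out[[length(out) + 1L]] <- cbind(
        data.frame(class_name = cl, sector = sec, stringsAsFactors = FALSE), row)
    }
  }
  do.call(rbind, out)
}

#' Fraction of genes with concordant modification levels
#'
#' Percent of defined-ratio genes whose ratio lies within `cutoff` of the
#' median ratio.
#'
#' @param records Disparity records.
#' @param cutoff Log2 half-width (default 0.5, ~1.4-fold).
#' @export
concordance_fraction <- function(records, cutoff = 0.5) {
  r <- records$ratio[!is.na(records$ratio)]
  if (length(r) == 0) stop("no defined ratios")
  100 * mean(abs(r - median(r)) <= cutoff)
}

#' Per-class mean acetylation and methylation
#'
#' @param records Disparity records (uses the ac/me columns).
#' @param classes Class table.
#' @return list(means = data.frame(class_name, mean_ac, mean_me, n_genes),
#'   correlation = across-class Pearson r of the means).
#' @export
group_mean_disparity <- function(records, classes) {
  out <- list()
  for (cl in unique(classes$class_name)) {
    sel <- records[records$gene_id %in%
                     classes$gene_id[classes$class_name == cl], ]
    sel <- sel[!is.na(sel$ac) & !is.na(sel$me), ]
    if (nrow(sel) == 0) {
      warning("class ", cl, " has no genes with valid signals; dropped")
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      class_name = cl, mean_ac = mean(sel$ac), mean_me = mean(sel$me),
      n_genes = nrow(sel), stringsAsFactors = FALSE)
  }
  means <- do.call(rbind, out)
  corr <- if (nrow(means) >= 3) cor(means$mean_ac, means$mean_me) else NA_real_
  list(means = means, correlation = corr)
}
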