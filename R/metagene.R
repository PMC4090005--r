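# Gene-anchored binned profiles, metagene traces, nucleosome-level signals and
# named-region means.

#' Define a gene-anchored profile window
#'
#' @param anchor "TSS" or "TTS".
#' @param start,end Signed bp relative to the anchor, half-open, counted along
#'   the direction of transcription.
#' @param bin Bin width, bp; `(end - start)` must be divisible by `bin`.
#' @export
window_def <- function(anchor = c("TSS", "TTS"), start, end, bin = 20L) {
  anchor <- match.arg(anchor)
  if (end <= start) stop("window end must exceed start")
  if ((end - start) %% bin != 0) stop("window width not divisible by bin")
  list(anchor = anchor, start = as.integer(start), end = as.integer(end),
       bin = as.integer(bin))
}

#' Standard TSS window: -500 to +900, 20 bp bins
#' @export
tss_window <- function() window_def("TSS", -500L, 900L, 20L)

#' Standard TTS window: -400 to +200, 20 bp bins
#' @export
tts_window <- function() window_def("TTS", -400L, 200L, 20L)

#' Named gene-region definitions
#'
#' The fixed regions used throughout the analysis: `prom` (TSS -320..-160),
#' `peak_ac` (TSS 0..+140), `peak_me` (TSS +100..+580), `end` (TTS -260..+60),
#' `orf_broad` (TSS -60..+580, essentially nucleosomes +1 to +4) and
#' `peak_ac_h3norm` (TSS -60..+140).
#'
#' @param name Region name.
#' @export
region_def <- function(name = c("prom", "peak_ac", "peak_me", "end",
                                "orf_broad", "peak_ac_h3norm")) {
  name <- match.arg(name)
  co <- switch(name,
    prom = c("TSS", -320L, -160L),
    peak_ac = c("TSS", 0L, 140L),
    peak_me = c("TSS", 100L, 580L),
    end = c("TTS", -260L, 60L),
    orf_broad = c("TSS", -60L, 580L),
    peak_ac_h3norm = c("TSS", -60L, 140L))
  list(name = name, anchor = co[1], start = as.integer(co[2]),
       end = as.integer(co[3]))
}

gene_anchor <- function(genes, anchor) {
  if (anchor == "TSS") genes$tss else genes$tts
}

#' Per-gene binned profile matrix
#'
#' Lays the window out in transcription orientation for every gene (genomic
#' coordinates are reverse-mapped for `-` strand genes) and reduces each bin
#' of the per-base track. Given a linear track each bin is
#' `log2(mean(linear) + pseudocount)`; given a log2 track it is the mean of
#' the log2 values (the mode is recorded as an attribute). Bins that extend
#' beyond the chromosome are masked (NA), not truncated.
#'
#' @param track A [coverage_track()].
#' @param genes Gene annotation data.frame.
#' @param window A [window_def()].
#' @param pseudocount Pseudocount used in "log2 of mean" mode.
#' @return genes x bins numeric matrix; rownames gene ids, colnames the bin
#'   start offsets; attributes `window` and `mode`.
#' @export
gene_profile_matrix <- function(track, genes, window = tss_window(),
                                pseudocount = 0.1) {
  unknown <- setdiff(unique(genes$chrom), names(track$signal))
  if (length(unknown) > 0)
    stop("genes on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  mode <- if (track$scale == "linear") "log2_of_mean" else "mean_of_log2"
  W <- window$end - window$start
  bins <- W %/% window$bin
  rel <- window$start:(window$end - 1L)
  out <- matrix(NA_real_, nrow(genes), bins,
                dimnames = list(genes$gene_id,
                                window$start + (seq_len(bins) - 1L) * window$bin))
  anchor <- gene_anchor(genes, window$anchor)
  sgn <- ifelse(genes$strand == "+", 1L, -1L)
  for (chr in unique(genes$chrom)) {
    gi <- which(genes$chrom == chr)
    v <- track$signal[[chr]]
    L <- length(v)
    M <- matrix(anchor[gi], length(gi), W) + outer(sgn[gi], rel)
    ok <- M >= 0 & M < L
    Mi <- M + 1L
    Mi[!ok] <- 1L
    V <- matrix(v[Mi], length(gi), W)
    V[!ok] <- NA_real_
    dim(V) <- c(length(gi), window$bin, bins)
    bm <- colMeans(aperm(V, c(2L, 1L, 3L)))  # (genes, bins) bin means
    if (mode == "log2_of_mean") bm <- log2(bm + pseudocount)
    out[gi, ] <- bm
  }
  attr(out, "window") <- window
  attr(out, "mode") <- mode
  out
}

#' Average metagene trace
#'
#' Per-bin mean over unmasked cells, optionally over a gene subset.
#' @param mat A [gene_profile_matrix()].
#' @param gene_subset Optional character vector of gene ids.
#' @export
average_profile <- function(mat, gene_subset = NULL) {
  if (!is.null(gene_subset)) {
    gene_subset <- intersect(gene_subset, rownames(mat))
    if (length(gene_subset) == 0) stop("empty gene subset")
    mat <- mat[gene_subset, , drop = FALSE]
  }
  if (nrow(mat) == 0) stop("empty gene subset")
  colMeans(mat, na.rm = TRUE)
}

#' Per-nucleosome modification levels
#'
#' Mean linear signal across each nucleosome interval, log2-transformed with a
#' pseudocount.
#'
#' @param track Linear [coverage_track()].
#' @param nucleosomes Nucleosome table (gene_id, index, chrom, start, end).
#' @param pseudocount Pseudocount before log2.
#' @return data.frame(gene_id, index, value).
#' @export
nucleosome_levels <- function(track, nucleosomes, pseudocount = 0.1) {
  if (track$scale != "linear")
    stop("nucleosome_levels expects a linear track")
  value <- numeric(nrow(nucleosomes))
  for (chr in unique(nucleosomes$chrom)) {
    i <- which(nucleosomes$chrom == chr)
    v <- track$signal[[chr]]
    L <- length(v)
    st <- nucleosomes$start[i]
    en <- nucleosomes$end[i]
    if (any(st < 0 | en > L)) stop("nucleosome interval outside chromosome")
    cs <- cumsum(c(0, v))
    value[i] <- log2((cs[en + 1L] - cs[st + 1L]) / (en - st) + pseudocount)
  }
  data.frame(gene_id = nucleosomes$gene_id, index = nucleosomes$index,
             value = value, stringsAsFactors = FALSE)
}

#' Per-gene mean signal over a named region
#'
#' The region is reduced through the same 20-bp binning as the profile
#' matrices (all named regions are aligned to the 20-bp grid) and the bin
#' values averaged, so region means are consistent with the corresponding
#' profile-matrix bins. A gene is flagged invalid when any bin is masked
#' (region beyond the chromosome) or when the region extends beyond the gene
#' (TSS-anchored regions require `length >= end`; TTS-anchored regions
#' `length >= -start`) - the exclusion that removes mostly short genes.
#'
#' @param track A [coverage_track()].
#' @param genes Gene annotation.
#' @param region A [region_def()] or compatible list.
#' @param pseudocount Pseudocount for linear tracks.
#' @param bin Bin width, bp.
#' @return data.frame(gene_id, region, value, valid); invalid values are NA.
#' @export
region_means <- function(track, genes, region, pseudocount = 0.1, bin = 20L) {
  w <- window_def(region$anchor, region$start, region$end, bin)
  mat <- gene_profile_matrix(track, genes, w, pseudocount = pseudocount)
  value <- rowMeans(mat)
  valid <- !is.na(value)
  if (region$anchor == "TSS" && region$end > 0)
    valid <- valid & genes$length >= region$end
  if (region$anchor == "TTS" && region$start < 0)
    valid <- valid & genes$length >= -region$start
  # genes lacking data: an all-zero linear region sits exactly at
  # log2(pseudocount) and carries no signal
  if (track$scale == "linear")
    valid <- valid & value > log2(pseudocount)
  value[!valid] <- NA_real_
  data.frame(gene_id = genes$gene_id, region = region$name, value = value,
             valid = valid, stringsAsFactors = FALSE)
}

#' Per-bin correlation of a profile matrix with a per-gene covariate
#'
#' @param mat A [gene_profile_matrix()] (or any genes x positions matrix).
#' @param y Per-gene values, named by gene id or aligned to `rownames(mat)`.
#' @param method "pearson" (default) or "spearman".
#' @param min_genes Minimum unmasked genes per bin; bins below are NA.
#' @return Named numeric vector of per-bin correlations.
#' @export
positional_correlation <- function(mat, y, method = c("pearson", "spearman"),
                                   min_genes = 3L) {
  method <- match.arg(method)
  if (!is.null(names(y))) y <- y[rownames(mat)]
  if (length(y) != nrow(mat)) stop("y must align with the matrix rows")
  apply(mat, 2, function(col) {
    ok <- !is.na(col) & !is.na(y)
    if (sum(ok) < min_genes) return(NA_real_)
    if (sd(col[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    cor(col[ok], y[ok], method = method)
  })
}
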