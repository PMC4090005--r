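# Expression quantification and expression-derived gene classifications.

#' Quantify per-gene expression from read counts
#'
#' RPKM-style: per replicate, `count / (length * total_mapped) * scale`
#' followed by `log2(. + pseudocount)`; the final value is the mean over
#' replicates. Invariant to uniform library scaling and to gene order.
#'
#' @param counts Integer matrix genes x replicates, rownames = gene ids.
#' @param gene_lengths Named vector of gene lengths, bp.
#' @param scale_constant RPKM-like constant (default 1e9).
#' @param pseudocount Added before log2.
#' @return data.frame(gene_id, value, rep1, rep2, ...).
#' @export
quantify_expression <- function(counts, gene_lengths, scale_constant = 1e9,
                                pseudocount = 0.1) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts need gene ids as rownames")
  len <- gene_lengths[rownames(counts)]
  if (any(is.na(len)) || any(len <= 0)) stop("missing or non-positive gene length")
  totals <- colSums(counts)
  if (any(totals == 0)) stop("replicate with zero total mapped reads")
  repvals <- sweep(counts, 2, totals, `/`) / len * scale_constant
  repvals <- log2(repvals + pseudocount)
  out <- data.frame(gene_id = rownames(counts),
                    value = rowMeans(repvals),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(repvals))
}

#' Classify genes by expression responsiveness
#'
#' Responsiveness is the standard deviation of a gene's expression across a
#' condition compendium; the top `n` genes are "responsive" and the bottom
#' `n` "non_responsive". Ties are broken by gene id order.
#'
#' @param compendium Numeric matrix conditions x genes.
#' @param n Genes per class (default 1000).
#' @return data.frame(gene_id, class_name) plus an `sd` attribute with the
#'   per-gene statistic.
#' @export
responsiveness_classes <- function(compendium, n = 1000L) {
  if (nrow(compendium) < 2) stop("compendium needs at least 2 conditions")
  if (2L * n > ncol(compendium))
    stop("n too large: responsive and non-responsive sets would overlap")
  s <- apply(compendium, 2, sd)
  ord <- order(-s, colnames(compendium))
  ids <- colnames(compendium)[ord]
  out <- rbind(
    data.frame(gene_id = ids[seq_len(n)], class_name = "responsive",
               stringsAsFactors = FALSE),
    data.frame(gene_id = ids[(length(ids) - n + 1L):length(ids)],
               class_name = "non_responsive", stringsAsFactors = FALSE))
  attr(out, "sd") <- s
  out
}

#' Top-k gene class from a score vector
#'
#' @param scores Named per-gene scores (e.g. periodicity probabilities).
#' @param k Class size (default 800).
#' @param name Class label.
#' @return data.frame(gene_id, class_name).
#' @export
top_k_class <- function(scores, k = 800L, name = "periodic") {
  if (k > length(scores)) stop("k exceeds the number of genes")
  ord <- order(-scores, names(scores))
  data.frame(gene_id = names(scores)[ord][seq_len(k)], class_name = name,
             stringsAsFactors = FALSE)
}
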