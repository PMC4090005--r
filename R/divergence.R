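# Interspecies comparison at orthologous genes: paired signals, divergence
# exceedance, Lowess-residual divergent-gene extraction, and threshold-based
# co-change classification. Differences are oriented species A - species B
# throughout.

#' Pair region signals across species and take differences
#'
#' Keeps only ortholog pairs whose signal is valid in both species; the
#' difference is `value_a - value_b` (log2 scale).
#'
#' @param signals_a,signals_b [region_means()] outputs for the two species.
#' @param ortholog_map data.frame(gene_id_a, gene_id_b), one-to-one.
#' @return data.frame(gene_id_a, gene_id_b, value_a, value_b, d).
#' @export
paired_region_signals <- function(signals_a, signals_b, ortholog_map) {
  ia <- match(ortholog_map$gene_id_a, signals_a$gene_id)
  ib <- match(ortholog_map$gene_id_b, signals_b$gene_id)
  va <- signals_a$value[ia]
  vb <- signals_b$value[ib]
  ok <- !is.na(va) & !is.na(vb)
  if ("valid" %in% names(signals_a)) ok <- ok & signals_a$valid[ia]
  if ("valid" %in% names(signals_b)) ok <- ok & signals_b$valid[ib]
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) stop("no ortholog pairs with valid signals in both species")
  data.frame(gene_id_a = ortholog_map$gene_id_a[ok],
             gene_id_b = ortholog_map$gene_id_b[ok],
             value_a = va[ok], value_b = vb[ok], d = va[ok] - vb[ok],
             stringsAsFactors = FALSE)
}

#' Interspecies profile correlation
#'
#' Per-bin Pearson correlation over ortholog-paired profile matrices, plus the
#' overall correlation over all unmasked (gene, bin) cells.
#'
#' @param matrix_a,matrix_b Profile matrices with rows aligned ortholog-wise
#'   (same dimensions and window).
#' @return list(per_bin, overall).
#' @export
interspecies_profile_correlation <- function(matrix_a, matrix_b) {
  if (!all(dim(matrix_a) == dim(matrix_b)))
    stop("profile matrices must share dimensions (ortholog-aligned rows)")
  if (nrow(matrix_a) < 3) stop("need at least 3 paired genes")
  per_bin <- vapply(seq_len(ncol(matrix_a)), function(j) {
    a <- matrix_a[, j]; b <- matrix_b[, j]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
    cor(a[ok], b[ok])
  }, numeric(1))
  names(per_bin) <- colnames(matrix_a)
  ok <- !is.na(matrix_a) & !is.na(matrix_b)
  overall <- cor(matrix_a[ok], matrix_b[ok])
  list(per_bin = per_bin, overall = overall)
}

#' Percent of genes whose |difference| exceeds each threshold
#'
#' @param differences Numeric vector of log2 differences.
#' @param thresholds Threshold grid (default 0 to 2 by 0.1).
#' @return data.frame(threshold, percent); monotone non-increasing.
#' @export
divergence_exceedance <- function(differences,
                                  thresholds = seq(0, 2, by = 0.1)) {
  d <- differences[!is.na(differences)]
  if (length(d) == 0) stop("no differences")
  data.frame(threshold = thresholds,
             percent = vapply(thresholds,
                              function(t) 100 * mean(abs(d) > t), numeric(1)))
}

#' Extract the most divergent genes from a Lowess fit
#'
#' Fits Lowess of `y` (species B) on `x` (species A), computes residuals
#' `y - fit(x)` and returns the `n_per_side` most negative residuals (species
#' A higher) and most positive residuals (species B higher). Deterministic
#' tie-break by gene id.
#'
#' @param x,y Paired signals for species A and B.
#' @param gene_ids Gene identifiers aligned with x/y.
#' @param n_per_side Genes per extracted set (default 800).
#' @param span Lowess span (default 0.3).
#' @param iter Robustness iterations (default 2).
#' @return list(set_a_high, set_b_high, residuals).
#' @export
lowess_divergent_genes <- function(x, y, gene_ids, n_per_side = 800L,
                                   span = 0.3, iter = 2L) {
  stopifnot(length(x) == length(y), length(x) == length(gene_ids))
  if (2L * n_per_side > length(x))
    stop("n_per_side too large for ", length(x), " genes")
  fit <- lowess(x, y, f = span, iter = iter)
  fitted <- approx(fit$x, fit$y, xout = x, rule = 2, ties = mean)$y
  resid <- y - fitted
  ord_hi <- order(-resid, gene_ids)
  ord_lo <- order(resid, gene_ids)
  list(set_b_high = gene_ids[ord_hi[seq_len(n_per_side)]],
       set_a_high = gene_ids[ord_lo[seq_len(n_per_side)]],
       residuals = setNames(resid, gene_ids))
}

#' Classify paired interspecies changes
#'
#' A change is significant when `|d| > threshold` (default 0.4 log2,
#' ~1.3-fold). Labels: `none` (neither significant), `only_first`,
#' `only_second`, `consistent` (both significant, same sign), `opposite`.
#'
#' @param d1,d2 Paired log2 differences.
#' @param threshold Significance threshold.
#' @return list(labels, proportions) - proportions sum to 1.
#' @export
classify_change_pair <- function(d1, d2, threshold = 0.4) {
  stopifnot(length(d1) == length(d2))
  s1 <- abs(d1) > threshold
  s2 <- abs(d2) > threshold
  labels <- rep("none", length(d1))
  labels[s1 & !s2] <- "only_first"
  labels[!s1 & s2] <- "only_second"
  labels[s1 & s2 & sign(d1) == sign(d2)] <- "consistent"
  labels[s1 & s2 & sign(d1) != sign(d2)] <- "opposite"
  lv <- c("none", "only_first", "only_second", "consistent", "opposite")
  labels <- factor(labels, levels = lv)
  props <- setNames(as.numeric(table(labels)) / length(labels), lv)
  list(labels = labels, proportions = props)
}

#' Correlation of paired differences gated on significance
#'
#' Pearson r over genes where both `|d_expr|` and `|d_mod|` exceed the
#' threshold.
#'
#' @param d_expr,d_mod Paired log2 differences.
#' @param threshold Gate (default 0.4).
#' @export
threshold_gated_correlation <- function(d_expr, d_mod, threshold = 0.4) {
  ok <- !is.na(d_expr) & !is.na(d_mod) &
    abs(d_expr) > threshold & abs(d_mod) > threshold
  if (sum(ok) < 3) stop("fewer than 3 genes pass the significance gate")
  cor(d_expr[ok], d_mod[ok])
}

#' Percent of sign-consistent changes vs modification threshold
#'
#' For each modification threshold `t`, among genes with `|d_expr| >
#' expr_threshold` and `|d_mod| > t`, the percent with matching signs.
#'
#' @param d_expr,d_mod Paired log2 differences.
#' @param expr_threshold Expression gate (default 0.4).
#' @param thresholds Modification threshold grid.
#' @return data.frame(threshold, percent, n); empty gates give NA.
#' @export
consistency_vs_threshold <- function(d_expr, d_mod, expr_threshold = 0.4,
                                     thresholds = seq(0, 2, by = 0.1)) {
  gated_e <- abs(d_expr) > expr_threshold
  rows <- lapply(thresholds, function(t) {
    ok <- gated_e & abs(d_mod) > t & !is.na(d_expr) & !is.na(d_mod)
    n <- sum(ok)
    pct <- if (n == 0) NA_real_ else
      100 * mean(sign(d_expr[ok]) == sign(d_mod[ok]))
    data.frame(threshold = t, percent = pct, n = n)
  })
  do.call(rbind, rows)
}

#' Fold enrichment of expression-divergent genes vs modification threshold
#'
#' Divergent = the `n_extreme` genes with the largest `|d_expr|`;
#' non-divergent = the `n_extreme` smallest. At each modification threshold
#' the fold is the count of divergent genes passing it over the count of
#' non-divergent genes passing it.
#'
#' @param d_expr,d_mod Paired log2 differences.
#' @param n_extreme Set size (default 1000).
#' @param thresholds Modification threshold grid.
#' @return data.frame(threshold, fold, n_divergent, n_nondivergent); zero
#'   denominators give NA fold.
#' @export
divergent_enrichment_curve <- function(d_expr, d_mod, n_extreme = 1000L,
                                       thresholds = seq(0, 2, by = 0.1)) {
  if (2L * n_extreme > length(d_expr))
    stop("n_extreme too large for ", length(d_expr), " genes")
  ord <- order(-abs(d_expr))
  div <- ord[seq_len(n_extreme)]
  nondiv <- rev(ord)[seq_len(n_extreme)]
  rows <- lapply(thresholds, function(t) {
    a <- sum(abs(d_mod[div]) > t)
    b <- sum(abs(d_mod[nondiv]) > t)
    data.frame(threshold = t, fold = if (b == 0) NA_real_ else a / b,
               n_divergent = a, n_nondivergent = b)
  })
  do.call(rbind, rows)
}

#' Classify genes by concurrent three-way interspecies variation
#'
#' Labels: `none` (no significant change in any parameter), `all_consistent`
#' (all three significant with the same sign), `ac_me_not_expr`,
#' `ac_expr_not_me`, `me_expr_not_ac` (the named pair significant and
#' sign-consistent, the third parameter not consistent with them), and a
#' residual `other`.
#'
#' @param d_ac,d_me,d_expr Paired log2 differences.
#' @param threshold Significance threshold (default 0.4).
#' @return Factor of labels, one per gene.
#' @export
triple_classification <- function(d_ac, d_me, d_expr, threshold = 0.4) {
  stopifnot(length(d_ac) == length(d_me), length(d_ac) == length(d_expr))
  sa <- abs(d_ac) > threshold
  sm <- abs(d_me) > threshold
  se <- abs(d_expr) > threshold
  same <- function(u, v) sign(u) == sign(v)
  labels <- rep("other", length(d_ac))
  labels[!sa & !sm & !se] <- "none"
  all_c <- sa & sm & se & same(d_ac, d_me) & same(d_me, d_expr)
  labels[all_c] <- "all_consistent"
  pair <- function(p1s, p2s, p1, p2, third_s, third) {
    p1s & p2s & same(p1, p2) & !(third_s & same(third, p1)) & !all_c
  }
  labels[pair(sa, sm, d_ac, d_me, se, d_expr)] <- "ac_me_not_expr"
  labels[pair(sa, se, d_ac, d_expr, sm, d_me)] <- "ac_expr_not_me"
  labels[pair(sm, se, d_me, d_expr, sa, d_ac)] <- "me_expr_not_ac"
  factor(labels, levels = c("none", "all_consistent", "ac_me_not_expr",
                            "ac_expr_not_me", "me_expr_not_ac", "other"))
}
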