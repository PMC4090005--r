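# Shared fixtures and independent oracles.

# small two-chromosome annotation for hand-built tests
tiny_genes <- function() {
  data.frame(
    gene_id = c("g1", "g2", "g3"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tss = c(1000L, 3500L, 800L),
    tts = c(2200L, 2300L, 1600L),
    length = c(1200L, 1200L, 800L),
    stringsAsFactors = FALSE)
}

tiny_sizes <- function() c(chr1 = 5000L, chr2 = 3000L)

# coverage track with constant value everywhere
const_track <- function(value, sizes = tiny_sizes(), scale = "linear") {
  coverage_track(lapply(sizes, function(L) rep(value, L)),
                 sample = "const", scale = scale)
}

# coverage track with seeded random integer signal
random_track <- function(sizes = tiny_sizes(), seed = 1, max_value = 20L) {
  set.seed(seed)
  coverage_track(lapply(sizes, function(L) {
    as.numeric(sample.int(max_value + 1L, L, replace = TRUE) - 1L)
  }), sample = "random", scale = "linear")
}

# a small but complete simulation, cheap enough for unit tests
quick_config <- function(...) {
  sim_config(n_genes = 120L, n_chroms = 2L, reads_per_sample = 5e4,
             rna_depth = 2e5, seed = 42L, ...)
}

# --- oracles --------------------------------------------------------------

# naive strand-shift scan: rank (or not) once, plain cor() per shift over the
# fixed overlap window; independent of the sliding-sum implementation
oracle_shift_scan <- function(fwd, rev, max_shift, method = "spearman") {
  x <- as.numeric(unlist(fwd$profile, use.names = FALSE))
  y <- as.numeric(unlist(rev$profile, use.names = FALSE))
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  n0 <- length(x) - max_shift
  rr <- vapply(0:max_shift, function(s)
    cor(x[1:n0], y[(1 + s):(n0 + s)]), numeric(1))
  list(offset = (0:max_shift)[which.max(rr)], correlations = rr)
}

# exhaustive hypergeometric enumeration: all n-subsets of an N-universe
oracle_hypergeom_enum <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  overlap <- colSums(subsets <= K)  # marked items are 1..K
  c(p_enrich = mean(overlap >= k), p_deplete = mean(overlap <= k))
}

# both one-sided tails for every feasible overlap k, by full enumeration
oracle_hypergeom_tails <- function(N, K, n) {
  overlap <- colSums(utils::combn(N, n) <= K)
  ks <- max(0L, n + K - N):min(n, K)
  data.frame(k = ks,
             p_enrich = vapply(ks, function(k) mean(overlap >= k), numeric(1)),
             p_deplete = vapply(ks, function(k) mean(overlap <= k), numeric(1)))
}

# independent three-way classification rule, written from the definition
oracle_triple_label <- function(a, m, e, t) {
  sig <- c(abs(a) > t, abs(m) > t, abs(e) > t)
  if (!any(sig)) return("none")
  if (all(sig) && sign(a) == sign(m) && sign(m) == sign(e))
    return("all_consistent")
  if (sig[1] && sig[2] && sign(a) == sign(m) &&
      !(sig[3] && sign(e) == sign(a))) return("ac_me_not_expr")
  if (sig[1] && sig[3] && sign(a) == sign(e) &&
      !(sig[2] && sign(m) == sign(a))) return("ac_expr_not_me")
  if (sig[2] && sig[3] && sign(m) == sign(e) &&
      !(sig[1] && sign(a) == sign(m))) return("me_expr_not_ac")
  "other"
}
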