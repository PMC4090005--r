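make_profiles <- function(reads, sizes = tiny_sizes())
  build_strand_profiles(reads, sizes)

test_that("strand profiles count first bases per strand", {
  reads <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                      pos = c(5L, 5L, 5L, 10L),
                      strand = c("+", "+", "+", "-"))
  p <- make_profiles(reads)
  expect_equal(p$fwd$profile$chr1[6], 3L)
  expect_equal(p$fwd$total_reads, 3L)
  expect_equal(p$rev$profile$chr2[11], 1L)
  expect_equal(sum(unlist(p$rev$profile)), 1L)

  empty <- make_profiles(reads[0, ])
  expect_equal(sum(unlist(empty$fwd$profile)), 0L)

  oob <- data.frame(chrom = "chr1", pos = 5000L, strand = "+")
  expect_error(make_profiles(oob), "out-of-bounds")
})

test_that("fragment-length scan matches the brute-force oracle", {
  set.seed(21)
  L <- 4000L
  base <- rpois(L, 0.5) + rbinom(L, 3, 0.05)
  # identical strands: offset 0, perfect correlation
  p0 <- list(profile = list(chr = base), strand = "+", total_reads = sum(base))
  est <- estimate_fragment_length(p0, p0, max_shift = 200)
  expect_equal(est$offset, 0L)
  expect_equal(est$corr_at_offset, 1, tolerance = 1e-12)

  # reverse profile delayed by exactly 100 bp
  rev <- list(profile = list(chr = c(numeric(100), base[1:(L - 100)])),
              strand = "-", total_reads = sum(base))
  est <- estimate_fragment_length(p0, rev, max_shift = 200)
  expect_equal(est$offset, 100L)
  ora <- oracle_shift_scan(p0, rev, 200)
  expect_equal(est$offset, ora$offset)
  expect_equal(unname(est$correlations), ora$correlations, tolerance = 1e-9)

  # random instances, both correlation flavours
  for (seed in 1:10) {
    set.seed(seed)
    f <- list(profile = list(c1 = rpois(1500, 0.4), c2 = rpois(800, 0.6)))
    r <- list(profile = list(c1 = rpois(1500, 0.4), c2 = rpois(800, 0.6)))
    for (m in c("spearman", "pearson")) {
      est <- estimate_fragment_length(f, r, max_shift = 120, method = m)
      ora <- oracle_shift_scan(f, r, 120, method = m)
      expect_equal(est$offset, ora$offset)
      expect_equal(unname(est$correlations), ora$correlations,
                   tolerance = 1e-9)
    }
  }

  const <- list(profile = list(chr = rep(1, 1000)))
  expect_error(estimate_fragment_length(const, const, 100), "constant")
})

test_that("strand merging shifts half the offset each way and conserves mass", {
  reads <- data.frame(chrom = c("chr1", "chr1"), pos = c(100L, 224L),
                      strand = c("+", "-"))
  p <- make_profiles(reads)
  tr <- merge_strands(p$fwd, p$rev, 124L)
  expect_equal(tr$signal$chr1[163], 2)  # 100+62 and 224-62, both at base 162
  expect_equal(sum(tr$signal$chr1), 2)

  # offset 0 is the elementwise sum
  tr0 <- merge_strands(p$fwd, p$rev, 0L)
  expect_equal(tr0$signal$chr1,
               as.numeric(p$fwd$profile$chr1 + p$rev$profile$chr1))

  # conservation: total signal + counted edge losses = read count
  for (seed in 1:25) {
    set.seed(seed)
    n <- 500L
    reads <- data.frame(
      chrom = sample(names(tiny_sizes()), n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE))
    reads$pos <- as.integer(floor(runif(n) * tiny_sizes()[reads$chrom]))
    p <- make_profiles(reads)
    off <- sample(0:300, 1)
    tr <- merge_strands(p$fwd, p$rev, off)
    expect_equal(tr$total + tr$edge_dropped, n)
  }
})

test_that("library-size normalization equalizes totals to the lowest", {
  t1 <- const_track(1, c(chr1 = 100L))   # total 100
  t2 <- const_track(2, c(chr1 = 100L))   # total 200
  out <- normalize_to_lowest_total(list(t1, t2))
  expect_equal(out[[2]]$signal$chr1, rep(1, 100))
  expect_identical(normalize_to_lowest_total(list(t1))[[1]]$signal, t1$signal)

  tracks <- lapply(1:5, function(s) random_track(seed = s))
  out <- normalize_to_lowest_total(tracks)
  totals <- vapply(out, function(t) t$total, numeric(1))
  expect_equal(max(abs(totals / min(vapply(tracks, function(t) t$total,
                                           numeric(1))) - 1)), 0,
               tolerance = 1e-9)
  expect_error(normalize_to_lowest_total(list(const_track(0))), "zero-total")
})

test_that("log2 transform applies the pseudocount once and flags the scale", {
  tr <- coverage_track(list(chr1 = c(0, 3, 7)))
  lg <- log2_track(tr, pseudocount = 1)
  expect_equal(lg$signal$chr1, c(0, 2, 3))
  expect_equal(lg$scale, "log2")
  expect_error(log2_track(lg), "already log2")

  # monotone: higher linear signal stays higher after the transform
  a <- random_track(seed = 2)
  b <- coverage_track(lapply(a$signal, function(v) v + 1))
  la <- log2_track(a); lb <- log2_track(b)
  expect_true(all(unlist(lb$signal) > unlist(la$signal)))
})

test_that("moving-window smoothing centers the window and preserves mass", {
  ct <- const_track(4)
  expect_equal(smooth_track(ct, 140)$signal$chr1, ct$signal$chr1)

  v <- numeric(1001); v[501] <- 141
  tr <- coverage_track(list(chr1 = v))
  sm <- smooth_track(tr, 141)
  expect_equal(sm$signal$chr1[431:571], rep(1, 141))
  expect_equal(sum(sm$signal$chr1), 141)  # interior delta: mass preserved

  expect_error(smooth_track(coverage_track(list(chr1 = 1:50)), 60), "larger")
})

test_that("H3 normalization subtracts occupancy on the log scale", {
  mod <- log2_track(random_track(seed = 3), 1)
  expect_equal(unlist(h3_normalize(mod, mod)$signal), unlist(mod$signal) * 0)
  h3c <- log2_track(const_track(3), 1)  # constant log2 value 2
  out <- h3_normalize(mod, h3c)
  expect_equal(unlist(out$signal), unlist(mod$signal) - 2)
  expect_error(h3_normalize(mod, const_track(3)), "log2")
})
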