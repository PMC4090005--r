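# From stranded read positions to normalized, log-scale per-base coverage.

#' Build forward/reverse first-base profiles
#'
#' Scores the first sequenced base of every read into separate per-chromosome
#' integer count vectors for the forward and reverse strands.
#'
#' @param reads data.frame(chrom, pos, strand) with 0-based positions.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return list(fwd, rev): each of class `strand_profile` with fields
#'   `profile` (named list of integer vectors), `strand`, `total_reads`.
#' @export
build_strand_profiles <- function(reads, chrom_sizes) {
  unknown <- setdiff(unique(reads$chrom), names(chrom_sizes))
  if (length(unknown) > 0)
    stop("reads on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  oob <- reads$pos < 0 | reads$pos >= chrom_sizes[reads$chrom]
  if (any(oob))
    stop("out-of-bounds read position(s), e.g. ",
         reads$chrom[which(oob)[1]], ":", reads$pos[which(oob)[1]])
  one <- function(st) {
    sel <- reads[reads$strand == st, , drop = FALSE]
    prof <- lapply(names(chrom_sizes), function(chr) {
      p <- sel$pos[sel$chrom == chr]
      tabulate(p + 1L, nbins = chrom_sizes[[chr]])
    })
    names(prof) <- names(chrom_sizes)
    structure(list(profile = prof, strand = st, total_reads = nrow(sel)),
              class = "strand_profile")
  }
  list(fwd = one("+"), rev = one("-"))
}

# mid-ranks in O(L) for small nonnegative integer vectors (read counts);
# falls back to rank() otherwise
count_midranks <- function(v) {
  if (any(v < 0) || any(v != floor(v)) || max(v) > 1e6) return(rank(v))
  tab <- tabulate(as.integer(v) + 1L, nbins = as.integer(max(v)) + 1L)
  mid <- cumsum(tab) - (tab - 1) / 2
  mid[as.integer(v) + 1L]
}

#' Estimate the average fragment length by strand cross-correlation
#'
#' Shifts the reverse-strand first-base profile towards the forward-strand
#' profile one base at a time and reports the shift maximizing their
#' correlation. The default "spearman" flavour rank-transforms each
#' concatenated profile once (mid-ranks) and computes Pearson correlations of
#' the rank vectors over the fixed overlap window `[1, L - max_shift]`; ties in
#' the scan are broken towards the smaller shift.
#'
#' @param fwd,rev Strand profiles from [build_strand_profiles()].
#' @param max_shift Maximum shift scanned, bp.
#' @param method "spearman" (rank) or "pearson".
#' @return list(offset, corr_at_offset, correlations) where `correlations` is
#'   the full scan indexed by shift 0..max_shift.
#' @export
estimate_fragment_length <- function(fwd, rev, max_shift = 400L,
                                     method = c("spearman", "pearson")) {
  method <- match.arg(method)
  x <- as.numeric(unlist(fwd$profile, use.names = FALSE))
  y <- as.numeric(unlist(rev$profile, use.names = FALSE))
  if (length(x) == 0 || length(y) == 0) stop("empty strand profiles")
  if (length(x) != length(y)) stop("strand profiles differ in length")
  if (method == "spearman") {
    x <- count_midranks(x)
    y <- count_midranks(y)
  }
  L <- length(x)
  n0 <- L - max_shift
  if (n0 < 3) stop("profiles shorter than max_shift")
  xs <- x[seq_len(n0)]
  if (sd(xs) == 0) stop("constant forward profile: correlation undefined")
  Sx <- sum(xs); Sxx <- sum(xs * xs)
  cy <- cumsum(y); cy2 <- cumsum(y * y)
  shifts <- 0:max_shift
  # cross-products sum(xs * y[s+1 .. s+n0]) for all shifts in one FFT pass;
  # window sums/variances come from cumulative sums
  M <- stats::nextn(L, c(2L, 3L, 5L))
  fx <- stats::fft(c(xs, numeric(M - n0)))
  fy <- stats::fft(c(y, numeric(M - L)))
  Sxy <- Re(stats::fft(Conj(fx) * fy, inverse = TRUE))[1:(max_shift + 1L)] / M
  Sy <- cy[n0 + shifts] - c(0, cy[seq_len(max_shift)])
  Syy <- cy2[n0 + shifts] - c(0, cy2[seq_len(max_shift)])
  vy <- Syy - Sy * Sy / n0
  rr <- (Sxy - Sx * Sy / n0) / sqrt((Sxx - Sx * Sx / n0) * vy)
  rr[vy <= 0] <- NA_real_
  if (all(is.na(rr))) stop("constant reverse profile: correlation undefined")
  best <- which.max(rr)  # first maximum = smallest shift on ties
  list(offset = shifts[best], corr_at_offset = rr[best],
       correlations = setNames(rr, shifts))
}

#' Merge strand profiles into a per-base coverage track
#'
#' The forward profile is shifted right by `floor(offset/2)` and the reverse
#' profile left by the remainder, then the two are summed. Signal shifted past
#' chromosome edges is dropped and counted in the track's `edge_dropped` field.
#'
#' @param fwd,rev Strand profiles.
#' @param offset Estimated fragment length, bp (>= 0).
#' @param sample Sample label.
#' @return A linear-scale [coverage_track()].
#' @export
merge_strands <- function(fwd, rev, offset, sample = "sample") {
  stopifnot(offset >= 0)
  a <- offset %/% 2L
  b <- offset - a
  dropped <- 0
  signal <- lapply(names(fwd$profile), function(chr) {
    f <- fwd$profile[[chr]]
    r <- rev$profile[[chr]]
    L <- length(f)
    out <- numeric(L)
    if (a < L) out[(1L + a):L] <- f[1:(L - a)]
    if (b < L) out[1:(L - b)] <- out[1:(L - b)] + r[(1L + b):L]
    dropped <<- dropped + (if (a > 0) sum(f[(L - a + 1L):L]) else 0) +
      (if (b > 0) sum(r[1:b]) else 0)
    out
  })
  names(signal) <- names(fwd$profile)
  coverage_track(signal, sample = sample, scale = "linear",
                 fragment_length = offset, edge_dropped = dropped)
}

#' Normalize a set of tracks to the lowest total
#'
#' Each linear track is scaled by `min(totals) / own total`, so all
#' post-normalization totals equal the smallest library.
#'
#' @param tracks List of linear [coverage_track()]s.
#' @return List of tracks with equal totals.
#' @export
normalize_to_lowest_total <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  if (any(vapply(tracks, function(t) t$scale != "linear", logical(1))))
    stop("normalize_to_lowest_total requires linear tracks")
  totals <- vapply(tracks, function(t) t$total, numeric(1))
  if (any(totals <= 0)) stop("zero-total track cannot be normalized")
  target <- min(totals)
  lapply(tracks, function(t) {
    f <- target / t$total
    t$signal <- lapply(t$signal, function(v) v * f)
    t$total <- sum(vapply(t$signal, sum, numeric(1)))
    t
  })
}

#' Log2-transform a linear track
#'
#' `value <- log2(value + pseudocount)`; the scale flag is set to "log2".
#' @param track Linear [coverage_track()].
#' @param pseudocount Added before the log (default 0.1).
#' @export
log2_track <- function(track, pseudocount = 0.1) {
  if (track$scale != "linear") stop("track is already log2-transformed")
  track$signal <- lapply(track$signal, function(v) log2(v + pseudocount))
  track$scale <- "log2"
  track$total <- sum(vapply(track$signal, sum, numeric(1)))
  track
}

#' Smooth a track with a centered moving window
#'
#' An even window is widened by one base to center it (140 -> 141); edge
#' windows are truncated to the available bases.
#'
#' @param track A [coverage_track()].
#' @param window Window size, bp (default 140 as used for H3 occupancy).
#' @export
smooth_track <- function(track, window = 140L) {
  w <- as.integer(window)
  if (w %% 2L == 0L) w <- w + 1L
  h <- w %/% 2L
  track$signal <- lapply(track$signal, function(v) {
    L <- length(v)
    if (w > L) stop("smoothing window larger than chromosome")
    cs <- cumsum(c(0, v))
    i <- seq_len(L)
    lo <- pmax(i - h, 1L)
    hi <- pmin(i + h, L)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  track$total <- sum(vapply(track$signal, sum, numeric(1)))
  track
}

#' Normalize a modification track for H3 occupancy
#'
#' Subtracts the (log2, typically smoothed) H3 track from the log2
#' modification track, elementwise.
#'
#' @param mod Log2-scale modification [coverage_track()].
#' @param h3 Log2-scale (smoothed) H3 [coverage_track()].
#' @export
h3_normalize <- function(mod, h3) {
  if (mod$scale != "log2" || h3$scale != "log2")
    stop("h3_normalize requires log2-scale tracks")
  if (!identical(names(mod$signal), names(h3$signal)) ||
      !identical(track_lengths(mod), track_lengths(h3)))
    stop("tracks cover different chromosomes")
  mod$signal <- mapply(`-`, mod$signal, h3$signal, SIMPLIFY = FALSE)
  mod$sample <- paste0(mod$sample, "_h3norm")
  mod$total <- sum(vapply(mod$signal, sum, numeric(1)))
  mod
}

#' Build a normalized coverage track from reads in one call
#'
#' Convenience chain: strand profiles, fragment-length estimation (or a fixed
#' length), strand merging. Returns the linear track; the estimated offset and
#' strand correlation ride along in the track metadata.
#'
#' @param reads data.frame(chrom, pos, strand).
#' @param chrom_sizes Named integer vector.
#' @param fragment_length "auto" (default) or a fixed integer.
#' @param max_shift Scan limit for the estimator.
#' @param sample Sample label.
#' @export
build_track <- function(reads, chrom_sizes, fragment_length = "auto",
                        max_shift = 400L, sample = "sample") {
  prof <- build_strand_profiles(reads, chrom_sizes)
  if (identical(fragment_length, "auto")) {
    est <- estimate_fragment_length(prof$fwd, prof$rev, max_shift = max_shift)
    offset <- est$offset
    corr <- est$corr_at_offset
  } else {
    offset <- as.integer(fragment_length)
    corr <- NA_real_
  }
  tr <- merge_strands(prof$fwd, prof$rev, offset, sample = sample)
  tr$strand_correlation <- corr
  tr
}
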