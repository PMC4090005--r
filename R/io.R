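#' @importFrom utils read.delim write.table head
#' @importFrom stats cor sd median rnorm rpois runif setNames approx lowess
#'   phyper quantile rbinom
NULL

# All genomic coordinates are 0-based, half-open internally. BED input is
# interpreted per the BED standard; gene tables are documented as 0-based.

#' Read position convention for reverse-strand reads
#'
#' For a reverse-strand alignment spanning `[start, end)` the first sequenced
#' base is the last base of the interval, i.e. `end - 1`. Exposed as a named
#' constant so the convention is visible in code that depends on it.
#' @export
REV_READ_POS_OFFSET <- -1L

#' Read a gene annotation table
#'
#' Tab-separated file with header columns `gene_id`, `chrom`, `strand`,
#' `tss`, `tts` (0-based base positions). For `-` strand genes `tss > tts` in
#' genomic coordinates. A `length` column is derived as `|tts - tss|`.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns gene_id, chrom, strand, tss, tts, length.
#' @export
read_genes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "chrom", "strand", "tss", "tts")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("gene table ", path, " lacks columns: ", paste(missing, collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("gene table strand must be '+' or '-'")
  bad <- which(!is.finite(df$tss) | !is.finite(df$tts) | df$tss %% 1 != 0 |
                 df$tts %% 1 != 0 | df$tss < 0 | df$tts < 0)
  if (length(bad) > 0)
    stop("malformed coordinates in gene table at line(s): ",
         paste(head(bad + 1L, 5), collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in gene table: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  if (any(df$tss == df$tts)) stop("gene with tss == tts")
  if (any((df$strand == "+" & df$tts <= df$tss) |
          (df$strand == "-" & df$tts >= df$tss)))
    stop("strand/coordinate mismatch: '+' genes need tts > tss, '-' genes tts < tss")
  df <- df[, required]
  df$tss <- as.integer(df$tss)
  df$tts <- as.integer(df$tts)
  df$length <- abs(df$tts - df$tss)
  df
}

#' Write a gene annotation table
#' @param genes Data frame as returned by [read_genes()].
#' @param path Output TSV path.
#' @export
write_genes <- function(genes, path) {
  write.table(genes[, c("gene_id", "chrom", "strand", "tss", "tts")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read stranded aligned-read positions from BED6
#'
#' The scored position is the first sequenced base: BED `start` for `+`
#' alignments and `end - 1` for `-` alignments (see [REV_READ_POS_OFFSET]).
#'
#' @param path BED file path.
#' @param chrom_sizes Optional named integer vector; unknown chromosomes are a
#'   validation error when supplied.
#' @return data.frame with columns chrom, pos (0-based), strand.
#' @export
read_reads <- function(path, chrom_sizes = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("BED reads must carry a strand")
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(chrom), names(chrom_sizes))
    if (length(unknown) > 0)
      stop("unknown chromosome(s) in reads: ", paste(unknown, collapse = ", "))
  }
  # rtracklayer is 1-based closed; BED start = start - 1, BED end = end
  pos <- ifelse(strand == "+",
                GenomicRanges::start(gr) - 1L,
                GenomicRanges::end(gr) - 1L)
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             stringsAsFactors = FALSE)
}

#' Write reads as BED6 (fixed-width intervals)
#'
#' Inverse of [read_reads()] for simulated data: each read becomes a
#' `read_length` interval whose first sequenced base is `pos`.
#' @param reads data.frame(chrom, pos, strand).
#' @param path Output path.
#' @param read_length Interval width in bp.
#' @export
write_reads <- function(reads, path, read_length = 40L) {
  start0 <- ifelse(reads$strand == "+", reads$pos,
                   reads$pos - (read_length - 1L))
  gr <- GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, width = read_length),
    strand = reads$strand)
  gr$name <- sprintf("r%d", seq_along(gr))
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Construct a coverage track
#'
#' A coverage track holds one numeric vector of per-base signal per named
#' chromosome, plus metadata (sample name, scale, totals).
#' @param signal Named list of numeric vectors.
#' @param sample Sample label.
#' @param scale "linear" or "log2".
#' @param fragment_length Fragment length used when merging strands (or NA).
#' @param edge_dropped Signal mass dropped past chromosome edges when merging.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(signal, sample = "track", scale = c("linear", "log2"),
                           fragment_length = NA_real_, edge_dropped = 0) {
  scale <- match.arg(scale)
  stopifnot(is.list(signal), !is.null(names(signal)))
  structure(list(signal = signal, sample = sample, scale = scale,
                 fragment_length = fragment_length,
                 edge_dropped = edge_dropped,
                 total = sum(vapply(signal, sum, numeric(1)))),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track '%s': %d chromosome(s), scale=%s, total=%.4g\n",
              x$sample, length(x$signal), x$scale, x$total))
  invisible(x)
}

track_lengths <- function(track) vapply(track$signal, length, integer(1))

#' Write a coverage track to bedGraph
#'
#' Adjacent equal-value runs are merged. Zero runs are emitted by default so
#' that `read_bedgraph(write_bedgraph(x))` reproduces the track exactly.
#' @param track A [coverage_track()].
#' @param path Output path.
#' @param emit_zeros Emit zero-valued runs (default TRUE).
#' @export
write_bedgraph <- function(track, path, emit_zeros = TRUE) {
  if (any(vapply(track$signal, function(v) any(!is.finite(v)), logical(1))))
    stop("track contains non-finite values; cannot write bedGraph")
  runs <- lapply(names(track$signal), function(chr) {
    v <- track$signal[[chr]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- if (emit_zeros) rep(TRUE, length(r$values)) else r$values != 0
    data.frame(chrom = chr, start = starts[keep], end = ends[keep],
               score = r$values[keep], stringsAsFactors = FALSE)
  })
  runs <- do.call(rbind, runs)
  gr <- GenomicRanges::GRanges(runs$chrom,
                               IRanges::IRanges(runs$start, runs$end),
                               score = runs$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#' @param path bedGraph path.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param sample Sample label for the track.
#' @param scale Scale flag to stamp on the track.
#' @export
read_bedgraph <- function(path, chrom_sizes, sample = basename(path),
                          scale = "linear") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(chrom), names(chrom_sizes))
  if (length(unknown) > 0)
    stop("bedGraph chromosome(s) not in chrom_sizes: ",
         paste(unknown, collapse = ", "))
  signal <- lapply(names(chrom_sizes), function(chr) numeric(chrom_sizes[[chr]]))
  names(signal) <- names(chrom_sizes)
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  sc <- gr$score
  for (chr in unique(chrom)) {
    i <- which(chrom == chr)
    v <- signal[[chr]]
    for (j in i) v[st[j]:en[j]] <- sc[j]
    signal[[chr]] <- v
  }
  coverage_track(signal, sample = sample, scale = scale)
}

#' Read a typed TSV table
#'
#' @param path TSV path.
#' @param kind One of "nucleosomes" (gene_id, index, chrom, start, end),
#'   "orthologs" (gene_id_a, gene_id_b; one-to-one), "classes"
#'   (gene_id, class_name), "compendium" (conditions x genes matrix with a
#'   leading `condition` column).
#' @return Typed data.frame, or a numeric matrix for "compendium".
#' @export
read_table <- function(path, kind = c("nucleosomes", "orthologs", "classes",
                                      "compendium")) {
  kind <- match.arg(kind)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- function(cols) {
    missing <- setdiff(cols, names(df))
    if (length(missing) > 0)
      stop(kind, " table lacks columns: ", paste(missing, collapse = ", "))
  }
  switch(kind,
    nucleosomes = {
      need(c("gene_id", "index", "chrom", "start", "end"))
      if (any(df$index == 0)) stop("nucleosome index 0 is not allowed")
      if (any(df$end <= df$start)) stop("nucleosome with end <= start")
      if (anyDuplicated(df[, c("gene_id", "index")]))
        stop("duplicate (gene_id, index) in nucleosome table")
      df$index <- as.integer(df$index)
      df$start <- as.integer(df$start)
      df$end <- as.integer(df$end)
      df
    },
    orthologs = {
      need(c("gene_id_a", "gene_id_b"))
      if (anyDuplicated(df$gene_id_a) || anyDuplicated(df$gene_id_b))
        stop("ortholog map is not one-to-one")
      df
    },
    classes = {
      need(c("gene_id", "class_name"))
      df
    },
    compendium = {
      need("condition")
      m <- as.matrix(df[, setdiff(names(df), "condition"), drop = FALSE])
      rownames(m) <- df$condition
      storage.mode(m) <- "double"
      m
    })
}

#' Write a typed TSV table (inverse of [read_table()])
#' @param x Table (or matrix for kind "compendium").
#' @param path Output path.
#' @param kind Table kind, see [read_table()].
#' @export
write_table_kind <- function(x, path, kind = c("nucleosomes", "orthologs",
                                               "classes", "compendium")) {
  kind <- match.arg(kind)
  if (kind == "compendium") {
    df <- data.frame(condition = rownames(x), x, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
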