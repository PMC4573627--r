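# Binned RPM coverage tracks.
#
# A "read set" is a data.frame with columns chrom, pos (internal 0-based
# anchor position of the read), strand, plus attributes `mark` (label) and
# `N` (total mapped reads). A "binned track" is a list(mark, bin_size,
# values, N) where values is a named list of per-chromosome RPM vectors of
# length ceiling(chrom_length / bin_size).

#' Read aligned reads from a BED file
#'
#' Each alignment is reduced to a single anchor position: its strand-aware
#' 5'-most base by default, or the interval midpoint.
#'
#' @param path BED file of alignments (one histone-mark library).
#' @param mark mark label to attach.
#' @param read_anchor \code{"five_prime"} (default) or \code{"midpoint"}.
#' @return read-set data.frame (see package details).
#' @export
read_alignments_bed <- function(path, mark,
                                read_anchor = c("five_prime", "midpoint")) {
  read_anchor <- match.arg(read_anchor)
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  s0 <- GenomicRanges::start(gr) - 1
  e0 <- as.numeric(GenomicRanges::end(gr))
  pos <- if (read_anchor == "five_prime") {
    ifelse(strand == "+", s0, e0 - 1)
  } else {
    floor((s0 + e0 - 1) / 2)
  }
  rs <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   pos = pos, strand = strand, stringsAsFactors = FALSE)
  attr(rs, "mark") <- mark
  attr(rs, "N") <- nrow(rs)
  rs
}

#' Bin index of a genomic position
#'
#' Bin \code{i} covers the internal half-open interval
#' \code{[i * bin_size, (i + 1) * bin_size)}; indices are 0-based.
#'
#' @param position internal 0-based position(s).
#' @param bin_size bin width in bp.
#' @return integer bin index (vectorized).
#' @export
assign_bin <- function(position, bin_size = 100) {
  if (length(bin_size) != 1 || bin_size <= 0) stop("bin_size must be > 0")
  if (any(position < 0)) stop("positions must be >= 0")
  floor(position / bin_size)
}

n_bins <- function(chrom_length, bin_size) as.integer(ceiling(chrom_length / bin_size))

#' Count reads per fixed-width genomic bin
#'
#' @param readset read-set data.frame (chrom, pos columns).
#' @param genome named vector of chromosome lengths.
#' @param bin_size bin width in bp.
#' @param out_of_bounds what to do with reads beyond chromosome bounds:
#'   \code{"error"} (default) or \code{"drop"} with a warning.
#' @return list(counts = named list of integer vectors, n_assigned).
#' @export
bin_reads <- function(readset, genome, bin_size = 100,
                      out_of_bounds = c("error", "drop")) {
  out_of_bounds <- match.arg(out_of_bounds)
  bad_chrom <- !readset$chrom %in% names(genome)
  if (any(bad_chrom))
    stop("reads on chromosomes absent from the genome table: ",
         paste(unique(readset$chrom[bad_chrom]), collapse = ", "))
  oob <- readset$pos < 0 | readset$pos >= genome[readset$chrom]
  if (any(oob)) {
    if (out_of_bounds == "error")
      stop(sprintf("%d reads beyond chromosome bounds", sum(oob)))
    warning(sprintf("dropping %d reads beyond chromosome bounds", sum(oob)))
    readset <- readset[!oob, , drop = FALSE]
  }
  counts <- lapply(names(genome), function(ch) {
    nb <- n_bins(genome[[ch]], bin_size)
    pos <- readset$pos[readset$chrom == ch]
    if (length(pos) == 0) return(integer(nb))
    tabulate(assign_bin(pos, bin_size) + 1L, nbins = nb)
  })
  names(counts) <- names(genome)
  list(counts = counts, n_assigned = nrow(readset))
}

#' Normalize binned counts to reads per million per bin (RPM)
#'
#' Each bin value is \code{R_i * 1e6 / N} where \code{R_i} is the read count
#' in bin i and \code{N} the total mapped reads of the library.
#'
#' @param counts named list of integer count vectors (from [bin_reads()]).
#' @param N library size (total mapped reads).
#' @param mark mark label.
#' @param bin_size bin width in bp.
#' @return a binned track: list(mark, bin_size, values, N).
#' @export
rpm_normalize <- function(counts, N, mark = NA_character_, bin_size = 100) {
  if (length(N) != 1 || is.na(N) || N <= 0) stop("library size N must be > 0")
  if (is.list(counts)) values <- lapply(counts, function(v) v * 1e6 / N)
  else values <- list(counts * 1e6 / N)
  structure(list(mark = mark, bin_size = bin_size, values = values, N = N),
            class = "binned_track")
}

#' Build an RPM track from a read set
#'
#' @inheritParams bin_reads
#' @param N library size; defaults to the read set's own count.
#' @return a binned track.
#' @export
binned_track_from_reads <- function(readset, genome, bin_size = 100,
                                    N = attr(readset, "N"),
                                    out_of_bounds = c("error", "drop")) {
  if (is.null(N)) N <- nrow(readset)
  b <- bin_reads(readset, genome, bin_size, out_of_bounds)
  rpm_normalize(b$counts, N, mark = attr(readset, "mark"), bin_size = bin_size)
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned RPM track '%s': %d chromosome(s), bin %d bp, N = %d\n",
              x$mark, length(x$values), x$bin_size, as.integer(x$N)))
  invisible(x)
}

#' Export an RPM track as bedGraph
#' @param track binned track.
#' @param path output path.
#' @export
write_track_bedgraph <- function(track, path) {
  grl <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    GenomicRanges::GRanges(ch, IRanges::IRanges(
      start = (seq_along(v) - 1) * track$bin_size + 1,
      end = seq_along(v) * track$bin_size), score = v)
  })
  gr <- do.call(c, grl)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
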