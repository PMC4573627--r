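# Strand-oriented multi-mark profile features around anchor positions.
#
# Anchors are data.frames with columns id, chrom, pos (internal 0-based),
# strand. Feature vectors are mark-major: for each mark, 2k bins ordered
# u_k .. u_1, d_1 .. d_k in the transcriptional orientation of the anchor,
# where d_1 is the bin containing the anchor itself.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Anchor table at the TSSs of annotated transcripts
#' @param tx transcript data.frame from [read_annotations()].
#' @return anchors data.frame (id, chrom, pos, strand).
#' @export
anchors_from_transcripts <- function(tx) {
  data.frame(id = tx$id, chrom = tx$chrom, pos = tss_of(tx),
             strand = tx$strand, stringsAsFactors = FALSE)
}

# Bin indices (0-based, possibly out of range) read by one anchor, in
# feature order u_k..u_1, d_1..d_k.
profile_bin_indices <- function(anchor_bin, strand, k) {
  if (strand == "-") seq(anchor_bin + k, anchor_bin - k + 1)
  else seq(anchor_bin - k, anchor_bin + k - 1)
}

#' Extract the multi-mark profile feature vector of one anchor
#'
#' For minus-strand anchors the genomic bin order is reversed so that
#' "upstream" is transcriptionally upstream. Bins beyond the chromosome
#' ends contribute 0.
#'
#' @param tracks named list of binned tracks (one per mark), common bin size.
#' @param anchor single-row anchor data.frame.
#' @param k bins per side.
#' @param marks mark order; defaults to \code{names(tracks)}.
#' @return numeric vector of length \code{length(marks) * 2k}.
#' @export
extract_profile <- function(tracks, anchor, k, marks = names(tracks)) {
  m <- build_matrix(tracks, anchor, labels = NULL, k = k, marks = marks)
  m$X[1, ]
}

#' Build a profile feature matrix over many anchors
#'
#' @param tracks named list of binned tracks.
#' @param anchors anchors data.frame (id, chrom, pos, strand).
#' @param labels optional numeric labels in \{-1, +1\}, aligned with anchors.
#' @param k bins per side.
#' @param marks mark order; defaults to \code{names(tracks)}.
#' @return list(X, y, anchors, marks, k, bin_size) of class
#'   \code{profile_matrix}; X has one row per anchor, mark-major columns.
#' @export
build_matrix <- function(tracks, anchors, labels = NULL, k, marks = names(tracks)) {
  if (anyDuplicated(anchors$id)) stop("duplicated anchor ids")
  if (!all(marks %in% names(tracks)))
    stop("unknown mark(s): ",
         paste(setdiff(marks, names(tracks)), collapse = ", "))
  if (!is.null(labels)) {
    if (length(labels) != nrow(anchors))
      stop("labels length does not match anchors")
    if (!all(labels %in% c(-1, 1))) stop("labels must be -1 or +1")
  }
  bin_size <- tracks[[marks[1]]]$bin_size
  na <- nrow(anchors)
  X <- matrix(0, nrow = na, ncol = length(marks) * 2 * k)
  if (na > 0) {
    abin <- assign_bin(anchors$pos, bin_size)
    # per-anchor bin index matrix (na x 2k), strand-oriented
    offs_plus <- seq(-k, k - 1)
    idx <- outer(abin, offs_plus, `+`)
    neg <- anchors$strand == "-"
    if (any(neg)) {
      idx[neg, ] <- outer(abin[neg], rev(offs_plus) + 1, `+`)
    }
    for (mi in seq_along(marks)) {
      tr <- tracks[[marks[mi]]]
      if (tr$bin_size != bin_size) stop("tracks must share a bin size")
      cols <- (mi - 1) * 2 * k + seq_len(2 * k)
      for (ch in unique(anchors$chrom)) {
        rows <- which(anchors$chrom == ch)
        v <- tr$values[[ch]]
        if (is.null(v)) stop("chromosome absent from track: ", ch)
        ii <- idx[rows, , drop = FALSE]
        ok <- ii >= 0 & ii < length(v)
        vals <- matrix(0, nrow = length(rows), ncol = 2 * k)
        vals[ok] <- v[ii[ok] + 1L]
        X[rows, cols] <- vals
      }
    }
  }
  colnames(X) <- as.vector(vapply(marks, function(m)
    paste0(m, ".", c(paste0("u", k:1), paste0("d", 1:k))),
    character(2 * k)))
  structure(list(X = X, y = labels, anchors = anchors, marks = marks,
                 k = k, bin_size = bin_size), class = "profile_matrix")
}

#' Sample random genomic anchor positions
#'
#' Chromosomes are chosen proportional to length, positions uniformly, and
#' each anchor receives a uniformly random strand. Optionally rejects
#' positions falling inside exclusion intervals (e.g. around annotated
#' TSSs, see [tss_exclusion_zones()]).
#'
#' @param genome named vector of chromosome lengths.
#' @param n number of anchors.
#' @param seed integer seed (reproducible); NULL uses the current RNG state.
#' @param exclusion optional data.frame (chrom, start, end) of internal
#'   intervals to avoid.
#' @param id_prefix prefix for generated anchor ids.
#' @return anchors data.frame.
#' @export
sample_random_anchors <- function(genome, n, seed = NULL, exclusion = NULL,
                                  id_prefix = "rand") {
  if (n <= 0) stop("n must be > 0")
  if (!is.null(exclusion) && nrow(exclusion) > 0) {
    excl_total <- sum(vapply(names(genome), function(ch) {
      e <- exclusion[exclusion$chrom == ch, , drop = FALSE]
      if (nrow(e) == 0) return(0)
      ir <- IRanges::reduce(IRanges::IRanges(
        pmax(e$start, 0) + 1, pmin(e$end, genome[[ch]])))
      sum(IRanges::width(ir))
    }, numeric(1)))
    if (excl_total >= sum(genome))
      stop("exclusion zones cover the entire genome")
  }
  with_seed(seed, {
    out_chrom <- character(0); out_pos <- numeric(0); out_strand <- character(0)
    tries <- 0
    while (length(out_pos) < n) {
      tries <- tries + 1
      if (tries > 1000) stop("exclusion leaves too little sampleable space")
      need <- n - length(out_pos)
      m <- max(need, ceiling(need * 1.5))
      ch <- sample(names(genome), m, replace = TRUE, prob = genome / sum(genome))
      pos <- floor(runif(m) * genome[ch])
      strand <- sample(c("+", "-"), m, replace = TRUE)
      keep <- rep(TRUE, m)
      if (!is.null(exclusion) && nrow(exclusion) > 0) {
        for (i in seq_len(m)) {
          e <- exclusion[exclusion$chrom == ch[i], , drop = FALSE]
          if (nrow(e) > 0 && any(pos[i] >= e$start & pos[i] < e$end))
            keep[i] <- FALSE
        }
      }
      out_chrom <- c(out_chrom, ch[keep])
      out_pos <- c(out_pos, pos[keep])
      out_strand <- c(out_strand, strand[keep])
    }
    data.frame(id = paste0(id_prefix, seq_len(n)),
               chrom = out_chrom[seq_len(n)], pos = out_pos[seq_len(n)],
               strand = out_strand[seq_len(n)], stringsAsFactors = FALSE)
  })
}

#' Exclusion intervals around transcript TSSs
#' @param tx transcript data.frame.
#' @param distance half-width in bp around each TSS.
#' @return data.frame (chrom, start, end), internal coordinates.
#' @export
tss_exclusion_zones <- function(tx, distance) {
  pos <- tss_of(tx)
  data.frame(chrom = tx$chrom, start = pmax(pos - distance, 0),
             end = pos + distance + 1, stringsAsFactors = FALSE)
}

#' Metagene mean profile of one mark around anchors
#'
#' Per-bin arithmetic mean of strand-oriented RPM profiles across anchors,
#' over +/- W bp.
#'
#' @param tracks named list of binned tracks.
#' @param anchors anchors data.frame (at least one row).
#' @param mark mark label.
#' @param W half-window in bp (default 2000).
#' @return data.frame(offset, mean_rpm); offset is the bp offset of each
#'   bin start from the anchor, negative upstream.
#' @export
mean_profile <- function(tracks, anchors, mark, W = 2000) {
  if (nrow(anchors) == 0) stop("at least one anchor required")
  bin_size <- tracks[[mark]]$bin_size
  k <- as.integer(W / bin_size)
  m <- build_matrix(tracks, anchors, labels = NULL, k = k, marks = mark)
  data.frame(offset = seq(-k, k - 1) * bin_size,
             mean_rpm = colMeans(m$X))
}

#' Export a mean profile as TSV
#' @param profile data.frame from [mean_profile()].
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export anchors as BED6
#' @param anchors anchors data.frame.
#' @param path output path.
#' @export
write_anchors_bed <- function(anchors, path) {
  gr <- GenomicRanges::GRanges(anchors$chrom,
    IRanges::IRanges(start = anchors$pos + 1, width = 1),
    strand = anchors$strand)
  gr$name <- anchors$id
  gr$score <- 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
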