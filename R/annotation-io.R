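#' @importFrom stats rnorm rpois runif setNames aggregate p.adjust plogis
#'   glm binomial coef predict sd quantile median rbinom
#' @importFrom utils read.delim write.table head tail
NULL

# Internal coordinate convention, used everywhere inside the package:
# 0-based half-open [start, end). All printed/emitted coordinates are
# 1-based inclusive (GFF3, Table-style TSVs), converted at the I/O boundary.

#' Construct a table of genomic intervals
#'
#' Intervals use the package-internal 0-based half-open convention.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand character vector, each one of \code{"+"}, \code{"-"},
#'   \code{"*"} (unstranded).
#' @return data.frame with columns chrom, start, end, strand.
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  if (any(!df$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  if (any(df$start < 0) || any(df$start >= df$end))
    stop("intervals must satisfy 0 <= start < end")
  df
}

#' Read a chromosome-sizes table
#'
#' @param path two-column TSV (chromosome name, length in bp), no header.
#' @return named numeric vector of chromosome lengths.
#' @export
read_genome_table <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("chromosome sizes file must have two columns")
  len <- as.numeric(df[[2]])
  if (any(is.na(len)) || any(len <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(df[[1]])) stop("duplicate chromosome names")
  setNames(len, as.character(df[[1]]))
}

#' Write a chromosome-sizes table
#' @param genome named numeric vector of chromosome lengths.
#' @param path output path.
#' @export
write_genome_table <- function(genome, path) {
  write.table(data.frame(names(genome), as.integer(genome)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Light syntactic validation so parse errors carry a line number; the
# actual parsing is delegated to rtracklayer.
validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 9)
      stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields", i))
    if (!fields[7] %in% c("+", "-", ".", "?"))
      stop(sprintf("malformed GFF3 line %d: unknown strand symbol '%s'",
                   i, fields[7]))
    if (is.na(suppressWarnings(as.integer(fields[4]))) ||
        is.na(suppressWarnings(as.integer(fields[5]))))
      stop(sprintf("malformed GFF3 line %d: non-numeric coordinates", i))
  }
  invisible(length(lines))
}

#' Read gene or miRNA annotations from GFF3
#'
#' Protein-coding genes are records of type \code{gene} with their
#' \code{exon} children attached; miRNAs are records of type
#' \code{miRNA_primary_transcript} or \code{miRNA} (miRBase style) and are
#' treated as unspliced single intervals. Coordinates are converted from
#' GFF3 1-based inclusive to the internal 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @param kind_filter \code{"protein_coding"} or \code{"miRNA"}.
#' @return data.frame with columns id, chrom, start, end, strand, kind and a
#'   list-column \code{exons} (each element a data.frame of internal
#'   start/end pairs, sorted, possibly empty).
#' @export
read_annotations <- function(path, kind_filter = c("protein_coding", "miRNA")) {
  kind_filter <- match.arg(kind_filter)
  validate_gff3_lines(path)
  empty <- data.frame(id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), kind = character(),
                      stringsAsFactors = FALSE)
  empty$exons <- list()
  lines <- readLines(path, warn = FALSE)
  if (!any(!(lines == "" | startsWith(lines, "#")))) return(empty)
  gr <- rtracklayer::import(path, format = "gff3")
  types <- as.character(gr$type)
  sel_types <- if (kind_filter == "protein_coding") "gene"
               else c("miRNA_primary_transcript", "miRNA")
  parents <- gr[types %in% sel_types]
  if (length(parents) == 0) return(empty)
  ids <- as.character(parents$ID)
  if (any(is.na(ids)) || anyDuplicated(ids))
    stop("annotation records must carry unique ID attributes")
  out <- data.frame(
    id = ids,
    chrom = as.character(GenomicRanges::seqnames(parents)),
    start = GenomicRanges::start(parents) - 1,
    end = as.numeric(GenomicRanges::end(parents)),
    strand = as.character(GenomicRanges::strand(parents)),
    kind = kind_filter, stringsAsFactors = FALSE)
  exlist <- rep(list(data.frame(start = numeric(), end = numeric())),
                nrow(out))
  if (kind_filter == "protein_coding") {
    ex <- gr[types == "exon"]
    if (length(ex) > 0) {
      par <- vapply(ex$Parent, function(p) as.character(p)[1], character(1))
      exdf <- data.frame(parent = par,
                         start = GenomicRanges::start(ex) - 1,
                         end = as.numeric(GenomicRanges::end(ex)),
                         stringsAsFactors = FALSE)
      for (i in seq_len(nrow(out))) {
        e <- exdf[exdf$parent == out$id[i], c("start", "end")]
        if (nrow(e) > 0) {
          e <- e[order(e$start), , drop = FALSE]
          rownames(e) <- NULL
          exlist[[i]] <- e
        }
      }
    }
  }
  out$exons <- exlist
  out
}

#' Introns of an annotated transcript
#'
#' Introns are the gaps between consecutive exons; records without exon
#' children have no introns.
#'
#' @param tx single-row transcript as returned by [read_annotations()].
#' @return data.frame of internal start/end pairs (possibly empty).
#' @export
introns_of <- function(tx) {
  ex <- tx$exons[[1]]
  if (is.null(ex) || nrow(ex) < 2)
    return(data.frame(start = numeric(), end = numeric()))
  ex <- ex[order(ex$start), , drop = FALSE]
  data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1])
}

#' Transcription start site of annotated transcripts
#'
#' The 5'-most transcribed base: internal \code{start} on the plus strand,
#' \code{end - 1} on the minus strand.
#'
#' @param tx data.frame with chrom, start, end, strand columns (one or more
#'   rows).
#' @return numeric vector of internal 0-based TSS positions.
#' @export
tss_of <- function(tx) {
  if (any(!tx$strand %in% c("+", "-")))
    stop("tss_of requires stranded records")
  ifelse(tx$strand == "+", tx$start, tx$end - 1)
}

# --- coordinate strings -----------------------------------------------------

# "chr1:3961348-3961464(-)" (en-dash tolerated) -> internal interval.
# The span is 1-based inclusive, as printed in annotation tables.
parse_coord_string <- function(s) {
  s <- gsub("–", "-", s)
  m <- regmatches(s, regexec("^([^:]+):([0-9]+)-([0-9]+)\\(([-+])\\)$", s))[[1]]
  if (length(m) != 5)
    stop(sprintf("unparseable coordinate string '%s'", s))
  list(chrom = m[2], start = as.numeric(m[3]) - 1, end = as.numeric(m[4]),
       strand = m[5])
}

format_coord_string <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d(%s)", chrom, as.integer(start) + 1L, as.integer(end),
          strand)
}

# TSS interval strings print as (a, a+width): a fencepost pair whose
# difference is the bin width (100 bp in the published table). Internally
# the pair (a, b) denotes the half-open interval [a-1, b-1).
parse_tss_string <- function(s) {
  s <- gsub("–", "-", s)
  m <- regmatches(s, regexec("^([0-9]+)-([0-9]+)$", s))[[1]]
  if (length(m) != 3) stop(sprintf("unparseable TSS interval '%s'", s))
  list(start = as.numeric(m[2]) - 1, end = as.numeric(m[3]) - 1)
}

format_tss_string <- function(start, end) {
  sprintf("%d-%d", as.integer(start) + 1L, as.integer(end) + 1L)
}

empty_calls <- function() {
  data.frame(index = integer(), mirna_id = character(),
             mirna_name = character(), chrom = character(),
             mirna_start = numeric(), mirna_end = numeric(),
             strand = character(), tss_start = numeric(),
             tss_end = numeric(), score = numeric(), qvalue = numeric(),
             category = character(), stringsAsFactors = FALSE)
}

#' Read a prediction table of miRNA TSS calls
#'
#' Tab-separated with columns index, mirna_id, mirna_name, mirna_coords
#' (\code{chrom:start-end(strand)}, 1-based inclusive), strand, tss_coords
#' (fencepost pair, see Details), score, qvalue, category. En-dash
#' separators are normalized to ASCII hyphens.
#'
#' @details TSS interval strings are printed as \code{a-b} with
#'   \code{b - a} equal to the bin width; internally they become the
#'   half-open interval \code{[a-1, b-1)}.
#'
#' @param path TSV path.
#' @return data.frame of calls with internal coordinates.
#' @export
read_prediction_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) return(empty_calls())
  coords <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(parse_coord_string(df$mirna_coords[i]),
             error = function(e) stop(sprintf("row %d: %s", i, conditionMessage(e))))
  })
  tss <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(parse_tss_string(df$tss_coords[i]),
             error = function(e) stop(sprintf("row %d: %s", i, conditionMessage(e))))
  })
  data.frame(
    index = as.integer(df$index),
    mirna_id = as.character(df$mirna_id),
    mirna_name = as.character(df$mirna_name),
    chrom = vapply(coords, `[[`, character(1), "chrom"),
    mirna_start = vapply(coords, `[[`, numeric(1), "start"),
    mirna_end = vapply(coords, `[[`, numeric(1), "end"),
    strand = vapply(coords, `[[`, character(1), "strand"),
    tss_start = vapply(tss, `[[`, numeric(1), "start"),
    tss_end = vapply(tss, `[[`, numeric(1), "end"),
    score = if ("score" %in% names(df)) as.numeric(df$score) else NA_real_,
    qvalue = if ("qvalue" %in% names(df)) as.numeric(df$qvalue) else NA_real_,
    category = if ("category" %in% names(df)) as.character(df$category)
               else NA_character_,
    stringsAsFactors = FALSE)
}

#' Write a prediction table of miRNA TSS calls
#'
#' Inverse of [read_prediction_table()]; coordinates are re-emitted in the
#' printed conventions so that a read/write round trip is the identity.
#'
#' @param calls data.frame of calls (internal coordinates).
#' @param path optional output path; when NULL the TSV text is returned.
#' @return the TSV text, invisibly when written to a file.
#' @export
write_prediction_table <- function(calls, path = NULL) {
  header <- paste("index", "mirna_id", "mirna_name", "mirna_coords",
                  "strand", "tss_coords", "score", "qvalue", "category",
                  sep = "\t")
  rows <- character(0)
  if (nrow(calls) > 0) {
    rows <- vapply(seq_len(nrow(calls)), function(i) {
      paste(calls$index[i], calls$mirna_id[i], calls$mirna_name[i],
            format_coord_string(calls$chrom[i], calls$mirna_start[i],
                                calls$mirna_end[i], calls$strand[i]),
            calls$strand[i],
            format_tss_string(calls$tss_start[i], calls$tss_end[i]),
            ifelse(is.na(calls$score[i]), "NA",
                   format(calls$score[i], digits = 10)),
            ifelse(is.na(calls$qvalue[i]), "NA",
                   format(calls$qvalue[i], digits = 10)),
            calls$category[i], sep = "\t")
    }, character(1))
  }
  txt <- paste(c(header, rows, ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(c(header, rows), path)
    return(invisible(txt))
  }
  txt
}

#' Export TSS calls as BED6
#' @param calls data.frame of calls with a TSS interval.
#' @param path output BED path.
#' @export
write_calls_bed <- function(calls, path) {
  called <- calls[!is.na(calls$tss_start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    called$chrom,
    IRanges::IRanges(start = called$tss_start + 1, end = called$tss_end),
    strand = called$strand)
  gr$name <- called$mirna_name
  gr$score <- ifelse(is.na(called$score), 0, called$score)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
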