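# Shared in-code fixtures: toy tracks, tiny simulated studies, and genome
# mirroring used by the strand-symmetry checks.

toy_track <- function(values, mark = "M", bin_size = 100, N = 1e6,
                      chrom = "chr1") {
  if (!is.list(values)) values <- setNames(list(values), chrom)
  structure(list(mark = mark, bin_size = bin_size, values = values, N = N),
            class = "binned_track")
}

toy_readset <- function(chrom, pos, strand = "+", mark = "M") {
  rs <- data.frame(chrom = chrom, pos = pos,
                   strand = rep_len(strand, length(pos)),
                   stringsAsFactors = FALSE)
  attr(rs, "mark") <- mark
  attr(rs, "N") <- nrow(rs)
  rs
}

# Small end-to-end study shared by several files; sized to run in seconds.
tiny_study <- function(seed = 3, genome = c(chr1 = 1.5e6), n_genes = 200,
                       n_mirnas = 12, ...) {
  cfg <- sim_config(genome = genome, n_genes = n_genes, n_mirnas = n_mirnas,
                    seed = seed, ...)
  ann <- simulate_annotations(cfg)
  reads <- simulate_reads(cfg, ann)
  tracks <- tracks_from_readsets(reads, cfg$genome)
  list(cfg = cfg, ann = ann, reads = reads, tracks = tracks)
}

tiny_svm_config <- function(seed = 1)
  svm_config(C_grid = c(1, 10), gamma_grid = c(1e-3, 1e-2), cv_folds = 3,
             seed = seed)

# --- genome mirroring (reflection of every chromosome + strand flip) --------

mirror_pos <- function(pos, L) L - 1 - pos

mirror_anchors <- function(anchors, genome) {
  anchors$pos <- mirror_pos(anchors$pos, genome[anchors$chrom])
  anchors$strand <- ifelse(anchors$strand == "+", "-", "+")
  anchors
}

mirror_annotations <- function(tx, genome) {
  L <- genome[tx$chrom]
  s <- tx$start; e <- tx$end
  tx$start <- L - e
  tx$end <- L - s
  tx$strand <- ifelse(tx$strand == "+", "-", "+")
  if ("exons" %in% names(tx)) {
    tx$exons <- lapply(seq_len(nrow(tx)), function(i) {
      ex <- tx$exons[[i]]
      if (nrow(ex) == 0) return(ex)
      out <- data.frame(start = L[i] - ex$end, end = L[i] - ex$start)
      out[order(out$start), , drop = FALSE]
    })
  }
  tx
}

mirror_readsets <- function(readsets, genome) {
  lapply(readsets, function(rs) {
    out <- data.frame(chrom = rs$chrom,
                      pos = mirror_pos(rs$pos, genome[rs$chrom]),
                      strand = ifelse(rs$strand == "+", "-", "+"),
                      stringsAsFactors = FALSE)
    attr(out, "mark") <- attr(rs, "mark")
    attr(out, "N") <- attr(rs, "N")
    out
  })
}

# GFF3 text helpers for parser tests
write_gff3_lines <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}
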