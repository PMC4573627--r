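# High-level wiring shared by the command-line entry points and scripts.

#' Training matrix: gene-TSS positives vs random-position negatives
#'
#' Positives are profiles around every protein-coding gene TSS; negatives
#' are profiles around uniformly random genomic positions with random
#' strands (by default without any exclusion zone).
#'
#' @param tracks named list of binned tracks.
#' @param genes gene annotation data.frame.
#' @param genome named vector of chromosome lengths.
#' @param k bins per side (default 10).
#' @param n_random number of random negatives (default 10000).
#' @param seed seed for the negative sampling.
#' @param exclude_near_tss optional distance in bp; negatives are then
#'   rejected within this distance of an annotated gene TSS.
#' @param marks mark order; defaults to \code{names(tracks)}.
#' @return a labeled \code{profile_matrix} (+1 TSS, -1 random).
#' @export
build_training_matrix <- function(tracks, genes, genome, k = 10,
                                  n_random = 10000, seed = 1,
                                  exclude_near_tss = NULL,
                                  marks = names(tracks)) {
  pos <- anchors_from_transcripts(genes)
  excl <- if (!is.null(exclude_near_tss))
    tss_exclusion_zones(genes, exclude_near_tss) else NULL
  neg <- sample_random_anchors(genome, n_random, seed = seed,
                               exclusion = excl, id_prefix = "neg")
  anchors <- rbind(pos, neg)
  labels <- c(rep(1, nrow(pos)), rep(-1, nrow(neg)))
  build_matrix(tracks, anchors, labels, k = k, marks = marks)
}

#' Train the TSS classifier from tracks and gene annotations
#'
#' Builds the positive/negative matrix, takes a stratified random half for
#' training (mirroring the half/half evaluation design) or the full matrix,
#' and fits the grid-searched RBF-SVM.
#'
#' @inheritParams build_training_matrix
#' @param config an [svm_config()].
#' @param train_on \code{"all"} (default, used before scanning) or
#'   \code{"half"} (hold the other half out for evaluation).
#' @return list(model, matrix, split) — split is NULL when training on all.
#' @export
train_tss_classifier <- function(tracks, genes, genome, k = 10,
                                 n_random = 10000, seed = 1,
                                 config = svm_config(seed = seed),
                                 train_on = c("all", "half"),
                                 exclude_near_tss = NULL,
                                 marks = names(tracks)) {
  train_on <- match.arg(train_on)
  pm <- build_training_matrix(tracks, genes, genome, k, n_random, seed,
                              exclude_near_tss, marks)
  if (train_on == "half") {
    sp <- split_half(pm, seed = seed)
    list(model = train_svm(sp$train, config), matrix = pm, split = sp)
  } else {
    list(model = train_svm(pm, config), matrix = pm, split = NULL)
  }
}

#' Load per-mark alignment BED files from a directory
#'
#' Files named \code{<mark>.bed}; marks are ordered alphabetically unless
#' \code{marks} is given.
#'
#' @param dir directory of BED files.
#' @param marks optional mark order.
#' @param read_anchor read anchor rule, see [read_alignments_bed()].
#' @return named list of read sets.
#' @export
read_mark_beds <- function(dir, marks = NULL,
                           read_anchor = c("five_prime", "midpoint")) {
  files <- sort(list.files(dir, pattern = "\\.bed$", full.names = TRUE))
  if (length(files) == 0) stop("no .bed files in ", dir)
  found <- sub("\\.bed$", "", basename(files))
  if (!is.null(marks)) {
    missing <- setdiff(marks, found)
    if (length(missing) > 0)
      stop("missing mark BED file(s): ", paste(missing, collapse = ", "))
    files <- files[match(marks, found)]
    found <- marks
  }
  rs <- lapply(seq_along(files), function(i)
    read_alignments_bed(files[i], found[i], read_anchor))
  names(rs) <- found
  rs
}

#' Summary counts of a calls table
#' @param calls categorized calls data.frame.
#' @return named list of counts per category plus intronic-shared count.
#' @export
call_counts <- function(calls) {
  list(n_mirnas = nrow(calls),
       independent = sum(calls$category == "independent"),
       shared_upstream = sum(calls$category == "shared_upstream"),
       none = sum(calls$category == "none"),
       intronic_shared = sum(calls$category == "shared_upstream" &
                               calls$intronic))
}
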