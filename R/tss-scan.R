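# Upstream scanning of miRNA loci: candidate TSS bins on a grid anchored at
# the miRNA 5' end, classifier scoring, empirical p-values against decoy
# positions, Benjamini-Hochberg FDR across the pooled candidates, one call
# per miRNA, and categorization against upstream protein-coding genes.

#' Candidate TSS bins upstream of a miRNA
#'
#' Candidates are consecutive \code{bin_size} windows on a grid anchored at
#' the miRNA 5' end, extending \code{max_upstream} bp in the transcriptional
#' upstream direction (higher coordinates for minus-strand miRNAs), ordered
#' proximal to distal and truncated at chromosome ends.
#'
#' @param mirna single-row annotation data.frame (id, chrom, start, end,
#'   strand; internal coordinates).
#' @param genome named vector of chromosome lengths.
#' @param bin_size bin width in bp (default 100).
#' @param max_upstream scan depth in bp (default 10000).
#' @return data.frame(mirna_id, chrom, start, end, strand, anchor, offset)
#'   with one row per candidate; \code{offset} is the distance in bp from
#'   the miRNA 5' end to the proximal edge of the candidate bin and
#'   \code{anchor} the internal position of the bin center used for scoring.
#' @export
candidate_bins <- function(mirna, genome, bin_size = 100, max_upstream = 10000) {
  if (!mirna$strand %in% c("+", "-")) stop("miRNA must be stranded")
  if (!mirna$chrom %in% names(genome))
    stop("chromosome absent from genome table: ", mirna$chrom)
  L <- genome[[mirna$chrom]]
  p0 <- tss_of(mirna)
  j <- seq_len(floor(max_upstream / bin_size))
  if (mirna$strand == "+") {
    start <- p0 - j * bin_size
    end <- start + bin_size
    anchor <- p0 - ((j - 1) * bin_size + bin_size / 2)
  } else {
    start <- p0 + (j - 1) * bin_size
    end <- start + bin_size
    anchor <- p0 + ((j - 1) * bin_size + bin_size / 2)
  }
  keep <- end > 0 & start < L
  df <- data.frame(mirna_id = mirna$id, chrom = mirna$chrom,
                   start = pmax(start[keep], 0), end = pmin(end[keep], L),
                   strand = mirna$strand,
                   anchor = pmin(pmax(anchor[keep], 0), L - 1),
                   offset = (j[keep] - 1) * bin_size,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Empirical p-values against a decoy score distribution
#'
#' \code{p = (r + 1) / (n + 1)} with \code{r} the number of decoy (null)
#' scores greater than or equal to the candidate score; ties count, and the
#' add-one correction keeps p strictly positive.
#'
#' @param scores candidate decision scores.
#' @param null_scores decoy decision scores (non-empty).
#' @return numeric p-values in (0, 1].
#' @export
empirical_pvalues <- function(scores, null_scores) {
  n <- length(null_scores)
  if (n == 0) stop("decoy score set is empty")
  sn <- sort(null_scores)
  n_lt <- findInterval(scores, sn, left.open = TRUE)  # strictly below score
  r <- n - n_lt
  (r + 1) / (n + 1)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up adjustment; input order is preserved.
#'
#' @param pvalues numeric vector, each in (0, 1].
#' @return q-values in input order.
#' @export
bh_qvalues <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Call at most one TSS per miRNA
#'
#' Among this miRNA's candidates at \code{q <= fdr}, the highest-scoring
#' one is called; score ties go to the most proximal candidate.
#'
#' @param candidates this miRNA's candidate rows with \code{score} and
#'   \code{qvalue} columns (q-values must have been computed on the pooled
#'   candidate set of all miRNAs).
#' @param fdr FDR threshold (default 0.1).
#' @return the selected candidate row, or NULL when none passes.
#' @export
call_tss <- function(candidates, fdr = 0.1) {
  pass <- candidates[!is.na(candidates$qvalue) & candidates$qvalue <= fdr, ,
                     drop = FALSE]
  if (nrow(pass) == 0) return(NULL)
  pass[order(-pass$score, pass$offset), , drop = FALSE][1, , drop = FALSE]
}

# Gene TSSs transcriptionally upstream of position p0 on the given strand
# (genes of either strand count); empty when the chromosome has none.
upstream_gene_tss_positions <- function(chrom, p0, strand, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) return(numeric(0))
  gt <- tss_of(g)
  if (strand == "+") gt[gt <= p0] else gt[gt >= p0]
}

# Nearest of those to the miRNA 5' end itself; NA when there is none.
nearest_upstream_gene_tss <- function(chrom, p0, strand, genes) {
  gt <- upstream_gene_tss_positions(chrom, p0, strand, genes)
  if (length(gt) == 0) return(NA_real_)
  if (strand == "+") max(gt) else min(gt)
}

mirna_is_intronic <- function(mirna, genes) {
  g <- genes[genes$chrom == mirna$chrom, , drop = FALSE]
  for (i in seq_len(nrow(g))) {
    if (g$start[i] > mirna$start || g$end[i] < mirna$end) next
    intr <- introns_of(g[i, , drop = FALSE])
    if (nrow(intr) > 0 &&
        any(intr$start <= mirna$start & intr$end >= mirna$end))
      return(TRUE)
  }
  FALSE
}

#' Categorize miRNA TSS calls against upstream genes
#'
#' A call is \code{shared_upstream} when the midpoint of its TSS bin lies
#' within \code{shared_tol} bp of the TSS of a transcriptionally upstream
#' gene (the closest such gene TSS to the call), otherwise
#' \code{independent}; miRNAs without a passing candidate are \code{none}.
#' The intronic flag is set when the miRNA interval is fully contained in
#' an intron of a protein-coding gene.
#'
#' @param calls calls data.frame (one row per miRNA; NA TSS for no call)
#'   carrying the miRNA interval columns.
#' @param genes protein-coding gene annotations (with exons).
#' @param shared_tol sharing tolerance in bp (default 100).
#' @return calls with category, distance_to_upstream_gene_tss and intronic
#'   columns filled in.
#' @export
categorize <- function(calls, genes, shared_tol = 100) {
  n <- nrow(calls)
  calls$category <- rep("none", n)
  calls$distance_to_upstream_gene_tss <- rep(NA_real_, n)
  calls$intronic <- rep(FALSE, n)
  for (i in seq_len(n)) {
    mir <- data.frame(id = calls$mirna_id[i], chrom = calls$chrom[i],
                      start = calls$mirna_start[i], end = calls$mirna_end[i],
                      strand = calls$strand[i], stringsAsFactors = FALSE)
    mir$exons <- list(data.frame(start = numeric(), end = numeric()))
    calls$intronic[i] <- mirna_is_intronic(mir, genes)
    if (is.na(calls$tss_start[i])) next
    p0 <- tss_of(mir)
    gtss <- upstream_gene_tss_positions(mir$chrom, p0, mir$strand, genes)
    mid <- (calls$tss_start[i] + calls$tss_end[i]) / 2
    if (length(gtss) > 0) {
      d <- min(abs(mid - gtss))
      calls$distance_to_upstream_gene_tss[i] <- d
      calls$category[i] <- if (d <= shared_tol) "shared_upstream" else "independent"
    } else {
      calls$category[i] <- "independent"
    }
  }
  calls
}

#' Scan all miRNAs for TSSs with FDR control
#'
#' Runs the full calling stage: decoy anchors are sampled away from
#' annotated gene TSSs and scored with the trained classifier to form the
#' null score distribution; every candidate bin of every miRNA is scored,
#' converted to an empirical p-value, and adjusted by Benjamini-Hochberg
#' across the pooled candidate set; at most one TSS is called per miRNA and
#' calls are categorized.
#'
#' @param model trained classifier.
#' @param tracks named list of binned tracks.
#' @param mirnas miRNA annotation data.frame.
#' @param genes protein-coding gene annotation data.frame.
#' @param genome named vector of chromosome lengths.
#' @param max_upstream scan depth in bp (default 10000).
#' @param fdr FDR threshold (default 0.1).
#' @param shared_tol sharing tolerance in bp (default 100).
#' @param n_decoys number of decoy positions for the null (default 10000).
#' @param decoy_seed seed for decoy sampling.
#' @param decoy_exclusion_bp decoys are rejected within this distance of an
#'   annotated gene TSS (default 1000), so the null represents non-promoter
#'   background rather than a mixture containing true promoters.
#' @param decoys optional anchors data.frame to use as decoys instead of
#'   sampling.
#' @return list(calls, candidates, null_scores); \code{calls} has one row
#'   per miRNA with TSS interval, score, q-value, category, distances and
#'   intronic flag.
#' @export
scan_mirna_tss <- function(model, tracks, mirnas, genes, genome,
                           max_upstream = 10000, fdr = 0.1, shared_tol = 100,
                           n_decoys = 10000, decoy_seed = 1,
                           decoy_exclusion_bp = 1000, decoys = NULL) {
  bin_size <- tracks[[model$marks[1]]]$bin_size
  if (is.null(decoys))
    decoys <- sample_random_anchors(
      genome, n_decoys, seed = decoy_seed,
      exclusion = if (nrow(genes) > 0)
        tss_exclusion_zones(genes, decoy_exclusion_bp) else NULL,
      id_prefix = "decoy")
  null_scores <- predict_scores(
    model, build_matrix(tracks, decoys, k = model$k, marks = model$marks))$score

  cand_list <- lapply(seq_len(nrow(mirnas)), function(i)
    candidate_bins(mirnas[i, , drop = FALSE], genome, bin_size, max_upstream))
  cands <- do.call(rbind, cand_list)
  if (is.null(cands) || nrow(cands) == 0)
    stop("no candidate bins; check the miRNA annotation")
  anch <- data.frame(id = paste0(cands$mirna_id, "_c", seq_len(nrow(cands))),
                     chrom = cands$chrom, pos = cands$anchor,
                     strand = cands$strand, stringsAsFactors = FALSE)
  sc <- predict_scores(model,
                       build_matrix(tracks, anch, k = model$k,
                                    marks = model$marks))
  cands$score <- sc$score
  cands$probability <- sc$probability
  cands$pvalue <- empirical_pvalues(cands$score, null_scores)
  cands$qvalue <- bh_qvalues(cands$pvalue)

  rows <- lapply(seq_len(nrow(mirnas)), function(i) {
    m <- mirnas[i, , drop = FALSE]
    sel <- call_tss(cands[cands$mirna_id == m$id, , drop = FALSE], fdr)
    data.frame(mirna_id = m$id,
               mirna_name = if ("name" %in% names(m)) m$name else m$id,
               chrom = m$chrom, mirna_start = m$start, mirna_end = m$end,
               strand = m$strand,
               tss_start = if (is.null(sel)) NA_real_ else sel$start,
               tss_end = if (is.null(sel)) NA_real_ else sel$end,
               score = if (is.null(sel)) NA_real_ else sel$score,
               qvalue = if (is.null(sel)) NA_real_ else sel$qvalue,
               distance_to_mirna = if (is.null(sel)) NA_real_ else sel$offset,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  calls <- categorize(calls, genes, shared_tol)
  calls$index <- seq_len(nrow(calls))
  list(calls = calls, candidates = cands, null_scores = null_scores)
}

#' Distance summaries for miRNAs and their calls
#'
#' \code{upstream_gene}: per miRNA, distance from its 5' end to the nearest
#' transcriptionally upstream gene TSS (NA when the chromosome has no
#' upstream gene), with a 1 kb histogram class. \code{independent_gap}: per
#' independent call, the gap in bp between the called TSS bin and the miRNA
#' interval.
#'
#' @param mirnas miRNA annotations.
#' @param genes gene annotations.
#' @param calls categorized calls (may be NULL to skip gaps).
#' @param class_width histogram class width in bp (default 1000).
#' @return list(upstream_gene, independent_gap) of data.frames.
#' @export
distance_summaries <- function(mirnas, genes, calls = NULL,
                               class_width = 1000) {
  p0 <- tss_of(mirnas)
  d <- vapply(seq_len(nrow(mirnas)), function(i) {
    g <- nearest_upstream_gene_tss(mirnas$chrom[i], p0[i],
                                   mirnas$strand[i], genes)
    if (is.na(g)) NA_real_ else abs(p0[i] - g)
  }, numeric(1))
  upstream <- data.frame(mirna_id = mirnas$id, distance = d,
                         class_kb = floor(d / class_width),
                         stringsAsFactors = FALSE)
  gap_df <- data.frame(mirna_id = character(), gap = numeric(),
                       stringsAsFactors = FALSE)
  if (!is.null(calls)) {
    ind <- calls[calls$category == "independent" & !is.na(calls$tss_start), ,
                 drop = FALSE]
    if (nrow(ind) > 0) {
      mp0 <- tss_of(data.frame(chrom = ind$chrom, start = ind$mirna_start,
                               end = ind$mirna_end, strand = ind$strand))
      gap <- ifelse(ind$strand == "+", mp0 - ind$tss_end,
                    ind$tss_start - mp0)
      gap_df <- data.frame(mirna_id = ind$mirna_id, gap = gap,
                           stringsAsFactors = FALSE)
    }
  }
  list(upstream_gene = upstream, independent_gap = gap_df)
}
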