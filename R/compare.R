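# Cross-method TSS agreement: two TSS positions for the same miRNA agree
# when they lie within a tolerance (100 bp in the published comparisons).

#' Construct a TSS call set for one method
#'
#' @param method method label.
#' @param mirna_id character vector of miRNA identifiers (unique).
#' @param position numeric TSS positions (interval-valued calls should be
#'   reduced to their midpoints beforehand; see [tss_set_from_calls()]).
#' @param chrom optional chromosome names.
#' @return data.frame of class \code{tss_set}.
#' @export
tss_set <- function(method, mirna_id, position, chrom = NA_character_) {
  if (anyDuplicated(mirna_id)) stop("one TSS per miRNA per set")
  structure(data.frame(mirna_id = as.character(mirna_id),
                       chrom = chrom, position = as.numeric(position),
                       stringsAsFactors = FALSE),
            method = method, class = c("tss_set", "data.frame"))
}

#' TSS set from a calls table
#'
#' Interval calls are reduced to their bin midpoints; uncalled miRNAs are
#' dropped.
#'
#' @param calls calls data.frame (from [scan_mirna_tss()]).
#' @param method method label.
#' @return a \code{tss_set}.
#' @export
tss_set_from_calls <- function(calls, method = "histone_svm") {
  called <- calls[!is.na(calls$tss_start), , drop = FALSE]
  tss_set(method, called$mirna_id,
          (called$tss_start + called$tss_end) / 2, called$chrom)
}

#' Read a TSS set from TSV
#' @param path TSV with columns mirna_id, chrom, position (1-based).
#' @param method method label.
#' @return a \code{tss_set} (internal 0-based positions).
#' @export
read_tss_set <- function(path, method) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  tss_set(method, df$mirna_id, df$position - 1,
          if ("chrom" %in% names(df)) df$chrom else NA_character_)
}

#' miRNAs whose TSSs agree between two methods
#'
#' Agreement: the same miRNA is present in both sets with positions within
#' \code{tol} bp of each other (and on the same chromosome when known).
#'
#' @param a,b \code{tss_set} objects.
#' @param tol distance tolerance in bp (default 100).
#' @return character vector of agreeing miRNA ids.
#' @export
match_pair <- function(a, b, tol = 100) {
  shared <- intersect(a$mirna_id, b$mirna_id)
  if (length(shared) == 0) return(character(0))
  pa <- a$position[match(shared, a$mirna_id)]
  pb <- b$position[match(shared, b$mirna_id)]
  ok <- abs(pa - pb) <= tol
  ca <- a$chrom[match(shared, a$mirna_id)]
  cb <- b$chrom[match(shared, b$mirna_id)]
  known <- !is.na(ca) & !is.na(cb)
  ok[known] <- ok[known] & ca[known] == cb[known]
  sort(shared[ok])
}

#' Venn partition counts of 2-3 TSS call sets
#'
#' Pairwise agreement uses [match_pair()]; a miRNA is consistent for all
#' three methods only when all three pairwise agreements hold (the pairwise
#' rule is not transitive near the tolerance).
#'
#' @param sets list of 2 or 3 \code{tss_set} objects.
#' @param tol distance tolerance in bp (default 100).
#' @return list with per-region counts and the agreeing id sets.
#' @export
overlap_counts <- function(sets, tol = 100) {
  if (length(sets) < 2 || length(sets) > 3)
    stop("overlap_counts supports 2 or 3 sets")
  labs <- vapply(seq_along(sets), function(i) {
    m <- attr(sets[[i]], "method")
    if (is.null(m)) paste0("set", i) else m
  }, character(1))
  pairs <- utils::combn(length(sets), 2, simplify = FALSE)
  agree <- lapply(pairs, function(p) match_pair(sets[[p[1]]], sets[[p[2]]], tol))
  names(agree) <- vapply(pairs, function(p)
    paste(labs[p[1]], labs[p[2]], sep = "&"), character(1))
  out <- list(methods = labs, pairwise = lapply(agree, length),
              pairwise_ids = agree)
  if (length(sets) == 3) {
    triple <- Reduce(intersect, agree)
    out$triple <- length(triple)
    out$triple_ids <- triple
    out$pairwise_only <- lapply(agree, function(g) setdiff(g, triple))
  }
  out
}
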