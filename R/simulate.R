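# Synthetic genomes with planted promoter structure.
#
# The generator emulates a compact plant genome: protein-coding genes every
# ~4.5-5.5 kb, miRNA loci planted in four configurations (independent
# promoter in a gene desert, promoter shared with the nearest upstream
# gene, intronic inside a host gene, or no promoter signal at all), and
# per-mark ChIP-Seq read sets with Poisson background plus Gaussian
# TSS-proximal enrichment whose shapes caricature the published metagene
# profiles: one strongly peaked mark, five moderately peaked, two flat and
# one broad gene-body mark.

#' Default per-mark enrichment specification
#'
#' \code{amplitude} is the expected number of TSS-proximal reads per
#' promoter anchor, \code{offset}/\code{sd} the mean (downstream-shifted)
#' and spread in bp of the Gaussian read cloud around each TSS, and
#' \code{background_rate} the uniform background in reads per bp.
#'
#' @return data.frame with one row per histone mark.
#' @export
default_mark_spec <- function() {
  data.frame(
    mark = c("H3K4me3", "H3K4me2", "H3K9Ac", "H3K18Ac", "H3K27me3",
             "H3K36me2", "H3K36me3", "H3K9me2", "H3K27me1"),
    amplitude = c(90, 50, 50, 45, 35, 40, 40, 0, 0),
    offset = c(200, 250, 200, 200, 300, 600, 1000, 0, 0),
    sd = c(300, 350, 300, 300, 500, 700, 900, 1, 1),
    background_rate = c(0.005, 0.007, 0.007, 0.008, 0.009, 0.008, 0.008,
                        0.015, 0.015),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults describe the package's reference study condition: a ~13.8 Mb
#' two-chromosome genome carrying about 2,000 genes (one per 4.5-5.5 kb, as
#' in a compact plant genome), 60 miRNA loci with a category mix echoing
#' the published call partition (roughly 15% independent, 30% sharing the
#' upstream gene promoter, 10% intronic, 45% without promoter signal), and
#' nine mark libraries of roughly 2e5 reads each.
#'
#' @param genome named vector of chromosome lengths (multiples of bin_size).
#' @param n_genes number of protein-coding genes (includes hosts of shared
#'   and intronic miRNAs).
#' @param n_mirnas number of miRNA loci.
#' @param mirna_fractions named fractions (independent, shared, intronic,
#'   none) summing to 1.
#' @param marks per-mark enrichment data.frame (see [default_mark_spec()]).
#' @param bin_size bin width in bp.
#' @param gene_length_range,intergenic_gap_range bp ranges controlling gene
#'   spacing (TSS-to-TSS roughly their sums).
#' @param independent_tss_range bp range of planted independent TSS
#'   distances upstream of the miRNA 5' end.
#' @param desert_lead bp of gene-free space upstream of desert miRNAs so no
#'   gene TSS falls inside their scan window.
#' @param seed integer seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(genome = c(chr1 = 7.4e6, chr2 = 6.4e6),
                       n_genes = 2000, n_mirnas = 60,
                       mirna_fractions = c(independent = 0.15, shared = 0.30,
                                           intronic = 0.10, none = 0.45),
                       marks = default_mark_spec(), bin_size = 100,
                       gene_length_range = c(1000, 2500),
                       intergenic_gap_range = c(2500, 3500),
                       independent_tss_range = c(300, 8000),
                       desert_lead = 10500, seed = 1) {
  if (abs(sum(mirna_fractions) - 1) > 1e-8)
    stop("mirna_fractions must sum to 1")
  if (any(mirna_fractions < 0)) stop("mirna_fractions must be >= 0")
  if (any(genome <= 0)) stop("chromosome lengths must be > 0")
  if (any(marks$amplitude < 0) || any(marks$background_rate < 0))
    stop("rates must be >= 0")
  structure(list(genome = genome, n_genes = n_genes, n_mirnas = n_mirnas,
                 mirna_fractions = mirna_fractions, marks = marks,
                 bin_size = bin_size,
                 gene_length_range = gene_length_range,
                 intergenic_gap_range = intergenic_gap_range,
                 independent_tss_range = independent_tss_range,
                 desert_lead = desert_lead, seed = seed),
            class = "sim_config")
}

runif1 <- function(range) round(runif(1, range[1], range[2]))

# Local layout of one unit in plus orientation; entities are later shifted
# to the chromosome cursor and (for minus orientation) mirrored in place.
# Returns list(len, genes, mirnas); coordinates local, strands relative "+".
layout_unit <- function(kind, cfg) {
  glen <- runif1(cfg$gene_length_range)
  gap <- runif1(cfg$intergenic_gap_range)
  mlen <- runif1(c(80, 300))
  genes <- data.frame(start = numeric(), end = numeric(), strand = character(),
                      n_exons = integer(), long_intron = logical())
  mirnas <- data.frame(start = numeric(), end = numeric(), strand = character(),
                       category = character(), planted = numeric())
  if (kind == "gene") {
    genes <- data.frame(start = 0, end = glen, strand = "+",
                        n_exons = sample(2:4, 1), long_intron = FALSE)
    len <- glen + gap
  } else if (kind == "shared") {
    d <- runif1(c(200, 1200))
    genes <- data.frame(start = 0, end = glen, strand = "+",
                        n_exons = sample(2:4, 1), long_intron = FALSE)
    mirnas <- data.frame(start = glen + d, end = glen + d + mlen,
                         strand = "+", category = "shared", planted = 0)
    len <- glen + d + mlen + gap
  } else if (kind == "intronic") {
    glen <- max(glen, 3200)
    genes <- data.frame(start = 0, end = glen, strand = "+",
                        n_exons = 2L, long_intron = TRUE)
    # host exon1 [0,300), intron [300, 2800), exon2 [2800, glen)
    mstart <- 800
    mirnas <- data.frame(start = mstart, end = mstart + mlen, strand = "+",
                         category = "intronic", planted = 0)
    len <- glen + gap
  } else if (kind %in% c("independent", "none")) {
    lead <- cfg$desert_lead
    d <- if (kind == "independent") runif1(cfg$independent_tss_range) else 0
    mstart <- lead + d
    mirnas <- data.frame(start = mstart, end = mstart + mlen, strand = "+",
                         category = kind,
                         planted = if (kind == "independent") lead else NA_real_)
    len <- mstart + mlen + 500
  } else stop("unknown unit kind")
  list(len = len, genes = genes, mirnas = mirnas)
}

mirror_unit <- function(u) {
  L <- u$len
  flip <- function(df) {
    if (nrow(df) == 0) return(df)
    s <- df$start; e <- df$end
    df$start <- L - e; df$end <- L - s
    df$strand <- ifelse(df$strand == "+", "-", "+")
    df
  }
  u$genes <- flip(u$genes)
  u$mirnas <- flip(u$mirnas)
  if (nrow(u$mirnas) > 0 && !is.na(u$mirnas$planted[1]))
    u$mirnas$planted <- L - u$mirnas$planted - 1
  u
}

# Exon structure for a laid-out gene (internal absolute coordinates).
make_exons <- function(start, end, strand, n_exons, long_intron) {
  glen <- end - start
  if (long_intron) {
    # fixed first intron hosting an intronic miRNA (strand "+" local sense
    # is already resolved: for "-" genes the first exon is at the right end)
    if (strand == "+") {
      ex <- data.frame(start = c(start, start + 2800),
                       end = c(start + 300, end))
    } else {
      ex <- data.frame(start = c(start, end - 300),
                       end = c(end - 2800, end))
    }
    return(ex)
  }
  if (n_exons < 2 || glen < 400)
    return(data.frame(start = start, end = end))
  cuts <- sort(sample(seq(100, glen - 100, by = 50), 2 * (n_exons - 1)))
  bounds <- c(0, cuts, glen)
  ex <- data.frame(start = start + bounds[seq(1, length(bounds) - 1, by = 2)],
                   end = start + bounds[seq(2, length(bounds), by = 2)])
  ex[ex$end > ex$start, , drop = FALSE]
}

#' Simulate gene and miRNA annotations with planted promoter truth
#'
#' Genes and miRNA loci are laid out left to right along the configured
#' chromosomes as shuffled units: plain genes, genes trailed by a
#' promoter-sharing miRNA, genes hosting an intronic miRNA, and gene-desert
#' units holding an independent-promoter or signal-free miRNA (the desert
#' guarantees no gene TSS inside the scan window). Each unit is mirrored
#' with probability 1/2 so both strands are used.
#'
#' @param config a [sim_config()].
#' @return list(genes, mirnas, truth): annotation data.frames (internal
#'   coordinates; genes carry exon structure) and the truth table
#'   (mirna_id, category, planted_tss, chrom, strand).
#' @export
simulate_annotations <- function(config) {
  cfg <- config
  counts <- round(cfg$n_mirnas * cfg$mirna_fractions)
  counts[1] <- cfg$n_mirnas - sum(counts[-1])
  kinds <- c(rep("independent", counts["independent"]),
             rep("shared", counts["shared"]),
             rep("intronic", counts["intronic"]),
             rep("none", counts["none"]))
  n_plain <- cfg$n_genes - counts["shared"] - counts["intronic"]
  if (n_plain < 0) stop("n_genes too small for the miRNA category mix")
  units <- c(kinds, rep("gene", n_plain))
  with_seed(cfg$seed, {
    units <- sample(units)
    genes <- list(); mirnas <- list(); truth <- list()
    chroms <- names(cfg$genome)
    ci <- 1; cur <- 1000
    gi <- 0; mi <- 0
    for (kind in units) {
      u <- layout_unit(kind, cfg)
      if (runif(1) < 0.5) u <- mirror_unit(u)
      while (cur + u$len > cfg$genome[[chroms[ci]]] - 1000) {
        ci <- ci + 1
        if (ci > length(chroms))
          stop("genome too small for the requested layout")
        cur <- 1000
      }
      ch <- chroms[ci]
      if (nrow(u$genes) > 0) {
        gi <- gi + 1
        g <- u$genes
        gene <- data.frame(id = sprintf("g%04d", gi), chrom = ch,
                           start = cur + g$start, end = cur + g$end,
                           strand = g$strand, kind = "protein_coding",
                           stringsAsFactors = FALSE)
        gene$exons <- list(make_exons(gene$start, gene$end, g$strand,
                                      g$n_exons, g$long_intron))
        genes[[length(genes) + 1]] <- gene
      }
      if (nrow(u$mirnas) > 0) {
        mi <- mi + 1
        m <- u$mirnas
        id <- sprintf("mir%04d", mi)
        mirnas[[length(mirnas) + 1]] <- data.frame(
          id = id, name = id, chrom = ch, start = cur + m$start,
          end = cur + m$end, strand = m$strand, kind = "miRNA",
          stringsAsFactors = FALSE)
        planted <- if (m$category == "none") NA_real_
          else if (m$category %in% c("shared", "intronic")) {
            g <- genes[[length(genes)]]
            tss_of(g)
          } else cur + m$planted
        truth[[length(truth) + 1]] <- data.frame(
          mirna_id = id, category = m$category, planted_tss = planted,
          chrom = ch, strand = m$strand, stringsAsFactors = FALSE)
      }
      cur <- cur + u$len
    }
    genes <- do.call(rbind, genes)
    mirnas <- if (length(mirnas) > 0) do.call(rbind, mirnas) else
      data.frame(id = character(), name = character(), chrom = character(),
                 start = numeric(), end = numeric(), strand = character(),
                 kind = character(), stringsAsFactors = FALSE)
    truth <- if (length(truth) > 0) do.call(rbind, truth) else
      data.frame(mirna_id = character(), category = character(),
                 planted_tss = numeric(), chrom = character(),
                 strand = character(), stringsAsFactors = FALSE)
    if (nrow(mirnas) > 0) {
      mirnas$exons <- rep(list(data.frame(start = numeric(), end = numeric())),
                          nrow(mirnas))
    }
    list(genes = genes, mirnas = mirnas, truth = truth)
  })
}

# All planted promoter anchors seen by the read simulator: gene TSSs plus
# independent miRNA planted TSSs.
planted_anchors <- function(annotations) {
  g <- annotations$genes
  ga <- data.frame(chrom = g$chrom, pos = tss_of(g), strand = g$strand,
                   stringsAsFactors = FALSE)
  t <- annotations$truth
  ind <- t[t$category == "independent", , drop = FALSE]
  if (nrow(ind) > 0)
    ga <- rbind(ga, data.frame(chrom = ind$chrom, pos = ind$planted_tss,
                               strand = ind$strand, stringsAsFactors = FALSE))
  ga
}

#' Simulate per-mark ChIP-Seq read sets
#'
#' Per mark: uniform Poisson background over the genome plus, for every
#' planted promoter anchor, a Poisson(\code{amplitude}) number of reads at
#' positions drawn from a Gaussian centered \code{offset} bp downstream of
#' the anchor (in its transcriptional orientation) with spread \code{sd}.
#' Marks with amplitude 0 are background only.
#'
#' @param config a [sim_config()].
#' @param annotations output of [simulate_annotations()].
#' @param seed seed (defaults to \code{config$seed + 1}).
#' @return named list of read-set data.frames, one per mark.
#' @export
simulate_reads <- function(config, annotations, seed = config$seed + 1) {
  genome <- config$genome
  anchors <- planted_anchors(annotations)
  with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(config$marks))) {
      sp <- config$marks[i, ]
      nbg <- rpois(1, sp$background_rate * sum(genome))
      ch <- sample(names(genome), nbg, replace = TRUE,
                   prob = genome / sum(genome))
      pos <- floor(runif(nbg) * genome[ch])
      chrom <- ch
      if (sp$amplitude > 0 && nrow(anchors) > 0) {
        npk <- rpois(nrow(anchors), sp$amplitude)
        aidx <- rep(seq_len(nrow(anchors)), npk)
        delta <- round(rnorm(length(aidx), sp$offset, sp$sd))
        sgn <- ifelse(anchors$strand[aidx] == "+", 1, -1)
        ppos <- anchors$pos[aidx] + sgn * delta
        pch <- anchors$chrom[aidx]
        ok <- ppos >= 0 & ppos < genome[pch]
        chrom <- c(chrom, pch[ok])
        pos <- c(pos, ppos[ok])
      }
      strand <- sample(c("+", "-"), length(pos), replace = TRUE)
      rs <- data.frame(chrom = chrom, pos = pos, strand = strand,
                       stringsAsFactors = FALSE)
      attr(rs, "mark") <- sp$mark
      attr(rs, "N") <- nrow(rs)
      out[[sp$mark]] <- rs
    }
    out
  })
}

#' Build RPM tracks for all simulated marks
#' @param readsets named list of read sets (from [simulate_reads()]).
#' @param genome named vector of chromosome lengths.
#' @param bin_size bin width in bp.
#' @return named list of binned tracks.
#' @export
tracks_from_readsets <- function(readsets, genome, bin_size = 100) {
  lapply(readsets, binned_track_from_reads, genome = genome,
         bin_size = bin_size)
}

# --- GFF3 / BED / truth writers --------------------------------------------

annotations_to_granges <- function(tx, type_parent, type_child = NULL) {
  gr <- GenomicRanges::GRanges(tx$chrom,
    IRanges::IRanges(start = tx$start + 1, end = tx$end), strand = tx$strand)
  gr$type <- type_parent
  gr$ID <- tx$id
  gr$Name <- if ("name" %in% names(tx)) tx$name else tx$id
  if (!is.null(type_child) && "exons" %in% names(tx)) {
    ex <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
      e <- tx$exons[[i]]
      if (is.null(e) || nrow(e) == 0) return(NULL)
      data.frame(chrom = tx$chrom[i], start = e$start, end = e$end,
                 strand = tx$strand[i], parent = tx$id[i],
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(ex) && nrow(ex) > 0) {
      gre <- GenomicRanges::GRanges(ex$chrom,
        IRanges::IRanges(start = ex$start + 1, end = ex$end),
        strand = ex$strand)
      gre$type <- type_child
      gre$ID <- paste0(ex$parent, ".e", seq_len(nrow(ex)))
      gre$Name <- gre$ID
      gre$Parent <- S4Vectors::List(as.list(ex$parent))
      gr$Parent <- S4Vectors::List(rep(list(character(0)), length(gr)))
      gr <- c(gr, gre)
    }
  }
  gr
}

#' Write simulated annotations as GFF3
#' @param tx annotation data.frame (genes or miRNAs).
#' @param path output path.
#' @param kind \code{"protein_coding"} (gene + exon records) or
#'   \code{"miRNA"} (miRNA_primary_transcript records).
#' @export
write_annotations_gff3 <- function(tx, path,
                                   kind = c("protein_coding", "miRNA")) {
  kind <- match.arg(kind)
  if (nrow(tx) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- if (kind == "protein_coding")
    annotations_to_granges(tx, "gene", "exon")
  else annotations_to_granges(tx, "miRNA_primary_transcript")
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a read set as BED6 (width-1 intervals at the read anchor)
#' @param readset read-set data.frame.
#' @param path output path.
#' @export
write_reads_bed <- function(readset, path) {
  gr <- GenomicRanges::GRanges(readset$chrom,
    IRanges::IRanges(start = readset$pos + 1, width = 1),
    strand = readset$strand)
  gr$name <- rep(".", nrow(readset))
  gr$score <- rep(0, nrow(readset))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write the simulation truth table as JSON
#' @param annotations output of [simulate_annotations()].
#' @param config the [sim_config()] used.
#' @param path output path.
#' @export
write_sim_truth <- function(annotations, config, path) {
  jsonlite::write_json(
    list(seed = config$seed,
         genome = as.list(config$genome),
         mirna_fractions = as.list(config$mirna_fractions),
         marks = config$marks,
         truth = annotations$truth),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Materialize the packaged table of 42 published independent miRNA TSSs
#'
#' Copies the packaged machine-readable transcription (42 rows, coordinates
#' verbatim) to \code{path}, or returns the packaged file path.
#'
#' @param path optional destination.
#' @return path to the TSV.
#' @export
make_fixture_table1 <- function(path = NULL) {
  src <- system.file("extdata", "independent_tss_published.tsv",
                     package = "mirpromoter", mustWork = TRUE)
  if (is.null(path)) return(src)
  file.copy(src, path, overwrite = TRUE)
  path
}
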