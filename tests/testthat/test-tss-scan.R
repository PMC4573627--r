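mir <- function(chrom, start, end, strand, id = "m1")
  data.frame(id = id, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)

test_that("plus-strand candidates tile 10 kb upstream of the 5' end", {
  cb <- candidate_bins(mir("chr1", 20000, 20150, "+"), c(chr1 = 1e6))
  expect_equal(nrow(cb), 100)
  # proximal to distal, contiguous coverage of [10000, 20000)
  expect_equal(cb$start[1], 19900)
  expect_equal(cb$end[1], 20000)
  expect_equal(cb$start[100], 10000)
  expect_true(all(cb$end - cb$start == 100))
  expect_equal(sort(cb$start), seq(10000, 19900, by = 100))
  expect_equal(cb$offset, seq(0, 9900, by = 100))
  # scoring anchor is the bin midpoint
  expect_equal(cb$anchor[1], 19950)
  expect_equal(cb$anchor[2], 19850)
})

test_that("minus-strand candidates extend toward higher coordinates", {
  # published row 2: precursor chr1:4820355-4820549(-); the most proximal
  # candidate bin prints as 4820549-4820649
  co <- mirpromoter:::parse_coord_string("chr1:4820355-4820549(-)")
  cb <- candidate_bins(mir(co$chrom, co$start, co$end, co$strand),
                       c(chr1 = 30e6))
  expect_equal(nrow(cb), 100)
  expect_equal(mirpromoter:::format_tss_string(cb$start[1], cb$end[1]),
               "4820549-4820649")
  expect_equal(cb$offset[1], 0)
  expect_equal(cb$anchor[1], cb$start[1] + 50)
  # mirror image of the plus-strand rule
  expect_equal(cb$start[100], cb$start[1] + 9900)
})

test_that("candidates are truncated at chromosome ends", {
  # plus-strand 5' end at 350: bins at 250, 150, 50 and a clipped [0, 50)
  cb <- candidate_bins(mir("chr1", 350, 500, "+"), c(chr1 = 1e6))
  expect_equal(nrow(cb), 4)
  expect_equal(cb$start, c(250, 150, 50, 0))
  expect_equal(cb$end, c(350, 250, 150, 50))
  # minus-strand near the right end
  cb2 <- candidate_bins(mir("chr1", 500, 750, "-"), c(chr1 = 1000))
  expect_equal(nrow(cb2), 3)
  expect_equal(cb2$start, c(749, 849, 949))
  expect_equal(cb2$end, c(849, 949, 1000))
  expect_error(candidate_bins(mir("chrX", 350, 500, "+"), c(chr1 = 1e6)),
               "chrX")
  expect_error(candidate_bins(mir("chr1", 350, 500, "*"), c(chr1 = 1e6)),
               "strand")
})

test_that("empirical p-values use the add-one rank rule", {
  null <- 1:999
  expect_equal(empirical_pvalues(1000, null), 1 / 1000)
  expect_equal(empirical_pvalues(0, null), 1)
  # ties with null scores count against the candidate
  expect_equal(empirical_pvalues(999, null), 2 / 1000)
  expect_equal(empirical_pvalues(c(1000, 0), null), c(0.001, 1))
  expect_error(empirical_pvalues(1, numeric(0)), "empty")
  # p-values never reach 0 and never exceed 1
  set.seed(3)
  p <- empirical_pvalues(rnorm(100), rnorm(500))
  expect_true(all(p > 0 & p <= 1))
})

test_that("BH adjustment matches hand-computed q-values", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_qvalues(c(0.03, 0.01, 0.02)), c(0.03, 0.03, 0.03))
  expect_equal(bh_qvalues(c(0.01, 0.4, 1)), c(0.03, 0.6, 1))
  expect_equal(bh_qvalues(0.05), 0.05)
  expect_error(bh_qvalues(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_qvalues(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(bh_qvalues(c(0.5, NA)), "\\(0, 1\\]")
})

test_that("call_tss picks the best passing candidate, ties to proximal", {
  cand <- data.frame(mirna_id = "m1", start = c(900, 700, 500),
                     end = c(1000, 800, 600), offset = c(0, 200, 400),
                     score = c(1, 3, 3), qvalue = c(0.05, 0.05, 0.05))
  sel <- call_tss(cand, fdr = 0.1)
  expect_equal(sel$offset, 200)  # tie between scores 3 broken proximally
  # nothing passes
  cand$qvalue <- c(0.5, 0.2, 0.9)
  expect_null(call_tss(cand, fdr = 0.1))
  # fdr threshold is inclusive
  cand$qvalue <- c(0.1, 0.5, 0.5)
  expect_equal(call_tss(cand, fdr = 0.1)$offset, 0)
})

empty_genes <- function()
  data.frame(id = character(), chrom = character(), start = numeric(),
             end = numeric(), strand = character(),
             stringsAsFactors = FALSE)

one_gene <- function(chrom, start, end, strand, id = "g1",
                     exons = data.frame(start = numeric(), end = numeric())) {
  g <- data.frame(id = id, chrom = chrom, start = start, end = end,
                  strand = strand, stringsAsFactors = FALSE)
  g$exons <- list(exons)
  g
}

call_row <- function(tss_start, tss_end, mirna_start = 20000,
                     mirna_end = 20150, strand = "+", chrom = "chr1") {
  data.frame(mirna_id = "m1", chrom = chrom, mirna_start = mirna_start,
             mirna_end = mirna_end, strand = strand, tss_start = tss_start,
             tss_end = tss_end, stringsAsFactors = FALSE)
}

test_that("a call within tolerance of an upstream gene TSS is shared", {
  # gene TSS at 15040, call bin [14900, 15000): midpoint 14950, distance 90
  g <- one_gene("chr1", 15040, 17000, "+")
  out <- categorize(call_row(14900, 15000), g, shared_tol = 100)
  expect_equal(out$category, "shared_upstream")
  expect_equal(out$distance_to_upstream_gene_tss, 90)
  # 2 kb away: independent
  g2 <- one_gene("chr1", 13000, 14000, "+")
  out2 <- categorize(call_row(14900, 15000), g2, shared_tol = 100)
  expect_equal(out2$category, "independent")
  # no upstream gene at all: independent
  out3 <- categorize(call_row(14900, 15000), empty_genes(), shared_tol = 100)
  expect_equal(out3$category, "independent")
  expect_true(is.na(out3$distance_to_upstream_gene_tss))
  # downstream genes do not count
  g4 <- one_gene("chr1", 25000, 27000, "+")
  out4 <- categorize(call_row(14900, 15000), g4, shared_tol = 100)
  expect_true(is.na(out4$distance_to_upstream_gene_tss))
})

test_that("sharing uses the closest upstream gene TSS, not the nearest gene", {
  # two upstream genes; the call sits on the farther gene's TSS
  g <- rbind(one_gene("chr1", 18000, 19000, "+", id = "near"),
             one_gene("chr1", 14950, 16000, "+", id = "far"))
  out <- categorize(call_row(14900, 15000), g, shared_tol = 100)
  expect_equal(out$category, "shared_upstream")
})

test_that("no-call rows stay category none", {
  out <- categorize(call_row(NA, NA), empty_genes())
  expect_equal(out$category, "none")
})

test_that("intronic flag requires full containment in an intron", {
  ex <- data.frame(start = c(10000, 14000), end = c(11000, 16000))
  host <- one_gene("chr1", 10000, 16000, "+", exons = ex)
  # miRNA inside the intron [11000, 14000)
  out <- categorize(call_row(NA, NA, mirna_start = 12000, mirna_end = 12150),
                    host)
  expect_true(out$intronic)
  # miRNA overlapping an exon is not intronic
  out2 <- categorize(call_row(NA, NA, mirna_start = 13800, mirna_end = 14200),
                     host)
  expect_false(out2$intronic)
  # intergenic miRNA is not intronic
  out3 <- categorize(call_row(NA, NA, mirna_start = 20000, mirna_end = 20150),
                     host)
  expect_false(out3$intronic)
})

test_that("published independent calls reproduce their gaps to the miRNA", {
  calls <- read_prediction_table(make_fixture_table1())
  mirnas <- data.frame(id = calls$mirna_id, chrom = calls$chrom,
                       start = calls$mirna_start, end = calls$mirna_end,
                       strand = calls$strand, stringsAsFactors = FALSE)
  ds <- distance_summaries(mirnas, empty_genes(), calls)
  gaps <- ds$independent_gap
  expect_equal(nrow(gaps), 42)
  expect_equal(gaps$gap[gaps$mirna_id == "MI0000989"], 300)   # ath-MIR171b
  expect_equal(gaps$gap[gaps$mirna_id == "MI0001005"], 2100)  # ath-MIR394a
  expect_equal(gaps$gap[gaps$mirna_id == "MI0000208"], 0)     # ath-MIR167a
  expect_true(all(gaps$gap >= 0 & gaps$gap < 10000))
  expect_true(all(gaps$gap %% 100 == 0))
  # no genes supplied: upstream distances are all NA
  expect_true(all(is.na(ds$upstream_gene$distance)))
})

test_that("upstream gene distances fall in 1 kb histogram classes", {
  mirnas <- mir("chr1", 20000, 20150, "+")
  g <- one_gene("chr1", 17500, 19000, "+")
  ds <- distance_summaries(mirnas, g, calls = NULL)
  expect_equal(ds$upstream_gene$distance, 2500)
  expect_equal(ds$upstream_gene$class_kb, 2)
})

test_that("scanning a simulated genome controls calls end to end", {
  st <- tiny_study(seed = 3)
  tr <- train_tss_classifier(st$tracks, st$ann$genes, st$cfg$genome,
                             n_random = 200, seed = 2,
                             config = tiny_svm_config(2))
  res <- scan_mirna_tss(tr$model, st$tracks, st$ann$mirnas, st$ann$genes,
                        st$cfg$genome, n_decoys = 2000, decoy_seed = 7)
  calls <- res$calls
  expect_equal(nrow(calls), nrow(st$ann$mirnas))
  called <- calls[!is.na(calls$tss_start), , drop = FALSE]
  # every called bin has the bin width (none of these sit at a chromosome end)
  expect_true(all(called$tss_end - called$tss_start == 100))
  expect_true(all(called$qvalue <= 0.1))
  expect_true(all(called$distance_to_mirna %% 100 == 0))
  expect_true(all(calls$category %in%
                  c("independent", "shared_upstream", "none")))
  expect_true(all(calls$category[is.na(calls$tss_start)] == "none"))
  # independent planted TSSs are recovered near the planted position
  truth <- st$ann$truth
  ind <- merge(calls, truth[truth$category == "independent", ],
               by = "mirna_id")
  ind <- ind[!is.na(ind$tss_start), , drop = FALSE]
  expect_true(nrow(ind) > 0)
  expect_true(all(ind$planted_tss >= ind$tss_start - 100 &
                  ind$planted_tss <= ind$tss_end + 100))

  # the set of called miRNAs grows monotonically with the FDR threshold
  cands <- res$candidates
  called_at <- function(fdr) {
    ids <- unique(cands$mirna_id)
    ids[vapply(ids, function(id)
      !is.null(call_tss(cands[cands$mirna_id == id, , drop = FALSE], fdr)),
      logical(1))]
  }
  expect_true(all(called_at(0.02) %in% called_at(0.1)))
  expect_true(all(called_at(0.1) %in% called_at(0.3)))

  # call_counts tallies the categories
  cc <- call_counts(calls)
  expect_equal(cc$n_mirnas, nrow(calls))
  expect_equal(cc$independent + cc$shared_upstream + cc$none, nrow(calls))
})
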