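# mirpromoter

Identification of microRNA promoters from multi-mark histone-modification
ChIP-Seq data.

Plant pri-miRNAs are processed so quickly that their 5' ends are rarely
observed, but active promoters leave a durable chromatin signature:
H3K4me3 and acetylation marks peak just downstream of transcription start
sites (TSSs). `mirpromoter` learns that signature from protein-coding gene
TSSs and scans upstream of each miRNA locus for it.

## Method

1. **Coverage.** Each ChIP-Seq library is reduced to one anchor per read
   and counted into 100 bp bins, normalized to reads per million per bin:
   `RPM_i = R_i * 1e6 / N`.
2. **Features.** Around each anchor, the RPM values of the 2k bins
   `u_k..u_1, d_1..d_k` (in transcriptional orientation, `d_1` = the
   anchor's bin) are concatenated mark by mark; 9 marks at the default
   k = 10 give 180 features.
3. **Classifier.** An RBF-kernel SVM (`e1071`) separates gene-TSS profiles
   from random genomic positions; `C` and `gamma` come from seeded
   cross-validated grid search, scores are oriented TSS-positive and
   calibrated to probabilities by Platt scaling.
4. **Scanning.** Candidate bins on a 100 bp grid anchored at the miRNA
   5' end, up to 10 kb upstream, are scored at their midpoints; empirical
   p-values against decoy positions (sampled away from gene TSSs) are
   adjusted by Benjamini–Hochberg across all candidates, and at most one
   bin per miRNA is called at FDR 0.1.
5. **Categories.** Calls within 100 bp of the closest upstream gene TSS
   are `shared_upstream`, others `independent`; miRNAs without a passing
   candidate are `none`; intronic miRNAs are flagged.

A fully seeded synthetic-genome generator (planted gene and miRNA
promoters, Poisson background + Gaussian peak reads per mark) supports
end-to-end validation, and `overlap_counts()` computes cross-method TSS
agreement at 100 bp tolerance.

## Worked example

```r
library(mirpromoter)

cfg    <- sim_config(genome = c(chr1 = 1.5e6), n_genes = 200,
                     n_mirnas = 12, seed = 42)
ann    <- simulate_annotations(cfg)
tracks <- tracks_from_readsets(simulate_reads(cfg, ann), cfg$genome)
tracks$H3K4me3
#> binned RPM track 'H3K4me3': 1 chromosome(s), bin 100 bp, N = 25879

fit <- train_tss_classifier(tracks, ann$genes, cfg$genome, n_random = 200,
         seed = 1, config = svm_config(C_grid = c(1, 10),
                                       gamma_grid = c(1e-3, 1e-2),
                                       cv_folds = 3, seed = 1))
fit$model
#> RBF-SVM TSS classifier: C = 10, gamma = 0.001, 180 features (9 marks, k = 10)

res <- scan_mirna_tss(fit$model, tracks, ann$mirnas, ann$genes, cfg$genome,
                      n_decoys = 5000, decoy_seed = 2)
res$calls[, c("mirna_name", "tss_start", "tss_end", "qvalue",
              "distance_to_mirna", "category")]
#>    mirna_name tss_start tss_end  qvalue distance_to_mirna        category
#> 1     mir0001    126233  126333 0.00667              2800 shared_upstream
#> 2     mir0002    146417  146517 0.00667              2300     independent
#> 3     mir0003    216785  216885 0.00667              1800 shared_upstream
#> 4     mir0004    230006  230106 0.00667              1400     independent
#> 5     mir0005    262883  262983 0.00667              1300     independent
#> 6     mir0006        NA      NA      NA                NA            none
#> ...
unlist(call_counts(res$calls))
#>        n_mirnas     independent shared_upstream            none intronic_shared
#>              12               5               2               5               0
```

All seven miRNAs with planted promoter signal are called and all five
signal-free miRNAs are left uncalled. Two calls on promoter-sharing
miRNAs land a bin away from the host gene TSS — just outside the 100 bp
sharing tolerance — and are reported as independent; the candidate grid is
anchored at the miRNA 5' end, so this quantization effect is expected.

The same pipeline is available from the command line via the installed
`exec/mirpromoter` script:

```sh
mirpromoter simulate --out-dir study --seed 5
mirpromoter train    --genes study/genes.gff3 --sizes study/chrom.sizes \
                     --reads-dir study/reads --out study/model.rds
mirpromoter scan     --model study/model.rds --mirnas study/mirnas.gff3 \
                     --genes study/genes.gff3 --sizes study/chrom.sizes \
                     --reads-dir study/reads --out-dir study/scan
```

Every command is bit-reproducible under a fixed `--seed` and writes a JSON
run report with resolved parameters and input checksums.

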