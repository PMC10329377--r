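#!/usr/bin/env Rscript
# SNP-by-SNP TRD scan of the simulated cohort: fits the null, allelic
# (overall and parent-specific) and genotypic models at every marker by grid
# quadrature, computes Bayes factors and DIC, selects the model and labels
# the inheritance pattern. Writes the full region table under results/.

suppressMessages(library(trdtrio))
gt <- read_genotypes("results/data/cohort_genotypes.tsv", "matrix_tsv")
ped <- read_pedigree("results/data/cohort_pedigree.tsv")

t0 <- Sys.time()
records <- trd_scan(gt, ped, mode = "snp")
cat("scanned", nrow(records), "markers in", format(Sys.time() - t0), "\n")

write.table(records, "results/scan_records.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sig <- records[records$bf_best >= 100, ]
cat(nrow(sig), "markers reach decisive evidence (BF >= 100):\n")
print(sig[, c("chrom", "start_bp", "allele", "selected", "pattern",
              "primary_est", "under_represented")])
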