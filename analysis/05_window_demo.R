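#!/usr/bin/env Rscript
# Haplotype-window demonstration: plant a 4-SNP recessive-lethal haplotype,
# run the sliding-window scan with biallelic recoding (each haplotype allele
# H_j against the pooled rest H_-j), and report the winning window allele.

suppressMessages(library(trdtrio))
dir.create("results", showWarnings = FALSE)

sim <- sim_trios(sim_config(
  n_sires = 150, offspring_per_sire = 40, n_chrom = 1, snps_per_chrom = 12,
  freq_b = 0.5,
  loci = list(list(chrom = 1, snp = 5:8, hap = "1111",
                   mechanism = "recessive_lethal", freq_b = 0.25)),
  seed = 1))
cat("planted recessive-lethal haplotype 1111 over SNPs 5-8; removed",
    sim$truth$n_removed, "non-viable offspring\n")

records <- trd_scan(sim$gt, sim$ped, mode = "windows", window_sizes = c(2, 4),
                    min_carrier_count = 20)
write.table(records, "results/window_records.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

best <- records[which.max(records$bf_best), ]
cat("top window allele:", best$allele, "\n")
cat("  selected model:", best$selected, " pattern:", best$pattern, "\n")
cat(sprintf("  alpha_g = %.2f, delta_g = %.2f, carrier frequency %.3f\n",
            best$est1, best$est2, best$carrier_freq))
cat(nrow(records), "window-allele records written\n")
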