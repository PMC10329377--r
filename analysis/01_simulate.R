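#!/usr/bin/env Rscript
# Build the synthetic study cohort: a half-sib trio population with three
# planted distortion mechanisms (overall allelic TRD, sire-specific TRD, a
# complete recessive lethal) on a 5-chromosome genome, plus a small null
# cohort used for calibration. Writes the datasets and the generating truth
# under results/.

suppressMessages(library(trdtrio))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
seed <- 1

fx <- make_fixture("planted_three_signals", seed = seed)
write_genotypes(fx$gt, "results/data/cohort_genotypes.tsv", "matrix_tsv")
write.table(fx$ped, "results/data/cohort_pedigree.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(fx$truth, "results/data/cohort_truth.json",
                     dataframe = "rows", auto_unbox = TRUE, digits = NA)

null_fx <- make_fixture("null_genome", seed = seed)
write_genotypes(null_fx$gt, "results/data/null_genotypes.tsv", "matrix_tsv")
write.table(null_fx$ped, "results/data/null_pedigree.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("cohort:", ncol(fx$gt$geno), "individuals,", nrow(fx$gt$geno), "SNPs;",
    nrow(fx$ped), "trios\n")
cat("planted loci:\n")
print(fx$truth[, c("marker_id", "mechanism", "alpha_s", "alpha_d",
                   "alpha_g", "delta_g", "n_removed")])
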