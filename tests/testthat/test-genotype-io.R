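test_that("VCF genotypes decode codes, phase and missingness", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 "FORMAT", "ind1", "ind2", sep = "\t"),
           paste("1", "1000", "snp1", "A", "C", ".", ".", ".", "GT", "0|1", "1|1", sep = "\t"),
           paste("1", "2000", "snp2", "G", "T", ".", ".", ".", "GT", "./.", "0/1", sep = "\t"),
           paste("1", "3000", "snp3", "G", "T,A", ".", ".", ".", "GT", "0/1", "0/0", sep = "\t"))
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  expect_message(gt <- read_genotypes(f, "vcf"), "non-biallelic")
  expect_equal(nrow(gt$geno), 2L)  # multi-allelic record dropped
  expect_equal(unname(gt$geno["snp1", ]), c(1L, 2L))
  expect_true(is.na(gt$geno["snp2", "ind1"]))
  expect_equal(unname(gt$geno["snp2", "ind2"]), 1L)
  # phase: snp1 entries phased, snp2/ind2 unphased
  expect_equal(unname(gt$hap1["snp1", ]), c(0L, 1L))
  expect_true(is.na(gt$hap1["snp2", "ind2"]))
})

test_that("matrix dialect round-trips codes, phase and missingness", {
  sim <- sim_trios(sim_config(n_sires = 5, offspring_per_sire = 5,
                              snps_per_chrom = 20, missing_rate = 0.1, seed = 42))
  for (dialect in c("matrix_tsv", "vcf")) {
    f <- tempfile()
    write_genotypes(sim$gt, f, dialect)
    back <- read_genotypes(f, dialect)
    expect_equal(back$geno, sim$gt$geno, info = dialect)
    expect_equal(back$hap1, sim$gt$hap1, info = dialect)
    expect_equal(back$hap2, sim$gt$hap2, info = dialect)
    expect_equal(back$map$pos_bp, sim$gt$map$pos_bp, info = dialect)
  }
})

test_that("duplicate marker ids and malformed cells are rejected", {
  map <- data.frame(chrom = "1", marker_id = c("m1", "m1"), pos_bp = c(1L, 2L))
  expect_error(genotype_table(matrix(0L, 2, 2), map), "duplicated")
  f <- tempfile()
  writeLines(c("marker_id\tchrom\tpos_bp\ts1", "m1\t1\t100\t7"), f)
  expect_error(read_genotypes(f, "matrix_tsv"), "malformed")
})

test_that("mendelian_check agrees with exhaustive gamete enumeration", {
  gametes <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  for (s in 0:2) for (d in 0:2) for (o in 0:2) {
    possible <- o %in% outer(gametes[[s + 1]], gametes[[d + 1]], `+`)
    expect_identical(mendelian_check(s, d, o), possible,
                     info = paste(s, d, o))
  }
  expect_false(mendelian_check(0, 0, 1))  # (AA, AA, AB)
  expect_true(mendelian_check(1, 1, 2))   # (AB, AB, BB)
})

test_that("assemble_trios drops missing, counts distinct het parents, flags small sets", {
  # 9 complete trios -> unusable at the default threshold
  ped9 <- data.frame(offspring = paste0("O", 1:9), sire = "S1",
                     dam = paste0("D", 1:9))
  g <- setNames(rep(1L, 19), c("S1", paste0("D", 1:9), paste0("O", 1:9)))
  geno <- matrix(g, nrow = 1, dimnames = list("m1", names(g)))
  gt <- genotype_table(geno, data.frame(chrom = "1", marker_id = "m1", pos_bp = 1L))
  ts <- assemble_trios(gt, ped9, "m1")
  expect_false(attr(ts, "usable"))
  expect_equal(attr(ts, "n_het_sires"), 1L)  # distinct parents, not trios

  # empty pedigree
  ts0 <- assemble_trios(gt, ped9[0, ], "m1")
  expect_equal(nrow(ts0), 0L)
  expect_equal(attr(ts0, "n_informative"), 0L)

  # missing genotypes: count equals brute-force over complete triples
  set.seed(7)
  tr <- random_trios(100)
  g_off <- tr$g_off
  g_off[sample(100, 10)] <- NA
  ids <- c(unique(tr$sire), tr$dam, tr$offspring)
  g_all <- c(setNames(sample(0:2, length(unique(tr$sire)), TRUE), unique(tr$sire)),
             setNames(tr$g_dam, tr$dam), setNames(g_off, tr$offspring))
  geno <- matrix(g_all, nrow = 1, dimnames = list("m1", names(g_all)))
  gt2 <- genotype_table(geno, data.frame(chrom = "1", marker_id = "m1", pos_bp = 1L))
  ts2 <- assemble_trios(gt2, tr[, 1:3], "m1", drop_inconsistent = FALSE)
  brute <- sum(!is.na(g_all[tr$sire]) & !is.na(g_all[tr$dam]) & !is.na(g_all[tr$offspring]))
  expect_equal(nrow(ts2), brute)

  # permutation invariance in pedigree row order
  perm <- sample(nrow(tr))
  ts3 <- assemble_trios(gt2, tr[perm, 1:3], "m1", drop_inconsistent = FALSE)
  expect_equal(sort(ts3$offspring), sort(ts2$offspring))
  expect_equal(attr(ts3, "n_informative"), attr(ts2, "n_informative"))
})

test_that("pedigree validation catches duplicates and self-ancestry", {
  expect_error(validate_pedigree(
    data.frame(offspring = c("A", "A"), sire = c("S", "S"), dam = c("D", "D"))),
    "duplicated")
  expect_error(validate_pedigree(
    data.frame(offspring = c("A", "B"), sire = c("B", "A"), dam = c("D1", "D2"))),
    "ancestor")
})

test_that("minor allele frequency folds and matches binomial sampling", {
  mk <- function(g) {
    geno <- matrix(as.integer(g), nrow = 1,
                   dimnames = list("m1", paste0("i", seq_along(g))))
    genotype_table(geno, data.frame(chrom = "1", marker_id = "m1", pos_bp = 1L))
  }
  expect_equal(minor_allele_frequency(mk(c(0, 0, 0, 0)), "m1"), 0)
  expect_equal(minor_allele_frequency(mk(c(0, 1, 1, 2)), "m1"), 0.5)
  expect_error(minor_allele_frequency(mk(rep(NA, 3)), "m1"), "missing")
  set.seed(3)
  g <- rbinom(1000, 2, 0.1)
  se <- sqrt(0.1 * 0.9 / (2 * 1000))
  expect_lt(abs(minor_allele_frequency(mk(g), "m1") - 0.1), 3 * se)
})
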