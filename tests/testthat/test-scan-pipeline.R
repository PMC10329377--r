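test_that("empirical null thresholds match exact binomial enumeration at n = 20", {
  nt <- build_null_table(c(20, 100), replicates = 1e6, p_null = 1e-5, seed = 1)
  # exact oracle: support of |k/20 - 0.5|, two-sided binomial tails
  k <- 0:20
  a_hat <- abs(k / 20 - 0.5)
  pr <- dbinom(k, 20, 0.5)
  support <- sort(unique(a_hat), decreasing = TRUE)
  exceed <- vapply(support, function(t) sum(pr[a_hat >= t]), numeric(1))
  exact_thr <- support[max(which(exceed <= 1e-5))]
  expect_equal(exact_thr, 0.5)  # P(|a| = 0.5) ~ 1.9e-6 <= 1e-5; 0.45 fails
  expect_equal(nt$threshold[nt$n_bin == 20 & nt$param == "alpha"], exact_thr)

  # monotonicity: thresholds shrink with information
  nt2 <- build_null_table(c(100, 10000), replicates = 2e5, p_null = 1e-4, seed = 2)
  for (p in unique(nt2$param)) {
    th <- nt2$threshold[nt2$param == p]
    expect_gt(th[1], th[2])
  }
  # reproducibility
  nt3 <- build_null_table(c(20, 100), replicates = 1e5, p_null = 1e-4, seed = 9)
  nt4 <- build_null_table(c(20, 100), replicates = 1e5, p_null = 1e-4, seed = 9)
  expect_identical(nt3, nt4)
})

test_that("filter ledger flags informative-parents, null-exceedance and CV", {
  nt <- build_null_table(c(100, 1000, 10000), replicates = 1e5, p_null = 1e-4,
                         seed = 3)
  rec <- data.frame(chrom = "1", start_bp = 1e6, end_bp = 1e6, n_snp = 1L,
                    allele = "m1", marker_ids = "m1", carrier_freq = 0.3,
                    n_trios = 500L, n_informative = 1000L,
                    n_het_sires = 19L, n_het_dams = 50L, n_inconsistent = 0L,
                    bf_overall = 500, bf_parent_specific = 200, bf_genotypic = 100,
                    bf_best = 500, dic_null = 100, dic_overall = 90,
                    dic_parent_specific = 92, dic_genotypic = 93,
                    selected = "allelic_overall", pattern = "overall-TRD",
                    est1 = 0.2, est2 = NA, primary_param = "alpha",
                    primary_est = 0.2, cv = 0.05, under_represented = 400L,
                    decisive = TRUE)
  out <- apply_filters(rec, nt)
  expect_false(out$f_informative)  # 19 sires, 50 dams: below both floors
  expect_true(out$f_null)
  expect_true(out$f_cv)
  expect_false(out$pass)

  ok <- rec
  ok$n_het_sires <- 25L
  expect_true(apply_filters(ok, nt)$pass)
  dams_only <- rec
  dams_only$n_het_dams <- 150L
  expect_true(apply_filters(dams_only, nt)$f_informative)

  # a null-level estimate fails the exceedance filter
  weak <- ok
  weak$est1 <- 0.005; weak$primary_est <- 0.005
  expect_false(apply_filters(weak, nt)$f_null)
  # an unstable posterior fails the CV filter
  shaky <- ok
  shaky$cv <- 0.35
  expect_false(apply_filters(shaky, nt)$f_cv)
})

test_that("a single fully-skewed sire family fails the robustness filter", {
  fx <- make_fixture("single_skewed_sire", seed = 1)
  sc <- trd_scan(fx$gt, fx$ped, mode = "snp", min_trios = 10)
  expect_equal(nrow(sc), 1L)
  expect_true(sc$bf_best[1] >= 100)  # the planted artifact is "decisive"
  nt <- build_null_table(c(100, 1000), replicates = 1e5, p_null = 1e-4, seed = 4)
  out <- apply_filters(sc, nt, gt = fx$gt, ped = fx$ped)
  expect_false(out$f_sire_robust)
  expect_false(out$pass)
})

test_that("best-BF deduplication equals brute-force overlap clustering", {
  recs <- data.frame(chrom = "1",
                     start_bp = c(100, 150, 400, 900) * 1000,
                     end_bp = c(200, 260, 500, 950) * 1000,
                     bf_best = c(150, 90, 120, 80))
  out <- dedup_best_bf(recs)
  expect_equal(out$bf_best, c(150, 120, 80))  # chain {1,2} keeps 150

  set.seed(47)
  rnd <- data.frame(chrom = sample(c("1", "2"), 60, TRUE),
                    start_bp = sample(1e6, 60))
  rnd$end_bp <- rnd$start_bp + sample(5e4, 60)
  rnd$bf_best <- runif(60, 1, 1000)
  out2 <- dedup_best_bf(rnd)
  # brute force: transitive overlap clusters per chromosome, then argmax
  brute <- do.call(rbind, lapply(split(rnd, rnd$chrom), function(r) {
    n <- nrow(r)
    adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
      r$start_bp[i] <= r$end_bp[j] && r$start_bp[j] <= r$end_bp[i]))
    comp <- as.numeric(seq_len(n))
    repeat {
      new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), numeric(1))
      if (identical(new, comp)) break
      comp <- new
    }
    do.call(rbind, lapply(split(r, comp), function(g) g[which.max(g$bf_best), ]))
  }))
  expect_setequal(out2$bf_best, brute$bf_best)
})

test_that("kernel smoothing preserves isolated peaks and decays as a Gaussian", {
  rec <- data.frame(chrom = "1", start_bp = 1e6, end_bp = 1e6, bf_best = 100)
  q <- data.frame(chrom = "1", pos_bp = c(1e6, 1.5e6, 2e6))
  tr <- kernel_smooth(rec, 5e5, query = q)
  expect_equal(tr$y[1], 100)
  expect_equal(tr$y[2], 100 * exp(-1/2), tolerance = 1e-10)
  expect_equal(tr$y[3], 100 * exp(-2), tolerance = 1e-10)

  two <- data.frame(chrom = "1", start_bp = c(0, 1e7), end_bp = c(0, 1e7),
                    bf_best = c(100, 100))
  mid <- kernel_smooth(two, 5e5, query = data.frame(chrom = "1", pos_bp = 5e6))
  expect_lt(mid$y, 1e-10 * 100)

  # linearity in BF and translation equivariance
  shifted <- rec
  shifted$start_bp <- shifted$end_bp <- rec$start_bp + 7e6
  doubled <- rec
  doubled$bf_best <- 200
  q2 <- data.frame(chrom = "1", pos_bp = q$pos_bp + 7e6)
  expect_equal(kernel_smooth(shifted, 5e5, query = q2)$y, tr$y)
  expect_equal(kernel_smooth(doubled, 5e5, query = q)$y, 2 * tr$y)
})

test_that("significance half-widths use rounded two-sided normal quantiles", {
  expect_equal(significance_halfwidth(5e5, 0.95), 980000)
  expect_equal(significance_halfwidth(5e5, 0.99), 1290000)
  expect_equal(significance_halfwidth(5e5, 0.999), 1645000)
  expect_error(significance_halfwidth(5e5, 1.2), "coverage")
})

test_that("core regions are separated local maxima of the smoothed track", {
  one <- data.frame(chrom = "1", start_bp = 2e6, end_bp = 2e6, bf_best = 500)
  core1 <- extract_core_regions(kernel_smooth(one, 5e5), 100)
  expect_equal(nrow(core1), 1L)
  expect_equal(core1$peak_bp, 2e6, tolerance = 5e4)
  expect_equal(core1$end_bp - core1$peak_bp, 980000)

  two <- data.frame(chrom = "1", start_bp = c(2e6, 7e6), end_bp = c(2e6, 7e6),
                    bf_best = c(500, 300))
  core2 <- extract_core_regions(kernel_smooth(two, 5e5), 100)
  expect_equal(nrow(core2), 2L)

  flat <- data.frame(chrom = "1", start_bp = 2e6, end_bp = 2e6, bf_best = 0)
  expect_equal(nrow(extract_core_regions(kernel_smooth(flat, 5e5), 0)), 0L)
})

test_that("under-represented offspring arithmetic", {
  expect_equal(under_represented(10000, 0.25), 5000L)
  expect_equal(under_represented(123, 0), 0L)
  expect_equal(under_represented(0, 0.4), 0L)
  expect_error(under_represented(10, 0.7))
  cnt <- counts_of(ABxAB = c(AA = 10, AB = 260, BB = 120))
  expect_equal(missing_homozygotes(cnt, -0.6), as.integer(round(390 / 4) - 10))
})

test_that("an all-null genome yields no decisive records", {
  fx <- make_fixture("null_genome", seed = 5)
  sc <- trd_scan(fx$gt, fx$ped, mode = "snp")
  expect_gt(nrow(sc), 40)
  expect_equal(sum(sc$bf_best >= 100), 0L)
})

test_that("a planted recessive-lethal haplotype wins its window scan", {
  loci <- list(list(chrom = 1, snp = 3:6, hap = "1111",
                    mechanism = "recessive_lethal", freq_b = 0.3))
  sim <- sim_trios(sim_config(n_sires = 80, offspring_per_sire = 30,
                              snps_per_chrom = 8, freq_b = 0.5, loci = loci,
                              seed = 8))
  sc <- trd_scan(sim$gt, sim$ped, mode = "windows", window_sizes = 4,
                 min_carrier_count = 20)
  expect_gt(nrow(sc), 0)
  best <- sc[which.max(sc$bf_best), ]
  expect_equal(best$start_bp, sim$gt$map$pos_bp[3])  # the planted window
  expect_match(best$allele, "1111$")
  expect_equal(best$pattern, "recessive")
})
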