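test_that("grid posterior reproduces Beta closed forms", {
  zero <- counts_of()
  f0 <- grid_fit(zero, "allelic_overall", 201)
  expect_equal(exp(f0$log_marginal), 1, tolerance = 1e-10)
  expect_equal(f0$post_mass, f0$prior_w / sum(f0$prior_w), tolerance = 1e-12)
  expect_equal(sum(f0$post_mass), 1, tolerance = 1e-10)

  # 10 A-transmissions, 0 B: posterior on u = alpha + 0.5 is Beta(11, 1)
  ten <- counts_of(ABxAA = c(AA = 10))
  f <- grid_fit(ten, "allelic_overall", 1001)
  expect_equal(exp(f$log_marginal), 1 / 11, tolerance = 1e-4)
  expect_equal(posterior_summary(f)$mean, 11 / 12 - 0.5, tolerance = 1e-4)
})

test_that("Bayes factors match exact integrals and Savage-Dickey to 3 digits", {
  ten <- counts_of(ABxAA = c(AA = 10))
  bf10 <- bayes_factor(ten, "allelic_overall", 1001)
  expect_equal(bf10, 1024 / 11, tolerance = 1e-3)
  five <- counts_of(ABxAA = c(AA = 5, AB = 5))
  bf55 <- bayes_factor(five, "allelic_overall", 1001)
  expect_equal(bf55, 1024 / 2772, tolerance = 1e-3)  # 1/Beta integral = 1/2772
  expect_equal(bayes_factor(counts_of(), "allelic_overall"), 1)

  for (cnt in list(ten, five)) {
    f <- grid_fit(cnt, "allelic_overall", 1001)
    expect_equal(savage_dickey_bf(f), bayes_factor(cnt, f), tolerance = 1e-3)
  }
  # 2-parameter models: flat-prior nested-model identity
  set.seed(17)
  cnt2 <- sample_counts("genotypic", c(-0.2, 0.1), c(40, 40, 40, 40, 80))
  for (m in c("allelic_parent_specific", "genotypic")) {
    f <- grid_fit(cnt2, m, 1001)
    expect_equal(savage_dickey_bf(f), bayes_factor(cnt2, f), tolerance = 1e-3,
                 info = m)
  }
})

test_that("MCMC matches the grid reference and is seed-reproducible", {
  mend <- counts_of(ABxAB = c(AA = 400, AB = 800, BB = 400))
  ch <- run_mcmc(mend, "allelic_overall", iterations = 11000, burn_in = 1000,
                 seed = 1)
  s <- posterior_summary(ch)
  mcse <- s$sd / sqrt(ch$n_effective[["alpha"]])
  expect_lt(abs(s$mean), 3 * mcse + 1e-4)

  ten <- counts_of(ABxAA = c(AA = 10))
  ch2 <- run_mcmc(ten, "allelic_overall", iterations = 21000, burn_in = 1000,
                  seed = 2)
  s2 <- posterior_summary(ch2)
  mcse2 <- s2$sd / sqrt(ch2$n_effective[["alpha"]])
  expect_lt(abs(s2$mean - (11 / 12 - 0.5)), 3 * mcse2)

  ch3 <- run_mcmc(ten, "allelic_overall", iterations = 11000, burn_in = 1000, seed = 7)
  ch4 <- run_mcmc(ten, "allelic_overall", iterations = 11000, burn_in = 1000, seed = 7)
  expect_identical(ch3$samples, ch4$samples)
})

test_that("MCMC and grid agree on a battery of random count tables", {
  set.seed(23)
  for (i in 1:6) {
    model <- sample(c("allelic_overall", "allelic_parent_specific", "genotypic"), 1)
    pars <- switch(model,
      allelic_overall = runif(1, -0.3, 0.3),
      allelic_parent_specific = runif(2, -0.3, 0.3),
      genotypic = { a <- runif(1, -0.5, 0.5); c(a, runif(1, -0.3, 1 - abs(a) - 0.05)) })
    cnt <- sample_counts(model, pars, sample(30:120, 5, TRUE))
    g <- posterior_summary(grid_fit(cnt, model, 201))
    ch <- run_mcmc(cnt, model, iterations = 16000, burn_in = 1000, seed = i)
    m <- posterior_summary(ch)
    for (p in g$param) {
      mcse <- m$sd[m$param == p] / sqrt(ch$n_effective[[p]])
      expect_lt(abs(g$mean[g$param == p] - m$mean[m$param == p]),
                4 * mcse + 0.01)
    }
  }
})

test_that("DIC reduces to the null deviance with no parameters and ranks true models", {
  cnt <- counts_of(ABxAA = c(AA = 30, AB = 34))
  expect_equal(dic(cnt, "null"), -2 * trd_loglik(cnt, "null"))

  # parent-specific truth: sire-only TRD
  set.seed(29)
  cnt_ps <- sample_counts("allelic_parent_specific", c(0.4, 0),
                          c(500, 500, 500, 500, 0))
  d_ov <- dic(cnt_ps, "allelic_overall", grid_fit(cnt_ps, "allelic_overall", 201))
  d_ps <- dic(cnt_ps, "allelic_parent_specific",
              grid_fit(cnt_ps, "allelic_parent_specific", 201))
  expect_lt(d_ps, d_ov - 3)

  # complete recessive lethality favors the genotypic model
  cnt_rl <- sample_counts("genotypic", c(-2/3, 1/3), c(300, 300, 300, 300, 800))
  fits <- lapply(c(o = "allelic_overall", p = "allelic_parent_specific",
                   g = "genotypic"), function(m) dic(cnt_rl, m, grid_fit(cnt_rl, m, 201)))
  expect_lt(fits$g, min(fits$o, fits$p) - 3)
})

test_that("model selection applies the 3-unit parsimony rule", {
  sel <- select_model(c(allelic_overall = 100, allelic_parent_specific = 99))
  expect_equal(sel$selected, "allelic_overall")
  sel2 <- select_model(c(allelic_overall = 100, genotypic = 90))
  expect_equal(sel2$selected, "genotypic")
  sel3 <- select_model(c(null = 100, allelic_overall = 98.5))
  expect_equal(sel3$selected, "null")
})

test_that("pattern classification reproduces the canonical genotypic labels", {
  gsum <- function(a, d) data.frame(param = c("alpha_g", "delta_g"),
                                    mean = c(a, d), sd = 0.01, median = c(a, d),
                                    lower = c(a, d) - 0.02, upper = c(a, d) + 0.02,
                                    cv = 0.05)
  expect_equal(classify_pattern("genotypic", gsum(-0.66, 0.33)), "recessive")
  expect_equal(classify_pattern("genotypic", gsum(0.05, 0.25)), "heterosis excess")
  expect_equal(classify_pattern("genotypic", gsum(-0.40, -0.25)), "heterosis deficiency")
  expect_equal(classify_pattern("genotypic", gsum(0.09, -0.04)), "homozygote advantage")
  expect_equal(classify_pattern("genotypic", gsum(-0.05, 0.04)), "homozygote disadvantage")

  asum <- function(s, d, s_sig, d_sig) {
    half <- function(sig, m) if (sig) abs(m) * 0.5 else abs(m) + 0.05
    data.frame(param = c("alpha_s", "alpha_d"), mean = c(s, d), sd = 0.01,
               median = c(s, d),
               lower = c(s - half(s_sig, s), d - half(d_sig, d)),
               upper = c(s + half(s_sig, s), d + half(d_sig, d)), cv = 0.05)
  }
  expect_equal(classify_pattern("allelic_parent_specific", asum(-0.4, 0.0, TRUE, FALSE)),
               "sire-TRD")
  expect_equal(classify_pattern("allelic_parent_specific", asum(0.01, -0.3, FALSE, TRUE)),
               "dam-TRD")
  expect_equal(classify_pattern("allelic_parent_specific", asum(-0.4, -0.2, TRUE, TRUE)),
               "sire+dam-TRD")
  expect_equal(classify_pattern("allelic_overall", NULL), "overall-TRD")
})

test_that("decisive Bayes factors under the null are rare (calibration)", {
  set.seed(37)
  n_dec <- 0
  for (i in 1:100) {
    cnt <- sample_counts("null", numeric(), rep(200, 5))
    bf <- max(vapply(c("allelic_overall", "allelic_parent_specific", "genotypic"),
                     function(m) bayes_factor(cnt, m, 201), numeric(1)))
    if (bf >= 100) n_dec <- n_dec + 1
  }
  expect_lte(n_dec, 1)
})

test_that("allelic parameter recovery is unbiased with calibrated intervals", {
  # scaled-down recovery grid: 40 replicates at n = 5000 across 4 truths
  set.seed(43)
  for (truth in c(-0.3, -0.1, 0.1, 0.3)) {
    means <- numeric(10)
    cover <- logical(10)
    for (r in 1:10) {
      cnt <- sample_counts("allelic_overall", truth, c(1250, 1250, 1250, 1250, 0))
      s <- posterior_summary(grid_fit(cnt, "allelic_overall", 201))
      means[r] <- s$mean
      cover[r] <- s$lower <= truth && truth <= s$upper
    }
    expect_lt(abs(mean(means) - truth), 0.02)
    expect_gte(mean(cover), 0.7)   # 10 replicates: >= 7 covering
  }
})
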