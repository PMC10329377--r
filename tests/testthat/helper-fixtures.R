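# shared helpers: small count tables, random trios, multinomial sampling
# from the model kernels

# build a mating_counts table from named cell counts, e.g.
# counts_of(ABxAA = c(AA = 10)) or counts_of(ABxAB = c(AA = 4, AB = 8, BB = 4))
counts_of <- function(...) {
  cells <- list(...)
  m <- matrix(0, 5, 3, dimnames = list(c("ABxAA", "ABxBB", "AAxAB", "BBxAB", "ABxAB"),
                                       c("AA", "AB", "BB")))
  for (mt in names(cells)) m[mt, names(cells[[mt]])] <- cells[[mt]]
  mating_counts(m)
}

# random Mendelian-consistent trios as a bare data.frame
random_trios <- function(n, seed = 1) {
  set.seed(seed)
  g_s <- sample(0:2, n, replace = TRUE)
  g_d <- sample(0:2, n, replace = TRUE)
  gam <- function(g) ifelse(g == 1L, rbinom(length(g), 1, 0.5), as.integer(g == 2L))
  data.frame(offspring = paste0("O", seq_len(n)),
             sire = paste0("S", sample(50, n, replace = TRUE)),
             dam = paste0("D", seq_len(n)),
             g_sire = g_s, g_dam = g_d, g_off = gam(g_s) + gam(g_d))
}

# multinomial offspring counts from a model kernel at given per-mating sizes
sample_counts <- function(model, params, n_per_mating) {
  m <- matrix(0, 5, 3, dimnames = list(c("ABxAA", "ABxBB", "AAxAB", "BBxAB", "ABxAB"),
                                       c("AA", "AB", "BB")))
  p <- model_probs(model, params)
  for (i in seq_len(5)) {
    if (n_per_mating[i] > 0) m[i, ] <- stats::rmultinom(1, n_per_mating[i], p[i, ])
  }
  mating_counts(m)
}

# small phased genotype table built by hand
tiny_phased_gt <- function(h1, h2, chrom = "1", spacing = 1000L) {
  n_mark <- nrow(h1)
  colnames(h1) <- colnames(h2) <- paste0("i", seq_len(ncol(h1)))
  map <- data.frame(chrom = chrom, marker_id = paste0("m", seq_len(n_mark)),
                    pos_bp = seq_len(n_mark) * spacing)
  genotype_table(h1 + h2, map, hap1 = h1, hap2 = h2)
}
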