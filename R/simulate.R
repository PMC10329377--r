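#' Simulation configuration for half-sib trio data
#'
#' Describes a gene-drop experiment mirroring the structure of large
#' dairy-cattle trio datasets: paternal half-sib families (each dam produces
#' one offspring), biallelic SNPs on one or more chromosomes at regular
#' spacing, founder allele frequencies, and a list of loci carrying known
#' distortion mechanisms. Defaults give a compact but realistically
#' structured cohort; the inter-SNP spacing default (50 kb) matches the
#' order of a 50K bovine array.
#'
#' @param n_sires number of sires.
#' @param offspring_per_sire scalar, per-sire vector, or `c(min, max)` range
#'   sampled uniformly (half-sib family sizes from tens to thousands are
#'   supported).
#' @param n_chrom,snps_per_chrom,spacing_bp genome layout.
#' @param freq_b founder frequency of allele B per SNP: scalar, vector of
#'   length `n_chrom * snps_per_chrom`, or `NULL` to draw each from
#'   `U(0.1, 0.9)`.
#' @param loci list of planted-mechanism specs; each element a list with
#'   `chrom`, `snp` (index within the chromosome), `mechanism` (one of
#'   `"null"`, `"allelic"`, `"genotypic"`, `"recessive_lethal"`), mechanism
#'   parameters (`alpha_s`, `alpha_d` or `alpha_g`, `delta_g`), and optional
#'   `freq_b` override at that SNP. `recessive_lethal` is shorthand for
#'   `genotypic(-2/3, +1/3)`: complete lethality of the AA genotype.
#' @param error_rate,missing_rate genotyping-error and missingness rates
#'   applied to the emitted table (see [inject_errors()]).
#' @param recomb_rate recombination probability per base pair between
#'   adjacent markers (default 1e-8, i.e. 1 cM/Mbp).
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sires = 100, offspring_per_sire = 20, n_chrom = 1,
                       snps_per_chrom = 50, spacing_bp = 50000, freq_b = NULL,
                       loci = list(), error_rate = 0, missing_rate = 0,
                       recomb_rate = 1e-8, seed = 1) {
  for (lc in loci) {
    stopifnot(lc$mechanism %in% c("null", "allelic", "genotypic", "recessive_lethal"))
    if (lc$mechanism == "allelic") {
      stopifnot(abs(lc$alpha_s) <= 0.5, abs(lc$alpha_d %||% lc$alpha_s) <= 0.5)
    }
    if (lc$mechanism == "genotypic") {
      stopifnot(genotypic_valid(lc$alpha_g, lc$delta_g))
    }
  }
  structure(list(n_sires = n_sires, offspring_per_sire = offspring_per_sire,
                 n_chrom = n_chrom, snps_per_chrom = snps_per_chrom,
                 spacing_bp = spacing_bp, freq_b = freq_b, loci = loci,
                 error_rate = error_rate, missing_rate = missing_rate,
                 recomb_rate = recomb_rate, seed = seed),
            class = "sim_config")
}

## one meiosis per column: parent haplotype matrices (snp x n), recombination
## probability per adjacent interval
.meiosis <- function(h_a, h_b, r) {
  n <- ncol(h_a)
  m <- nrow(h_a)
  src <- matrix(FALSE, m, n)
  cur <- stats::runif(n) < 0.5
  src[1, ] <- cur
  if (m > 1) {
    cross <- matrix(stats::runif((m - 1) * n) < r, m - 1, n)
    for (k in 2:m) {
      cur <- xor(cur, cross[k - 1, ])
      src[k, ] <- cur
    }
  }
  out <- h_a
  out[src] <- h_b[src]
  out
}

#' Gene-drop simulation of a half-sib trio cohort
#'
#' Founder (sire and dam) haplotypes are drawn SNP-wise from the configured
#' allele frequencies; each offspring receives one recombinant gamete from
#' its sire and one from its dam. At allelic-distortion loci a heterozygous
#' parent transmits allele A with probability `0.5 + alpha_s` (sire) or
#' `0.5 + alpha_d` (dam), implemented by accept-reject on the gamete. At
#' genotypic loci the zygote is retained with probability proportional to
#' the ratio of the mating-specific genotypic kernel to the Mendelian
#' kernel, so surviving offspring genotypes follow the genotypic model
#' exactly; rejected zygotes are tallied as removed (non-viable) offspring.
#'
#' @param config a [sim_config()].
#' @return list with `gt` (phased [genotype_table()] over all parents and
#'   offspring), `ped` (pedigree data.frame), and `truth` (per-locus
#'   data.frame: marker, mechanism, true parameters, founder and realized
#'   parental carrier frequency of allele B, removed-offspring count).
#' @export
sim_trios <- function(config) {
  set.seed(config$seed)
  n_snp_total <- config$n_chrom * config$snps_per_chrom
  freq <- config$freq_b
  if (is.null(freq)) freq <- stats::runif(n_snp_total, 0.1, 0.9)
  if (length(freq) == 1) freq <- rep(freq, n_snp_total)
  stopifnot(length(freq) == n_snp_total)

  map <- data.frame(
    chrom = rep(as.character(seq_len(config$n_chrom)), each = config$snps_per_chrom),
    marker_id = paste0("c", rep(seq_len(config$n_chrom), each = config$snps_per_chrom),
                       "_s", rep(seq_len(config$snps_per_chrom), config$n_chrom)),
    pos_bp = rep(seq_len(config$snps_per_chrom) * config$spacing_bp, config$n_chrom))

  ## planted loci: index into the global map, apply frequency overrides.
  ## A locus may span several SNPs (a planted haplotype): `snp` is then a
  ## vector of indices and `hap` the carrier haplotype string; the carrier
  ## segment plays the role of allele B.
  loci <- lapply(config$loci, function(lc) {
    lc$idx <- (lc$chrom - 1L) * config$snps_per_chrom + lc$snp
    if (length(lc$idx) > 1 && is.null(lc$hap)) {
      stop("multi-SNP locus needs a carrier haplotype string `hap`")
    }
    if (lc$mechanism == "recessive_lethal") {
      lethal_b <- identical(lc$lethal, "B") || length(lc$idx) > 1
      lc$mechanism <- "genotypic"
      lc$alpha_g <- if (lethal_b) 2 / 3 else -2 / 3
      lc$delta_g <- 1 / 3
      lc$recessive_lethal <- TRUE
    }
    if (lc$mechanism == "allelic" && is.null(lc$alpha_d)) lc$alpha_d <- lc$alpha_s
    lc
  })
  for (lc in loci) {
    if (!is.null(lc$freq_b) && length(lc$idx) == 1) freq[lc$idx] <- lc$freq_b
  }

  ops <- config$offspring_per_sire
  n_off_per_sire <- if (length(ops) == 1) rep(ops, config$n_sires)
    else if (length(ops) == 2 && config$n_sires != 2)
      sample(seq(ops[1], ops[2]), config$n_sires, replace = TRUE)
    else { stopifnot(length(ops) == config$n_sires); ops }
  n_off <- sum(n_off_per_sire)

  sire_ids <- paste0("S", seq_len(config$n_sires))
  dam_ids <- paste0("D", seq_len(n_off))
  off_ids <- paste0("O", seq_len(n_off))
  ped <- data.frame(offspring = off_ids,
                    sire = rep(sire_ids, n_off_per_sire),
                    dam = dam_ids)
  sire_of <- rep(seq_len(config$n_sires), n_off_per_sire)

  n_par <- config$n_sires + n_off   # sires + one dam per offspring
  ## founder haplotypes, snp x individual, one matrix per slot
  par_h1 <- matrix(stats::rbinom(n_snp_total * n_par, 1, freq), n_snp_total)
  par_h2 <- matrix(stats::rbinom(n_snp_total * n_par, 1, freq), n_snp_total)
  ## planted multi-SNP carrier haplotypes: set the segment to the carrier
  ## string at the target frequency, scrub chance copies elsewhere
  for (lc in loci) {
    if (length(lc$idx) == 1) next
    hap_vec <- as.integer(strsplit(lc$hap, "")[[1]])
    stopifnot(length(hap_vec) == length(lc$idx))
    for (hmat in c("h1", "h2")) {
      m <- if (hmat == "h1") par_h1 else par_h2
      carrier <- stats::runif(n_par) < (lc$freq_b %||% 0.05)
      m[lc$idx, carrier] <- hap_vec
      chance <- !carrier & colSums(m[lc$idx, , drop = FALSE] == hap_vec) == length(hap_vec)
      if (any(chance)) {   # flip one SNP so only planted carriers carry it
        flip_row <- lc$idx[sample.int(length(lc$idx), sum(chance), replace = TRUE)]
        m[cbind(flip_row, which(chance))] <- 1L - m[cbind(flip_row, which(chance))]
      }
      if (hmat == "h1") par_h1 <- m else par_h2 <- m
    }
  }
  sire_cols <- seq_len(config$n_sires)
  dam_cols <- config$n_sires + seq_len(n_off)

  off_h1 <- matrix(NA_integer_, n_snp_total, n_off)  # paternal slot
  off_h2 <- matrix(NA_integer_, n_snp_total, n_off)
  removed <- stats::setNames(rep(0L, length(loci)),
                             vapply(loci, function(l) map$marker_id[l$idx[1]], ""))

  for (ch in seq_len(config$n_chrom)) {
    rows <- which(map$chrom == as.character(ch))
    r <- pmin(0.5, config$recomb_rate * diff(map$pos_bp[rows]))
    ch_loci <- Filter(function(l) l$chrom == ch, loci)

    sh1 <- par_h1[rows, sire_cols, drop = FALSE]
    sh2 <- par_h2[rows, sire_cols, drop = FALSE]
    dh1 <- par_h1[rows, dam_cols, drop = FALSE]
    dh2 <- par_h2[rows, dam_cols, drop = FALSE]

    sg <- .meiosis(sh1[, sire_of, drop = FALSE], sh2[, sire_of, drop = FALSE], r)
    dg <- .meiosis(dh1, dh2, r)

    ## Mechanisms act on the focal locus of the transmitted gametes only;
    ## flanking transmission stays Mendelian (hitchhiking of linked markers
    ## through within-family coupling is deliberately not emulated, so a
    ## planted signal stays local).
    for (lc in ch_loci) {
      lr <- match(lc$idx, rows)
      ## carrier dosage (copies of allele B / of the carrier segment)
      seg_eq <- function(m, lrows, hap_vec) {
        if (length(lrows) == 1) m[lrows, ] else
          as.integer(colSums(m[lrows, , drop = FALSE] == hap_vec) == length(hap_vec))
      }
      hap_vec <- if (length(lr) > 1) as.integer(strsplit(lc$hap, "")[[1]]) else 1L
      s1 <- seg_eq(sh1, lr, hap_vec)[sire_of]
      s2 <- seg_eq(sh2, lr, hap_vec)[sire_of]
      d1 <- seg_eq(dh1, lr, hap_vec)
      d2 <- seg_eq(dh2, lr, hap_vec)
      tx_s <- seg_eq(sg, lr, hap_vec)   # transmitted carrier status
      tx_d <- seg_eq(dg, lr, hap_vec)

      if (lc$mechanism == "allelic") {
        for (side in c("s", "d")) {
          a <- if (side == "s") lc$alpha_s else lc$alpha_d
          if (a == 0) next
          p1 <- if (side == "s") s1 else d1
          p2 <- if (side == "s") s2 else d2
          het <- which(p1 != p2)
          if (!length(het)) next
          new_tx <- stats::rbinom(length(het), 1, 0.5 - a)  # P(carrier B) = 0.5 - a
          if (side == "s") {
            sh_src1 <- sh1[, sire_of, drop = FALSE]; sh_src2 <- sh2[, sire_of, drop = FALSE]
            sg <- .write_focal(sg, sh_src1, sh_src2, lr, het, new_tx, p1)
            tx_s[het] <- new_tx
          } else {
            sh_src1 <- dh1; sh_src2 <- dh2
            dg <- .write_focal(dg, sh_src1, sh_src2, lr, het, new_tx, p1)
            tx_d[het] <- new_tx
          }
        }
      } else if (lc$mechanism == "genotypic") {
        gs <- s1 + s2
        gd <- d1 + d2
        informative <- which(gs == 1L | gd == 1L)
        n_rm <- 0L
        if (length(informative)) {
          active <- informative
          cur_s <- tx_s; cur_d <- tx_d
          guard <- 0
          while (length(active)) {
            guard <- guard + 1
            if (guard > 100000) stop("viability rejection did not converge")
            w <- .genotypic_accept_prob(gs[active], gd[active],
                                        cur_s[active] + cur_d[active],
                                        lc$alpha_g, lc$delta_g)
            die <- stats::runif(length(active)) >= w
            n_rm <- n_rm + sum(die)
            dead <- active[die]
            if (length(dead)) {
              ## conceive a replacement: Mendelian redraw of the focal alleles
              cur_s[dead] <- ifelse(gs[dead] == 1L,
                                    stats::rbinom(length(dead), 1, 0.5),
                                    as.integer(gs[dead] == 2L))
              cur_d[dead] <- ifelse(gd[dead] == 1L,
                                    stats::rbinom(length(dead), 1, 0.5),
                                    as.integer(gd[dead] == 2L))
            }
            active <- dead
          }
          chg_s <- which(cur_s != tx_s)
          chg_d <- which(cur_d != tx_d)
          sh_src1 <- sh1[, sire_of, drop = FALSE]; sh_src2 <- sh2[, sire_of, drop = FALSE]
          sg <- .write_focal(sg, sh_src1, sh_src2, lr, chg_s, cur_s[chg_s], s1)
          sh_src1 <- dh1; sh_src2 <- dh2
          dg <- .write_focal(dg, sh_src1, sh_src2, lr, chg_d, cur_d[chg_d], d1)
        }
        mid <- map$marker_id[lc$idx[1]]
        removed[names(removed) == mid] <- removed[names(removed) == mid] + n_rm
      }
    }
    off_h1[rows, ] <- sg
    off_h2[rows, ] <- dg
  }

  h1 <- cbind(par_h1[, sire_cols], par_h1[, dam_cols], off_h1)
  h2 <- cbind(par_h2[, sire_cols], par_h2[, dam_cols], off_h2)
  colnames(h1) <- colnames(h2) <- c(sire_ids, dam_ids, off_ids)
  gt <- genotype_table(h1 + h2, map, hap1 = h1, hap2 = h2)
  if (config$error_rate > 0 || config$missing_rate > 0) {
    gt <- inject_errors(gt, config$error_rate, config$missing_rate)
  }

  truth <- if (length(loci)) do.call(rbind, lapply(loci, function(lc) {
    if (length(lc$idx) == 1) {
      par_freq <- mean(c(par_h1[lc$idx, ], par_h2[lc$idx, ]))
      founder_freq <- freq[lc$idx]
    } else {
      hap_vec <- as.integer(strsplit(lc$hap, "")[[1]])
      is_car <- function(m) colSums(m[lc$idx, , drop = FALSE] == hap_vec) == length(hap_vec)
      par_freq <- mean(c(is_car(par_h1), is_car(par_h2)))
      founder_freq <- lc$freq_b %||% NA_real_
    }
    data.frame(marker_id = map$marker_id[lc$idx[1]],
               chrom = as.character(lc$chrom), pos_bp = map$pos_bp[lc$idx[1]],
               n_snp = length(lc$idx),
               hap = if (length(lc$idx) > 1) lc$hap else NA_character_,
               mechanism = if (isTRUE(lc$recessive_lethal)) "recessive_lethal"
                           else lc$mechanism,
               alpha_s = lc$alpha_s %||% NA_real_,
               alpha_d = lc$alpha_d %||% NA_real_,
               alpha_g = lc$alpha_g %||% NA_real_,
               delta_g = lc$delta_g %||% NA_real_,
               freq_b_founder = founder_freq,
               freq_b_parents = par_freq,
               n_removed = removed[[map$marker_id[lc$idx[1]]]])
  })) else data.frame()

  list(gt = gt, ped = ped, truth = truth)
}

## overwrite the transmitted focal allele (single SNP) or focal segment
## (multi-SNP carrier haplotype) of gametes `who` so its carrier status
## equals `carrier`; for segments, copy whichever parental haplotype has the
## requested status (`p1_carrier` = carrier status of the parent's first hap)
.write_focal <- function(gam, p_h1, p_h2, lrows, who, carrier, p1_carrier) {
  if (!length(who)) return(gam)
  if (length(lrows) == 1) {
    gam[lrows, who] <- carrier
    return(gam)
  }
  use1 <- p1_carrier[who] == carrier
  for (j in seq_along(who)) {
    src <- if (use1[j]) p_h1 else p_h2
    gam[lrows, who[j]] <- src[lrows, who[j]]
  }
  gam
}

## acceptance probability of a zygote under the genotypic kernel relative to
## Mendelian sampling, scaled so the max over possible offspring is 1
.genotypic_accept_prob <- function(g_sire, g_dam, g_off, alpha_g, delta_g) {
  key <- paste0(pmin(g_sire, 3), "_", g_dam)
  mating <- ifelse(g_sire == 1 & g_dam == 0, "ABxAA",
            ifelse(g_sire == 1 & g_dam == 2, "ABxBB",
            ifelse(g_sire == 0 & g_dam == 1, "AAxAB",
            ifelse(g_sire == 2 & g_dam == 1, "BBxAB",
            ifelse(g_sire == 1 & g_dam == 1, "ABxAB", NA)))))
  w <- rep(1, length(g_off))
  for (m in unique(mating[!is.na(mating)])) {
    pt <- genotypic_probs(m, alpha_g, delta_g)
    pm <- allelic_probs(m, 0, 0)
    ratio <- ifelse(pm > 0, pt / pm, 0)
    ratio <- ratio / max(ratio)
    sel <- !is.na(mating) & mating == m
    w[sel] <- ratio[g_off[sel] + 1L]
  }
  w
}

#' Inject genotyping errors and missingness
#'
#' Each entry is independently flipped to a random *different* genotype code
#' with probability `error_rate` and set missing with probability
#' `missing_rate`. Flipped entries lose their phase (an erroneous call
#' carries no valid haplotype assignment); masked entries lose everything.
#'
#' @param gt a [genotype_table()].
#' @param error_rate,missing_rate rates in `[0, 1]`.
#' @param seed optional seed.
#' @return the modified table, with attributes `n_flipped` and `n_masked`.
#' @export
inject_errors <- function(gt, error_rate, missing_rate, seed = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 1, missing_rate >= 0, missing_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  geno <- gt$geno
  present <- !is.na(geno)
  flip <- present & matrix(stats::runif(length(geno)) < error_rate, nrow(geno))
  if (any(flip)) {
    old <- geno[flip]
    shift <- sample(1:2, sum(flip), replace = TRUE)
    geno[flip] <- (old + shift) %% 3L
    if (is.phased(gt)) {
      gt$hap1[flip] <- NA_integer_
      gt$hap2[flip] <- NA_integer_
    }
  }
  mask <- matrix(stats::runif(length(geno)) < missing_rate, nrow(geno))
  if (any(mask)) {
    geno[mask] <- NA_integer_
    if (is.phased(gt)) {
      gt$hap1[mask] <- NA_integer_
      gt$hap2[mask] <- NA_integer_
    }
  }
  out <- genotype_table(geno, gt$map, hap1 = gt$hap1, hap2 = gt$hap2)
  attr(out, "n_flipped") <- sum(flip)
  attr(out, "n_masked") <- sum(mask & present)
  out
}

#' Named deterministic simulation fixtures
#'
#' Small datasets used across the validation suite:
#' * `null_genome` — one chromosome, 50 SNPs, no distortion (calibration).
#' * `planted_three_signals` — 5 chromosomes x 200 SNPs, 300 sires x 50
#'   offspring, three planted loci: overall allelic TRD (`alpha = -0.3`),
#'   sire-specific TRD (`alpha_s = -0.4`, `alpha_d = 0`), and a complete
#'   recessive lethal.
#' * `single_skewed_sire` — 25 heterozygous sires, one of which transmits
#'   allele B to all 60 of its offspring while the rest segregate
#'   Mendelian-ly (genotyping-artifact fixture; built directly, not
#'   gene-dropped).
#' * `table1_patterns` — five genotypic loci at the canonical pattern
#'   parameter pairs: recessive (-0.66, 0.33), heterosis excess
#'   (0.05, 0.25), heterosis deficiency (-0.40, -0.25), homozygote advantage
#'   (0.09, -0.04), homozygote disadvantage (-0.05, 0.04).
#'
#' @param name fixture name.
#' @param seed integer seed.
#' @return list with `gt`, `ped`, `truth` as in [sim_trios()].
#' @export
make_fixture <- function(name = c("null_genome", "planted_three_signals",
                                  "single_skewed_sire", "table1_patterns"),
                         seed = 1) {
  name <- match.arg(name)
  if (name == "null_genome") {
    return(sim_trios(sim_config(n_sires = 50, offspring_per_sire = 20,
                                n_chrom = 1, snps_per_chrom = 50, seed = seed)))
  }
  if (name == "planted_three_signals") {
    loci <- list(
      list(chrom = 1, snp = 100, mechanism = "allelic",
           alpha_s = -0.3, alpha_d = -0.3, freq_b = 0.5),
      list(chrom = 3, snp = 50, mechanism = "allelic",
           alpha_s = -0.4, alpha_d = 0, freq_b = 0.5),
      list(chrom = 5, snp = 150, mechanism = "recessive_lethal", freq_b = 0.8))
    return(sim_trios(sim_config(n_sires = 300, offspring_per_sire = 50,
                                n_chrom = 5, snps_per_chrom = 200,
                                loci = loci, seed = seed)))
  }
  if (name == "table1_patterns") {
    pars <- list(c(-0.66, 0.33), c(0.05, 0.25), c(-0.40, -0.25),
                 c(0.09, -0.04), c(-0.05, 0.04))
    loci <- lapply(seq_along(pars), function(i) {
      list(chrom = 1, snp = i * 8 - 4, mechanism = "genotypic",
           alpha_g = pars[[i]][1], delta_g = pars[[i]][2], freq_b = 0.5)
    })
    return(sim_trios(sim_config(n_sires = 200, offspring_per_sire = 50,
                                n_chrom = 1, snps_per_chrom = 40,
                                loci = loci, seed = seed)))
  }
  ## single_skewed_sire: constructed directly — one large fully-skewed
  ## heterozygous sire family among 24 small Mendelian families, the
  ## archetypal genotyping-error artifact
  set.seed(seed)
  n_sires <- 25
  off_per <- c(60, rep(5, 24))
  n_off <- sum(off_per)
  sire_ids <- paste0("S", seq_len(n_sires))
  dam_ids <- paste0("D", seq_len(n_off))
  off_ids <- paste0("O", seq_len(n_off))
  ped <- data.frame(offspring = off_ids, sire = rep(sire_ids, off_per),
                    dam = dam_ids)
  ## all sires het (1), all dams hom A (0); sire S1 always transmits B
  sire_tx <- c(rep(1L, off_per[1]),
               stats::rbinom(n_off - off_per[1], 1, 0.5))
  g_off <- sire_tx                       # dam transmits A (0)
  g <- c(stats::setNames(rep(1L, n_sires), sire_ids),
         stats::setNames(rep(0L, n_off), dam_ids),
         stats::setNames(g_off, off_ids))
  geno <- matrix(g, nrow = 1, dimnames = list("c1_s1", names(g)))
  map <- data.frame(chrom = "1", marker_id = "c1_s1", pos_bp = 50000L)
  list(gt = genotype_table(geno, map), ped = ped,
       truth = data.frame(marker_id = "c1_s1", mechanism = "skewed_sire_artifact"))
}
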