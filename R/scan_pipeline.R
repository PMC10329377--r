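#' Genome scan for transmission ratio distortion
#'
#' Runs the TRD machinery over every SNP (mode `"snp"`) or over every
#' haplotype allele of every sliding window (mode `"windows"`): trios are
#' assembled at each (pseudo-)marker, Mendelian-inconsistent trios excluded,
#' offspring counts tabulated by mating, the three TRD models fitted by grid
#' quadrature, Bayes factors and DIC computed, the best model selected and
#' its inheritance pattern labelled. Markers/alleles with fewer than
#' `min_trios` usable trios are skipped, mirroring the marker-selection rule
#' of large trio datasets.
#'
#' @param gt a [genotype_table()] (phased for window mode).
#' @param ped pedigree data.frame.
#' @param mode `"snp"` or `"windows"`.
#' @param window_sizes window sizes in SNPs for window mode.
#' @param models TRD models to fit.
#' @param min_trios minimum trio count per marker (default 10).
#' @param resolution grid resolution per dimension.
#' @param bf_decisive decisive Bayes-factor threshold (default 100,
#'   Jeffreys' scale).
#' @param min_carrier_count minimum parental-haplotype count for a window
#'   allele to be analyzed (default 2).
#' @return data.frame of region records, one row per SNP or per
#'   (window, haplotype allele): coordinates, allele id, carrier frequency,
#'   informative-parent counts, per-model Bayes factors and DIC, selected
#'   model, posterior estimates, CV of the primary parameter, pattern label
#'   and under-represented offspring count.
#' @export
trd_scan <- function(gt, ped, mode = c("snp", "windows"),
                     window_sizes = c(2, 4, 7, 10, 20),
                     models = c("allelic_overall", "allelic_parent_specific",
                                "genotypic"),
                     min_trios = 10, resolution = 201, bf_decisive = 100,
                     min_carrier_count = 2) {
  mode <- match.arg(mode)
  parents <- unique(c(ped$sire, ped$dam))
  rows <- list()
  scan_one <- function(marker, chrom, start_bp, end_bp, n_snp, allele_id,
                       carrier_freq, marker_ids) {
    trios <- assemble_trios(gt, ped, marker, min_trios = min_trios)
    if (!attr(trios, "usable")) return(NULL)
    counts <- tabulate_matings(trios)
    fr <- fit_models(counts, models = models, resolution = resolution,
                     bf_decisive = bf_decisive)
    ssel <- if (fr$selected == "null") NULL else fr$summaries[[fr$selected]]
    prim <- .primary_param(fr$selected, ssel)
    n_inf <- attr(counts, "n_informative")
    urep <- if (fr$selected %in% c("allelic_overall", "allelic_parent_specific"))
      under_represented(n_inf, prim$mean) else if (fr$selected == "genotypic")
      missing_homozygotes(counts, ssel$mean[ssel$param == "alpha_g"]) else 0L
    est <- stats::setNames(rep(NA_real_, 2), c("est1", "est2"))
    if (!is.null(ssel)) est[seq_len(nrow(ssel))] <- ssel$mean
    data.frame(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
               n_snp = n_snp, allele = allele_id,
               marker_ids = paste(marker_ids, collapse = ","),
               carrier_freq = carrier_freq,
               n_trios = nrow(trios), n_informative = n_inf,
               n_het_sires = attr(counts, "n_het_sires"),
               n_het_dams = attr(counts, "n_het_dams"),
               n_inconsistent = attr(counts, "n_inconsistent"),
               bf_overall = unname(fr$bf["allelic_overall"]),
               bf_parent_specific = unname(fr$bf["allelic_parent_specific"]),
               bf_genotypic = unname(fr$bf["genotypic"]),
               bf_best = fr$bf_best,
               dic_null = unname(fr$dic["null"]),
               dic_overall = unname(fr$dic["allelic_overall"]),
               dic_parent_specific = unname(fr$dic["allelic_parent_specific"]),
               dic_genotypic = unname(fr$dic["genotypic"]),
               selected = fr$selected, pattern = fr$pattern,
               est1 = unname(est[1]), est2 = unname(est[2]),
               primary_param = prim$param, primary_est = prim$mean,
               cv = prim$cv, under_represented = urep,
               decisive = fr$decisive)
  }
  if (mode == "snp") {
    for (i in seq_len(nrow(gt$map))) {
      mid <- gt$map$marker_id[i]
      g_par <- gt$geno[mid, parents[parents %in% colnames(gt$geno)]]
      cf <- if (all(is.na(g_par))) NA_real_ else mean(g_par, na.rm = TRUE) / 2
      rows[[length(rows) + 1L]] <-
        scan_one(mid, gt$map$chrom[i], gt$map$pos_bp[i], gt$map$pos_bp[i],
                 1L, mid, cf, mid)
    }
  } else {
    if (!is.phased(gt)) stop("window mode requires phased genotypes")
    for (size in window_sizes) {
      wins <- make_windows(gt$map, size)
      for (w in seq_len(nrow(wins))) {
        win <- wins[w, , drop = FALSE]
        alle <- enumerate_alleles(gt, win, ped)
        alle <- alle[alle$count >= min_carrier_count, , drop = FALSE]
        for (a in seq_len(nrow(alle))) {
          pseudo <- recode_biallelic(gt, win, alle$allele[a])
          rows[[length(rows) + 1L]] <-
            scan_one(pseudo, win$chrom, win$start_bp, win$end_bp, size,
                     attr(pseudo, "marker_id"), alle$frequency[a],
                     unlist(win$marker_ids))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

## primary parameter of the selected model: alpha for the overall model, the
## larger-magnitude of (alpha_s, alpha_d) for the parent-specific model,
## alpha_g for the genotypic model
.primary_param <- function(model, summary) {
  if (is.null(summary) || model == "null") {
    return(list(param = NA_character_, mean = 0, cv = NA_real_))
  }
  row <- switch(model,
    allelic_overall = summary[summary$param == "alpha", ],
    allelic_parent_specific = summary[which.max(abs(summary$mean)), ],
    genotypic = summary[summary$param == "alpha_g", ])
  list(param = row$param, mean = row$mean, cv = row$cv)
}

#' Expected number of under-represented offspring
#'
#' For an allelic TRD of magnitude `|alpha|` acting on `n` informative
#' offspring, the number of missing (non-viable or never-conceived)
#' offspring is approximately `n * 2 * |alpha|`.
#'
#' @param n_informative informative offspring count (>= 0).
#' @param trd_magnitude TRD estimate, `|trd| <= 0.5`.
#' @return integer count.
#' @export
under_represented <- function(n_informative, trd_magnitude) {
  stopifnot(n_informative >= 0, abs(trd_magnitude) <= 0.5)
  as.integer(round(n_informative * 2 * abs(trd_magnitude)))
}

#' Non-observed homozygous offspring from carrier-by-carrier matings
#'
#' Under Mendelian segregation a quarter of AB x AB offspring should carry
#' the homozygous genotype disadvantaged by the fitted additive TRD; the
#' shortfall `round(n_ABxAB / 4) - observed` estimates the missing
#' homozygotes of a (partially) lethal allele.
#'
#' @param counts a [mating_counts()] table.
#' @param alpha_g fitted additive TRD; its sign picks the disadvantaged
#'   homozygote (AA when negative, BB when positive).
#' @return integer count (can be negative when the class is over-observed).
#' @export
missing_homozygotes <- function(counts, alpha_g) {
  n_hh <- sum(unclass(counts)["ABxAB", ])
  cls <- if (alpha_g < 0) "AA" else "BB"
  as.integer(round(n_hh / 4) - unclass(counts)["ABxAB", cls])
}

#' Empirical null-distribution thresholds for TRD estimates
#'
#' Simulates TRD estimators under pure Mendelian (gamete-sampling) noise and
#' tabulates, per informative-offspring bin, the smallest magnitude whose
#' two-sided exceedance probability is at most `p_null`. A scan estimate
#' below its bin threshold is the kind of distortion chance alone produces.
#' The allelic estimator is the transmission proportion `k/n - 0.5` with
#' `k ~ Binomial(n, 1/2)`; genotypic-model estimators are the moment
#' estimators from AB x AB offspring (`alpha_hat = 2 (pAA - pBB)`,
#' `delta_hat = 2 pAB - 1`) under Mendelian multinomial sampling of the
#' bin's AB x AB share.
#'
#' @param bins vector of informative-offspring counts (bin representatives).
#' @param mating_mix named proportions of informative offspring across the
#'   five mating types (used to size the AB x AB share of a bin); defaults
#'   to equal fifths.
#' @param replicates Monte-Carlo replicates per bin; at least `10 / p_null`
#'   is recommended (a warning is issued otherwise).
#' @param p_null two-sided exceedance probability (default 1e-5, i.e. a
#'   "< 0.001% margin error").
#' @param seed integer seed.
#' @return A `null_table` data.frame: `n_bin`, `param` (`alpha`, `alpha_g`,
#'   `delta_g`), `threshold`.
#' @export
build_null_table <- function(bins, mating_mix = NULL, replicates = 1e6,
                             p_null = 1e-5, seed = 1) {
  stopifnot(length(bins) >= 1, all(bins >= 1), p_null > 0, p_null < 1)
  if (replicates < 10 / p_null) {
    warning("replicates < 10 / p_null; thresholds will be noisy")
  }
  if (is.null(mating_mix)) {
    mating_mix <- stats::setNames(rep(0.2, 5), .matings)
  }
  set.seed(seed)
  thr <- function(x) {
    ## smallest support value with empirical two-sided exceedance <= p_null
    r <- rle(sort(x, decreasing = TRUE))
    cum <- cumsum(r$lengths)   # count of x >= each distinct value
    ok <- cum / length(x) <= p_null
    if (!any(ok)) return(r$values[1])
    r$values[max(which(ok))]
  }
  out <- lapply(bins, function(n) {
    k <- stats::rbinom(replicates, n, 0.5)
    a_hat <- abs(k / n - 0.5)
    n_hh <- max(1L, round(n * mating_mix[["ABxAB"]]))
    n_aa <- stats::rbinom(replicates, n_hh, 0.25)
    n_ab <- stats::rbinom(replicates, n_hh - n_aa, 2 / 3)
    n_bb <- n_hh - n_aa - n_ab
    ag_hat <- abs(2 * (n_aa - n_bb) / n_hh)
    dg_hat <- abs(2 * n_ab / n_hh - 1)
    data.frame(n_bin = n, param = c("alpha", "alpha_g", "delta_g"),
               threshold = c(thr(a_hat), thr(ag_hat), thr(dg_hat)))
  })
  structure(do.call(rbind, out), class = c("null_table", "data.frame"),
            p_null = p_null, replicates = replicates, seed = seed)
}

## threshold lookup: use the bin at or below n (smaller bins have larger,
## hence conservative, thresholds)
.null_threshold <- function(null_table, n, param) {
  nt <- null_table[null_table$param == param, ]
  nt <- nt[order(nt$n_bin), ]
  i <- findInterval(n, nt$n_bin)
  nt$threshold[max(1L, i)]
}

#' Apply the post-scan filtering ledger
#'
#' Appends four independent pass/fail flags to each region record and their
#' conjunction:
#' 1. `f_informative` — at least 20 heterozygous sires and/or 100
#'    heterozygous dams.
#' 2. `f_sire_robust` — the signal survives removing, one family at a time,
#'    each of the `k_skew` largest fully-skewed heterozygous-sire families
#'    (a het sire whose every unambiguous transmission is the same allele);
#'    a decisive record whose refitted Bayes factor drops below
#'    `bf_decisive` after any such removal fails. Requires `gt` and `ped`
#'    to re-assemble trios; records that are not decisive pass vacuously.
#' 3. `f_null` — the selected model's parameter magnitude(s) exceed the
#'    empirical-null threshold for the record's informative-offspring bin.
#' 4. `f_cv` — posterior coefficient of variation of the primary parameter
#'    at most `cv_max` (default 20%).
#'
#' @param records scan output from [trd_scan()].
#' @param null_table a [build_null_table()] result.
#' @param gt,ped data needed for the sire-robustness refits (optional; the
#'   flag is `NA` without them).
#' @param k_skew number of most-skewed families to hold out (default 2).
#' @param bf_decisive decisive Bayes-factor threshold.
#' @param cv_max CV ceiling.
#' @param resolution grid resolution for refits.
#' @return `records` with columns `f_informative`, `f_sire_robust`,
#'   `f_null`, `f_cv`, `pass`.
#' @export
apply_filters <- function(records, null_table, gt = NULL, ped = NULL,
                          k_skew = 2, bf_decisive = 100, cv_max = 0.2,
                          resolution = 201) {
  if (!nrow(records)) return(records)
  records$f_informative <- records$n_het_sires >= 20 | records$n_het_dams >= 100
  records$f_null <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    if (r$selected == "null") return(FALSE)
    if (r$selected == "genotypic") {
      abs(r$est1) > .null_threshold(null_table, r$n_informative, "alpha_g") ||
        abs(r$est2) > .null_threshold(null_table, r$n_informative, "delta_g")
    } else {
      thr <- .null_threshold(null_table, r$n_informative, "alpha")
      max(abs(r$est1), abs(r$est2), na.rm = TRUE) > thr
    }
  }, logical(1))
  records$f_cv <- !is.na(records$cv) & records$cv <= cv_max
  records$f_sire_robust <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    if (!isTRUE(r$decisive)) return(TRUE)
    if (is.null(gt) || is.null(ped)) return(NA)
    sire_robust_check(gt, ped, r, k_skew = k_skew, bf_decisive = bf_decisive,
                      resolution = resolution)
  }, logical(1))
  ## conjunction; an unevaluable sire-robustness flag (no gt/ped) is not a fail
  records$pass <- records$f_informative & records$f_null & records$f_cv &
    vapply(records$f_sire_robust, function(x) isTRUE(x) || is.na(x), logical(1))
  records
}

## leave-fully-skewed-sire-family-out robustness refit for one record
sire_robust_check <- function(gt, ped, record, k_skew = 2, bf_decisive = 100,
                              resolution = 201) {
  marker <- .record_pseudo_marker(gt, record)
  trios <- assemble_trios(gt, ped, marker, min_trios = 1)
  het <- trios[trios$g_sire == 1L, , drop = FALSE]
  if (!nrow(het)) return(TRUE)
  ## sire's transmitted allele where unambiguous
  tx <- rep(NA_integer_, nrow(het))
  tx[het$g_dam == 0L] <- het$g_off[het$g_dam == 0L]            # AA dam: off AA->A(0), AB->B(1)
  tx[het$g_dam == 2L] <- het$g_off[het$g_dam == 2L] - 1L       # BB dam: AB->A, BB->B
  hh <- het$g_dam == 1L & het$g_off != 1L
  tx[hh] <- ifelse(het$g_off[hh] == 0L, 0L, 1L)
  known <- !is.na(tx)
  per_sire <- split(tx[known], het$sire[known])
  skewed <- names(per_sire)[vapply(per_sire, function(v)
    length(v) >= 2 && length(unique(v)) == 1, logical(1))]
  if (!length(skewed)) return(TRUE)
  sizes <- vapply(per_sire[skewed], length, integer(1))
  hold <- skewed[order(-sizes)][seq_len(min(k_skew, length(skewed)))]
  for (s in hold) {
    sub <- trios[trios$sire != s, , drop = FALSE]
    attr(sub, "n_het_sires") <- length(unique(sub$sire[sub$g_sire == 1L]))
    attr(sub, "n_het_dams") <- length(unique(sub$dam[sub$g_dam == 1L]))
    counts <- tabulate_matings(sub)
    bfs <- vapply(c("allelic_overall", "allelic_parent_specific", "genotypic"),
                  function(m) bayes_factor(counts, m, resolution), numeric(1))
    if (max(bfs) < bf_decisive) return(FALSE)
  }
  TRUE
}

## rebuild the (pseudo-)marker genotype column a record was fitted on
.record_pseudo_marker <- function(gt, record) {
  if (record$n_snp == 1L) return(record$allele)
  parts <- strsplit(record$allele, ":")[[1]]
  win <- data.frame(chrom = record$chrom, start_bp = record$start_bp,
                    end_bp = record$end_bp, size = record$n_snp,
                    marker_ids = I(list(strsplit(record$marker_ids, ",")[[1]])))
  recode_biallelic(gt, win, parts[length(parts)])
}

#' Keep only the best record per overlapping-region cluster
#'
#' Among records whose `[start_bp, end_bp]` intervals overlap (transitively)
#' on the same chromosome, only the record with the highest Bayes factor is
#' retained; ties go to the smallest interval, then the leftmost.
#'
#' @param records scan records with `bf_best`.
#' @return the deduplicated records.
#' @export
dedup_best_bf <- function(records) {
  if (!nrow(records)) return(records)
  keep <- lapply(split(seq_len(nrow(records)), records$chrom), function(idx) {
    r <- records[idx, ]
    o <- order(r$start_bp, r$end_bp)
    idx <- idx[o]; r <- r[o, ]
    cluster <- cumsum(c(TRUE, r$start_bp[-1] > cummax(r$end_bp)[-nrow(r)]))
    vapply(split(seq_along(idx), cluster), function(ii) {
      rr <- r[ii, ]
      best <- order(-rr$bf_best, rr$end_bp - rr$start_bp, rr$start_bp)[1]
      idx[ii][best]
    }, integer(1))
  })
  out <- records[sort(unlist(keep)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gaussian-kernel smoothing of Bayes factors along the genome
#'
#' For query position `k_i`, `y_hat_i = sum_j (2 pi sigma^2)^{-1/2}
#' exp(-(k_i - k_j)^2 / (2 sigma^2)) BF_j` over the record anchors `k_j`
#' (interval midpoints), computed per chromosome. By default the track is
#' rescaled by `sqrt(2 pi sigma^2)` so an isolated record's peak equals its
#' Bayes factor; `rescale = "max"` instead normalizes the track maximum
#' to 1.
#'
#' @param records deduplicated scan records with `bf_best`.
#' @param sigma kernel bandwidth in base pairs (the scan default set is
#'   500 kb, 2 Mb, 5 Mb).
#' @param query optional data.frame (`chrom`, `pos_bp`) of query positions;
#'   default is a regular grid at `sigma / 10` spacing spanning each
#'   chromosome's anchors +/- 3 sigma.
#' @param rescale `"peak"` (isolated-peak-preserving) or `"max"`.
#' @return A `smooth_track` data.frame (`chrom`, `pos_bp`, `y`) with
#'   attribute `sigma`.
#' @export
kernel_smooth <- function(records, sigma, query = NULL,
                          rescale = c("peak", "max")) {
  rescale <- match.arg(rescale)
  stopifnot(sigma > 0)
  bf <- records$bf_best
  ## overflowed Bayes factors (beyond double range) enter as a large finite
  ## value so the Gaussian decay around their anchor stays representable
  bf[!is.finite(bf)] <- 1e300
  anchors <- data.frame(chrom = records$chrom,
                        pos = (records$start_bp + records$end_bp) / 2,
                        bf = bf)
  tracks <- lapply(unique(anchors$chrom), function(ch) {
    a <- anchors[anchors$chrom == ch, ]
    q <- if (is.null(query)) {
      seq(max(0, min(a$pos) - 3 * sigma), max(a$pos) + 3 * sigma, by = sigma / 10)
    } else query$pos_bp[query$chrom == ch]
    if (!length(q)) return(NULL)
    y <- vapply(q, function(p) sum(exp(-(p - a$pos)^2 / (2 * sigma^2)) * a$bf),
                numeric(1))
    data.frame(chrom = ch, pos_bp = q, y = y)
  })
  out <- do.call(rbind, tracks[!vapply(tracks, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(chrom = character(), pos_bp = numeric(),
                                      y = numeric())
  if (rescale == "max" && nrow(out) && max(out$y) > 0) out$y <- out$y / max(out$y)
  structure(out, class = c("smooth_track", "data.frame"), sigma = sigma,
            rescale = rescale)
}

#' Significance half-width of a smoothed-Bayes-factor peak
#'
#' The distance from a peak within which TRD is deemed significant at the
#' given coverage: the two-sided standard-normal quantile for that coverage,
#' rounded to two decimals, times the kernel bandwidth. With a 500 kb
#' bandwidth this gives +/- 980,000 bp (95%), +/- 1,290,000 bp (99%) and
#' +/- 1,645,000 bp (99.9%).
#'
#' @param sigma kernel bandwidth in base pairs.
#' @param coverage coverage level in (0, 1), e.g. 0.95, 0.99, 0.999.
#' @return half-width in base pairs.
#' @export
significance_halfwidth <- function(sigma, coverage) {
  stopifnot(sigma > 0)
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)")
  z <- round(stats::qnorm(1 - (1 - coverage) / 2), 2)
  z * sigma
}

#' Extract core TRD regions from a smoothed track
#'
#' Local maxima of the smoothed Bayes factor above `min_peak` define
#' candidate cores; two adjacent maxima are distinct cores only when the
#' valley between them falls below half the smaller peak, otherwise they
#' merge (the higher peak represents the merged core). The significance
#' span of each core is the peak position +/- the 95% half-width of the
#' track's bandwidth.
#'
#' @param track a [kernel_smooth()] result (rescale `"peak"`).
#' @param min_peak minimum smoothed value for a core peak.
#' @return data.frame (`chrom`, `peak_bp`, `peak_value`, `start_bp`,
#'   `end_bp`), zero rows for a flat track.
#' @export
extract_core_regions <- function(track, min_peak) {
  sigma <- attr(track, "sigma")
  hw <- significance_halfwidth(sigma, 0.95)
  res <- lapply(unique(track$chrom), function(ch) {
    t <- track[track$chrom == ch, ]
    t <- t[order(t$pos_bp), ]
    y <- t$y
    n <- length(y)
    if (n < 3) return(NULL)
    is_max <- c(FALSE, y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
    peaks <- which(is_max & y > min_peak)
    if (!length(peaks)) return(NULL)
    ## drop plateau duplicates
    peaks <- peaks[c(TRUE, diff(peaks) > 1)]
    merged <- list(peaks[1])
    for (p in peaks[-1]) {
      last <- merged[[length(merged)]]
      valley <- min(y[max(last):p])
      if (valley < 0.5 * min(y[max(last)], y[p])) {
        merged[[length(merged) + 1L]] <- p
      } else {
        merged[[length(merged)]] <- c(last, p)
      }
    }
    do.call(rbind, lapply(merged, function(grp) {
      top <- grp[which.max(y[grp])]
      data.frame(chrom = ch, peak_bp = t$pos_bp[top], peak_value = y[top],
                 start_bp = max(0, t$pos_bp[top] - hw),
                 end_bp = t$pos_bp[top] + hw)
    }))
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(chrom = character(), peak_bp = numeric(),
                                      peak_value = numeric(),
                                      start_bp = numeric(), end_bp = numeric())
  rownames(out) <- NULL
  out
}
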