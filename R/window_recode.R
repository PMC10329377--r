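#' Sliding SNP windows over a marker map
#'
#' Windows are contiguous runs of `size` markers in map order and never span
#' chromosomes; with `step = 1` a chromosome with `n` markers yields
#' `max(0, n - size + 1)` windows.
#'
#' @param map marker map data.frame (`chrom`, `marker_id`, `pos_bp`), sorted
#'   as in a [genotype_table()].
#' @param size window size in SNPs (>= 2); the scan default set is
#'   `c(2, 4, 7, 10, 20)`.
#' @param step slide step in markers (default 1, overlapping windows).
#' @return data.frame with one row per window: `chrom`, `start_bp`, `end_bp`,
#'   `size`, and a list-column `marker_ids`.
#' @export
make_windows <- function(map, size, step = 1) {
  stopifnot(size >= 2, step >= 1)
  out <- lapply(split(map, map$chrom), function(m) {
    m <- m[order(m$pos_bp), , drop = FALSE]
    n <- nrow(m)
    if (n < size) return(NULL)
    starts <- seq(1L, n - size + 1L, by = step)
    data.frame(chrom = m$chrom[starts],
               start_bp = m$pos_bp[starts],
               end_bp = m$pos_bp[starts + size - 1L],
               size = size,
               marker_ids = I(lapply(starts, function(s) m$marker_id[s:(s + size - 1L)])))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), size = integer(),
                      marker_ids = I(list()))
  }
  rownames(out) <- NULL
  out
}

window_hap_strings <- function(gt, window) {
  if (!is.phased(gt)) stop("window analysis requires phased genotypes")
  ids <- window$marker_ids[[1]] %||% window$marker_ids
  ids <- unlist(ids)
  h1 <- gt$hap1[ids, , drop = FALSE]
  h2 <- gt$hap2[ids, , drop = FALSE]
  ok <- colSums(is.na(h1)) == 0 & colSums(is.na(h2)) == 0
  list(s1 = apply(h1[, ok, drop = FALSE], 2, paste, collapse = ""),
       s2 = apply(h2[, ok, drop = FALSE], 2, paste, collapse = ""),
       included = colnames(gt$geno)[ok])
}

#' Enumerate haplotype alleles in a window
#'
#' Distinct haplotype strings observed among the *parental* haplotypes of the
#' pedigree, with carrier frequencies over all included parental haplotypes.
#' Individuals with a missing or unphased entry at any window marker are
#' excluded. TRD at a window conditions on parental genotypes, so enumeration
#' is restricted to parents.
#'
#' @param gt a phased [genotype_table()].
#' @param window one row of [make_windows()] output.
#' @param ped pedigree data.frame; parents are the union of its `sire` and
#'   `dam` columns. When `NULL`, all individuals are treated as parents.
#' @return data.frame (`allele`, `count`, `frequency`) sorted by decreasing
#'   frequency; zero rows when no phased individuals remain.
#' @export
enumerate_alleles <- function(gt, window, ped = NULL) {
  hs <- window_hap_strings(gt, window)
  keep <- if (is.null(ped)) hs$included else
    intersect(hs$included, unique(c(ped$sire, ped$dam)))
  idx <- hs$included %in% keep
  haps <- c(hs$s1[idx], hs$s2[idx])
  if (!length(haps)) {
    return(data.frame(allele = character(), count = integer(), frequency = numeric()))
  }
  tab <- sort(table(haps), decreasing = TRUE)
  data.frame(allele = names(tab), count = as.integer(tab),
             frequency = as.integer(tab) / length(haps), row.names = NULL)
}

#' Recode a haplotype allele as a biallelic pseudo-marker
#'
#' Each individual's pseudo-genotype is its number of haplotypes equal to the
#' focal string `allele` (H_j), all other strings pooled as H_-j; individuals
#' with a missing/unphased window entry get a missing pseudo-genotype. The
#' resulting column feeds the same trio/TRD machinery as a real SNP.
#'
#' @param gt a phased [genotype_table()].
#' @param window one row of [make_windows()] output.
#' @param allele haplotype string (length = window size).
#' @return named integer vector over all individuals in `gt` with attribute
#'   `marker_id` of the form `"chrom:start-end:allele"`.
#' @export
recode_biallelic <- function(gt, window, allele) {
  hs <- window_hap_strings(gt, window)
  pseudo <- rep(NA_integer_, ncol(gt$geno))
  names(pseudo) <- colnames(gt$geno)
  pseudo[hs$included] <- (hs$s1 == allele) + (hs$s2 == allele)
  attr(pseudo, "marker_id") <- paste0(window$chrom, ":", window$start_bp, "-",
                                      window$end_bp, ":", allele)
  pseudo
}
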