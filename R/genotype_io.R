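#' Genotype table
#'
#' Container for diploid biallelic genotypes of a cohort: a markers-by-
#' individuals matrix of allele-B dosage codes (0/1/2, `NA` = missing), an
#' optional pair of haplotype matrices giving the phased allele in each
#' chromosome slot, and a marker map. All downstream machinery (trio assembly,
#' window recoding, TRD model fitting) works on this container.
#'
#' @param geno integer matrix, markers in rows and individuals in columns,
#'   entries in `{0, 1, 2, NA}` counting copies of allele B. Row names are
#'   marker ids, column names sample ids.
#' @param map data.frame with columns `chrom`, `marker_id`, `pos_bp`
#'   (1-based base-pair position), one row per row of `geno`.
#' @param hap1,hap2 optional integer matrices of the same shape as `geno` with
#'   entries in `{0, 1, NA}`: the phased allele in each slot (`hap1` =
#'   paternal slot by convention). An entry is phased iff both slots are
#'   non-missing; phased slots must sum to the dosage code.
#'
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(geno, map, hap1 = NULL, hap2 = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(is.data.frame(map), all(c("chrom", "marker_id", "pos_bp") %in% names(map)))
  if (nrow(map) != nrow(geno)) {
    stop("map has ", nrow(map), " rows but geno has ", nrow(geno))
  }
  if (anyDuplicated(map$marker_id)) {
    stop("duplicated marker ids: ",
         paste(unique(map$marker_id[duplicated(map$marker_id)]), collapse = ", "))
  }
  rownames(geno) <- map$marker_id
  ## sort by chromosome then position; positions must be strictly increasing
  ord <- order(map$chrom, map$pos_bp)
  map <- map[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  rownames(map) <- NULL
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2)) stop("genotype codes must be 0, 1, 2 or NA")
  if (!is.null(hap1) || !is.null(hap2)) {
    stopifnot(!is.null(hap1), !is.null(hap2))
    hap1 <- as.matrix(hap1)[ord, , drop = FALSE]
    hap2 <- as.matrix(hap2)[ord, , drop = FALSE]
    storage.mode(hap1) <- "integer"
    storage.mode(hap2) <- "integer"
    stopifnot(identical(dim(hap1), dim(geno)), identical(dim(hap2), dim(geno)))
    ph <- !is.na(hap1) & !is.na(hap2)
    if (any(ph & (hap1 + hap2 != geno), na.rm = TRUE)) {
      stop("phased slots inconsistent with dosage codes")
    }
    dimnames(hap1) <- dimnames(geno)
    dimnames(hap2) <- dimnames(geno)
  }
  structure(list(geno = geno, hap1 = hap1, hap2 = hap2, map = map),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$geno), "markers x", ncol(x$geno), "individuals;",
      if (is.phased(x)) "phased" else "unphased", "\n")
  cat("chromosomes:", paste(unique(x$map$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' Is a genotype table (fully) phased?
#'
#' @param gt a [genotype_table()].
#' @return `TRUE` when haplotype slots are present.
#' @export
is.phased <- function(gt) !is.null(gt$hap1)

#' Read genotypes from file
#'
#' Two dialects are supported. `"vcf"` reads a Variant Call Format file
#' through \pkg{vcfR}: only biallelic SNP records are retained (multi-allelic
#' records are dropped with a message), the GT field is decoded with `"|"`
#' marking phased and `"/"` unphased entries, and allele B is the ALT allele.
#' `"matrix_tsv"` reads the package's plain-text matrix: a header row
#' `marker_id chrom pos_bp <sample ids...>`, then one row per marker with
#' dosage codes `0/1/2/NA`; phased entries may be written `a|b`.
#'
#' @param path file path.
#' @param dialect `"matrix_tsv"` or `"vcf"`.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, dialect = c("matrix_tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(dialect,
         vcf = read_genotypes_vcf(path),
         matrix_tsv = read_genotypes_matrix(path))
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L
  n_drop <- sum(!biallelic)
  if (n_drop > 0) message("dropped ", n_drop, " non-biallelic-SNP record(s)")
  if (!any(biallelic)) stop("no biallelic SNP records in ", path)
  gtmat <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gtmat))) {
    gtmat <- matrix(gtmat, nrow = nrow(fix), dimnames = list(fix[, "ID"], names(gtmat)))
  }
  gtmat <- gtmat[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  ids <- fix[, "ID"]
  if (any(is.na(ids) | ids == ".")) {
    ids <- ifelse(is.na(ids) | ids == ".",
                  paste0(fix[, "CHROM"], "_", fix[, "POS"]), ids)
  }
  map <- data.frame(chrom = fix[, "CHROM"], marker_id = ids,
                    pos_bp = as.integer(fix[, "POS"]))
  parse_slot <- function(i) {
    a <- sub("^([0-9.])[|/]([0-9.])$", paste0("\\", i), gtmat)
    a[a == "." | !a %in% c("0", "1")] <- NA
    m <- matrix(as.integer(a), nrow = nrow(gtmat), dimnames = dimnames(gtmat))
    m
  }
  bad <- !grepl("^[0-9.][|/][0-9.]$", gtmat) & !is.na(gtmat)
  if (any(bad)) stop("malformed GT field at marker ",
                     rownames(gtmat)[which(bad, arr.ind = TRUE)[1, 1]])
  a1 <- parse_slot(1)
  a2 <- parse_slot(2)
  geno <- a1 + a2
  phased <- matrix(grepl("|", gtmat, fixed = TRUE), nrow = nrow(gtmat))
  hap1 <- ifelse(phased, a1, NA_integer_)
  hap2 <- ifelse(phased, a2, NA_integer_)
  if (!any(phased)) {
    hap1 <- NULL
    hap2 <- NULL
  }
  genotype_table(geno, map, hap1 = hap1, hap2 = hap2)
}

read_genotypes_matrix <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  need <- c("marker_id", "chrom", "pos_bp")
  if (!all(need %in% names(raw)[1:3])) {
    stop("matrix_tsv header must start with marker_id, chrom, pos_bp")
  }
  samples <- names(raw)[-(1:3)]
  map <- data.frame(chrom = raw$chrom, marker_id = raw$marker_id,
                    pos_bp = as.integer(raw$pos_bp))
  cells <- as.matrix(raw[, -(1:3), drop = FALSE])
  phased_cell <- grepl("|", cells, fixed = TRUE)
  ok <- is.na(cells) | cells %in% c("0", "1", "2", "NA", "") | grepl("^[01]\\|[01]$", cells)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("malformed genotype cell at marker ", raw$marker_id[bad[1]],
         ", sample ", samples[bad[2]])
  }
  h1 <- ifelse(phased_cell, as.integer(substr(cells, 1, 1)), NA_integer_)
  h2 <- ifelse(phased_cell, as.integer(substr(cells, 3, 3)), NA_integer_)
  geno <- ifelse(phased_cell, h1 + h2,
                 suppressWarnings(as.integer(cells)))
  dim(geno) <- dim(cells)
  dim(h1) <- dim(cells)
  dim(h2) <- dim(cells)
  colnames(geno) <- samples
  if (!any(phased_cell)) {
    h1 <- NULL
    h2 <- NULL
  } else {
    colnames(h1) <- samples
    colnames(h2) <- samples
  }
  genotype_table(geno, map, hap1 = h1, hap2 = h2)
}

#' Write genotypes to file
#'
#' Inverse of [read_genotypes()]: `"matrix_tsv"` preserves codes, phase and
#' missingness exactly (phased entries are written `a|b`); `"vcf"` writes a
#' minimal VCF 4.2 body with REF=A, ALT=B and the GT field (phased `"|"`,
#' unphased `"/"`, missing `"./."`).
#'
#' @param gt a [genotype_table()].
#' @param path output file path.
#' @param dialect `"matrix_tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path, dialect = c("matrix_tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "matrix_tsv") {
    cells <- matrix(as.character(gt$geno), nrow = nrow(gt$geno))
    if (is.phased(gt)) {
      ph <- !is.na(gt$hap1) & !is.na(gt$hap2)
      cells[ph] <- paste0(gt$hap1[ph], "|", gt$hap2[ph])
    }
    cells[is.na(cells)] <- "NA"
    out <- cbind(gt$map$marker_id, gt$map$chrom, gt$map$pos_bp, cells)
    colnames(out) <- c("marker_id", "chrom", "pos_bp", colnames(gt$geno))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", colnames(gt$geno)), collapse = "\t")),
               con)
    gt_cell <- function(i) {
      g <- gt$geno[i, ]
      cell <- rep("./.", length(g))
      if (is.phased(gt)) {
        ph <- !is.na(gt$hap1[i, ]) & !is.na(gt$hap2[i, ])
      } else ph <- rep(FALSE, length(g))
      cell[ph] <- paste0(gt$hap1[i, ph], "|", gt$hap2[i, ph])
      un <- !ph & !is.na(g)
      cell[un] <- c("0/0", "0/1", "1/1")[g[un] + 1L]
      cell
    }
    for (i in seq_len(nrow(gt$geno))) {
      writeLines(paste(c(gt$map$chrom[i], gt$map$pos_bp[i], gt$map$marker_id[i],
                         "A", "B", ".", ".", ".", "GT", gt_cell(i)),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a pedigree table
#'
#' Tab-delimited file with a header and three columns: offspring, sire, dam
#' (ids). Offspring ids must be unique and no individual may be its own
#' ancestor within the table.
#'
#' @param path file path.
#' @return data.frame with columns `offspring`, `sire`, `dam`.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.delim(path, colClasses = "character")
  names(ped)[1:3] <- c("offspring", "sire", "dam")
  validate_pedigree(ped[, 1:3])
}

#' Validate a pedigree data.frame
#'
#' @param ped data.frame with columns `offspring`, `sire`, `dam`.
#' @return `ped`, checked.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(all(c("offspring", "sire", "dam") %in% names(ped)))
  if (anyDuplicated(ped$offspring)) stop("duplicated offspring ids in pedigree")
  ## self-ancestry check: walk up parent links from each offspring
  parent <- split(c(ped$sire, ped$dam), rep(ped$offspring, 2))
  for (id in ped$offspring) {
    seen <- character()
    frontier <- parent[[id]]
    while (length(frontier)) {
      if (id %in% frontier) stop("individual ", id, " is its own ancestor")
      seen <- union(seen, frontier)
      frontier <- setdiff(unlist(parent[frontier[frontier %in% names(parent)]]), seen)
    }
  }
  ped
}

## possible offspring dosages for each (sire, dam) dosage pair
.mendel_offspring <- local({
  gam <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  out <- vector("list", 9)
  for (s in 0:2) for (d in 0:2) {
    out[[s * 3 + d + 1]] <- sort(unique(outer(gam[[s + 1]], gam[[d + 1]], `+`)))
  }
  out
})

#' Mendelian consistency of a genotype trio
#'
#' A trio is consistent when some pair of parental gametes can produce the
#' offspring genotype. Vectorized over trios.
#'
#' @param g_sire,g_dam,g_off dosage codes in `{0,1,2}` (non-missing).
#' @return logical vector, `TRUE` = consistent.
#' @export
mendelian_check <- function(g_sire, g_dam, g_off) {
  stopifnot(!anyNA(g_sire), !anyNA(g_dam), !anyNA(g_off))
  .mendel_consistent[g_sire * 9L + g_dam * 3L + g_off + 1L]
}

## flat lookup over all 27 (sire, dam, offspring) dosage triples
.mendel_consistent <- local({
  v <- logical(27)
  for (s in 0:2) for (d in 0:2) for (o in 0:2) {
    v[s * 9 + d * 3 + o + 1] <- o %in% .mendel_offspring[[s * 3 + d + 1]]
  }
  v
})

#' Assemble parent-offspring trios at one marker
#'
#' Joins the pedigree to the genotype table at a single marker, dropping
#' trios with any missing genotype and (by default) Mendelian-inconsistent
#' trios, which are tallied as presumptive genotyping errors. Heterozygous
#' sire/dam counts are over distinct parent individuals, not trios; an
#' informative offspring is one whose mating has at least one heterozygous
#' parent. The set is flagged unusable when fewer than `min_trios` trios
#' remain.
#'
#' @param gt a [genotype_table()].
#' @param ped pedigree data.frame (`offspring`, `sire`, `dam`).
#' @param marker marker id present in `gt`.
#' @param min_trios minimum usable trio count (default 10).
#' @param drop_inconsistent exclude Mendelian-inconsistent trios (default TRUE).
#' @return A `trio_set`: data.frame of retained trios (`offspring`, `sire`,
#'   `dam`, `g_sire`, `g_dam`, `g_off`) with attributes `marker`,
#'   `n_het_sires`, `n_het_dams`, `n_informative`, `n_inconsistent`,
#'   `n_skipped`, `usable`.
#' @export
assemble_trios <- function(gt, ped, marker, min_trios = 10, drop_inconsistent = TRUE) {
  if (is.character(marker)) {
    if (!marker %in% rownames(gt$geno)) stop("unknown marker: ", marker)
    g <- gt$geno[marker, ]
  } else {
    ## pre-extracted named genotype vector (pseudo-marker column)
    g <- marker
    marker <- attr(g, "marker_id") %||% "pseudo"
  }
  known <- ped$sire %in% names(g) & ped$dam %in% names(g) & ped$offspring %in% names(g)
  n_skipped <- sum(!known)
  ped <- ped[known, , drop = FALSE]
  tr <- data.frame(offspring = ped$offspring, sire = ped$sire, dam = ped$dam,
                   g_sire = unname(g[ped$sire]), g_dam = unname(g[ped$dam]),
                   g_off = unname(g[ped$offspring]))
  complete <- !is.na(tr$g_sire) & !is.na(tr$g_dam) & !is.na(tr$g_off)
  tr <- tr[complete, , drop = FALSE]
  n_inconsistent <- 0L
  if (nrow(tr) && drop_inconsistent) {
    cons <- mendelian_check(tr$g_sire, tr$g_dam, tr$g_off)
    n_inconsistent <- sum(!cons)
    tr <- tr[cons, , drop = FALSE]
  }
  rownames(tr) <- NULL
  het_s <- unique(tr$sire[tr$g_sire == 1L])
  het_d <- unique(tr$dam[tr$g_dam == 1L])
  structure(tr,
            class = c("trio_set", "data.frame"),
            marker = marker,
            n_het_sires = length(het_s),
            n_het_dams = length(het_d),
            n_informative = sum(tr$g_sire == 1L | tr$g_dam == 1L),
            n_inconsistent = n_inconsistent,
            n_skipped = n_skipped,
            usable = nrow(tr) >= min_trios)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Minor allele frequency at a marker
#'
#' Computed over all individuals with a non-missing genotype; the folded
#' frequency `min(f, 1 - f)` is returned.
#'
#' @param gt a [genotype_table()].
#' @param marker marker id.
#' @return frequency in `[0, 0.5]`.
#' @export
minor_allele_frequency <- function(gt, marker) {
  if (!marker %in% rownames(gt$geno)) stop("unknown marker: ", marker)
  g <- gt$geno[marker, ]
  g <- g[!is.na(g)]
  if (!length(g)) stop("all genotypes missing at ", marker)
  f <- mean(g) / 2
  min(f, 1 - f)
}
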