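## Informative mating types (sire x dam) and their offspring cells.
## Dosage convention: genotype codes count copies of allele B, so
## AA = 0, AB = 1, BB = 2. "A" is the reference allele of the kernels
## P(A) = 0.5 + alpha etc.; orientation is a labelling convention only.
.matings <- c("ABxAA", "ABxBB", "AAxAB", "BBxAB", "ABxAB")
.off_classes <- c("AA", "AB", "BB")

## structurally possible offspring cells per mating
.mating_cells <- list(
  ABxAA = c("AA", "AB"),
  ABxBB = c("AB", "BB"),
  AAxAB = c("AA", "AB"),
  BBxAB = c("AB", "BB"),
  ABxAB = c("AA", "AB", "BB")
)

## flat index of the 11 non-structural cells within the 5 x 3 count matrix
.cell_index <- local({
  idx <- cbind(mating = rep(seq_along(.matings), lengths(.mating_cells)),
               off = match(unlist(.mating_cells), .off_classes))
  idx
})

#' Offspring-count table by mating type
#'
#' The data vector of all TRD likelihoods: offspring genotype counts
#' cross-classified by the five informative mating types (sire x dam order
#' preserved). Cells that are impossible under a mating (e.g. a BB offspring
#' from AB x AA) are structural zeros and never counted.
#'
#' @param counts 5 x 3 numeric matrix with rownames
#'   `c("ABxAA","ABxBB","AAxAB","BBxAB","ABxAB")` and colnames
#'   `c("AA","AB","BB")`. Missing dimnames are assumed in that order.
#' @param n_het_sires,n_het_dams distinct heterozygous parents behind the
#'   counts (carried through for filtering).
#' @param n_inconsistent Mendelian-inconsistent trios excluded upstream.
#' @return A `mating_counts` object.
#' @export
mating_counts <- function(counts, n_het_sires = NA_integer_,
                          n_het_dams = NA_integer_, n_inconsistent = 0L) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(5L, 3L)), all(counts >= 0))
  dimnames(counts) <- list(.matings, .off_classes)
  structural <- matrix(TRUE, 5, 3, dimnames = dimnames(counts))
  structural[.cell_index] <- FALSE
  if (any(counts[structural] != 0)) stop("nonzero count in a structurally impossible cell")
  structure(counts, class = "mating_counts",
            n_het_sires = n_het_sires, n_het_dams = n_het_dams,
            n_informative = sum(counts), n_inconsistent = n_inconsistent)
}

#' @export
print.mating_counts <- function(x, ...) {
  cat("mating_counts:", attr(x, "n_informative"), "informative offspring;",
      attr(x, "n_het_sires"), "het sires,", attr(x, "n_het_dams"), "het dams\n")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Tabulate trios into a mating-count table
#'
#' Classifies each trio by the ordered (sire, dam) genotype pair; matings with
#' two homozygous parents are uninformative for TRD and excluded from the
#' table. Mendelian-inconsistent trios must already have been excluded (see
#' [assemble_trios()]).
#'
#' @param trios a `trio_set` from [assemble_trios()], or any data.frame with
#'   columns `g_sire`, `g_dam`, `g_off`.
#' @return A [mating_counts()] object.
#' @export
tabulate_matings <- function(trios) {
  m <- matrix(0, 5, 3, dimnames = list(.matings, .off_classes))
  if (nrow(trios)) {
    key <- trios$g_sire * 3L + trios$g_dam   # 0..8
    mating <- c(NA, "AAxAB", NA, "ABxAA", "ABxAB", "ABxBB", NA, "BBxAB", NA)[key + 1L]
    keep <- !is.na(mating)
    if (any(keep)) {
      tab <- table(factor(mating[keep], levels = .matings),
                   factor(.off_classes[trios$g_off[keep] + 1L], levels = .off_classes))
      m <- m + unclass(tab)
    }
  }
  mating_counts(m,
                n_het_sires = attr(trios, "n_het_sires") %||% NA_integer_,
                n_het_dams = attr(trios, "n_het_dams") %||% NA_integer_,
                n_inconsistent = attr(trios, "n_inconsistent") %||% 0L)
}

#' Allelic-model offspring probabilities for one mating
#'
#' Transmission from a heterozygous parent is biased: the parent transmits
#' allele A with probability `0.5 + alpha` (overall model) or `0.5 + alpha_s`
#' / `0.5 + alpha_d` for sire and dam (parent-specific model). Homozygous
#' parents transmit their only allele.
#'
#' @param mating one of `"ABxAA","ABxBB","AAxAB","BBxAB","ABxAB"`.
#' @param alpha_s,alpha_d sire and dam TRD in `[-0.5, 0.5]`; pass the same
#'   value for the overall (parent-unspecific) model.
#' @return named probability vector over `AA`, `AB`, `BB` (structural zeros
#'   included), summing to 1.
#' @export
allelic_probs <- function(mating, alpha_s, alpha_d = alpha_s) {
  if (abs(alpha_s) > 0.5 || abs(alpha_d) > 0.5) {
    stop("allelic TRD parameters must lie in [-0.5, 0.5]")
  }
  ps <- 0.5 + alpha_s  # P(sire transmits A)
  pd <- 0.5 + alpha_d  # P(dam transmits A)
  p <- switch(mating,
    ABxAA = c(AA = ps, AB = 1 - ps, BB = 0),
    ABxBB = c(AA = 0, AB = ps, BB = 1 - ps),
    AAxAB = c(AA = pd, AB = 1 - pd, BB = 0),
    BBxAB = c(AA = 0, AB = pd, BB = 1 - pd),
    ABxAB = c(AA = ps * pd,
              AB = ps * (1 - pd) + (1 - ps) * pd,
              BB = (1 - ps) * (1 - pd)),
    stop("unknown mating: ", mating))
  p
}

#' Check the genotypic-model parametric space
#'
#' The admissible region is the probability simplex of the AB x AB kernel:
#' `1 + alpha_g - delta_g >= 0`, `1 - alpha_g - delta_g >= 0` and
#' `1 + delta_g >= 0`, i.e. `alpha_g` in `[-1, 1]` and `delta_g` in
#' `[-1, 1 - |alpha_g|]`.
#'
#' @param alpha_g,delta_g additive and dominance TRD (vectorized).
#' @param tol boundary tolerance.
#' @return logical vector.
#' @export
genotypic_valid <- function(alpha_g, delta_g, tol = 1e-12) {
  (1 + alpha_g - delta_g >= -tol) & (1 - alpha_g - delta_g >= -tol) &
    (1 + delta_g >= -tol) & (abs(alpha_g) <= 1 + tol)
}

#' Genotypic-model offspring probabilities for one mating
#'
#' Distortion acts on the offspring genotype itself: from AB x AB the
#' offspring probabilities are `(1+a-d)/4, (1+d)/2, (1-a-d)/4` for
#' `(AA, AB, BB)` with additive TRD `a` and dominance TRD `d`. In
#' heterozygous-by-homozygous matings only two genotypes are possible and the
#' kernel is renormalized for the overall loss of individuals: from a mating
#' with an AA parent, `P(AA) = (1+a-d) / (2(1+a/2))`,
#' `P(AB) = (1+d) / (2(1+a/2))`; with a BB parent the mirrored form divides
#' by `2(1-a/2)`. Parent order is irrelevant.
#'
#' @param mating one of `"ABxAA","ABxBB","AAxAB","BBxAB","ABxAB"`.
#' @param alpha_g,delta_g parameters satisfying [genotypic_valid()].
#' @return named probability vector over `AA`, `AB`, `BB`, summing to 1.
#' @export
genotypic_probs <- function(mating, alpha_g, delta_g) {
  if (!genotypic_valid(alpha_g, delta_g)) {
    stop("(alpha_g, delta_g) outside the genotypic parametric space")
  }
  a <- alpha_g; d <- delta_g
  ## clamp roundoff negatives at the simplex boundary (|error| <= tol)
  p <- pmax(switch(mating,
    ABxAA = ,
    AAxAB = c(AA = (1 + a - d) / (2 * (1 + a / 2)),
              AB = (1 + d) / (2 * (1 + a / 2)), BB = 0),
    ABxBB = ,
    BBxAB = c(AA = 0, AB = (1 + d) / (2 * (1 - a / 2)),
              BB = (1 - a - d) / (2 * (1 - a / 2))),
    ABxAB = c(AA = (1 + a - d) / 4, AB = (1 + d) / 2, BB = (1 - a - d) / 4),
    stop("unknown mating: ", mating)), 0)
  p
}

#' Offspring-probability matrix under a TRD model
#'
#' @param model one of `"null"`, `"allelic_overall"`,
#'   `"allelic_parent_specific"`, `"genotypic"`.
#' @param params numeric vector: nothing for `null`, `alpha` for the overall
#'   model, `c(alpha_s, alpha_d)` for the parent-specific model,
#'   `c(alpha_g, delta_g)` for the genotypic model.
#' @return 5 x 3 probability matrix (rows = matings).
#' @export
model_probs <- function(model, params = numeric()) {
  f <- switch(model,
    null = function(m) allelic_probs(m, 0, 0),
    allelic_overall = function(m) allelic_probs(m, params[1], params[1]),
    allelic_parent_specific = function(m) allelic_probs(m, params[1], params[2]),
    genotypic = function(m) genotypic_probs(m, params[1], params[2]),
    stop("unknown model: ", model))
  t(vapply(.matings, f, numeric(3)))
}

#' Multinomial log-likelihood of a mating-count table
#'
#' `sum n * log p` over matings and offspring cells; the multinomial
#' coefficient is omitted, being constant across models it cancels in Bayes
#' factors and DIC differences. A cell with `n > 0` and `p = 0` yields
#' `-Inf` (a legal return).
#'
#' @param counts a [mating_counts()] table (or 5 x 3 count matrix).
#' @param model,params as in [model_probs()].
#' @return log-likelihood (real or `-Inf`).
#' @export
trd_loglik <- function(counts, model, params = numeric()) {
  p <- model_probs(model, params)
  n <- unclass(counts)[.cell_index]
  lp <- log(p[.cell_index])
  contrib <- n * lp
  contrib[n == 0] <- 0
  sum(contrib)
}

## number of free parameters per model (used by the parsimony rule)
.model_npar <- c(null = 0L, allelic_overall = 1L,
                 allelic_parent_specific = 2L, genotypic = 2L)
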