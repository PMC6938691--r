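# Per-variant filter statistics: genotype missing rate, Mendelian error
# rate over pedigree trios, the biallelic exact test of Hardy-Weinberg
# equilibrium, allele balance of heterozygotes (ABHet) and minor allele
# frequency. All are vectorized over the sites of a VariantCallSet.

#' Genotype missing rate per variant
#'
#' Fraction of missing alleles: a fully missing diploid genotype contributes
#' two missing alleles; under the `"partial"` half-call policy a half call
#' contributes one.
#'
#' @param vcs a [VariantCallSet-class].
#' @return numeric vector in \[0, 1\].
#' @export
missingRate <- function(vcs) {
  (rowSums(is.na(.gt1(vcs))) + rowSums(is.na(.gt2(vcs)))) / (2L * ncol(vcs))
}

#' Mendelian error rate per variant
#'
#' A trio is evaluable iff child and both parents have non-missing
#' genotypes; it is a Mendelian error iff the child's genotype cannot be
#' formed by drawing one allele from each parent. Returns errors divided by
#' evaluable trios, `NA` when no trio is evaluable. Computed for autosomes
#' only; sex chromosomes and mitochondria return `NA` (hemizygote
#' transmission rules are out of scope).
#'
#' @param vcs a [VariantCallSet-class].
#' @param ped a [Pedigree-class], or `NULL` (all `NA`).
#' @return numeric vector in \[0, 1\] or `NA`.
#' @export
mendelErrorRate <- function(vcs, ped = NULL) {
  n <- nrow(vcs)
  out <- rep(NA_real_, n)
  if (is.null(ped)) return(out)
  trios <- pedTrios(ped)
  if (!nrow(trios)) return(out)
  samp <- colnames(vcs)
  usable <- trios$child %in% samp & trios$father %in% samp &
    trios$mother %in% samp
  if (any(!usable))
    warning(sum(!usable), " trio(s) reference samples absent from the call",
            " set and are not evaluable")
  trios <- trios[usable, , drop = FALSE]
  if (!nrow(trios)) return(out)

  g1 <- .gt1(vcs); g2 <- .gt2(vcs)
  auto <- .isAutosome(variantChrom(vcs))
  errs <- evals <- integer(n)
  for (i in seq_len(nrow(trios))) {
    c1 <- g1[, trios$child[i]];  c2 <- g2[, trios$child[i]]
    f1 <- g1[, trios$father[i]]; f2 <- g2[, trios$father[i]]
    m1 <- g1[, trios$mother[i]]; m2 <- g2[, trios$mother[i]]
    ev <- !(is.na(c1) | is.na(c2) | is.na(f1) | is.na(f2) |
            is.na(m1) | is.na(m2))
    ok <- ((c1 == f1 | c1 == f2) & (c2 == m1 | c2 == m2)) |
          ((c2 == f1 | c2 == f2) & (c1 == m1 | c1 == m2))
    evals <- evals + ev
    errs <- errs + (ev & !ok)
  }
  has <- auto & evals > 0L
  out[has] <- errs[has] / evals[has]
  out
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' The biallelic exact test conditional on allele counts: the p-value is the
#' sum of the null (hypergeometric-sampling) probabilities of every
#' heterozygote count at most as probable as the observed one. No mid-p
#' correction is applied. Monomorphic sites and sites where only one
#' heterozygote count is attainable return 1. Vectorized over triples.
#'
#' @param nHomRef,nHet,nHomAlt genotype counts from non-missing biallelic
#'   genotypes (for multi-allelic sites, pool alternate alleles first, see
#'   [hweExactPBySite()]).
#' @return p-values in (0, 1\]; `NA` where all three counts are zero.
#' @export
hweExactP <- function(nHomRef, nHet, nHomAlt) {
  mapply(.snphwe, as.integer(nHomRef), as.integer(nHet),
         as.integer(nHomAlt), USE.NAMES = FALSE)
}

## Exact HWE test via the standard stable recurrence over heterozygote
## counts (conditional on allele counts). Probabilities are accumulated from
## the modal het count outward; counts with probability <= (1 + 1e-7) x the
## observed configuration's probability contribute to the p-value.
.snphwe <- function(homRef, het, homAlt) {
  n <- homRef + het + homAlt
  if (n == 0L) return(NA_real_)
  rare <- 2L * min(homRef, homAlt) + het
  if (rare == 0L) return(1)
  ## attainable het counts share the parity of the rare-allele count
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(hets))
  ## start at the modal heterozygote count for numerical stability
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if ((mid %% 2L) != (rare %% 2L)) mid <- mid + 1L
  iMid <- match(mid, hets)
  probs[iMid] <- 1
  ## going down: P(h-2) = P(h) * h*(h-1) / ((rare-h+2)*(2n-rare-h+2))
  h <- mid
  i <- iMid
  while (h >= 2L) {
    probs[i - 1L] <- probs[i] * h * (h - 1) /
      ((rare - h + 2) * (2 * n - rare - h + 2))
    h <- h - 2L
    i <- i - 1L
  }
  ## going up: P(h+2) = P(h) * (rare-h)*(2n-rare-h) / ((h+2)*(h+1))
  h <- mid
  i <- iMid
  while (h <= rare - 2L) {
    probs[i + 1L] <- probs[i] * (rare - h) * (2 * n - rare - h) /
      ((h + 2) * (h + 1))
    h <- h + 2L
    i <- i + 1L
  }
  probs <- probs / sum(probs)
  pObs <- probs[match(het, hets)]
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' HWE exact-test p-values for every site of a call set
#'
#' Genotype classes are formed by pooling all alternate alleles into one
#' class (reference vs non-reference), so the biallelic exact test applies
#' to multi-allelic sites as well. Non-missing genotypes only.
#'
#' @param vcs a [VariantCallSet-class].
#' @return numeric vector of p-values, `NA` for all-missing sites.
#' @export
hweExactPBySite <- function(vcs) {
  g1 <- .gt1(vcs); g2 <- .gt2(vcs)
  a1 <- g1 > 0L; a2 <- g2 > 0L
  homRef <- rowSums(!a1 & !a2, na.rm = TRUE)
  het <- rowSums(xor(a1, a2), na.rm = TRUE)
  homAlt <- rowSums(a1 & a2, na.rm = TRUE)
  hweExactP(homRef, het, homAlt)
}

#' Allele balance of heterozygotes (ABHet)
#'
#' Pooled (not averaged) over ref/alt heterozygous samples: the sum of their
#' reference-allele read depths divided by the sum of their total allelic
#' depths. Alt/alt heterozygotes (e.g. 1/2) are excluded since reference
#' balance is undefined for them. On chromosome X only samples recorded as
#' female in the pedigree are used (all samples when no pedigree is given).
#' `NA` when no qualifying heterozygote has usable AD.
#'
#' @param vcs a [VariantCallSet-class].
#' @param ped optional [Pedigree-class] providing sample sex for the
#'   chromosome X rule.
#' @return numeric vector in \[0, 1\] or `NA`.
#' @export
abHet <- function(vcs, ped = NULL) {
  het <- .refAltHet(vcs)
  adR <- .adRef(vcs); adT <- .adTotal(vcs)
  use <- het & !is.na(adR) & !is.na(adT)
  poolRatio <- function(cols) {
    num <- rowSums((adR * use)[, cols, drop = FALSE], na.rm = TRUE)
    den <- rowSums((adT * use)[, cols, drop = FALSE], na.rm = TRUE)
    ifelse(den > 0, num / den, NA_real_)
  }
  out <- poolRatio(seq_len(ncol(vcs)))
  onX <- toupper(variantChrom(vcs)) == "X"
  if (any(onX) && !is.null(ped)) {
    females <- intersect(pedFemales(ped), colnames(vcs))
    outX <- if (length(females)) poolRatio(females) else rep(NA_real_, nrow(vcs))
    out[onX] <- outX[onX]
  }
  out
}

#' Minor allele frequency (reference vs pooled alternate)
#'
#' Frequency of the less frequent allele class among non-missing alleles,
#' pooling all alternate alleles; the minor class may be the reference.
#'
#' @param vcs a [VariantCallSet-class].
#' @return numeric vector in \[0, 0.5\]; `NA` for all-missing sites.
#' @export
minorAlleleFreq <- function(vcs) {
  g1 <- .gt1(vcs); g2 <- .gt2(vcs)
  nonMiss <- rowSums(!is.na(g1)) + rowSums(!is.na(g2))
  altN <- rowSums(g1 > 0L, na.rm = TRUE) + rowSums(g2 > 0L, na.rm = TRUE)
  p <- ifelse(nonMiss > 0, altN / nonMiss, NA_real_)
  pmin(p, 1 - p)
}

#' Compute the full per-variant statistics table
#'
#' Assembles the filter statistics and, when calibration objects are
#' supplied, the seven classifier features, into one data.frame with one row
#' per site of `vcs` (columns: `key`, `chrom`, `pos`, `ref`, `alt`, `type`,
#' `missing_rate`, `mendel_error_rate`, `hwe_p`, `abhet`, `maf`, and the
#' features `mean_dp`, `sd_dp`, `outlier_dp`, `mean_gq`, `sd_gq`,
#' `outlier_gq`, `gc`).
#'
#' @param vcs a [VariantCallSet-class].
#' @param ped optional [Pedigree-class] (Mendelian errors, chrX ABHet rule).
#' @param thresholds optional [OutlierThresholds-class] for outlier ratios.
#' @param gcIndex optional [GCWindowIndex-class] for window GC content.
#' @return a data.frame, one row per variant.
#' @export
computeVariantStats <- function(vcs, ped = NULL, thresholds = NULL,
                                gcIndex = NULL) {
  sm <- .rowMeanSd(.dp(vcs))
  sq <- .rowMeanSd(.gq(vcs))
  outl <- if (!is.null(thresholds)) outlierRatios(vcs, thresholds)
          else list(dp = rep(NA_real_, nrow(vcs)),
                    gq = rep(NA_real_, nrow(vcs)))
  gc <- if (!is.null(gcIndex)) gcOfVariant(vcs, gcIndex)
        else rep(NA_real_, nrow(vcs))
  data.frame(
    key = variantKey(vcs),
    chrom = variantChrom(vcs),
    pos = variantPos(vcs),
    ref = refAllele(vcs),
    alt = vapply(altAlleles(vcs), paste, "", collapse = ","),
    type = variantType(vcs),
    missing_rate = missingRate(vcs),
    mendel_error_rate = mendelErrorRate(vcs, ped),
    hwe_p = hweExactPBySite(vcs),
    abhet = abHet(vcs, ped),
    maf = minorAlleleFreq(vcs),
    mean_dp = sm$mean, sd_dp = sm$sd, outlier_dp = outl$dp,
    mean_gq = sq$mean, sd_gq = sq$sd, outlier_gq = outl$gq,
    gc = gc,
    stringsAsFactors = FALSE)
}
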