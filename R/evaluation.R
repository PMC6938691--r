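# Quality-assessment metrics for a labeled variant set: Ti/Tv (variant- and
# sample-level, known/novel), genotype discordance against a microarray,
# known/novel split, multi-allelic and rare fractions, singletons.

.isTransition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
  (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

## Per-site transition/transversion counts, each alternate allele counted
## once; rows must be SNVs.
.tiTvCounts <- function(vcs) {
  ref <- refAllele(vcs)
  altL <- altAlleles(vcs)
  nAlt <- lengths(altL)
  alt <- unlist(as.list(altL), use.names = FALSE)
  isTi <- .isTransition(rep(ref, nAlt), alt)
  ## matrix site x altIndex of transition flags (NA beyond a site's alts)
  tiMat <- matrix(NA, nrow(vcs), max(nAlt))
  tiMat[cbind(rep(seq_len(nrow(vcs)), nAlt),
              sequence(nAlt))] <- isTi
  tiMat
}

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T; everything else among single-base
#' changes is a transversion. Variant-level: each biallelic SNV counts once
#' and each alternate allele of a multi-allelic SNV counts once. With
#' `perSample = TRUE`, the ratio is computed for each individual over the
#' alternate alleles it carries. The mitochondrial contig is excluded by
#' default since its substitution spectrum is atypical. `NA` when the
#' transversion count is zero. Passing indels is an error.
#'
#' @param vcs a [VariantCallSet-class] of SNVs.
#' @param perSample compute one ratio per sample instead of one overall.
#' @param excludeMito drop the mitochondrial contig (default TRUE).
#' @return a single ratio, or a named numeric vector per sample.
#' @export
titvRatio <- function(vcs, perSample = FALSE, excludeMito = TRUE) {
  if (any(variantType(vcs) != "snv"))
    stop("titvRatio is defined for SNVs only; split the indel stream out")
  if (excludeMito)
    vcs <- vcs[!(toupper(variantChrom(vcs)) %in% .MITO_CHROMS), ]
  if (nrow(vcs) == 0L)
    return(if (perSample) stats::setNames(rep(NA_real_, ncol(vcs)),
                                          colnames(vcs)) else NA_real_)
  tiMat <- .tiTvCounts(vcs)
  if (!perSample) {
    ti <- sum(tiMat, na.rm = TRUE)
    tv <- sum(!tiMat, na.rm = TRUE)
    return(if (tv == 0) NA_real_ else ti / tv)
  }
  g1 <- .gt1(vcs); g2 <- .gt2(vcs)
  ti <- tv <- numeric(ncol(vcs))
  for (a in seq_len(ncol(tiMat))) {
    hasAlt <- !is.na(tiMat[, a])
    carrier <- (g1 == a | g2 == a)
    carrier[is.na(carrier)] <- FALSE
    carrier <- carrier & hasAlt
    ti <- ti + colSums(carrier & tiMat[, a])
    tv <- tv + colSums(carrier & !tiMat[, a])
  }
  out <- ifelse(tv > 0, ti / tv, NA_real_)
  stats::setNames(out, colnames(vcs))
}

#' Genotype discordance between sequencing and microarray
#'
#' For each sequenced site present in the microarray extract, the fraction
#' of individuals (non-missing on both platforms) whose unordered allele
#' pair differs between the two. Sites whose ref/alt definition disagrees
#' with the array's are skipped with a warning (strand flips are not
#' resolved). Sites absent from the array, and sites with no comparable
#' sample, are `NA`.
#'
#' @param vcs a [VariantCallSet-class].
#' @param chip a [MicroarrayGenotypes-class].
#' @return numeric vector, one value (or `NA`) per site of `vcs`.
#' @export
genotypeDiscordance <- function(vcs, chip) {
  out <- rep(NA_real_, nrow(vcs))
  key <- paste0(variantChrom(vcs), ":", variantPos(vcs))
  chipKey <- paste0(chip@sites$chrom, ":", chip@sites$pos)
  hit <- match(key, chipKey)
  rows <- which(!is.na(hit))
  if (!length(rows)) return(out)
  common <- intersect(colnames(vcs), colnames(chip@calls))
  if (!length(common)) return(out)

  ref <- refAllele(vcs); altL <- altAlleles(vcs)
  g1 <- .gt1(vcs)[, common, drop = FALSE]
  g2 <- .gt2(vcs)[, common, drop = FALSE]
  skipped <- 0L
  for (r in rows) {
    cs <- chip@sites[hit[r], ]
    alts <- altL[[r]]
    if (!(nchar(ref[r]) == 1L && length(alts) == 1L && nchar(alts) == 1L &&
          cs$ref == ref[r] && cs$alt == alts)) {
      skipped <- skipped + 1L
      next
    }
    alleles <- c(ref[r], alts)
    a1 <- alleles[g1[r, ] + 1L]; a2 <- alleles[g2[r, ] + 1L]
    seqCall <- ifelse(is.na(a1) | is.na(a2), NA_character_,
                      paste0(pmin(a1, a2), pmax(a1, a2)))
    chipCall <- chip@calls[hit[r], common]
    comparable <- !is.na(seqCall) & !is.na(chipCall)
    if (any(comparable))
      out[r] <- mean(seqCall[comparable] != chipCall[comparable])
  }
  if (skipped)
    warning(skipped, " site(s) skipped: allele definitions disagree ",
            "between call set and microarray")
  out
}

#' Split a variant set into known and novel
#'
#' Exact (chrom, pos, ref, alt) matching by default (a multi-allelic site is
#' known if any alternate allele matches); the positional fallback matches
#' on (chrom, pos) only and is flagged in the result.
#'
#' @param vcs a [VariantCallSet-class].
#' @param known a [KnownSites-class].
#' @param mode `"exact"` or `"position"`; `"exact"` requires an
#'   allele-resolved resource.
#' @return list: `known`, `novel` (counts), `knownPct`, `isKnown` (logical
#'   per site), `mode`.
#' @export
knownNovelSplit <- function(vcs, known, mode = c("exact", "position")) {
  mode <- match.arg(mode)
  if (mode == "exact" && !known@hasAlleles) {
    mode <- "position"
    warning("known-sites resource has no alleles; falling back to ",
            "positional matching")
  }
  if (mode == "exact") {
    altL <- altAlleles(vcs)
    nAlt <- lengths(altL)
    keys <- paste0(rep(variantChrom(vcs), nAlt), ":",
                   rep(variantPos(vcs), nAlt), "_",
                   rep(refAllele(vcs), nAlt), "/",
                   unlist(as.list(altL), use.names = FALSE))
    hitAllele <- keys %in% known@full
    isKnown <- as.logical(rowsum(as.integer(hitAllele),
                                 rep(seq_len(nrow(vcs)), nAlt)) > 0L)
  } else {
    isKnown <- paste0(variantChrom(vcs), ":", variantPos(vcs)) %in%
      known@posOnly
  }
  n <- length(isKnown)
  list(known = sum(isKnown), novel = sum(!isKnown),
       knownPct = if (n) 100 * sum(isKnown) / n else NA_real_,
       isKnown = isKnown, mode = mode)
}

#' Summarize quality metrics for a variant set
#'
#' Assembles the variant-level and sample-level metric tables for one
#' (typically labeled) variant set. Optional resources that are absent make
#' the affected metrics `NA`. Rare/common is split at MAF < 0.03.
#'
#' Variant-level: SNV/indel counts, known counts and percent, multi-allelic
#' SNV count and percent, mean missing rate, mean Mendelian error rate,
#' mean discordance, rare-variant fraction, variant-level Ti/Tv.
#' Sample-level (one row per sample): SNVs carried, novel SNVs carried,
#' singletons, Ti/Tv over known and novel SNVs carried, indels carried.
#'
#' @param vcs a [VariantCallSet-class].
#' @param ped optional [Pedigree-class].
#' @param chip optional [MicroarrayGenotypes-class].
#' @param known optional [KnownSites-class].
#' @return list with elements `variant_level` (named list) and
#'   `sample_level` (data.frame).
#' @export
summarizeQc <- function(vcs, ped = NULL, chip = NULL, known = NULL) {
  isSnv <- variantType(vcs) == "snv"
  snvs <- vcs[isSnv, ]
  nSnv <- nrow(snvs); nIndel <- sum(!isSnv)
  multi <- lengths(altAlleles(snvs)) > 1L

  ks <- if (!is.null(known)) knownNovelSplit(vcs, known) else NULL
  isKnown <- if (!is.null(ks)) ks$isKnown else rep(NA, nrow(vcs))
  maf <- minorAlleleFreq(vcs)

  vl <- list(
    total_snvs = nSnv,
    total_indels = nIndel,
    known_snvs = if (!is.null(ks)) sum(isKnown & isSnv) else NA_integer_,
    known_snvs_pct = if (!is.null(ks) && nSnv)
      100 * sum(isKnown & isSnv) / nSnv else NA_real_,
    known_indels = if (!is.null(ks)) sum(isKnown & !isSnv) else NA_integer_,
    known_indels_pct = if (!is.null(ks) && nIndel)
      100 * sum(isKnown & !isSnv) / nIndel else NA_real_,
    multi_allelic_snvs = sum(multi),
    multi_allelic_snvs_pct = if (nSnv) 100 * sum(multi) / nSnv else NA_real_,
    mean_missing_rate = mean(missingRate(vcs)),
    mean_mendel_error_rate = if (!is.null(ped))
      mean(mendelErrorRate(vcs, ped), na.rm = TRUE) else NA_real_,
    mean_discordance = if (!is.null(chip))
      mean(genotypeDiscordance(vcs, chip), na.rm = TRUE) else NA_real_,
    rare_fraction = if (any(!is.na(maf))) mean(maf < 0.03, na.rm = TRUE)
      else NA_real_,
    titv = if (nSnv) titvRatio(snvs) else NA_real_)

  samp <- colnames(vcs)
  carrierMat <- function(v) {
    g1 <- .gt1(v); g2 <- .gt2(v)
    m <- (g1 > 0L) | (g2 > 0L)
    m[is.na(m)] <- FALSE
    m
  }
  snvCarrier <- carrierMat(snvs)
  indelCarrier <- carrierMat(vcs[!isSnv, ])
  singleSites <- rowSums(snvCarrier) == 1L
  knownSnv <- if (!is.null(ks)) ks$isKnown[isSnv] else rep(NA, nSnv)

  sl <- data.frame(
    sample = samp,
    total_snvs = colSums(snvCarrier),
    novel_snvs = if (!is.null(ks))
      colSums(snvCarrier[!knownSnv, , drop = FALSE]) else NA_integer_,
    singletons = colSums(snvCarrier[singleSites, , drop = FALSE]),
    titv_known = if (!is.null(ks) && any(knownSnv))
      titvRatio(snvs[knownSnv, ], perSample = TRUE) else NA_real_,
    titv_novel = if (!is.null(ks) && any(!knownSnv))
      titvRatio(snvs[!knownSnv, ], perSample = TRUE) else NA_real_,
    total_indels = colSums(indelCarrier),
    row.names = NULL, stringsAsFactors = FALSE)
  list(variant_level = vl, sample_level = sl)
}
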