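# The seven classifier features: mean, SD and outlier ratio of per-sample
# depth (DP) and genotype quality (GQ), and the GC fraction of the fixed
# 1-kb reference window containing the variant.

#' Per-variant mean and SD of depth and genotype quality
#'
#' Mean and population SD (divide by n) over non-missing per-sample values;
#' the SD of a single value is 0, and a channel with no non-missing value
#' yields an `NA` pair.
#'
#' @param vcs a [VariantCallSet-class].
#' @return data.frame with columns `mean_dp`, `sd_dp`, `mean_gq`, `sd_gq`.
#' @export
summarizeDpGq <- function(vcs) {
  d <- .rowMeanSd(.dp(vcs))
  g <- .rowMeanSd(.gq(vcs))
  data.frame(mean_dp = d$mean, sd_dp = d$sd,
             mean_gq = g$mean, sd_gq = g$sd)
}

#' Calibrate dataset-wide DP/GQ outlier thresholds
#'
#' Pools every non-missing per-sample DP (resp. GQ) value across all
#' variants of one chromosome and takes the lower quartile of each pool
#' (linear interpolation between order statistics, the `type = 7` quantile
#' rule). One chromosome suffices and keeps the cost low; calibrate on a
#' different chromosome via `chrom`.
#'
#' @param vcs a [VariantCallSet-class].
#' @param chrom calibration chromosome (default `"1"`).
#' @return an [OutlierThresholds-class].
#' @export
calibrateOutlierThresholds <- function(vcs, chrom = "1") {
  chrom <- normalizeChrom(chrom)
  rows <- variantChrom(vcs) == chrom
  if (!any(rows))
    stop("no variants on chromosome '", chrom,
         "'; pass another chromosome to calibrate outlier thresholds on")
  q1 <- function(m) {
    v <- m[rows, , drop = FALSE]
    v <- v[!is.na(v)]
    if (!length(v))
      stop("no non-missing values on calibration chromosome '", chrom, "'")
    unname(quantile(v, 0.25, type = 7))
  }
  new("OutlierThresholds", dpQ1 = q1(.dp(vcs)), gqQ1 = q1(.gq(vcs)),
      sourceChrom = chrom)
}

#' Per-variant outlier ratios of DP and GQ
#'
#' Proportion of samples whose value falls strictly below the calibrated
#' lower-quartile threshold; samples with a missing value are excluded from
#' the denominator, and a channel with no non-missing value is `NA`.
#'
#' @param vcs a [VariantCallSet-class].
#' @param thresholds an [OutlierThresholds-class].
#' @return list with numeric vectors `dp` and `gq`.
#' @export
outlierRatios <- function(vcs, thresholds) {
  ratio <- function(m, thr) {
    k <- rowSums(!is.na(m))
    ifelse(k > 0, rowSums(m < thr, na.rm = TRUE) / k, NA_real_)
  }
  list(dp = ratio(.dp(vcs), thresholds@dpQ1),
       gq = ratio(.gq(vcs), thresholds@gqQ1))
}

#' Build a windowed GC-content index from a reference genome
#'
#' Splits every chromosome into consecutive fixed-size windows from its
#' first base (the last window may be short) and records, per window,
#' (# G or C) / (# A, C, G or T), case-insensitively; other bases (N, IUPAC
#' ambiguity codes) count in neither numerator nor denominator.
#'
#' @param fasta path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @param windowSize window size in base pairs (default 1000).
#' @return a [GCWindowIndex-class].
#' @export
buildGcIndex <- function(fasta, windowSize = 1000L) {
  seqs <- if (is(fasta, "DNAStringSet")) fasta
          else Biostrings::readDNAStringSet(fasta)
  names(seqs) <- normalizeChrom(sub("\\s.*$", "", names(seqs)))
  windowSize <- as.integer(windowSize)
  windows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    chunks <- IRanges::breakInChunks(length(s), chunksize = windowSize)
    lf <- Biostrings::letterFrequency(Biostrings::Views(s, chunks),
                                      c("A", "C", "G", "T"))
    informative <- rowSums(lf)
    gc <- (lf[, "G"] + lf[, "C"]) / informative
    gc[informative == 0] <- NA_real_
    as.numeric(gc)
  })
  names(windows) <- names(seqs)
  new("GCWindowIndex", windows = windows, windowSize = windowSize)
}

#' GC content of the window containing each variant
#'
#' Window `floor((pos - 1) / windowSize)` on the variant's chromosome; `NA`
#' (with one warning) for variants on contigs absent from the reference.
#'
#' @param vcs a [VariantCallSet-class], or a character vector of chromosome
#'   names (then `pos` must be given).
#' @param index a [GCWindowIndex-class].
#' @param pos positions, only when `vcs` is a chromosome vector.
#' @return numeric vector of GC fractions or `NA`.
#' @export
gcOfVariant <- function(vcs, index, pos = NULL) {
  if (is(vcs, "VariantCallSet")) {
    chrom <- variantChrom(vcs)
    pos <- variantPos(vcs)
  } else {
    chrom <- normalizeChrom(vcs)
  }
  win <- (pos - 1L) %/% index@windowSize + 1L
  out <- rep(NA_real_, length(chrom))
  miss <- !(chrom %in% names(index@windows))
  if (any(miss))
    warning(sum(miss), " variant(s) on contigs absent from the reference; ",
            "GC content set to NA")
  for (ch in unique(chrom[!miss])) {
    sel <- chrom == ch
    gcs <- index@windows[[ch]]
    w <- win[sel]
    w[w > length(gcs)] <- NA_integer_
    out[sel] <- gcs[w]
  }
  out
}

#' Assemble the classifier feature matrix
#'
#' The seven features in their canonical order (`mean_dp`, `sd_dp`,
#' `outlier_dp`, `mean_gq`, `sd_gq`, `outlier_gq`, `gc`), as used by
#' training and prediction.
#'
#' @param vcs a [VariantCallSet-class].
#' @param thresholds an [OutlierThresholds-class].
#' @param gcIndex a [GCWindowIndex-class].
#' @return numeric matrix, one row per variant.
#' @export
qcFeatures <- function(vcs, thresholds, gcIndex) {
  s <- summarizeDpGq(vcs)
  o <- outlierRatios(vcs, thresholds)
  m <- cbind(mean_dp = s$mean_dp, sd_dp = s$sd_dp, outlier_dp = o$dp,
             mean_gq = s$mean_gq, sd_gq = s$sd_gq, outlier_gq = o$gq,
             gc = gcOfVariant(vcs, gcIndex))
  m[, .FEATURES, drop = FALSE]
}
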