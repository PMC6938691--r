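#' @importFrom methods new is validObject slot
#' @importFrom stats quantile rbinom rnorm rpois rnbinom runif median predict
#' @importFrom utils read.table write.table packageVersion
NULL

## Canonical classifier feature order, fixed across training and prediction.
.FEATURES <- c("mean_dp", "sd_dp", "outlier_dp",
               "mean_gq", "sd_gq", "outlier_gq", "gc")

.SEX_CHROMS <- c("X", "Y")
.MITO_CHROMS <- c("MT", "M")

#' Normalize chromosome names
#'
#' Strips an optional "chr" prefix so that VCF, FASTA, known-site and
#' microarray inputs agree on naming.
#'
#' @param x character vector of chromosome names.
#' @return character vector without the "chr" prefix.
#' @export
normalizeChrom <- function(x) sub("^chr", "", as.character(x))

.isAutosome <- function(chrom) {
  !(toupper(chrom) %in% c(.SEX_CHROMS, .MITO_CHROMS))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Population-style row mean/SD over a matrix with NAs; SD divides by n.
.rowMeanSd <- function(m) {
  k <- rowSums(!is.na(m))
  s <- rowSums(m, na.rm = TRUE)
  mu <- ifelse(k > 0, s / k, NA_real_)
  ss <- rowSums(m * m, na.rm = TRUE)
  v <- ifelse(k > 0, pmax(ss / k - mu^2, 0), NA_real_)
  list(mean = mu, sd = sqrt(v), n = k)
}

.fmtNum <- function(x, digits = 6L) {
  out <- ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
  out
}
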