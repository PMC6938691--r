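# Filter stage: partition variants into HIGH / LOW / UNDETERMINED from the
# per-variant statistics table and a FilterConfig.

.QC_LEVELS <- c("HIGH", "LOW", "UNDETERMINED")

#' Classify variants by hard filters
#'
#' A variant is LOW if any bad bound is triggered (`stat <= lo` or
#' `stat >= hi`; `NA` statistics never trigger). Otherwise it is HIGH if
#' every good bound whose statistic is non-`NA` is satisfied (inclusive
#' interval) and the number of `NA` statistics among good-bound statistics
#' is at most the configured tolerance. Everything else is UNDETERMINED.
#'
#' The Mendelian-error bound is treated as absent when its column is
#' entirely `NA` (no pedigree); every other statistic keeps its bound, with
#' per-variant `NA`s handled by the tolerance rule. A bound naming a column
#' that does not exist is an error.
#'
#' @param stats data.frame from [computeVariantStats()], possibly with extra
#'   user-supplied statistic columns.
#' @param config a [FilterConfig-class].
#' @return factor with levels HIGH, LOW, UNDETERMINED, one per row.
#' @export
classifyByFilters <- function(stats, config) {
  validObject(config)
  n <- nrow(stats)
  activeBounds <- function(bounds, which) {
    missing <- setdiff(names(bounds), colnames(stats))
    if (length(missing))
      stop(which, " bounds reference unknown statistics column(s): ",
           paste(missing, collapse = ", "))
    ## the Mendelian-error bound is structurally absent without a pedigree;
    ## other statistics keep their bounds and NAs count per variant
    drop <- vapply(names(bounds), function(s)
      s == "mendel_error_rate" && all(is.na(stats[[s]])), logical(1))
    if (any(drop))
      message("dropping ", which, " bound(s) with no data: ",
              paste(names(bounds)[drop], collapse = ", "))
    bounds[!drop]
  }
  bad <- activeBounds(config@bad, "bad")
  good <- activeBounds(config@good, "good")

  isLow <- rep(FALSE, n)
  for (s in names(bad)) {
    b <- bad[[s]]; v <- stats[[s]]
    trig <- !is.na(v) & (v <= b[1] | v >= b[2])
    isLow <- isLow | trig
  }
  goodOk <- rep(TRUE, n)
  naCount <- rep(0L, n)
  for (s in names(good)) {
    g <- good[[s]]; v <- stats[[s]]
    nas <- is.na(v)
    goodOk <- goodOk & (nas | (v >= g[1] & v <= g[2]))
    naCount <- naCount + nas
  }
  isHigh <- !isLow & goodOk & naCount <= config@naTolerance
  factor(ifelse(isLow, "LOW", ifelse(isHigh, "HIGH", "UNDETERMINED")),
         levels = .QC_LEVELS)
}

#' ABHet-only baseline classification
#'
#' The simple allele-balance filter used as a comparison baseline: LOW iff
#' ABHet > 0.7 or < 0.3 (strict), HIGH otherwise, including sites whose
#' ABHet is undefined. Never UNDETERMINED.
#'
#' @param stats data.frame with an `abhet` column, or a numeric vector of
#'   ABHet values.
#' @return factor with levels HIGH, LOW, UNDETERMINED (the latter unused).
#' @export
classifyAbhetBaseline <- function(stats) {
  ab <- if (is.data.frame(stats)) stats$abhet else stats
  low <- !is.na(ab) & (ab > 0.7 | ab < 0.3)
  factor(ifelse(low, "LOW", "HIGH"), levels = .QC_LEVELS)
}

#' Summarize a filter-stage partition
#'
#' Counts and fractions per class. The filter stage works best when roughly
#' 4-16% of variants land in the low-quality class (enough unambiguous
#' negatives to train on, without swallowing good variants); a fraction
#' outside that band raises a warning suggesting threshold adjustment.
#'
#' @param labels factor from [classifyByFilters()].
#' @return list with `counts` and `fractions` (named numeric vectors).
#' @export
partitionReport <- function(labels) {
  labels <- factor(labels, levels = .QC_LEVELS)
  counts <- table(labels)
  total <- sum(counts)
  fractions <- if (total > 0) as.numeric(counts) / total
               else rep(NA_real_, 3)
  names(fractions) <- names(counts)
  lowFrac <- fractions[["LOW"]]
  if (total > 0 && (lowFrac < 0.04 || lowFrac > 0.16))
    warning(sprintf(
      paste0("low-quality fraction %.3f is outside the recommended 4-16%% ",
             "band; consider adjusting the filter thresholds"), lowFrac))
  list(counts = c(as.list(counts), total = total) |>
         unlist() |> as.integer() |>
         stats::setNames(c(.QC_LEVELS, "total")),
       fractions = fractions)
}
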