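# Reading and writing the standard formats: VCF (via VariantAnnotation),
# PED, known-sites lists, microarray genotype tables, label TSVs and the
# filtered high-/low-quality VCFs.

#' Read a multi-sample VCF into a VariantCallSet
#'
#' Sites are kept un-split (one row per multi-allelic site). Missing FORMAT
#' subfields become `NA`, never 0. Per-sample DP is taken from FORMAT/DP and
#' falls back to the sum of AD when DP is absent; if both are absent it is
#' `NA`.
#'
#' @param path VCF v4.x file, plain or bgzipped.
#' @param region optional chromosome name; only that chromosome is kept.
#' @param halfCalls policy for half-missing genotypes such as `./1`:
#'   `"missing"` (default) treats the whole genotype as missing; `"partial"`
#'   keeps the called allele and counts one missing allele.
#' @return a [VariantCallSet-class].
#' @export
readVariantCallSet <- function(path, region = NULL,
                               halfCalls = c("missing", "partial")) {
  halfCalls <- match.arg(halfCalls)
  vcf <- VariantAnnotation::readVcf(path)
  g <- VariantAnnotation::geno(vcf)
  gt <- g$GT
  if (is.null(gt)) stop("VCF has no GT FORMAT field")
  nr <- nrow(gt); nc <- ncol(gt)

  a1 <- sub("[/|].*$", "", gt)
  a2 <- sub("^[^/|]*[/|]", "", gt)
  a2[!grepl("[/|]", gt)] <- "."   # haploid call: second allele missing
  g1 <- suppressWarnings(array(as.integer(a1), dim = dim(gt)))
  g2 <- suppressWarnings(array(as.integer(a2), dim = dim(gt)))
  if (halfCalls == "missing") {
    half <- xor(is.na(g1), is.na(g2))
    g1[half] <- NA_integer_
    g2[half] <- NA_integer_
  }

  naMat <- function() matrix(NA_integer_, nr, nc)
  dp <- if (!is.null(g$DP)) {
    m <- g$DP; storage.mode(m) <- "integer"; m
  } else naMat()

  gq <- if (!is.null(g$GQ)) {
    m <- g$GQ; storage.mode(m) <- "integer"; m
  } else naMat()

  adRef <- naMat(); adTot <- naMat()
  if (!is.null(g$AD)) {
    ad <- g$AD
    if (is.list(ad)) {
      adRef[] <- vapply(ad, function(x) {
        if (is.null(x) || all(is.na(x))) NA_integer_ else as.integer(x[1])
      }, integer(1))
      adTot[] <- vapply(ad, function(x) {
        if (is.null(x) || all(is.na(x))) NA_integer_
        else as.integer(sum(x, na.rm = TRUE))
      }, integer(1))
      nAllele <- 1L + lengths(VariantAnnotation::alt(vcf))
      adLen <- matrix(vapply(ad, function(x) length(x[!is.na(x)]),
                             integer(1)), nr, nc)
      bad <- adLen > 0L & adLen != nAllele
      if (any(bad))
        warning(sum(bad), " AD entries do not match the site allele count; ",
                "treated as missing")
      adRef[bad] <- NA_integer_
      adTot[bad] <- NA_integer_
    } else if (length(dim(ad)) == 3L) {
      adRef[] <- as.integer(ad[, , 1L])
      adTot[] <- as.integer(apply(ad, c(1L, 2L), function(x)
        if (all(is.na(x))) NA_integer_ else sum(x, na.rm = TRUE)))
    }
  }
  ## DP fallback: per-sample sum of AD
  fb <- is.na(dp) & !is.na(adTot)
  dp[fb] <- adTot[fb]

  rr <- SummarizedExperiment::rowRanges(vcf)
  id <- names(rr) %||% rep(NA_character_, nr)
  key <- paste0(as.character(GenomicRanges::seqnames(rr)), ":",
                GenomicRanges::start(rr))
  id[startsWith(id, key)] <- NA_character_  # synthesized keys, not real IDs

  vcs <- VariantCallSet(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = lapply(VariantAnnotation::alt(vcf), as.character),
    gt1 = g1, gt2 = g2, dp = dp, gq = gq, adRef = adRef, adTotal = adTot,
    variantId = id, samples = colnames(gt))
  if (!is.null(region))
    vcs <- vcs[variantChrom(vcs) == normalizeChrom(region), ]
  vcs
}

#' Read a PED-style pedigree file
#'
#' Whitespace-delimited, at least six columns (family, individual, father,
#' mother, sex, phenotype). Sex code 1 is MALE, 2 is FEMALE, anything else
#' UNKNOWN; a `0` parent marks a founder. Duplicate individual ids are
#' fatal; an empty file yields an empty pedigree.
#'
#' @param path PED file path.
#' @return a [Pedigree-class].
#' @export
readPedigree <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) return(Pedigree())
  tab <- read.table(text = lines, header = FALSE, colClasses = "character")
  if (ncol(tab) < 6)
    stop("PED file must have at least 6 columns, found ", ncol(tab))
  if (anyDuplicated(tab[[2]]))
    stop("duplicate individual id in pedigree: ",
         paste(unique(tab[[2]][duplicated(tab[[2]])]), collapse = ", "))
  sex <- ifelse(tab[[5]] == "1", "MALE",
                ifelse(tab[[5]] == "2", "FEMALE", "UNKNOWN"))
  Pedigree(id = tab[[2]], father = tab[[3]], mother = tab[[4]], sex = sex)
}

#' Read a known-sites resource
#'
#' Accepts a VCF (alleles resolved, one entry per alternate allele) or a
#' TSV: 5+ columns are read as (chrom, pos, id, ref, alt); 3 columns as
#' (chrom, pos, id) enabling positional lookups only.
#'
#' @param path VCF or TSV file.
#' @return a [KnownSites-class].
#' @export
readKnownSites <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^##fileformat=VCF", first) || grepl("\\.vcf(\\.gz)?$", path)) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    altL <- lapply(VariantAnnotation::alt(vcf), as.character)
    n <- lengths(altL)
    return(KnownSites(
      chrom = rep(as.character(GenomicRanges::seqnames(rr)), n),
      pos = rep(GenomicRanges::start(rr), n),
      ref = rep(as.character(VariantAnnotation::ref(vcf)), n),
      alt = unlist(altL, use.names = FALSE)))
  }
  tab <- read.table(path, header = FALSE, colClasses = "character",
                    comment.char = "#")
  if (ncol(tab) >= 5)
    KnownSites(chrom = tab[[1]], pos = tab[[2]], ref = tab[[4]],
               alt = tab[[5]])
  else if (ncol(tab) >= 2)
    KnownSites(chrom = tab[[1]], pos = tab[[2]])
  else stop("known-sites TSV needs at least chrom and pos columns")
}

#' Read a microarray genotype table
#'
#' Tab-separated with header: columns `chrom`, `pos`, `ref`, `alt` followed
#' by one column per sample holding base-pair genotypes (`"AG"`, `"NN"` for
#' missing).
#'
#' @param path TSV file path.
#' @return a [MicroarrayGenotypes-class].
#' @export
readMicroarray <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% colnames(tab)))
    stop("microarray table must have columns ",
         paste(need, collapse = ", "))
  sampleCols <- setdiff(colnames(tab), need)
  MicroarrayGenotypes(chrom = tab$chrom, pos = tab$pos, ref = tab$ref,
                      alt = tab$alt,
                      calls = as.matrix(tab[, sampleCols, drop = FALSE]))
}

#' Write per-variant QC labels to TSV
#'
#' One row per variant: chrom, pos, ref, alt, label (HIGH/LOW), stage
#' (FILTER/PREDICTED) and probability (empty for FILTER-stage variants).
#' Additional columns in `results` are appended.
#'
#' @param path output TSV path.
#' @param results data.frame with at least columns `chrom`, `pos`, `ref`,
#'   `alt`, `label`, `stage`, `probability`.
#' @param nExpected optional input variant count; a mismatch is fatal.
#' @return invisibly, the path.
#' @export
writeLabels <- function(path, results, nExpected = NULL) {
  need <- c("chrom", "pos", "ref", "alt", "label", "stage", "probability")
  if (!all(need %in% colnames(results)))
    stop("results must have columns ", paste(need, collapse = ", "))
  if (!is.null(nExpected) && nrow(results) != nExpected)
    stop("result count (", nrow(results),
         ") does not match variant count (", nExpected, ")")
  if (!all(results$label %in% c("HIGH", "LOW")))
    stop("labels must be HIGH or LOW")
  out <- results
  out$probability <- ifelse(
    out$stage == "FILTER" | is.na(out$probability), "",
    sprintf("%.6f", out$probability))
  extra <- setdiff(colnames(out), need)
  out <- out[, c(need, extra)]
  for (cn in extra)
    if (is.numeric(out[[cn]])) out[[cn]] <- .fmtNum(out[[cn]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split a VCF into high- and low-quality files
#'
#' Streams the original file and copies each data line verbatim into the
#' high- or low-quality output according to `labels` (given in file order),
#' so records are preserved byte-faithfully apart from the removed lines.
#'
#' @param vcfPath original VCF (plain or gzipped).
#' @param labels character vector, `"HIGH"`/`"LOW"`, one per data line.
#' @param highPath,lowPath output paths.
#' @return invisibly, `c(high = <n>, low = <n>)` line counts.
#' @export
writeFilteredVcfs <- function(vcfPath, labels, highPath, lowPath) {
  lines <- readLines(vcfPath, warn = FALSE)
  hdr <- startsWith(lines, "#")
  body <- lines[!hdr]
  if (length(body) != length(labels))
    stop("label count (", length(labels),
         ") does not match VCF record count (", length(body), ")")
  if (!all(labels %in% c("HIGH", "LOW")))
    stop("labels must be HIGH or LOW")
  writeLines(c(lines[hdr], body[labels == "HIGH"]), highPath)
  writeLines(c(lines[hdr], body[labels == "LOW"]), lowPath)
  invisible(c(high = sum(labels == "HIGH"), low = sum(labels == "LOW")))
}
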