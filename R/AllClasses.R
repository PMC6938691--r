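#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

# ---------------------------------------------------------------------------
# VariantCallSet
# ---------------------------------------------------------------------------

#' VariantCallSet: a multi-sample variant call set
#'
#' An S4 container for the per-site, per-sample information the QC pipeline
#' consumes, extending [SummarizedExperiment::RangedSummarizedExperiment].
#' Rows are variant sites (kept un-split: a multi-allelic site is one row),
#' columns are samples. Assays (all integer matrices, `NA` = missing):
#'
#' * `gt1`, `gt2` — the two allele indices of the unphased diploid genotype
#'   (0 = reference, k = k-th alternate allele);
#' * `dp` — per-sample read depth;
#' * `gq` — per-sample phred-scaled genotype quality;
#' * `adRef`, `adTotal` — reference-allele read depth and total allelic depth
#'   (the sum over all alleles of the AD field).
#'
#' Row metadata carries `ref` (reference allele string), `alt`
#' (a [S4Vectors::List] of alternate allele strings), `variantId` and `type`
#' (`"snv"` if ref and every alt are single bases, otherwise `"indel"`).
#'
#' @seealso [readVariantCallSet()] to build one from a VCF file.
#' @aliases VariantCallSet-class
#' @exportClass VariantCallSet
setClass("VariantCallSet", contains = "RangedSummarizedExperiment")

setValidity("VariantCallSet", function(object) {
  msgs <- character()
  need <- c("gt1", "gt2", "dp", "gq", "adRef", "adTotal")
  have <- SummarizedExperiment::assayNames(object)
  if (!all(need %in% have))
    return(paste("missing assays:", paste(setdiff(need, have), collapse = ", ")))
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("ref", "alt", "type") %in% colnames(rd)))
    return("rowData must contain 'ref', 'alt' and 'type'")
  if (nrow(object) > 0) {
    if (any(GenomicRanges::start(SummarizedExperiment::rowRanges(object)) < 1))
      msgs <- c(msgs, "positions must be >= 1")
    nAlleles <- 1L + lengths(rd$alt)
    g1 <- SummarizedExperiment::assay(object, "gt1")
    g2 <- SummarizedExperiment::assay(object, "gt2")
    gmax <- pmax(apply(g1, 1L, max, na.rm = TRUE) |> suppressWarnings(),
                 apply(g2, 1L, max, na.rm = TRUE) |> suppressWarnings())
    bad <- is.finite(gmax) & gmax >= nAlleles
    if (any(bad))
      msgs <- c(msgs, sprintf("%d site(s) carry allele indices beyond their allele count",
                              sum(bad)))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a VariantCallSet from parsed components
#'
#' @param chrom character vector of chromosome names (a "chr" prefix is
#'   stripped).
#' @param pos integer vector of 1-based positions.
#' @param ref character vector of reference alleles.
#' @param alt list (or [S4Vectors::List]) of character vectors of alternate
#'   alleles, one element per site.
#' @param gt1,gt2 integer matrices (sites x samples) of allele indices,
#'   `NA` for missing calls.
#' @param dp,gq integer matrices of per-sample depth and genotype quality.
#' @param adRef,adTotal integer matrices of reference-allele and total
#'   allelic depth; default all-`NA`.
#' @param variantId optional character vector of site identifiers.
#' @param samples optional character vector of sample names (defaults to
#'   `colnames(gt1)`).
#' @return a [VariantCallSet-class] object.
#' @examples
#' vcs <- VariantCallSet(
#'   chrom = "1", pos = 100L, ref = "A", alt = list("G"),
#'   gt1 = matrix(c(0L, 0L), 1), gt2 = matrix(c(1L, 0L), 1),
#'   dp = matrix(c(30L, 28L), 1), gq = matrix(c(99L, 95L), 1),
#'   samples = c("s1", "s2"))
#' missingRate(vcs)
#' @export
VariantCallSet <- function(chrom, pos, ref, alt, gt1, gt2, dp, gq,
                           adRef = NULL, adTotal = NULL,
                           variantId = NULL, samples = NULL) {
  chrom <- normalizeChrom(chrom)
  n <- length(chrom)
  asMat <- function(m) {
    if (is.null(m)) m <- matrix(NA_integer_, n, ncol(gt1))
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    m
  }
  gt1 <- asMat(gt1); gt2 <- asMat(gt2)
  dp <- asMat(dp); gq <- asMat(gq)
  adRef <- asMat(adRef); adTotal <- asMat(adTotal)
  samples <- samples %||% colnames(gt1) %||% paste0("S", seq_len(ncol(gt1)))
  altL <- IRanges::CharacterList(lapply(alt, as.character))
  altMax <- vapply(as.list(altL), function(a) max(nchar(a)), numeric(1))
  type <- ifelse(nchar(ref) == 1L & altMax == 1L, "snv", "indel")
  rr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(pos), width = 1L))
  S4Vectors::mcols(rr) <- S4Vectors::DataFrame(
    ref = as.character(ref), alt = altL,
    variantId = variantId %||% rep(NA_character_, n),
    type = type)
  dimnames(gt1) <- dimnames(gt2) <- dimnames(dp) <- dimnames(gq) <-
    dimnames(adRef) <- dimnames(adTotal) <- list(NULL, samples)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(gt1 = gt1, gt2 = gt2, dp = dp, gq = gq,
                  adRef = adRef, adTotal = adTotal),
    rowRanges = rr)
  colnames(se) <- samples
  new("VariantCallSet", se)
}

#' @describeIn VariantCallSet number of variant sites
#' @param x,object a `VariantCallSet`.
#' @export
nVariants <- function(x) nrow(x)

#' @describeIn VariantCallSet normalized chromosome of each site
#' @export
variantChrom <- function(x)
  as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(x)))

#' @describeIn VariantCallSet 1-based position of each site
#' @export
variantPos <- function(x)
  GenomicRanges::start(SummarizedExperiment::rowRanges(x))

#' @describeIn VariantCallSet reference allele strings
#' @export
refAllele <- function(x) SummarizedExperiment::rowData(x)$ref

#' @describeIn VariantCallSet alternate alleles as a CharacterList
#' @export
altAlleles <- function(x) SummarizedExperiment::rowData(x)$alt

#' @describeIn VariantCallSet `"snv"` or `"indel"` per site
#' @export
variantType <- function(x) SummarizedExperiment::rowData(x)$type

#' @describeIn VariantCallSet stable site keys `chrom:pos_ref/alt1,alt2`
#' @export
variantKey <- function(x) {
  paste0(variantChrom(x), ":", variantPos(x), "_", refAllele(x), "/",
         vapply(altAlleles(x), paste, "", collapse = ","))
}

.gt1 <- function(x) SummarizedExperiment::assay(x, "gt1")
.gt2 <- function(x) SummarizedExperiment::assay(x, "gt2")
.dp  <- function(x) SummarizedExperiment::assay(x, "dp")
.gq  <- function(x) SummarizedExperiment::assay(x, "gq")
.adRef <- function(x) SummarizedExperiment::assay(x, "adRef")
.adTotal <- function(x) SummarizedExperiment::assay(x, "adTotal")

#' @describeIn VariantCallSet per-sample read-depth matrix
#' @export
readDepth <- function(x) .dp(x)

#' @describeIn VariantCallSet per-sample genotype-quality matrix
#' @export
genoQuality <- function(x) .gq(x)

## TRUE where the sample is a ref/alt heterozygote (exactly one allele is 0);
## alt/alt heterozygotes such as 1/2 are excluded because reference-read
## balance is undefined for them.
.refAltHet <- function(x) {
  g1 <- .gt1(x); g2 <- .gt2(x)
  het <- (g1 == 0L & g2 > 0L) | (g1 > 0L & g2 == 0L)
  het[is.na(het)] <- FALSE
  het
}

setMethod("show", "VariantCallSet", function(object) {
  ty <- table(factor(variantType(object), c("snv", "indel")))
  cat(sprintf("VariantCallSet: %d sites (%d SNVs, %d indels) x %d samples\n",
              nrow(object), ty[["snv"]], ty[["indel"]], ncol(object)))
  if (nrow(object))
    cat("  chromosomes:", paste(unique(variantChrom(object)), collapse = ", "),
        "\n")
})

# ---------------------------------------------------------------------------
# Pedigree
# ---------------------------------------------------------------------------

#' Pedigree of sequenced individuals
#'
#' Holds individual ids, parental links and sex, and derives the complete
#' trios used for Mendelian-error computation. Parent ids that are "0" or do
#' not refer to a declared individual mark founders; such children form no
#' trio.
#'
#' @aliases Pedigree-class
#' @exportClass Pedigree
setClass("Pedigree", representation(members = "data.frame"))

setValidity("Pedigree", function(object) {
  m <- object@members
  if (!all(c("id", "father", "mother", "sex") %in% colnames(m)))
    return("members must have columns id, father, mother, sex")
  if (anyDuplicated(m$id))
    return("duplicate individual ids")
  if (!all(m$sex %in% c("MALE", "FEMALE", "UNKNOWN")))
    return("sex must be MALE, FEMALE or UNKNOWN")
  TRUE
})

#' Construct a Pedigree
#'
#' @param id character vector of unique individual ids.
#' @param father,mother character vectors of parent ids; `NA` or `"0"` marks
#'   a founder.
#' @param sex `"MALE"`, `"FEMALE"` or `"UNKNOWN"` (recycled if length 1).
#' @return a [Pedigree-class] object.
#' @export
Pedigree <- function(id = character(), father = NA_character_,
                     mother = NA_character_, sex = "UNKNOWN") {
  n <- length(id)
  clean <- function(p) {
    p <- rep_len(as.character(p), n)
    p[p %in% c("0", "")] <- NA_character_
    p
  }
  m <- data.frame(id = as.character(id), father = clean(father),
                  mother = clean(mother), sex = rep_len(sex, n),
                  stringsAsFactors = FALSE)
  new("Pedigree", members = m)
}

#' @describeIn Pedigree complete trios as a data.frame (child, father, mother)
#' @param ped a `Pedigree`.
#' @export
pedTrios <- function(ped) {
  m <- ped@members
  keep <- !is.na(m$father) & !is.na(m$mother) &
    m$father %in% m$id & m$mother %in% m$id
  data.frame(child = m$id[keep], father = m$father[keep],
             mother = m$mother[keep], stringsAsFactors = FALSE)
}

#' @describeIn Pedigree ids of individuals recorded as female
#' @export
pedFemales <- function(ped) ped@members$id[ped@members$sex == "FEMALE"]

#' @describeIn Pedigree all individual ids
#' @export
pedIds <- function(ped) ped@members$id

setMethod("show", "Pedigree", function(object) {
  cat(sprintf("Pedigree: %d individuals, %d complete trios\n",
              nrow(object@members), nrow(pedTrios(object))))
})

# ---------------------------------------------------------------------------
# KnownSites
# ---------------------------------------------------------------------------

#' Known-sites resource (dbSNP-style)
#'
#' A deterministic membership test for previously catalogued variants, keyed
#' by (chrom, pos, ref, alt) with a positional (chrom, pos) fallback.
#' Duplicate entries collapse.
#'
#' @aliases KnownSites-class
#' @exportClass KnownSites
setClass("KnownSites", representation(full = "character",
                                      posOnly = "character",
                                      hasAlleles = "logical"))

#' Construct a KnownSites resource
#'
#' @param chrom,pos site coordinates.
#' @param ref,alt optional allele columns; when absent only positional
#'   lookups are possible.
#' @return a [KnownSites-class] object.
#' @export
KnownSites <- function(chrom, pos, ref = NULL, alt = NULL) {
  chrom <- normalizeChrom(chrom)
  posKey <- unique(paste0(chrom, ":", pos))
  hasAlleles <- !is.null(ref) && !is.null(alt)
  full <- if (hasAlleles)
    unique(paste0(chrom, ":", pos, "_", ref, "/", alt)) else character()
  new("KnownSites", full = full, posOnly = posKey, hasAlleles = hasAlleles)
}

setMethod("show", "KnownSites", function(object) {
  cat(sprintf("KnownSites: %d positions%s\n", length(object@posOnly),
              if (object@hasAlleles)
                sprintf(" (%d allele-resolved entries)", length(object@full))
              else " (positions only)"))
})

# ---------------------------------------------------------------------------
# MicroarrayGenotypes
# ---------------------------------------------------------------------------

#' Microarray genotype extract
#'
#' Biallelic SNV genotypes from an orthogonal genotyping platform, used to
#' compute sequencing/array genotype discordance. Calls are stored as sorted
#' base pairs (e.g. `"AG"`); `NA` marks a missing call.
#'
#' @aliases MicroarrayGenotypes-class
#' @exportClass MicroarrayGenotypes
setClass("MicroarrayGenotypes",
         representation(sites = "data.frame", calls = "matrix"))

setValidity("MicroarrayGenotypes", function(object) {
  if (nrow(object@sites) != nrow(object@calls))
    return("sites and calls row counts differ")
  s <- object@sites
  if (nrow(s) && !all(nchar(s$ref) == 1L & nchar(s$alt) == 1L))
    return("microarray sites must be biallelic SNVs")
  TRUE
})

#' Construct a MicroarrayGenotypes object
#'
#' @param chrom,pos,ref,alt biallelic SNV site definitions.
#' @param calls character matrix (sites x samples) of base-pair genotypes
#'   such as `"AG"`; `NA` or `"NN"` for missing.
#' @return a [MicroarrayGenotypes-class] object.
#' @export
MicroarrayGenotypes <- function(chrom, pos, ref, alt, calls) {
  calls <- as.matrix(calls)
  calls[calls %in% c("NN", "", ".")] <- NA_character_
  ## store calls with alphabetically sorted alleles
  sorted <- vapply(calls, function(g) {
    if (is.na(g)) return(NA_character_)
    paste(sort(strsplit(g, "")[[1]]), collapse = "")
  }, character(1))
  dim(sorted) <- dim(calls); dimnames(sorted) <- dimnames(calls)
  sites <- data.frame(chrom = normalizeChrom(chrom), pos = as.integer(pos),
                      ref = as.character(ref), alt = as.character(alt),
                      stringsAsFactors = FALSE)
  new("MicroarrayGenotypes", sites = sites, calls = sorted)
}

setMethod("show", "MicroarrayGenotypes", function(object) {
  cat(sprintf("MicroarrayGenotypes: %d sites x %d samples\n",
              nrow(object@sites), ncol(object@calls)))
})

# ---------------------------------------------------------------------------
# Feature calibration objects
# ---------------------------------------------------------------------------

#' Dataset-wide outlier thresholds for DP and GQ
#'
#' Lower-quartile depth and genotype-quality values pooled over every
#' non-missing per-sample value on one calibration chromosome; computed once
#' per dataset and reused for every variant's outlier-ratio features.
#'
#' @aliases OutlierThresholds-class
#' @exportClass OutlierThresholds
setClass("OutlierThresholds",
         representation(dpQ1 = "numeric", gqQ1 = "numeric",
                        sourceChrom = "character"))

setValidity("OutlierThresholds", function(object) {
  if (object@dpQ1 < 0 || object@gqQ1 < 0) "thresholds must be >= 0" else TRUE
})

setMethod("show", "OutlierThresholds", function(object) {
  cat(sprintf("OutlierThresholds: DP q1 = %g, GQ q1 = %g (chromosome %s)\n",
              object@dpQ1, object@gqQ1, object@sourceChrom))
})

#' Per-chromosome GC content in fixed-size windows
#'
#' Windows tile each chromosome from its first base; the last window may be
#' short. Bases outside A/C/G/T are excluded from numerator and denominator;
#' a window with no informative base is `NA`.
#'
#' @aliases GCWindowIndex-class
#' @exportClass GCWindowIndex
setClass("GCWindowIndex",
         representation(windows = "list", windowSize = "integer"))

setMethod("show", "GCWindowIndex", function(object) {
  cat(sprintf("GCWindowIndex: %d chromosome(s), %d-bp windows\n",
              length(object@windows), object@windowSize))
})

# ---------------------------------------------------------------------------
# FilterConfig
# ---------------------------------------------------------------------------

#' Hard-filter threshold configuration
#'
#' Two threshold sets over the per-variant statistics. Each entry is a
#' numeric `c(lo, hi)`:
#'
#' * `good` — a variant is high-quality only if every statistic lies inside
#'   its closed interval `[lo, hi]` (use `-Inf`/`Inf` for one-sided bounds);
#' * `bad` — a variant is low-quality if any statistic falls at or outside
#'   an interval, i.e. `stat <= lo` or `stat >= hi`.
#'
#' Good bounds must be strictly stricter than bad bounds on every shared
#' statistic, so the HIGH/LOW/UNDETERMINED classes are disjoint. An `NA`
#' statistic can never trigger a bad bound; `naTolerance` is the number of
#' `NA` statistics among good-bound statistics a variant may carry and still
#' be called high-quality. Entries named after extra columns in the
#' statistics table act as user-defined filters.
#'
#' @aliases FilterConfig-class
#' @exportClass FilterConfig
setClass("FilterConfig",
         representation(good = "list", bad = "list", naTolerance = "integer"))

setValidity("FilterConfig", function(object) {
  chk <- function(b) all(vapply(b, function(x)
    is.numeric(x) && length(x) == 2 && !any(is.na(x)) && x[1] <= x[2],
    logical(1)))
  if (!chk(object@good) || !chk(object@bad))
    return("every bound must be a numeric c(lo, hi) with lo <= hi")
  shared <- intersect(names(object@good), names(object@bad))
  for (s in shared) {
    g <- object@good[[s]]; b <- object@bad[[s]]
    loOk <- b[1] < g[1] || (b[1] == -Inf && g[1] == -Inf)
    hiOk <- g[2] < b[2] || (b[2] == Inf && g[2] == Inf)
    if (!loOk || !hiOk)
      return(sprintf(
        "good bound for '%s' must be strictly inside the bad bound", s))
  }
  if (object@naTolerance < 0) return("naTolerance must be >= 0")
  TRUE
})

#' Build a FilterConfig
#'
#' Defaults are stringent GWAS-style thresholds: high-quality requires
#' missing rate <= 0.01, Mendelian error rate <= 0.01, HWE p >= 1e-2 and
#' ABHet in \[0.45, 0.55\]; low-quality is triggered by missing rate >= 0.05,
#' Mendelian error rate >= 0.05, HWE p <= 1e-6 or ABHet at or outside
#' \[0.25, 0.75\]. Override any entry, or add entries for user-supplied
#' statistics columns.
#'
#' @param good,bad named lists of numeric `c(lo, hi)` bounds; entries given
#'   here replace the defaults entry-wise. Set an entry to `NULL` to drop it.
#' @param naTolerance integer; how many `NA` statistics among good-bound
#'   statistics a high-quality variant may carry (default 0).
#' @return a validated [FilterConfig-class].
#' @examples
#' cfg <- filterConfig(good = list(missing_rate = c(-Inf, 0.02)))
#' @export
filterConfig <- function(good = list(), bad = list(), naTolerance = 0L) {
  dgood <- list(missing_rate = c(-Inf, 0.01),
                mendel_error_rate = c(-Inf, 0.01),
                hwe_p = c(1e-2, Inf),
                abhet = c(0.45, 0.55))
  dbad <- list(missing_rate = c(-Inf, 0.05),
               mendel_error_rate = c(-Inf, 0.05),
               hwe_p = c(1e-6, Inf),
               abhet = c(0.25, 0.75))
  merge <- function(d, user) {
    for (nm in names(user)) d[nm] <- list(user[[nm]])
    d[!vapply(d, is.null, logical(1))]
  }
  new("FilterConfig", good = merge(dgood, good), bad = merge(dbad, bad),
      naTolerance = as.integer(naTolerance))
}

setMethod("show", "FilterConfig", function(object) {
  fmt <- function(b) paste(vapply(names(b), function(n)
    sprintf("%s in [%g, %g]", n, b[[n]][1], b[[n]][2]), ""), collapse = "; ")
  cat("FilterConfig\n  good (all required):", fmt(object@good),
      "\n  bad (any triggers, at/outside):", fmt(object@bad),
      "\n  NA tolerance:", object@naTolerance, "\n")
})

# ---------------------------------------------------------------------------
# TrainingSet and QcModel
# ---------------------------------------------------------------------------

#' Balanced classifier training set
#'
#' Feature matrix in the canonical seven-feature order with equal HIGH and
#' LOW class counts (the majority class is downsampled to the minority
#' size), `NA` cells median-imputed and flagged.
#'
#' @aliases TrainingSet-class
#' @exportClass TrainingSet
setClass("TrainingSet",
         representation(features = "matrix", labels = "factor",
                        ids = "character", seed = "integer",
                        medians = "numeric", imputed = "logical"))

setValidity("TrainingSet", function(object) {
  if (nrow(object@features) != length(object@labels))
    return("feature rows and labels differ in length")
  tab <- table(object@labels)
  if (length(tab) == 2 && tab[1] != tab[2])
    return("training classes are not balanced")
  if (anyNA(object@features))
    return("feature matrix must not contain NA")
  TRUE
})

setMethod("show", "TrainingSet", function(object) {
  tab <- table(object@labels)
  cat(sprintf("TrainingSet: %d rows (%s), %d features, seed %d\n",
              nrow(object@features),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              ncol(object@features), object@seed))
})

#' Fitted variant-quality classifier
#'
#' A random forest over the seven sequencing-quality features together with
#' everything needed to reproduce its predictions: feature order, the
#' training-set feature medians used for imputation, normalized feature
#' importances, the probability threshold and the training seed.
#'
#' @aliases QcModel-class
#' @exportClass QcModel
setClass("QcModel",
         representation(forest = "ANY", nTrees = "integer",
                        probabilityThreshold = "numeric",
                        featureOrder = "character",
                        featureImportances = "numeric",
                        trainingSeed = "integer",
                        featureMedians = "numeric",
                        version = "character"))

setValidity("QcModel", function(object) {
  imp <- object@featureImportances
  if (any(imp < 0)) return("importances must be >= 0")
  if (abs(sum(imp) - 1) > 1e-9) return("importances must sum to 1")
  if (!identical(names(imp), object@featureOrder))
    return("importances must be named in feature order")
  if (object@probabilityThreshold < 0 || object@probabilityThreshold > 1)
    return("probability threshold must be in [0, 1]")
  TRUE
})

setMethod("show", "QcModel", function(object) {
  cat(sprintf(
    "QcModel: %d trees, probability threshold %.2f, seed %d\n",
    object@nTrees, object@probabilityThreshold, object@trainingSeed))
  imp <- sort(object@featureImportances, decreasing = TRUE)
  cat("  importance:", paste(sprintf("%s=%.3f", names(imp), imp),
                             collapse = " "), "\n")
})
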