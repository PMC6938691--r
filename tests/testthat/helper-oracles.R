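# Independent oracles and in-code fixtures shared across the test files.

## --- HWE exact-test oracle -------------------------------------------------
## Direct enumeration of the conditional null distribution of the
## heterozygote count via the closed form
##   P(nAB | nA, n) = n! / (nAA! nAB! nBB!) * 2^nAB * nA! * nB! / (2n)!
## evaluated in log-factorials; the p-value sums the probabilities of every
## heterozygote count at most as probable (up to a 1e-7 relative tie
## tolerance) as the observed one. Independent of the package's recurrence.
hweOracle <- function(homRef, het, homAlt) {
  n <- homRef + het + homAlt
  if (n == 0) return(NA_real_)
  nA <- 2 * homRef + het
  nB <- 2 * homAlt + het
  minor <- min(nA, nB)
  hets <- seq.int(minor %% 2, minor, by = 2)
  logP <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (nB - h) / 2
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logP - max(logP))
  p <- p / sum(p)
  pObs <- p[match(het, hets)]
  min(1, sum(p[p <= pObs * (1 + 1e-7)]))
}

## --- Mendelian-consistency oracle ------------------------------------------
## Brute force: a child genotype is consistent iff some choice of one allele
## from the father and one from the mother reproduces it (unordered).
mendelConsistentOracle <- function(father, mother, child) {
  for (fa in father) for (mo in mother) {
    if ((fa == child[1] && mo == child[2]) ||
        (fa == child[2] && mo == child[1])) return(TRUE)
  }
  FALSE
}

## --- tiny in-code VariantCallSet builders ----------------------------------

## One-site call set from explicit per-sample genotypes given as
## c(a1, a2) pairs; NA for missing.
makeSiteVcs <- function(genos, chrom = "1", pos = 100L, ref = "A",
                        alt = "G", dp = NULL, gq = NULL,
                        adRef = NULL, adTot = NULL, samples = NULL) {
  ns <- length(genos)
  g1 <- matrix(vapply(genos, function(g) as.integer(g)[1], integer(1)), 1)
  g2 <- matrix(vapply(genos, function(g) as.integer(g)[2], integer(1)), 1)
  toM <- function(v) if (is.null(v)) NULL else matrix(as.integer(v), 1)
  VariantCallSet(chrom = chrom, pos = pos, ref = ref, alt = list(alt),
                 gt1 = g1, gt2 = g2, dp = toM(dp), gq = toM(gq),
                 adRef = toM(adRef), adTotal = toM(adTot),
                 samples = samples %||% sprintf("s%d", seq_len(ns)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Multi-site SNV set from ref/alt vectors with trivial genotypes, for
## Ti/Tv-style tests.
makeSnvSet <- function(ref, alt, chrom = "1", gt1 = NULL, gt2 = NULL,
                       samples = c("s1", "s2")) {
  n <- length(ref)
  ns <- length(samples)
  VariantCallSet(chrom = rep(chrom, length.out = n), pos = seq_len(n) * 10L,
                 ref = ref, alt = lapply(alt, identity),
                 gt1 = gt1 %||% matrix(0L, n, ns),
                 gt2 = gt2 %||% matrix(1L, n, ns),
                 dp = matrix(30L, n, ns), gq = matrix(99L, n, ns),
                 samples = samples)
}

## A small deterministic trio pedigree.
makeTrioPed <- function(nFam = 1L) {
  ids <- as.vector(vapply(seq_len(nFam), function(f)
    sprintf(c("dad%02d", "mom%02d", "kid%02d"), f), character(3)))
  Pedigree(id = ids,
           father = as.vector(rbind(NA, NA, ids[seq(1, by = 3,
                                                    length.out = nFam)])),
           mother = as.vector(rbind(NA, NA, ids[seq(2, by = 3,
                                                    length.out = nFam)])),
           sex = rep(c("MALE", "FEMALE", "MALE"), nFam))
}

## Plain-text VCF fixture written to a temp file; returns the path.
writeToyVcf <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1,length=10000>",
    "##contig=<ID=2,length=10000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    "1\t100\t.\tA\tG\t50\tPASS\t.\tGT:DP:GQ:AD\t0/1:30:99:15,15\t0/0:28:95:28,0",
    "1\t200\t.\tA\tG,T\t50\tPASS\t.\tGT:DP:GQ:AD\t1/2:20:80:0,10,10\t./.:.:.:.",
    "1\t300\trs1\tC\tT\t50\tPASS\t.\tGT:DP:GQ\t0/1:10:50\t1/1:12:60",
    "2\t150\t.\tT\tTA\t50\tPASS\t.\tGT:GQ:AD\t0/1:90:12,14\t0/0:85:20,0",
    "1\t400\t.\tA\tC\t50\tPASS\t.\tGT:DP:GQ\t./1:9:10\t0/0:22:70"),
    path)
  path
}

## Balanced TrainingSet with a planted signal in selected features.
## signalFeatures get mean shift `shift` between classes; others are noise.
makeTrainingSet <- function(n = 200L, signalFeatures = "mean_gq",
                            shift = 5, seed = 42L, sd = 1) {
  feats <- c("mean_dp", "sd_dp", "outlier_dp", "mean_gq", "sd_gq",
             "outlier_gq", "gc")
  withr::with_seed(seed, {
    y <- factor(rep(c("HIGH", "LOW"), each = n / 2),
                levels = c("LOW", "HIGH"))
    x <- matrix(rnorm(n * length(feats), sd = sd), n,
                dimnames = list(NULL, feats))
    for (f in signalFeatures)
      x[y == "HIGH", f] <- x[y == "HIGH", f] + shift
    new("TrainingSet", features = x, labels = y,
        ids = sprintf("v%04d", seq_len(n)), seed = as.integer(seed),
        medians = apply(x, 2, median), imputed = rep(FALSE, n))
  })
}

## Small, fast simulation shared by several files (built once per session).
.simCache <- new.env(parent = emptyenv())
smallStudy <- function() {
  if (is.null(.simCache$small)) {
    dir <- file.path(tempdir(), "vf-small-study")
    cfg <- simulationConfig(nVariants = 2500L, nFamilies = 12L,
                            chromLength = 250000L, seed = 101L)
    .simCache$small <- list(cfg = cfg, paths = simulateStudy(cfg, dir))
  }
  .simCache$small
}
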