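# Synthetic cohort generator: a toy diploid reference with a GC gradient,
# trio-structured families, founder genotypes drawn at Hardy-Weinberg
# equilibrium, Mendelian transmission to children, and planted "good" vs
# "bad" variants whose correlated error signals (Mendel errors, chip
# discordance, ABHet skew, missingness, low/dispersed DP and GQ) all arise
# from one mechanism: post-transmission allele flips plus per-class
# DP/GQ/AD sampling distributions.

#' Simulation configuration
#'
#' Parameters of the synthetic study. The defaults describe a separable
#' family-based design: 20 trio families (60 samples), 20,000 variants of
#' which 10% are planted low-quality, two 600-kb autosomes with a GC
#' gradient, deep well-balanced sequencing for good variants and shallow,
#' noisy, error-injected sequencing for bad ones.
#'
#' Profiles are lists with elements `gq_mean`, `gq_sd`, `dp_mean`,
#' `missing_rate`, `error_rate` (post-transmission allele-flip probability
#' per genotype) and `ab` (reference-read fraction of heterozygous AD
#' draws; 0.5 is balanced).
#'
#' @param nFamilies number of trio families.
#' @param nVariants total variant sites.
#' @param fractionBad fraction of sites planted as low-quality, in (0, 1).
#' @param fractionIndel fraction of sites simulated as 1-bp indels.
#' @param fractionMultiAllelic fraction of SNV sites given a second
#'   alternate allele.
#' @param goodProfile,badProfile per-class distribution parameters (see
#'   Details).
#' @param chroms,chromLength chromosome names and common length (bp).
#' @param windowSize GC window size in bp.
#' @param gcRange GC fraction at the first and last window of each
#'   chromosome (linear gradient).
#' @param knownProb probability that a good / bad variant is listed in the
#'   known-sites resource.
#' @param chipFraction fraction of common (allele frequency >= 0.1)
#'   biallelic good+bad SNVs put on the microarray.
#' @param seed integer master seed; identical config + seed reproduce
#'   identical files.
#' @return a named list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nFamilies = 20L,
                             nVariants = 20000L,
                             fractionBad = 0.10,
                             fractionIndel = 0.10,
                             fractionMultiAllelic = 0.005,
                             goodProfile = list(gq_mean = 90, gq_sd = 8,
                                                dp_mean = 35,
                                                missing_rate = 0.002,
                                                error_rate = 0, ab = 0.5),
                             badProfile = list(gq_mean = 30, gq_sd = 20,
                                               dp_mean = 12,
                                               missing_rate = 0.08,
                                               error_rate = 0.3, ab = 0.8),
                             chroms = c("1", "2"),
                             chromLength = 600000L,
                             windowSize = 1000L,
                             gcRange = c(0.3, 0.7),
                             knownProb = c(good = 0.85, bad = 0.3),
                             chipFraction = 0.3,
                             seed = 1L) {
  stopifnot(fractionBad > 0, fractionBad < 1,
            chromLength >= windowSize, nFamilies >= 1, nVariants >= 1)
  cfg <- list(nFamilies = as.integer(nFamilies),
              nVariants = as.integer(nVariants),
              fractionBad = fractionBad, fractionIndel = fractionIndel,
              fractionMultiAllelic = fractionMultiAllelic,
              goodProfile = goodProfile, badProfile = badProfile,
              chroms = chroms, chromLength = as.integer(chromLength),
              windowSize = as.integer(windowSize), gcRange = gcRange,
              knownProb = knownProb, chipFraction = chipFraction,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate the toy reference genome
#'
#' Random A/C/G/T sequence whose per-window GC probability follows a linear
#' gradient across each chromosome, so window GC content has dynamic range.
#' Deterministic given the config seed.
#'
#' @param cfg a [simulationConfig()].
#' @param path optional FASTA output path; when `NULL` nothing is written.
#' @return a [Biostrings::DNAStringSet] (invisibly written to `path`).
#' @export
simulateReference <- function(cfg, path = NULL) {
  seqs <- withr::with_seed(cfg$seed, {
    lapply(seq_along(cfg$chroms), function(i) {
      L <- cfg$chromLength
      nWin <- ceiling(L / cfg$windowSize)
      gcw <- seq(cfg$gcRange[1], cfg$gcRange[2], length.out = nWin)
      gcVec <- rep(gcw, each = cfg$windowSize)[seq_len(L)]
      isGC <- runif(L) < gcVec
      second <- runif(L) < 0.5
      base <- ifelse(isGC, ifelse(second, "G", "C"),
                     ifelse(second, "A", "T"))
      paste(base, collapse = "")
    })
  })
  dna <- Biostrings::DNAStringSet(unlist(seqs))
  names(dna) <- cfg$chroms
  if (!is.null(path)) Biostrings::writeXStringSet(dna, path)
  invisible(dna)
}

.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.BASES <- c("A", "C", "G", "T")

#' Simulate a trio cohort with planted good and bad variants
#'
#' Founder genotypes are drawn at Hardy-Weinberg equilibrium given a
#' per-variant allele frequency; each child inherits one allele from each
#' parent. Bad variants then receive post-transmission allele flips (which
#' create Mendelian errors and chip discordance), inflated missingness,
#' skewed heterozygote AD (binomial with the bad-profile balance at the
#' sample's depth) and low, dispersed GQ and DP. Good variants get the
#' converse. Alternate alleles of good SNVs are transitions two thirds of
#' the time (the genome-wide Ti/Tv expectation of ~2); bad alt alleles are
#' uniform over the three non-reference bases.
#'
#' @param cfg a [simulationConfig()].
#' @param reference a [Biostrings::DNAStringSet] from [simulateReference()].
#' @param dir output directory (created if needed).
#' @return named list of file paths: `vcf`, `ped`, `chip`, `known`,
#'   `truth`.
#' @export
simulateCohort <- function(cfg, reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nFam <- cfg$nFamilies
  samples <- as.vector(vapply(seq_len(nFam), function(f)
    sprintf(c("dad%02d", "mom%02d", "kid%02d"), f), character(3)))
  dadCol <- seq(1L, by = 3L, length.out = nFam)
  momCol <- dadCol + 1L
  kidCol <- dadCol + 2L
  founderCol <- sort(c(dadCol, momCol))
  nS <- length(samples)
  nV <- cfg$nVariants

  sim <- withr::with_seed(cfg$seed + 1L, {
    ## -- site definitions ------------------------------------------------
    chromIdx <- sort(sample.int(length(cfg$chroms), nV, replace = TRUE))
    chrom <- cfg$chroms[chromIdx]
    pos <- integer(nV)
    for (ci in seq_along(cfg$chroms)) {
      sel <- chromIdx == ci
      pos[sel] <- sort(sample(seq(2L, cfg$chromLength - 1L), sum(sel)))
    }
    isBad <- runif(nV) < cfg$fractionBad
    isIndel <- runif(nV) < cfg$fractionIndel
    seqStrings <- as.character(reference)
    refBase <- vapply(seq_len(nV), function(i)
      substr(seqStrings[[chromIdx[i]]], pos[i], pos[i]), character(1))

    alt1 <- character(nV); ref <- refBase
    ## SNV alternates: good transition-biased (2:1), bad uniform over the
    ## three non-reference bases
    snvRows <- which(!isIndel)
    uTi <- runif(nV)
    for (i in snvRows) {
      ti <- .TRANSITION[[refBase[i]]]
      alt1[i] <- if (!isBad[i]) {
        if (uTi[i] < 2 / 3) ti
        else sample(setdiff(.BASES, c(refBase[i], ti)), 1)
      } else sample(setdiff(.BASES, refBase[i]), 1)
    }
    ## indels: half 1-bp insertions, half 1-bp deletions
    indelRows <- which(isIndel)
    ins <- runif(length(indelRows)) < 0.5
    for (k in seq_along(indelRows)) {
      i <- indelRows[k]
      if (ins[k]) {
        alt1[i] <- paste0(refBase[i], sample(.BASES, 1))
      } else {
        nxt <- substr(seqStrings[[chromIdx[i]]], pos[i] + 1L, pos[i] + 1L)
        ref[i] <- paste0(refBase[i], nxt)
        alt1[i] <- refBase[i]
      }
    }
    ## second alternate allele for a small fraction of SNVs
    isMulti <- !isIndel & runif(nV) < cfg$fractionMultiAllelic
    alt2 <- rep(NA_character_, nV)
    for (i in which(isMulti))
      alt2[i] <- sample(setdiff(.BASES, c(refBase[i], alt1[i])), 1)
    nAlt <- 1L + !is.na(alt2)

    ## -- genotypes -------------------------------------------------------
    af1 <- runif(nV, 0.02, 0.5)
    af2 <- ifelse(isMulti, af1 * 0.2, 0)
    drawAllele <- function() {
      u <- matrix(runif(nV * length(founderCol)), nV)
      (u < af1) + (u >= af1 & u < af1 + af2) * 2L
    }
    G1 <- G2 <- matrix(0L, nV, nS)
    G1[, founderCol] <- drawAllele()
    G2[, founderCol] <- drawAllele()
    ## force polymorphism: a monomorphic draw gets one het founder
    mono <- rowSums(G1[, founderCol]) + rowSums(G2[, founderCol]) == 0L
    G2[mono, dadCol[1]] <- 1L
    ## transmission: one allele from each parent
    fromDadFirst <- matrix(runif(nV * nFam) < 0.5, nV)
    fromMomFirst <- matrix(runif(nV * nFam) < 0.5, nV)
    G1[, kidCol] <- ifelse(fromDadFirst, G1[, dadCol], G2[, dadCol])
    G2[, kidCol] <- ifelse(fromMomFirst, G1[, momCol], G2[, momCol])
    T1 <- G1; T2 <- G2   # truth (pre-error) genotypes

    prof <- function(field) ifelse(isBad, cfg$badProfile[[field]],
                                   cfg$goodProfile[[field]])
    ## post-transmission allele flips on bad variants
    errMask <- matrix(runif(nV * nS), nV) < prof("error_rate")
    if (any(errMask)) {
      flipFirst <- matrix(runif(nV * nS) < 0.5, nV)
      delta <- matrix(1L + floor(runif(nV * nS) *
                                 rep(nAlt, nS)), nV)
      m1 <- errMask & flipFirst
      m2 <- errMask & !flipFirst
      nAlleles <- matrix(rep(nAlt + 1L, nS), nV)
      G1[m1] <- (G1[m1] + delta[m1]) %% nAlleles[m1]
      G2[m2] <- (G2[m2] + delta[m2]) %% nAlleles[m2]
    }

    ## -- per-sample quality values --------------------------------------
    dpMean <- prof("dp_mean")
    dp <- matrix(0L, nV, nS)
    goodRow <- !isBad
    dp[goodRow, ] <- rpois(sum(goodRow) * nS, dpMean[goodRow])
    dp[isBad, ] <- rnbinom(sum(isBad) * nS, mu = dpMean[isBad], size = 2)
    gq <- matrix(pmin(99L, pmax(0L, round(rnorm(nV * nS,
                                                mean = prof("gq_mean"),
                                                sd = prof("gq_sd"))))),
                 nV)
    storage.mode(gq) <- "integer"

    ## -- allelic depths --------------------------------------------------
    bal <- matrix(prof("ab"), nV, nS)
    adRef <- adA1 <- adA2 <- matrix(0L, nV, nS)
    homRef <- G1 == 0L & G2 == 0L
    hetRef1 <- xor(G1 == 1L, G2 == 1L) & (G1 == 0L | G2 == 0L)
    hetRef2 <- xor(G1 == 2L, G2 == 2L) & (G1 == 0L | G2 == 0L)
    hom1 <- G1 == 1L & G2 == 1L
    hom2 <- G1 == 2L & G2 == 2L
    het12 <- (G1 == 1L & G2 == 2L) | (G1 == 2L & G2 == 1L)
    adRef[homRef] <- dp[homRef]
    adRef[hetRef1] <- rbinom(sum(hetRef1), dp[hetRef1], bal[hetRef1])
    adA1[hetRef1] <- dp[hetRef1] - adRef[hetRef1]
    adRef[hetRef2] <- rbinom(sum(hetRef2), dp[hetRef2], bal[hetRef2])
    adA2[hetRef2] <- dp[hetRef2] - adRef[hetRef2]
    adA1[hom1] <- dp[hom1]
    adA2[hom2] <- dp[hom2]
    adA1[het12] <- rbinom(sum(het12), dp[het12], 0.5)
    adA2[het12] <- dp[het12] - adA1[het12]

    missMask <- matrix(runif(nV * nS), nV) < prof("missing_rate")

    ## -- microarray extract (truth genotypes, pre-error) -----------------
    common <- which(!isIndel & !isMulti & af1 >= 0.1)
    chipRows <- sort(sample(common, floor(cfg$chipFraction * length(common))))
    chipMiss <- matrix(runif(length(chipRows) * nS) < 0.01,
                       length(chipRows))

    ## -- known-sites membership ------------------------------------------
    isKnown <- runif(nV) < ifelse(isBad, cfg$knownProb[["bad"]],
                                  cfg$knownProb[["good"]])
    list(chrom = chrom, pos = pos, ref = ref, alt1 = alt1, alt2 = alt2,
         nAlt = nAlt, isBad = isBad, isIndel = isIndel, isMulti = isMulti,
         G1 = G1, G2 = G2, T1 = T1, T2 = T2, dp = dp, gq = gq,
         adRef = adRef, adA1 = adA1, adA2 = adA2, missMask = missMask,
         chipRows = chipRows, chipMiss = chipMiss, isKnown = isKnown)
  })

  ## -- write VCF ----------------------------------------------------------
  altStr <- ifelse(is.na(sim$alt2), sim$alt1,
                   paste0(sim$alt1, ",", sim$alt2))
  gtStr <- matrix(paste0(sim$G1, "/", sim$G2), nV)
  adStr <- matrix(paste0(sim$adRef, ",", sim$adA1), nV)
  multiMat <- matrix(sim$nAlt > 1L, nV, nS)
  adStr[multiMat] <- paste0(adStr[multiMat],
                            ",", sim$adA2[multiMat])
  field <- matrix(paste0(gtStr, ":", sim$dp, ":", sim$gq, ":", adStr), nV)
  field[sim$missMask] <- "./.:.:.:."
  hdr <- c("##fileformat=VCFv4.2",
           "##source=VariantForestSimulator",
           sprintf("##contig=<ID=%s,length=%d>", cfg$chroms,
                   cfg$chromLength),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  lines <- do.call(paste, c(
    list(sim$chrom, sim$pos, ".", sim$ref, altStr, "50", "PASS", ".",
         "GT:DP:GQ:AD"),
    as.data.frame(field, stringsAsFactors = FALSE), list(sep = "\t")))
  vcfPath <- file.path(dir, "cohort.vcf")
  writeLines(c(hdr, lines), vcfPath)

  ## -- pedigree -----------------------------------------------------------
  pedPath <- file.path(dir, "cohort.ped")
  fam <- sprintf("F%02d", rep(seq_len(nFam), each = 3))
  father <- as.vector(rbind("0", "0", samples[dadCol]))
  mother <- as.vector(rbind("0", "0", samples[momCol]))
  sex <- rep(c("1", "2", "1"), nFam)
  write.table(data.frame(fam, samples, father, mother, sex, "0"),
              pedPath, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)

  ## -- truth labels -------------------------------------------------------
  truthPath <- file.path(dir, "truth.tsv")
  write.table(data.frame(chrom = sim$chrom, pos = sim$pos, ref = sim$ref,
                         alt = altStr,
                         class = ifelse(sim$isBad, "bad", "good")),
              truthPath, sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- known sites --------------------------------------------------------
  knownPath <- file.path(dir, "known.tsv")
  kr <- which(sim$isKnown)
  krep <- rep(kr, sim$nAlt[kr])
  altFlat <- ifelse(duplicated(krep), sim$alt2[krep], sim$alt1[krep])
  write.table(data.frame(sim$chrom[krep], sim$pos[krep], ".",
                         sim$ref[krep], altFlat),
              knownPath, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)

  ## -- microarray extract (sorted base-pair calls from truth genotypes) ---
  chipPath <- file.path(dir, "chip.tsv")
  cr <- sim$chipRows
  chipCalls <- matrix(NA_character_, length(cr), nS)
  if (length(cr)) {
    for (k in seq_along(cr)) {
      i <- cr[k]
      alleles <- c(sim$ref[i], sim$alt1[i])
      a1 <- alleles[sim$T1[i, ] + 1L]
      a2 <- alleles[sim$T2[i, ] + 1L]
      chipCalls[k, ] <- paste0(pmin(a1, a2), pmax(a1, a2))
    }
    chipCalls[sim$chipMiss] <- "NN"
  }
  chipTab <- data.frame(chrom = sim$chrom[cr], pos = sim$pos[cr],
                        ref = sim$ref[cr], alt = sim$alt1[cr],
                        chipCalls, stringsAsFactors = FALSE)
  colnames(chipTab) <- c("chrom", "pos", "ref", "alt", samples)
  write.table(chipTab, chipPath, sep = "\t", quote = FALSE,
              row.names = FALSE)

  list(vcf = vcfPath, ped = pedPath, chip = chipPath, known = knownPath,
       truth = truthPath)
}

#' Simulate reference plus cohort in one call
#'
#' Convenience wrapper: writes the FASTA and all cohort files into `dir`.
#'
#' @param cfg a [simulationConfig()].
#' @param dir output directory.
#' @return named list of paths (`fasta` plus everything from
#'   [simulateCohort()]).
#' @export
simulateStudy <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fastaPath <- file.path(dir, "reference.fa")
  ref <- simulateReference(cfg, fastaPath)
  c(list(fasta = fastaPath), simulateCohort(cfg, ref, dir))
}
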