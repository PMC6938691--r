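test_that("Ti/Tv counts transitions and transversions per alternate allele", {
  ## {A->G, C->T, A->C}: two transitions, one transversion
  vcs <- makeSnvSet(ref = c("A", "C", "A"), alt = list("G", "T", "C"))
  expect_equal(titvRatio(vcs), 2)
  ## only transitions: zero denominator
  expect_true(is.na(titvRatio(makeSnvSet(ref = c("A", "G"),
                                         alt = list("G", "A")))))
  ## 4 transitions, 2 transversions -> the expected genome-wide 2.0
  vcs2 <- makeSnvSet(ref = c("A", "G", "C", "T", "A", "C"),
                     alt = list("G", "A", "T", "C", "T", "G"))
  expect_equal(titvRatio(vcs2), 2)
  ## each alt of a multi-allelic SNV counts once: A->G,T is 1 Ti + 1 Tv
  multi <- makeSnvSet(ref = "A", alt = list(c("G", "T")))
  expect_equal(titvRatio(multi), 1)
  ## indels are a contract violation
  indel <- makeSnvSet(ref = "AT", alt = list("A"))
  expect_error(titvRatio(indel), "SNVs only")
})

test_that("mitochondrial sites are excluded from Ti/Tv by default", {
  vcs <- makeSnvSet(ref = c("A", "A", "A"), alt = list("G", "C", "C"),
                    chrom = c("1", "MT", "MT"))
  expect_true(is.na(titvRatio(vcs)))           # only the A->G site remains
  expect_equal(titvRatio(vcs, excludeMito = FALSE), 0.5)
})

test_that("sample-level Ti/Tv is computed over carried alternate alleles", {
  ## s1 carries the transition only, s2 carries both
  vcs <- makeSnvSet(ref = c("A", "A"), alt = list("G", "C"),
                    gt1 = matrix(c(0L, 0L, 0L, 0L), 2),
                    gt2 = matrix(c(1L, 0L, 1L, 1L), 2),
                    samples = c("s1", "s2"))
  ps <- titvRatio(vcs, perSample = TRUE)
  expect_true(is.na(ps[["s1"]]))               # 1 Ti, 0 Tv
  expect_equal(ps[["s2"]], 1)                  # 1 Ti, 1 Tv
})

test_that("substitution classes are preserved under a class-preserving relabeling", {
  ## swapping A<->G everywhere maps transitions to transitions
  ref <- c("A", "G", "C", "A"); alt <- list("G", "A", "A", "T")
  swap <- function(x) chartr("AG", "GA", x)
  a <- titvRatio(makeSnvSet(ref, alt))
  b <- titvRatio(makeSnvSet(swap(ref), lapply(alt, swap)))
  expect_equal(a, b)
})

test_that("genotype discordance compares unordered pairs on shared samples", {
  chip <- MicroarrayGenotypes(chrom = "1", pos = 100L, ref = "A", alt = "G",
                              calls = matrix(c("AG", "AA", "AG"), 1,
                                             dimnames = list(NULL,
                                                             c("s1", "s2", "s3"))))
  same <- makeSiteVcs(list(c(0L, 1L), c(0L, 0L)), samples = c("s1", "s2"))
  expect_equal(genotypeDiscordance(same, chip), 0)

  diff1 <- makeSiteVcs(list(c(1L, 1L)), samples = "s1")
  expect_equal(genotypeDiscordance(diff1, chip), 1)

  mixed <- makeSiteVcs(list(c(0L, 1L), c(NA, NA), c(1L, 1L)),
                       samples = c("s1", "s2", "s3"))
  expect_equal(genotypeDiscordance(mixed, chip), 0.5)  # s2 not comparable

  ## allele definitions must agree
  flipped <- makeSiteVcs(list(c(0L, 1L)), ref = "C", alt = "T",
                         samples = "s1")
  expect_warning(res <- genotypeDiscordance(flipped, chip), "disagree")
  expect_true(is.na(res))

  ## site absent from the chip
  off <- makeSiteVcs(list(c(0L, 1L)), pos = 999L, samples = "s1")
  expect_true(is.na(genotypeDiscordance(off, chip)))
})

test_that("a dataset is never discordant with itself", {
  st <- smallStudy()
  vcs <- readVariantCallSet(st$paths$vcf)
  snv <- vcs[variantType(vcs) == "snv" & lengths(altAlleles(vcs)) == 1L, ]
  snv <- snv[1:100, ]
  alleles <- cbind(refAllele(snv),
                   vapply(altAlleles(snv), `[`, "", 1))
  g1 <- SummarizedExperiment::assay(snv, "gt1")
  g2 <- SummarizedExperiment::assay(snv, "gt2")
  a1 <- matrix(alleles[cbind(rep(seq_len(nrow(snv)), ncol(snv)),
                             as.vector(g1) + 1L)], nrow(snv))
  a2 <- matrix(alleles[cbind(rep(seq_len(nrow(snv)), ncol(snv)),
                             as.vector(g2) + 1L)], nrow(snv))
  calls <- matrix(paste0(pmin(a1, a2), pmax(a1, a2)), nrow(snv),
                  dimnames = list(NULL, colnames(snv)))
  calls[is.na(a1) | is.na(a2)] <- NA
  chip <- MicroarrayGenotypes(variantChrom(snv), variantPos(snv),
                              refAllele(snv), alleles[, 2], calls)
  d <- genotypeDiscordance(snv, chip)
  expect_true(all(d[!is.na(d)] == 0))
})

test_that("known/novel splitting is exact with set semantics", {
  vcs <- makeSnvSet(ref = rep("A", 10), alt = as.list(rep("G", 10)))
  ks <- KnownSites(chrom = rep("1", 9), pos = c(seq(10L, 80L, 10L), 10L),
                   ref = rep("A", 9), alt = rep("G", 9))  # one duplicate
  sp <- knownNovelSplit(vcs, ks)
  expect_equal(sp$known, 8L)
  expect_equal(sp$novel, 2L)
  expect_equal(sp$knownPct, 80)

  empty <- KnownSites(character(), integer(), character(), character())
  sp0 <- knownNovelSplit(vcs, empty)
  expect_equal(sp0$known, 0L)
  expect_equal(sp0$knownPct, 0)

  ## positional fallback is flagged
  posOnly <- KnownSites(chrom = "1", pos = 10L)
  expect_warning(spPos <- knownNovelSplit(vcs, posOnly), "positional")
  expect_equal(spPos$mode, "position")
  expect_equal(spPos$known, 1L)
})

test_that("summary metrics: multi-allelic percent, graceful degradation, singletons", {
  alts <- c(rep(list("G"), 97), rep(list(c("G", "T")), 3))
  vcs <- makeSnvSet(ref = rep("A", 100), alt = alts)
  rep <- summarizeQc(vcs)
  expect_equal(rep$variant_level$multi_allelic_snvs_pct, 3)
  expect_equal(rep$variant_level$total_snvs, 100L)
  ## no pedigree / chip / known sites: affected metrics are NA
  expect_true(is.na(rep$variant_level$mean_mendel_error_rate))
  expect_true(is.na(rep$variant_level$mean_discordance))
  expect_equal(nrow(rep$sample_level), 2L)

  ## a unique carrier gets the singleton
  single <- makeSnvSet(ref = c("A", "A"), alt = list("G", "G"),
                       gt1 = matrix(0L, 2, 2),
                       gt2 = matrix(c(1L, 0L, 0L, 1L), 2),
                       samples = c("s1", "s2"))
  slv <- summarizeQc(single)$sample_level
  expect_equal(slv$singletons, c(1L, 1L))
  expect_equal(slv$total_snvs, c(1L, 1L))
})

test_that("variant-level counts are additive over any partition", {
  st <- smallStudy()
  vcs <- readVariantCallSet(st$paths$vcf)
  vcs <- vcs[1:400, ]
  ks <- readKnownSites(st$paths$known)
  withr::with_seed(77L, part <- runif(400) < 0.5)
  whole <- summarizeQc(vcs, known = ks)$variant_level
  a <- summarizeQc(vcs[part, ], known = ks)$variant_level
  b <- summarizeQc(vcs[!part, ], known = ks)$variant_level
  for (m in c("total_snvs", "total_indels", "known_snvs",
              "multi_allelic_snvs"))
    expect_equal(a[[m]] + b[[m]], whole[[m]], info = m)
})
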