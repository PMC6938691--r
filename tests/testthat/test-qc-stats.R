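test_that("missing rate counts missing alleles over 2n", {
  vcs <- makeSiteVcs(list(c(0L, 1L), c(0L, 0L), c(NA, NA), c(1L, 1L)))
  expect_equal(missingRate(vcs), 0.25)
  expect_equal(missingRate(makeSiteVcs(list(c(0L, 1L), c(1L, 1L)))), 0)
  expect_equal(missingRate(makeSiteVcs(list(c(NA, NA), c(NA, NA)))), 1)
})

test_that("Mendelian errors follow the one-allele-from-each-parent rule", {
  ped <- makeTrioPed()
  trioVcs <- function(f, m, c)
    makeSiteVcs(list(f, m, c), samples = c("dad01", "mom01", "kid01"))
  ## hom-ref parents cannot produce a het child
  expect_equal(mendelErrorRate(trioVcs(c(0L, 0L), c(0L, 0L), c(0L, 1L)), ped), 1)
  ## het x het permits every child genotype
  for (child in list(c(0L, 0L), c(0L, 1L), c(1L, 1L)))
    expect_equal(mendelErrorRate(trioVcs(c(0L, 1L), c(0L, 1L), child), ped), 0)
  ## missing member makes the trio non-evaluable
  expect_true(is.na(mendelErrorRate(trioVcs(c(0L, 0L), c(NA, NA), c(0L, 1L)),
                                    ped)))
})

test_that("all 27 ordered biallelic trio combinations match the brute-force oracle", {
  ped <- makeTrioPed()
  gts <- list(c(0L, 0L), c(0L, 1L), c(1L, 1L))
  consistent <- 0L
  for (f in gts) for (m in gts) for (c in gts) {
    vcs <- makeSiteVcs(list(f, m, c), samples = c("dad01", "mom01", "kid01"))
    got <- mendelErrorRate(vcs, ped)
    want <- as.numeric(!mendelConsistentOracle(f, m, c))
    expect_equal(got, want,
                 info = sprintf("F=%s M=%s C=%s", paste(f, collapse = "/"),
                                paste(m, collapse = "/"),
                                paste(c, collapse = "/")))
    consistent <- consistent + (want == 0)
  }
  expect_equal(consistent, 15L)  # hence 12 error combinations
})

test_that("multi-trio Mendelian error rates agree with the oracle and stay in [0,1]", {
  nFam <- 5L
  ped <- makeTrioPed(nFam)
  samples <- pedIds(ped)
  withr::with_seed(7L, {
    for (rep in 1:40) {
      genos <- lapply(seq_along(samples), function(i) {
        if (runif(1) < 0.1) c(NA_integer_, NA_integer_)
        else sort(sample(0:1, 2, replace = TRUE))
      })
      vcs <- makeSiteVcs(genos, samples = samples)
      got <- mendelErrorRate(vcs, ped)
      tr <- pedTrios(ped)
      res <- vapply(seq_len(nrow(tr)), function(k) {
        f <- genos[[match(tr$father[k], samples)]]
        m <- genos[[match(tr$mother[k], samples)]]
        c <- genos[[match(tr$child[k], samples)]]
        if (anyNA(c(f, m, c))) return(NA)
        !mendelConsistentOracle(f, m, c)
      }, logical(1))
      want <- if (all(is.na(res))) NA_real_ else mean(res, na.rm = TRUE)
      expect_equal(got, want)
      if (!is.na(got)) expect_lte(got, 1)
    }
  })
})

test_that("Mendelian error rate is NA off the autosomes and without a pedigree", {
  ped <- makeTrioPed()
  vcs <- makeSiteVcs(list(c(0L, 0L), c(0L, 0L), c(0L, 1L)),
                     chrom = "X", samples = c("dad01", "mom01", "kid01"))
  expect_true(is.na(mendelErrorRate(vcs, ped)))
  auto <- makeSiteVcs(list(c(0L, 0L), c(0L, 0L), c(0L, 1L)),
                      samples = c("dad01", "mom01", "kid01"))
  expect_true(is.na(mendelErrorRate(auto, NULL)))
  ## pedigree trio whose samples are absent from the VCF: warning, NA
  other <- makeSiteVcs(list(c(0L, 1L)), samples = "unrelated")
  expect_warning(res <- mendelErrorRate(other, ped), "absent")
  expect_true(is.na(res))
})

test_that("HWE exact test matches the spec's fixed points", {
  expect_equal(hweExactP(10, 0, 0), 1)    # monomorphic
  expect_equal(hweExactP(1, 1, 0), 1)     # single minor allele
  expect_equal(hweExactP(1, 3, 1), hweOracle(1, 3, 1), tolerance = 1e-12)
  expect_true(is.na(hweExactP(0, 0, 0)))
})

test_that("HWE exact test equals enumeration and is homref/homalt symmetric (n <= 8)", {
  for (n in 1:8) {
    for (aa in 0:n) for (ab in 0:(n - aa)) {
      bb <- n - aa - ab
      p <- hweExactP(aa, ab, bb)
      expect_equal(p, hweOracle(aa, ab, bb), tolerance = 1e-12,
                   info = sprintf("(%d,%d,%d)", aa, ab, bb))
      expect_identical(p, hweExactP(bb, ab, aa))
      expect_gt(p, 0)
      expect_lte(p, 1)
    }
  }
})

test_that("per-site HWE pools alternate alleles into one class", {
  ## genotypes 0/1, 1/2, 2/2, 0/0 -> pooled classes: het, homAlt, homAlt, homRef
  vcs <- VariantCallSet(chrom = "1", pos = 10L, ref = "A",
                        alt = list(c("G", "T")),
                        gt1 = matrix(c(0L, 1L, 2L, 0L), 1),
                        gt2 = matrix(c(1L, 2L, 2L, 0L), 1),
                        dp = matrix(20L, 1, 4), gq = matrix(99L, 1, 4))
  expect_equal(hweExactPBySite(vcs), hweExactP(1, 1, 2))
})

test_that("ABHet pools reads over ref/alt heterozygotes", {
  one <- makeSiteVcs(list(c(0L, 1L)), adRef = 5L, adTot = 10L)
  expect_equal(abHet(one), 0.5)
  two <- makeSiteVcs(list(c(0L, 1L), c(1L, 0L)),
                     adRef = c(7L, 3L), adTot = c(10L, 10L))
  expect_equal(abHet(two), 0.5)   # pooled, not averaged
  skew <- makeSiteVcs(list(c(0L, 1L), c(0L, 1L)),
                      adRef = c(9L, 5L), adTot = c(10L, 10L))
  expect_equal(abHet(skew), 0.7)  # exactly on the baseline boundary
})

test_that("ABHet ignores non-heterozygous samples and sample order", {
  base <- makeSiteVcs(list(c(0L, 1L), c(0L, 0L), c(1L, 1L), c(1L, 2L)),
                      alt = c("G", "T"),
                      adRef = c(6L, 99L, 0L, 3L), adTot = c(10L, 99L, 30L, 9L))
  ## only the first sample is a ref/alt het (1/2 het is excluded)
  expect_equal(abHet(base), 0.6)
  perm <- makeSiteVcs(list(c(1L, 2L), c(1L, 1L), c(0L, 1L), c(0L, 0L)),
                      alt = c("G", "T"),
                      adRef = c(3L, 0L, 6L, 99L), adTot = c(9L, 30L, 10L, 99L))
  expect_equal(abHet(perm), abHet(base))
  ## no qualifying het -> NA
  expect_true(is.na(abHet(makeSiteVcs(list(c(0L, 0L), c(1L, 1L)),
                                      adRef = c(9L, 0L), adTot = c(9L, 8L)))))
  ## het present but AD missing -> NA
  expect_true(is.na(abHet(makeSiteVcs(list(c(0L, 1L))))))
})

test_that("chromosome X ABHet uses females only when a pedigree is supplied", {
  ped <- makeTrioPed()   # mom01 is the only female
  vcs <- makeSiteVcs(list(c(0L, 1L), c(0L, 1L), c(0L, 1L)), chrom = "X",
                     adRef = c(9L, 5L, 9L), adTot = c(10L, 10L, 10L),
                     samples = c("dad01", "mom01", "kid01"))
  expect_equal(abHet(vcs, ped), 0.5)
  ## without a pedigree every sample is used
  expect_equal(abHet(vcs), 23 / 30)
})

test_that("minor allele frequency pools alternates and may pick the reference", {
  expect_equal(minorAlleleFreq(makeSiteVcs(list(c(0L, 0L), c(0L, 0L), c(0L, 1L)))),
               1 / 6, tolerance = 1e-12)
  expect_equal(minorAlleleFreq(makeSiteVcs(list(c(0L, 1L), c(0L, 1L)))), 0.5)
  expect_equal(minorAlleleFreq(makeSiteVcs(list(c(1L, 1L), c(1L, 1L), c(0L, 1L)))),
               1 / 6, tolerance = 1e-12)
  expect_true(is.na(minorAlleleFreq(makeSiteVcs(list(c(NA, NA))))))
})

test_that("the statistics table has one row per site with all columns", {
  vcs <- readVariantCallSet(writeToyVcf())
  st <- computeVariantStats(vcs)
  expect_equal(nrow(st), nVariants(vcs))
  expect_true(all(c("missing_rate", "mendel_error_rate", "hwe_p", "abhet",
                    "maf", "mean_dp", "sd_dp", "outlier_dp", "mean_gq",
                    "sd_gq", "outlier_gq", "gc") %in% colnames(st)))
  ## no thresholds/GC index supplied: those features are NA
  expect_true(all(is.na(st$outlier_dp)))
  expect_true(all(is.na(st$gc)))
})
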