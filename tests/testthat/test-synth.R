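# seeded generators: reference genes, allele suite, accession panels

test_that("makeReference builds valid complete ORFs deterministically", {
  ref <- makeReference(513, gc = 0.42, seed = 1)
  expect_equal(nchar(cds(ref)), 1542)
  prot <- translateCds(cds(ref))
  expect_equal(nchar(as.character(prot)), 513)
  expect_false(attr(prot, "no_stop"))
  # determinism
  expect_identical(cds(makeReference(513, gc = 0.42, seed = 1)), cds(ref))
  expect_false(identical(cds(makeReference(513, gc = 0.42, seed = 2)),
                         cds(ref)))
  expect_error(makeReference(10), "at least 50")
})

test_that("the allele suite lands every allele in its intended class", {
  fx <- getFixture()$fixture
  expectClass <- list(
    f3h = c("GmF3'H" = "identical",
            "gmf3'h-a1" = "frameshift_premature_stop",
            "gmf3'h-a2" = "in_frame_indel",
            "gmf3'h-b" = "frameshift_premature_stop"),
    f35h = c("GmF3'5'H-a" = "identical",
             "GmF3'5'H-b" = "missense",
             "gmf3'5'h" = "frameshift_premature_stop"))
  for (locus in names(expectClass)) {
    for (an in names(expectClass[[locus]])) {
      ef <- classifyEffect(fx[[locus]]$reference, fx[[locus]]$alleles[[an]])
      expect_identical(effectClass(ef), expectClass[[locus]][[an]],
                       info = an)
    }
  }
  # the two frameshift deletions share a downstream stop: 394 residues
  for (an in c("gmf3'h-a1", "gmf3'h-b"))
    expect_equal(proteinLength(classifyEffect(fx$f3h$reference,
                                              fx$f3h$alleles[[an]])), 394)
  # 53-bp insertion allele: +53 nt, truncation at 467 residues
  wt <- cds(fx$f35h$reference)
  ins <- applyVariants(fx$f35h$reference, fx$f35h$alleles[["gmf3'5'h"]])
  expect_equal(nchar(ins) - nchar(wt), 53)
  expect_equal(proteinLength(classifyEffect(fx$f35h$reference,
                                            fx$f35h$alleles[["gmf3'5'h"]])),
               467)
  # missense allele carries exactly the V475E change
  efb <- classifyEffect(fx$f35h$reference, fx$f35h$alleles[["GmF3'5'H-b"]])
  expect_equal(nrow(aaChanges(efb)), 1)
  expect_equal(aaChanges(efb)$pos, 475)
  expect_identical(aaChanges(efb)$ref_aa, "V")
  expect_identical(aaChanges(efb)$alt_aa, "E")
})

test_that("the allele suite is byte-reproducible per seed", {
  a <- makeAlleleSuite(seed = 9)
  b <- makeAlleleSuite(seed = 9)
  expect_identical(cds(a$f3h$reference), cds(b$f3h$reference))
  expect_identical(a$f35h$templates, b$f35h$templates)
  expect_false(identical(cds(makeAlleleSuite(seed = 10)$f3h$reference),
                         cds(a$f3h$reference)))
})

test_that("designIndel on the insertion allele gives a 53-bp split", {
  fx <- getFixture()$fixture
  tpl <- pcrTemplate(fx$f35h$reference)
  insVar <- alleleVariants(fx$f35h$alleles[["gmf3'5'h"]])[[1]]
  insTpl <- fx$f35h$templates[["gmf3'5'h"]]
  m <- designIndel(tpl, insTpl, insVar)
  pr <- expectedProfiles(m)
  expect_equal(pr$alt - pr$ref, 53L)
})

test_that("fixed-count panels reproduce the survey allele distribution", {
  panel <- makePanel(panelSpec(seed = 3), fixedCounts = TRUE)
  expect_equal(nrow(panel), 272)
  expect_equal(sum(panel$group == "elite"), 24)
  counts <- table(panel$group, panel$F3H_allele)
  expect_equal(unname(counts["elite", c("GmF3'H", "gmf3'h-a1",
                                        "gmf3'h-a2", "gmf3'h-b")]),
               c(11L, 4L, 2L, 7L))
  expect_equal(unname(counts["wild", "GmF3'H"]), 102L)
  freqs <- alleleFrequencies(data.frame(
    group = "elite",
    allele = colnames(counts),
    count = as.integer(counts["elite", ])))
  expect_setequal(freqs$percent, c(45.8, 16.7, 8.3, 29.2))
})

test_that("panel sampling is seeded and respects the frequency spec", {
  p1 <- makePanel(panelSpec(seed = 12))
  p2 <- makePanel(panelSpec(seed = 12))
  expect_identical(p1, p2)
  # large panel: empirical frequencies within 3 binomial s.e. of spec
  spec <- panelSpec(groupSizes = c(elite = 0L, landrace = 10000L,
                                   wild = 0L), seed = 13)
  big <- makePanel(spec)
  pExp <- spec$f3hFreqs["landrace", ]
  for (a in names(pExp)) {
    pHat <- mean(big$F3H_allele == a)
    se <- sqrt(pExp[[a]] * (1 - pExp[[a]]) / 10000)
    expect_lt(abs(pHat - pExp[[a]]), 3 * se + 1e-9)
  }
})

test_that("sampled phenotypes recover the penetrance spec", {
  spec <- panelSpec(groupSizes = c(elite = 0L, landrace = 8000L,
                                   wild = 0L), seed = 14)
  big <- makePanel(spec)
  tab <- associationTable(big, "F3H_allele", "pubescence")
  pen <- spec$pubescencePenetrance
  for (a in rownames(tab$counts)) {
    n <- tab$counts[a, "n"]
    p <- pen[a, "tawny"]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(tab$counts[a, "tawny"] / n - p), 3 * se + 1e-9)
  }
})
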