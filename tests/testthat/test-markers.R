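# virtual PCR, marker design and assay prediction

test_that("virtualPcr reproduces coordinate arithmetic and mismatches", {
  set.seed(91)
  template <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                    collapse = "")
  # primers matching the template ends reproduce the template
  p0 <- PrimerPair(substr(template, 1, 20),
                   revComp(substr(template, 181, 200)))
  expect_identical(as.character(virtualPcr(template, p0)), template)
  # forward at 21, reverse match ending at 120: 100-bp product
  p1 <- PrimerPair(substr(template, 21, 40),
                   revComp(substr(template, 101, 120)))
  amp <- virtualPcr(template, p1)
  expect_equal(nchar(amp), 100)
  expect_equal(attr(amp, "fwd_start"), 21)
  expect_equal(attr(amp, "rev_end"), 120)
  # two designed mismatches appear in the product at exactly their offsets
  fwd <- substr(template, 21, 40)
  orig <- fwd
  substr(fwd, 5, 5) <- if (substr(fwd, 5, 5) == "A") "C" else "A"
  substr(fwd, 19, 19) <- if (substr(fwd, 19, 19) == "G") "T" else "G"
  mm <- data.frame(offset = c(5L, 19L),
                   template_base = c(substr(orig, 5, 5), substr(orig, 19, 19)),
                   primer_base = c(substr(fwd, 5, 5), substr(fwd, 19, 19)),
                   stringsAsFactors = FALSE)
  p2 <- PrimerPair(fwd, revComp(substr(template, 101, 120)), mismatches = mm)
  amp2 <- as.character(virtualPcr(template, p2))
  ref2 <- substr(template, 21, 120)
  d <- which(strsplit(amp2, "")[[1]] != strsplit(ref2, "")[[1]])
  expect_equal(d, c(5L, 19L))
})

test_that("virtualPcr flags missing and ambiguous amplification", {
  template <- strrep("ACGT", 50)
  expect_error(
    virtualPcr(template, PrimerPair("GGGGGGGGGGGGGGG", "CCCCCCCCCCCCCCC")),
    "no amplification")
  # repetitive template: both primers bind many times
  expect_error(
    virtualPcr(template, PrimerPair(substr(template, 1, 12),
                                    revComp(substr(template, 150, 161)))),
    "ambiguous")
})

test_that("designCaps finds a natural diagnostic site and empty cases", {
  set.seed(101)
  bg <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE,
                     prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
  # scrub any accidental ApoI family matches, then plant one
  while (nrow(findSites(bg, defaultEnzymes()$ApoI)) > 0) {
    p <- findSites(bg, defaultEnzymes()$ApoI)$position[1]
    substr(bg, p + 2, p + 2) <- "C"
  }
  refSeq <- bg
  substr(refSeq, 201, 206) <- "GAATTC"
  altSeq <- refSeq
  substr(altSeq, 203, 203) <- "C"            # SNP destroys the site
  v <- Variant("substitution", 203, "A", "C")
  cand <- designCaps(refSeq, altSeq, v)
  expect_gt(length(cand), 0)
  m <- cand[[1]]
  expect_identical(markerType(m), "CAPS")
  expect_identical(enzymeName(markerEnzyme(m)), "ApoI")
  # profiles verified by direct digestion of the virtual products
  pr <- expectedProfiles(m)
  expect_equal(as.integer(predictAssay(m, refSeq)), pr$ref)
  expect_equal(as.integer(predictAssay(m, altSeq)), pr$alt)
  expect_true(profilesDistinguishable(pr$ref, pr$alt, 20))
  # identical alleles: nothing to design
  expect_length(designCaps(refSeq, refSeq, v), 0)
})

test_that("designCaps round-trip soundness on random SNP alleles", {
  set.seed(111)
  for (i in 1:5) {
    bg <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                collapse = "")
    pos <- sample(150:350, 1)
    site <- sample(expandIupac("RAATTY"), 1)
    substr(bg, pos, pos + 5) <- site
    alt <- bg
    substr(alt, pos + 2, pos + 2) <- "G"     # AATT core broken
    v <- Variant("substitution", pos + 2, substr(bg, pos + 2, pos + 2), "G")
    for (m in designCaps(bg, alt, v)) {
      pr <- expectedProfiles(m)
      expect_true(profilesDistinguishable(pr$ref, pr$alt, 20))
      amp <- nchar(virtualPcr(bg, primerPair(m)))
      expect_equal(sum(pr$ref), amp)
    }
  }
})

test_that("designDcaps defers to CAPS unless forced", {
  fxm <- getFixture()
  refSeq <- cds(fxm$fixture$f3h$reference)
  a1Seq <- fxm$fixture$f3h$templates[["gmf3'h-a1"]]
  v <- Variant("deletion", 973, ref = "A")
  # ApoI discriminates naturally at 973: default policy returns nothing
  expect_length(designDcaps(refSeq, a1Seq, v), 0)
  expect_gt(length(designDcaps(refSeq, a1Seq, v, force = TRUE)), 0)
})

test_that("designDcaps mismatch count matches the exhaustive oracle", {
  set.seed(121)
  mja <- defaultEnzymes()["MjaIV"]
  tested <- 0L
  for (i in 1:12) {
    # 60-bp toy alleles differing by a 1-bp deletion in the middle;
    # natural GTNNAC-family matches are scrubbed so the engineered site
    # is the only possible cut in both search and oracle
    seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
    while (nrow(findSites(seq, mja$MjaIV)) > 0) {
      p <- findSites(seq, mja$MjaIV)$position[1]
      substr(seq, p, p) <- if (substr(seq, p, p) == "C") "A" else "C"
    }
    pos <- 35L
    alt <- paste0(substr(seq, 1, pos - 1), substring(seq, pos + 1))
    if (nrow(findSites(alt, mja$MjaIV)) > 0) next  # junction made a site
    tested <- tested + 1L
    v <- Variant("deletion", pos, ref = substr(seq, pos, pos))
    cand <- designDcaps(seq, alt, v, enzymes = mja,
                        constraints = designConstraints(
                          primerLength = c(12L, 27L),
                          productRange = c(40L, 60L)),
                        force = TRUE)
    oracleMin <- oracleDcapsMinMismatches(seq, alt, pos, "GTNNAC")
    if (length(cand) == 0) {
      # no valid design: the oracle must not find a discriminating
      # placement within the mismatch budget either
      expect_gt(oracleMin, 3)
    } else {
      expect_equal(attr(cand[[1]], "mismatch_count"), oracleMin)
      # the engineered site must cut exactly one allele
      pr <- expectedProfiles(cand[[1]])
      expect_true(xor(length(pr$ref) > 1, length(pr$alt) > 1))
    }
  }
  expect_gte(tested, 5)
})

test_that("designDcaps reproduces the two-mismatch GT geometry", {
  fx <- getFixture()$fixture
  a1 <- fx$f3h$templates[["gmf3'h-a1"]]
  a2 <- fx$f3h$templates[["gmf3'h-a2"]]
  v <- Variant("insertion", 965, alt = "A")   # a2 = a1 + ins A after 965
  cand <- designDcaps(a1, a2, v, enzymes = defaultEnzymes()["MjaIV"],
                      force = TRUE)
  expect_gt(length(cand), 0)
  expect_equal(attr(cand[[1]], "mismatch_count"), 2L)
  mmBases <- cand[[1]]@primers@mismatches$primer_base
  expect_identical(paste(mmBases, collapse = ""), "GT")
})

test_that("designIndel enforces gel resolution and exact size difference", {
  set.seed(131)
  seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
  ins30 <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                 collapse = "")
  v30 <- Variant("insertion", 150, alt = ins30)
  alt <- applyVariants(seq, list(v30))
  m <- designIndel(seq, alt, v30)
  pr <- expectedProfiles(m)
  expect_equal(pr$alt - pr$ref, 30L)
  expect_equal(as.integer(predictAssay(m, seq)), pr$ref)
  expect_equal(as.integer(predictAssay(m, alt)), pr$alt)
  # a 1-bp indel is refused at the default 20-bp resolution
  v1 <- Variant("deletion", 150, ref = substr(seq, 150, 150))
  alt1 <- applyVariants(seq, list(v1))
  expect_error(designIndel(seq, alt1, v1), "resolution")
})

test_that("predicted profiles conserve amplicon length", {
  fxm <- getFixture()
  templates <- c(fxm$fixture$f3h$templates, fxm$fixture$f35h$templates)
  for (m in fxm$markers) {
    for (an in names(expectedProfiles(m))) {
      amp <- virtualPcr(templates[[an]], primerPair(m))
      expect_equal(sum(expectedProfiles(m)[[an]]), nchar(amp),
                   info = paste(markerName(m), an))
    }
  }
})
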