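# variant application, translation and effect classification

test_that("applyVariants reproduces the string-splice oracle", {
  set.seed(11)
  ref <- randomOrf(10)
  # identity
  expect_identical(applyVariants(ref, Allele("wt", "x")), ref)
  # 1-nt deletion at pos 10: splice oracle ref[1..9] + ref[11..]
  del <- Allele("d", "x", list(Variant("deletion", 10,
                                       ref = substr(ref, 10, 10))))
  got <- applyVariants(ref, del)
  expect_identical(got, paste0(substr(ref, 1, 9), substring(ref, 11)))
  expect_equal(nchar(got), nchar(ref) - 1L)
  # insertion after 11 plus deletion at 19: length conserved
  comp <- Allele("c", "x", list(
    Variant("insertion", 11, alt = "A"),
    Variant("deletion", 19, ref = substr(ref, 19, 19))))
  expect_equal(nchar(applyVariants(ref, comp)), nchar(ref))
  # substitution splice oracle
  sub <- Allele("s", "x", list(Variant("substitution", 7,
                                       ref = substr(ref, 7, 7),
                                       alt = setdiff(c("A", "C", "G", "T"),
                                                     substr(ref, 7, 7))[1])))
  got <- applyVariants(ref, sub)
  expect_identical(substr(got, 1, 6), substr(ref, 1, 6))
  expect_identical(substring(got, 8), substring(ref, 8))
})

test_that("applyVariants validates reference bases and overlap", {
  ref <- "ATGAAACCCGGGTAA"
  wrong <- Allele("w", "x", list(Variant("deletion", 4, ref = "C")))
  expect_error(applyVariants(ref, wrong), "inconsistency")
  expect_error(
    Allele("o", "x", list(Variant("deletion", 4, ref = "AA"),
                          Variant("substitution", 5, "A", "T"))),
    "non-overlapping")
  outOfRange <- Allele("r", "x", list(Variant("deletion", 99, ref = "A")))
  expect_error(applyVariants(ref, outOfRange), "outside")
})

test_that("translation follows the standard code and stop semantics", {
  expect_identical(as.character(translateCds("ATGTAA")), "M")
  noStop <- translateCds("ATGGCCGCC")
  expect_identical(as.character(noStop), "MAA")
  expect_true(attr(noStop, "no_stop"))
  expect_error(translateCds("CCCTAA", strict = TRUE), "ATG")
  expect_error(translateCds("AT"), "shorter")
  # random 300-codon ORF against the Biostrings translation oracle
  set.seed(7)
  orf <- randomOrf(300)
  mine <- as.character(translateCds(orf))
  oracle <- as.character(Biostrings::translate(Biostrings::DNAString(orf)))
  expect_identical(mine, sub("\\*$", "", oracle))
})

test_that("effect classification separates the five classes", {
  set.seed(21)
  ref <- ReferenceGene("toy", randomOrf(50))
  # reference allele
  ef <- classifyEffect(ref, Allele("wt", "toy"))
  expect_identical(effectClass(ef), "identical")
  expect_equal(proteinLength(ef), nchar(cds(ref)) / 3L - 1L)
  # frameshift by deleting nt 100; truncation length from the
  # re-translation oracle on the spliced string
  spliced <- paste0(substr(cds(ref), 1, 99), substring(cds(ref), 101))
  fs <- classifyEffect(ref, Allele("fs", "toy", list(
    Variant("deletion", 100, ref = substr(cds(ref), 100, 100)))))
  expect_identical(effectClass(fs), "frameshift_premature_stop")
  expect_equal(proteinLength(fs),
               nchar(as.character(translateCds(spliced))))
  expect_equal(netLengthShift(fs), -1L)
})

test_that("a compensated insertion+deletion stays in frame", {
  fx <- getFixture()$fixture
  ef <- classifyEffect(fx$f3h$reference, fx$f3h$alleles[["gmf3'h-a2"]])
  expect_identical(effectClass(ef), "in_frame_indel")
  expect_equal(netLengthShift(ef), 0L)
  expect_lte(nrow(aaChanges(ef)), 3)
  expect_gte(nrow(aaChanges(ef)), 1)
  expect_equal(proteinLength(ef),
               proteinLength(classifyEffect(fx$f3h$reference,
                                            fx$f3h$alleles[["GmF3'H"]])))
})

test_that("variant round-trips: applying the inverse restores the reference", {
  set.seed(31)
  ref <- randomOrf(60)
  cases <- list(
    Variant("substitution", 50, ref = substr(ref, 50, 50),
            alt = setdiff(c("A", "C", "G", "T"), substr(ref, 50, 50))[2]),
    Variant("deletion", 40, ref = substr(ref, 40, 42)),
    Variant("insertion", 33, alt = "GATTACA"))
  for (v in cases) {
    mutated <- applyVariants(ref, list(v))
    restored <- applyVariants(mutated, list(invertVariant(v)))
    expect_identical(restored, ref)
  }
})

test_that("frame conservation property over random indel alleles", {
  set.seed(41)
  ref <- ReferenceGene("toy", randomOrf(120))
  n <- nchar(cds(ref))
  for (i in 1:30) {
    pos <- sample(10:(n - 30), 1)
    len <- sample(1:5, 1)
    v <- if (runif(1) < 0.5)
      Variant("deletion", pos, ref = substr(cds(ref), pos, pos + len - 1))
    else
      Variant("insertion", pos,
              alt = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                          collapse = ""))
    ef <- classifyEffect(ref, Allele("v", "toy", list(v)))
    if (netLengthShift(ef) %% 3 != 0)
      expect_identical(effectClass(ef), "frameshift_premature_stop")
    else
      expect_true(effectClass(ef) %in%
                    c("in_frame_indel", "frameshift_premature_stop"))
  }
})

test_that("earlier frameshifts never yield longer proteins", {
  set.seed(51)
  ref <- ReferenceGene("toy", randomOrf(200))
  positions <- sort(sample(10:580, 12))
  lengths <- vapply(positions, function(p) {
    ef <- classifyEffect(ref, Allele("v", "toy", list(
      Variant("deletion", p, ref = substr(cds(ref), p, p)))))
    expect_identical(effectClass(ef), "frameshift_premature_stop")
    proteinLength(ef)
  }, integer(1))
  expect_true(all(diff(lengths) >= 0))
})

test_that("complete-ORF invariants are enforced on ReferenceGene", {
  expect_error(ReferenceGene("x", "ATGCCTAA"), "divisible")
  expect_error(ReferenceGene("x", "CCCGCTTAA"), "ATG")
  expect_error(ReferenceGene("x", "ATGTAAGCTTAA"), "stop")
  expect_error(ReferenceGene("x", "ATGNNNTAA"), "ambiguity")
  expect_s4_class(ReferenceGene("x", "atggctTAA"), "ReferenceGene")
})
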