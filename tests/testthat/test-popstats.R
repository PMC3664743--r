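# allele frequencies, Nei diversity and association tables

test_that("allele frequencies reproduce the survey percentages", {
  freqs <- alleleFrequencies(sojaAlleleCounts())
  f3hElite <- freqs[freqs$locus == "GmF3'H" & freqs$group == "elite", ]
  expect_equal(f3hElite$percent, c(45.8, 16.7, 8.3, 29.2))
  expect_equal(sum(f3hElite$proportion), 1)
  f35hWild <- freqs[freqs$locus == "GmF3'5'H" & freqs$group == "wild", ]
  expect_equal(f35hWild$percent, c(92.2, 5.9, 2.0))
  # single allele: 100 %
  one <- alleleFrequencies(data.frame(group = "g", allele = "a", count = 7))
  expect_equal(one$percent, 100)
  expect_error(
    alleleFrequencies(data.frame(group = "g", allele = "a", count = 0)),
    "empty group")
})

test_that("Nei diversity matches the printed indices and bounds", {
  printed <- list(list(c(11, 4, 2, 7), 0.67),
                  list(c(92, 9, 4, 41), 0.52),
                  list(c(102), 0.00),
                  list(c(5, 7, 12), 0.62),
                  list(c(43, 50, 53), 0.66),
                  list(c(94, 6, 2), 0.15))
  for (case in printed)
    expect_equal(round(neiDiversity(case[[1]]), 2), case[[2]])
  # symmetry bound: k equifrequent alleles give exactly 1 - 1/k
  for (k in 2:6)
    expect_equal(neiDiversity(rep(1 / k, k)), 1 - 1 / k)
})

test_that("Nei diversity is label-invariant and maximal at equifrequency", {
  set.seed(141)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    p <- as.numeric(rmultinom(1, 500, runif(k) + 0.05)) / 500
    expect_equal(neiDiversity(p), neiDiversity(sample(p)))
    expect_lte(neiDiversity(p), 1 - 1 / k + 1e-12)
  }
})

test_that("association tables reproduce the survey rows", {
  assoc <- sojaAssociationCounts()
  p4 <- panelFromCounts(assoc$f3h_pubescence)
  t4 <- associationTable(p4, "F3H_allele", "pubescence")
  expect_equal(t4$percents["GmF3'H", "tawny"], 86.3)
  expect_equal(t4$counts["GmF3'H", "n"], 205L)
  expect_identical(t4$display["GmF3'H", "tawny"], "177 (86.3)")
  p5 <- panelFromCounts(assoc$f35h_flower)
  t5 <- associationTable(p5, "F35H_allele", "flower")
  expect_equal(t5$percents["gmf3'5'h", "white"], 82.1)
  # row percentages sum to 100 within rounding slack
  expect_true(all(abs(rowSums(t4$percents) - 100) <= 0.3))
  expect_true(all(abs(rowSums(t5$percents) - 100) <= 0.3))
})

test_that("association percentages match an independent tally oracle", {
  set.seed(151)
  panel <- makePanel(panelSpec(seed = 33))
  tab <- associationTable(panel, "F3H_allele", "pubescence")
  for (a in rownames(tab$counts)) {
    sub <- panel[panel$F3H_allele == a, ]
    for (lv in c("tawny", "gray")) {
      n <- sum(sub$pubescence == lv)
      expect_equal(tab$counts[a, lv], n)
      expect_equal(tab$percents[a, lv],
                   roundHalfUp2(100 * n / nrow(sub)))
    }
  }
})

test_that("absent alleles give zero rows and bad phenotypes give errors", {
  p <- data.frame(accession = c("a", "b"),
                  F3H_allele = factor(c("x", "x"), levels = c("x", "y")),
                  pubescence = c("tawny", "gray"),
                  stringsAsFactors = FALSE)
  tab <- associationTable(p, "F3H_allele", "pubescence")
  expect_equal(unname(tab$counts["y", c("tawny", "gray")]), c(0L, 0L))
  bad <- data.frame(accession = "z", F3H_allele = "x",
                    pubescence = "mauve", stringsAsFactors = FALSE)
  expect_error(associationTable(bad, "F3H_allele", "pubescence"),
               "mauve")
})

test_that("explained fractions reproduce the survey statistics", {
  assoc <- sojaAssociationCounts()
  p4 <- panelFromCounts(assoc$f3h_pubescence)
  tawny <- explainedFraction(p4, "F3H_allele", "GmF3'H",
                             "pubescence", "tawny")
  expect_equal(tawny$numerator, 177L)
  expect_equal(tawny$denominator, 192L)
  expect_equal(tawny$percent, 92.2)
  gray <- explainedFraction(p4, "F3H_allele", c("gmf3'h-a1", "gmf3'h-b"),
                            "pubescence", "gray")
  expect_equal(gray$numerator, 51L)
  expect_equal(gray$denominator, 80L)
  expect_equal(gray$percent, 63.8)
  p5 <- panelFromCounts(assoc$f35h_flower)
  purple <- explainedFraction(p5, "F35H_allele",
                              c("GmF3'5'H-a", "GmF3'5'H-b"),
                              "flower", "purple")
  expect_equal(purple$percent, 94.0)
  # the full allele set always explains 100 %
  all4 <- explainedFraction(p4, "F3H_allele", unique(p4$F3H_allele),
                            "pubescence", "gray")
  expect_equal(all4$percent, 100)
  empty <- p4[p4$pubescence == "tawny", ]
  expect_error(explainedFraction(empty, "F3H_allele", "GmF3'H",
                                 "pubescence", "gray"),
               "undefined fraction")
})

test_that("two-locus genotype tables reproduce the survey rows", {
  assoc <- sojaAssociationCounts()
  p6 <- panelFromCounts(assoc$combined_seedcoat)
  t6 <- combinedGenotypeTable(p6, "F3H_allele", "F35H_allele", "seedcoat")
  expect_equal(t6$percents["GmF3'H and GmF3'5'H-a", "black"], 65.0)
  expect_equal(t6$percents["gmf3'h-b and gmf3'5'h", "yellow"], 90.9)
  # restricting to an unobserved combination yields a zero row
  t0 <- combinedGenotypeTable(p6, "F3H_allele", "F35H_allele", "seedcoat",
                              combinations = list(c("gmf3'h-a1",
                                                    "gmf3'5'h")))
  expect_equal(unname(t0$counts[1, "n"]), 0L)
})
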