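PUBESCENCE_LEVELS <- c("tawny", "gray")
FLOWER_LEVELS <- c("purple", "white")
SEEDCOAT_LEVELS <- c("yellow", "green", "brown", "black", "double")

phenotypeLevels <- function(field) {
  switch(field,
    pubescence = PUBESCENCE_LEVELS,
    flower = FLOWER_LEVELS,
    seedcoat = SEEDCOAT_LEVELS,
    stop("unknown phenotype field '", field, "'"))
}

#' Allele frequencies per germplasm group
#'
#' @param counts data.frame with columns \code{group}, \code{allele},
#'   \code{count} (an allele-count table, e.g.
#'   \code{\link{sojaAlleleCounts}}), or a named list of named count
#'   vectors
#' @return data.frame with columns group, allele, count, proportion,
#'   percent (percent rounded half-up to 1 decimal); proportions sum to 1
#'   within each group
#' @examples
#' alleleFrequencies(data.frame(group = "elite",
#'   allele = c("A", "B"), count = c(3, 1)))
#' @export
alleleFrequencies <- function(counts) {
  counts <- asCountTable(counts)
  # a multi-locus table is totalled per locus-within-group
  key <- if ("locus" %in% names(counts))
    paste(counts$locus, counts$group) else counts$group
  totals <- tapply(counts$count, key, sum)
  if (any(totals <= 0))
    stop("empty group(s): ",
         paste(names(totals)[totals <= 0], collapse = ", "))
  counts$proportion <- counts$count / as.numeric(totals[key])
  counts$percent <- roundHalfUp(100 * counts$proportion, 1L)
  counts
}

asCountTable <- function(counts) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("group", "allele", "count") %in% names(counts)))
    return(counts)
  }
  do.call(rbind, lapply(names(counts), function(g)
    data.frame(group = g, allele = names(counts[[g]]),
               count = as.numeric(counts[[g]]),
               stringsAsFactors = FALSE)))
}

#' Nei's gene diversity index
#'
#' \eqn{h = 1 - \sum_i p_i^2}, the probability that two alleles drawn at
#' random differ; 0 for a monomorphic locus, at most \eqn{1 - 1/k} for k
#' alleles. Computed in the uncorrected form (no \eqn{n/(n-1)} sample-size
#' correction), which is the form the package's shipped count tables
#' reproduce.
#'
#' @param freqs numeric vector of allele proportions (summing to 1) or raw
#'   counts (normalised internally)
#' @return h, full precision; round to 2 decimals for reporting
#' @examples
#' neiDiversity(c(11, 4, 2, 7))   # 0.6701...
#' @export
neiDiversity <- function(freqs) {
  freqs <- as.numeric(freqs)
  if (any(freqs < 0) || sum(freqs) <= 0)
    stop("frequencies must be non-negative with positive sum")
  p <- freqs / sum(freqs)
  1 - sum(p^2)
}

checkPhenotypeValues <- function(panel, field) {
  lv <- phenotypeLevels(field)
  bad <- !panel[[field]] %in% lv
  if (any(bad))
    stop("unknown ", field, " value(s) '",
         paste(unique(panel[[field]][bad]), collapse = "', '"),
         "' for accession(s) ",
         paste(head(panel$accession[bad], 5L), collapse = ", "))
  invisible(lv)
}

#' Allele-by-phenotype association table
#'
#' Cross-tabulates an allele column of a genotype matrix against a
#' phenotype field, reporting counts, row percentages (rounded half-up to
#' 1 decimal) and "n (p.p)" display cells, one row per allele.
#'
#' @param panel genotype matrix data.frame (columns \code{accession},
#'   allele column named by \code{locus}, and the phenotype field)
#' @param locus name of the allele column (e.g. "F3H_allele")
#' @param phenotypeField "pubescence", "flower" or "seedcoat"
#' @return list with components \code{counts} (matrix, alleles x
#'   categories, plus n), \code{percents} (matrix), \code{display}
#'   (character matrix of "n (p.p)" cells)
#' @export
associationTable <- function(panel, locus, phenotypeField) {
  stopifnot(locus %in% names(panel))
  lv <- checkPhenotypeValues(panel, phenotypeField)
  alleles <- if (is.factor(panel[[locus]])) levels(panel[[locus]])
             else unique(panel[[locus]])
  counts <- table(factor(panel[[locus]], levels = alleles),
                  factor(panel[[phenotypeField]], levels = lv))
  counts <- matrix(as.integer(counts), nrow = length(alleles),
                   dimnames = list(alleles, lv))
  n <- rowSums(counts)
  pct <- 100 * counts / ifelse(n > 0, n, NA_real_)
  pct <- roundHalfUp(pct, 1L)
  pct[is.na(pct)] <- 0
  display <- matrix(mapply(formatCountPct, counts, pct),
                    nrow = nrow(counts), dimnames = dimnames(counts))
  list(counts = cbind(counts, n = n), percents = pct, display = display)
}

#' Fraction of a phenotype explained by an allele set
#'
#' Among accessions showing \code{phenotypeValue}, the share carrying any
#' allele in \code{alleleSet}.
#'
#' @param panel genotype matrix data.frame
#' @param locus allele column name
#' @param alleleSet character vector of allele names
#' @param phenotypeField phenotype column name
#' @param phenotypeValue the phenotype category of interest
#' @return list(numerator, denominator, percent), percent rounded half-up
#'   to 1 decimal
#' @examples
#' p <- data.frame(accession = 1:4, a = c("x", "x", "y", "y"),
#'                 pubescence = c("tawny", "tawny", "tawny", "gray"))
#' explainedFraction(p, "a", "x", "pubescence", "tawny")  # 2/3
#' @export
explainedFraction <- function(panel, locus, alleleSet, phenotypeField,
                              phenotypeValue) {
  checkPhenotypeValues(panel, phenotypeField)
  alleleSet <- normalizeAlleleName(alleleSet)
  withPheno <- panel[[phenotypeField]] == phenotypeValue
  den <- sum(withPheno)
  if (den == 0L)
    stop("undefined fraction: no accession shows ", phenotypeField,
         " = ", phenotypeValue)
  num <- sum(withPheno & normalizeAlleleName(panel[[locus]]) %in% alleleSet)
  list(numerator = num, denominator = den,
       percent = roundHalfUp(100 * num / den, 1L))
}

#' Two-locus genotype by phenotype association table
#'
#' Rows are two-locus genotype combinations (all observed, or the subset
#' given in \code{combinations} as a list of c(alleleA, alleleB)).
#'
#' @param panel genotype matrix data.frame
#' @param locusA,locusB allele column names
#' @param phenotypeField phenotype column name
#' @param combinations optional list of two-element character vectors
#'   selecting rows
#' @return as \code{\link{associationTable}}
#' @export
combinedGenotypeTable <- function(panel, locusA, locusB, phenotypeField,
                                  combinations = NULL) {
  stopifnot(all(c(locusA, locusB) %in% names(panel)))
  checkPhenotypeValues(panel, phenotypeField)
  combo <- paste(panel[[locusA]], panel[[locusB]], sep = " and ")
  panel$..combo <- combo
  if (!is.null(combinations)) {
    keep <- vapply(combinations, paste, character(1L), collapse = " and ")
    panel <- panel[combo %in% keep, , drop = FALSE]
    panel$..combo <- factor(panel$..combo, levels = keep)
  }
  associationTable(panel, "..combo", phenotypeField)
}
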