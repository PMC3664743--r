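#' Allele distribution counts of the reference soybean survey
#'
#' The allele counts, by germplasm group, of the 272-accession soybean
#' panel the package's default fixtures emulate (24 elite cultivars, 146
#' local landraces, 102 wild soybeans; four GmF3'H alleles and three
#' GmF3'5'H alleles). These counts drive the default sampling frequencies
#' of \code{\link{makePanel}} and are the inputs to
#' \code{\link{alleleFrequencies}} and \code{\link{neiDiversity}}.
#'
#' @return data.frame with columns locus, group, allele, count
#' @examples
#' counts <- sojaAlleleCounts()
#' subset(counts, locus == "GmF3'H" & group == "elite")
#' @export
sojaAlleleCounts <- function() {
  f3h <- c("GmF3'H", "gmf3'h-a1", "gmf3'h-a2", "gmf3'h-b")
  f35h <- c("GmF3'5'H-a", "GmF3'5'H-b", "gmf3'5'h")
  rbind(
    data.frame(locus = "GmF3'H", group = rep(c("elite", "landrace", "wild"),
                                             each = 4L),
               allele = rep(f3h, 3L),
               count = c(11L, 4L, 2L, 7L,
                         92L, 9L, 4L, 41L,
                         102L, 0L, 0L, 0L),
               stringsAsFactors = FALSE),
    data.frame(locus = "GmF3'5'H", group = rep(c("elite", "landrace", "wild"),
                                               each = 3L),
               allele = rep(f35h, 3L),
               count = c(5L, 7L, 12L,
                         43L, 50L, 53L,
                         94L, 6L, 2L),
               stringsAsFactors = FALSE))
}

#' Allele-by-phenotype counts of the reference soybean survey
#'
#' The genotype-by-phenotype contingency counts of the 272-accession
#' survey panel: GmF3'H allele against pubescence color and seed-coat
#' color, GmF3'5'H allele against flower color and seed-coat color, and
#' seed-coat color for three selected two-locus genotype combinations.
#' Each component is a long-format count table that
#' \code{\link{panelFromCounts}} can expand into an accession panel.
#'
#' @return named list of data.frames: \code{f3h_pubescence},
#'   \code{f3h_seedcoat}, \code{f35h_flower}, \code{f35h_seedcoat},
#'   \code{combined_seedcoat}
#' @export
sojaAssociationCounts <- function() {
  f3h <- c("GmF3'H", "gmf3'h-a1", "gmf3'h-a2", "gmf3'h-b")
  f35h <- c("GmF3'5'H-a", "GmF3'5'H-b", "gmf3'5'h")
  long <- function(alleleCol, alleles, field, levels, counts) {
    df <- expand.grid(a = levels, b = alleles, stringsAsFactors = FALSE)
    out <- data.frame(b = df$b, a = df$a, count = as.integer(counts),
                      stringsAsFactors = FALSE)
    names(out) <- c(alleleCol, field, "count")
    out
  }
  # counts listed per allele, phenotype levels varying fastest
  list(
    f3h_pubescence = long("F3H_allele", f3h, "pubescence",
      PUBESCENCE_LEVELS,
      c(177L, 28L, 2L, 11L, 5L, 1L, 8L, 40L)),
    f3h_seedcoat = long("F3H_allele", f3h, "seedcoat", SEEDCOAT_LEVELS,
      c(46L, 16L, 31L, 93L, 19L,
        11L, 0L, 1L, 0L, 1L,
        5L, 0L, 1L, 0L, 0L,
        38L, 8L, 1L, 0L, 1L)),
    f35h_flower = long("F35H_allele", f35h, "flower", FLOWER_LEVELS,
      c(131L, 11L, 56L, 7L, 12L, 55L)),
    f35h_seedcoat = long("F35H_allele", f35h, "seedcoat", SEEDCOAT_LEVELS,
      c(32L, 8L, 10L, 78L, 14L,
        19L, 9L, 18L, 11L, 6L,
        49L, 7L, 6L, 4L, 1L)),
    combined_seedcoat = {
      combos <- list(c("GmF3'H", "GmF3'5'H-a"),
                     c("GmF3'H", "GmF3'5'H-b"),
                     c("gmf3'h-b", "gmf3'5'h"))
      counts <- c(15L, 4L, 9L, 78L, 14L,
                  9L, 7L, 17L, 11L, 4L,
                  20L, 2L, 0L, 0L, 0L)
      data.frame(
        F3H_allele = rep(vapply(combos, `[`, character(1L), 1L), each = 5L),
        F35H_allele = rep(vapply(combos, `[`, character(1L), 2L), each = 5L),
        seedcoat = rep(SEEDCOAT_LEVELS, 3L),
        count = counts, stringsAsFactors = FALSE)
    })
}

#' Expand a count table into an accession panel
#'
#' Replicates each row of a long-format count table \code{count} times
#' and adds an accession id, yielding a genotype-matrix-shaped data.frame
#' usable by \code{\link{associationTable}},
#' \code{\link{explainedFraction}} and
#' \code{\link{combinedGenotypeTable}}. This fixed-count expansion
#' reproduces a printed contingency table exactly (no sampling).
#'
#' @param counts data.frame whose last column is \code{count}
#' @param prefix accession-id prefix
#' @return data.frame with an \code{accession} column and one row per
#'   accession
#' @export
panelFromCounts <- function(counts, prefix = "ACC") {
  stopifnot(is.data.frame(counts), "count" %in% names(counts))
  idx <- rep(seq_len(nrow(counts)), counts$count)
  out <- counts[idx, setdiff(names(counts), "count"), drop = FALSE]
  out <- cbind(accession = sprintf("%s%04d", prefix, seq_along(idx)), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# counts for one locus, in the alleleFrequencies() input shape
locusCounts <- function(locus) {
  x <- sojaAlleleCounts()
  x[x$locus == locus, c("group", "allele", "count")]
}
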