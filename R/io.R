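# File formats: FASTA via Biostrings; TSV/CSV with headers for variant,
# enzyme and marker tables and genotype matrices. All readers normalize
# allele/locus spellings (Unicode prime and "p" alias -> ASCII apostrophe).

#' Read reference sequences from a FASTA file
#'
#' @param path FASTA file
#' @param complete enforce complete-ORF invariants on each record
#' @return named list of \linkS4class{ReferenceGene}
#' @export
readReferenceFasta <- function(path, complete = TRUE) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i)
    ReferenceGene(normalizeAlleleName(names(seqs)[i]),
                  as.character(seqs[[i]]), complete = complete))
  names(out) <- vapply(out, geneId, character(1L))
  out
}

#' Write named sequences to FASTA (60-column wrap)
#'
#' @param seqs named character vector or list of sequences
#' @param path output file
#' @export
writeFasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(as.list(seqs)))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a variant table into Allele objects
#'
#' Expected TSV columns: \code{locus}, \code{allele}, \code{kind},
#' \code{pos}, \code{ref}, \code{alt} (ref/alt may be "." or empty).
#' Rows sharing locus+allele are combined into one multi-variant allele.
#'
#' @param path TSV file
#' @return named list of \linkS4class{Allele} (names "locus:allele")
#' @export
readVariantTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("locus", "allele", "kind", "pos", "ref", "alt")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("variant table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  df$locus <- normalizeAlleleName(df$locus)
  df$allele <- normalizeAlleleName(df$allele)
  clean <- function(x) ifelse(x %in% c(".", NA), "", x)
  key <- paste(df$locus, df$allele, sep = ":")
  out <- lapply(split(seq_len(nrow(df)), key)[unique(key)], function(i) {
    rows <- df[i, , drop = FALSE]
    rows <- rows[order(as.integer(rows$pos)), , drop = FALSE]
    vars <- lapply(seq_len(nrow(rows)), function(j)
      Variant(rows$kind[j], as.integer(rows$pos[j]),
              ref = clean(rows$ref[j]), alt = clean(rows$alt[j])))
    Allele(rows$allele[1L], rows$locus[1L], vars)
  })
  out
}

#' Write alleles to a variant table TSV
#'
#' @param alleles list of \linkS4class{Allele}
#' @param path output TSV
#' @export
writeVariantTable <- function(alleles, path) {
  rows <- do.call(rbind, lapply(alleles, function(a) {
    if (length(a@variants) == 0L) return(NULL)
    do.call(rbind, lapply(a@variants, function(v)
      data.frame(locus = a@locus, allele = a@name, kind = v@kind,
                 pos = v@pos,
                 ref = if (nzchar(v@ref)) v@ref else ".",
                 alt = if (nzchar(v@alt)) v@alt else ".",
                 stringsAsFactors = FALSE)))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a restriction-enzyme table
#'
#' Expected TSV columns: \code{name}, \code{site}, \code{cut_top},
#' \code{cut_bottom} (cut columns may be empty/"." for
#' site-presence-only enzymes).
#'
#' @param path TSV file
#' @return named list of \linkS4class{RestrictionEnzyme}
#' @export
readEnzymeTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "site", "cut_top", "cut_bottom")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("enzyme table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  num <- function(x) suppressWarnings(as.integer(ifelse(x %in% c(".", ""),
                                                        NA, x)))
  out <- lapply(seq_len(nrow(df)), function(i)
    RestrictionEnzyme(df$name[i], df$site[i],
                      num(df$cut_top)[i], num(df$cut_bottom)[i]))
  names(out) <- df$name
  out
}

#' Write an enzyme list to TSV
#'
#' @param enzymes list of \linkS4class{RestrictionEnzyme}
#' @param path output TSV
#' @export
writeEnzymeTable <- function(enzymes, path) {
  df <- do.call(rbind, lapply(enzymes, function(e)
    data.frame(name = e@name, site = e@site,
               cut_top = ifelse(is.na(e@cutTop), ".",
                                as.character(e@cutTop)),
               cut_bottom = ifelse(is.na(e@cutBottom), ".",
                                   as.character(e@cutBottom)),
               stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write an accession panel (genotype matrix) CSV
#'
#' Columns: accession, group, F3H_allele, F35H_allele, pubescence,
#' flower, seedcoat (allele spellings normalized on read).
#'
#' @param path CSV file
#' @return data.frame
#' @export
readPanelCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("F3H_allele", "F35H_allele"), names(df)))
    df[[col]] <- normalizeAlleleName(df[[col]])
  df
}

#' @rdname readPanelCsv
#' @param panel data.frame to write
#' @export
writePanelCsv <- function(panel, path) {
  write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a digestion report TSV
#'
#' One row per sequence: name, length, number of cuts, and fragment sizes
#' joined with "+" (fragments always sum to the length).
#'
#' @param seqs named character vector of sequences
#' @param enzyme a \linkS4class{RestrictionEnzyme}
#' @param path output TSV
#' @return the report data.frame, invisibly written to \code{path}
#' @export
writeDigestReport <- function(seqs, enzyme, path) {
  rows <- do.call(rbind, lapply(names(seqs), function(nm) {
    d <- digestSequence(seqs[[nm]], enzyme)
    data.frame(name = nm, length = d@inputLength,
               n_cuts = length(d@cutPositions),
               fragments = paste(d@fragments, collapse = "+"),
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}

#' Plain-text diversity and association report
#'
#' Renders the allele-distribution table (counts with "n (p.p)" cells and
#' per-group Nei diversity) and, when association counts are supplied,
#' the allele-by-phenotype tables, mirroring the layout of the survey
#' tables.
#'
#' @param counts allele count table (see \code{\link{alleleFrequencies}})
#' @param associations optional list of long-format association count
#'   tables (as \code{\link{sojaAssociationCounts}})
#' @return character vector of report lines
#' @export
diversityReport <- function(counts, associations = NULL) {
  counts <- asCountTable(counts)
  freqs <- alleleFrequencies(counts)
  if (!"locus" %in% names(freqs)) freqs$locus <- "locus"
  lines <- character()
  for (loc in unique(freqs$locus)) {
    for (g in unique(freqs$group)) {
      x <- freqs[freqs$group == g & freqs$locus == loc, ]
      if (nrow(x) == 0L) next
      lines <- c(lines, sprintf("%s / %s (n = %d)", loc, g, sum(x$count)))
      lines <- c(lines, sprintf("  %-12s %s", x$allele,
                                formatCountPct(x$count, x$percent)))
      lines <- c(lines, sprintf("  Nei's gene diversity: %.2f",
                                roundHalfUp(neiDiversity(x$count), 2L)))
    }
  }
  if (!is.null(associations)) {
    for (nm in names(associations)) {
      df <- associations[[nm]]
      field <- setdiff(names(df), c("F3H_allele", "F35H_allele", "count"))
      panel <- panelFromCounts(df)
      alleleCols <- intersect(c("F3H_allele", "F35H_allele"), names(df))
      tab <- if (length(alleleCols) == 2L)
        combinedGenotypeTable(panel, "F3H_allele", "F35H_allele", field)
      else associationTable(panel, alleleCols, field)
      lines <- c(lines, "", sprintf("Association: %s", nm))
      hdr <- paste(sprintf("%-12s", colnames(tab$display)), collapse = "")
      lines <- c(lines, paste0(sprintf("  %-24s", "allele"), hdr))
      for (r in rownames(tab$display))
        lines <- c(lines, paste0(sprintf("  %-24s", r),
                                 paste(sprintf("%-12s", tab$display[r, ]),
                                       collapse = "")))
    }
  }
  lines
}
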