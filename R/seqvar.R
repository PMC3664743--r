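#' Apply an allele's variants to a reference CDS
#'
#' Variants are applied right-to-left (descending position) so that every
#' stated 1-based coordinate refers to the unmodified reference frame and
#' never needs shifting; this is the package's canonical variant
#' semantics. Insertions add their bases immediately after \code{pos}.
#'
#' @param ref a \linkS4class{ReferenceGene} or a plain CDS string
#' @param allele an \linkS4class{Allele} (or a list of
#'   \linkS4class{Variant}s)
#' @return the allele CDS as a character scalar; its length equals the
#'   reference length plus the summed net length of the variants
#' @examples
#' ref <- ReferenceGene("toy", "ATGGCTGCTGCTTAA")
#' applyVariants(ref, Allele("d", "toy", list(Variant("deletion", 7, ref = "G"))))
#' @export
applyVariants <- function(ref, allele) {
  seq <- if (is(ref, "ReferenceGene")) ref@cds else toupper(as.character(ref))
  variants <- if (is(allele, "Allele")) {
    validObject(allele)
    allele@variants
  } else allele
  if (length(variants) == 0L) return(seq)
  ord <- order(vapply(variants, function(v) v@pos, integer(1L)),
               decreasing = TRUE)
  for (v in variants[ord]) {
    validObject(v)
    n <- nchar(seq)
    endRef <- v@pos + max(nchar(v@ref), if (v@kind == "insertion") 0L else 1L) - 1L
    if (v@pos > n || endRef > n)
      stop("variant at position ", v@pos, " falls outside the ", n, "-nt CDS")
    if (v@kind != "insertion") {
      found <- substr(seq, v@pos, v@pos + nchar(v@ref) - 1L)
      if (found != v@ref)
        stop("variant/reference inconsistency at position ", v@pos,
             ": reference has '", found, "', variant expects '", v@ref, "'")
    }
    seq <- switch(v@kind,
      substitution = paste0(substr(seq, 1L, v@pos - 1L), v@alt,
                            substring(seq, v@pos + nchar(v@ref))),
      deletion = paste0(substr(seq, 1L, v@pos - 1L),
                        substring(seq, v@pos + nchar(v@ref))),
      insertion = paste0(substr(seq, 1L, v@pos), v@alt,
                         substring(seq, v@pos + 1L)))
  }
  seq
}

#' The exact inverse of a variant
#'
#' Produces the variant that undoes \code{v} when applied to the mutated
#' sequence: substitutions swap ref/alt, a deletion at \code{pos} becomes
#' an insertion after \code{pos - 1}, and an insertion after \code{pos}
#' becomes a deletion starting at \code{pos + 1}.
#'
#' @param v a \linkS4class{Variant}
#' @return the inverse \linkS4class{Variant}
#' @export
invertVariant <- function(v) {
  switch(v@kind,
    substitution = Variant("substitution", v@pos, ref = v@alt, alt = v@ref),
    deletion = Variant("insertion", v@pos - 1L, alt = v@ref),
    insertion = Variant("deletion", v@pos + 1L, ref = v@alt))
}

#' Translate a CDS with the standard genetic code
#'
#' Translation starts at base 1 and stops at the first in-frame stop codon
#' (not counted as a residue); trailing bases after the stop, and any
#' incomplete final codon, are ignored. If no stop codon is found the full
#' translation is returned with the \code{no_stop} attribute set.
#'
#' @param cdsSeq CDS string (length >= 3) over A/C/G/T
#' @param strict require an ATG initiator codon
#' @return protein string; attribute \code{no_stop} is TRUE when
#'   translation ran off the end without a stop codon
#' @examples
#' translateCds("ATGTAA")      # "M"
#' translateCds("ATGGCCGCC")   # "MAA", no stop
#' @export
translateCds <- function(cdsSeq, strict = FALSE) {
  cdsSeq <- toupper(as.character(cdsSeq))
  if (nchar(cdsSeq) < 3L) stop("CDS shorter than one codon")
  if (strict && substr(cdsSeq, 1L, 3L) != "ATG")
    stop("strict mode: CDS does not start with ATG")
  codons <- splitCodons(cdsSeq)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stopAt <- which(aa == "*")
  if (length(stopAt)) {
    prot <- paste(aa[seq_len(stopAt[1L] - 1L)], collapse = "")
    attr(prot, "no_stop") <- FALSE
  } else {
    prot <- paste(aa, collapse = "")
    attr(prot, "no_stop") <- TRUE
  }
  prot
}

#' Classify the protein-level effect of an allele
#'
#' Compares the translation of the reference CDS with the translation of
#' the variant-applied CDS and assigns one of five classes:
#' \describe{
#'   \item{identical}{no sequence change at all}
#'   \item{synonymous}{DNA changed, protein unchanged}
#'   \item{missense}{substitutions only, protein changed, same length}
#'   \item{in_frame_indel}{indels with net shift divisible by 3 and no
#'     premature stop (covers compensated insertion+deletion pairs, whose
#'     frame is restored before the effect can propagate)}
#'   \item{frameshift_premature_stop}{net shift not divisible by 3, or any
#'     change creating a stop codon upstream of the reference stop}
#' }
#' A 1-bp deletion anywhere before the reference stop is therefore a
#' frameshift unless a nearby insertion restores the frame.
#'
#' @param ref a \linkS4class{ReferenceGene}
#' @param allele an \linkS4class{Allele}
#' @return an \linkS4class{EffectReport}
#' @examples
#' ref <- ReferenceGene("toy", paste0("ATG", strrep("GCT", 40), "TAA"))
#' classifyEffect(ref, Allele("fs", "toy", list(Variant("deletion", 10, ref = "T"))))
#' @export
classifyEffect <- function(ref, allele) {
  stopifnot(is(ref, "ReferenceGene"), is(allele, "Allele"))
  refSeq <- ref@cds
  altSeq <- applyVariants(ref, allele)
  netShift <- nchar(altSeq) - nchar(refSeq)
  refProt <- translateCds(refSeq)
  altProt <- translateCds(altSeq)
  hasIndel <- any(vapply(allele@variants, function(v) v@kind != "substitution",
                         logical(1L)))
  aaCh <- data.frame(pos = integer(), ref_aa = character(),
                     alt_aa = character(), stringsAsFactors = FALSE)

  if (altSeq == refSeq) {
    cls <- "identical"
  } else if (as.character(altProt) == as.character(refProt)) {
    cls <- "synonymous"
  } else if (netShift %% 3L != 0L) {
    cls <- "frameshift_premature_stop"
  } else if (nchar(altProt) < nchar(refProt) + netShift / 3L &&
             !attr(altProt, "no_stop")) {
    # frame conserved overall but a stop appears upstream of where the
    # reference stop lands after the in-frame shift
    cls <- "frameshift_premature_stop"
  } else if (hasIndel) {
    cls <- "in_frame_indel"
  } else {
    cls <- "missense"
  }

  if (cls %in% c("missense", "in_frame_indel") &&
      nchar(altProt) == nchar(refProt)) {
    r <- strsplit(as.character(refProt), "")[[1L]]
    a <- strsplit(as.character(altProt), "")[[1L]]
    d <- which(r != a)
    aaCh <- data.frame(pos = d, ref_aa = r[d], alt_aa = a[d],
                       stringsAsFactors = FALSE)
  }

  new("EffectReport", effectClass = cls,
      proteinLength = nchar(as.character(altProt)),
      aaChanges = aaCh, netLengthShift = as.integer(netShift))
}
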