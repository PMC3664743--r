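#' @import methods
#' @importFrom stats setNames rbinom runif
#' @importFrom utils read.delim read.csv write.csv write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

EFFECT_CLASSES <- c("identical", "synonymous", "missense",
                    "in_frame_indel", "frameshift_premature_stop")

#' ReferenceGene: a coding sequence in its own 1-based coordinate frame
#'
#' Holds a protein-coding sequence over {A,C,G,T}. When \code{complete} is
#' \code{TRUE} the CDS must start with ATG, have length divisible by 3 and
#' contain exactly one in-frame stop codon, at its end. All variant
#' coordinates in the package are 1-based positions on this CDS, counted
#' from the A of the start codon. An optional \code{flank3} slot carries
#' downstream (3') template sequence so PCR assays may extend past the stop
#' codon, as they do on genomic DNA.
#'
#' @slot id gene identifier
#' @slot cds coding sequence (character scalar, A/C/G/T)
#' @slot flank3 3' flanking template sequence (may be "")
#' @slot complete whether CDS completeness invariants are enforced
#' @exportClass ReferenceGene
setClass("ReferenceGene",
  representation(id = "character", cds = "character",
                 flank3 = "character", complete = "logical"),
  prototype(flank3 = "", complete = TRUE))

setValidity("ReferenceGene", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a non-empty string")
  if (length(object@cds) != 1L || nchar(object@cds) == 0L)
    msg <- c(msg, "'cds' must be a non-empty sequence")
  if (grepl("[^ACGT]", object@cds))
    msg <- c(msg, "'cds' may only contain A/C/G/T (no ambiguity codes)")
  if (length(object@flank3) == 1L && nzchar(object@flank3) &&
      grepl("[^ACGT]", object@flank3))
    msg <- c(msg, "'flank3' may only contain A/C/G/T")
  if (isTRUE(object@complete)) {
    n <- nchar(object@cds)
    if (n %% 3L != 0L)
      msg <- c(msg, "complete CDS length must be divisible by 3")
    else {
      codons <- substring(object@cds, seq(1L, n, 3L), seq(3L, n, 3L))
      if (codons[1L] != "ATG")
        msg <- c(msg, "complete CDS must start with ATG")
      stops <- which(codons %in% STOP_CODONS)
      if (!identical(stops, length(codons)))
        msg <- c(msg, "complete CDS must have exactly one in-frame stop, at its end")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ReferenceGene
#'
#' @param id gene identifier
#' @param cds coding sequence (character scalar or \code{DNAString})
#' @param flank3 optional 3' flanking sequence appended to the PCR template
#' @param complete enforce ATG start / terminal single stop invariants
#' @return a \linkS4class{ReferenceGene}
#' @examples
#' ReferenceGene("toy", "ATGGCCTAA")
#' @export
ReferenceGene <- function(id, cds, flank3 = "", complete = TRUE) {
  new("ReferenceGene", id = as.character(id),
      cds = toupper(as.character(cds)),
      flank3 = toupper(as.character(flank3)), complete = complete)
}

#' Variant: a single substitution, insertion or deletion on a CDS
#'
#' Coordinates are 1-based on the reference CDS. For substitutions and
#' deletions \code{pos} is the first reference base affected; insertions
#' place \code{alt} immediately *after* \code{pos} (so an "insertion of an
#' adenine at position 965" leaves base 965 intact and adds an A between
#' 965 and 966).
#'
#' @slot kind "substitution", "insertion" or "deletion"
#' @slot pos 1-based CDS position
#' @slot ref reference bases removed ("" for insertions)
#' @slot alt alternate bases added ("" for deletions)
#' @exportClass Variant
setClass("Variant",
  representation(kind = "character", pos = "integer",
                 ref = "character", alt = "character"))

setValidity("Variant", function(object) {
  msg <- character()
  if (!object@kind %in% c("substitution", "insertion", "deletion"))
    msg <- c(msg, "kind must be substitution/insertion/deletion")
  if (length(object@pos) != 1L || is.na(object@pos) || object@pos < 1L)
    msg <- c(msg, "pos must be a positive integer")
  if (grepl("[^ACGT]", object@ref) || grepl("[^ACGT]", object@alt))
    msg <- c(msg, "ref/alt must be over A/C/G/T")
  if (object@kind == "substitution" &&
      (nchar(object@ref) != nchar(object@alt) || nchar(object@ref) < 1L))
    msg <- c(msg, "substitution needs |ref| == |alt| >= 1")
  if (object@kind == "insertion" && (nchar(object@ref) != 0L || nchar(object@alt) == 0L))
    msg <- c(msg, "insertion needs empty ref and non-empty alt")
  if (object@kind == "deletion" && (nchar(object@alt) != 0L || nchar(object@ref) == 0L))
    msg <- c(msg, "deletion needs empty alt and non-empty ref")
  if (length(msg)) msg else TRUE
})

#' Construct a Variant
#'
#' @param kind "substitution", "insertion" or "deletion"
#' @param pos 1-based CDS position (insertions go after this base)
#' @param ref reference bases ("" for insertion)
#' @param alt alternate bases ("" for deletion)
#' @return a \linkS4class{Variant}
#' @examples
#' Variant("deletion", 973, ref = "A")          # 1-bp frameshift deletion
#' Variant("insertion", 965, alt = "A")         # insertion after base 965
#' Variant("substitution", 1424, "T", "A")      # SNP
#' @export
Variant <- function(kind, pos, ref = "", alt = "") {
  new("Variant", kind = match.arg(kind, c("substitution", "insertion", "deletion")),
      pos = as.integer(pos), ref = toupper(ref), alt = toupper(alt))
}

# zero-width for insertions; [pos, pos + |ref| - 1] otherwise
variantSpan <- function(v) {
  if (v@kind == "insertion") c(v@pos + 0.5, v@pos + 0.5)
  else c(v@pos, v@pos + nchar(v@ref) - 1L)
}

#' Allele: a named set of variants relative to a reference gene
#'
#' An empty variant list denotes the reference allele itself.
#'
#' @slot name allele name (e.g. "gmf3'h-a1")
#' @slot locus identifier of the reference gene the variants refer to
#' @slot variants list of \linkS4class{Variant}, ascending position,
#'   non-overlapping
#' @exportClass Allele
setClass("Allele",
  representation(name = "character", locus = "character", variants = "list"))

setValidity("Allele", function(object) {
  msg <- character()
  if (!all(vapply(object@variants, is, logical(1L), "Variant")))
    msg <- c(msg, "variants must all be Variant objects")
  else if (length(object@variants) > 1L) {
    spans <- t(vapply(object@variants, variantSpan, numeric(2L)))
    ord <- order(spans[, 1L])
    spans <- spans[ord, , drop = FALSE]
    if (any(spans[-1L, 1L] <= spans[-nrow(spans), 2L]))
      msg <- c(msg, "variants must be non-overlapping")
    pos <- vapply(object@variants, function(v) v@pos, integer(1L))
    if (is.unsorted(pos))
      msg <- c(msg, "variants must be in ascending position order")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an Allele
#'
#' @param name allele name
#' @param locus reference gene id
#' @param variants list of \linkS4class{Variant} (ascending position)
#' @return an \linkS4class{Allele}
#' @examples
#' Allele("gmf3'h-a1", "GmF3'H", list(Variant("deletion", 973, ref = "A")))
#' @export
Allele <- function(name, locus, variants = list()) {
  new("Allele", name = as.character(name), locus = as.character(locus),
      variants = variants)
}

#' EffectReport: protein-level consequence of an allele
#'
#' @slot effectClass one of identical, synonymous, missense,
#'   in_frame_indel, frameshift_premature_stop
#' @slot proteinLength residues in the translated allele product
#' @slot aaChanges data.frame (pos, ref_aa, alt_aa); empty for
#'   identical/synonymous
#' @slot netLengthShift net nucleotide length change of the allele CDS
#' @exportClass EffectReport
setClass("EffectReport",
  representation(effectClass = "character", proteinLength = "integer",
                 aaChanges = "data.frame", netLengthShift = "integer"))

setValidity("EffectReport", function(object) {
  if (!object@effectClass %in% EFFECT_CLASSES)
    return("unknown effect class")
  if (object@effectClass %in% c("identical", "synonymous") &&
      nrow(object@aaChanges) > 0L)
    return("identical/synonymous reports must have no aa changes")
  TRUE
})

#' RestrictionEnzyme: IUPAC recognition site plus cut offsets
#'
#' \code{cutTop}/\code{cutBottom} give the position *after which* the top
#' (respectively bottom) strand is cut, counted from the first base of the
#' recognition site on the strand carrying the site. Offsets beyond the
#' site length describe Type IIS enzymes cutting downstream (HphI,
#' GGTGA(8/7): cutTop = 13, cutBottom = 12). \code{NA} offsets put the
#' enzyme in site-presence-only mode: sites can be located but fragment
#' sizes are not predicted.
#'
#' @slot name enzyme name
#' @slot site IUPAC recognition sequence
#' @slot cutTop top-strand cut offset (NA = presence-only)
#' @slot cutBottom bottom-strand cut offset
#' @slot palindromic whether the site family equals its reverse complement
#' @exportClass RestrictionEnzyme
setClass("RestrictionEnzyme",
  representation(name = "character", site = "character",
                 cutTop = "integer", cutBottom = "integer",
                 palindromic = "logical"))

setValidity("RestrictionEnzyme", function(object) {
  msg <- character()
  if (!nzchar(object@site) ||
      grepl("[^ACGTRYSWKMBDHVN]", object@site))
    msg <- c(msg, "site must be a non-empty IUPAC DNA string")
  if (is.na(object@cutTop) != is.na(object@cutBottom))
    msg <- c(msg, "cutTop and cutBottom must both be set or both NA")
  if (length(msg)) msg else TRUE
})

#' Construct a RestrictionEnzyme
#'
#' @param name enzyme name
#' @param site IUPAC recognition sequence
#' @param cutTop,cutBottom cut offsets (see class docs); NA for
#'   site-presence-only mode
#' @return a \linkS4class{RestrictionEnzyme}
#' @examples
#' RestrictionEnzyme("ApoI", "RAATTY", 1, 5)       # R^AATTY
#' RestrictionEnzyme("HphI", "GGTGA", 13, 12)      # GGTGA(8/7), Type IIS
#' @export
RestrictionEnzyme <- function(name, site, cutTop = NA, cutBottom = NA) {
  site <- toupper(site)
  new("RestrictionEnzyme", name = as.character(name), site = site,
      cutTop = as.integer(cutTop), cutBottom = as.integer(cutBottom),
      palindromic = isPalindromicSite(site))
}

#' DigestResult: cut coordinates and fragment sizes of a linear digestion
#'
#' Fragment lengths always sum to the input length; for a linear molecule
#' there is one more fragment than cut.
#'
#' @slot cutPositions ascending top-strand coordinates; a cut at k severs
#'   the backbone between bases k and k+1
#' @slot fragments fragment lengths, 5' to 3'
#' @slot inputLength length of the digested sequence
#' @slot droppedCuts number of cuts falling outside the molecule (Type IIS
#'   sites near an end)
#' @exportClass DigestResult
setClass("DigestResult",
  representation(cutPositions = "integer", fragments = "integer",
                 inputLength = "integer", droppedCuts = "integer"))

setValidity("DigestResult", function(object) {
  if (length(object@fragments) &&
      sum(object@fragments) != object@inputLength)
    return("fragments must sum to input length")
  if (length(object@fragments) != length(object@cutPositions) + 1L)
    return("linear digest must have |cuts| + 1 fragments")
  TRUE
})

#' PrimerPair: a forward/reverse primer pair with designed mismatches
#'
#' The reverse primer is given 5'->3' on the bottom strand, as synthesised.
#' \code{mismatches} records deliberate template mismatches on the forward
#' primer (the dCAPS mechanism): amplicons carry the primer base, not the
#' template base, at those offsets.
#'
#' @slot forward forward primer 5'->3' (top strand)
#' @slot reverse reverse primer 5'->3' (bottom strand)
#' @slot mismatches data.frame (offset, template_base, primer_base);
#'   offsets are 1-based within the forward primer
#' @exportClass PrimerPair
setClass("PrimerPair",
  representation(forward = "character", reverse = "character",
                 mismatches = "data.frame"))

setValidity("PrimerPair", function(object) {
  msg <- character()
  if (grepl("[^ACGT]", object@forward) || grepl("[^ACGT]", object@reverse))
    msg <- c(msg, "primers must be over A/C/G/T")
  mm <- object@mismatches
  if (nrow(mm)) {
    if (!all(c("offset", "template_base", "primer_base") %in% names(mm)))
      msg <- c(msg, "mismatches need offset/template_base/primer_base columns")
    else if (any(mm$offset < 1L | mm$offset > nchar(object@forward)))
      msg <- c(msg, "mismatch offsets must lie within the forward primer")
  }
  if (length(msg)) msg else TRUE
})

emptyMismatches <- function() {
  data.frame(offset = integer(), template_base = character(),
             primer_base = character(), stringsAsFactors = FALSE)
}

#' Construct a PrimerPair
#'
#' @param forward forward primer, 5'->3' top strand
#' @param reverse reverse primer, 5'->3' bottom strand
#' @param mismatches data.frame of designed forward-primer mismatches
#'   (columns offset, template_base, primer_base)
#' @return a \linkS4class{PrimerPair}
#' @export
PrimerPair <- function(forward, reverse, mismatches = emptyMismatches()) {
  new("PrimerPair", forward = toupper(forward), reverse = toupper(reverse),
      mismatches = mismatches)
}

setClassUnion("RestrictionEnzymeOrNULL", c("RestrictionEnzyme", "NULL"))

#' GeneMarker: a CAPS, dCAPS or InDel assay with expected band profiles
#'
#' @slot name marker name (e.g. "F3'H-ApoI")
#' @slot markerType "CAPS", "dCAPS" or "InDel"
#' @slot primers the \linkS4class{PrimerPair}
#' @slot enzyme the \linkS4class{RestrictionEnzyme}, or NULL for InDel
#'   markers
#' @slot expectedProfiles named list: allele name -> sorted band sizes (bp)
#' @exportClass GeneMarker
setClass("GeneMarker",
  representation(name = "character", markerType = "character",
                 primers = "PrimerPair", enzyme = "RestrictionEnzymeOrNULL",
                 expectedProfiles = "list"))

setValidity("GeneMarker", function(object) {
  msg <- character()
  if (!object@markerType %in% c("CAPS", "dCAPS", "InDel"))
    msg <- c(msg, "markerType must be CAPS, dCAPS or InDel")
  if (object@markerType == "InDel" && !is.null(object@enzyme))
    msg <- c(msg, "InDel markers carry no enzyme")
  if (object@markerType != "InDel" && is.null(object@enzyme))
    msg <- c(msg, "CAPS/dCAPS markers need exactly one enzyme")
  if (length(object@expectedProfiles) &&
      is.null(names(object@expectedProfiles)))
    msg <- c(msg, "expectedProfiles must be named by allele")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneMarker
#'
#' @param name marker name
#' @param markerType "CAPS", "dCAPS" or "InDel"
#' @param primers a \linkS4class{PrimerPair}
#' @param enzyme a \linkS4class{RestrictionEnzyme} (NULL for InDel)
#' @param expectedProfiles named list of per-allele sorted band sizes
#' @return a \linkS4class{GeneMarker}
#' @export
GeneMarker <- function(name, markerType, primers, enzyme = NULL,
                       expectedProfiles = list()) {
  expectedProfiles <- lapply(expectedProfiles,
                             function(x) sort(as.integer(x), decreasing = TRUE))
  new("GeneMarker", name = as.character(name), markerType = markerType,
      primers = primers, enzyme = enzyme,
      expectedProfiles = expectedProfiles)
}

#' GenotypeCall: allele call for one accession at one locus
#'
#' NO_CALL is a first-class result, never an error; \code{note} records why
#' (insufficient or contradictory marker evidence).
#'
#' @slot accession accession id ("" when calling a bare pattern set)
#' @slot locus locus id
#' @slot allele allele name or "NO_CALL"
#' @slot note free-text audit note
#' @slot evidence named list: marker name -> matched band profile
#' @exportClass GenotypeCall
setClass("GenotypeCall",
  representation(accession = "character", locus = "character",
                 allele = "character", note = "character",
                 evidence = "list"))

GenotypeCall <- function(locus, allele, note = "", evidence = list(),
                         accession = "") {
  new("GenotypeCall", accession = accession, locus = locus,
      allele = allele, note = note, evidence = evidence)
}
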