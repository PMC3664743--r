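#' @include AllClasses.R
NULL

#' Accessors for sojaCAPS classes
#'
#' Small accessor generics for the package's S4 classes; prefer these over
#' direct slot access.
#'
#' @param x an object of the relevant class
#' @return the slot value
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setGeneric("cds", function(x) standardGeneric("cds"))
#' @rdname accessors
#' @export
setGeneric("pcrTemplate", function(x) standardGeneric("pcrTemplate"))
#' @rdname accessors
#' @export
setGeneric("alleleName", function(x) standardGeneric("alleleName"))
#' @rdname accessors
#' @export
setGeneric("alleleLocus", function(x) standardGeneric("alleleLocus"))
#' @rdname accessors
#' @export
setGeneric("alleleVariants", function(x) standardGeneric("alleleVariants"))
#' @rdname accessors
#' @export
setGeneric("effectClass", function(x) standardGeneric("effectClass"))
#' @rdname accessors
#' @export
setGeneric("proteinLength", function(x) standardGeneric("proteinLength"))
#' @rdname accessors
#' @export
setGeneric("aaChanges", function(x) standardGeneric("aaChanges"))
#' @rdname accessors
#' @export
setGeneric("netLengthShift", function(x) standardGeneric("netLengthShift"))
#' @rdname accessors
#' @export
setGeneric("enzymeName", function(x) standardGeneric("enzymeName"))
#' @rdname accessors
#' @export
setGeneric("recognitionSite", function(x) standardGeneric("recognitionSite"))
#' @rdname accessors
#' @export
setGeneric("cutOffsets", function(x) standardGeneric("cutOffsets"))
#' @rdname accessors
#' @export
setGeneric("cutPositions", function(x) standardGeneric("cutPositions"))
#' @rdname accessors
#' @export
setGeneric("fragmentSizes", function(x) standardGeneric("fragmentSizes"))
#' @rdname accessors
#' @export
setGeneric("markerName", function(x) standardGeneric("markerName"))
#' @rdname accessors
#' @export
setGeneric("markerType", function(x) standardGeneric("markerType"))
#' @rdname accessors
#' @export
setGeneric("markerEnzyme", function(x) standardGeneric("markerEnzyme"))
#' @rdname accessors
#' @export
setGeneric("primerPair", function(x) standardGeneric("primerPair"))
#' @rdname accessors
#' @export
setGeneric("expectedProfiles", function(x) standardGeneric("expectedProfiles"))
#' @rdname accessors
#' @export
setGeneric("calledAllele", function(x) standardGeneric("calledAllele"))
#' @rdname accessors
#' @export
setGeneric("callNote", function(x) standardGeneric("callNote"))
#' @rdname accessors
#' @export
setGeneric("callEvidence", function(x) standardGeneric("callEvidence"))

setMethod("geneId", "ReferenceGene", function(x) x@id)
setMethod("cds", "ReferenceGene", function(x) x@cds)
setMethod("pcrTemplate", "ReferenceGene", function(x) paste0(x@cds, x@flank3))
setMethod("alleleName", "Allele", function(x) x@name)
setMethod("alleleLocus", "Allele", function(x) x@locus)
setMethod("alleleVariants", "Allele", function(x) x@variants)
setMethod("effectClass", "EffectReport", function(x) x@effectClass)
setMethod("proteinLength", "EffectReport", function(x) x@proteinLength)
setMethod("aaChanges", "EffectReport", function(x) x@aaChanges)
setMethod("netLengthShift", "EffectReport", function(x) x@netLengthShift)
setMethod("enzymeName", "RestrictionEnzyme", function(x) x@name)
setMethod("recognitionSite", "RestrictionEnzyme", function(x) x@site)
setMethod("cutOffsets", "RestrictionEnzyme",
          function(x) c(top = x@cutTop, bottom = x@cutBottom))
setMethod("cutPositions", "DigestResult", function(x) x@cutPositions)
setMethod("fragmentSizes", "DigestResult", function(x) x@fragments)
setMethod("markerName", "GeneMarker", function(x) x@name)
setMethod("markerType", "GeneMarker", function(x) x@markerType)
setMethod("markerEnzyme", "GeneMarker", function(x) x@enzyme)
setMethod("primerPair", "GeneMarker", function(x) x@primers)
setMethod("expectedProfiles", "GeneMarker", function(x) x@expectedProfiles)
setMethod("calledAllele", "GenotypeCall", function(x) x@allele)
setMethod("callNote", "GenotypeCall", function(x) x@note)
setMethod("callEvidence", "GenotypeCall", function(x) x@evidence)

setMethod("show", "ReferenceGene", function(object) {
  cat(sprintf("ReferenceGene '%s': %d-nt CDS", object@id, nchar(object@cds)))
  if (nzchar(object@flank3))
    cat(sprintf(" + %d-nt 3' flank", nchar(object@flank3)))
  cat(if (object@complete) " (complete ORF)\n" else "\n")
})

setMethod("show", "Variant", function(object) {
  desc <- switch(object@kind,
    substitution = sprintf("%s%d%s", object@ref, object@pos, object@alt),
    insertion = sprintf("ins %s after %d", object@alt, object@pos),
    deletion = sprintf("del %s at %d", object@ref, object@pos))
  cat(sprintf("Variant [%s] %s\n", object@kind, desc))
})

setMethod("show", "Allele", function(object) {
  cat(sprintf("Allele '%s' at locus '%s': %d variant(s)%s\n",
              object@name, object@locus, length(object@variants),
              if (length(object@variants) == 0L) " (reference allele)" else ""))
  for (v in object@variants) show(v)
})

setMethod("show", "EffectReport", function(object) {
  cat(sprintf("EffectReport: %s; protein %d aa; net shift %+d nt; %d aa change(s)\n",
              object@effectClass, object@proteinLength,
              object@netLengthShift, nrow(object@aaChanges)))
})

setMethod("show", "RestrictionEnzyme", function(object) {
  cut <- if (is.na(object@cutTop)) "site-presence only"
         else sprintf("cut top after %d / bottom after %d",
                      object@cutTop, object@cutBottom)
  cat(sprintf("RestrictionEnzyme %s: %s (%s)%s\n", object@name, object@site,
              cut, if (object@palindromic) " [palindromic]" else ""))
})

setMethod("show", "DigestResult", function(object) {
  cat(sprintf("DigestResult: %d cut(s) -> fragments [%s] of %d bp\n",
              length(object@cutPositions),
              paste(object@fragments, collapse = ", "),
              object@inputLength))
})

setMethod("show", "GeneMarker", function(object) {
  enz <- if (is.null(object@enzyme)) "-" else object@enzyme@name
  cat(sprintf("GeneMarker '%s' (%s/%s)\n", object@name, object@markerType, enz))
  for (a in names(object@expectedProfiles))
    cat(sprintf("  %-12s %s\n", a,
                paste(object@expectedProfiles[[a]], collapse = " + ")))
})

setMethod("show", "GenotypeCall", function(object) {
  cat(sprintf("GenotypeCall %s @ %s: %s%s\n",
              if (nzchar(object@accession)) object@accession else "<pattern>",
              object@locus, object@allele,
              if (nzchar(object@note)) paste0(" (", object@note, ")") else ""))
})
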