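#' Match an observed band pattern against a marker's expected profiles
#'
#' Returns every allele whose expected profile has the same band count and
#' every band within \code{tolerance} bp of the observed one. The 5-bp
#' default absorbs 1-bp allele-length differences (133 vs 132 bp products)
#' while keeping diagnostic gaps (133 vs 105 bp) unambiguous.
#'
#' @param observed integer vector of observed band sizes (bp)
#' @param marker a \linkS4class{GeneMarker} with expected profiles
#' @param tolerance per-band matching tolerance in bp
#' @return character vector of matching allele names (possibly empty; the
#'   caller decides NO_CALL)
#' @export
matchBandPattern <- function(observed, marker, tolerance = 5L) {
  stopifnot(is(marker, "GeneMarker"))
  profiles <- marker@expectedProfiles
  if (length(profiles) == 0L) stop("marker has no expected profiles")
  obs <- sort(as.integer(observed), decreasing = TRUE)
  hit <- vapply(profiles, function(p) {
    length(p) == length(obs) && all(abs(p - obs) <= tolerance)
  }, logical(1L))
  names(profiles)[hit]
}

# observed pattern "cut" when it matches a multi-band profile better than
# the single-band one; NA when it matches neither
patternIsCut <- function(observed, marker, tolerance = 5L) {
  hits <- matchBandPattern(observed, marker, tolerance)
  if (length(hits) == 0L) return(NA)
  any(vapply(marker@expectedProfiles[hits], length, integer(1L)) > 1L)
}

#' Call the GmF3'H allele from its three marker band patterns
#'
#' Implements the two-step decision tree: F3'H-ApoI uncut isolates
#' \{gmf3'h-a1, gmf3'h-a2\}, resolved by F3'H-MjaIV (cut, 105-bp
#' diagnostic fragment -> a1; uncut -> a2); ApoI cut isolates \{GmF3'H,
#' gmf3'h-b\}, resolved by F3'H-EcoNI (cut -> GmF3'H, uncut -> b). A
#' missing resolving pattern or a contradictory one yields NO_CALL with an
#' explanatory note, never an error.
#'
#' @param patterns named list of observed band-size vectors; recognised
#'   names are "F3'H-ApoI", "F3'H-MjaIV", "F3'H-EcoNI" (ASCII/prime
#'   aliases accepted)
#' @param markers named list of the three \linkS4class{GeneMarker}s (same
#'   names), e.g. from \code{\link{sojaMarkers}}
#' @param tolerance band-matching tolerance (bp)
#' @return a \linkS4class{GenotypeCall}
#' @export
classifyF3h <- function(patterns, markers, tolerance = 5L) {
  names(patterns) <- normalizeAlleleName(names(patterns))
  names(markers) <- normalizeAlleleName(names(markers))
  locus <- "GmF3'H"
  getPat <- function(nm) patterns[[nm]]
  apoi <- getPat("F3'H-ApoI")
  if (is.null(apoi))
    return(GenotypeCall(locus, "NO_CALL", "missing F3'H-ApoI pattern"))
  apoiCut <- patternIsCut(apoi, markers[["F3'H-ApoI"]], tolerance)
  if (is.na(apoiCut))
    return(GenotypeCall(locus, "NO_CALL",
                        "F3'H-ApoI pattern matches no expected profile"))
  ev <- list("F3'H-ApoI" = apoi)
  if (!apoiCut) {                    # {a1, a2}, resolve with MjaIV
    mja <- getPat("F3'H-MjaIV")
    if (is.null(mja))
      return(GenotypeCall(locus, "NO_CALL",
                          "ApoI uncut: need F3'H-MjaIV to resolve a1/a2",
                          ev))
    mjaCut <- patternIsCut(mja, markers[["F3'H-MjaIV"]], tolerance)
    ev[["F3'H-MjaIV"]] <- mja
    if (is.na(mjaCut))
      return(GenotypeCall(locus, "NO_CALL",
                          "F3'H-MjaIV pattern matches no expected profile",
                          ev))
    allele <- if (mjaCut) "gmf3'h-a1" else "gmf3'h-a2"
    return(GenotypeCall(locus, allele, "", ev))
  }
  econ <- getPat("F3'H-EcoNI")       # {WT, b}, resolve with EcoNI
  if (is.null(econ))
    return(GenotypeCall(locus, "NO_CALL",
                        "ApoI cut: need F3'H-EcoNI to resolve GmF3'H/b", ev))
  econCut <- patternIsCut(econ, markers[["F3'H-EcoNI"]], tolerance)
  ev[["F3'H-EcoNI"]] <- econ
  if (is.na(econCut))
    return(GenotypeCall(locus, "NO_CALL",
                        "F3'H-EcoNI pattern matches no expected profile", ev))
  allele <- if (econCut) "GmF3'H" else "gmf3'h-b"
  GenotypeCall(locus, allele, "", ev)
}

#' Call the GmF3'5'H allele from its two marker band patterns
#'
#' F3'5'H-In at ~395 bp (53-bp insertion) -> gmf3'5'h; at ~342 bp the call
#' is resolved by F3'5'H-HphI (cut, 225+117 -> GmF3'5'H-a; uncut ->
#' GmF3'5'H-b).
#'
#' @param patterns named list of observed band-size vectors ("F3'5'H-In",
#'   "F3'5'H-HphI")
#' @param markers named list of the two \linkS4class{GeneMarker}s
#' @param tolerance band-matching tolerance (bp)
#' @return a \linkS4class{GenotypeCall}
#' @export
classifyF35h <- function(patterns, markers, tolerance = 5L) {
  names(patterns) <- normalizeAlleleName(names(patterns))
  names(markers) <- normalizeAlleleName(names(markers))
  locus <- "GmF3'5'H"
  indel <- patterns[["F3'5'H-In"]]
  if (is.null(indel))
    return(GenotypeCall(locus, "NO_CALL", "missing F3'5'H-In pattern"))
  hits <- matchBandPattern(indel, markers[["F3'5'H-In"]], tolerance)
  ev <- list("F3'5'H-In" = indel)
  if (length(hits) == 0L)
    return(GenotypeCall(locus, "NO_CALL",
                        "F3'5'H-In pattern matches no expected profile", ev))
  if ("gmf3'5'h" %in% hits && length(hits) == 1L)
    return(GenotypeCall(locus, "gmf3'5'h", "", ev))
  hph <- patterns[["F3'5'H-HphI"]]
  if (is.null(hph))
    return(GenotypeCall(locus, "NO_CALL",
                        "In at 342 bp: need F3'5'H-HphI to resolve a/b", ev))
  hphCut <- patternIsCut(hph, markers[["F3'5'H-HphI"]], tolerance)
  ev[["F3'5'H-HphI"]] <- hph
  if (is.na(hphCut))
    return(GenotypeCall(locus, "NO_CALL",
                        "F3'5'H-HphI pattern matches no expected profile", ev))
  allele <- if (hphCut) "GmF3'5'H-a" else "GmF3'5'H-b"
  GenotypeCall(locus, allele, "", ev)
}

#' Genotype a whole accession panel by virtual assays
#'
#' For every accession, runs \code{\link{predictAssay}} for each marker on
#' the accession's allele template sequence at each locus and feeds the
#' band patterns to the locus decision trees. Identical templates are
#' memoised, so panels with few distinct alleles genotype quickly.
#' Per-accession failures are recorded as NO_CALL with a note; the run
#' continues.
#'
#' @param panel data.frame with at least an \code{accession} column plus
#'   \code{F3H_allele}/\code{F35H_allele} truth columns naming each
#'   accession's allele (as produced by \code{\link{makePanel}})
#' @param fixture a locus fixture from \code{\link{makeAlleleSuite}} (for
#'   allele template sequences)
#' @param markers named marker list from \code{\link{sojaMarkers}}
#' @param tolerance band-matching tolerance (bp)
#' @return data.frame: accession, F3H_call, F3H_note, F35H_call, F35H_note
#' @export
genotypePanel <- function(panel, fixture, markers, tolerance = 5L) {
  stopifnot(is.data.frame(panel), "accession" %in% names(panel))
  panel$F3H_allele <- normalizeAlleleName(panel$F3H_allele)
  panel$F35H_allele <- normalizeAlleleName(panel$F35H_allele)
  names(markers) <- normalizeAlleleName(names(markers))
  f3hMarkers <- markers[c("F3'H-ApoI", "F3'H-MjaIV", "F3'H-EcoNI")]
  f35hMarkers <- markers[c("F3'5'H-In", "F3'5'H-HphI")]
  cacheF3h <- new.env(parent = emptyenv())
  cacheF35h <- new.env(parent = emptyenv())

  callLocus <- function(alleleName, templates, markerSet, classifier, cache) {
    if (!is.null(cache[[alleleName]])) return(cache[[alleleName]])
    res <- tryCatch({
      tpl <- templates[[alleleName]]
      if (is.null(tpl)) stop("unknown allele '", alleleName, "'")
      pats <- lapply(markerSet, function(m)
        as.integer(predictAssay(m, tpl)))
      classifier(pats, markerSet, tolerance)
    }, error = function(e)
      GenotypeCall("?", "NO_CALL", conditionMessage(e)))
    cache[[alleleName]] <- res
    res
  }

  n <- nrow(panel)
  out <- data.frame(accession = panel$accession,
                    F3H_call = character(n), F3H_note = character(n),
                    F35H_call = character(n), F35H_note = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    c1 <- callLocus(panel$F3H_allele[i], fixture$f3h$templates,
                    f3hMarkers, classifyF3h, cacheF3h)
    c2 <- callLocus(panel$F35H_allele[i], fixture$f35h$templates,
                    f35hMarkers, classifyF35h, cacheF35h)
    out$F3H_call[i] <- c1@allele
    out$F3H_note[i] <- c1@note
    out$F35H_call[i] <- c2@allele
    out$F35H_note[i] <- c2@note
  }
  out
}
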