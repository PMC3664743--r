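#' Design constraints for marker construction
#'
#' @param primerLength allowed primer length range (nt)
#' @param productRange allowed PCR product size range (bp)
#' @param minBandSeparation smallest band-size difference resolvable on the
#'   gel (bp); the 20-bp default is a proxy for 2\% agarose resolution
#' @param maxMismatches maximum designed mismatches on a dCAPS forward
#'   primer
#' @param min3primeAnchor number of primer 3'-terminal bases required to
#'   match the template exactly (0 allows mismatches at the very 3' end,
#'   the classical dCAPS geometry)
#' @return a list of class \code{DesignConstraints}
#' @export
designConstraints <- function(primerLength = c(18L, 27L),
                              productRange = c(80L, 600L),
                              minBandSeparation = 20L,
                              maxMismatches = 3L,
                              min3primeAnchor = 0L) {
  stopifnot(all(primerLength > 0L), all(productRange > 0L),
            minBandSeparation > 0L, maxMismatches >= 0L,
            min3primeAnchor >= 0L)
  structure(list(primerLength = as.integer(primerLength),
                 productRange = as.integer(productRange),
                 minBandSeparation = as.integer(minBandSeparation),
                 maxMismatches = as.integer(maxMismatches),
                 min3primeAnchor = as.integer(min3primeAnchor)),
            class = "DesignConstraints")
}

# 1-based start positions where `primer` binds `template`, allowing
# mismatches only at the declared offsets (overlapping hits included)
primerBindingSites <- function(template, primer, mismatchOffsets = integer()) {
  chars <- strsplit(primer, "")[[1L]]
  if (length(mismatchOffsets)) chars[mismatchOffsets] <- "."
  pat <- paste0("(?=", paste(chars, collapse = ""), ")")
  m <- gregexpr(pat, template, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m)
}

#' Virtual PCR: amplify a template with a primer pair
#'
#' Both primers must bind the template exactly once; binding is exact
#' except at the forward primer's declared designed-mismatch offsets. The
#' returned amplicon carries the primer sequences (dCAPS semantics: the
#' product inherits primer mismatches, which is what completes an
#' engineered recognition site).
#'
#' @param template DNA string
#' @param primers a \linkS4class{PrimerPair}
#' @return amplicon string, with attributes \code{fwd_start} and
#'   \code{rev_end} (template coordinates)
#' @export
virtualPcr <- function(template, primers) {
  stopifnot(is(primers, "PrimerPair"))
  template <- toupper(as.character(template))
  fwd <- primers@forward
  revTop <- revComp(primers@reverse)
  fpos <- primerBindingSites(template, fwd, primers@mismatches$offset)
  rpos <- primerBindingSites(template, revTop)
  if (length(fpos) == 0L || length(rpos) == 0L)
    stop("no amplification: ",
         if (length(fpos) == 0L) "forward" else "reverse",
         " primer does not bind the template")
  # keep only orientations that give a product
  rend <- rpos + nchar(revTop) - 1L
  pairs <- expand.grid(f = fpos, r = rend)
  pairs <- pairs[pairs$r - pairs$f + 1L >= nchar(fwd) + nchar(revTop), ,
                 drop = FALSE]
  if (nrow(pairs) == 0L)
    stop("no amplification: primers do not face each other")
  if (nrow(pairs) > 1L)
    stop("ambiguous amplification: ", nrow(pairs), " primer configurations")
  fwdStart <- pairs$f[1L]
  revEnd <- pairs$r[1L]
  amp <- substr(template, fwdStart, revEnd)
  substr(amp, 1L, nchar(fwd)) <- fwd
  substr(amp, nchar(amp) - nchar(revTop) + 1L, nchar(amp)) <- revTop
  attr(amp, "fwd_start") <- fwdStart
  attr(amp, "rev_end") <- revEnd
  amp
}

#' Predict the gel band profile of a marker on an allele sequence
#'
#' Runs \code{\link{virtualPcr}} and, for CAPS/dCAPS markers, digests the
#' amplicon with the marker's enzyme. Band sizes are returned in
#' descending order; bands closer than \code{minBandSeparation} are
#' flagged as co-migrating.
#'
#' @param marker a \linkS4class{GeneMarker}
#' @param alleleSeq template DNA string for the allele
#' @param minBandSeparation gel resolution used for the co-migration flag
#' @return integer vector of band sizes (descending); attribute
#'   \code{comigrating} is TRUE when two bands would not be resolved
#' @export
predictAssay <- function(marker, alleleSeq, minBandSeparation = 20L) {
  stopifnot(is(marker, "GeneMarker"))
  amp <- virtualPcr(alleleSeq, marker@primers)
  bands <- if (is.null(marker@enzyme)) nchar(amp)
           else fragmentSizes(digestSequence(as.character(amp), marker@enzyme))
  bands <- sort(as.integer(bands), decreasing = TRUE)
  attr(bands, "comigrating") <- length(bands) > 1L &&
    any(abs(diff(bands)) < minBandSeparation)
  bands
}

#' Are two band profiles distinguishable on a gel?
#'
#' Profiles with the same band count are distinguishable when some band
#' differs by at least \code{minSep}; with different band counts, when
#' some band of one profile is at least \code{minSep} away from every band
#' of the other.
#'
#' @param a,b integer vectors of band sizes
#' @param minSep minimum resolvable band-size difference (bp)
#' @return logical
#' @export
profilesDistinguishable <- function(a, b, minSep = 20L) {
  a <- sort(as.integer(a)); b <- sort(as.integer(b))
  if (length(a) == length(b)) return(any(abs(a - b) >= minSep))
  nearest <- function(x, y) vapply(x, function(v) min(abs(v - y)), numeric(1L))
  max(c(nearest(a, b), nearest(b, a))) >= minSep
}

# --- internal design helpers -----------------------------------------------

# check that altSeq is refSeq with exactly `variant` applied
checkVariantPair <- function(refSeq, altSeq, variant) {
  applied <- applyVariants(refSeq, list(variant))
  if (applied != altSeq)
    stop("ref/alt sequences do not differ by exactly the given variant")
  invisible(TRUE)
}

# does `base` satisfy the IUPAC letter `code`?
iupacMatchesBase <- function(code, base) base %in% IUPAC_EXPANSION[[code]]

# sites (start positions, + strand frame) within [from, to] of seq
sitesInWindow <- function(seq, enzyme, from, to) {
  s <- findSites(seq, enzyme)
  s[s$position >= from & s$position <= to, , drop = FALSE]
}

# amplicon primers taken verbatim from the template ends
flankingPrimers <- function(seq, start, end, primerLen = 20L) {
  PrimerPair(substr(seq, start, start + primerLen - 1L),
             revComp(substr(seq, end - primerLen + 1L, end)))
}

#' Design CAPS markers discriminating two alleles at a variant
#'
#' Searches the enzyme table for recognition sites that overlap the
#' variant in exactly one of the two alleles (a natural cut-site gained or
#' lost), then places an amplicon around the diagnostic site such that the
#' per-allele digestion profiles are distinguishable at the gel
#' resolution. Candidates are sorted by fewest non-diagnostic cut sites,
#' then by product size, then by enzyme name.
#'
#' @param refSeq,altSeq the two allele sequences (differing only by
#'   \code{variant})
#' @param variant the discriminating \linkS4class{Variant}, in
#'   \code{refSeq} coordinates
#' @param enzymes list of \linkS4class{RestrictionEnzyme} (default
#'   \code{\link{defaultEnzymes}})
#' @param constraints a \code{\link{designConstraints}} list
#' @param maxCandidates cap on returned markers
#' @return list of \linkS4class{GeneMarker} (possibly empty); each carries
#'   \code{expectedProfiles} for "ref" and "alt"
#' @export
designCaps <- function(refSeq, altSeq, variant,
                       enzymes = defaultEnzymes(),
                       constraints = designConstraints(),
                       maxCandidates = 5L) {
  refSeq <- toupper(as.character(refSeq))
  altSeq <- toupper(as.character(altSeq))
  if (refSeq == altSeq) return(list())
  checkVariantPair(refSeq, altSeq, variant)
  shift <- nchar(altSeq) - nchar(refSeq)
  out <- list()
  for (enz in enzymes) {
    if (is.na(enz@cutTop)) next
    L <- nchar(enz@site)
    from <- max(1L, variant@pos - L - 2L)
    toR <- min(nchar(refSeq), variant@pos + nchar(variant@ref) + L + 2L)
    toA <- min(nchar(altSeq), variant@pos + nchar(variant@alt) + L + 2L)
    nRef <- nrow(sitesInWindow(refSeq, enz, from, toR))
    nAlt <- nrow(sitesInWindow(altSeq, enz, from, toA))
    if (nRef == nAlt) next            # not diagnostic at this variant
    cutAllele <- if (nRef > nAlt) "ref" else "alt"
    cutSeq <- if (cutAllele == "ref") refSeq else altSeq
    wTo <- if (cutAllele == "ref") toR else toA
    sitePos <- sitesInWindow(cutSeq, enz, from, wTo)$position[1L]
    cand <- capsAmplicons(refSeq, altSeq, enz, sitePos, cutAllele,
                          constraints)
    out <- c(out, cand)
  }
  if (length(out) == 0L) return(out)
  score <- vapply(out, function(m) {
    pr <- m@expectedProfiles
    extra <- max(length(pr$ref), length(pr$alt)) - 2L
    size <- max(unlist(pr))
    extra * 1e6 + size
  }, numeric(1L))
  nm <- vapply(out, function(m) m@name, character(1L))
  out <- out[order(score, nm)]
  head(out, maxCandidates)
}

# enumerate amplicon placements around a diagnostic site and keep those
# whose two profiles are gel-distinguishable
capsAmplicons <- function(refSeq, altSeq, enz, sitePos, cutAllele,
                          constraints) {
  primerLen <- constraints$primerLength[1L] + 2L
  minSep <- constraints$minBandSeparation
  sizes <- unique(pmin(constraints$productRange[2L],
                       pmax(constraints$productRange[1L],
                            c(150L, 250L, 350L, 500L))))
  offsets <- c(0.25, 0.4, 0.6, 0.75)
  cutSeq <- if (cutAllele == "ref") refSeq else altSeq
  othSeq <- if (cutAllele == "ref") altSeq else refSeq
  res <- list()
  for (size in sizes) {
    for (fr in offsets) {
      start <- as.integer(sitePos - round(size * fr))
      end <- start + size - 1L
      if (start < 1L || end > min(nchar(refSeq), nchar(altSeq))) next
      primers <- flankingPrimers(cutSeq, start, end, primerLen)
      bandsCut <- tryCatch(
        fragmentSizes(digestSequence(
          as.character(virtualPcr(cutSeq, primers)), enz)),
        error = function(e) NULL)
      bandsOth <- tryCatch(
        fragmentSizes(digestSequence(
          as.character(virtualPcr(othSeq, primers)), enz)),
        error = function(e) NULL)
      if (is.null(bandsCut) || is.null(bandsOth)) next
      if (length(bandsCut) < 2L) next      # diagnostic site must cut
      if (!profilesDistinguishable(bandsCut, bandsOth, minSep)) next
      profiles <- list(sort(bandsCut, decreasing = TRUE),
                       sort(bandsOth, decreasing = TRUE))
      names(profiles) <- c(cutAllele, setdiff(c("ref", "alt"), cutAllele))
      res[[length(res) + 1L]] <- GeneMarker(
        name = sprintf("%s-CAPS-%d", enz@name, size),
        markerType = "CAPS", primers = primers, enzyme = enz,
        expectedProfiles = profiles[c("ref", "alt")])
    }
  }
  # deduplicate identical profile geometries
  key <- vapply(res, function(m)
    paste(unlist(m@expectedProfiles), collapse = ","), character(1L))
  res[!duplicated(key)]
}

#' Design dCAPS markers: engineer a recognition site via primer mismatches
#'
#' When no natural site discriminates the alleles, a recognition site is
#' completed by mismatched bases in the forward-primer tail such that the
#' site forms in exactly one allele; the variant base itself must come
#' from the template (downstream of the primer 3' end), never from the
#' primer. For every enzyme and every alignment of its site covering the
#' variant, the placement needing the fewest mismatches (at most
#' \code{maxMismatches}) is kept.
#'
#' By default the search defers to CAPS: if any enzyme in the table
#' already discriminates naturally at the variant, an empty list is
#' returned unless \code{force = TRUE}.
#'
#' @inheritParams designCaps
#' @param force design dCAPS even where a natural CAPS site exists
#' @param side "forward" (canonical, mismatches on the forward primer) or
#'   "reverse" (design against the reverse-complement template)
#' @return list of \linkS4class{GeneMarker}, sorted by mismatch count,
#'   product size, enzyme name; each carries a \code{mismatch_count}
#'   attribute
#' @export
designDcaps <- function(refSeq, altSeq, variant,
                        enzymes = defaultEnzymes(),
                        constraints = designConstraints(),
                        force = FALSE, side = c("forward", "reverse"),
                        maxCandidates = 5L) {
  side <- match.arg(side)
  refSeq <- toupper(as.character(refSeq))
  altSeq <- toupper(as.character(altSeq))
  if (refSeq == altSeq) return(list())
  checkVariantPair(refSeq, altSeq, variant)
  if (side == "reverse") {
    rc <- reverseComplementPair(refSeq, altSeq, variant)
    return(designDcaps(rc$ref, rc$alt, rc$variant, enzymes, constraints,
                       force = force, side = "forward",
                       maxCandidates = maxCandidates))
  }
  if (!force && length(designCaps(refSeq, altSeq, variant, enzymes,
                                  constraints, maxCandidates = 1L)))
    return(list())

  out <- list()
  for (enz in enzymes) {
    if (is.na(enz@cutTop)) next
    cand <- dcapsPlacements(refSeq, altSeq, variant, enz, constraints)
    out <- c(out, cand)
  }
  if (length(out) == 0L) return(out)
  mm <- vapply(out, function(m) attr(m, "mismatch_count"), integer(1L))
  size <- vapply(out, function(m) max(unlist(m@expectedProfiles)), numeric(1L))
  nm <- vapply(out, function(m) m@enzyme@name, character(1L))
  out <- out[order(mm, size, nm)]
  head(out, maxCandidates)
}

# all valid primer-tail site placements for one enzyme; returns markers
dcapsPlacements <- function(refSeq, altSeq, variant, enz, constraints) {
  L <- nchar(enz@site)
  siteLetters <- strsplit(enz@site, "")[[1L]]
  minSep <- constraints$minBandSeparation
  vstart <- if (variant@kind == "insertion") variant@pos + 1L else variant@pos
  res <- list()
  # site occupies ref positions [w, w+L-1]; primer 3' end at e inside the
  # site; template part (e+1 .. w+L-1) must contain the first
  # variant-affected base so the allele state is read from the template
  for (w in seq(max(1L, vstart - L + 1L), vstart)) {
    if (w + L - 1L > min(nchar(refSeq), nchar(altSeq))) next
    eMax <- min(vstart - 1L, w + L - 2L)
    if (eMax < w) next
    for (e in seq(w, eMax)) {
      primerLen <- max(constraints$primerLength[1L], e - w + 1L + 15L)
      pstart <- e - primerLen + 1L
      if (pstart < 1L) next
      # build the primer: template bases, with site letters imposed over
      # the tail [w..e]; count mismatches against the template
      tpl <- strsplit(substr(refSeq, pstart, e), "")[[1L]]
      nMM <- 0L
      for (j in seq(w, e)) {
        k <- j - pstart + 1L
        code <- siteLetters[j - w + 1L]
        if (!iupacMatchesBase(code, tpl[k])) {
          tpl[k] <- IUPAC_EXPANSION[[code]][1L]
          nMM <- nMM + 1L
        }
      }
      if (nMM == 0L) next                      # natural site, CAPS territory
      if (nMM > constraints$maxMismatches) next
      if (constraints$min3primeAnchor > 0L) {
        anchor <- seq(e - constraints$min3primeAnchor + 1L, e)
        mmPos <- pstart - 1L +
          which(tpl != strsplit(substr(refSeq, pstart, e), "")[[1L]])
        if (any(mmPos %in% anchor)) next
      }
      primerFwd <- paste(tpl, collapse = "")
      mmOffsets <- which(strsplit(primerFwd, "")[[1L]] !=
                           strsplit(substr(refSeq, pstart, e), "")[[1L]])
      mmDf <- data.frame(
        offset = as.integer(mmOffsets),
        template_base = strsplit(substr(refSeq, pstart, e), "")[[1L]][mmOffsets],
        primer_base = strsplit(primerFwd, "")[[1L]][mmOffsets],
        stringsAsFactors = FALSE)
      # product end: keep the product compact (classical dCAPS gel window)
      prodLen <- min(max(constraints$productRange[1L], primerLen + L + 60L),
                     constraints$productRange[2L])
      pend <- min(pstart + prodLen - 1L, nchar(refSeq), nchar(altSeq))
      if (pend < w + L - 1L) next          # engineered site must fit
      if (pend - 19L <= e) next            # room for the reverse primer
      primers <- PrimerPair(primerFwd,
                            revComp(substr(refSeq, pend - 19L, pend)),
                            mismatches = mmDf)
      bandsRef <- tryCatch(predictAssayRaw(refSeq, primers, enz),
                           error = function(e) NULL)
      bandsAlt <- tryCatch(predictAssayRaw(altSeq, primers, enz),
                           error = function(e) NULL)
      if (is.null(bandsRef) || is.null(bandsAlt)) next
      cutRef <- length(bandsRef) > 1L
      cutAlt <- length(bandsAlt) > 1L
      if (cutRef == cutAlt) next               # must cut exactly one allele
      if (!profilesDistinguishable(bandsRef, bandsAlt, minSep)) next
      m <- GeneMarker(
        name = sprintf("%s-dCAPS-%dmm", enz@name, nMM),
        markerType = "dCAPS", primers = primers, enzyme = enz,
        expectedProfiles = list(ref = bandsRef, alt = bandsAlt))
      attr(m, "mismatch_count") <- nMM
      res[[length(res) + 1L]] <- m
    }
  }
  res
}

predictAssayRaw <- function(seq, primers, enz) {
  amp <- virtualPcr(seq, primers)
  sort(fragmentSizes(digestSequence(as.character(amp), enz)),
       decreasing = TRUE)
}

# map an allele pair and its variant onto the reverse-complement strand
reverseComplementPair <- function(refSeq, altSeq, variant) {
  n <- nchar(refSeq)
  v <- switch(variant@kind,
    substitution = Variant("substitution",
                           n - variant@pos - nchar(variant@ref) + 2L,
                           ref = revComp(variant@ref),
                           alt = revComp(variant@alt)),
    insertion = Variant("insertion", n - variant@pos,
                        alt = revComp(variant@alt)),
    deletion = Variant("deletion",
                       n - variant@pos - nchar(variant@ref) + 2L,
                       ref = revComp(variant@ref)))
  list(ref = revComp(refSeq), alt = revComp(altSeq), variant = v)
}

#' Design an InDel marker from a length polymorphism
#'
#' Places flanking primers around an insertion/deletion so the two PCR
#' products differ by exactly the indel length; refused when the length
#' difference is below the gel resolution.
#'
#' @inheritParams designCaps
#' @param variant an insertion or deletion \linkS4class{Variant}
#' @return a single \linkS4class{GeneMarker} of type "InDel"
#' @export
designIndel <- function(refSeq, altSeq, variant,
                        constraints = designConstraints()) {
  refSeq <- toupper(as.character(refSeq))
  altSeq <- toupper(as.character(altSeq))
  if (!variant@kind %in% c("insertion", "deletion"))
    stop("InDel markers require an insertion or deletion variant")
  checkVariantPair(refSeq, altSeq, variant)
  indelLen <- abs(nchar(altSeq) - nchar(refSeq))
  if (indelLen < constraints$minBandSeparation)
    stop("size-resolution error: ", indelLen,
         "-bp difference is below the ", constraints$minBandSeparation,
         "-bp gel resolution")
  span <- variantSpan(variant)
  margin <- 40L
  start <- max(1L, as.integer(floor(span[1L])) - margin)
  end <- min(nchar(refSeq),
             as.integer(ceiling(span[2L])) + nchar(variant@ref) + margin)
  primerLen <- constraints$primerLength[1L]
  if (start + primerLen - 1L >= span[1L] || end - primerLen + 1L <= span[2L])
    stop("cannot place primers flanking the indel")
  primers <- flankingPrimers(refSeq, start, end, primerLen)
  refLen <- end - start + 1L
  altLen <- refLen + (nchar(altSeq) - nchar(refSeq))
  GeneMarker(name = sprintf("InDel-%dbp", indelLen), markerType = "InDel",
             primers = primers,
             expectedProfiles = list(ref = refLen, alt = altLen))
}
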