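# Seeded generators: reference genes, the two synthetic flavonoid
# hydroxylase loci with their seven alleles and five markers, and
# accession panels with the survey's statistical structure.

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE)[
  Biostrings::GENETIC_CODE != "*"], character())

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

# random string of sense codons with an approximate GC target
randomSenseCodons <- function(nCodons, gc = 0.5) {
  gcw <- vapply(strsplit(SENSE_CODONS, ""), function(ch)
    sum(ch %in% c("G", "C")), numeric(1L))
  w <- exp(gcw * log(gc / (1 - gc) + 1e-9))
  paste(sample(SENSE_CODONS, nCodons, replace = TRUE, prob = w),
        collapse = "")
}

#' Generate a random complete reference CDS
#'
#' Builds a CDS of \code{lengthCodons} sense codons starting with ATG plus
#' one terminal stop codon; deterministic for a given seed.
#'
#' @param lengthCodons number of residues (>= 50)
#' @param gc approximate GC content target
#' @param seed integer seed (NULL = use current RNG state)
#' @param id gene identifier
#' @return a \linkS4class{ReferenceGene} of length
#'   \code{3 * (lengthCodons + 1)} nt
#' @examples
#' ref <- makeReference(513, gc = 0.42, seed = 1)
#' nchar(cds(ref))   # 1542
#' @export
makeReference <- function(lengthCodons, gc = 0.5, seed = NULL,
                          id = "synthetic") {
  if (lengthCodons < 50L)
    stop("reference CDS must have at least 50 codons")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  withSeed(seed, {
    body <- randomSenseCodons(lengthCodons - 1L, gc)
    ReferenceGene(id, paste0("ATG", body, "TAA"))
  })
}

# --- constrained construction of the two soja loci -------------------------

STOP_TRIPLETS <- c("TAA", "TAG", "TGA")

hasStopAt <- function(seq, starts) {
  substring(seq, starts, starts + 2L) %in% STOP_TRIPLETS
}

# replace character at position i
setBase <- function(seq, i, base) {
  substr(seq, i, i) <- base
  seq
}

# fix stop codons on the -1 frameshift lattice (triplet starts ~ 2 mod 3)
# by rewriting the triplet's third base, which is the first base of a
# native codon: setting it to "C" cannot create a stop in either frame
scrubShiftedStops <- function(seq, from, to, fixedMask) {
  starts <- seq.int(from, to - 2L, by = 3L)
  for (p in starts[hasStopAt(seq, starts)]) {
    if (fixedMask[p + 2L]) next   # fixed-region triplets are pre-verified
    seq <- setBase(seq, p + 2L, "C")
  }
  seq
}

# try to break an unwanted recognition-site match by mutating one free
# base without creating a stop in the native frame or the shifted lattice
breakSiteAt <- function(seq, start, len, fixedMask, shiftRegion = NULL) {
  for (q in seq(start, start + len - 1L)) {
    if (q > length(fixedMask) || fixedMask[q]) next
    for (b in setdiff(DNA_BASES, substr(seq, q, q))) {
      cand <- setBase(seq, q, b)
      codonStart <- q - (q - 1L) %% 3L
      if (hasStopAt(cand, codonStart)) next
      if (!is.null(shiftRegion) && q >= shiftRegion[1L] && q <= shiftRegion[2L]) {
        p <- q - (q - shiftRegion[1L]) %% 3L
        if (p + 2L <= nchar(cand) && hasStopAt(cand, p)) next
      }
      return(cand)
    }
  }
  NULL
}

# count matches of an enzyme's site family in a plain string
countSites <- function(seq, enzyme) nrow(findSites(seq, enzyme))

# impose a named character vector of fixed bases (names = positions)
imposeBases <- function(seq, fixed) {
  for (i in seq_along(fixed))
    seq <- setBase(seq, as.integer(names(fixed)[i]), fixed[[i]])
  seq
}

fixedVector <- function(...) {
  parts <- list(...)
  out <- character()
  for (p in parts) {
    bases <- strsplit(p$bases, "")[[1L]]
    names(bases) <- seq(p$at, p$at + length(bases) - 1L)
    out <- c(out, bases)
  }
  out
}

# GmF3'H synthetic locus: 1542-nt CDS with the engineered neighbourhoods
# of the three frameshift/indel variants and the ApoI/MjaIV/EcoNI assay
# geometries (see the methods vignette for the coordinate derivation)
buildF3hLocus <- function(maxTries = 60L) {
  fixed <- fixedVector(
    list(at = 1L, bases = "ATG"),
    # codons 322-326: N322 context, MjaIV template half-site (968 A, 969 C),
    # ApoI site GAATTC at 971-976 with the deletable A at 973
    list(at = 964L, bases = "AATCACCGAATTC"),
    # EcoNI dCAPS neighbourhood: natural C at 1160, mismatch target at
    # 1161, TCC codon, the deletable C at 1164, then the AGG site tail
    list(at = 1160L, bases = "CATCCGCAAGG"),
    # shared -1-frame stop giving both frameshift alleles a 394-aa product
    list(at = 1184L, bases = "TAA"),
    list(at = 1540L, bases = "TAA"))
  fixedMask <- rep(FALSE, 1542L)
  fixedMask[as.integer(names(fixed))] <- TRUE
  shiftRegion <- c(974L, 1186L)

  enz <- defaultEnzymes()
  for (try in seq_len(maxTries)) {
    seq <- paste0("ATG", randomSenseCodons(512L, gc = 0.42), "TAA")
    seq <- imposeBases(seq, fixed)
    seq <- scrubShiftedStops(seq, shiftRegion[1L], 1183L, fixedMask)
    ok <- TRUE
    for (round in seq_len(200L)) {
      viol <- f3hViolations(seq, enz)
      if (is.null(viol)) break
      fixedSeq <- breakSiteAt(seq, viol[1L], viol[2L], fixedMask, shiftRegion)
      if (is.null(fixedSeq)) { ok <- FALSE; break }
      seq <- fixedSeq
    }
    if (ok && is.null(f3hViolations(seq, enz))) return(seq)
  }
  stop("could not satisfy GmF3'H locus constraints after ", maxTries,
       " attempts")
}

# first unwanted site (start, length) in the assay windows, or NULL
f3hViolations <- function(seq, enz) {
  checks <- list(
    # ApoI amplicon 767..1305 must contain exactly the 971 site
    list(enzyme = enz$ApoI, window = c(767L, 1305L), keep = 971L),
    # no natural MjaIV site in the MjaIV amplicon 939..1071
    list(enzyme = enz$MjaIV, window = c(939L, 1071L), keep = NA),
    # no natural EcoNI site in the EcoNI amplicon 1141..1307
    list(enzyme = enz$EcoNI, window = c(1141L, 1307L), keep = NA))
  for (ck in checks) {
    s <- findSites(substr(seq, ck$window[1L], ck$window[2L]), ck$enzyme)
    pos <- s$position + ck$window[1L] - 1L
    bad <- if (is.na(ck$keep)) pos else setdiff(pos, ck$keep)
    if (length(bad))
      return(c(bad[1L], nchar(ck$enzyme@site)))
    if (!is.na(ck$keep) && !(ck$keep %in% pos))
      stop("engineered ApoI site lost during scrubbing")   # cannot happen
  }
  NULL
}

# GmF3'5'H synthetic locus: 1530-nt CDS + 130-nt 3' flank; HphI site at
# 1422 (destroyed by the T1424A substitution, V475E), synonymous SNP
# codons at 1057 and 1507, and a 53-bp insertion cassette after 1352
# engineered to truncate the product at 467 residues
buildF35hLocus <- function(maxTries = 60L) {
  fixed <- fixedVector(
    list(at = 1L, bases = "ATG"),
    list(at = 1057L, bases = "GCC"),   # codon 353, C1059A synonymous
    list(at = 1420L, bases = "CA"),    # keep codon 474 stop-free
    list(at = 1422L, bases = "GGTGA"), # HphI site; codon 475 = GTG (V)
    list(at = 1507L, bases = "GCC"),   # codon 503, C1509T synonymous
    list(at = 1528L, bases = "TAA"))
  fixedMask <- rep(FALSE, 1660L)
  fixedMask[as.integer(names(fixed))] <- TRUE

  enz <- defaultEnzymes()
  for (try in seq_len(maxTries)) {
    cdsSeq <- paste0("ATG", randomSenseCodons(508L, gc = 0.42), "TAA")
    flank <- randomDnaString(130L, gc = 0.42)
    seq <- imposeBases(paste0(cdsSeq, flank), fixed)
    ok <- TRUE
    for (round in seq_len(200L)) {
      viol <- f35hViolations(seq, enz)
      if (is.null(viol)) break
      fixedSeq <- breakSiteAt(seq, viol[1L], viol[2L], fixedMask)
      if (is.null(fixedSeq)) { ok <- FALSE; break }
      seq <- fixedSeq
    }
    if (ok && is.null(f35hViolations(seq, enz))) return(seq)
  }
  stop("could not satisfy GmF3'5'H locus constraints after ", maxTries,
       " attempts")
}

f35hViolations <- function(seq, enz) {
  # HphI amplicon 1210..1551 must contain exactly the 1422 site
  s <- findSites(substr(seq, 1210L, 1551L), enz$HphI)
  pos <- s$position + 1209L
  bad <- setdiff(pos, 1422L)
  if (length(bad)) return(c(bad[1L], nchar(enz$HphI@site)))
  if (!(1422L %in% pos)) stop("engineered HphI site lost during scrubbing")
  NULL
}

# the 53-bp insertion cassette: frame inside the cassette is stop-free
# until the TAA at cassette offsets 50..52, which lands in codon 468 of
# the shifted product
makeInsertionCassette <- function() {
  paste0("C", randomSenseCodons(16L, gc = 0.42), "TAA",
         sample(DNA_BASES, 1L))
}

#' Build the synthetic GmF3'H / GmF3'5'H loci with their seven alleles
#'
#' Constructs, deterministically for a given seed, two reference loci that
#' reproduce the allele architecture of the soybean flavonoid hydroxylase
#' genes: GmF3'H (1542-nt CDS, 513 residues) with gmf3'h-a1 (del A973,
#' frameshift, 394-aa product), gmf3'h-a2 (ins A after 965 + del A973,
#' in-frame, local amino-acid changes only) and gmf3'h-b (del C1164,
#' frameshift, 394-aa product); and GmF3'5'H (1530-nt CDS, 509 residues,
#' plus a 130-nt 3' flank on the PCR template) with GmF3'5'H-b (C1059A,
#' T1424A giving V475E, C1509T) and gmf3'5'h (53-bp insertion after 1352,
#' truncating at 467 residues). Recognition-site neighbourhoods are
#' engineered (and assay windows scrubbed of confounding sites) so that
#' the five gene-tagged markers of \code{\link{sojaMarkers}} are
#' designable with their canonical band profiles.
#'
#' Every allele is verified with \code{\link{classifyEffect}} to land in
#' its intended effect class before the fixture is returned.
#'
#' @param seed integer seed; the fixture is byte-reproducible per seed
#' @param maxTries bounded retries of the whole constraint-satisfaction
#'   construction before giving up with diagnostics
#' @return list with components \code{f3h} and \code{f35h}, each holding
#'   \code{reference} (\linkS4class{ReferenceGene}), \code{alleles}
#'   (named list of \linkS4class{Allele}) and \code{templates} (named list
#'   of PCR template strings per allele)
#' @export
makeAlleleSuite <- function(seed = 1L, maxTries = 25L) {
  withSeed(seed, {
    lastErr <- NULL
    for (try in seq_len(maxTries)) {
      fixture <- tryCatch({
        fx <- buildSuiteOnce()
        verifyAlleleSuite(fx)
        buildMarkerSet(fx, verify = TRUE)   # assay geometry must hold too
        fx
      }, error = function(e) { lastErr <<- e; NULL })
      if (!is.null(fixture)) return(fixture)
    }
    stop("allele-suite construction failed after ", maxTries,
         " attempts; last error: ", conditionMessage(lastErr))
  })
}

# one unverified construction attempt (advances the RNG stream)
buildSuiteOnce <- function() {
  f3hSeq <- buildF3hLocus()
  f3hRef <- ReferenceGene("GmF3'H", f3hSeq)
  f3hAlleles <- list(
    "GmF3'H" = Allele("GmF3'H", "GmF3'H"),
    "gmf3'h-a1" = Allele("gmf3'h-a1", "GmF3'H",
                         list(Variant("deletion", 973L, ref = "A"))),
    "gmf3'h-a2" = Allele("gmf3'h-a2", "GmF3'H",
                         list(Variant("insertion", 965L, alt = "A"),
                              Variant("deletion", 973L, ref = "A"))),
    "gmf3'h-b" = Allele("gmf3'h-b", "GmF3'H",
                        list(Variant("deletion", 1164L, ref = "C"))))

  f35hSeq <- buildF35hLocus()
  f35hCds <- substr(f35hSeq, 1L, 1530L)
  f35hFlank <- substring(f35hSeq, 1531L)
  f35hRef <- ReferenceGene("GmF3'5'H", f35hCds, flank3 = f35hFlank)
  cassette <- makeInsertionCassette()
  f35hAlleles <- list(
    "GmF3'5'H-a" = Allele("GmF3'5'H-a", "GmF3'5'H"),
    "GmF3'5'H-b" = Allele("GmF3'5'H-b", "GmF3'5'H",
                          list(Variant("substitution", 1059L, "C", "A"),
                               Variant("substitution", 1424L, "T", "A"),
                               Variant("substitution", 1509L, "C", "T"))),
    "gmf3'5'h" = Allele("gmf3'5'h", "GmF3'5'H",
                        list(Variant("insertion", 1352L, alt = cassette))))

  list(
    f3h = list(reference = f3hRef, alleles = f3hAlleles,
               templates = lapply(f3hAlleles, function(a)
                 applyVariants(f3hRef, a))),
    f35h = list(reference = f35hRef, alleles = f35hAlleles,
                templates = lapply(f35hAlleles, function(a)
                  paste0(applyVariants(f35hRef, a), f35hFlank))))
}

# effect-class and product-length assertions for a freshly built fixture
verifyAlleleSuite <- function(fixture) {
  expect <- list(
    f3h = list("GmF3'H" = c("identical", 513L),
               "gmf3'h-a1" = c("frameshift_premature_stop", 394L),
               "gmf3'h-a2" = c("in_frame_indel", 513L),
               "gmf3'h-b" = c("frameshift_premature_stop", 394L)),
    f35h = list("GmF3'5'H-a" = c("identical", 509L),
                "GmF3'5'H-b" = c("missense", 509L),
                "gmf3'5'h" = c("frameshift_premature_stop", 467L)))
  for (locus in names(expect)) {
    ref <- fixture[[locus]]$reference
    for (an in names(expect[[locus]])) {
      ef <- classifyEffect(ref, fixture[[locus]]$alleles[[an]])
      want <- expect[[locus]][[an]]
      if (ef@effectClass != want[1L] ||
          ef@proteinLength != as.integer(want[2L]))
        stop("fixture verification failed for ", an, ": got ",
             ef@effectClass, "/", ef@proteinLength, " aa, expected ",
             want[1L], "/", want[2L], " aa")
    }
  }
  invisible(TRUE)
}

#' The five gene-tagged markers on a synthetic locus fixture
#'
#' Instantiates the marker set on the fixture's engineered coordinates:
#' F3'H-ApoI (CAPS, 539/538-bp products, reference cut 334+205),
#' F3'H-MjaIV (dCAPS, two GT mismatches at the forward-primer 3' end
#' completing GTNNAC; gmf3'h-a1 cut with a 105-bp diagnostic fragment),
#' F3'H-EcoNI (dCAPS, one C mismatch completing CCTNNNNNAGG; gmf3'h-b
#' uncut at 166 bp), F3'5'H-In (InDel, 342/395 bp) and F3'5'H-HphI (CAPS,
#' GmF3'5'H-a cut 225+117, GmF3'5'H-b uncut 342). Expected per-allele
#' profiles are verified against \code{\link{predictAssay}} at build time,
#' so marker geometry and stored profiles can never drift apart.
#'
#' @param fixture a fixture from \code{\link{makeAlleleSuite}}
#' @return named list of five \linkS4class{GeneMarker} objects
#' @export
sojaMarkers <- function(fixture) {
  buildMarkerSet(fixture, verify = TRUE)
}

buildMarkerSet <- function(fixture, verify = TRUE) {
  f3h <- cds(fixture$f3h$reference)
  f35h <- pcrTemplate(fixture$f35h$reference)
  enz <- defaultEnzymes()
  sub <- function(s, a, b) substr(s, a, b)

  mjaFwd <- sub(f3h, 939L, 965L)
  substr(mjaFwd, 26L, 27L) <- "GT"
  mjaMm <- data.frame(offset = c(26L, 27L),
                      template_base = c(substr(f3h, 964L, 964L),
                                        substr(f3h, 965L, 965L)),
                      primer_base = c("G", "T"), stringsAsFactors = FALSE)
  econFwd <- sub(f3h, 1141L, 1161L)
  substr(econFwd, 21L, 21L) <- "C"
  econMm <- data.frame(offset = 21L,
                       template_base = substr(f3h, 1161L, 1161L),
                       primer_base = "C", stringsAsFactors = FALSE)

  markers <- list(
    "F3'H-ApoI" = GeneMarker(
      "F3'H-ApoI", "CAPS",
      PrimerPair(sub(f3h, 767L, 786L), revComp(sub(f3h, 1286L, 1305L))),
      enzyme = enz$ApoI,
      expectedProfiles = list(
        "GmF3'H" = c(334L, 205L), "gmf3'h-a1" = 538L,
        "gmf3'h-a2" = 539L, "gmf3'h-b" = c(333L, 205L))),
    "F3'H-MjaIV" = GeneMarker(
      "F3'H-MjaIV", "dCAPS",
      PrimerPair(mjaFwd, revComp(sub(f3h, 1052L, 1071L)), mismatches = mjaMm),
      enzyme = enz$MjaIV,
      expectedProfiles = list(
        "GmF3'H" = c(106L, 27L), "gmf3'h-a1" = c(105L, 27L),
        "gmf3'h-a2" = 133L, "gmf3'h-b" = c(106L, 27L))),
    "F3'H-EcoNI" = GeneMarker(
      "F3'H-EcoNI", "dCAPS",
      PrimerPair(econFwd, revComp(sub(f3h, 1288L, 1307L)), mismatches = econMm),
      enzyme = enz$EcoNI,
      expectedProfiles = list(
        "GmF3'H" = c(143L, 24L), "gmf3'h-a1" = c(143L, 24L),
        "gmf3'h-a2" = c(143L, 24L), "gmf3'h-b" = 166L)),
    "F3'5'H-In" = GeneMarker(
      "F3'5'H-In", "InDel",
      PrimerPair(sub(f35h, 1060L, 1079L), revComp(sub(f35h, 1382L, 1401L))),
      expectedProfiles = list(
        "GmF3'5'H-a" = 342L, "GmF3'5'H-b" = 342L, "gmf3'5'h" = 395L)),
    "F3'5'H-HphI" = GeneMarker(
      "F3'5'H-HphI", "CAPS",
      PrimerPair(sub(f35h, 1210L, 1232L), revComp(sub(f35h, 1532L, 1551L))),
      enzyme = enz$HphI,
      expectedProfiles = list(
        "GmF3'5'H-a" = c(225L, 117L), "GmF3'5'H-b" = 342L,
        "gmf3'5'h" = c(278L, 117L))))

  if (!verify) return(markers)
  # design-time soundness: stored profiles must equal predicted assays
  templates <- c(fixture$f3h$templates, fixture$f35h$templates)
  for (m in markers) {
    for (an in names(m@expectedProfiles)) {
      got <- as.integer(predictAssay(m, templates[[an]]))
      want <- m@expectedProfiles[[an]]
      if (!identical(got, as.integer(want)))
        stop("marker ", m@name, " profile mismatch for ", an, ": predicted ",
             paste(got, collapse = "+"), ", stored ",
             paste(want, collapse = "+"))
    }
  }
  markers
}

#' Specification of a synthetic accession panel
#'
#' Defaults reproduce the reference survey's structure: group sizes
#' 24/146/102 (elite cultivars, landraces, wild soybeans), group-specific
#' allele frequencies from \code{\link{sojaAlleleCounts}}, and phenotype
#' penetrance P(phenotype | allele) from the survey's association counts
#' (pubescence and seed-coat color conditional on the GmF3'H allele,
#' flower color conditional on the GmF3'5'H allele).
#'
#' @param groupSizes named integer vector (elite/landrace/wild)
#' @param seed integer seed used by \code{\link{makePanel}}
#' @return list of class \code{PanelSpec}
#' @export
panelSpec <- function(groupSizes = c(elite = 24L, landrace = 146L,
                                     wild = 102L),
                      seed = 1L) {
  counts <- sojaAlleleCounts()
  freqTable <- function(locus) {
    x <- counts[counts$locus == locus, ]
    tapply(x$count, list(x$group, x$allele), sum)[names(groupSizes), ,
                                                  drop = FALSE]
  }
  assoc <- sojaAssociationCounts()
  penetrance <- function(df, alleleCol, field) {
    m <- tapply(df$count, list(df[[alleleCol]], df[[field]]), sum)
    m[is.na(m)] <- 0
    sweep(m, 1L, rowSums(m), "/")
  }
  structure(list(
    groupSizes = groupSizes,
    f3hFreqs = sweep(freqTable("GmF3'H"), 1L,
                     rowSums(freqTable("GmF3'H")), "/"),
    f35hFreqs = sweep(freqTable("GmF3'5'H"), 1L,
                      rowSums(freqTable("GmF3'5'H")), "/"),
    pubescencePenetrance = penetrance(assoc$f3h_pubescence, "F3H_allele",
                                      "pubescence"),
    flowerPenetrance = penetrance(assoc$f35h_flower, "F35H_allele",
                                  "flower"),
    seedcoatPenetrance = penetrance(assoc$f3h_seedcoat, "F3H_allele",
                                    "seedcoat"),
    seed = as.integer(seed)), class = "PanelSpec")
}

#' Simulate an accession panel with genotype truth
#'
#' Draws, per germplasm group, allele assignments i.i.d. from the spec's
#' group frequency vectors (soybean is selfing; one allele per accession
#' and locus) and phenotypes from the allele-conditional penetrance maps.
#' In \code{fixedCounts} mode the allele counts per group are the exact
#' expected counts (largest-remainder rounding of frequency times group
#' size) instead of a random draw, reproducing a printed allele
#' distribution; phenotypes are still sampled.
#'
#' @param spec a \code{\link{panelSpec}}
#' @param fixedCounts reproduce expected allele counts exactly
#' @return data.frame: accession, group, F3H_allele, F35H_allele,
#'   pubescence, flower, seedcoat (the allele columns are the truth table
#'   for recovery tests)
#' @export
makePanel <- function(spec = panelSpec(), fixedCounts = FALSE) {
  stopifnot(inherits(spec, "PanelSpec"))
  withSeed(spec$seed, {
    drawAlleles <- function(freqs, n) {
      alleles <- names(freqs)
      if (fixedCounts) {
        cnt <- largestRemainder(freqs * n)
        rep(alleles, cnt)
      } else {
        sample(alleles, n, replace = TRUE, prob = freqs)
      }
    }
    rows <- list()
    for (g in names(spec$groupSizes)) {
      n <- spec$groupSizes[[g]]
      if (n == 0L) next
      rows[[g]] <- data.frame(
        group = g,
        F3H_allele = drawAlleles(spec$f3hFreqs[g, ], n),
        F35H_allele = drawAlleles(spec$f35hFreqs[g, ], n),
        stringsAsFactors = FALSE)
    }
    panel <- do.call(rbind, rows)
    drawPheno <- function(pen, alleles) {
      lv <- colnames(pen)
      vapply(alleles, function(a)
        sample(lv, 1L, prob = pen[a, ]), character(1L))
    }
    panel$pubescence <- drawPheno(spec$pubescencePenetrance,
                                  panel$F3H_allele)
    panel$flower <- drawPheno(spec$flowerPenetrance, panel$F35H_allele)
    panel$seedcoat <- drawPheno(spec$seedcoatPenetrance, panel$F3H_allele)
    panel <- cbind(accession = sprintf("SYN%04d", seq_len(nrow(panel))),
                   panel, stringsAsFactors = FALSE)
    rownames(panel) <- NULL
    panel
  })
}

# integer counts summing to round(sum(x)), proportional to x
largestRemainder <- function(x) {
  total <- round(sum(x))
  base <- floor(x)
  rem <- x - base
  short <- total - sum(base)
  if (short > 0L) {
    up <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[up] <- base[up] + 1L
  }
  as.integer(base)
}
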