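# Shared fixtures and independent brute-force oracles for the test suite.
# The oracles deliberately avoid the implementation paths they check.

# memoised locus fixture + marker set (built once per test run)
.fixtureCache <- new.env(parent = emptyenv())
getFixture <- function(seed = 1L) {
  key <- paste0("fx", seed)
  if (is.null(.fixtureCache[[key]])) {
    fx <- makeAlleleSuite(seed = seed)
    .fixtureCache[[key]] <- list(fixture = fx, markers = sojaMarkers(fx))
  }
  .fixtureCache[[key]]
}

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracleRevComp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1L]]]), collapse = "")
}

# does `word` (plain ACGT) satisfy the IUPAC pattern `site`?
oracleSiteMatch <- function(word, site) {
  w <- strsplit(word, "")[[1L]]
  s <- strsplit(site, "")[[1L]]
  length(w) == length(s) &&
    all(mapply(function(b, code) b %in% IUPAC_ORACLE[[code]], w, s))
}

# recursive enumeration of all exact words of an IUPAC pattern
oracleExpand <- function(site) {
  if (nchar(site) == 0L) return("")
  first <- IUPAC_ORACLE[[substr(site, 1L, 1L)]]
  rest <- oracleExpand(substring(site, 2L))
  as.vector(outer(first, rest, paste0))
}

# brute-force site scan at every offset, both strands for
# non-palindromic sites; returns data.frame(position, strand)
oracleFindSites <- function(seq, site) {
  L <- nchar(site)
  n <- nchar(seq)
  hits <- list()
  rcSite <- oracleRevComp(site)
  for (i in seq_len(max(0L, n - L + 1L))) {
    word <- substr(seq, i, i + L - 1L)
    if (oracleSiteMatch(word, site))
      hits[[length(hits) + 1L]] <- data.frame(position = i, strand = "+",
                                              stringsAsFactors = FALSE)
  }
  if (!setequal(oracleExpand(site), oracleExpand(rcSite))) {
    for (i in seq_len(max(0L, n - L + 1L))) {
      word <- substr(seq, i, i + L - 1L)
      if (oracleSiteMatch(word, rcSite))
        hits[[length(hits) + 1L]] <- data.frame(position = i, strand = "-",
                                                stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(position = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(out$position, out$strand), , drop = FALSE]
}

# exhaustive dCAPS search: minimal number of primer-tail mismatches that
# completes `site` over the variant in exactly one of the two alleles
oracleDcapsMinMismatches <- function(refSeq, altSeq, vstart, site) {
  L <- nchar(site)
  s <- strsplit(site, "")[[1L]]
  best <- Inf
  for (w in seq(max(1L, vstart - L + 1L), vstart)) {
    if (w + L - 1L > min(nchar(refSeq), nchar(altSeq))) next
    for (e in seq(w, min(vstart - 1L, w + L - 2L))) {
      if (e < w) next
      # primer part [w..e]: impose site letters, count mismatches
      mm <- 0L
      primerLetters <- character(e - w + 1L)
      ok <- TRUE
      for (j in seq(w, e)) {
        b <- substr(refSeq, j, j)
        code <- s[j - w + 1L]
        if (b %in% IUPAC_ORACLE[[code]]) primerLetters[j - w + 1L] <- b
        else { primerLetters[j - w + 1L] <- IUPAC_ORACLE[[code]][1L]
               mm <- mm + 1L }
      }
      if (mm == 0L) next   # natural site: CAPS, not dCAPS
      tailLen <- L - (e - w + 1L)
      wordRef <- paste0(paste(primerLetters, collapse = ""),
                        substr(refSeq, e + 1L, e + tailLen))
      wordAlt <- paste0(paste(primerLetters, collapse = ""),
                        substr(altSeq, e + 1L, e + tailLen))
      if (nchar(wordRef) < L || nchar(wordAlt) < L) next
      cutRef <- oracleSiteMatch(wordRef, site)
      cutAlt <- oracleSiteMatch(wordAlt, site)
      if (cutRef != cutAlt) best <- min(best, mm)
      if (!ok) next
    }
  }
  best
}

# independent half-up rounding to 1 decimal
roundHalfUp2 <- function(x) floor(x * 10 + 0.5) / 10

# random complete ORF as a plain string (independent of makeReference)
randomOrf <- function(nCodons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- setdiff(names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"], "ATG")
  paste0("ATG", paste(sample(sense, nCodons - 1L, replace = TRUE),
                      collapse = ""), "TAA")
}
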