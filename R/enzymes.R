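IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

#' Expand an IUPAC-degenerate site into its exact DNA words
#'
#' @param site IUPAC DNA string (e.g. "GTNNAC")
#' @return character vector of all exact expansions; its length is the
#'   product of the per-letter degeneracies
#' @examples
#' expandIupac("RAATTY")   # 4 words
#' length(expandIupac("GTNNAC"))  # 16
#' @export
expandIupac <- function(site) {
  letters <- strsplit(toupper(site), "")[[1L]]
  bad <- setdiff(letters, names(IUPAC_EXPANSION))
  if (length(bad)) stop("invalid IUPAC letter(s): ", paste(bad, collapse = ", "))
  words <- expand.grid(lapply(letters, function(l) IUPAC_EXPANSION[[l]]),
                       stringsAsFactors = FALSE)
  sort(do.call(paste0, words))
}

# a site family is palindromic when its expansion set equals the
# expansion set of its reverse complement (e.g. RAATTY, GTNNAC, CCTNNNNNAGG)
isPalindromicSite <- function(site) {
  setequal(expandIupac(site), expandIupac(revComp(site)))
}

#' Find all occurrences of an enzyme's recognition site
#'
#' Scans the top strand for the (possibly degenerate) site and, for
#' non-palindromic enzymes, also for its reverse complement. Overlapping
#' matches are all reported. Palindromic site families match identically
#' on both strands, so each physical site is reported once, on "+".
#'
#' @param seq DNA string over A/C/G/T
#' @param enzyme a \linkS4class{RestrictionEnzyme}
#' @return data.frame with columns \code{position} (1-based start of the
#'   match on the top strand) and \code{strand} ("+" or "-")
#' @export
findSites <- function(seq, enzyme) {
  stopifnot(is(enzyme, "RestrictionEnzyme"))
  seq <- toupper(as.character(seq))
  if (grepl("[^ACGT]", seq)) stop("sequence must be over A/C/G/T")
  subject <- Biostrings::DNAString(seq)
  scan1 <- function(site) {
    if (nchar(site) > nchar(seq)) return(integer())
    Biostrings::start(Biostrings::matchPattern(site, subject, fixed = FALSE))
  }
  pos <- scan1(enzyme@site)
  strand <- rep("+", length(pos))
  if (!enzyme@palindromic) {
    rcpos <- scan1(revComp(enzyme@site))
    pos <- c(pos, rcpos)
    strand <- c(strand, rep("-", length(rcpos)))
  }
  ord <- order(pos, strand)
  data.frame(position = as.integer(pos[ord]), strand = strand[ord],
             stringsAsFactors = FALSE)
}

# top-strand cut coordinates ("cut after base k") implied by the site
# matches; minus-strand sites mirror the bottom-strand offset
cutCoordinates <- function(sites, enzyme) {
  if (nrow(sites) == 0L) return(integer())
  L <- nchar(enzyme@site)
  ifelse(sites$strand == "+",
         sites$position + enzyme@cutTop - 1L,
         sites$position + L - 1L - enzyme@cutBottom)
}

#' Digest a linear sequence in silico
#'
#' Computes top-strand cut coordinates from every recognition-site match
#' (both strands for non-palindromic enzymes), deduplicates them, drops
#' cuts falling outside the molecule (Type IIS sites near an end, counted
#' in \code{droppedCuts}) and returns the resulting fragment lengths,
#' which always sum to the input length.
#'
#' @param seq DNA string over A/C/G/T
#' @param enzyme a \linkS4class{RestrictionEnzyme} with cut offsets
#' @return a \linkS4class{DigestResult}
#' @examples
#' apoi <- RestrictionEnzyme("ApoI", "RAATTY", 1, 5)
#' digestSequence(paste0(strrep("C", 10), "GAATTT", strrep("C", 10)), apoi)
#' @export
digestSequence <- function(seq, enzyme) {
  stopifnot(is(enzyme, "RestrictionEnzyme"))
  if (is.na(enzyme@cutTop))
    stop("enzyme '", enzyme@name, "' has no cut offsets; ",
         "use findSites() for site-presence-only assays")
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  cuts <- cutCoordinates(findSites(seq, enzyme), enzyme)
  inRange <- cuts >= 1L & cuts <= n - 1L
  dropped <- sum(!inRange)
  cuts <- sort(unique(cuts[inRange]))
  fragments <- diff(c(0L, cuts, n))
  new("DigestResult", cutPositions = as.integer(cuts),
      fragments = as.integer(fragments), inputLength = as.integer(n),
      droppedCuts = as.integer(dropped))
}

#' The package's default enzyme table
#'
#' ApoI (R^AATTY), MjaIV (GT^NNAC), EcoNI (CCTNN^NNNAGG) and HphI
#' (GGTGA(8/7), Type IIS). Gel assays only require site presence/absence
#' and fragment sizes, so the offsets are conventional REBASE-style values
#' and can be overridden via \code{\link{readEnzymeTable}}.
#'
#' @return named list of \linkS4class{RestrictionEnzyme} objects
#' @export
defaultEnzymes <- function() {
  list(
    ApoI  = RestrictionEnzyme("ApoI", "RAATTY", 1, 5),
    MjaIV = RestrictionEnzyme("MjaIV", "GTNNAC", 2, 4),
    EcoNI = RestrictionEnzyme("EcoNI", "CCTNNNNNAGG", 5, 6),
    HphI  = RestrictionEnzyme("HphI", "GGTGA", 13, 12))
}
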