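---
title: "Methods: allele modelling, marker geometry and panel statistics in sojaCAPS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele modelling, marker geometry and panel statistics in sojaCAPS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sojaCAPS)
```

# Scope and model

sojaCAPS models allelic variation in two soybean flavonoid hydroxylase
genes — *GmF3'H* (flavonoid 3'-hydroxylase, the *T* locus) and
*GmF3'5'H* (flavonoid 3',5'-hydroxylase, associated with *W1*) — and
the PCR-based assays used to score that variation: CAPS, dCAPS and
InDel markers. The pipeline has four layers:

1. **Sequence/variant layer.** A `ReferenceGene` holds a complete CDS
   (ATG start, single terminal stop, A/C/G/T only). An `Allele` is an
   ordered, non-overlapping set of `Variant`s (substitution, insertion,
   deletion) in 1-based CDS coordinates counted from the A of the start
   codon. `classifyEffect` translates reference and allele products and
   assigns one of five classes (identical, synonymous, missense,
   in-frame indel, frameshift/premature stop).
2. **Digestion layer.** `RestrictionEnzyme` objects carry an
   IUPAC-degenerate recognition site and two cut offsets;
   `digestSequence` turns site matches into top-strand cut coordinates
   and fragment sizes.
3. **Assay layer.** `virtualPcr` amplifies a template with a primer
   pair whose forward primer may carry declared mismatches (the dCAPS
   mechanism); `predictAssay` digests the product and reports gel
   bands. `designCaps`, `designDcaps` and `designIndel` search for
   discriminating assays; `classifyF3h`/`classifyF35h` invert band
   patterns into allele calls.
4. **Panel layer.** `genotypePanel` applies the assays and decision
   trees to an accession panel; `alleleFrequencies`, `neiDiversity`,
   `associationTable`, `explainedFraction` and `combinedGenotypeTable`
   compute the population statistics.

The package assumes a selfing crop scored as homozygous: each accession
carries a single allele per locus, and heterozygous band unions are out
of scope.

# Variant semantics and effect classification

Coordinates never shift: variants are applied right-to-left (descending
position), so every stated position refers to the unmodified reference
frame. Insertions place their bases *after* the stated position; this
is what makes "insertion of an A at 965" compatible with a deletion at
973 in the same allele. Ambiguity codes are rejected in CDS input so
translation and digestion semantics stay exact.

Effect classes are decided from the translated products:

* net length shift not divisible by 3 → frameshift/premature stop;
* frame conserved but a stop appears upstream of where the reference
  stop lands after the shift → frameshift/premature stop (this also
  covers nonsense SNPs and compensated indel pairs whose out-of-frame
  window happens to create a stop);
* frame conserved, indels present, no premature stop → in-frame indel
  (the compensated insertion+deletion of *gmf3'h-a2* lands here, with
  only local amino-acid changes);
* substitutions only → missense or synonymous by protein comparison.

Translation uses the standard genetic code (via the Biostrings code
table), stops at the first in-frame stop, ignores trailing bases, and
flags products that run off the end without a stop.

# Digestion conventions

`findSites` matches the recognition site (and, for non-palindromic
enzymes such as HphI, its reverse complement) at every position,
overlapping hits included. Degenerate matching is delegated to
`Biostrings::matchPattern(fixed = FALSE)`; the test suite checks it
against a brute-force IUPAC-expansion scan.

Cut offsets are REBASE-style: `cutTop` is the position *after which*
the top strand is cut, counted from the site start on the strand
carrying the site; offsets beyond the site length describe Type IIS
enzymes (HphI GGTGA(8/7) has `cutTop = 13`). For a site found on the
minus strand at top positions `[p, p+L-1]`, the top-strand cut falls
after `p + L - 1 - cutBottom`. Cuts outside the molecule (Type IIS
near an end) are dropped and counted. Fragment sizes are differences of
sorted unique top-strand cuts, so they always sum to the input length.
One consequence, stated openly: because fragment coordinates follow the
top-strand convention, digesting the reverse complement shifts the two
terminal fragments by the enzyme's overhang (|cutTop − cutBottom|);
internal fragments are identical. None of the shipped assays depends
on this.

The shipped enzyme table covers ApoI (R^AATTY), MjaIV (GT^NNAC,
offsets assumed in the REBASE style since gel assays only need
presence/absence and sizes), EcoNI (CCTNN^NNNAGG) and HphI. Offsets
live in a user-editable TSV (`readEnzymeTable`), and enzymes without
offsets operate in site-presence-only mode (`findSites` works,
`digestSequence` refuses).

# Marker design

`virtualPcr` requires each primer to bind exactly once, exactly —
except at declared forward-primer mismatch offsets. The amplicon
carries the primer sequence, which is what completes an engineered
dCAPS site in the product. Designed mismatches are restricted to the
forward primer (the classical geometry); a `side = "reverse"` flag
re-runs the search on the reverse-complement template.

`designCaps` looks for enzymes whose site overlaps the variant in
exactly one allele, then slides candidate amplicons around the
diagnostic site and keeps those whose two digestion profiles are
distinguishable at the gel resolution. Candidates are sorted by fewest
non-diagnostic cuts, then product size, then enzyme name — a
deterministic order. `designDcaps` enumerates every alignment of each
enzyme's site covering the variant and every primer 3'-end position
inside the site, imposes the site letters on the primer tail, counts
mismatches, and keeps placements that (a) need at most `maxMismatches`
(default 3) mismatches, (b) read the variant base from the template,
never the primer, and (c) cut exactly one allele. The returned
mismatch count is minimal over placements; the test suite verifies this
against an exhaustive independent search on 60-bp alleles.
`designIndel` places flanking primers and refuses indels below the gel
resolution.

Tunable `designConstraints` defaults: primer length 18–27 nt, product
80–600 bp, `minBandSeparation` 20 bp (a proxy for what 2 % agarose
resolves — the tightest diagnostic gap the assays rely on is 133 vs
105 bp), `min3primeAnchor` 0 (dCAPS mismatches sit at the very 3' end,
as in the GT tail of the MjaIV assay).

# Genotyping decision trees

Band matching uses a ±5 bp per-band tolerance: wide enough to absorb
the 1-bp product-length differences between deletion and reference
alleles (133/132 bp), narrow enough to keep every diagnostic gap
unambiguous. The *GmF3'H* tree: ApoI uncut → {a1, a2}, resolved by
MjaIV (cut → a1); ApoI cut → {wild type, b}, resolved by EcoNI
(cut → wild type). The *GmF3'5'H* tree: InDel product ≈395 bp →
insertion allele; ≈342 bp resolved by HphI (cut → a). Missing or
contradictory evidence yields `NO_CALL` with an audit note — never an
exception — so panel runs are restartable and auditable.

# The synthetic loci

No accession sequences are public, so the generator *constructs* loci
that reproduce the published allele architecture exactly. For
*GmF3'H* (1542-nt CDS, 513 residues) the fixed design elements are: an
ApoI site GAATTC at 971–976 whose A973 is the base deleted in
*gmf3'h-a1*/*a2*; a template half-site next to 965 so a two-mismatch
GT primer tail completes GTNNAC in the deletion allele but not when
the extra A of *gmf3'h-a2* shifts the spacing; an EcoNI neighbourhood
at 1160–1170 completed by a single primer C mismatch and broken by the
C1164 deletion of *gmf3'h-b*; and a stop triplet planted on the −1
frameshift lattice at 1184–1186. Because both 1-bp deletions (973 and
1164) shift to the *same* downstream frame, that one stop truncates
both frameshift alleles at 394 residues, matching the reported
394-residue products of both alleles (a variant report of a
six-residue product for the b allele is inconsistent with the shared
frame and was not followed). All other positions are random sense codons; the builder
scrubs stop codons from the shifted lattice and confounding
recognition sites from the assay windows, then verifies every allele's
effect class and every marker's band profile before returning, retrying
from fresh randomness if needed.

For *GmF3'5'H* the product length is reported variously as 509 or
501 residues; the package uses 509 (1530-nt CDS) because the C1509T
substitution requires a CDS of at least 1509 nt, which a 501-residue
CDS cannot contain. The locus carries synonymous-SNP codons at
1057–1059 and 1507–1509, a GGTGA (HphI) site at 1422–1426 arranged so
codon 475 is GTG (valine) and the T1424A substitution of *GmF3'5'H-b*
turns it into GAG (V475E) while destroying the site, and a 53-bp
insertion cassette after 1352 whose internal TAA lands in codon 468 of
the shifted frame, truncating the product at 467 residues. The HphI
amplicon (225+117/342) extends past the stop codon, so the PCR
template carries a 130-nt synthetic 3' flank — exactly as the real
assay amplifies genomic DNA beyond the CDS.

Marker product sizes follow the reported assay sizes (205+334/538
ApoI; 27+105/133 MjaIV; 24+143/166 EcoNI; 342/395 InDel; 225+117/342
HphI). Where alternative reported gel readings disagree (540/322+208
for ApoI; 167/140 for EcoNI), the tabulated sizes are canonical and
the alternatives fall within the ±5 bp matching tolerance.

# Accession panels

`panelSpec` defaults are the reference survey's structure: groups of
24 elite cultivars, 146 landraces and 102 wild soybeans; group-specific
allele frequencies from the shipped count tables; phenotype penetrance
P(phenotype | allele) with pubescence and seed-coat color conditional
on the *GmF3'H* allele and flower color conditional on the *GmF3'5'H*
allele. Sampling is i.i.d. within groups with a single seed threaded
through all draws, so panels are byte-reproducible. A fixed-count mode
replaces the allele draw with largest-remainder expected counts,
reproducing a printed allele distribution exactly (phenotypes are
still sampled). Separately, `panelFromCounts` expands any printed
contingency table into an accession panel with those exact counts —
the published tables are marginals of an unpublished joint dataset, so
each statistic is reproduced from its own table rather than from one
(under-determined) joint panel.

What the generator does *not* emulate: linkage or any dependence
between the two loci (the two-locus seed-coat table is reproduced via
fixed counts, not the sampler), population structure beyond the three
groups, genotyping noise, gel-scoring error, and heterozygosity.
Passing tests therefore demonstrate correctness of the assay geometry
and statistics on clean data, not robustness to noisy gels or real
population structure.

# Numerical choices

* **Nei's index is uncorrected** (`h = 1 − Σp²`), not the unbiased
  n/(n−1) form: the uncorrected form reproduces all six published
  indices after 2-dp rounding, while the corrected form fails for the
  24-accession elite group (e.g. 0.70 instead of 0.67).
* **Rounding is half away from zero** at the printed precision (1 dp
  for percentages, 2 dp for h), applied only at report time; internal
  values keep full precision.
* **Tie-breaks** in design output are deterministic (mismatches, then
  product size, then enzyme name), so identical inputs give identical
  marker lists.
* **Degenerate inputs**: empty variant lists are the reference allele;
  an enzyme with no sites yields a single fragment; empty allele
  frequency groups and zero phenotype denominators are errors;
  unknown phenotype vocabulary names the offending accession.
* **Allele names** are canonically ASCII (`GmF3'H`); the Unicode prime
  and a "p" alias (`GmF3pH`) are normalized on input.
* **Problem sizes** used by the shipped tests and the acceptance
  script — 272-accession default panels, 6000–10000-accession panels
  for penetrance-recovery checks, 20 seeds for end-to-end recovery —
  were chosen as the smallest sizes at which sampling error (3
  binomial standard errors) is clearly separated from the effects
  being measured.

# Known limitations

Primer thermodynamics are out of scope: assays here are constructed on
synthetic templates, not discovered on genomic ones, so `virtualPcr`
binds primers by exact sequence (plus declared mismatches) rather than
by melting temperature. Methylation sensitivity, partial digestion and
band intensity are not modelled. The genotype decision trees encode the
two shipped loci; new loci require writing a new tree (the band-pattern
matcher itself is generic).
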