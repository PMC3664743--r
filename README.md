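# sojaCAPS

Gene-tagged marker design and virtual genotyping for the soybean
flavonoid hydroxylase alleles.

## The problem

Pubescence, flower and seed-coat pigmentation in soybean (*Glycine*
subgenus *soja*) are controlled in part by two cytochrome-P450 genes of
the flavonoid pathway: the flavonoid 3'-hydroxylase gene *GmF3'H* (the
classical *T* locus) and the flavonoid 3',5'-hydroxylase gene *GmF3'5'H*
(associated with *W1*). Natural alleles of these genes differ by small
coding-sequence lesions — a frameshifting 1-bp deletion (del A973 in
*gmf3'h-a1*), a compensated insertion+deletion pair (ins A after 965 +
del A973 in *gmf3'h-a2*, in frame), another 1-bp deletion (del C1164 in
*gmf3'h-b*), a triple-SNP allele (*GmF3'5'H-b*, carrying the missense
change V475E) and a 53-bp insertion (*gmf3'5'h*). Breeders score these
alleles with cheap PCR assays:

* **CAPS** (cleaved amplified polymorphic sequence): the lesion creates
  or destroys a natural restriction site; the digest band pattern is
  diagnostic (e.g. *Apo*I, R^AATTY, at the del A973 site).
* **dCAPS** (derived CAPS): no natural site exists, so mismatched bases
  in the forward-primer tail complete a recognition site (GTNNAC for
  *Mja*IV, CCTNNNNNAGG for *Eco*NI) in exactly one allele.
* **InDel**: flanking primers read the 53-bp length difference directly
  (342 vs 395 bp products).

This package implements the whole workflow as tested, seedable code:
allele modelling and protein-level effect classification, in-silico
digestion with IUPAC-degenerate sites, marker design and band-profile
prediction, multi-marker decision-tree genotyping of accession panels,
and the downstream population statistics. Because the germplasm
sequences themselves are not public, a constrained synthetic-locus
generator reconstructs reference genes whose alleles and assays have
exactly the published geometry.

## The statistics at the core

For allele proportions `p_i` within a germplasm group, Nei's gene
diversity is the uncorrected heterozygosity

    h = 1 - sum_i p_i^2

(0 for a monomorphic locus, at most `1 - 1/k` for `k` alleles).
Genotype–phenotype structure is summarised by contingency tables of
allele against phenotype category with row percentages, and by
"explained fractions": among accessions showing a phenotype, the share
carrying a given allele set.

## Worked example

```r
library(sojaCAPS)

fx <- makeAlleleSuite(seed = 1)   # synthetic GmF3'H / GmF3'5'H loci
mk <- sojaMarkers(fx)             # the five gene-tagged markers

mk[["F3'H-ApoI"]]
#> GeneMarker 'F3'H-ApoI' (CAPS/ApoI)
#>   GmF3'H       334 + 205
#>   gmf3'h-a1    538
#>   gmf3'h-a2    539
#>   gmf3'h-b     333 + 205

mk[["F3'H-MjaIV"]]
#> GeneMarker 'F3'H-MjaIV' (dCAPS/MjaIV)
#>   GmF3'H       106 + 27
#>   gmf3'h-a1    105 + 27
#>   gmf3'h-a2    133
#>   gmf3'h-b     106 + 27

classifyEffect(fx$f3h$reference, fx$f3h$alleles[["gmf3'h-a1"]])
#> EffectReport: frameshift_premature_stop; protein 394 aa; net shift -1 nt; 0 aa change(s)

panel <- makePanel(panelSpec(seed = 7))      # 24/146/102 accessions
calls <- genotypePanel(panel, fx, mk)
mean(calls$F3H_call == panel$F3H_allele &
     calls$F35H_call == panel$F35H_allele)
#> [1] 1

x <- subset(sojaAlleleCounts(), locus == "GmF3'H" & group == "elite")
x$count
#> [1] 11  4  2  7
neiDiversity(x$count)   # rounds to 0.67
```

The ApoI marker separates `{GmF3'H, gmf3'h-b}` (cut) from `{gmf3'h-a1,
gmf3'h-a2}` (uncut); MjaIV then resolves a1 (105-bp diagnostic
fragment) from a2, and EcoNI resolves the wild type from b. The two
F3'5'H markers work the same way (395-bp InDel product for the
insertion allele; HphI 225+117 vs uncut 342 for a vs b). `genotypePanel`
runs those decision trees on every accession and recovers every planted
allele on clean synthetic data.

A thin command-line wrapper over the same functions lives in
`inst/scripts/capspipe.R` (subcommands `simulate`, `design`, `digest`,
`genotype`, `stats`, `report`).

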