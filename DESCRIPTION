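Package: sojaCAPS
Title: CAPS, dCAPS and InDel Marker Design and Virtual Genotyping for
    Soybean Flavonoid Hydroxylase Alleles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models allelic variation in the soybean flavonoid
    3'-hydroxylase (GmF3'H, T locus) and flavonoid 3',5'-hydroxylase
    (GmF3'5'H, W1 locus) coding sequences and implements the gene-tagged
    marker workflow built on them: variant application and protein-level
    effect classification (frameshift/premature stop, compensated
    in-frame indels, missense), in-silico restriction digestion with
    IUPAC-degenerate recognition sites, design of CAPS, dCAPS
    (primer-introduced sites) and InDel markers, virtual PCR and
    band-profile prediction, multi-marker decision-tree genotyping of
    accession panels, and population statistics (allele frequency
    distributions, Nei's gene diversity, allele-phenotype association
    and explained-fraction tables). A seeded synthetic-data generator
    reconstructs reference loci, the seven named alleles, the five
    gene-tagged markers and accession panels with group-specific allele
    frequencies and phenotype penetrance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
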