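Package: nsltp
Title: Genome-Wide Survey of Plant Non-Specific Lipid Transfer Protein
    Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identification and characterization of plant non-specific
    lipid transfer protein (nsLTP) gene families, built around the
    allotetraploid cotton (Gossypium hirsutum) family survey.  Implements
    the candidate filter cascade (signal peptide, mature-protein length,
    eight-cysteine motif, start methionine, optional domain check),
    eight-cysteine-motif (ECM) detection and gap-signature typing into the
    Boutrot type system, mature-protein physicochemical properties
    (molecular weight, isoelectric point), tandem/segmental duplication
    calling with Nei-Gojobori (1986) Ka/Ks, neighbor-joining phylogenies
    with bootstrap support, and fiber-development expression analyses
    (RPKM, trend clustering, differential expression, ortholog comparison,
    qPCR 2^-dCt).  A seeded synthetic-data module generates nsLTP-like
    genes, decoy candidates, chromosome layouts with planted duplications,
    and expression matrices with planted temporal profiles, so the whole
    pipeline runs and is testable without genome downloads.  The published
    138-gene G. hirsutum catalog is packaged as a machine-readable
    fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
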