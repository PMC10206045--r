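Package: wrkykit
Title: WRKY Transcription-Factor Family Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification and analysis of WRKY transcription-factor gene
    families in plant genomes. Detects WRKY domains (the conserved WRKYGQK
    heptapeptide paired with a C2H2 or C2HC zinc finger) in protein sequences,
    classifies proteins into groups I, IIa-IIe and III by domain count,
    zinc-finger type and subgroup signature motifs, with phylogeny-assisted
    label transfer for structurally unclassifiable members. Types duplicate
    gene pairs as whole-genome, tandem, proximal, transposed or dispersed
    duplications from gene order and collinear blocks, and estimates Ka/Ks
    under the Nei-Gojobori (1986) counting method with Jukes-Cantor
    correction. A fold-change expression screen intersects differentially
    expressed genes across colored-versus-white flower contrasts to nominate
    candidate anthocyanin regulators, supported by 2^-ddCt qPCR arithmetic
    and hypergeometric term enrichment. Seeded synthetic-data generators and
    fixtures transcribed from published azalea (Rhododendron simsii) WRKY
    tables make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
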