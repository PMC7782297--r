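Package: ystrtools
Title: Y-STR Haplotype Analysis for Surname and Founder-Lineage Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for patrilineal surname studies based on Y-chromosome
    short tandem repeat (Y-STR) haplotypes typed on the 16-locus Yfiler
    panel. Provides a haplotype/population data model that handles the
    multi-copy locus DYS385 and duplicated allele patterns at nominally
    single-copy loci, a documented CSV dialect for haplotype tables,
    pairwise percent-similarity matrices, identity-class detection,
    counting-method ("frequentist") haplotype frequency estimation, allele
    frequency and modal-allele summaries, founder-signature matching and
    genetic-footprint allele sharing, and a stepwise-mutation-model
    simulator for synthetic surname studies. Ships the haplotypes of a
    published O'Brien surname study (surname, general Irish and control
    populations) as plain-text fixtures, together with the Dal Riata,
    O'Brien-footprint and Sykes founder signatures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: graphics, jsonlite, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
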