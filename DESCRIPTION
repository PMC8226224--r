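Package: scubshift
Title: Synonymous Codon Usage Bias Shift Analysis for Hybrid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify shifts in synonymous codon usage bias (SCUB)
    between a recipient cultivar and a derived (somatic hybrid /
    introgression) line from matched coding-sequence collections.
    Computes per-amino-acid and total third-position base composition over
    the 59-codon synonymous set, CpG-deamination (DNA methylation)
    signature ratios within codons and across codon boundaries,
    indel-flanking versus indel-remote codon usage from pairwise CDS
    alignments, and chromosome-based partitions (introgressed versus
    non-introgressed chromosomes, allelic groups, sub-genomes), with
    chi-square cross-table tests, Welch t-tests, coefficients of variation
    and Cronbach's alpha. Includes a ground-truthed synthetic CDS
    evolution simulator (CpG-biased substitution, frame-preserving indels,
    indel-proximal substitution enrichment) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
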