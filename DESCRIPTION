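Package: stopswitch
Title: Design and Quantification of Base-Editor-Switchable Stop Codons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational workflow for engineering fluorescent-reporter
    alleles that are silenced by a cytosine-base-editor-installed premature
    termination codon and re-activated by adenine base editing. Enumerates
    CBE-installable stop codons in a coding sequence under PAM and
    editing-window constraints, designs ABE reversion guides across Cas9
    orthologues with bystander annotation, quantifies editing outcomes from
    single-end amplicon sequencing reads, estimates transgene copy number
    from droplet digital PCR partition counts by Poisson statistics, and
    links per-copy edited-allele fractions to reporter-positive cell
    fractions in multi-copy genomes. Includes ground-truthed simulators for
    amplicon reads, ddPCR partitions and multi-copy cell populations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
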