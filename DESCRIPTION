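Package: cladefp
Title: Active-Site Fingerprinting and Subfamily Delineation for Protein
    Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reference-anchored comparative analysis of protein families:
    extracts the residues every family member presents at a named set of
    active-site positions (numbered on a reference sequence and carried
    through a multiple sequence alignment), links these fingerprints to a
    distance-based phylogeny, classifies subfamilies by the presence or
    absence of an indel segment such as an oligomerization loop, and ranks
    divergent candidates by active-site distance. Ships a built-in
    progressive aligner, neighbor-joining tree construction with outgroup
    rooting, a configurable cluster definition format with defaults for the
    fungal vanillyl alcohol oxidase (VAO) family, and a seeded simulator of
    clade-structured families with planted active-site states and loop
    indels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
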