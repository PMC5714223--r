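Package: homofold
Title: Joint Secondary Structure Prediction and Multiple Alignment of
    Homologous RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Iterative joint estimation of RNA secondary structures and a
    multiple sequence alignment for a set of homologous RNA sequences.
    Pairwise alignment posteriors from a three-state pair hidden Markov
    model and per-sequence base-pair probabilities from a partition
    function over non-crossing canonical structures inform each other
    through two coupling channels: a structural match score acts as a
    prior on the alignment HMM, and alignment-mapped pairing proclivities
    from homologs enter the partition function as extrinsic information.
    After a fixed number of iterations a probabilistic-consistency
    progressive alignment produces the final multiple sequence alignment
    and a maximum expected accuracy dynamic program predicts per-sequence
    structures. Includes readers and writers for FASTA, CT, dot-bracket,
    aligned FASTA and Stockholm, accuracy scoring with the one-position
    slippage rule for base pairs, and a deterministic generator of
    synthetic homolog families with known alignments and structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
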