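Package: cas9smfret
Title: Kinetic Analysis of Cas9-RNA Target Recognition from Single-Molecule
    FRET Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and kinetic analysis of single-molecule FRET (smFRET)
    recordings of CRISPR-Cas9 ribonucleoprotein binding to DNA targets.
    Provides an exact continuous-time Markov chain simulator of the two-step
    (PAM sampling then RNA-DNA heteroduplex) binding scheme with camera
    frame integration, Gaussian detection noise and photobleaching; donor and
    acceptor intensity correction to FRET efficiency trajectories; three-state
    Gaussian-emission hidden Markov model idealization with Viterbi decoding
    and transition-density summaries; dwell-time extraction with survival
    analysis by single- and double-exponential maximum likelihood including
    censoring and photobleach correction; bimolecular association rate
    estimation from concentration series; and counting of PAM-plus-seed query
    sequences in genome FASTA files against the random-sequence expectation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
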