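Package: epitopescan
Title: Linear Epitope Mapping from Display-Selection Sequencing
Version: 0.1.0
Authors@R:
    person("epitopescan", "developers", email = "dev@example.org",
           role = c("aut", "cre"))
Description: Maps linear antibody epitopes genome-wide from mRNA-display
    selection sequencing. For every 12-residue window of a reference
    proteome the package compares the theoretical inverse cumulative
    distribution of substitution-matrix similarity scores expected from a
    random peptide library (P) with the empirical distribution observed in
    selected peptides (Q), and summarises the discrepancy per window with a
    Pearson chi-square distance. High-scoring windows mark binding sites;
    a genome-wide ranking exposes cross-reactivity. Includes read
    demultiplexing and NNK-cassette translation, round-wise motif tracking
    and convergence logos, a seeded selection simulator with planted
    ground truth, a reaction-diffusion simulator of antibody penetration
    into tissue, and exact Mann-Whitney group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
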