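# Shared fixtures: tiny proteomes, restricted-alphabet frequency models,
# and independent oracles (standard genetic code frozen from a reference
# table; brute-force enumerators live in the tests that use them).

GENETIC_CODE_ORACLE <- c("AAA" = "K", "AAC" = "N", "AAG" = "K", "AAT" = "N", "ACA" = "T", "ACC" = "T", "ACG" = "T", "ACT" = "T", "AGA" = "R", "AGC" = "S", "AGG" = "R", "AGT" = "S", "ATA" = "I", "ATC" = "I", "ATG" = "M", "ATT" = "I", "CAA" = "Q", "CAC" = "H", "CAG" = "Q", "CAT" = "H", "CCA" = "P", "CCC" = "P", "CCG" = "P", "CCT" = "P", "CGA" = "R", "CGC" = "R", "CGG" = "R", "CGT" = "R", "CTA" = "L", "CTC" = "L", "CTG" = "L", "CTT" = "L", "GAA" = "E", "GAC" = "D", "GAG" = "E", "GAT" = "D", "GCA" = "A", "GCC" = "A", "GCG" = "A", "GCT" = "A", "GGA" = "G", "GGC" = "G", "GGG" = "G", "GGT" = "G", "GTA" = "V", "GTC" = "V", "GTG" = "V", "GTT" = "V", "TAA" = "*", "TAC" = "Y", "TAG" = "*", "TAT" = "Y", "TCA" = "S", "TCC" = "S", "TCG" = "S", "TCT" = "S", "TGA" = "*", "TGC" = "C", "TGG" = "W", "TGT" = "C", "TTA" = "L", "TTC" = "F", "TTG" = "L", "TTT" = "F")

B62 <- build_substitution_matrix("blosum62_mod")
FREQ_NNN <- make_frequency_model("nnn_no_stop")

# frequency model supported on a restricted residue set (emulates a small
# alphabet on the 20-letter machinery)
restricted_freq <- function(residues, probs = NULL) {
    if (is.null(probs)) probs <- rep(1 / length(residues), length(residues))
    freqs <- setNames(rep(0, 20), aa_alphabet())
    freqs[residues] <- probs
    structure(list(model = "custom", freqs = freqs), class = "freq_model")
}

# exhaustive enumeration oracle: exact inverse cumulative distribution of
# sum_j s(a_j, w_j) over all |alphabet|^L peptides, a_j ~ freqs
enumerate_window_dist <- function(window, mat, freq) {
    res <- names(freq$freqs)[freq$freqs > 0]
    w <- strsplit(window, "")[[1]]
    L <- length(w)
    cap <- L * mat$s_max
    grid <- do.call(expand.grid, rep(list(res), L))
    pmf <- numeric(cap + 1L)
    for (i in seq_len(nrow(grid))) {
        a <- as.character(unlist(grid[i, ]))
        s <- sum(mat$scores[cbind(a, w)])
        p <- prod(freq$freqs[a])
        pmf[s + 1L] <- pmf[s + 1L] + p
    }
    rev(cumsum(rev(pmf)))
}

# small deterministic peptide sets
random_peptides <- function(n, L = 12L, seed = 1L, residues = aa_alphabet()) {
    set.seed(seed)
    apply(matrix(sample(residues, n * L, replace = TRUE), n), 1, paste,
          collapse = "")
}

tiny_db <- function(seqs = c(A = "ACDEFGHIKLMNPQRSTVWYACDEFGHIKL",
                             B = "LKIHGFEDCAYWVTSRQPNMLKIHGFEDCA")) {
    protein_db(names(seqs), unname(seqs))
}

# independent oracle: enumerate every assignment of the pooled values to
# the x-group with combn(), recompute U for each, take tail fractions
mw_oracle <- function(x, y, alternative) {
    pool <- c(x, y)
    nx <- length(x)
    u_of <- function(idx) {
        xs <- pool[idx]; ys <- pool[-idx]
        sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
    }
    u_obs <- u_of(seq_len(nx))
    us <- apply(utils::combn(length(pool), nx), 2, u_of)
    p_le <- mean(us <= u_obs + 1e-9)
    p_ge <- mean(us >= u_obs - 1e-9)
    switch(alternative,
           "two-sided" = min(1, 2 * min(p_le, p_ge)),
           "greater" = p_ge, "less" = p_le)
}

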