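# Theoretical score-distribution maps (P).
#
# For a peptide drawn residue-wise i.i.d. from a frequency model, the
# similarity score against a fixed L-residue window is a sum of L
# independent per-site scores; its exact distribution is an integer
# convolution of the site distributions.  P is stored per window as an
# inverse cumulative distribution Pr(score >= s), s = 0..L*s_max.

#' Enumerate the 32 NNK codons
#'
#' N = any base at positions 1-2, K = G or T at position 3. 31 codons are
#' sense; TAG is the single reachable stop.
#'
#' @return Character vector of 32 codons.
#' @export
nnk_codons <- function() {
    b <- c("A", "C", "G", "T")
    as.vector(outer(outer(b, b, paste0), c("G", "T"), paste0))
}

#' Per-site amino-acid frequency model of the random library
#'
#' * `"uniform"` — every residue 1/20 ("20^12 random amino acids").
#' * `"nnn_no_stop"` — codon multiplicities over the 61 sense codons of a
#'   uniformly random base triplet (an ideally random cDNA library,
#'   conditioned on no stop). The default model for P.
#' * `"nnk_no_stop"` — multiplicities over the 31 sense NNK codons (the
#'   physical library design).
#' * `"empirical"` — observed residue frequencies in a (naive, round-0)
#'   count table, weighted by read counts.
#'
#' @param model Model name.
#' @param counts `peptide_counts`, required for `"empirical"`.
#' @return `freq_model`: list with `model` and `freqs` (named over the
#'   canonical alphabet, summing to 1).
#' @export
make_frequency_model <- function(model = c("nnn_no_stop", "nnk_no_stop",
                                           "uniform", "empirical"),
                                 counts = NULL) {
    model <- match.arg(model)
    if (model == "uniform") {
        freqs <- setNames(rep(1 / 20, 20), AA_ALPHABET)
    } else if (model == "empirical") {
        if (is.null(counts) || length(counts$counts) == 0L)
            stop("empirical model requires a non-empty count table")
        chars <- strsplit(names(counts$counts), "")
        w <- rep(counts$counts, lengths(chars))
        tab <- tapply(w, factor(unlist(chars), levels = AA_ALPHABET), sum,
                      default = 0)
        freqs <- setNames(as.numeric(tab) / sum(tab), AA_ALPHABET)
    } else {
        codons <- if (model == "nnk_no_stop") nnk_codons()
                  else names(Biostrings::GENETIC_CODE)
        aa <- Biostrings::GENETIC_CODE[codons]
        aa <- aa[aa != "*"]
        tab <- table(factor(aa, levels = AA_ALPHABET))
        freqs <- setNames(as.numeric(tab) / sum(tab), AA_ALPHABET)
    }
    structure(list(model = model, freqs = freqs), class = "freq_model")
}

# 20 x (s_max+1) matrix: row a = pmf of the site score s(X, a), X ~ freqs.
site_pmf_matrix <- function(matrix, freq) {
    sm <- matrix$s_max
    out <- base::matrix(0, nrow = 20L, ncol = sm + 1L,
                        dimnames = list(AA_ALPHABET, 0:sm))
    for (a in AA_ALPHABET)
        for (b in AA_ALPHABET)
            out[a, matrix$scores[b, a] + 1L] <-
                out[a, matrix$scores[b, a] + 1L] + freq$freqs[[b]]
    out
}

#' Distribution of the per-site similarity score against one residue
#'
#' @param residue Single amino-acid letter (window residue).
#' @param matrix A `subst_matrix`.
#' @param freq A `freq_model` for the random peptide residue.
#' @return Named numeric vector: probability mass over scores `0..s_max`.
#' @export
site_score_distribution <- function(residue, matrix, freq) {
    if (!residue %in% AA_ALPHABET)
        stop("residue outside the 20-letter alphabet: ", residue)
    site_pmf_matrix(matrix, freq)[residue, ]
}

# pmf -> inverse cumulative Pr(score >= s)
as_inv_cum <- function(pmf) rev(cumsum(rev(pmf)))

# row-wise inverse cumulative of an n x (cap+1) pmf/histogram matrix,
# via multiplication with a lower-triangular ones matrix (BLAS-fast)
inv_cum_rows <- function(m) {
    k <- ncol(m)
    tri <- base::matrix(0, k, k)
    tri[lower.tri(tri, diag = TRUE)] <- 1   # col s+1 sums rows >= s
    m %*% tri
}

#' Score distribution of a random peptide against one window
#'
#' Exact integer convolution of the `L` site distributions, returned in
#' inverse cumulative form over the full support `0..L*s_max`.
#'
#' @param window Amino-acid string of length L.
#' @param matrix A `subst_matrix`.
#' @param freq A `freq_model`.
#' @return `score_distribution`: list with `support` (integers) and
#'   `inv_cum` (`Pr(score >= s)`, non-increasing, `inv_cum[1] = 1`).
#' @export
window_score_distribution <- function(window, matrix, freq) {
    idx <- aa_index(window)
    if (anyNA(idx)) stop("window contains non-alphabet residues: ", window)
    L <- ncol(idx)
    cap <- L * matrix$s_max
    pmf <- cpp_pmap_windows(as.integer(idx[1, ]), site_pmf_matrix(matrix, freq),
                            L, cap)[1, ]
    structure(list(support = 0:cap, inv_cum = as_inv_cum(pmf)),
              class = "score_distribution")
}

#' Build the theoretical P-map over a whole protein database
#'
#' One inverse cumulative score distribution per fully contained window
#' (1-based start positions) of every protein of length >= L.  Identical
#' residue multisets share one convolution (the distribution depends on a
#' window only through its multiset).
#'
#' @param db A `protein_db`.
#' @param matrix A `subst_matrix`.
#' @param freq A `freq_model`.
#' @param L Window length (default 12).
#' @return `position_dist_map`: list with `dists` (per protein an
#'   `n_windows x (cap+1)` matrix of inverse cumulative rows), `L`, `cap`,
#'   `matrix_name`, `model`, `skipped` (proteins shorter than L).
#' @export
build_pmap <- function(db, matrix, freq, L = 12L) {
    stopifnot(inherits(db, "protein_db"), nrow(db) > 0L, L >= 1L)
    cap <- L * matrix$s_max
    spm <- site_pmf_matrix(matrix, freq)
    short <- nchar(db$sequence) < L
    if (any(short))
        message(sum(short), " protein(s) shorter than L = ", L, " skipped")
    dists <- list()
    for (i in which(!short)) {
        idx <- aa_index(db$sequence[i])[1, ]
        if (anyNA(idx)) {   # masked residues: distributions undefined there
            pmf <- matrix(NA_real_, nrow = length(idx) - L + 1L, ncol = cap + 1L)
            ok <- !is.na(idx)
            runs <- rle(ok)
            pos <- 1L
            for (r in seq_along(runs$lengths)) {
                if (runs$values[r] && runs$lengths[r] >= L) {
                    seg <- idx[pos:(pos + runs$lengths[r] - 1L)]
                    pmf[pos:(pos + runs$lengths[r] - L), ] <-
                        cpp_pmap_windows(seg, spm, L, cap)
                }
                pos <- pos + runs$lengths[r]
            }
        } else {
            pmf <- cpp_pmap_windows(idx, spm, L, cap)
        }
        dists[[db$protein_id[i]]] <- inv_cum_rows(pmf)
    }
    structure(list(dists = dists, L = as.integer(L), cap = cap,
                   matrix_name = matrix$name, model = freq$model,
                   skipped = db$protein_id[short]),
              class = "position_dist_map")
}

#' @export
print.position_dist_map <- function(x, ...) {
    cat(sprintf("P-map: %d protein(s), L = %d, support 0..%d, matrix %s, model %s\n",
                length(x$dists), x$L, x$cap, x$matrix_name, x$model))
    invisible(x)
}

#' Export one window's distribution as TSV
#'
#' @param map A `position_dist_map` or `qmap`.
#' @param protein_id,window_start Window address (1-based start).
#' @param path Output TSV (`score`, `inv_cum`).
#' @return `path`, invisibly.
#' @export
export_window_distribution <- function(map, protein_id, window_start, path) {
    m <- map$dists[[protein_id]]
    if (is.null(m)) stop("unknown protein: ", protein_id)
    df <- data.frame(score = 0:map$cap, inv_cum = m[window_start, ])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
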