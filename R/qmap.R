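# Empirical score-distribution maps (Q): the observed counterpart of P,
# computed from selected-peptide count tables.

#' Similarity scores of one peptide along a protein
#'
#' Ungapped, frame-locked: the score at window `i` is
#' `sum_j s(peptide[j], protein[i + j - 1])`.
#'
#' @param peptide Amino-acid string of length L.
#' @param protein Protein sequence (string).
#' @param matrix A `subst_matrix`.
#' @return Integer vector of window scores (empty if the protein is shorter
#'   than the peptide).
#' @export
peptide_window_scores <- function(peptide, protein, matrix) {
    p <- aa_index(peptide)[1, ]
    if (anyNA(p)) stop("peptide contains non-alphabet residues")
    t <- aa_index(protein)[1, ]
    if (length(t) < length(p)) return(integer(0))
    if (anyNA(t)) stop("protein contains non-alphabet residues")
    cpp_peptide_window_scores(p, t, matrix$scores)
}

#' Build the empirical Q-map from selected peptides
#'
#' For every window of every protein, the histogram of similarity scores
#' over the selected peptides — weighted by read count (`"reads"`, the
#' default: the experimental distribution is computed read-level) or one
#' per unique peptide (`"unique"`, robust to PCR bias) — converted to
#' inverse cumulative form on the same support as the P-map.
#'
#' @param counts A `peptide_counts` table.
#' @param db A `protein_db`.
#' @param matrix A `subst_matrix`.
#' @param L Window length; must equal the peptide length of `counts`.
#' @param weighting `"reads"` or `"unique"`.
#' @return `qmap` (also a `position_dist_map`): as [build_pmap()], plus
#'   `n_reads_used` and `weighting`.
#' @export
build_qmap <- function(counts, db, matrix, L = 12L,
                       weighting = c("reads", "unique")) {
    weighting <- match.arg(weighting)
    stopifnot(inherits(counts, "peptide_counts"), inherits(db, "protein_db"))
    if (length(counts$counts) == 0L) stop("empty count table: no peptides to score")
    peps <- names(counts$counts)
    if (any(nchar(peps) != L))
        stop("peptide length does not match L = ", L)
    pm <- aa_index(peps)
    if (anyNA(pm)) stop("count table contains non-alphabet peptides")
    w <- if (weighting == "reads") as.numeric(counts$counts)
         else rep(1, length(peps))
    total <- sum(w)
    cap <- L * matrix$s_max
    short <- nchar(db$sequence) < L
    dists <- list()
    for (i in which(!short)) {
        idx <- aa_index(db$sequence[i])[1, ]
        if (anyNA(idx))
            stop("protein ", db$protein_id[i], " contains non-alphabet residues;",
                 " load the database with ambiguous = \"drop\"")
        hist <- cpp_window_hist(pm, w, idx, matrix$scores, cap)
        dists[[db$protein_id[i]]] <- inv_cum_rows(hist / total)
    }
    structure(list(dists = dists, L = as.integer(L), cap = cap,
                   matrix_name = matrix$name, model = "empirical",
                   skipped = db$protein_id[short],
                   n_reads_used = as.integer(round(sum(counts$counts))),
                   weighting = weighting, round = counts$round,
                   sample_id = counts$sample_id),
              class = c("qmap", "position_dist_map"))
}

#' Merge Q-maps built from shards of one count table
#'
#' Weighted average of the inverse cumulative rows by the number of reads
#' (or unique peptides) behind each shard; identical to building one Q-map
#' from the merged table.
#'
#' @param ... `qmap` objects over the same proteome/matrix/L.
#' @return A merged `qmap`.
#' @export
merge_qmaps <- function(...) {
    maps <- list(...)
    stopifnot(length(maps) >= 1L)
    base <- maps[[1]]
    wts <- vapply(maps, function(m) as.numeric(m$n_reads_used), numeric(1))
    for (m in maps[-1])
        if (m$cap != base$cap || m$matrix_name != base$matrix_name ||
            !identical(names(m$dists), names(base$dists)))
            stop("qmaps are not compatible")
    out <- base
    for (pid in names(base$dists)) {
        acc <- base$dists[[pid]] * wts[1]
        for (k in seq_along(maps)[-1])
            acc <- acc + maps[[k]]$dists[[pid]] * wts[k]
        out$dists[[pid]] <- acc / sum(wts)
    }
    out$n_reads_used <- as.integer(sum(wts))
    out
}
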