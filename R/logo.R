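# Motif tracking across selection rounds and convergence logos at the
# top-scoring window.

#' Match a wildcard motif anywhere in a peptide
#'
#' `X` in the pattern matches any residue; the pattern may start at any
#' offset of the peptide.
#'
#' @param peptides Character vector of peptides.
#' @param pattern Motif string over the 20 amino acids plus `X`
#'   (e.g. the anti-FLAG motif `"DYKXXD"`).
#' @return Logical vector.
#' @export
match_motif <- function(peptides, pattern) {
    stopifnot(nchar(pattern) >= 1L,
              !grepl(sprintf("[^%sX]", paste(AA_ALPHABET, collapse = "")), pattern))
    pat <- strsplit(pattern, "")[[1]]
    m <- nchar(pattern)
    vapply(strsplit(peptides, ""), function(pv) {
        n <- length(pv)
        if (n < m) return(FALSE)
        for (off in 0:(n - m))
            if (all(pat == "X" | pat == pv[off + seq_len(m)])) return(TRUE)
        FALSE
    }, logical(1))
}

#' Motif read fraction per selection round
#'
#' @param tables List of `peptide_counts` for one sample, any round order.
#' @param pattern Motif string (see [match_motif()]).
#' @return Data.frame (`round`, `matched_reads`, `total_reads`,
#'   `fraction`), ordered by round; empty rounds report `NA` fraction.
#' @export
motif_fraction_by_round <- function(tables, pattern) {
    rows <- lapply(tables, function(tab) {
        total <- sum(tab$counts)
        matched <- if (total > 0)
            sum(tab$counts[match_motif(names(tab$counts), pattern)]) else 0L
        data.frame(round = tab$round, matched_reads = matched,
                   total_reads = total,
                   fraction = if (total > 0) matched / total else NA_real_)
    })
    out <- do.call(rbind, rows)
    out[order(out$round), , drop = FALSE]
}

#' Build a convergence logo from the most abundant peptides
#'
#' The `top_n` unique peptides by read count (ties by lexicographic
#' peptide) are stacked into a position frequency matrix weighted by read
#' counts.  With `align_to`, each peptide is first shifted to the offset
#' maximising its ungapped similarity score against the given window
#' (overlap-only scoring, ties to the smallest offset), so logos can be
#' anchored to the top-scoring protein window.
#'
#' @param counts A `peptide_counts`.
#' @param top_n Number of unique peptides to stack (default 1000).
#' @param align_to Optional list `(window = <L-aa string>, matrix =
#'   <subst_matrix>, max_shift = <int>)`; default no alignment (offset 0).
#' @param display_threshold Convergence fraction at or above which a
#'   residue is flagged for display (default 0.20).
#' @return `logo_matrix`: list with `freq` (20 x L column-stochastic
#'   matrix), `display` (logical 20 x L, `freq >= display_threshold`),
#'   `n_peptides`, `n_reads`, `offsets`, `display_threshold`.
#' @export
build_logo <- function(counts, top_n = 1000L, align_to = NULL,
                       display_threshold = 0.20) {
    stopifnot(inherits(counts, "peptide_counts"), top_n >= 1L)
    peps <- names(counts$counts)
    if (length(peps) == 0L) stop("empty count table")
    L <- counts$L
    ord <- order(-counts$counts, peps)
    if (length(peps) < top_n)
        warning("only ", length(peps), " unique peptides (< top_n = ", top_n, ")")
    sel <- ord[seq_len(min(top_n, length(peps)))]
    peps <- peps[sel]
    w <- as.numeric(counts$counts[sel])
    offsets <- rep(0L, length(peps))
    if (!is.null(align_to)) {
        win <- aa_index(align_to$window)[1, ]
        S <- align_to$matrix$scores
        max_shift <- align_to$max_shift %||% (L - 1L)
        pm <- aa_index(peps)
        shifts <- (-max_shift):max_shift
        best <- rep(-Inf, length(peps))
        for (s in shifts) {
            # peptide position j maps to window position j + s
            j <- seq_len(L)
            ok <- j + s >= 1L & j + s <= length(win)
            sc <- rowSums(matrix(S[cbind(as.vector(pm[, j[ok], drop = FALSE]) + 1L,
                                         rep(win[j[ok] + s] + 1L,
                                             each = length(peps)))],
                                 nrow = length(peps)))
            upd <- sc > best
            best[upd] <- sc[upd]
            offsets[upd] <- s
        }
    }
    freq <- matrix(0, nrow = 20L, ncol = L, dimnames = list(AA_ALPHABET, NULL))
    pm <- aa_index(peps)
    for (i in seq_along(peps)) {
        j <- seq_len(L)
        col <- j + offsets[i]
        ok <- col >= 1L & col <= L
        idx <- cbind(pm[i, j[ok]] + 1L, col[ok])
        freq[idx] <- freq[idx] + w[i]
    }
    colsum <- colSums(freq)
    colsum[colsum == 0] <- 1
    freq <- sweep(freq, 2L, colsum, "/")
    structure(list(freq = freq, display = freq >= display_threshold,
                   n_peptides = length(peps), n_reads = sum(w),
                   offsets = offsets, display_threshold = display_threshold),
              class = "logo_matrix")
}

#' Convergence-ratio difference between two residues at one position
#'
#' The displayed-logo analogue of a mutational scan: how much more often
#' the wild-type residue converged than a mutant at the same position.
#'
#' @param logo A `logo_matrix`.
#' @param position Column index (1..L).
#' @param wt,mt Amino-acid letters.
#' @return `freq(wt) - freq(mt)` at the position, in \[-1, 1\].
#' @export
delta_convergence <- function(logo, position, wt, mt) {
    stopifnot(inherits(logo, "logo_matrix"),
              position >= 1L, position <= ncol(logo$freq))
    if (!wt %in% AA_ALPHABET || !mt %in% AA_ALPHABET)
        stop("residues must be one of the 20 amino acids")
    unname(logo$freq[wt, position] - logo$freq[mt, position])
}

#' Write a logo frequency matrix as TSV
#' @param logo A `logo_matrix`.
#' @param path Output TSV (rows = amino acids, columns = positions).
#' @return `path`, invisibly.
#' @export
write_logo <- function(logo, path) {
    df <- data.frame(aa = rownames(logo$freq), logo$freq, check.names = FALSE)
    colnames(df) <- c("aa", paste0("pos", seq_len(ncol(logo$freq))))
    write_tsv_provenance(df, path, c(
        n_peptides = logo$n_peptides, n_reads = logo$n_reads,
        display_threshold = logo$display_threshold))
}
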