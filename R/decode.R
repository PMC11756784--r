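# Per-window epitope scores: the Pearson chi-square distance between the
# theoretical (P) and empirical (Q) inverse cumulative score distributions,
# summed over the score support ("decode score"), plus genome-wide ranking
# and plot-ready downsampling.

#' Pearson chi-square distance between two score distributions
#'
#' `d(s) = (Q(s) - P(s))^2 / max(P(s), floor)` at every score level, with
#' the theoretical distribution in the denominator; the floor guards the
#' far tail where P underflows to zero.
#'
#' @param P,Q `score_distribution` objects (or bare numeric inverse
#'   cumulative vectors) on identical support.
#' @param floor Denominator floor (default 1e-12).
#' @return List: `d` (per-score distances) and `sum`.
#' @export
chi2_distance <- function(P, Q, floor = 1e-12) {
    p <- if (inherits(P, "score_distribution")) P$inv_cum else P
    q <- if (inherits(Q, "score_distribution")) Q$inv_cum else Q
    if (length(p) != length(q))
        stop("P and Q supports differ (", length(p), " vs ", length(q), ")")
    d <- (q - p)^2 / pmax(p, floor)
    list(d = d, sum = sum(d))
}

#' Per-window decode scores along every protein
#'
#' For each window the chi-square distances between P and Q are summed over
#' the full score support; the resulting per-position track peaks at
#' windows whose selected-peptide similarity distribution departs from the
#' random-library expectation, i.e. at binding sites.
#'
#' @param pmap A `position_dist_map` from [build_pmap()].
#' @param qmap A `qmap` from [build_qmap()] over the same proteome, matrix
#'   and L (checked).
#' @param floor Chi-square denominator floor.
#' @return Named list of `decode_track` objects (`protein_id`, `scores`,
#'   `L`, `matrix_name`, `round`).
#' @export
decode_tracks <- function(pmap, qmap, floor = 1e-12) {
    if (pmap$L != qmap$L || pmap$cap != qmap$cap ||
        pmap$matrix_name != qmap$matrix_name)
        stop("P-map and Q-map provenance differs (matrix/L)")
    ids <- names(pmap$dists)
    if (!identical(sort(ids), sort(names(qmap$dists))))
        stop("P-map and Q-map cover different proteins")
    tracks <- lapply(ids, function(pid) {
        p <- pmap$dists[[pid]]
        q <- qmap$dists[[pid]]
        d <- (q - p)^2 / pmax(p, floor)
        structure(list(protein_id = pid, scores = rowSums(d), L = pmap$L,
                       matrix_name = pmap$matrix_name,
                       round = qmap$round %||% NA_integer_),
                  class = "decode_track")
    })
    setNames(tracks, ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalise a decode-score track by its mean
#'
#' Scores are divided by the track mean (so tracks from different
#' selections can share one axis); the normalised track has mean 1.
#'
#' @param track A `decode_track` with positive mean.
#' @return The normalised `decode_track`.
#' @export
normalize_track <- function(track) {
    stopifnot(inherits(track, "decode_track"))
    m <- mean(track$scores)
    if (!is.finite(m) || m <= 0) stop("track mean must be positive")
    track$scores <- track$scores / m
    track$normalized <- TRUE
    track
}

#' Genome-wide ranking of decode scores
#'
#' All (protein, window) scores sorted descending — ties broken by
#' protein ID then window start — plus a per-protein table of each
#' protein's maximum score, its position and its rank among protein
#' maxima.
#'
#' @param tracks List of `decode_track`s (all proteins of one selection).
#' @return `genome_scan`: list with `records` (data.frame `rank`,
#'   `protein_id`, `window_start`, `score`) and `proteins` (data.frame
#'   `rank`, `protein_id`, `window_start`, `max_score`).
#' @export
proteome_scan_rank <- function(tracks) {
    stopifnot(length(tracks) >= 1L)
    rec <- do.call(rbind, lapply(tracks, function(tr)
        data.frame(protein_id = tr$protein_id,
                   window_start = seq_along(tr$scores),
                   score = tr$scores, stringsAsFactors = FALSE)))
    ord <- order(-rec$score, rec$protein_id, rec$window_start)
    rec <- rec[ord, , drop = FALSE]
    rec <- data.frame(rank = seq_len(nrow(rec)), rec, row.names = NULL)
    pro <- do.call(rbind, lapply(tracks, function(tr) {
        w <- which.max(tr$scores)   # earliest window on ties
        data.frame(protein_id = tr$protein_id, window_start = w,
                   max_score = tr$scores[w], stringsAsFactors = FALSE)
    }))
    pord <- order(-pro$max_score, pro$protein_id, pro$window_start)
    pro <- pro[pord, , drop = FALSE]
    pro <- data.frame(rank = seq_len(nrow(pro)), pro, row.names = NULL)
    structure(list(records = rec, proteins = pro), class = "genome_scan")
}

#' @export
print.genome_scan <- function(x, ...) {
    cat(sprintf("genome scan: %d windows over %d proteins; top hit %s @ %d (score %.4g)\n",
                nrow(x$records), nrow(x$proteins), x$records$protein_id[1],
                x$records$window_start[1], x$records$score[1]))
    invisible(x)
}

#' Largest-Triangle-Three-Buckets downsampling
#'
#' Shape-preserving reduction of an ordered series for plotting: the series
#' is split into `ceiling(n * ratio)` buckets, the first and last points
#' are always kept, and from every interior bucket the point forming the
#' largest triangle with the previously selected point and the next
#' bucket's mean is retained (so spikes survive).
#'
#' @param y Numeric series, ordered by position.
#' @param ratio Fraction of points to keep, in (0, 1].
#' @param x Optional positions (default `seq_along(y)`).
#' @return Data.frame with the retained `x` and `y` (input unchanged when
#'   `n < 3` or `ratio = 1`).
#' @export
lttb_downsample <- function(y, ratio, x = seq_along(y)) {
    stopifnot(ratio > 0, ratio <= 1, length(x) == length(y))
    n <- length(y)
    n_out <- ceiling(n * ratio)
    if (n < 3L || ratio == 1 || n_out >= n)
        return(data.frame(x = x, y = y))
    if (n_out < 3L) n_out <- 3L
    nb <- n_out - 2L                       # interior buckets
    # bucket b holds interior points bounds[b] .. bounds[b+1] - 1
    bounds <- floor((0:nb) * (n - 2L) / nb) + 2L
    keep <- integer(n_out)
    keep[1] <- 1L
    a <- 1L
    for (b in seq_len(nb)) {
        seg <- bounds[b]:(bounds[b + 1L] - 1L)
        nxt <- if (b < nb) bounds[b + 1L]:(bounds[b + 2L] - 1L) else n
        mx <- mean(x[nxt]); my <- mean(y[nxt])
        area <- abs((x[a] - mx) * (y[seg] - y[a]) - (x[a] - x[seg]) * (my - y[a]))
        a <- seg[which.max(area)]
        keep[b + 1L] <- a
    }
    keep[n_out] <- n
    data.frame(x = x[keep], y = y[keep])
}

#' Write decode-score tracks / scans as TSV
#'
#' @param tracks List of `decode_track`s.
#' @param path Output TSV (`protein_id`, `window_start`, `score`,
#'   `normalized_score`).
#' @param provenance Optional named character vector written as `#` header.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, provenance = character(0)) {
    rows <- do.call(rbind, lapply(tracks, function(tr)
        data.frame(protein_id = tr$protein_id,
                   window_start = seq_along(tr$scores),
                   score = tr$scores,
                   normalized_score = tr$scores / mean(tr$scores),
                   stringsAsFactors = FALSE)))
    write_tsv_provenance(rows, path, provenance)
}

write_tsv_provenance <- function(df, path, provenance = character(0)) {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in names(provenance))
        writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
    utils::write.table(format(df, trim = TRUE, digits = 15, scientific = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
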