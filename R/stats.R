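# Replicate comparison of score tracks and exact group tests.

#' Correlation between two decode-score tracks
#'
#' @param track_a,track_b `decode_track`s (or bare numeric vectors) over
#'   the same protein, equal length.
#' @param method `"pearson"` or `"spearman"` (ties by average ranks).
#' @return The coefficient, or `NA` (with a message) when either track has
#'   zero variance.
#' @export
track_correlation <- function(track_a, track_b,
                              method = c("pearson", "spearman")) {
    method <- match.arg(method)
    a <- if (inherits(track_a, "decode_track")) track_a$scores else track_a
    b <- if (inherits(track_b, "decode_track")) track_b$scores else track_b
    if (length(a) != length(b)) stop("tracks differ in length")
    if (inherits(track_a, "decode_track") && inherits(track_b, "decode_track") &&
        track_a$protein_id != track_b$protein_id)
        stop("tracks cover different proteins")
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        message("zero-variance track: correlation undefined")
        return(NA_real_)
    }
    cor(a, b, method = method)
}

# Mann-Whitney U of x vs y from raw values (pairs won + half ties).
mw_u_statistic <- function(x, y) {
    r <- rank(c(x, y))          # mid-ranks
    sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Exact Mann-Whitney U test
#'
#' Exact p by enumeration over all assignments of the pooled values to the
#' two groups (shift-algorithm over the mid-rank-sum distribution, so ties
#' are handled exactly), used whenever the combined sample size is <= 25;
#' larger samples fall back to the normal approximation with tie
#' correction, flagged in the result.
#'
#' Two-sided p is `2 * min(P(U <= u), P(U >= u))` capped at 1.
#'
#' @param x,y Numeric group samples (non-empty).
#' @param alternative `"two-sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @return List: `U`, `p`, `method` (`"exact"` or `"normal"`), `n_x`,
#'   `n_y`.
#' @export
mann_whitney_exact <- function(x, y, alternative = c("two-sided", "greater",
                                                     "less")) {
    alternative <- match.arg(alternative)
    if (!length(x) || !length(y)) stop("both groups must be non-empty")
    nx <- length(x); ny <- length(y); n <- nx + ny
    U <- mw_u_statistic(x, y)
    if (n <= 25L) {
        # distribution of the x-group rank sum over all C(n, nx) label
        # assignments; 2x mid-ranks are integers, so an integer DP applies
        r2 <- as.integer(round(2 * rank(c(x, y))))
        dist <- ranksum_distribution(r2, nx)     # counts over 2*ranksum
        u2 <- as.integer(round(2 * U + nx * (nx + 1)))   # 2 * ranksum_x
        total <- sum(dist$count)
        p_le <- sum(dist$count[dist$value <= u2]) / total
        p_ge <- sum(dist$count[dist$value >= u2]) / total
        p <- switch(alternative,
                    "two-sided" = min(1, 2 * min(p_le, p_ge)),
                    "greater" = p_ge,
                    "less" = p_le)
        method <- "exact"
    } else {
        r <- rank(c(x, y))
        ties <- table(r)
        mu <- nx * ny / 2
        sig2 <- nx * ny / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
        z <- (U - mu) / sqrt(sig2)
        p <- switch(alternative,
                    "two-sided" = min(1, 2 * pnorm(-abs(z))),
                    "greater" = pnorm(z, lower.tail = FALSE),
                    "less" = pnorm(z))
        method <- "normal"
    }
    list(U = U, p = p, method = method, n_x = nx, n_y = ny)
}

# Exact distribution of the sum of nx values chosen from the integer
# multiset vals: returns data.frame(value, count of subsets).
ranksum_distribution <- function(vals, nx) {
    total <- sum(vals)
    # dp[k+1][s+1] = number of k-subsets summing to s
    dp <- matrix(0, nrow = nx + 1L, ncol = total + 1L)
    dp[1L, 1L] <- 1
    for (v in vals) {
        kmax <- nx
        for (k in kmax:1L) {
            shifted <- c(rep(0, v), dp[k, seq_len(total + 1L - v)])
            dp[k + 1L, ] <- dp[k + 1L, ] + shifted
        }
    }
    s <- which(dp[nx + 1L, ] > 0) - 1L
    data.frame(value = s, count = dp[nx + 1L, s + 1L])
}

#' Per-group summary of genome scans on one protein
#'
#' For serum-style comparisons: each sample's maximum decode score on a
#' designated protein and that protein's genome-wide rank.
#'
#' @param scans Named list of `genome_scan`s (one per sample).
#' @param protein_id Protein to summarise.
#' @param group Group label vector aligned with `scans`.
#' @return Data.frame (`sample`, `group`, `max_score`, `rank`).
#' @export
group_scores <- function(scans, protein_id, group) {
    stopifnot(length(scans) == length(group))
    rows <- lapply(seq_along(scans), function(i) {
        pro <- scans[[i]]$proteins
        j <- match(protein_id, pro$protein_id)
        if (is.na(j)) stop("protein ", protein_id, " absent from scan ", i)
        data.frame(sample = names(scans)[i] %||% as.character(i),
                   group = group[i], max_score = pro$max_score[j],
                   rank = pro$rank[j], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
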