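#' Build an amino-acid substitution matrix for similarity scoring
#'
#' Selection from a randomised peptide library never produces alignments with
#' meaningful negative similarity, so the scoring tables used throughout the
#' package floor all negative entries at zero (`zero_floor = TRUE`).  Two
#' tables are bundled:
#'
#' * `"blosum62_mod"` — the standard BLOSUM62 matrix (taken from
#'   \pkg{Biostrings}) with negative entries replaced by 0.  Maximum entry
#'   11 (W/W).
#' * `"wac_mod"` — a compact table with maximum entry 4 and a much narrower
#'   score range, which shrinks the score support roughly three-fold and with
#'   it the cost of the distribution computations.  The bundled file is a
#'   *synthetic* stand-in (zero-floored BLOSUM62 clipped at 4; see
#'   `inst/extdata/wac_synthetic.tsv`) that preserves the documented
#'   properties of such low-range tables; supply `path` to use a measured
#'   table instead.
#'
#' @param name `"blosum62_mod"`, `"wac_mod"`, or `"custom"` (requires `path`).
#' @param zero_floor Replace negative entries with 0 (the default used by the
#'   whole scoring pipeline).  `FALSE` returns the raw table.
#' @param path Optional TSV with a header row of amino acids and one labelled
#'   row per amino acid (see [write_substitution_matrix()]).
#' @return An object of class `subst_matrix`: list with `name`, `alphabet`,
#'   `scores` (20 x 20 integer matrix in canonical alphabet order) and
#'   `s_max` (largest entry).
#' @examples
#' m <- build_substitution_matrix("blosum62_mod")
#' m$scores["W", "W"]   # 11
#' min(m$scores)        # 0
#' @export
build_substitution_matrix <- function(name = c("blosum62_mod", "wac_mod", "custom"),
                                      zero_floor = TRUE, path = NULL) {
    name <- match.arg(name)
    if (name == "custom" || !is.null(path)) {
        if (is.null(path)) stop("name = \"custom\" requires `path`")
        scores <- read_matrix_tsv(path)
        if (name == "custom") name <- paste0("custom:", basename(path))
    } else if (name == "blosum62_mod") {
        scores <- blosum62_raw()
    } else {
        scores <- read_matrix_tsv(system.file("extdata", "wac_synthetic.tsv",
                                              package = "epitopescan", mustWork = TRUE))
    }
    scores <- scores[AA_ALPHABET, AA_ALPHABET]
    if (!isTRUE(all.equal(scores, t(scores))))
        stop("substitution matrix is not symmetric")
    if (any(scores != round(scores)))
        stop("substitution matrix entries must be integers")
    storage.mode(scores) <- "integer"
    if (zero_floor) scores[scores < 0L] <- 0L
    structure(list(name = name, alphabet = AA_ALPHABET, scores = scores,
                   s_max = max(scores), zero_floor = zero_floor),
              class = "subst_matrix")
}

# Standard published BLOSUM62, via the Biostrings data set, restricted to the
# 20 canonical residues.
blosum62_raw <- function() {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    m <- env$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
    storage.mode(m) <- "double"
    m
}

read_matrix_tsv <- function(path) {
    df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
    rn <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- rn
    missing <- setdiff(AA_ALPHABET, intersect(rownames(m), colnames(m)))
    if (length(missing))
        stop("matrix file lacks amino acid(s): ", paste(missing, collapse = ", "))
    storage.mode(m) <- "double"
    m[AA_ALPHABET, AA_ALPHABET]
}

#' Write a substitution matrix as TSV
#'
#' Header row of amino acids, one labelled row per amino acid; leading
#' comment lines (`#`) carry provenance.
#'
#' @param mat A `subst_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_substitution_matrix <- function(mat, path) {
    stopifnot(inherits(mat, "subst_matrix"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# substitution matrix: %s (zero_floor=%s, s_max=%d)",
                       mat$name, mat$zero_floor, mat$s_max), con)
    writeLines(paste(c("aa", colnames(mat$scores)), collapse = "\t"), con)
    for (a in rownames(mat$scores))
        writeLines(paste(c(a, mat$scores[a, ]), collapse = "\t"), con)
    invisible(path)
}

#' @export
print.subst_matrix <- function(x, ...) {
    cat(sprintf("substitution matrix '%s': 20 x 20, s_max = %d, zero_floor = %s\n",
                x$name, x$s_max, x$zero_floor))
    invisible(x)
}
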