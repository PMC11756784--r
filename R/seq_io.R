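# Reading proteomes and selection reads, and turning reads into peptide
# count tables.  All heavy formats go through Biostrings; plain-text reads
# (one sequence per line) are also accepted.

#' Read a UniProt-style proteome FASTA into a protein database
#'
#' @param path FASTA file.
#' @param ambiguous Policy for sequences containing non-standard residues
#'   (B, J, O, U, X, Z): `"drop"` removes the protein and logs it,
#'   `"mask"` keeps it (windows touching masked residues are later skipped).
#' @return `protein_db`: data.frame with columns `protein_id`, `description`,
#'   `sequence`, plus attribute `discarded` (named counts by reason).
#' @export
read_fasta_db <- function(path, ambiguous = c("drop", "mask")) {
    ambiguous <- match.arg(ambiguous)
    set <- Biostrings::readAAStringSet(path)
    if (length(set) == 0L) stop("empty FASTA: ", path)
    headers <- names(set)
    ids <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicate protein ID(s): ", paste(unique(dup), collapse = ", "))
    seqs <- toupper(as.character(set))
    protein_db(ids, seqs, desc, ambiguous = ambiguous)
}

#' Construct a protein database from vectors
#'
#' @param protein_id Unique identifiers.
#' @param sequence Amino-acid sequences (uppercased on input).
#' @param description Optional descriptions.
#' @param ambiguous See [read_fasta_db()].
#' @return A `protein_db` data.frame.
#' @export
protein_db <- function(protein_id, sequence, description = "",
                       ambiguous = c("drop", "mask")) {
    ambiguous <- match.arg(ambiguous)
    stopifnot(length(protein_id) == length(sequence), !anyDuplicated(protein_id))
    sequence <- toupper(sequence)
    ok <- !grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), sequence)
    discarded <- c(ambiguous_residues = 0L)
    if (ambiguous == "drop" && any(!ok)) {
        discarded["ambiguous_residues"] <- sum(!ok)
        message(sum(!ok), " protein(s) dropped (non-standard residues)")
        protein_id <- protein_id[ok]
        sequence <- sequence[ok]
        description <- rep_len(description, length(ok))[ok]
    }
    db <- data.frame(protein_id = protein_id,
                     description = rep_len(description, length(protein_id)),
                     sequence = sequence, stringsAsFactors = FALSE)
    attr(db, "discarded") <- discarded
    class(db) <- c("protein_db", "data.frame")
    db
}

#' Write a protein database as FASTA
#' @param db A `protein_db`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta_db <- function(db, path) {
    set <- Biostrings::AAStringSet(setNames(db$sequence, trimws(paste(
        db$protein_id, db$description))))
    Biostrings::writeXStringSet(set, path)
    invisible(path)
}

#' Read selection reads from FASTQ, FASTA or plain text
#'
#' Base qualities are ignored. Plain text is one nucleotide sequence per
#' line (blank lines skipped).
#'
#' @param path Input file; format chosen by extension (`.fastq`/`.fq`,
#'   `.fasta`/`.fa`, otherwise plain text).
#' @return Character vector of uppercase nucleotide reads.
#' @export
read_reads <- function(path) {
    lower <- tolower(path)
    if (grepl("\\.(fastq|fq)$", lower))
        reads <- as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
    else if (grepl("\\.(fasta|fa|fna)$", lower))
        reads <- as.character(Biostrings::readDNAStringSet(path))
    else {
        reads <- readLines(path)
        reads <- reads[nzchar(reads)]
    }
    unname(toupper(reads))
}

hamming <- function(a, b) {
    stopifnot(nchar(a) == nchar(b))
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Demultiplex reads by 5' barcode
#'
#' Each read is assigned to the unique barcode matching its prefix within
#' `max_mismatch` substitutions; reads matching no barcode go to the
#' `"unassigned"` bin.  Barcode pairs closer than `2 * max_mismatch + 1`
#' would make assignment ambiguous and raise a configuration error.
#'
#' @param reads Character vector of nucleotide reads.
#' @param barcode_map Named character vector `barcode -> sample_id`, or a
#'   two-column data.frame/TSV path (`barcode`, `sample_id`).
#' @param max_mismatch 0 or 1 substitutions tolerated in the barcode.
#' @return List of `read_batch` objects (one per sample, barcode stripped),
#'   plus `unassigned` reads and an `assignment` count table.
#' @export
demultiplex_reads <- function(reads, barcode_map, max_mismatch = 0L) {
    stopifnot(max_mismatch %in% c(0L, 1L))
    if (is.character(barcode_map) && length(barcode_map) == 1L &&
        file.exists(barcode_map)) {
        df <- utils::read.delim(barcode_map, header = FALSE, comment.char = "#",
                                stringsAsFactors = FALSE)
        barcode_map <- setNames(df[[2]], toupper(df[[1]]))
    }
    barcodes <- names(barcode_map)
    blen <- unique(nchar(barcodes))
    if (length(blen) != 1L) stop("barcodes must share one length")
    for (i in seq_along(barcodes)) for (j in seq_along(barcodes))
        if (i < j && hamming(barcodes[i], barcodes[j]) <= 2L * max_mismatch)
            stop("barcodes ", barcodes[i], " and ", barcodes[j],
                 " are within ", 2L * max_mismatch, " mismatches: ambiguous")
    prefix <- substr(reads, 1L, blen)
    assign_idx <- match(prefix, barcodes)
    if (max_mismatch == 1L && anyNA(assign_idx)) {
        miss <- which(is.na(assign_idx))
        pm <- matrix(unlist(strsplit(prefix[miss], "")), ncol = blen, byrow = TRUE)
        for (k in seq_along(barcodes)) {
            bc <- strsplit(barcodes[k], "")[[1]]
            d <- rowSums(pm != matrix(bc, nrow = length(miss), ncol = blen,
                                      byrow = TRUE))
            hit <- d <= 1L
            assign_idx[miss[hit]] <- k
        }
    }
    batches <- lapply(seq_along(barcodes), function(k) {
        r <- reads[which(assign_idx == k)]
        read_batch(sample_id = unname(barcode_map[k]), round = NA_integer_,
                   sequences = substring(r, blen + 1L))
    })
    names(batches) <- unname(barcode_map)
    assignment <- c(setNames(tabulate(assign_idx, length(barcodes)),
                             unname(barcode_map)),
                    unassigned = sum(is.na(assign_idx)))
    list(batches = batches, unassigned = reads[is.na(assign_idx)],
         assignment = assignment)
}

#' A batch of reads for one sample / selection round
#' @param sample_id Sample label.
#' @param round Selection round (0 = naive library).
#' @param sequences Nucleotide reads.
#' @return A `read_batch` list.
#' @export
read_batch <- function(sample_id, round, sequences) {
    structure(list(sample_id = sample_id, round = round, sequences = sequences),
              class = "read_batch")
}

# Constant flanks of the (NNK)12 cassette in the display template:
# ...GGAGATATACAT ATG (NNK)12 TGCGGCAGCGGCAGC...
DEFAULT_ANCHOR5 <- "GGAGATATACATATG"
DEFAULT_ANCHOR3 <- "TGCGGCAGCGGCAGC"

#' Extract the 36-nt randomised region from reads
#'
#' Locates the constant flanks of the (NNK)12 cassette and returns the
#' region between them.  Reads missing an anchor, with anchors in
#' conflicting positions, or with a region length other than 36 are
#' discarded with a reason code.
#'
#' @param reads Character vector of nucleotide reads.
#' @param anchor5,anchor3 Constant flanks (defaults from the display
#'   template; the 5' anchor ends with the ATG start codon).
#' @param max_mismatch Substitutions tolerated within each anchor (0 or 1).
#' @return List: `region` (character vector of extracted 36-mers) and
#'   `discarded` (named counts: `no_anchor5`, `no_anchor3`,
#'   `anchor_conflict`, `bad_length`).
#' @export
extract_random_region <- function(reads, anchor5 = DEFAULT_ANCHOR5,
                                  anchor3 = DEFAULT_ANCHOR3,
                                  max_mismatch = 0L) {
    stopifnot(max_mismatch %in% c(0L, 1L))
    find_anchor <- function(reads, anchor) {
        pos <- regexpr(anchor, reads, fixed = TRUE)
        if (max_mismatch == 1L && any(pos < 0L)) {
            miss <- which(pos < 0L)
            al <- nchar(anchor)
            av <- strsplit(anchor, "")[[1]]
            for (i in miss) {
                rv <- strsplit(reads[i], "")[[1]]
                n <- length(rv)
                if (n < al) next
                for (st in seq_len(n - al + 1L)) {
                    if (sum(rv[st:(st + al - 1L)] != av) <= 1L) {
                        pos[i] <- st
                        break
                    }
                }
            }
        }
        as.integer(pos)
    }
    p5 <- find_anchor(reads, anchor5)
    p3 <- find_anchor(reads, anchor3)
    reason <- rep(NA_character_, length(reads))
    reason[p5 < 0L] <- "no_anchor5"
    reason[is.na(reason) & p3 < 0L] <- "no_anchor3"
    start <- p5 + nchar(anchor5)
    reason[is.na(reason) & p3 < start] <- "anchor_conflict"
    len <- p3 - start
    reason[is.na(reason) & len != 36L] <- "bad_length"
    keep <- is.na(reason)
    region <- substr(reads[keep], start[keep], p3[keep] - 1L)
    reasons <- c("no_anchor5", "no_anchor3", "anchor_conflict", "bad_length")
    discarded <- setNames(vapply(reasons, function(r) sum(reason == r, na.rm = TRUE),
                                 integer(1)), reasons)
    list(region = region, discarded = discarded)
}

#' Translate 36-nt NNK cassette regions into 12-mer peptides
#'
#' Standard genetic code.  Regions containing `N` are discarded
#' (`ambiguous_base`); regions containing a stop codon are discarded
#' (`stop_codon`).  Under NNK sampling the only reachable stop is TAG.
#'
#' @param regions Character vector of 36-nt sequences (an error otherwise:
#'   length filtering is the caller's contract, see
#'   [extract_random_region()]).
#' @return List: `peptide` (12-aa strings) and `discarded` (named counts).
#' @export
translate_nnk <- function(regions) {
    if (length(regions) && any(nchar(regions) != 36L))
        stop("translate_nnk expects 36-nt regions")
    ambiguous <- grepl("N", regions, fixed = TRUE)
    pep <- rep(NA_character_, length(regions))
    if (any(!ambiguous)) {
        keep <- which(!ambiguous)
        codons <- matrix("", length(keep), 12L)
        for (j in 1:12)
            codons[, j] <- substr(regions[keep], 3L * j - 2L, 3L * j)
        aa <- matrix(Biostrings::GENETIC_CODE[codons], length(keep), 12L)
        pep[keep] <- do.call(paste0, as.data.frame(aa, stringsAsFactors = FALSE))
    }
    has_stop <- grepl("*", pep, fixed = TRUE)
    ok <- !ambiguous & !has_stop
    list(peptide = pep[ok],
         discarded = c(ambiguous_base = sum(ambiguous),
                       stop_codon = sum(has_stop, na.rm = TRUE)))
}

#' Collapse peptides into a count table
#'
#' @param peptides Character vector of 12-mer peptides.
#' @param sample_id,round Labels carried on the table.
#' @param discarded Named integer vector of upstream discard counts.
#' @param L Expected peptide length (default 12).
#' @return `peptide_counts`: list with `sample_id`, `round`, `counts`
#'   (named integer vector, peptide -> count), `total_reads`
#'   (`sum(counts) + sum(discarded)`), `discarded`.
#' @export
build_count_table <- function(peptides, sample_id = "sample", round = 0L,
                              discarded = integer(0), L = 12L) {
    if (length(peptides) == 0L)
        warning("empty peptide input: zero-total count table")
    if (length(peptides) && any(nchar(peptides) != L))
        stop("all peptides must have length ", L)
    if (length(peptides) && any(grepl("*", peptides, fixed = TRUE)))
        stop("stop symbols are not allowed in peptides")
    tab <- table(peptides)
    counts <- setNames(as.integer(tab), names(tab))
    structure(list(sample_id = sample_id, round = as.integer(round),
                   counts = counts,
                   total_reads = length(peptides) + sum(discarded),
                   discarded = discarded, L = as.integer(L)),
              class = "peptide_counts")
}

#' Read/write peptide count tables as TSV
#'
#' Two columns (`peptide`, `count`); `#`-prefixed header lines carry
#' sample, round and discard provenance and are restored on read.
#'
#' @param x A `peptide_counts`.
#' @param path File path.
#' @return `write_count_table`: `path` invisibly; `read_count_table`: the
#'   `peptide_counts` object.
#' @export
write_count_table <- function(x, path) {
    stopifnot(inherits(x, "peptide_counts"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# sample_id: %s", x$sample_id), con)
    writeLines(sprintf("# round: %d", x$round), con)
    writeLines(sprintf("# total_reads: %d", x$total_reads), con)
    if (length(x$discarded))
        writeLines(sprintf("# discarded: %s",
                           paste(names(x$discarded), x$discarded,
                                 sep = "=", collapse = ",")), con)
    writeLines("peptide\tcount", con)
    ord <- order(names(x$counts))
    writeLines(paste(names(x$counts)[ord], x$counts[ord], sep = "\t"), con)
    invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "#")]
    get <- function(key, default = NA) {
        m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
        if (!length(m)) return(default)
        trimws(sub(sprintf("^# %s:", key), "", m[1]))
    }
    discarded <- integer(0)
    d <- get("discarded", NA)
    if (!is.na(d)) {
        kv <- strsplit(strsplit(d, ",")[[1]], "=")
        discarded <- setNames(as.integer(vapply(kv, `[`, "", 2L)),
                              vapply(kv, `[`, "", 1L))
    }
    df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    counts <- setNames(as.integer(df$count), df$peptide)
    tab <- build_count_table(rep(names(counts), counts),
                             sample_id = get("sample_id", "sample"),
                             round = as.integer(get("round", 0)),
                             discarded = discarded,
                             L = if (length(counts)) nchar(names(counts)[1]) else 12L)
    tab
}

#' @export
print.peptide_counts <- function(x, ...) {
    cat(sprintf("peptide count table: sample '%s' round %d, %d unique / %d reads (%d discarded)\n",
                x$sample_id, x$round, length(x$counts), x$total_reads,
                sum(x$discarded)))
    invisible(x)
}
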