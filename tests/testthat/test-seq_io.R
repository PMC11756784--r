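test_that("FASTA databases round-trip with IDs and descriptions preserved", {
    db <- protein_db(c("sp|P1|X", "sp|P2|Y"),
                     c("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEV",
                       "ACDEFGHIKLMNPQRSTVWY"),
                     description = c("protein one", "protein two"))
    fa <- tempfile(fileext = ".fasta")
    write_fasta_db(db, fa)
    db2 <- read_fasta_db(fa)
    expect_identical(db2$protein_id, db$protein_id)
    expect_identical(db2$sequence, db$sequence)
    # independent record count: ">" lines
    expect_identical(sum(startsWith(readLines(fa), ">")), nrow(db2))
})

test_that("ambiguous residues follow the drop policy; duplicates error", {
    fa <- tempfile(fileext = ".fasta")
    writeLines(c(">ok", "ACDEFGHIKLMN", ">hasX", "ACDEFGHIKXMN"), fa)
    expect_message(db <- read_fasta_db(fa, ambiguous = "drop"), "dropped")
    expect_identical(db$protein_id, "ok")
    expect_identical(unname(attr(db, "discarded")["ambiguous_residues"]), 1L)
    db_mask <- read_fasta_db(fa, ambiguous = "mask")
    expect_identical(nrow(db_mask), 2L)

    writeLines(c(">dup", "ACDE", ">dup", "ACDF"), fa)
    expect_error(read_fasta_db(fa), "dup")
    writeLines(character(0), fa)
    expect_error(read_fasta_db(fa))
})

test_that("demultiplexing assigns within the mismatch budget and logs the rest", {
    bc <- c(ACGTAC = "s1", TGCAGG = "s2")
    reads <- c(paste0("ACGTAC", "AAAA"),    # exact s1
               paste0("TGCAGG", "CCCC"),    # exact s2
               paste0("ACGAAC", "GGGG"),    # 1 mismatch of s1
               paste0("TTTTTT", "TTTT"))    # no match
    dm0 <- demultiplex_reads(reads, bc, max_mismatch = 0L)
    expect_identical(dm0$batches$s1$sequences, "AAAA")
    expect_identical(unname(dm0$assignment["unassigned"]), 2L)

    dm1 <- demultiplex_reads(reads, bc, max_mismatch = 1L)
    expect_setequal(dm1$batches$s1$sequences, c("AAAA", "GGGG"))
    expect_identical(unname(dm1$assignment["unassigned"]), 1L)
    # conservation: assigned + unassigned = input
    expect_identical(sum(dm1$assignment), length(reads))

    # barcodes within the mismatch radius are a configuration error
    expect_error(demultiplex_reads(reads, c(ACGTAC = "a", ACGTAG = "b"),
                                   max_mismatch = 1L), "ambiguous")
})

test_that("random-region extraction enforces anchors and length", {
    a5 <- "GGAGATATACATATG"; a3 <- "TGCGGCAGCGGCAGC"
    insert36 <- strrep("GCT", 12)
    reads <- c(paste0("TT", a5, insert36, a3, "AA"),        # good
               paste0(a5, substr(insert36, 1, 35), a3),     # 35 nt
               paste0(a5, insert36),                        # no anchor3
               paste0(insert36, a3))                        # no anchor5
    ex <- extract_random_region(reads)
    expect_identical(ex$region, insert36)
    expect_identical(unname(ex$discarded[c("bad_length", "no_anchor3",
                                           "no_anchor5")]), c(1L, 1L, 1L))
    # conservation: extracted + discarded = input
    expect_identical(length(ex$region) + sum(ex$discarded), length(reads))

    # one substitution inside the 5' anchor rescued at max_mismatch = 1
    mut <- paste0(sub("^G", "C", a5), insert36, a3)
    expect_identical(extract_random_region(mut)$discarded[["no_anchor5"]], 1L)
    expect_identical(extract_random_region(mut, max_mismatch = 1L)$region,
                     insert36)
})

test_that("NNK translation follows the standard code and discards stops/Ns", {
    expect_identical(translate_nnk(strrep("GCT", 12))$peptide,
                     strrep("A", 12))
    tr <- translate_nnk(paste0("TAG", strrep("GCT", 11)))
    expect_length(tr$peptide, 0)
    expect_identical(unname(tr$discarded["stop_codon"]), 1L)
    trN <- translate_nnk(paste0("GCN", strrep("GCT", 11)))
    expect_identical(unname(trN$discarded["ambiguous_base"]), 1L)
    expect_error(translate_nnk("GCTGCT"), "36")
})

test_that("translation agrees with the frozen reference code on every codon", {
    codons <- names(GENETIC_CODE_ORACLE)
    regions <- paste0(codons, strrep("GGT", 11))
    for (i in seq_along(codons)) {
        tr <- translate_nnk(regions[i])
        expected <- GENETIC_CODE_ORACLE[[codons[i]]]
        if (expected == "*") {
            expect_identical(unname(tr$discarded["stop_codon"]), 1L,
                             info = codons[i])
        } else {
            expect_identical(substr(tr$peptide, 1, 1), expected,
                             info = codons[i])
        }
    }
    # exactly 1 of the 32 NNK codons is a stop (TAG)
    nnk_aa <- GENETIC_CODE_ORACLE[nnk_codons()]
    expect_identical(sum(nnk_aa == "*"), 1L)
    expect_identical(names(nnk_aa)[nnk_aa == "*"], "TAG")
})

test_that("count tables collapse multisets order-independently and round-trip", {
    peps <- c(strrep("A", 12), strrep("A", 12), strrep("C", 12))
    tab <- build_count_table(peps, "s1", 2L,
                             discarded = c(stop_codon = 3L))
    expect_identical(unname(tab$counts[strrep("A", 12)]), 2L)
    expect_identical(tab$total_reads, 6L)
    expect_identical(sum(tab$counts) + sum(tab$discarded), tab$total_reads)
    tab_perm <- build_count_table(rev(peps), "s1", 2L,
                                  discarded = c(stop_codon = 3L))
    expect_identical(tab_perm$counts[order(names(tab_perm$counts))],
                     tab$counts[order(names(tab$counts))])

    tsv <- tempfile(fileext = ".tsv")
    write_count_table(tab, tsv)
    tab2 <- read_count_table(tsv)
    expect_identical(tab2$counts[names(tab$counts)], tab$counts)
    expect_identical(tab2$round, 2L)
    expect_identical(tab2$total_reads, tab$total_reads)
    expect_identical(tab2$discarded, tab$discarded)

    expect_warning(empty <- build_count_table(character(0)), "empty")
    expect_identical(empty$total_reads, 0L)
    expect_error(build_count_table(c("SHORT")), "length")
})

test_that("simulated reads are conserved through counting", {
    tab <- generate_library(n_reads = 1e4L, seed = 7L)
    expect_identical(sum(tab$counts) + sum(tab$discarded), 10000L)
})
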