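test_that("motif matching honours wildcards and offsets", {
    expect_true(match_motif("DYKDDDDKAGSG", "DYKXXD"))
    expect_false(match_motif("AAAAAAAAAAAA", "DYKXXD"))
    expect_true(all(match_motif(random_peptides(20, 12, seed = 2), "XXXXXX")))
    # equals a regex scan on random peptides
    peps <- random_peptides(1e4, 12, seed = 31)
    expect_identical(match_motif(peps, "DYKXXD"), grepl("DYK..D", peps))
    expect_error(match_motif("AAAA", "DY*"))
})

test_that("motif fractions per round are count-weighted and order-invariant", {
    mk <- function(peps, counts, round) {
        tab <- build_count_table(rep(peps, counts), "s", round)
        tab
    }
    flag <- "DYKDDDDKAGSG"; other <- "AAAAAAAAAAAA"
    t1 <- mk(c(flag, other), c(3, 1), 1L)
    mf <- motif_fraction_by_round(list(t1), "DYKXXD")
    expect_equal(mf$fraction, 0.75)

    t2 <- mk(flag, 5, 2L)
    mf2 <- motif_fraction_by_round(list(t2, t1), "DYKXXD")
    expect_identical(mf2$round, c(1L, 2L))
    expect_equal(mf2$fraction, c(0.75, 1.0))

    empty <- suppressWarnings(build_count_table(character(0), "s", 3L))
    mf3 <- motif_fraction_by_round(list(t1, empty), "DYKXXD")
    expect_true(is.na(mf3$fraction[2]))
})

test_that("logos stack count-weighted frequencies that sum to one", {
    tab <- build_count_table(c("ACAAAAAAAAAA", "ADAAAAAAAAAA"), "s", 1L)
    logo <- build_logo(tab, top_n = 2)
    expect_equal(colSums(logo$freq), rep(1, 12), tolerance = 1e-9)
    expect_equal(unname(logo$freq["A", 1]), 1)
    expect_equal(unname(logo$freq["C", 2]), 0.5)
    expect_equal(unname(logo$freq["D", 2]), 0.5)

    # degenerate: all peptides identical -> point-mass columns
    tab1 <- build_count_table(rep("ACDEFGHIKLMN", 3), "s", 1L)
    logo1 <- build_logo(tab1, top_n = 1)
    expect_true(all(apply(logo1$freq, 2, max) == 1))

    # count weighting equals replicating peptides
    tabw <- build_count_table(rep(c("ACAAAAAAAAAA", "ADAAAAAAAAAA"), c(3, 1)),
                              "s", 1L)
    tabr <- build_count_table(c(rep("ACAAAAAAAAAA", 3), "ADAAAAAAAAAA"),
                              "s", 1L)
    expect_equal(build_logo(tabw, top_n = 2)$freq,
                 build_logo(tabr, top_n = 2)$freq, tolerance = 1e-12)

    expect_warning(build_logo(tab, top_n = 10), "top_n")
})

test_that("hotspot positions converge in a planted table; background does not", {
    # 500 peptides carrying D/Y/K/D at positions 1/2/3/6, random elsewhere,
    # mixed with 500 fully random peptides
    set.seed(17)
    carrier <- random_peptides(500, 12, seed = 170)
    for (p in c(1, 2, 3, 6))
        substr(carrier, p, p) <- c("D", "Y", "K", "", "", "D")[p]
    noise <- random_peptides(500, 12, seed = 171)
    tab <- build_count_table(c(carrier, noise), "s", 3L)
    logo <- build_logo(tab, top_n = 1000)
    expect_gte(logo$freq["D", 1], 0.20)
    expect_gte(logo$freq["Y", 2], 0.20)
    expect_gte(logo$freq["K", 3], 0.20)
    expect_gte(logo$freq["D", 6], 0.20)
    hot <- c("1" = "D", "2" = "Y", "3" = "K", "6" = "D")
    for (p in names(hot))
        expect_true(logo$display[hot[[p]], as.integer(p)])
    # non-hotspot columns stay below the display threshold
    expect_lt(max(logo$freq[, c(4, 5, 7:12)]), 0.20)
})

test_that("window-anchored alignment shifts peptides to their best offset", {
    win <- "WWWWAAAAAAAA"
    # peptide matching the window shifted right by 2
    pep <- paste0("CC", substr(win, 1, 10))
    tab <- build_count_table(pep, "s", 1L)
    logo <- build_logo(tab, top_n = 1,
                       align_to = list(window = win, matrix = B62))
    expect_identical(logo$offsets, -2L)
    # after shifting, the W block lands on columns 1..4... peptide pos 3
    # maps to window pos 1
    expect_equal(unname(logo$freq["W", 1]), 1)

    # offset 0 wins ties (identical peptide)
    tab0 <- build_count_table(win, "s", 1L)
    logo0 <- build_logo(tab0, top_n = 1,
                        align_to = list(window = win, matrix = B62))
    expect_identical(logo0$offsets, 0L)
})

test_that("delta convergence is a bounded frequency difference", {
    tab <- build_count_table(rep(c("ACAAAAAAAAAA", "ADAAAAAAAAAA"), c(9, 1)),
                             "s", 1L)
    logo <- build_logo(tab, top_n = 2)
    expect_equal(delta_convergence(logo, 2, "C", "D"), 0.8, tolerance = 1e-12)
    expect_identical(delta_convergence(logo, 2, "C", "C"), 0)
    expect_error(delta_convergence(logo, 2, "C", "B"), "amino")
    for (p in 1:12)
        expect_true(abs(delta_convergence(logo, p, "A", "W")) <= 1)
})
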