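test_that("frequency models match codon enumeration", {
    u <- make_frequency_model("uniform")
    expect_true(all(abs(u$freqs - 0.05) < 1e-15))

    # independent enumeration over the frozen reference code
    nnk_aa <- GENETIC_CODE_ORACLE[nnk_codons()]
    nnk_aa <- nnk_aa[nnk_aa != "*"]
    nnk <- make_frequency_model("nnk_no_stop")
    expect_equal(sum(nnk$freqs), 1, tolerance = 1e-12)
    expect_equal(unname(nnk$freqs["M"]), 1 / 31, tolerance = 1e-12)
    for (a in aa_alphabet())
        expect_equal(unname(nnk$freqs[a]), sum(nnk_aa == a) / 31,
                     tolerance = 1e-12, info = a)

    nnn_aa <- GENETIC_CODE_ORACLE[GENETIC_CODE_ORACLE != "*"]
    nnn <- make_frequency_model("nnn_no_stop")
    expect_equal(unname(nnn$freqs["L"]), 6 / 61, tolerance = 1e-12)
    for (a in aa_alphabet())
        expect_equal(unname(nnn$freqs[a]), sum(nnn_aa == a) / 61,
                     tolerance = 1e-12, info = a)

    tab <- build_count_table(c("AAAAAAAAAAAC", "AAAAAAAAAAAC", "CAAAAAAAAAAA"),
                             "s", 0L)
    emp <- make_frequency_model("empirical", counts = tab)
    expect_equal(unname(emp$freqs["C"]), 3 / 36, tolerance = 1e-12)
    expect_error(make_frequency_model("empirical"), "count table")
})

test_that("site distributions are exact sums over residues", {
    freq <- make_frequency_model("uniform")
    for (res in c("W", "A", "P")) {
        d <- site_score_distribution(res, B62, freq)
        # brute force over the 20 residues
        expected <- numeric(B62$s_max + 1)
        for (a in aa_alphabet())
            expected[B62$scores[a, res] + 1] <-
                expected[B62$scores[a, res] + 1] + 0.05
        expect_equal(unname(d), expected, tolerance = 1e-15, info = res)
    }
    # point-mass frequency gives a point mass at the self score
    pm <- restricted_freq("W", 1)
    d <- site_score_distribution("W", B62, pm)
    expect_identical(unname(which(d > 0)) - 1L, B62$scores["W", "W"])
    expect_error(site_score_distribution("X", B62, freq), "alphabet")
})

test_that("window distributions equal exhaustive enumeration (alphabets <= 4, L <= 6)", {
    alphabets <- list(c("A", "C"), c("A", "C", "D"), c("A", "C", "D", "W"))
    set.seed(42)
    for (res in alphabets) {
        freq <- restricted_freq(res)
        # and one non-uniform frequency over the same support
        p <- seq_along(res); p <- p / sum(p)
        freq2 <- restricted_freq(res, p)
        for (L in c(1L, 2L, 4L, 6L)) {
            for (rep in 1:2) {
                win <- paste(sample(res, L, replace = TRUE), collapse = "")
                for (fr in list(freq, freq2)) {
                    got <- window_score_distribution(win, B62, fr)
                    expect_equal(got$inv_cum,
                                 enumerate_window_dist(win, B62, fr),
                                 tolerance = 1e-12, info = win)
                }
            }
        }
    }
})

test_that("window distributions: structural invariants and multiset dependence", {
    freq <- FREQ_NNN
    d <- window_score_distribution("WYELMKRHND", B62, freq)
    expect_equal(d$inv_cum[1], 1, tolerance = 1e-14)
    expect_true(all(diff(d$inv_cum) <= 1e-15))
    expect_true(all(d$inv_cum >= -1e-15 & d$inv_cum <= 1 + 1e-15))

    # L = 1 reduces to the site distribution in inverse cumulative form
    s1 <- window_score_distribution("W", B62, freq)
    site <- site_score_distribution("W", B62, freq)
    expect_equal(s1$inv_cum, rev(cumsum(rev(unname(site)))), tolerance = 1e-14)

    # permutations of a window share one distribution
    a <- window_score_distribution("AACD", B62, freq)
    b <- window_score_distribution("DACA", B62, freq)
    expect_equal(a$inv_cum, b$inv_cum, tolerance = 1e-12)
})

test_that("build_pmap covers every window and skips short proteins", {
    db <- protein_db(c("long", "short"),
                     c(random_peptides(1, 100, seed = 3)[1], "ACDEF"))
    expect_message(pm <- build_pmap(db, B62, FREQ_NNN, L = 12L), "skipped")
    expect_identical(names(pm$dists), "long")
    expect_identical(nrow(pm$dists$long), 100L - 12L + 1L)
    expect_identical(pm$skipped, "short")
    expect_identical(ncol(pm$dists$long), 12L * B62$s_max + 1L)
    # every row is a valid inverse cumulative distribution
    expect_equal(unname(pm$dists$long[, 1]), rep(1, 89), tolerance = 1e-12)
    expect_true(all(pm$dists$long[, -1] - pm$dists$long[, -ncol(pm$dists$long)]
                    <= 1e-12))

    # identical windows (here: identical proteins) give identical rows
    db2 <- protein_db(c("p1", "p2"), rep(db$sequence[1], 2))
    pm2 <- build_pmap(db2, B62, FREQ_NNN)
    expect_identical(pm2$dists$p1, pm2$dists$p2)

    expect_error(build_pmap(protein_db(character(0), character(0)),
                            B62, FREQ_NNN))
})
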