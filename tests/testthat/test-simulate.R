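# Reduced scales are used for the slower properties and noted inline; the
# full-scale defaults are exercised by test-acceptance.R.

test_that("library generation is seed-deterministic with NNK stop arithmetic", {
    a <- generate_library(2e4L, seed = 5L)
    b <- generate_library(2e4L, seed = 5L)
    expect_identical(a$counts, b$counts)
    expect_identical(a$discarded, b$discarded)
    c_ <- generate_library(2e4L, seed = 6L)
    expect_false(identical(a$counts, c_$counts))

    # stop-discard fraction ~ 1 - (31/32)^12
    tab <- generate_library(1e5L, seed = 1L)
    frac <- tab$discarded[["stop_codon"]] / tab$total_reads
    expect_lt(abs(frac - (1 - (31 / 32)^12)), 0.01)
})

test_that("library residue frequencies converge to the NNK model", {
    tab <- generate_library(1e6L, seed = 2L)
    nnk <- make_frequency_model("nnk_no_stop")
    emp <- make_frequency_model("empirical", counts = tab)
    expect_lt(max(abs(emp$freqs - nnk$freqs)), 0.005)
})

test_that("null selection is a plain resample; zero capture errors", {
    db <- tiny_db()
    pool <- generate_library(2e4L, seed = 3L)
    truth0 <- selection_truth(db, "A", 5L, enrichment_strength = 0)
    out <- selection_round(pool, truth0, n_out = 2e4L, seed = 4L)
    # motif fraction stays within sampling error of the input
    pat <- "AXXAXXXXXXXX"
    f_in <- motif_fraction_by_round(list(pool), pat)$fraction
    f_out <- motif_fraction_by_round(list(out), pat)$fraction
    expect_lt(abs(f_in - f_out), 3 * sqrt(f_in * (1 - f_in) / 2e4))

    # scaling pool counts leaves the multinomial distribution unchanged
    pool2 <- pool
    pool2$counts <- pool2$counts * 2L
    truth <- selection_truth(db, "A", 5L)
    expect_identical(selection_round(pool, truth, 1e4L, seed = 9L)$counts,
                     selection_round(pool2, truth, 1e4L, seed = 9L)$counts)

    truth_dead <- selection_truth(db, "A", 5L, background_binding = 0,
                                  enrichment_strength = 1e9,
                                  half_saturation = 999)
    expect_error(selection_round(pool, truth_dead, 1e4L, seed = 1L), "zero")
})

test_that("experiments conserve reads and carry a usable truth", {
    db <- make_toy_proteome(10L, 60L, seed = 1L)
    truth <- selection_truth(db, "P0005", 20L)
    exp <- simulate_experiment(db, truth, rounds = 2L, reads_per_round = 5e3L,
                               library_size = 5e4L, seed = 11L)
    expect_length(exp$rounds, 3L)
    for (r in 2:3)
        expect_identical(sum(exp$rounds[[r]]$counts), 5000L)
    expect_identical(exp$rounds[[2]]$round, 1L)
    expect_identical(exp$truth$epitope,
                     substr(db$sequence[db$protein_id == "P0005"], 20, 31))
    # byte-identical reruns
    exp2 <- simulate_experiment(db, truth, rounds = 2L, reads_per_round = 5e3L,
                                library_size = 5e4L, seed = 11L)
    for (r in 1:3)
        expect_identical(exp$rounds[[r]]$counts, exp2$rounds[[r]]$counts)

    expect_error(simulate_experiment(db, selection_truth(db, "P0001", 1L),
                                     library_size = 10),
                 "library_size|reads")
})

test_that("stronger enrichment never worsens the planted window's rank", {
    # reduced scale: 20 x 150-aa proteome, 2 rounds, 2e4 reads, 2e5 pool
    db <- make_toy_proteome(20L, 150L, seed = 7L)
    truth_at <- function(s) selection_truth(db, "P0010", 70L,
                                            enrichment_strength = s)
    pm <- build_pmap(db, B62, FREQ_NNN)
    ranks <- vapply(c(0.25, 1, 4), function(s) {
        exp <- simulate_experiment(db, truth_at(s), rounds = 2L,
                                   reads_per_round = 2e4L,
                                   library_size = 2e5L, seed = 31L)
        qm <- build_qmap(exp$rounds[[3]], db, B62)
        scan <- proteome_scan_rank(decode_tracks(pm, qm))
        scan$proteins$rank[scan$proteins$protein_id == "P0010"]
    }, numeric(1))
    expect_true(all(diff(ranks) <= 0))
})

test_that("serum mimics recover multiple planted epitopes; titration degrades the signal", {
    # pool depth matters here for the same reason as in the default world:
    # chance single-clone spikes shrink quadratically with pool size
    db <- make_toy_proteome(20L, 150L, seed = 7L)
    pm <- build_pmap(db, B62, FREQ_NNN)
    truths <- list(selection_truth(db, "P0003", 40L),
                   selection_truth(db, "P0015", 90L))
    exp <- simulate_experiment(db, truths, rounds = 3L,
                               reads_per_round = 5e4L,
                               library_size = 1e6L, seed = 41L)
    qm <- build_qmap(exp$rounds[[4]], db, B62)
    scan <- proteome_scan_rank(decode_tracks(pm, qm))
    top2 <- scan$proteins$protein_id[1:2]
    expect_setequal(top2, c("P0003", "P0015"))

    # spike-in titration: a smaller antibody fraction weakens the planted
    # window signal monotonically, and the rank ends worse at trace level
    at_fraction <- function(f) {
        tr <- selection_truth(db, "P0010", 70L, antibody_fraction = f)
        exp <- simulate_experiment(db, tr, rounds = 2L, reads_per_round = 5e4L,
                                   library_size = 1e6L, seed = 51L)
        qm <- build_qmap(exp$rounds[[3]], db, B62)
        scan <- proteome_scan_rank(decode_tracks(pm, qm))
        i <- scan$proteins$protein_id == "P0010"
        c(score = scan$proteins$max_score[i], rank = scan$proteins$rank[i])
    }
    res <- vapply(c(1, 0.05, 0.002), at_fraction, numeric(2))
    expect_true(all(diff(res["score", ]) < 0))
    expect_gt(res["rank", 3], res["rank", 1])
})
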