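# Seeded simulator of display-selection experiments with planted ground
# truth: NNK naive libraries, affinity-weighted selection rounds, and
# sequencing sampling.  Stands in for raw selection NGS data so the whole
# scoring pipeline is testable end to end.

#' Generate a random toy proteome
#'
#' Residues drawn i.i.d. from a frequency model; deterministic under seed.
#'
#' @param n_proteins Number of proteins (default 100).
#' @param length Protein length (default 300).
#' @param seed RNG seed.
#' @param freq A `freq_model` (default `"nnn_no_stop"`).
#' @return A `protein_db` with IDs `P0001`, `P0002`, ...
#' @export
make_toy_proteome <- function(n_proteins = 100L, length = 300L, seed = 1L,
                              freq = make_frequency_model("nnn_no_stop")) {
    with_seed(seed, {
        seqs <- vapply(seq_len(n_proteins), function(i)
            paste(sample(AA_ALPHABET, length, replace = TRUE,
                         prob = freq$freqs), collapse = ""), character(1))
        protein_db(sprintf("P%04d", seq_len(n_proteins)), seqs,
                   description = "synthetic random protein")
    })
}

#' Planted ground truth for a simulated selection
#'
#' The planted epitope is one 12-mer window of one proteome protein.  A
#' subset of window positions are hotspots: residues whose identity is
#' energetically critical for binding (a hotspot mutation strongly
#' reduces affinity).  By default (`grading = "delta"`) only the planted
#' residue itself carries the hotspot energy; `grading = "similarity"`
#' grades the energy of residue `a` by `s(a, w) / s(w, w)` so
#' conservative substitutions retain partial binding.  Hotspots spanning
#' the whole window (default positions 1, 2, 4, 6, 7, 9, 11, 12) pin the
#' peptide-to-window register, which is what makes the recovered window
#' position a sharp observable.
#'
#' Capture saturates: a peptide with summed hotspot energy `E` is
#' captured with probability `background + (1 - background) *
#' plogis(enrichment_strength * (E - half_saturation))`.  Saturation is
#' what keeps the selected pool clonally diverse — without it the single
#' best clone present in the naive sample takes over the pool within
#' three rounds.  The defaults (energy 3.0 per hotspot, half-saturation
#' 12, i.e. four matched hotspots give 50% capture) make the round-3 pool
#' a few-thousand-clone mixture dominated by 4-of-8 and 5-of-8 hotspot
#' matchers at the default pool size of [simulate_experiment()].
#'
#' @param db A `protein_db`.
#' @param protein_id Protein carrying the epitope.
#' @param window_start 1-based window start.
#' @param hotspots Hotspot positions within the window (1..L).
#' @param energy Binding energy of a perfect hotspot match (log scale;
#'   default 3.0).
#' @param enrichment_strength Slope of the capture-saturation curve
#'   (default 1.0; 0 disables selection — every peptide is captured with
#'   the same probability).
#' @param background_binding Non-specific capture probability
#'   (default 0.01).
#' @param half_saturation Summed hotspot energy at 50% capture
#'   (default 12).
#' @param grading `"delta"` (planted residue only) or `"similarity"`.
#' @param antibody_fraction Fraction of the capturing antibody pool that
#'   this truth's antibody makes up (default 1; scales the specific
#'   capture term, emulating spike-in titrations into serum).
#' @param matrix `subst_matrix` used to grade near-match residues when
#'   `grading = "similarity"`.
#' @param L Window length (12).
#' @return `selection_truth`: list incl. `epitope` (the window sequence)
#'   and `hotspot_weights` (per-position named energy vectors).
#' @export
selection_truth <- function(db, protein_id, window_start,
                            hotspots = c(1L, 2L, 4L, 6L, 7L, 9L, 11L, 12L),
                            energy = 3.0, enrichment_strength = 1.0,
                            background_binding = 0.01, half_saturation = 12,
                            grading = c("delta", "similarity"),
                            antibody_fraction = 1,
                            matrix = build_substitution_matrix("blosum62_mod"),
                            L = 12L) {
    grading <- match.arg(grading)
    seq <- db$sequence[db$protein_id == protein_id]
    if (length(seq) != 1L) stop("unknown protein: ", protein_id)
    if (window_start < 1L || window_start + L - 1L > nchar(seq))
        stop("window does not fit inside ", protein_id)
    epitope <- substr(seq, window_start, window_start + L - 1L)
    stopifnot(all(hotspots >= 1L), all(hotspots <= L), energy >= 0,
              enrichment_strength >= 0, background_binding >= 0)
    eps <- strsplit(epitope, "")[[1]]
    weights <- vector("list", L)
    for (p in seq_len(L)) {
        if (p %in% hotspots) {
            w <- eps[p]
            weights[[p]] <- if (grading == "similarity")
                setNames(energy * matrix$scores[AA_ALPHABET, w] /
                             matrix$scores[w, w], AA_ALPHABET)
            else
                setNames(energy * (AA_ALPHABET == w), AA_ALPHABET)
        } else {
            weights[[p]] <- setNames(rep(0, 20), AA_ALPHABET)
        }
    }
    structure(list(epitope_protein_id = protein_id,
                   window_start = as.integer(window_start),
                   epitope = epitope, hotspots = as.integer(hotspots),
                   hotspot_weights = weights, energy = energy,
                   enrichment_strength = enrichment_strength,
                   background_binding = background_binding,
                   half_saturation = half_saturation,
                   antibody_fraction = antibody_fraction, L = as.integer(L)),
              class = "selection_truth")
}

#' Simulate a naive NNK library
#'
#' Each read is 12 NNK codons drawn uniformly at the nucleotide level
#' (uniform N, K in G/T), translated with the standard code; reads with a
#' stop codon (only TAG is reachable) are discarded and logged.
#'
#' @param n_reads Number of reads (default 1e5).
#' @param seed RNG seed.
#' @param error_rate Optional per-base substitution rate (default 0).
#' @param keep_regions Also return the nucleotide cassettes (for FASTQ
#'   emulation).
#' @return A `peptide_counts` (round 0); with `keep_regions`, attribute
#'   `regions` holds the kept 36-nt cassettes.
#' @export
generate_library <- function(n_reads = 1e5L, seed = 1L, error_rate = 0,
                             keep_regions = FALSE) {
    stopifnot(n_reads >= 1L)
    with_seed(seed, {
        codons <- nnk_codons()   # 32 equiprobable NNK codons
        draw <- matrix(sample(codons, 12L * n_reads, replace = TRUE),
                       nrow = n_reads)
        regions <- do.call(paste0, as.data.frame(draw, stringsAsFactors = FALSE))
        if (error_rate > 0) {
            bases <- c("A", "C", "G", "T")
            n_mut <- rbinom(1L, 36L * n_reads, error_rate)
            if (n_mut > 0) {
                at <- sample.int(36L * n_reads, n_mut)
                read_i <- (at - 1L) %/% 36L + 1L
                pos_i <- (at - 1L) %% 36L + 1L
                for (k in seq_len(n_mut))
                    substr(regions[read_i[k]], pos_i[k], pos_i[k]) <-
                        sample(bases, 1L)
            }
        }
        tr <- translate_nnk(regions)
        tab <- build_count_table(tr$peptide, sample_id = "sim", round = 0L,
                                 discarded = tr$discarded)
        if (keep_regions) attr(tab, "regions") <- regions
        tab
    })
}

# capture probability of each peptide under the planted truth:
# background + (1 - background) * plogis(strength * (E - E_half)), with E
# the best-offset summed hotspot energy.  With full-span hotspot maps only
# offset 0 applies.
capture_weights <- function(peptides, truth) {
    pm <- aa_index(peptides)
    L <- truth$L
    wmat <- do.call(cbind, truth$hotspot_weights)   # 20 x L
    n <- length(peptides)
    span <- range(which(vapply(truth$hotspot_weights,
                               function(w) any(w != 0), logical(1))))
    max_off <- L - (span[2] - span[1] + 1L)
    energy <- matrix(-Inf, n, 2L * max_off + 1L)
    for (k in -max_off:max_off) {
        # peptide position j + k carries the weight of window position j
        j <- seq_len(L)
        ok <- j + k >= 1L & j + k <= L & j >= span[1] & j <= span[2]
        e <- rowSums(matrix(wmat[cbind(as.vector(pm[, j[ok] + k, drop = FALSE]) + 1L,
                                       rep(j[ok], each = n))], nrow = n))
        energy[, k + max_off + 1L] <- e
    }
    best <- do.call(pmax, as.data.frame(energy))
    bg <- truth$background_binding
    f <- truth$antibody_fraction %||% 1
    bg + (1 - bg) * f * stats::plogis(truth$enrichment_strength *
                                          (best - truth$half_saturation))
}

# combined capture probability under one truth or a list of independent
# antibodies (a serum mimic): escape all of them to escape capture
capture_probability <- function(peptides, truth) {
    if (inherits(truth, "selection_truth"))
        return(capture_weights(peptides, truth))
    stopifnot(length(truth) >= 1L,
              all(vapply(truth, inherits, logical(1), "selection_truth")))
    p_escape <- 1
    for (tr in truth) p_escape <- p_escape * (1 - capture_weights(peptides, tr))
    1 - p_escape
}

#' One round of affinity-weighted selection
#'
#' Each peptide is captured with probability `background_binding +
#' (1 - background_binding) * plogis(enrichment_strength * (E -
#' half_saturation))`, `E` being its best-offset summed hotspot energy;
#' the next round (capture followed by re-amplification to `n_out`
#' molecules) is a multinomial draw with probabilities proportional to
#' `count * capture probability`.
#'
#' @param pool A `peptide_counts` (the current pool).
#' @param truth A `selection_truth`, or a list of them (a serum mimic:
#'   independent antibodies, capture by any one retains the peptide).
#' @param n_out Reads in the output round.
#' @param seed RNG seed.
#' @return A `peptide_counts` for the next round.
#' @export
selection_round <- function(pool, truth, n_out = 1e5L, seed = 1L) {
    stopifnot(inherits(pool, "peptide_counts"), length(pool$counts) > 0L)
    w <- capture_probability(names(pool$counts), truth)
    prob <- as.numeric(pool$counts) * w
    if (all(prob == 0)) stop("all capture weights are zero")
    with_seed(seed, {
        draw <- as.integer(rmultinom(1L, n_out, prob))
        keep <- draw > 0L
        tab <- structure(list(sample_id = pool$sample_id,
                              round = pool$round + 1L,
                              counts = setNames(draw[keep],
                                                names(pool$counts)[keep]),
                              total_reads = as.integer(n_out),
                              discarded = integer(0), L = pool$L),
                         class = "peptide_counts")
        tab
    })
}

#' Subsample a count table to a sequencing depth
#'
#' Multinomial draw of `n_reads` reads from the table, emulating the
#' sequencer sampling a small fraction of the physical pool.
#'
#' @param pool A `peptide_counts`.
#' @param n_reads Reads to draw.
#' @param seed RNG seed.
#' @return A `peptide_counts` with `sum(counts) = n_reads`.
#' @export
subsample_reads <- function(pool, n_reads, seed = 1L) {
    stopifnot(inherits(pool, "peptide_counts"))
    if (sum(pool$counts) <= n_reads) return(pool)
    with_seed(seed, {
        draw <- as.integer(rmultinom(1L, n_reads, as.numeric(pool$counts)))
        keep <- draw > 0L
        structure(list(sample_id = pool$sample_id, round = pool$round,
                       counts = setNames(draw[keep], names(pool$counts)[keep]),
                       total_reads = as.integer(n_reads),
                       discarded = integer(0), L = pool$L),
                  class = "peptide_counts")
    })
}

#' Simulate a complete selection experiment
#'
#' A naive NNK pool of `library_size` molecules is carried through
#' `rounds` affinity-weighted selection rounds against the planted truth;
#' after each round (including round 0) the sequencer samples
#' `reads_per_round` reads from the pool.  The pool is much deeper than
#' the sequencing depth, as in a real experiment (where it is deeper by
#' many orders of magnitude); this is what keeps the selected pool
#' clonally diverse.  Deterministic under `seed` (per-stage seeds are
#' derived from it).
#'
#' @param db A `protein_db` containing the epitope protein.
#' @param truth A `selection_truth` built on `db`, or a list of them.
#' @param rounds Number of selection rounds (default 3).
#' @param reads_per_round Reads sequenced per round (default 1e5).
#' @param library_size Molecules in the physical pool (default 4e6;
#'   deep pools keep single clones from dominating the selected rounds).
#' @param seed Master RNG seed.
#' @return `sim_experiment`: list with `rounds` (list of `peptide_counts`
#'   at sequencing depth, index 1 = round 0 naive library), `pools`
#'   (pool-depth tables), `truth`, `reads_per_round`, `seed`.
#' @export
simulate_experiment <- function(db, truth, rounds = 3L,
                                reads_per_round = 1e5L,
                                library_size = 4e6L, seed = 1L) {
    truths <- if (inherits(truth, "selection_truth")) list(truth) else truth
    stopifnot(all(vapply(truths, inherits, logical(1), "selection_truth")),
              library_size >= reads_per_round)
    if (!all(vapply(truths, `[[`, "", "epitope_protein_id") %in% db$protein_id))
        stop("truth protein not in proteome")
    seeds <- derive_seeds(seed, 2L * (rounds + 1L))
    pools <- tabs <- vector("list", rounds + 1L)
    pools[[1]] <- generate_library(library_size, seed = seeds[1])
    for (r in seq_len(rounds))
        pools[[r + 1L]] <- selection_round(pools[[r]], truth,
                                           n_out = library_size,
                                           seed = seeds[r + 1L])
    for (r in seq_len(rounds + 1L))
        tabs[[r]] <- subsample_reads(pools[[r]], reads_per_round,
                                     seed = seeds[rounds + 1L + r])
    structure(list(rounds = tabs, pools = pools, truth = truth,
                   reads_per_round = as.integer(reads_per_round),
                   library_size = as.integer(library_size),
                   seed = as.integer(seed)),
              class = "sim_experiment")
}

# derive k child seeds < 2^31 deterministically from one master seed
derive_seeds <- function(seed, k) {
    with_seed(seed, sample.int(.Machine$integer.max, k))
}

#' Default planted-epitope scenario
#'
#' The standard synthetic world used by the tests: 100-protein x 300-aa
#' random proteome, epitope planted at window 101 of protein `P0050`,
#' hotspots 1/2/4/6/7/9/11/12 at energy 3.0 with half-saturation 12,
#' enrichment strength 1.0, background 0.01, 3 rounds, 4e6-molecule pool
#' sequenced at 1e5 reads/round.
#'
#' @param seed Master seed.
#' @param reads_per_round,rounds,library_size Overrides of the defaults.
#' @param enrichment_strength Override of the default 1.0.
#' @return List: `db`, `truth`, `experiment`.
#' @export
default_planted_scenario <- function(seed = 1L, reads_per_round = 1e5L,
                                     rounds = 3L, library_size = 4e6L,
                                     enrichment_strength = 1.0) {
    db <- make_toy_proteome(100L, 300L, seed = 20260910L)
    truth <- selection_truth(db, "P0050", 101L,
                             enrichment_strength = enrichment_strength)
    exp <- simulate_experiment(db, truth, rounds = rounds,
                               reads_per_round = reads_per_round,
                               library_size = library_size, seed = seed)
    list(db = db, truth = truth, experiment = exp)
}
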