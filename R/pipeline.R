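# Pipeline orchestration: a single entry point dispatching the analysis
# stages, JSON configuration, provenance headers and hash-based resumption.

#' Default analysis configuration
#'
#' All tunables of the analysis with their defaults: window length `L`
#' (12, the library's random-region length), matrix (`blosum62_mod`),
#' frequency model (`nnn_no_stop`), chi-square floor (1e-12), logo top-N
#' (1000) and display threshold (0.20), LTTB plot-downsampling ratio
#' (1/50), Q weighting (`reads`), seed, and the output directory.
#'
#' @param ... Overrides of any default field.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
    cfg <- list(
        proteome = NULL,
        matrix = "blosum62_mod",
        freq_model = "nnn_no_stop",
        L = 12L,
        chi2_floor = 1e-12,
        top_n_logo = 1000L,
        display_threshold = 0.20,
        lttb_ratio = 1 / 50,
        weighting = "reads",
        seed = 1L,
        rounds = 3L,
        reads_per_round = 1e5,
        library_size = 4e6,
        out_dir = "epitopescan_out")
    over <- list(...)
    cfg[names(over)] <- over
    cfg
}

#' Read / write a configuration file (JSON)
#' @param path JSON file.
#' @param cfg Configuration list.
#' @return `read_config`: the configuration merged over the defaults;
#'   `write_config`: `path`, invisibly.
#' @export
read_config <- function(path) {
    do.call(default_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    invisible(path)
}

config_hash <- function(cfg, inputs = character(0)) {
    if (is.null(inputs)) inputs <- character(0)
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                                digits = NA, null = "null"), tmp)
    h <- tools::md5sum(tmp)[[1]]
    for (f in inputs[file.exists(inputs)])
        h <- paste0(h, ":", tools::md5sum(f)[[1]])
    tmp2 <- tempfile(); on.exit(unlink(tmp2), add = TRUE)
    writeLines(h, tmp2)
    tools::md5sum(tmp2)[[1]]
}

provenance_fields <- function(cfg, inputs = character(0)) {
    c(tool = paste0("epitopescan ",
                    as.character(utils::packageVersion("epitopescan"))),
      config_hash = config_hash(cfg, inputs),
      inputs = paste(inputs, collapse = ","))
}

# a stage is skipped when its output exists and records the same
# config+input hash
stage_current <- function(path, hash) {
    if (!file.exists(path)) return(FALSE)
    hdr <- readLines(path, n = 10L)
    any(grepl(hash, hdr, fixed = TRUE))
}

#' Run one pipeline stage
#'
#' Dispatches the analysis stages on a shared configuration:
#'
#' * `"demux"` — split reads by barcode (`inputs$reads`, `inputs$barcodes`).
#' * `"count"` — extract cassette, translate, write a count table
#'   (`inputs$reads` or a demuxed batch).
#' * `"pmap"` — build and cache the theoretical P-map for the configured
#'   proteome/matrix/model.
#' * `"score"` — build Q from a count-table TSV (`inputs$counts`), score
#'   against P (built on the fly if absent, logged), write the per-window
#'   track, the ranked genome scan, the top-K table and the LTTB plot
#'   table.
#' * `"logo"` — convergence logo at the top-scoring window
#'   (`inputs$counts`).
#' * `"motif"` — motif fraction per round (`inputs$counts` = vector of
#'   TSVs, `inputs$pattern`).
#' * `"simulate-selection"` — run the planted-truth simulator, write
#'   per-round count tables and a truth manifest.
#' * `"simulate-penetration"` — run the reaction-diffusion simulator,
#'   write depth profiles.
#' * `"compare"` — Mann-Whitney comparison of per-sample max scores
#'   (`inputs$scores`, `inputs$group`).
#'
#' Every output TSV carries `#` provenance headers (tool version, config
#' hash, inputs); a stage whose output already records the current hash is
#' skipped.
#'
#' @param command Stage name (above).
#' @param config Configuration list ([default_config()]) or JSON path.
#' @param inputs Named list of stage inputs.
#' @return Named character vector of artifact paths, invisibly.
#' @export
run_pipeline <- function(command = c("demux", "count", "pmap", "score",
                                     "logo", "motif", "simulate-selection",
                                     "simulate-penetration", "compare"),
                         config = default_config(), inputs = list()) {
    command <- match.arg(command)
    if (is.character(config)) config <- read_config(config)
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, file.path(config$out_dir, "config.json"))
    in_files <- unlist(inputs[vapply(inputs, is.character, logical(1))])
    if (is.null(in_files)) in_files <- character(0)
    in_files <- in_files[file.exists(in_files)]
    prov <- provenance_fields(config, in_files)
    hash <- prov[["config_hash"]]
    out <- function(name) file.path(config$out_dir, name)
    matrixx <- function() build_substitution_matrix(config$matrix)
    freq <- function() make_frequency_model(config$freq_model)
    proteome <- function() {
        if (is.null(config$proteome)) stop("config$proteome is required")
        read_fasta_db(config$proteome)
    }

    artifacts <- switch(command,
    "demux" = {
        reads <- read_reads(inputs$reads)
        dm <- demultiplex_reads(reads, inputs$barcodes,
                                max_mismatch = inputs$max_mismatch %||% 0L)
        paths <- character(0)
        for (sid in names(dm$batches)) {
            p <- out(sprintf("reads_%s.txt", sid))
            writeLines(dm$batches[[sid]]$sequences, p)
            paths[sid] <- p
        }
        rep <- out("demux_report.tsv")
        write_tsv_provenance(data.frame(sample = names(dm$assignment),
                                        reads = as.integer(dm$assignment)),
                             rep, prov)
        c(paths, report = rep)
    },
    "count" = {
        target <- out(sprintf("counts_%s_r%d.tsv",
                              inputs$sample_id %||% "sample",
                              inputs$round %||% 0L))
        if (stage_current(target, hash)) {
            message("count: output current, skipped")
            return(invisible(c(counts = target)))
        }
        reads <- read_reads(inputs$reads)
        ex <- extract_random_region(reads,
                                    anchor5 = inputs$anchor5 %||% DEFAULT_ANCHOR5,
                                    anchor3 = inputs$anchor3 %||% DEFAULT_ANCHOR3,
                                    max_mismatch = inputs$anchor_mismatch %||% 0L)
        tr <- translate_nnk(ex$region)
        tab <- build_count_table(tr$peptide,
                                 sample_id = inputs$sample_id %||% "sample",
                                 round = inputs$round %||% 0L,
                                 discarded = c(ex$discarded, tr$discarded))
        write_count_table_prov(tab, target, prov)
        c(counts = target)
    },
    "pmap" = {
        target <- out("pmap_cache.tsv")
        if (stage_current(target, hash) && file.exists(out("pmap_cache.rds"))) {
            message("pmap: output current, skipped")
            return(invisible(c(pmap = out("pmap_cache.rds"), index = target)))
        }
        db <- proteome()
        pm <- build_pmap(db, matrixx(), freq(), L = config$L)
        saveRDS(pm, out("pmap_cache.rds"))
        write_tsv_provenance(data.frame(protein_id = names(pm$dists),
                                        n_windows = vapply(pm$dists, nrow,
                                                           integer(1))),
                             target, prov)
        c(pmap = out("pmap_cache.rds"), index = target)
    },
    "score" = {
        score_arts <- c(tracks = out("tracks.tsv"), scan = out("scan.tsv"),
                        top_k = out("top_k.tsv"),
                        manhattan = out("manhattan_lttb.tsv"))
        if (all(vapply(score_arts, stage_current, logical(1), hash = hash))) {
            message("score: outputs current, skipped")
            return(invisible(score_arts))
        }
        db <- proteome()
        counts <- read_count_table(inputs$counts)
        pm_path <- out("pmap_cache.rds")
        if (file.exists(pm_path)) {
            pm <- readRDS(pm_path)
        } else {
            message("score: no cached P-map, building it now")
            pm <- build_pmap(db, matrixx(), freq(), L = config$L)
        }
        qm <- build_qmap(counts, db, matrixx(), L = config$L,
                         weighting = config$weighting)
        tracks <- decode_tracks(pm, qm, floor = config$chi2_floor)
        scan <- proteome_scan_rank(tracks)
        write_tracks(tracks, out("tracks.tsv"), prov)
        write_tsv_provenance(scan$records, out("scan.tsv"), prov)
        write_tsv_provenance(head(scan$records, inputs$top_k %||% 100L),
                             out("top_k.tsv"), prov)
        concat <- scan$records[order(match(scan$records$protein_id,
                                           names(tracks)),
                                     scan$records$window_start), ]
        ds <- lttb_downsample(concat$score, config$lttb_ratio)
        write_tsv_provenance(data.frame(position = ds$x, score = ds$y),
                             out("manhattan_lttb.tsv"), prov)
        c(tracks = out("tracks.tsv"), scan = out("scan.tsv"),
          top_k = out("top_k.tsv"), manhattan = out("manhattan_lttb.tsv"))
    },
    "logo" = {
        counts <- read_count_table(inputs$counts)
        align <- NULL
        if (!is.null(inputs$window))
            align <- list(window = inputs$window, matrix = matrixx())
        logo <- build_logo(counts, top_n = config$top_n_logo,
                           align_to = align,
                           display_threshold = config$display_threshold)
        write_logo(logo, out("logo.tsv"))
        c(logo = out("logo.tsv"))
    },
    "motif" = {
        tabs <- lapply(inputs$counts, read_count_table)
        mf <- motif_fraction_by_round(tabs, inputs$pattern)
        write_tsv_provenance(mf, out("motif_fractions.tsv"), prov)
        c(motif = out("motif_fractions.tsv"))
    },
    "simulate-selection" = {
        scen <- default_planted_scenario(seed = config$seed,
                                         reads_per_round = config$reads_per_round,
                                         rounds = config$rounds,
                                         library_size = config$library_size)
        paths <- character(0)
        for (i in seq_along(scen$experiment$rounds)) {
            p <- out(sprintf("sim_counts_r%d.tsv", i - 1L))
            write_count_table_prov(scen$experiment$rounds[[i]], p, prov)
            paths[sprintf("round%d", i - 1L)] <- p
        }
        write_fasta_db(scen$db, out("sim_proteome.fasta"))
        jsonlite::write_json(list(
            epitope_protein_id = scen$truth$epitope_protein_id,
            window_start = scen$truth$window_start,
            epitope = scen$truth$epitope,
            hotspots = scen$truth$hotspots,
            seed = config$seed), out("sim_truth.json"), auto_unbox = TRUE)
        c(paths, proteome = out("sim_proteome.fasta"),
          truth = out("sim_truth.json"))
    },
    "simulate-penetration" = {
        cfg <- do.call(penetration_config,
                       inputs$penetration %||% list())
        st <- simulate_penetration(cfg)
        write_penetration_profiles(st, out("penetration_profiles.tsv"))
        c(profiles = out("penetration_profiles.tsv"))
    },
    "compare" = {
        grp <- split(inputs$scores, inputs$group)
        if (length(grp) != 2L) stop("compare needs exactly two groups")
        mw <- mann_whitney_exact(grp[[1]], grp[[2]],
                                 alternative = inputs$alternative %||% "two-sided")
        write_tsv_provenance(data.frame(
            group_a = names(grp)[1], group_b = names(grp)[2],
            n_a = mw$n_x, n_b = mw$n_y, U = mw$U, p = mw$p,
            method = mw$method), out("compare.tsv"), prov)
        c(compare = out("compare.tsv"))
    })
    invisible(artifacts)
}

# count-table TSV with extra provenance comment lines
write_count_table_prov <- function(tab, path, prov) {
    write_count_table(tab, path)
    lines <- readLines(path)
    writeLines(c(sprintf("# %s: %s", names(prov), prov), lines), path)
    invisible(path)
}
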