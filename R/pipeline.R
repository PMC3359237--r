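## Orchestration: a single structured config drives the stage chain
## preprocess/collapse -> ncRNA filter -> conserved annotation ->
## isomiRs -> precursors -> novel -> targets -> expression, with a run
## manifest recording parameters, seed and input checksums.

#' Build and validate a pipeline configuration
#'
#' Unknown keys are rejected.  Either \code{simulate = TRUE} (inputs are
#' generated by the synthetic-data module under \code{sim}) or
#' \code{tags}/\code{refs}/\code{ncrna}/\code{est} are supplied.
#'
#' @param ... overrides of the defaults listed below.
#' @return list of class \code{RunConfig}.
#' @export
pipelineConfig <- function(...) {
    defaults <- list(
        simulate = TRUE,
        sim = simConfig(),
        tags = NULL, refs = NULL, ncrna = NULL, est = NULL,
        seed = 1L,
        min_total = 15L, min_libraries = 2L,        # conservation filter
        prefilter_total = 10L,                      # isomiR prefilter
        abundance_ratio = 1.5, promote_min = 1000,  # isomiR chain
        flank = 60L,                                # precursor windows
        novel_min_total = 20L, novel_threshold = 1, # novel scoring
        target_ratio = 0.7, tas3_ratio = 0.55,      # target scans
        run_targets = TRUE, run_novel = TRUE, run_precursors = TRUE,
        run_expression = TRUE,
        outdir = NULL)
    over <- list(...)
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(defaults, over)
    if (cfg$simulate) cfg$sim$seed <- as.integer(cfg$seed)
    structure(cfg, class = "RunConfig")
}

#' Run the full pipeline
#'
#' Stages run in fixed order; a rerun with the same config is
#' reproducible bit-for-bit (all randomness flows from \code{seed}).
#'
#' @param config a [pipelineConfig()].
#' @return list with per-stage outputs, the recovery-report inputs, and
#'   a \code{manifest}.
#' @export
runPipeline <- function(config = pipelineConfig()) {
    stopifnot(inherits(config, "RunConfig"))
    if (config$simulate) {
        sim <- simulateReferenceSets(config$sim)
        libs <- simulateLibraries(config$sim, sim)
        tags <- libs$tags
        refs <- sim$refs; ncrna <- sim$ncrna; est <- sim$est
        truth <- sim$truth
    } else {
        for (need in c("tags", "refs", "ncrna", "est"))
            if (is.null(config[[need]]))
                stop("stage inputs missing: ", need)
        tags <- config$tags; refs <- readMatureRefs(config$refs)
        ncrna <- config$ncrna; est <- config$est
        truth <- NULL; libs <- NULL
    }

    lengthdist <- lengthDistribution(tags)
    nc <- filterNcrna(tags, ncrna, refs)
    ann <- annotateExact(nc$tags, refs)
    cons <- conservationFilter(ann$hits, config$min_total,
                               config$min_libraries,
                               libraries = libNames(tags))
    ref_totals <- setNames(ann$hits$total, ann$hits$name)
    ref_totals <- c(ref_totals,
                    setNames(rep(0, sum(!refs$name %in% names(ref_totals))),
                             refs$name[!refs$name %in% names(ref_totals)]))
    pre <- prefilterTags(ann$residual, config$prefilter_total)
    iso <- isomirChain(pre$pass, refs, ref_totals,
                       unique(cons$kept$family[!cons$kept$is_star]),
                       config$abundance_ratio, config$promote_min)

    retained_seq <- if (!is.null(iso$calls))
        iso$calls$variant[iso$calls$retained] else character(0)
    residual <- ann$residual[!tagSequences(ann$residual) %in% retained_seq, ]

    ## precursors: validate kept matures (and rescue discarded hits that
    ## align perfectly with a validated precursor)
    precursors <- NULL; rescued <- NULL; prec_rate <- NA_real_
    if (config$run_precursors) {
        fp <- foldParams()
        validateMature <- function(seq) {
            wins <- findPrecursorCandidates(seq, est, config$flank)
            rows <- list()
            for (w in seq_len(nrow(wins))) {
                st <- foldMinEnergy(wins$window_seq[w], fp)
                v <- validateHairpin(st, wins$mat_start[w], wins$mat_end[w])
                rows[[w]] <- cbind(wins[w, c("source_id", "strand",
                                             "win_start", "win_end")],
                                   mfe = structureMFE(st),
                                   norm_mfe = v$norm_mfe,
                                   verdict = v$verdict,
                                   stringsAsFactors = FALSE)
            }
            if (length(rows)) do.call(rbind, rows) else NULL
        }
        prec_list <- list()
        for (s in unique(cons$kept$sequence)) {
            pv <- validateMature(s)
            if (!is.null(pv))
                prec_list[[length(prec_list) + 1L]] <-
                    cbind(mature = s, pv, stringsAsFactors = FALSE)
        }
        precursors <- if (length(prec_list)) do.call(rbind, prec_list)
                      else NULL
        ## rescue: discarded hits with a validated precursor
        resc <- list()
        for (i in seq_len(nrow(cons$discarded))) {
            pv <- validateMature(cons$discarded$sequence[i])
            if (!is.null(pv) && any(pv$verdict))
                resc[[length(resc) + 1L]] <- cons$discarded[i, , drop = FALSE]
        }
        rescued <- if (length(resc)) do.call(rbind, resc) else NULL
        ## validation rate over planted genes (simulated runs only)
        if (!is.null(truth)) {
            ok <- vapply(seq_len(nrow(truth$genes)), function(g) {
                pv <- validateMature(truth$genes$mature[g])
                !is.null(pv) &&
                    any(pv$verdict &
                        pv$source_id == truth$genes$est_id[g])
            }, logical(1))
            prec_rate <- mean(ok)
        }
    }

    novel <- NULL
    if (config$run_novel)
        novel <- discoverNovel(residual, est, config$novel_min_total,
                               config$flank, config$novel_threshold)

    targets <- NULL; targets_scanned <- character(0)
    if (config$run_targets) {
        mirset <- cons$kept[!cons$kept$is_star, c("name", "sequence")]
        targets <- scanTargets(mirset, est, config$target_ratio)
        targets_scanned <- mirset$sequence
    }

    expr <- NULL
    if (config$run_expression && nrow(cons$kept)) {
        k <- poolFamilies(cons$kept, rescued, iso$calls, iso$promoted,
                          libraries = libNames(tags))
        if (nrow(k) >= 2L && any(rowSums(k > 0) == ncol(k))) {
            sf <- medianRatioSizeFactors(k)
            vst <- varianceStabilize(k, sf)
            expr <- c(list(counts = k), vst,
                      clusterExpression(vst$t))
        }
    }

    ## realised canonical reads per gene (for the novel-recovery metric)
    novel_reads <- NULL
    if (!is.null(libs))
        novel_reads <- rowSums(libs$bookkeeping$canonical_counts)

    manifest <- list(
        package_version = as.character(utils::packageVersion("mirbean")),
        seed = config$seed,
        parameters = unclass(config)[c("min_total", "min_libraries",
            "prefilter_total", "abundance_ratio", "promote_min", "flank",
            "novel_min_total", "novel_threshold", "target_ratio",
            "tas3_ratio")],
        n_tags = nrow(tags), libraries = libNames(tags))

    out <- list(tags = tags, lengthdist = lengthdist,
                ncrna_removed = nc$removed, hits = ann$hits,
                kept = cons$kept, discarded = cons$discarded,
                rescued = rescued, isomirs = iso,
                precursors = precursors,
                precursor_validation = prec_rate,
                novel_candidates = novel,
                novel_realised_reads = novel_reads,
                targets = targets, targets_scanned = targets_scanned,
                expression = expr, manifest = manifest,
                run_id = if (!is.null(truth)) truth$run_id else config$seed,
                truth = truth)

    if (!is.null(config$outdir)) writeRunArtifacts(out, config$outdir)
    out
}

writeRunArtifacts <- function(out, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeTable(out$kept, file.path(outdir, "conserved_kept.tsv"))
    writeTable(out$discarded, file.path(outdir, "conserved_discarded.tsv"))
    if (!is.null(out$isomirs$calls))
        writeTable(out$isomirs$calls, file.path(outdir, "isomirs.tsv"))
    if (!is.null(out$precursors))
        writeTable(out$precursors, file.path(outdir, "precursors.tsv"))
    if (!is.null(out$novel_candidates))
        writeTable(out$novel_candidates, file.path(outdir, "novel.tsv"))
    if (!is.null(out$targets))
        writeTable(out$targets, file.path(outdir, "targets.tsv"))
    if (!is.null(out$expression)) {
        writeTable(data.frame(family = rownames(out$expression$counts),
                              out$expression$counts, check.names = FALSE),
                   file.path(outdir, "family_counts.tsv"))
        writeTable(data.frame(family = rownames(out$expression$t),
                              round(out$expression$t, 6),
                              check.names = FALSE),
                   file.path(outdir, "family_vst.tsv"))
        writeLines(c(out$expression$organ_newick,
                     out$expression$family_newick),
                   file.path(outdir, "dendrograms.nwk"))
    }
    man <- out$manifest
    md5 <- tools::md5sum(list.files(outdir, full.names = TRUE,
                                    pattern = "\\.(tsv|nwk)$"))
    names(md5) <- basename(names(md5))
    man$file_md5 <- as.list(md5)
    writeLines(paste0(names(unlist(man)), "\t", unlist(man)),
               file.path(outdir, "manifest.tsv"))
    invisible(outdir)
}
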