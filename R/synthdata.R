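## Ground-truthed synthetic reference sets and four-organ small RNA
## libraries: planted miRNA genes with hairpin precursors embedded in
## ESTs, 3'-heterogeneous isomiRs, star strands with imperfect (G:U
## compatible) duplexes, planted target sites, ncRNA contamination and
## negative-binomial per-organ abundances.

#' Simulation configuration
#'
#' Defaults define the study conditions the rest of the package is
#' exercised under: four organ libraries, log-normal gene abundances
#' with negative-binomial counts, 21-nt-centred mature lengths with a
#' 24-nt-dominated contamination background (so redundant reads peak at
#' 21 nt and unique tags at 24 nt), star reads at a fraction of mature
#' reads, and 3'-dominated isomiR heterogeneity.
#'
#' @param n_genes planted miRNA genes (default 60).
#' @param n_families family labels to draw genes from (default 40).
#' @param organs library names.
#' @param mean_abundance log-normal median of the expected canonical
#'   mature reads per gene, summed over organs (default 120).
#' @param sdlog log-normal sdlog of gene abundance (default 1).
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2;
#'   default 0.25).
#' @param isomir_probs expected read ratios, relative to the canonical
#'   mature, of the isomiR types (3' extension, 3' -1/-2 truncations,
#'   5' -1 truncation, single internal substitution).
#' @param star_fraction expected star/mature read ratio (default 0.18).
#' @param contamination_frac fraction of library reads from ncRNA
#'   fragments and random tags (default 0.35).
#' @param length_mode_weights length distribution of contamination tags;
#'   default puts mode 24 (0.45) over 21 (0.10), the remainder spread
#'   over 16-30.
#' @param frac_novel fraction of genes whose mature is withheld from the
#'   reference set, making them discoverable only as novel (default
#'   0.25).
#' @param target_frac fraction of genes given a planted EST target site
#'   (default 0.5).
#' @param n_decoys decoy reference matures never expressed (default 15).
#' @param n_ncrna ncRNA set size (default 12).
#' @param n_contam unique contamination tags at the default
#'   contamination fraction; the effective count scales linearly with
#'   \code{contamination_frac} (default 900).
#' @param lib_size if non-NULL, per-organ totals are resampled
#'   (multinomially) to exactly this size.
#' @param seed integer seed; fixed seed implies byte-identical outputs.
#' @return list of class \code{SimConfig}.
#' @export
simConfig <- function(n_genes = 60L, n_families = 40L,
                      organs = c("LL", "RL", "SL", "FL"),
                      mean_abundance = 120, sdlog = 1,
                      dispersion = 0.25,
                      isomir_probs = c(ext3 = 0.20, trunc3_1 = 0.18,
                                       trunc3_2 = 0.08, trunc5_1 = 0.06,
                                       sub = 0.08),
                      star_fraction = 0.18, contamination_frac = 0.35,
                      length_mode_weights = c(`21` = 0.10, `24` = 0.45),
                      frac_novel = 0.25, target_frac = 0.5,
                      n_decoys = 15L, n_ncrna = 12L, n_contam = 900L,
                      lib_size = NULL, seed = 1L) {
    stopifnot(all(isomir_probs >= 0), star_fraction >= 0,
              contamination_frac >= 0, contamination_frac < 1,
              all(length_mode_weights >= 0),
              sum(length_mode_weights) <= 1,
              frac_novel >= 0, frac_novel <= 1, dispersion >= 0)
    structure(as.list(environment()), class = "SimConfig")
}

rseq <- function(n, p = c(A = 0.27, C = 0.23, G = 0.25, U = 0.25))
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")

## lengths for contamination tags per the configured mode weights
rlen <- function(n, w) {
    lens <- 16:30
    pr <- rep((1 - sum(w)) / (length(lens) - length(w)), length(lens))
    names(pr) <- lens
    pr[names(w)] <- w
    as.integer(sample(lens, n, replace = TRUE, prob = pr))
}

#' Generate ground-truthed synthetic reference sets
#'
#' Produces a mature reference set (planted matures and stars of
#' non-novel genes plus never-expressed decoys), an ncRNA set sharing no
#' sequence with any planted mature, and an EST set embedding one
#' hairpin precursor per gene (mature + loop of 8-15 nt + a
#' near-complementary star arm with 0-2 G:U-compatible substitutions,
#' inside flanking sequence) plus perfect/near-perfect target sites for
#' a configured subset of matures.  The annotated star window leaves a
#' 2-nt 3' overhang on each strand of the duplex.
#'
#' @param cfg a [simConfig()].
#' @return list with \code{refs}, \code{ncrna}, \code{est},
#'   \code{truth} (genes, targets, true_counts, run_id).
#' @export
simulateReferenceSets <- function(cfg = simConfig()) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed)
    n <- cfg$n_genes
    genes <- vector("list", n)
    seen <- character(0)
    fp <- foldParams()
    for (g in seq_len(n)) {
        ## rejection-sample until the planted precursor satisfies the
        ## hairpin validator on its own EST (generator-validator
        ## consistency is part of the generator's contract)
        repeat {
        repeat {
            L <- sample(c(20L, 21L, 22L), 1L, prob = c(0.25, 0.6, 0.15))
            mature <- rseq(L)
            if (!mature %in% seen) break
        }
        arm <- revComplement(mature)
        ## 0-2 G:U-compatible substitutions on the star arm interior
        n_gu <- sample(0:2, 1L)
        cand <- which(strsplit(arm, "")[[1]] %in% c("C", "A"))
        cand <- cand[cand > 3 & cand < L - 3]
        if (n_gu > 0 && length(cand) >= n_gu) {
            pos <- sample(cand, n_gu)
            a <- strsplit(arm, "")[[1]]
            a[pos] <- ifelse(a[pos] == "C", "U", "G")
            arm <- paste(a, collapse = "")
        }
        loop_len <- sample(8:15, 1L)
        loop <- rseq(loop_len)
        precursor <- paste0(mature, loop, arm)
        f5 <- rseq(sample(25:40, 1L)); f3 <- rseq(sample(25:40, 1L))
        est <- paste0(f5, precursor, f3)
        mat_start <- nchar(f5) + 1L
        wins <- findPrecursorCandidates(
            mature, data.frame(id = "x", sequence = est,
                               stringsAsFactors = FALSE), flank = 60L)
        ok <- FALSE
        for (w in seq_len(nrow(wins))) {
            if (wins$strand[w] != "+") next
            v <- validateHairpin(foldMinEnergy(wins$window_seq[w], fp),
                                 wins$mat_start[w], wins$mat_end[w])
            if (v$verdict) { ok <- TRUE; break }
        }
        ## the full EST must also validate (closure over whole windows)
        if (ok) {
            v2 <- validateHairpin(foldMinEnergy(est, fp), mat_start,
                                  mat_start + L - 1L)
            ok <- v2$verdict
        }
        if (ok) break
        }
        seen <- c(seen, mature)
        arm_start <- nchar(f5) + L + loop_len + 1L
        ## star: arm shifted by 2 to leave 2-nt 3' overhangs
        star <- substr(est, arm_start + 2L, arm_start + L + 1L)
        genes[[g]] <- list(
            gene = sprintf("simgene%03d", g),
            family = as.character(9000L + ((g - 1L) %% cfg$n_families)),
            mature = mature, star = star, precursor = precursor,
            est_id = sprintf("EST_prec_%03d", g), est_seq = est,
            mat_start = mat_start, mat_end = mat_start + L - 1L,
            star_start = arm_start + 2L, star_end = arm_start + L + 1L)
    }
    gdf <- do.call(rbind, lapply(genes, function(x)
        data.frame(x[setdiff(names(x), "est_seq")],
                   stringsAsFactors = FALSE)))
    gdf$novel <- seq_len(n) %in% sample(n, round(cfg$frac_novel * n))

    ## reference set: matures + stars of non-novel genes, plus decoys
    refs <- data.frame(name = character(), family = character(),
                       sequence = character(), is_star = logical(),
                       stringsAsFactors = FALSE)
    for (g in which(!gdf$novel)) {
        refs <- rbind(refs,
            data.frame(name = sprintf("sim-miR%s-%03d", gdf$family[g], g),
                       family = gdf$family[g], sequence = gdf$mature[g],
                       is_star = FALSE, stringsAsFactors = FALSE),
            data.frame(name = sprintf("sim-miR%s-%03d*", gdf$family[g], g),
                       family = gdf$family[g], sequence = gdf$star[g],
                       is_star = TRUE, stringsAsFactors = FALSE))
    }
    for (d in seq_len(cfg$n_decoys)) {
        repeat {
            s <- rseq(sample(20:22, 1L))
            if (!s %in% refs$sequence) break
        }
        refs <- rbind(refs, data.frame(
            name = sprintf("sim-miR%d-dec", 8000L + d),
            family = as.character(8000L + d), sequence = s,
            is_star = FALSE, stringsAsFactors = FALSE))
    }
    refs <- refs[!duplicated(refs$sequence), , drop = FALSE]

    ## ncRNA set: no planted mature may occur inside an entry
    ncrna <- character(cfg$n_ncrna)
    for (i in seq_len(cfg$n_ncrna)) {
        repeat {
            s <- rseq(sample(80:200, 1L))
            if (!any(vapply(gdf$mature, grepl, logical(1), x = s,
                            fixed = TRUE)) && !s %in% refs$sequence)
                break
        }
        ncrna[i] <- s
    }
    ncrna <- data.frame(id = sprintf("ncRNA%02d", seq_len(cfg$n_ncrna)),
                        sequence = ncrna, stringsAsFactors = FALSE)

    ## EST set: precursors + target sites + junk
    est <- data.frame(id = gdf$est_id,
                      sequence = vapply(genes, `[[`, "", "est_seq"),
                      stringsAsFactors = FALSE)
    tgt_genes <- which(runif(n) < cfg$target_frac)
    targets <- list()
    for (g in tgt_genes) {
        site <- revComplement(gdf$mature[g])
        Ls <- nchar(site)
        n_wob <- sample(0:2, 1L)
        sc <- strsplit(site, "")[[1]]
        wob <- which(sc %in% c("C", "A"))
        wob <- wob[wob > 2 & wob < Ls - 1]
        if (n_wob > 0 && length(wob) >= n_wob) {
            pos <- sample(wob, n_wob)
            sc[pos] <- ifelse(sc[pos] == "C", "U", "G")
            site <- paste(sc, collapse = "")
        }
        f5 <- rseq(sample(50:90, 1L)); f3 <- rseq(sample(50:90, 1L))
        targets[[length(targets) + 1L]] <- data.frame(
            gene = gdf$gene[g], mature = gdf$mature[g],
            est_id = sprintf("EST_tgt_%03d", g),
            site_start = nchar(f5) + 1L,
            site_end = nchar(f5) + Ls, n_wobble = n_wob,
            stringsAsFactors = FALSE)
        est <- rbind(est, data.frame(
            id = sprintf("EST_tgt_%03d", g),
            sequence = paste0(f5, site, f3), stringsAsFactors = FALSE))
    }
    targets <- if (length(targets)) do.call(rbind, targets) else NULL
    for (j in 1:5)
        est <- rbind(est, data.frame(id = sprintf("EST_junk_%02d", j),
                                     sequence = rseq(sample(150:300, 1L)),
                                     stringsAsFactors = FALSE))

    ## expected canonical mature reads per organ: log-normal gene effect
    ## split over organs by a Dirichlet weight (gamma normalisation)
    C <- exp(rnorm(n, log(cfg$mean_abundance), cfg$sdlog))
    W <- matrix(rgamma(n * length(cfg$organs), shape = 1.5), n)
    W <- W / rowSums(W)
    lambda <- C * W
    dimnames(lambda) <- list(gdf$gene, cfg$organs)

    list(refs = refs, ncrna = ncrna, est = est,
         truth = list(genes = gdf, targets = targets,
                      true_counts = lambda, run_id = cfg$seed))
}

#' Simulate four-organ small RNA libraries from a ground truth
#'
#' Per gene and organ, canonical mature, isomiR, and star read counts
#' are drawn from negative binomials around the configured expected
#' abundances; contamination tags are drawn from ncRNA fragments and
#' random 16-30-mers with the configured length modes.  With the default
#' weights the 24-nt class has the largest unique-tag count while
#' redundant reads peak at 21 nt.
#'
#' @param cfg the [simConfig()] used for [simulateReferenceSets()].
#' @param sim the result of [simulateReferenceSets()] (contains the
#'   ground truth).
#' @return list with \code{tags} (a [TagSet]) and \code{bookkeeping}
#'   (per-organ emitted totals and per-gene realised canonical counts).
#' @export
simulateLibraries <- function(cfg, sim) {
    stopifnot(inherits(cfg, "SimConfig"))
    if (is.null(sim$truth)) stop("missing ground truth")
    set.seed(cfg$seed + 1L)
    truth <- sim$truth
    gdf <- truth$genes
    lambda <- truth$true_counts
    organs <- cfg$organs
    size <- if (cfg$dispersion > 0) 1 / cfg$dispersion else Inf
    draw <- function(mu) {
        if (mu <= 0) return(0L)
        if (is.finite(size)) rnbinom(1L, mu = mu, size = size)
        else rpois(1L, mu)
    }
    acc_seq <- character(0); acc_org <- character(0); acc_n <- integer(0)
    emit <- function(s, o, k) {
        if (k > 0) {
            acc_seq[length(acc_seq) + 1L] <<- s
            acc_org[length(acc_org) + 1L] <<- o
            acc_n[length(acc_n) + 1L] <<- as.integer(k)
        }
    }
    canon_real <- matrix(0L, nrow(gdf), length(organs),
                         dimnames = list(gdf$gene, organs))
    for (g in seq_len(nrow(gdf))) {
        m <- gdf$mature[g]; L <- nchar(m)
        ## per-gene isomiR identities, fixed across organs
        iso <- c(ext3 = paste0(m, rseq(1L)),
                 trunc3_1 = substr(m, 1L, L - 1L),
                 trunc3_2 = substr(m, 1L, L - 2L),
                 trunc5_1 = substr(m, 2L, L))
        sp <- sample(5:(L - 4), 1L)
        sv <- strsplit(m, "")[[1]]
        sv[sp] <- sample(setdiff(c("A", "C", "G", "U"), sv[sp]), 1L)
        iso["sub"] <- paste(sv, collapse = "")
        for (o in organs) {
            mu <- lambda[g, o]
            k <- draw(mu)
            canon_real[g, o] <- k
            emit(m, o, k)
            for (t in names(cfg$isomir_probs))
                emit(iso[[t]], o, draw(mu * cfg$isomir_probs[[t]]))
            emit(gdf$star[g], o, draw(mu * cfg$star_fraction))
        }
    }
    ## contamination: ncRNA fragments (60%) and random tags (40%);
    ## tag count scales with contamination_frac (n_contam applies at the
    ## default fraction 0.35)
    n_eff <- if (cfg$contamination_frac <= 0) 0L else
        as.integer(round(cfg$n_contam * cfg$contamination_frac / 0.35))
    n_frag <- round(0.6 * n_eff)
    for (i in seq_len(n_eff)) {
        len <- rlen(1L, cfg$length_mode_weights)
        if (i <= n_frag) {
            src <- sim$ncrna$sequence[sample(nrow(sim$ncrna), 1L)]
            st <- sample(nchar(src) - len + 1L, 1L)
            s <- substr(src, st, st + len - 1L)
        } else {
            s <- rseq(len)
        }
        present <- sample(organs, 1L + rbinom(1L, length(organs) - 1L, 0.3))
        for (o in present) emit(s, o, 1L + draw(3))
    }
    reads <- rowsum(acc_n, paste(acc_org, acc_seq, sep = "\r"))
    key <- strsplit(rownames(reads), "\r", fixed = TRUE)
    tab <- data.frame(organ = vapply(key, `[[`, "", 1L),
                      sequence = vapply(key, `[[`, "", 2L),
                      n = as.integer(reads[, 1L]),
                      stringsAsFactors = FALSE)
    seqs <- sort(unique(tab$sequence))
    counts <- matrix(0L, length(seqs), length(organs),
                     dimnames = list(NULL, organs))
    counts[cbind(match(tab$sequence, seqs), match(tab$organ, organs))] <-
        tab$n
    if (!is.null(cfg$lib_size)) {
        for (j in seq_along(organs)) {
            tot <- sum(counts[, j])
            if (tot > 0)
                counts[, j] <- as.integer(
                    rmultinom(1L, cfg$lib_size, counts[, j] / tot))
        }
    }
    keep <- rowSums(counts) > 0
    tags <- sortTags(TagSet(seqs[keep], counts[keep, , drop = FALSE],
                            organs))
    list(tags = tags,
         bookkeeping = list(library_sizes = colSums(counts),
                            canonical_counts = canon_real,
                            run_id = cfg$seed))
}

#' Write per-organ FASTQ files for simulated libraries
#'
#' Expands tags to reads, appends the 3' adapter, pads with random
#' sequence and truncates to a fixed read length (read-through layout),
#' with a constant quality score.
#'
#' @param tags a [TagSet].
#' @param dir output directory.
#' @param adapter 3' adapter (default: the [preprocessParams()] default).
#' @param read_len fixed read length (default 40; inserts up to 30 nt keep at least 8 adapter bases).
#' @param q constant Phred quality character (default "I", Q40).
#' @return named vector of file paths.
#' @export
writeSimFastq <- function(tags, dir, adapter = NULL, read_len = 40L,
                          q = "I") {
    if (is.null(adapter)) adapter <- preprocessParams()$adapter
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    adapter_dna <- chartr("U", "T", adapter)
    out <- character(0)
    for (o in libNames(tags)) {
        k <- tagCounts(tags)[, o]
        sq <- rep(chartr("U", "T", tagSequences(tags)), k)
        full <- paste0(sq, adapter_dna,
                       strrep("A", pmax(0L, read_len - nchar(sq) -
                                            nchar(adapter_dna))))
        full <- substr(full, 1L, read_len)
        ids <- sprintf("@%s_read%06d", o, seq_along(full))
        path <- file.path(dir, paste0(o, ".fastq"))
        writeLines(rbind(ids, full, "+", strrep(q, read_len)), path)
        out[o] <- path
    }
    out
}

#' Recovery metrics of a pipeline run against the ground truth
#'
#' @param truth the \code{truth} element of [simulateReferenceSets()].
#' @param results a [runPipeline()] result from the same run (matching
#'   \code{run_id}; a mismatch is an error).
#' @param min_expected expected-read threshold for the conserved-recall
#'   denominator (default 15).
#' @param min_novel_reads realised-read threshold for the novel-recovery
#'   denominator (default 20).
#' @return named list of recall/precision metrics.
#' @export
groundTruthReport <- function(truth, results, min_expected = 15,
                              min_novel_reads = 20) {
    if (!identical(truth$run_id, results$run_id))
        stop("ground truth and results come from different runs")
    gdf <- truth$genes
    lam <- truth$true_counts
    ## conserved annotation recall / precision
    denom <- !gdf$novel & rowSums(lam) >= min_expected
    kept_seq <- results$kept$sequence
    recall <- if (any(denom))
        mean(gdf$mature[denom] %in% kept_seq) else NA_real_
    mature_kept <- results$kept[!results$kept$is_star, , drop = FALSE]
    precision <- if (nrow(mature_kept))
        mean(mature_kept$sequence %in% c(gdf$mature, gdf$star))
        else NA_real_
    ## precursor validation rate over planted genes
    prec_rate <- if (!is.null(results$precursor_validation))
        results$precursor_validation else NA_real_
    ## target recall: planted sites recovered by the scan
    tgt_recall <- NA_real_
    if (!is.null(truth$targets) && !is.null(results$targets)) {
        tt <- truth$targets
        scanned <- tt$mature %in% results$targets_scanned
        hit <- logical(nrow(tt))
        for (i in seq_len(nrow(tt))) {
            if (!scanned[i]) next
            cand <- results$targets[
                results$targets$target_id == tt$est_id[i], , drop = FALSE]
            hit[i] <- any(cand$site_start <= tt$site_end[i] &
                          cand$site_end >= tt$site_start[i])
        }
        if (any(scanned)) tgt_recall <- mean(hit[scanned])
    }
    ## novel recovery: expressed novel genes found among candidates
    nov_recall <- NA_real_
    if (!is.null(results$novel_candidates)) {
        realised <- results$novel_realised_reads
        dn <- gdf$novel & realised[gdf$gene] >= min_novel_reads
        if (any(dn))
            nov_recall <- mean(gdf$mature[dn] %in%
                                   results$novel_candidates$mature)
    }
    list(conserved_recall = recall, conserved_precision = precision,
         precursor_validation_rate = prec_rate,
         target_recall = tgt_recall, novel_recovery = nov_recall)
}
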