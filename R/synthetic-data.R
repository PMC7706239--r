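#' @include AllClasses.R
NULL

#' Configuration for the synthetic cohort generator
#'
#' Assembles and validates the full parameter set of
#' \code{\link{simulateCohort}}.  Defaults describe a desk-scale cohort
#' with the continental structure of a worldwide resequencing panel: five
#' continents of two populations each, twenty samples per population, 500
#' promoters with TSS +/- 100 windows and about six variants per promoter
#' (~3000 in total).  The sharing-class proportions default to a published
#' core-promoter spectrum (48\% private to population, 7\% private to
#' continent, 22\% shared across continents, 23\% shared across all
#' continents); the SNV transition probability 0.78 yields an expected
#' Ts/Tv of 0.78/0.22 = 3.55; the indel fraction 0.135 with insertion share
#' 0.45 mirrors the ~6\%/7.5\% insertion/deletion split of the same survey;
#' known-catalog coverage 0.904 and eQTL-significant fraction 0.12 match
#' its pooled known rate and expression-altering rate.
#'
#' @param seed Integer seed fixing all randomness.
#' @param continents Character vector of continent codes.
#' @param popsPerContinent Populations per continent (>= 2 needed for the
#'   private-to-continent class).
#' @param samplesPerPopulation Individuals per population.
#' @param nPromoters Number of core promoters.
#' @param windowUp,windowDown Promoter window half-widths (bp).
#' @param meanVariantsPerPromoter Poisson mean of variants per promoter.
#' @param sharingProps Length-4 proportions over the sharing classes
#'   (private to population, private to continent, shared across
#'   continents, shared across all continents), summing to 1.
#' @param transitionProb P(transition) for an SNV; expected Ts/Tv is
#'   \code{transitionProb / (1 - transitionProb)}.
#' @param indelFraction Fraction of variants that are indels.
#' @param insertionShare Fraction of indels that are insertions.
#' @param motifPlantRate Per-promoter, per-motif planting probability.
#' @param knownFraction Fraction of variants present in the known catalog
#'   (these carry rsIDs).
#' @param eqtlSigFraction Fraction of variants given a significant
#'   (p < 0.05) eQTL row.
#' @param nGwas Number of cohort rsIDs given GWAS-trait rows.
#' @param minCarriers Carrier floor realised in every "present" population.
#' @param carrierProb Per-sample carrier probability beyond the floor.
#' @param strayCarrierProb Probability that a non-present population shows
#'   \code{minCarriers - 1} carriers (exercises the presence filter).
#' @return A validated list of class \code{simConfig}.
#' @export
simConfig <- function(seed = 1L,
                      continents = c("AFR", "AMR", "EAS", "EUR", "SAS"),
                      popsPerContinent = 2L,
                      samplesPerPopulation = 20L,
                      nPromoters = 500L,
                      windowUp = 100L, windowDown = 100L,
                      meanVariantsPerPromoter = 6,
                      sharingProps = c(0.48, 0.07, 0.22, 0.23),
                      transitionProb = 0.78,
                      indelFraction = 0.135,
                      insertionShare = 0.45,
                      motifPlantRate = 0.5,
                      knownFraction = 0.904,
                      eqtlSigFraction = 0.12,
                      nGwas = 10L,
                      minCarriers = 2L,
                      carrierProb = 0.3,
                      strayCarrierProb = 0.2) {
    cfg <- list(seed = as.integer(seed), continents = continents,
                popsPerContinent = as.integer(popsPerContinent),
                samplesPerPopulation = as.integer(samplesPerPopulation),
                nPromoters = as.integer(nPromoters),
                windowUp = as.integer(windowUp),
                windowDown = as.integer(windowDown),
                meanVariantsPerPromoter = meanVariantsPerPromoter,
                sharingProps = sharingProps,
                transitionProb = transitionProb,
                indelFraction = indelFraction,
                insertionShare = insertionShare,
                motifPlantRate = motifPlantRate,
                knownFraction = knownFraction,
                eqtlSigFraction = eqtlSigFraction,
                nGwas = as.integer(nGwas),
                minCarriers = as.integer(minCarriers),
                carrierProb = carrierProb,
                strayCarrierProb = strayCarrierProb)
    probs <- c(cfg$sharingProps, cfg$transitionProb, cfg$indelFraction,
               cfg$insertionShare, cfg$motifPlantRate, cfg$knownFraction,
               cfg$eqtlSigFraction, cfg$carrierProb, cfg$strayCarrierProb)
    if (any(probs < 0 | probs > 1))
        stop("all probabilities must lie in [0, 1]")
    if (abs(sum(cfg$sharingProps) - 1) > 1e-9)
        stop("'sharingProps' must sum to 1")
    nc <- length(cfg$continents)
    if (nc < 1L || cfg$popsPerContinent < 1L)
        stop("need at least one continent and one population per continent")
    if (cfg$sharingProps[2] > 0 && cfg$popsPerContinent < 2L)
        stop("private-to-continent variants need >= 2 populations per continent")
    if (cfg$sharingProps[3] > 0 && nc < 3L)
        stop("shared-across-continents (but not all) needs >= 3 continents")
    if (cfg$sharingProps[4] > 0 && nc < 2L)
        stop("shared-across-all-continents needs >= 2 continents")
    if (cfg$minCarriers > cfg$samplesPerPopulation)
        stop("'minCarriers' exceeds the population sample size")
    class(cfg) <- "simConfig"
    cfg
}

#' Plant IUPAC motif instances into a promoter sequence
#'
#' With probability \code{rate} per motif, draws a concrete realisation of
#' the consensus (each position sampled uniformly from its allowed base
#' set) and writes it at a uniformly chosen position, rejecting positions
#' that overlap previously planted instances (bounded retries, then
#' error).  Operates on a transcription-oriented sequence; uses the
#' current RNG stream.
#'
#' @param seq A single DNA string (the oriented promoter window).
#' @param defs Motif definitions (\code{name}, \code{consensus}).
#' @param rate Planting probability per motif.
#' @param codes IUPAC table (see \code{\link{iupacCodes}}).
#' @param maxTries Rejection-sampling bound per motif.
#' @return List with \code{seq} (modified string) and \code{plants}
#'   (data.frame: \code{motif}, \code{start}, \code{end}, 1-based
#'   sequence positions, and the planted \code{instance}).
#' @export
plantMotifs <- function(seq, defs = corePromoterMotifs(), rate = 0.5,
                        codes = iupacCodes(), maxTries = 50L) {
    chars <- strsplit(seq, "")[[1]]
    taken <- rep(FALSE, length(chars))
    plants <- list()
    for (m in seq_len(nrow(defs))) {
        if (stats::runif(1) >= rate) next
        cons <- strsplit(toupper(defs$consensus[m]), "")[[1]]
        L <- length(cons)
        if (L > length(chars))
            stop("motif ", defs$name[m], " does not fit in the window")
        inst <- vapply(cons, function(k) {
            b <- codes[[k]]
            if (is.null(b)) stop("non-IUPAC code in consensus: ", k)
            b[sample.int(length(b), 1L)]
        }, character(1))
        placed <- FALSE
        for (try in seq_len(maxTries)) {
            s <- sample.int(length(chars) - L + 1L, 1L)
            if (!any(taken[s:(s + L - 1L)])) {
                chars[s:(s + L - 1L)] <- inst
                taken[s:(s + L - 1L)] <- TRUE
                plants[[length(plants) + 1L]] <-
                    data.frame(motif = defs$name[m], start = s,
                               end = s + L - 1L,
                               instance = paste(inst, collapse = ""))
                placed <- TRUE
                break
            }
        }
        if (!placed)
            stop("could not place motif ", defs$name[m], " after ",
                 maxTries, " tries")
    }
    plants <- if (length(plants)) do.call(rbind, plants)
              else data.frame(motif = character(), start = integer(),
                              end = integer(), instance = character())
    list(seq = paste(chars, collapse = ""), plants = plants)
}

# size-safe uniform draw of k elements from a vector (avoids sample()'s
# scalar-expansion surprise)
.pick <- function(x, k = 1L) x[sample.int(length(x), k)]

# draw a presence set (population codes) realising a sharing class
.drawPresence <- function(class_i, pops_by_cont) {
    nc <- length(pops_by_cont)
    if (class_i == 1L) {                       # private to population
        .pick(pops_by_cont[[sample.int(nc, 1L)]])
    } else if (class_i == 2L) {                # private to continent
        ci <- sample.int(nc, 1L)
        k <- .pick(2:length(pops_by_cont[[ci]]))
        .pick(pops_by_cont[[ci]], k)
    } else if (class_i == 3L) {                # shared, not all continents
        k <- .pick(2:(nc - 1L))
        cis <- sample.int(nc, k)
        unlist(lapply(pops_by_cont[cis], function(p)
            .pick(p, sample.int(length(p), 1L))), use.names = FALSE)
    } else {                                   # shared across all continents
        unlist(lapply(pops_by_cont, function(p)
            .pick(p, sample.int(length(p), 1L))), use.names = FALSE)
    }
}

#' Simulate a complete multi-population promoter-variant cohort
#'
#' Generates, deterministically for a given seed, all the files a cohort
#' analysis consumes — reference FASTA, TSS BED6, multi-sample VCF with GT
#' genotypes, sample manifest, known-variant / eQTL / GWAS catalog
#' snapshots — plus ground-truth tables for every downstream stage
#' (sharing class, variant type, transition flag, novelty, eQTL
#' significance, GWAS trait, planted motif positions).  Presence patterns
#' are drawn class-first: each variant's sharing class is sampled from
#' \code{sharingProps}, then a population set realising that class is
#' drawn, and each "present" population receives at least
#' \code{minCarriers} carriers (non-present populations receive at most
#' \code{minCarriers - 1}), so the downstream classifier can recover the
#' planted classes exactly.
#'
#' @param config A \code{\link{simConfig}}.
#' @param dir Output directory (created if needed).
#' @return List with file paths (\code{ref_fasta}, \code{tss_bed},
#'   \code{vcf}, \code{manifest}, \code{known}, \code{eqtl}, \code{gwas},
#'   \code{truth_variants}, \code{truth_motifs}) and in-memory objects:
#'   \code{truth} (per-variant data.frame), \code{motif_truth},
#'   \code{carriers} (planted carrier-count matrix), \code{manifest_df},
#'   \code{config}.
#' @export
simulateCohort <- function(config = simConfig(), dir = tempfile("simcohort")) {
    stopifnot(inherits(config, "simConfig"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(config$seed)
    up <- config$windowUp; down <- config$windowDown
    W <- up + down + 1L

    ## --- populations ------------------------------------------------------
    pops_by_cont <- lapply(config$continents, function(ct)
        paste0(ct, seq_len(config$popsPerContinent)))
    names(pops_by_cont) <- config$continents
    pops <- unlist(pops_by_cont, use.names = FALSE)
    manifest <- data.frame(
        sample = sprintf("S%04d", seq_len(length(pops) *
                                          config$samplesPerPopulation)),
        population = rep(pops, each = config$samplesPerPopulation),
        continent = rep(rep(config$continents,
                            each = config$popsPerContinent),
                        each = config$samplesPerPopulation))

    ## --- genome layout ----------------------------------------------------
    margin <- 200L; gap <- 100L
    spacing <- W + gap
    n <- config$nPromoters
    tss <- margin + (seq_len(n) - 1L) * spacing + up + 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    glen <- margin + n * spacing + margin
    genome <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)

    ## --- promoter sequences with planted motifs ---------------------------
    win_start <- ifelse(strand == "+", tss - up, tss - down)
    win_end <- ifelse(strand == "+", tss + down, tss + up)
    promoter_id <- sprintf("chr1:%d:%s", tss, strand)
    motif_truth <- vector("list", n)
    for (i in seq_len(n)) {
        oriented <- genome[win_start[i]:win_end[i]]
        if (strand[i] == "-") oriented <- rev(.complement(oriented))
        res <- plantMotifs(paste(oriented, collapse = ""),
                           rate = config$motifPlantRate)
        newchars <- strsplit(res$seq, "")[[1]]
        genomic <- if (strand[i] == "-") .complement(rev(newchars)) else newchars
        genome[win_start[i]:win_end[i]] <- genomic
        if (nrow(res$plants)) {
            p <- res$plants
            p$promoter_id <- promoter_id[i]
            # sequence position -> TSS-relative offset
            p$start_offset <- p$start - 1L - up
            p$end_offset <- p$end - 1L - up
            motif_truth[[i]] <- p
        }
    }
    motif_truth <- do.call(rbind, c(motif_truth[!vapply(motif_truth, is.null,
                                                        logical(1))],
                                    list(data.frame())))
    if (is.null(motif_truth) || !nrow(motif_truth))
        motif_truth <- data.frame(motif = character(), start = integer(),
                                  end = integer(), instance = character(),
                                  promoter_id = character(),
                                  start_offset = integer(),
                                  end_offset = integer())

    ## --- variants ---------------------------------------------------------
    pad <- 4L     # keep indel spans inside the window
    rows <- vector("list", n)
    for (i in seq_len(n)) {
        k <- stats::rpois(1L, config$meanVariantsPerPromoter)
        if (!k) next
        lo <- win_start[i] + 1L; hi <- win_end[i] - pad
        k <- min(k, hi - lo + 1L)
        posv <- sort(sample(lo:hi, k))
        rows[[i]] <- data.frame(promoter = i, pos = posv)
    }
    vr <- do.call(rbind, rows)
    nv <- nrow(vr)
    is_indel <- stats::runif(nv) < config$indelFraction
    is_ins <- is_indel & stats::runif(nv) < config$insertionShare
    is_del <- is_indel & !is_ins
    ref <- character(nv); alt <- character(nv); transition <- rep(NA, nv)
    bases <- c("A", "C", "G", "T")
    ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
    for (j in seq_len(nv)) {
        p <- vr$pos[j]
        anchor <- genome[p]
        if (is_ins[j]) {
            ilen <- sample.int(3L, 1L)
            ref[j] <- anchor
            alt[j] <- paste(c(anchor, sample(bases, ilen, replace = TRUE)),
                            collapse = "")
        } else if (is_del[j]) {
            dlen <- sample.int(3L, 1L)
            ref[j] <- paste(genome[p:(p + dlen)], collapse = "")
            alt[j] <- anchor
        } else {
            ref[j] <- anchor
            tr <- stats::runif(1) < config$transitionProb
            transition[j] <- tr
            alt[j] <- if (tr) unname(ts_partner[anchor])
                      else sample(setdiff(bases,
                                          c(anchor, ts_partner[anchor])), 1L)
        }
    }
    vtype <- ifelse(is_ins, "insertion",
                    ifelse(is_del, "deletion", "substitution"))
    key <- variantKey("chr1", vr$pos, ref, alt)

    ## --- sharing classes, presence, carriers ------------------------------
    class_i <- sample.int(4L, nv, replace = TRUE, prob = config$sharingProps)
    presence_sets <- lapply(class_i, .drawPresence, pops_by_cont = pops_by_cont)
    carriers <- matrix(0L, nv, length(pops), dimnames = list(key, pops))
    for (j in seq_len(nv)) {
        for (p in presence_sets[[j]])
            carriers[j, p] <- config$minCarriers +
                stats::rbinom(1L, config$samplesPerPopulation -
                                  config$minCarriers, config$carrierProb)
        absent <- setdiff(pops, presence_sets[[j]])
        stray <- absent[stats::runif(length(absent)) < config$strayCarrierProb]
        carriers[j, stray] <- config$minCarriers - 1L
    }

    ## --- genotypes --------------------------------------------------------
    gt <- matrix("0/0", nv, nrow(manifest),
                 dimnames = list(NULL, manifest$sample))
    sample_of_pop <- split(manifest$sample, manifest$population)
    for (j in seq_len(nv)) {
        for (p in pops) {
            cn <- carriers[j, p]
            if (cn > 0L) {
                who <- sample(sample_of_pop[[p]], cn)
                gt[j, who] <- ifelse(stats::runif(cn) < 0.1, "1/1", "0/1")
            }
        }
    }

    ## --- catalogs ---------------------------------------------------------
    known <- stats::runif(nv) < config$knownFraction
    rsid <- rep(NA_character_, nv)
    rsid[known] <- sprintf("rs%06d", 100000L + which(known))
    n_decoy <- 25L
    decoy_pos <- seq_len(n_decoy) + 10L          # inside the leading margin
    decoy <- data.frame(chrom = "chr1", pos = decoy_pos,
                        ref = genome[decoy_pos],
                        alt = vapply(genome[decoy_pos], function(b)
                            sample(setdiff(bases, b), 1L), character(1)),
                        rsid = sprintf("rs%06d", 900000L + seq_len(n_decoy)),
                        source = "catalog_only")
    known_df <- rbind(
        data.frame(chrom = "chr1", pos = vr$pos[known], ref = ref[known],
                   alt = alt[known], rsid = rsid[known], source = "panel"),
        decoy)

    eqtl_sig <- stats::runif(nv) < config$eqtlSigFraction
    tissues <- c("whole_blood", "liver", "lung", "thyroid", "skin",
                 "fibroblast", "brain_cortex", "muscle")
    gene_of <- sprintf("G%04d", vr$promoter)
    sig_rows <- data.frame(
        rsid = ifelse(is.na(rsid[eqtl_sig]), "", rsid[eqtl_sig]),
        chrom = "chr1", pos = vr$pos[eqtl_sig], ref = ref[eqtl_sig],
        alt = alt[eqtl_sig], gene = gene_of[eqtl_sig],
        tissue = sample(tissues, sum(eqtl_sig), replace = TRUE),
        p = stats::runif(sum(eqtl_sig), 1e-8, 0.0499),
        beta_sign = sample(c(-1L, 1L), sum(eqtl_sig), replace = TRUE))
    null_pick <- !eqtl_sig & stats::runif(nv) < 0.3
    null_rows <- data.frame(
        rsid = ifelse(is.na(rsid[null_pick]), "", rsid[null_pick]),
        chrom = "chr1", pos = vr$pos[null_pick], ref = ref[null_pick],
        alt = alt[null_pick], gene = gene_of[null_pick],
        tissue = sample(tissues, sum(null_pick), replace = TRUE),
        p = stats::runif(sum(null_pick), 0.05, 1),
        beta_sign = sample(c(-1L, 1L), sum(null_pick), replace = TRUE))
    eqtl_df <- rbind(sig_rows, null_rows)

    with_rs <- which(!is.na(rsid))
    gwas_pick <- .pick(with_rs, min(config$nGwas, length(with_rs)))
    gwas_trait <- rep(NA_character_, nv)
    gwas_trait[gwas_pick] <- sprintf("trait_%02d", seq_along(gwas_pick))
    gwas_df <- rbind(
        data.frame(rsid = rsid[gwas_pick], trait = gwas_trait[gwas_pick],
                   ancestry = "mixed"),
        data.frame(rsid = sprintf("rs%06d", 950000L + 1:5),
                   trait = sprintf("decoy_trait_%d", 1:5),
                   ancestry = "mixed"))

    ## --- ground truth -----------------------------------------------------
    # TSS-relative offset of the transcriptionally first changed base,
    # written out independently of the analysis code paths
    offs <- integer(nv); offe <- integer(nv)
    for (j in seq_len(nv)) {
        i <- vr$promoter[j]; p <- vr$pos[j]
        if (vtype[j] == "substitution") { g1 <- p; g2 <- p }
        else if (vtype[j] == "deletion") { g1 <- p + 1L
                                           g2 <- p + nchar(ref[j]) - 1L }
        else { g1 <- if (strand[i] == "+") p + 1L else p
               g2 <- g1 }   # insertion point: downstream flank of the gap
        if (strand[i] == "+") { o1 <- g1 - tss[i]; o2 <- g2 - tss[i] }
        else { o1 <- tss[i] - g2; o2 <- tss[i] - g1 }
        offs[j] <- o1; offe[j] <- o2
    }
    truth <- data.frame(
        key = key, chrom = "chr1", pos = vr$pos, ref = ref, alt = alt,
        rsid = rsid, vtype = vtype, transition = transition,
        class = .sharingLevels[class_i],
        presence = vapply(presence_sets, function(p)
            paste(sort(p), collapse = ","), character(1)),
        known = known, eqtl_sig = eqtl_sig, gwas_trait = gwas_trait,
        promoter_id = promoter_id[vr$promoter],
        gene = gene_of, offset = offs, offset_end = offe)

    ## --- emit files -------------------------------------------------------
    ref_fasta <- file.path(dir, "reference.fa")
    gseq <- Biostrings::DNAStringSet(paste(genome, collapse = ""))
    names(gseq) <- "chr1"
    Biostrings::writeXStringSet(gseq, ref_fasta, width = 80L)

    tss_bed <- file.path(dir, "tss.bed")
    # single-base feature: BED start+1 (= end) is the TSS on both strands
    bed <- data.frame(chrom = "chr1", start = tss - 1L, end = tss,
                      name = sprintf("G%04d", seq_len(n)),
                      score = 0L, strand = strand)
    utils::write.table(bed, tss_bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)

    manifest_path <- file.path(dir, "manifest.tsv")
    utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    vcf_path <- file.path(dir, "cohort.vcf")
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=chr1,length=%d>", glen),
             paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                    "Description=\"Genotype\">"),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", manifest$sample), collapse = "\t"))
    body <- paste(
        "chr1", vr$pos, ifelse(is.na(rsid), ".", rsid), ref, alt, ".",
        "PASS", ".", "GT",
        apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(hdr, body), vcf_path)

    known_path <- file.path(dir, "known_catalog.tsv")
    utils::write.table(known_df, known_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    eqtl_path <- file.path(dir, "eqtl.tsv")
    utils::write.table(eqtl_df, eqtl_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    gwas_path <- file.path(dir, "gwas.tsv")
    utils::write.table(gwas_df, gwas_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truth_path <- file.path(dir, "truth_variants.tsv")
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    motif_path <- file.path(dir, "truth_motifs.tsv")
    utils::write.table(motif_truth, motif_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    list(ref_fasta = ref_fasta, tss_bed = tss_bed, vcf = vcf_path,
         manifest = manifest_path, known = known_path, eqtl = eqtl_path,
         gwas = gwas_path, truth_variants = truth_path,
         truth_motifs = motif_path,
         truth = truth, motif_truth = motif_truth, carriers = carriers,
         manifest_df = manifest, config = config)
}

# base-wise DNA complement on a character vector
.complement <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    unname(comp[x])
}
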