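#' Configuration for an end-to-end correction run
#'
#' Collects every tunable parameter of the pipeline with the package
#' defaults; unknown keys are rejected. The classifier error rates default
#' to the simulation error rates (floored at 0.001, since the rank model
#' needs a strictly positive error rate).
#'
#' @param genomeLength,nHet Simulated genome length and number of planted
#'   heterozygous sites.
#' @param longCoverage,shortCoverage Requested fold coverages of the long
#'   (L) and short (S) read sets.
#' @param longErrorRate Total long-read error rate, split equally across
#'   substitutions, insertions and deletions.
#' @param shortErrorRate Short-read substitution rate (short reads are
#'   simulated substitution-only).
#' @param longMeanLen,longMinLen,shortMeanLen,shortMinLen Read-length
#'   parameters.
#' @param eLong,eShort Classifier error rates; `NULL` means matched to the
#'   simulation rates.
#' @param prior A [PriorSpec-class] for the zygosity classifier.
#' @param threshold Mapped-base fraction above which a long read joins Lm.
#' @param mapMode Mapping mode, see [mapReads()].
#' @param reference `"truth"` (use the simulation backbone as the anchor
#'   reference), `"assemble"` (build a [PseudoReference-class] from the
#'   long reads), or `"file"` (load `refFile`).
#' @param refFile FASTA path when `reference = "file"`.
#' @param assembly An [assemblyParams()] list for `reference = "assemble"`.
#' @param pool Voting pool at anchors, `"merged"` or `"short"`.
#' @param intervals Lower bounds of the heterozygous intervals evaluated.
#' @param retentionMode See [retention()].
#' @param seed Master seed; stage seeds are derived from it.
#' @param outdir Optional output directory for stage files.
#' @param verbose Log per-stage counts.
#' @return A named list of class `hetcorrConfig`.
#' @export
pipelineConfig <- function(genomeLength = 100000L, nHet = 500L,
                           longCoverage = 5, shortCoverage = 10,
                           longErrorRate = 0.15, shortErrorRate = 0.05,
                           longMeanLen = 2000L, longMinLen = 200L,
                           shortMeanLen = 100L, shortMinLen = 50L,
                           eLong = NULL, eShort = NULL,
                           prior = pointPrior(0.5), threshold = 0.90,
                           mapMode = "truth_anchored", reference = "truth",
                           refFile = NULL, assembly = assemblyParams(),
                           pool = "merged",
                           intervals = c(0.20, 0.25, 0.30, 0.35),
                           retentionMode = "balance", seed = 1L,
                           outdir = NULL, verbose = TRUE) {
    cfg <- as.list(environment())
    if (is.null(cfg$eLong)) cfg$eLong <- max(cfg$longErrorRate, 0.001)
    if (is.null(cfg$eShort)) cfg$eShort <- max(cfg$shortErrorRate, 0.001)
    stopIfNot(cfg$reference %in% c("truth", "assemble", "file"),
              "reference must be truth, assemble or file")
    stopIfNot(cfg$pool %in% c("merged", "short"),
              "pool must be merged or short")
    class(cfg) <- "hetcorrConfig"
    cfg
}

pipeLog <- function(verbose, ...) if (verbose) message("[hetcorr] ", ...)

#' Run the full heterozygosity-aware correction pipeline
#'
#' Executes the complete procedure: obtain an anchor reference (assembled
#' from the long reads or supplied), map the long reads and split them into
#' mapped (Lm) and unmapped (Lu) sets at the mapped-base threshold, map the
#' short reads to the reference and to each Lu read, build pileups, judge
#' the zygosity of every covered site from long and short evidence and
#' combine the judgments, correct Lm at the anchors and each Lu read from
#' its own short-read pileup, merge the corrected sets into L', and (when
#' ground truth is available) evaluate heterozygosity retention at the
#' planted sites.
#'
#' When `genome`/`longReads`/`shortReads` are not supplied, a dataset is
#' simulated under the configuration.
#'
#' @param config A [pipelineConfig()].
#' @param genome Optional [DiploidGenome-class] (simulated when `NULL`).
#' @param longReads,shortReads Optional [ReadSet-class] inputs.
#' @return A list with the inputs, the reference, per-stage alignments and
#'   pileups, the call and decision tables, `corrected` (L'), `edits`,
#'   `evaluation` (site table) and `summary` (per-interval accuracies and
#'   quality histogram), plus the `config`.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(genomeLength = 20000L, nHet = 100L, seed = 7L)
#' run <- runPipeline(cfg)
#' run$summary$accuracy
#' }
#' @export
runPipeline <- function(config = pipelineConfig(), genome = NULL,
                        longReads = NULL, shortReads = NULL) {
    v <- config$verbose
    seed <- config$seed
    if (is.null(genome)) {
        pipeLog(v, "simulating diploid genome: ", config$genomeLength,
                " bp, ", config$nHet, " het sites")
        genome <- makeDiploidGenome(config$genomeLength, config$nHet,
                                    seed = seed)
    }
    if (is.null(longReads)) {
        longReads <- simulateReads(genome, config$longCoverage,
                                   meanLen = config$longMeanLen,
                                   minLen = config$longMinLen,
                                   err = errorModel(config$longErrorRate),
                                   seed = seed + 1L, idPrefix = "L")
    }
    if (is.null(shortReads)) {
        shortReads <- simulateReads(genome, config$shortCoverage,
                                    meanLen = config$shortMeanLen,
                                    minLen = config$shortMinLen,
                                    err = errorModel(sub = config$shortErrorRate,
                                                     ins = 0, del = 0),
                                    seed = seed + 2L, idPrefix = "S")
    }
    pipeLog(v, "|L| = ", length(longReads), ", |S| = ", length(shortReads))

    contigs <- NULL
    mask <- NULL
    if (config$reference == "truth") {
        refChar <- as.character(genome@ref)
    } else if (config$reference == "file") {
        stopIfNot(!is.null(config$refFile), "reference = 'file' needs refFile")
        refChar <- as.character(readDNAStringSet(config$refFile)[[1L]])
    } else {
        pipeLog(v, "assembling pseudo reference from ", length(longReads),
                " long reads")
        asm <- assemblePseudoReference(longReads, config$assembly)
        refChar <- as.character(refSequence(asm$reference))
        mask <- spacerMask(asm$reference)
        contigs <- asm$contigs
        pipeLog(v, "pseudo reference: ", nchar(refChar), " bp from ",
                length(contigs), " contig(s)")
    }
    refLen <- nchar(refChar)

    alLong <- mapReads(longReads, refChar, mode = config$mapMode)
    parts <- splitLongReads(alLong, longReads, config$threshold)
    pipeLog(v, "|Lm| = ", length(parts$Lm), ", |Lu| = ", length(parts$Lu),
            " (threshold ", config$threshold, ")")
    stopIfNot(length(parts$Lm) + length(parts$Lu) == length(longReads),
              "internal invariant violated: Lm/Lu must partition L")

    alShort <- mapReads(shortReads, refChar, mode = config$mapMode)
    pileLong <- buildPileup(parts$LmAlignments, longReads, refLen, mask)
    pileShort <- buildPileup(alShort, shortReads, refLen, mask)

    callsLong <- callZygosity(pileLong, config$eLong, config$prior)
    callsShort <- callZygosity(pileShort, config$eShort, config$prior)
    decisions <- siteDecisions(callsLong, callsShort, pileLong, pileShort,
                               config$pool)
    pipeLog(v, "sites decided: ", nrow(decisions), " (long calls ",
            nrow(callsLong), ", short calls ", nrow(callsShort), ")")

    luMaps <- mapShortToLu(shortReads, parts$Lu,
                           mode = if (config$mapMode == "truth_anchored")
                               "truth_anchored" else "seeded")
    luOut <- correctUnmappedReads(parts$Lu, luMaps, config$eShort,
                                  config$prior, seed = seed + 4L)
    lmOut <- correctLongReads(parts$Lm, parts$LmAlignments, decisions,
                              refLen, seed = seed + 3L)
    corrected <- c(lmOut$reads, luOut$reads)
    edits <- rbind(lmOut$edits, luOut$edits)
    pipeLog(v, "corrected ", length(corrected), " reads, ", nrow(edits),
            " base edits")

    evaluation <- NULL
    summary <- NULL
    if (nrow(genome@hetSites) > 0L && nrow(corrected@truthSpans) > 0L) {
        evaluation <- evaluateHetSites(corrected, genome,
                                       intervals = config$intervals,
                                       mode = config$retentionMode)
        summary <- evaluationReport(evaluation, outdir = config$outdir)
        pipeLog(v, "retention accuracy: ",
                paste(sprintf("%s %.3f", names(summary$accuracy),
                              summary$accuracy), collapse = ", "))
    }

    if (!is.null(config$outdir)) {
        dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
        out <- corrected@sequences
        writeXStringSet(out, file.path(config$outdir, "corrected.fasta"))
        utils::write.table(edits, file.path(config$outdir, "edits.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(decisions, file.path(config$outdir, "calls.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }

    list(genome = genome, longReads = longReads, shortReads = shortReads,
         reference = refChar, contigs = contigs,
         longAlignments = alLong, shortAlignments = alShort,
         Lm = parts$Lm, Lu = parts$Lu,
         pileupLong = pileLong, pileupShort = pileShort,
         callsLong = callsLong, callsShort = callsShort,
         decisions = decisions, corrected = corrected, edits = edits,
         evaluation = evaluation, summary = summary, config = config)
}
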