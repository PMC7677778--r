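#' Voting pool for base replacement at one site
#'
#' The ranked allele counts used by the correction rules. At anchor sites of
#' mapped long reads the pool merges the long-read and short-read counts
#' (both pileups exist at the anchor); for unmapped long reads only
#' short-read counts are available. A `"short"` pool restricted to
#' short-read counts is offered at anchors as well.
#'
#' @param longCounts,shortCounts Named allele count vectors (or `NULL`).
#' @param pool `"merged"` or `"short"`.
#' @return A [RankedCounts-class]; ties follow the fixed allele order.
#' @examples
#' votingPool(c(A = 4, C = 1), c(A = 6, C = 5))  # merged {A:10, C:6}
#' @export
votingPool <- function(longCounts = NULL, shortCounts = NULL,
                       pool = c("merged", "short")) {
    pool <- match.arg(pool)
    v <- integer(5)
    names(v) <- ALLELES
    add <- function(x) {
        if (is.null(x)) return()
        rc <- rankAlleles(x)
        v[rc@alleles] <<- v[rc@alleles] + rc@counts
    }
    if (pool == "merged") add(longCounts)
    add(shortCounts)
    rankAlleles(v)
}

#' Correct one read base given the zygosity decision
#'
#' Under a homozygous decision the base is replaced with the most frequent
#' pool allele. Under a heterozygous decision a base already among the top
#' two pool alleles is left as it is; any other base is replaced with one of
#' the top two, chosen uniformly at random (seed the RNG for
#' reproducibility). A result of `"N"` means the base is deleted from the
#' output sequence.
#'
#' @param readBase The read base at the site.
#' @param hypothesis `"homozygous"` or `"heterozygous"`.
#' @param pool A [RankedCounts-class] voting pool with depth >= 1.
#' @return The corrected base (possibly `"N"` for deletion).
#' @examples
#' correctBase("C", "homozygous", rankAlleles(c(A = 5, C = 1)))   # "A"
#' correctBase("C", "heterozygous", rankAlleles(c(A = 5, C = 4))) # "C"
#' @export
correctBase <- function(readBase, hypothesis, pool) {
    stopIfNot(pool@depth >= 1L, "empty voting pool: site must be skipped")
    top1 <- pool@alleles[1L]
    top2 <- if (pool@d >= 2L) pool@alleles[2L] else top1
    if (hypothesis == "homozygous") return(top1)
    if (readBase %in% c(top1, top2)) return(readBase)
    sample(c(top1, top2), 1L)
}

#' Per-site correction decisions at the reference anchors
#'
#' Combines the long-read and short-read zygosity judgments at every anchor
#' (see [combineCalls()]) and ranks the voting pool, yielding for each
#' decidable site the final hypothesis and the top two pool alleles.
#'
#' @param callsLong,callsShort Call tables from [callZygosity()] for the
#'   long-read and short-read pileups (either may cover only part of the
#'   target).
#' @param pileupLong,pileupShort The corresponding pileup matrices.
#' @param pool `"merged"` (long + short counts, default) or `"short"`.
#' @return A `data.frame` with `site` (0-based), `H`, `top1`, `top2` for
#'   every site with a judgment and a nonempty pool.
#' @export
siteDecisions <- function(callsLong, callsShort, pileupLong, pileupShort,
                          pool = c("merged", "short")) {
    pool <- match.arg(pool)
    L <- nrow(pileupLong)
    stopIfNot(nrow(pileupShort) == L, "pileups must cover the same target")
    hL <- rep(NA_character_, L)
    hS <- rep(NA_character_, L)
    if (nrow(callsLong) > 0L) hL[callsLong$site + 1L] <- callsLong$call
    if (nrow(callsShort) > 0L) hS[callsShort$site + 1L] <- callsShort$call
    H <- combineHypotheses(hL, hS)
    poolCounts <- if (pool == "merged") pileupLong + pileupShort else pileupShort
    poolDepth <- rowSums(poolCounts)
    decided <- which(!is.na(H) & poolDepth > 0L)
    if (length(decided) == 0L)
        return(data.frame(site = integer(), H = character(),
                          top1 = character(), top2 = character(),
                          stringsAsFactors = FALSE))
    ranked <- cpp_rank_counts(poolCounts[decided, , drop = FALSE])
    d <- rowSums(ranked$sorted > 0L)
    top1 <- ALLELES[ranked$order[, 1L]]
    top2 <- ifelse(d >= 2L, ALLELES[ranked$order[, 2L]], top1)
    data.frame(site = decided - 1L, H = H[decided], top1 = top1, top2 = top2,
               stringsAsFactors = FALSE)
}

# vectorised correction of one read's bases against per-site decision
# vectors (indexed site + 1); returns the corrected characters ("" = base
# deleted) and the edit table
correctChars <- function(chars, refpos, Hv, t1v, t2v, readId) {
    pos1 <- refpos + 1L
    ok <- refpos >= 0L & pos1 <= length(Hv)
    ok[ok] <- !is.na(Hv[pos1[ok]])
    newChars <- chars
    idx <- which(ok)
    if (length(idx) > 0L) {
        p <- pos1[idx]
        H <- Hv[p]; a1 <- t1v[p]; a2 <- t2v[p]
        cur <- chars[idx]
        res <- ifelse(H == "homozygous", a1,
                      ifelse(cur == a1 | cur == a2, cur, NA_character_))
        rnd <- which(is.na(res))
        if (length(rnd) > 0L)
            res[rnd] <- ifelse(stats::runif(length(rnd)) < 0.5,
                               a1[rnd], a2[rnd])
        newChars[idx] <- res
    }
    changed <- which(newChars != chars)
    edits <- data.frame(read_id = rep(readId, length(changed)),
                        read_pos = changed - 1L,
                        old = chars[changed],
                        new = ifelse(newChars[changed] == "N", "deleted",
                                     newChars[changed]),
                        stringsAsFactors = FALSE)
    newChars[newChars == "N"] <- ""
    list(chars = newChars, edits = edits)
}

#' Correct mapped long reads at the reference anchors
#'
#' Applies the correction rules to every `Lm` read base aligned to a decided
#' anchor site: homozygous sites are replaced with the top pool allele,
#' heterozygous sites keep bases already among the top two pool alleles and
#' randomly re-assign other bases to one of the top two. A winning null
#' allele deletes the base from the output sequence. Insertions relative to
#' the reference have no anchor and are never touched.
#'
#' @param lm The mapped long-read [ReadSet-class] (Lm).
#' @param alignments Alignment rows for the `Lm` reads (from
#'   [splitLongReads()]).
#' @param decisions Decisions from [siteDecisions()].
#' @param targetLength Length of the reference the decisions index.
#' @param seed Integer seed for the random heterozygous replacements.
#' @return A list with `reads` (the corrected [ReadSet-class], `Lm'`) and
#'   `edits` (`data.frame` of `read_id`, `read_pos` 0-based in alignment
#'   orientation, `old`, `new`; `new = "deleted"` for removed bases).
#' @export
correctLongReads <- function(lm, alignments, decisions, targetLength,
                             seed = 1L) {
    Hv <- rep(NA_character_, targetLength)
    t1v <- rep(NA_character_, targetLength)
    t2v <- rep(NA_character_, targetLength)
    if (nrow(decisions) > 0L) {
        Hv[decisions$site + 1L] <- decisions$H
        t1v[decisions$site + 1L] <- decisions$top1
        t2v[decisions$site + 1L] <- decisions$top2
    }
    seqChars <- as.character(lm@sequences)
    ids <- names(lm@sequences)
    alIdx <- match(ids, alignments$read_id)
    editsList <- vector("list", length(ids))
    withSeed(seed, {
        for (i in seq_along(ids)) {
            ai <- alIdx[i]
            if (is.na(ai) || is.na(alignments$target_start[ai])) {
                editsList[[i]] <- NULL
                next
            }
            oriented <- seqChars[i]
            rc <- alignments$strand[ai] == "-"
            if (rc)
                oriented <- as.character(
                    reverseComplement(DNAString(oriented)))
            chars <- strsplit(oriented, "", fixed = TRUE)[[1L]]
            refpos <- cpp_base_refpos(alignments$cigar[ai],
                                      alignments$target_start[ai],
                                      length(chars))
            res <- correctChars(chars, refpos, Hv, t1v, t2v, ids[i])
            newSeq <- paste(res$chars, collapse = "")
            if (rc)
                newSeq <- as.character(reverseComplement(DNAString(newSeq)))
            seqChars[i] <- newSeq
            editsList[[i]] <- res$edits
        }
    })
    out <- DNAStringSet(seqChars)
    names(out) <- ids
    edits <- do.call(rbind, editsList)
    if (is.null(edits))
        edits <- data.frame(read_id = character(), read_pos = integer(),
                            old = character(), new = character(),
                            stringsAsFactors = FALSE)
    rownames(edits) <- NULL
    list(reads = new("ReadSet", sequences = out, truthSpans = lm@truthSpans),
         edits = edits)
}

#' Correct unmapped long reads using short reads only
#'
#' Each `Lu` read is treated as its own target: the short reads mapped onto
#' it (see [mapShortToLu()]) provide a per-position pileup, the classifier
#' judges each covered position from that short-read evidence alone, and the
#' same correction rules are applied to the read's own bases. Positions
#' without short-read coverage are left untouched; reads attracting no
#' short read pass through unchanged.
#'
#' @param lu The unmapped long-read [ReadSet-class] (Lu).
#' @param shortMaps Per-read alignments and pileups from [mapShortToLu()].
#' @param eShort Short-read per-base error rate for the classifier.
#' @param prior A [PriorSpec-class].
#' @param seed Integer seed for random heterozygous replacements.
#' @return A list with `reads` (`Lu'`) and `edits`, as in
#'   [correctLongReads()].
#' @export
correctUnmappedReads <- function(lu, shortMaps, eShort = 0.05,
                                 prior = pointPrior(0.5), seed = 1L) {
    seqChars <- as.character(lu@sequences)
    ids <- names(lu@sequences)
    editsList <- vector("list", length(ids))
    withSeed(seed, {
        for (i in seq_along(ids)) {
            sm <- shortMaps[[ids[i]]]
            if (is.null(sm) || sum(sm$pileup) == 0L) next
            calls <- callZygosity(sm$pileup, eShort, prior)
            if (nrow(calls) == 0L) next
            L <- nchar(seqChars[i])
            Hv <- rep(NA_character_, L)
            t1v <- rep(NA_character_, L)
            t2v <- rep(NA_character_, L)
            Hv[calls$site + 1L] <- calls$call
            t1v[calls$site + 1L] <- calls$top1
            t2v[calls$site + 1L] <- ifelse(is.na(calls$top2), calls$top1,
                                           calls$top2)
            chars <- strsplit(seqChars[i], "", fixed = TRUE)[[1L]]
            res <- correctChars(chars, seq_along(chars) - 1L, Hv, t1v, t2v,
                                ids[i])
            seqChars[i] <- paste(res$chars, collapse = "")
            editsList[[i]] <- res$edits
        }
    })
    out <- DNAStringSet(seqChars)
    names(out) <- ids
    edits <- do.call(rbind, editsList)
    if (is.null(edits))
        edits <- data.frame(read_id = character(), read_pos = integer(),
                            old = character(), new = character(),
                            stringsAsFactors = FALSE)
    rownames(edits) <- NULL
    list(reads = new("ReadSet", sequences = out, truthSpans = lu@truthSpans),
         edits = edits)
}
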