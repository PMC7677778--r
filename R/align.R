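#' Rank the allele counts of one pileup column
#'
#' Sorts alleles by observed count, descending, with ties broken by the
#' fixed allele order A < C < G < T < N, and drops zero-count alleles. The
#' number of distinct observed alleles `d` (the "bases distribution") and
#' the suffix depths \eqn{D_q = \sum_{j \ge q} |X_j|} drive the sequential
#' binomial likelihood.
#'
#' @param counts Integer counts, either named over a subset of
#'   `A,C,G,T,N` or unnamed in that order.
#' @return A [RankedCounts-class].
#' @examples
#' rankAlleles(c(A = 5, C = 5))       # tie broken A first, d = 2
#' rankAlleles(c(T = 7))              # d = 1
#' @export
rankAlleles <- function(counts) {
    v <- integer(5)
    names(v) <- ALLELES
    if (is.null(names(counts))) {
        stopIfNot(length(counts) <= 5L, "at most 5 allele counts")
        v[seq_along(counts)] <- as.integer(counts)
    } else {
        stopIfNot(all(names(counts) %in% ALLELES),
                  "allele names must be among A,C,G,T,N")
        v[names(counts)] <- as.integer(counts)
    }
    stopIfNot(all(v >= 0L), "counts must be non-negative")
    ord <- order(-v, seq_along(v))
    sorted <- v[ord]
    nz <- sorted > 0L
    new("RankedCounts", alleles = ALLELES[ord][nz],
        counts = as.integer(sorted[nz]), d = sum(nz), depth = sum(v))
}

#' @rdname rankAlleles
#' @param rc A [RankedCounts-class].
#' @return For `suffixDepths()`, the integer vector of suffix depths
#'   \eqn{D_q}, one per observed rank.
#' @export
suffixDepths <- function(rc) {
    rev(cumsum(rev(rc@counts)))
}

targetAsChar <- function(target) {
    if (is(target, "PseudoReference")) as.character(target@sequence)
    else if (is(target, "DNAString") || is(target, "DNAStringSet"))
        as.character(target)[[1L]]
    else as.character(target)
}

emptyAlignments <- function() {
    data.frame(read_id = character(), target_id = character(),
               target_start = integer(), strand = character(),
               score = numeric(), pct_mapped = numeric(), cigar = character(),
               read_length = integer(), stringsAsFactors = FALSE)
}

# build a k-mer -> positions index of the target (0-based positions)
kmerIndex <- function(targetChar, k) {
    n <- nchar(targetChar)
    if (n < k) return(list())
    kmers <- substring(targetChar, 1:(n - k + 1L), k:n)
    split(0:(n - k), kmers)
}

# locate a read on the target by shared k-mer diagonals; returns the window
# (0-based half-open) to align into, or NULL when no seed matches
seedWindow <- function(readChar, index, k, targetLen) {
    rl <- nchar(readChar)
    if (rl < k) return(NULL)
    stride <- max(1L, k %/% 3L)
    offs <- unique(c(seq(1L, rl - k + 1L, by = stride), rl - k + 1L))
    qk <- substring(readChar, offs, offs + k - 1L)
    hit <- index[qk]
    diags <- unlist(lapply(seq_along(hit), function(i) {
        p <- hit[[i]]
        if (is.null(p)) return(integer(0))
        p - (offs[i] - 1L)
    }), use.names = FALSE)
    if (length(diags) == 0L) return(NULL)
    # cluster diagonals coarsely and keep the best-supported cluster
    bucket <- round(diags / 50)
    best <- names(sort(table(bucket), decreasing = TRUE))[1L]
    sel <- diags[bucket == as.numeric(best)]
    pad <- max(30L, ceiling(0.2 * rl))
    c(max(0L, min(sel) - pad), min(targetLen, max(sel) + rl + pad))
}

alignIntoWindow <- function(readChar, targetChar, ws, we, match, mismatch, gap) {
    res <- cpp_glocal_align(readChar, substring(targetChar, ws + 1L, we),
                            match, mismatch, gap)
    list(start = ws + res$subject_start, score = res$score, cigar = res$cigar)
}

#' Map reads onto a target sequence
#'
#' Maps every read onto the target and keeps at most one (best-scoring)
#' alignment per read. Three modes are offered: `"seeded"` locates each read
#' by shared k-mers and aligns it into a padded window by semi-global
#' dynamic programming (both orientations are tried); `"exhaustive"` runs
#' the full semi-global dynamic program against the whole target, the
#' slow-but-exact oracle intended for small instances; `"truth_anchored"`
#' places simulated reads at their recorded truth coordinates and re-aligns
#' them locally inside a padded window, the fast mode for simulated data.
#'
#' The fraction of read bases aligned to the target (as match or
#' substitution columns) is reported as `pct_mapped`; insertions relative to
#' the target have no anchor and do not count as mapped.
#'
#' @param reads A [ReadSet-class].
#' @param target A [PseudoReference-class], [Biostrings::DNAString] or
#'   character scalar.
#' @param mode `"seeded"`, `"exhaustive"` or `"truth_anchored"`.
#' @param match,mismatch,gap Alignment scores (defaults 1, -1, -2).
#' @param k Seed k-mer length for `"seeded"` mode.
#' @param targetId Identifier stored in the `target_id` column.
#' @return A `data.frame` with one row per read: `read_id`, `target_id`,
#'   `target_start` (0-based), `strand`, `score`, `pct_mapped`, `cigar`
#'   (ops `M` = aligned column, `I` = read base without anchor, `D` =
#'   deleted target base), `read_length`. Unplaced reads carry `NA`
#'   coordinates and `pct_mapped = 0`.
#' @export
mapReads <- function(reads, target,
                     mode = c("seeded", "exhaustive", "truth_anchored"),
                     match = 1, mismatch = -1, gap = -2, k = 15L,
                     targetId = "ref") {
    mode <- match.arg(mode)
    targetChar <- targetAsChar(target)
    targetLen <- nchar(targetChar)
    stopIfNot(targetLen > 0L, "empty target")
    n <- length(reads)
    if (n == 0L) return(emptyAlignments())
    seqChars <- as.character(reads@sequences)
    ids <- names(reads@sequences)
    out <- data.frame(read_id = ids, target_id = targetId,
                      target_start = NA_integer_, strand = "+",
                      score = NA_real_, pct_mapped = 0,
                      cigar = NA_character_, read_length = nchar(seqChars),
                      stringsAsFactors = FALSE)

    if (mode == "truth_anchored") {
        ts <- reads@truthSpans
        stopIfNot(nrow(ts) > 0L,
                  "truth_anchored mapping requires truth spans on the reads")
        rcIdx <- which(ts$strand == "-")
        oriented <- seqChars
        if (length(rcIdx) > 0L)
            oriented[rcIdx] <- as.character(
                reverseComplement(DNAStringSet(seqChars[rcIdx])))
        for (i in seq_len(n)) {
            s <- ts$start[i]; e <- ts$end[i]
            pad <- max(20L, ceiling(0.15 * (e - s)))
            ws <- max(0L, s - pad); we <- min(targetLen, e + pad)
            r <- alignIntoWindow(oriented[i], targetChar, ws, we,
                                 match, mismatch, gap)
            out$target_start[i] <- r$start
            out$strand[i] <- ts$strand[i]
            out$score[i] <- r$score
            out$cigar[i] <- r$cigar
            out$pct_mapped[i] <- cigarAlignedBases(r$cigar) / nchar(oriented[i])
        }
        return(out)
    }

    rcChars <- as.character(reverseComplement(DNAStringSet(seqChars)))
    if (mode == "exhaustive") {
        for (i in seq_len(n)) {
            fwd <- alignIntoWindow(seqChars[i], targetChar, 0L, targetLen,
                                   match, mismatch, gap)
            rev <- alignIntoWindow(rcChars[i], targetChar, 0L, targetLen,
                                   match, mismatch, gap)
            best <- if (rev$score > fwd$score) rev else fwd
            st <- if (rev$score > fwd$score) "-" else "+"
            out$target_start[i] <- best$start
            out$strand[i] <- st
            out$score[i] <- best$score
            out$cigar[i] <- best$cigar
            out$pct_mapped[i] <- cigarAlignedBases(best$cigar) / nchar(seqChars[i])
        }
        return(out)
    }

    index <- kmerIndex(targetChar, k)
    for (i in seq_len(n)) {
        cand <- list()
        wf <- seedWindow(seqChars[i], index, k, targetLen)
        if (!is.null(wf))
            cand$`+` <- alignIntoWindow(seqChars[i], targetChar, wf[1L], wf[2L],
                                        match, mismatch, gap)
        wr <- seedWindow(rcChars[i], index, k, targetLen)
        if (!is.null(wr))
            cand$`-` <- alignIntoWindow(rcChars[i], targetChar, wr[1L], wr[2L],
                                        match, mismatch, gap)
        if (length(cand) == 0L) next  # no seed anywhere: read stays unplaced
        st <- names(cand)[which.max(vapply(cand, `[[`, 0, "score"))]
        best <- cand[[st]]
        out$target_start[i] <- best$start
        out$strand[i] <- st
        out$score[i] <- best$score
        out$cigar[i] <- best$cigar
        out$pct_mapped[i] <- cigarAlignedBases(best$cigar) / nchar(seqChars[i])
    }
    out
}

#' Split long reads into mapped (Lm) and unmapped (Lu) sets
#'
#' A read whose best alignment covers strictly more than `threshold` of its
#' bases (as match/substitution columns) is assigned to the mapped set
#' `Lm`; all other reads, including reads with no alignment at all, go to
#' `Lu`. The partition is total: every read lands in exactly one set.
#'
#' @param alignments Alignments from [mapReads()] (one row per read).
#' @param reads The [ReadSet-class] the alignments were computed from.
#' @param threshold Mapped-base fraction above which a read counts as
#'   mapped; default 0.90 (strictly greater than).
#' @return A list with `Lm`, `Lu` ([ReadSet-class]) and the corresponding
#'   alignment subsets `LmAlignments`, `LuAlignments`.
#' @export
splitLongReads <- function(alignments, reads, threshold = 0.90) {
    stopIfNot(nrow(alignments) == length(reads),
              "need exactly one alignment row per read")
    mapped <- !is.na(alignments$pct_mapped) & alignments$pct_mapped > threshold
    list(Lm = reads[mapped], Lu = reads[!mapped],
         LmAlignments = alignments[mapped, , drop = FALSE],
         LuAlignments = alignments[!mapped, , drop = FALSE])
}

#' Build a pileup of allele counts over a common target
#'
#' For every target position covered by at least one aligned read, counts
#' the read bases aligned there. A deletion spanning the position
#' contributes to the null allele `N`; insertions between anchor positions
#' have no anchor and are ignored. Positions under the spacer mask of an
#' assembled reference are zeroed out (they are not anchor points).
#'
#' @param alignments Alignments from [mapReads()].
#' @param reads The [ReadSet-class] the alignments refer to.
#' @param targetLength Length of the common target.
#' @param spacerMask Optional [IRanges::IRanges] of masked positions
#'   (1-based), e.g. `spacerMask(ref)` of a [PseudoReference-class].
#' @return An integer matrix `targetLength x 5` with columns `A,C,G,T,N`;
#'   row `i` is 0-based site `i - 1`.
#' @export
buildPileup <- function(alignments, reads, targetLength, spacerMask = NULL) {
    ok <- !is.na(alignments$target_start)
    al <- alignments[ok, , drop = FALSE]
    if (nrow(al) == 0L) {
        m <- matrix(0L, targetLength, 5L, dimnames = list(NULL, ALLELES))
        return(m)
    }
    seqChars <- as.character(reads@sequences[al$read_id])
    rc <- al$strand == "-"
    if (any(rc))
        seqChars[rc] <- as.character(
            reverseComplement(DNAStringSet(seqChars[rc])))
    m <- cpp_pileup(as.integer(al$target_start), al$cigar, seqChars,
                    as.integer(targetLength))
    colnames(m) <- ALLELES
    if (!is.null(spacerMask) && length(spacerMask) > 0L) {
        pos <- unlist(lapply(seq_along(spacerMask), function(i)
            IRanges::start(spacerMask)[i]:IRanges::end(spacerMask)[i]))
        m[pos, ] <- 0L
    }
    m
}

#' Map short reads to each unmapped long read separately
#'
#' Unmapped long reads (`Lu`) have no anchor on the shared reference, so the
#' short reads are mapped onto each `Lu` read individually and a per-read
#' pileup over the read's own positions is built. `Lu` reads that attract no
#' short read get an empty pileup and later pass through correction
#' unchanged.
#'
#' @param shortReads The short-read [ReadSet-class] (S).
#' @param lu The unmapped long-read [ReadSet-class] (Lu).
#' @param mode `"truth_anchored"` (preselect short reads overlapping the Lu
#'   read's truth interval, then re-align locally) or `"seeded"`.
#' @param match,mismatch,gap Alignment scores.
#' @param minOverlap In truth mode, the minimum overlap (fraction of the
#'   short read) between truth intervals for a short read to be considered.
#' @return A named list, one element per `Lu` read, each a list with
#'   `alignments` and `pileup` (rows = positions of that `Lu` read).
#' @export
mapShortToLu <- function(shortReads, lu,
                         mode = c("truth_anchored", "seeded"),
                         match = 1, mismatch = -1, gap = -2,
                         minOverlap = 0.5) {
    mode <- match.arg(mode)
    out <- vector("list", length(lu))
    names(out) <- names(lu@sequences)
    if (length(lu) == 0L) return(out)
    luChars <- as.character(lu@sequences)
    for (i in seq_along(out)) {
        luLen <- nchar(luChars[i])
        if (mode == "truth_anchored") {
            stopIfNot(nrow(lu@truthSpans) > 0L && nrow(shortReads@truthSpans) > 0L,
                      "truth_anchored mode requires truth spans on both sets")
            ls <- lu@truthSpans$start[i]; le <- lu@truthSpans$end[i]
            ss <- shortReads@truthSpans$start; se <- shortReads@truthSpans$end
            ov <- pmin(se, le) - pmax(ss, ls)
            sel <- which(ov >= minOverlap * (se - ss))
            if (length(sel) == 0L) {
                out[[i]] <- list(alignments = emptyAlignments(),
                                 pileup = matrix(0L, luLen, 5L,
                                                 dimnames = list(NULL, ALLELES)))
                next
            }
            sub <- shortReads[sel]
            al <- emptyAlignments()[rep(1L, 0L), ]
            subChars <- as.character(sub@sequences)
            rows <- lapply(seq_along(sel), function(j) {
                # anchor the short read at its coordinate offset inside Lu
                off <- sub@truthSpans$start[j] - ls
                sl <- nchar(subChars[j])
                pad <- max(20L, ceiling(0.2 * sl))
                ws <- max(0L, off - pad); we <- min(luLen, off + sl + pad)
                r <- alignIntoWindow(subChars[j], luChars[i], ws, we,
                                     match, mismatch, gap)
                data.frame(read_id = names(sub@sequences)[j],
                           target_id = names(lu@sequences)[i],
                           target_start = r$start, strand = "+",
                           score = r$score,
                           pct_mapped = cigarAlignedBases(r$cigar) / sl,
                           cigar = r$cigar, read_length = sl,
                           stringsAsFactors = FALSE)
            })
            al <- do.call(rbind, rows)
            pu <- cpp_pileup(as.integer(al$target_start), al$cigar, subChars,
                             luLen)
        } else {
            al <- mapReads(shortReads, luChars[i], mode = "seeded",
                           match = match, mismatch = mismatch, gap = gap,
                           targetId = names(lu@sequences)[i])
            al <- al[!is.na(al$target_start) & al$score > 0, , drop = FALSE]
            pu <- buildPileup(al, shortReads, luLen)
        }
        colnames(pu) <- ALLELES
        out[[i]] <- list(alignments = al, pileup = pu)
    }
    out
}

#' Import read alignments from a SAM/BAM file
#'
#' Accepts standard SAM/BAM produced by any external mapper as a substitute
#' for the internal mapper. Only the best (primary) record per read is kept.
#' CIGAR ops `M`, `=`, `X` become aligned columns, `I`/`S` unanchored read
#' bases, `D` deleted target bases; hard clips are dropped.
#'
#' @param file Path to a SAM or BAM file.
#' @return An alignments `data.frame` in the layout of [mapReads()].
#' @export
importAlignmentsSAM <- function(file) {
    stopIfNot(requireNamespace("Rsamtools", quietly = TRUE),
              "Rsamtools is required to import SAM/BAM")
    if (grepl("\\.sam$", file, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        file <- Rsamtools::asBam(file, destination = dest, overwrite = TRUE,
                                 indexDestination = FALSE)
    }
    b <- Rsamtools::scanBam(file,
        param = Rsamtools::ScanBamParam(
            what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
            flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                          isSupplementaryAlignment = FALSE)))[[1L]]
    n <- length(b$qname)
    cig <- gsub("[=X]", "M", b$cigar)
    cig <- gsub("([0-9]+)H", "", cig)
    rl <- vapply(seq_len(n), function(i) {
        if (is.na(cig[i])) return(nchar(as.character(b$seq[i])))
        ops <- cigarToOps(cig[i])
        sum(ops$len[ops$op %in% c("M", "I", "S")])
    }, 0L)
    aligned <- vapply(seq_len(n), function(i)
        if (is.na(cig[i])) 0L else cigarAlignedBases(cig[i]), 0L)
    unmapped <- bitwAnd(b$flag, 4L) > 0L
    data.frame(read_id = b$qname,
               target_id = as.character(b$rname),
               target_start = ifelse(unmapped, NA_integer_, b$pos - 1L),
               strand = ifelse(bitwAnd(b$flag, 16L) > 0L, "-", "+"),
               score = NA_real_,
               pct_mapped = ifelse(unmapped | rl == 0L, 0, aligned / rl),
               cigar = ifelse(unmapped, NA_character_, cig),
               read_length = rl, stringsAsFactors = FALSE)
}

#' Write alignments as SAM
#'
#' Minimal single-reference SAM writer for interoperability with external
#' tools; records carry position, strand flag, CIGAR and sequence.
#'
#' @param alignments Alignments from [mapReads()].
#' @param reads The corresponding [ReadSet-class].
#' @param targetName,targetLength Reference name and length for the header.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
writeSAM <- function(alignments, reads, targetName, targetLength, file) {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(c("@HD\tVN:1.6\tSO:unknown",
                 sprintf("@SQ\tSN:%s\tLN:%d", targetName, targetLength)), con)
    seqChars <- as.character(reads@sequences[alignments$read_id])
    rc <- !is.na(alignments$strand) & alignments$strand == "-"
    if (any(rc))
        seqChars[rc] <- as.character(
            reverseComplement(DNAStringSet(seqChars[rc])))
    for (i in seq_len(nrow(alignments))) {
        a <- alignments[i, ]
        if (is.na(a$target_start)) {
            writeLines(sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*",
                               a$read_id, seqChars[i]), con)
        } else {
            flag <- if (a$strand == "-") 16L else 0L
            writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
                               a$read_id, flag, targetName,
                               a$target_start + 1L, a$cigar, seqChars[i]), con)
        }
    }
    invisible(file)
}
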