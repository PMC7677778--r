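#' Assembly parameters
#'
#' Scoring and filtering parameters for the overlap-layout-consensus
#' assembler. An overlap between two reads is established when its local
#' alignment score exceeds `theta` and its aligned length lies between
#' `minLength` and `maxLength`.
#'
#' @param minLength,maxLength Bounds on the aligned overlap length
#'   (columns). `maxLength = Inf` disables the upper bound.
#' @param theta Minimum local-alignment score for an overlap.
#' @param match,mismatch,gap Smith-Waterman scores (defaults 1, -1, -2).
#' @param k Seed k-mer length for the pair prefilter.
#' @param prefilter If `TRUE` (default), only read pairs sharing at least
#'   one k-mer are scored; pairs genuinely overlapping by `minLength` or
#'   more always share a k-mer, so the prefilter never changes the result
#'   for them. Set `FALSE` to score all pairs (the oracle path).
#' @return A named list of parameters.
#' @export
assemblyParams <- function(minLength = 100L, maxLength = Inf, theta = 100,
                           match = 1, mismatch = -1, gap = -2, k = 15L,
                           prefilter = TRUE) {
    stopIfNot(minLength > 0 && minLength <= maxLength,
              "need 0 < minLength <= maxLength")
    stopIfNot(theta > 0, "theta must be positive")
    list(minLength = minLength, maxLength = maxLength, theta = theta,
         match = match, mismatch = mismatch, gap = gap, k = as.integer(k),
         prefilter = prefilter)
}

#' Compute pairwise overlaps between reads
#'
#' Scores every candidate read pair with a Smith-Waterman local alignment
#' and emits one overlap per pair whose score exceeds `theta` and whose
#' aligned length lies within `[minLength, maxLength]`. Pairs that do not
#' overlap are simply absent from the result.
#'
#' @param reads A [ReadSet-class].
#' @param params An [assemblyParams()] list.
#' @return A `data.frame` with columns `read_i`, `read_j` (read ids,
#'   `read_i < read_j` lexicographically), half-open spans `i_start`,
#'   `i_end`, `j_start`, `j_end` (0-based), `score` and `length` (alignment
#'   columns).
#' @export
computeOverlaps <- function(reads, params = assemblyParams()) {
    n <- length(reads)
    stopIfNot(n > 0L, "empty read set")
    ids <- names(reads@sequences)
    seqs <- as.character(reads@sequences)
    pairs <- if (params$prefilter && n > 1L) {
        buckets <- new.env(hash = TRUE, parent = emptyenv())
        k <- params$k
        for (i in seq_len(n)) {
            L <- nchar(seqs[i])
            if (L < k) next
            km <- unique(substring(seqs[i], 1:(L - k + 1L), k:L))
            for (x in km) {
                cur <- get0(x, envir = buckets, ifnotfound = integer(0))
                assign(x, c(cur, i), envir = buckets)
            }
        }
        pr <- unique(do.call(rbind, lapply(ls(buckets), function(x) {
            v <- get(x, envir = buckets)
            if (length(v) < 2L) return(NULL)
            t(utils::combn(sort(unique(v)), 2L))
        })))
        if (is.null(pr)) matrix(integer(0), 0L, 2L) else pr
    } else if (n > 1L) {
        t(utils::combn(seq_len(n), 2L))
    } else {
        matrix(integer(0), 0L, 2L)
    }
    rows <- lapply(seq_len(nrow(pairs)), function(r) {
        i <- pairs[r, 1L]; j <- pairs[r, 2L]
        al <- cpp_sw_align(seqs[i], seqs[j], params$match, params$mismatch,
                           params$gap)
        if (al$score <= params$theta) return(NULL)
        if (al$length < params$minLength || al$length > params$maxLength)
            return(NULL)
        data.frame(read_i = ids[i], read_j = ids[j],
                   i_start = al$a_start, i_end = al$a_end,
                   j_start = al$b_start, j_end = al$b_end,
                   score = al$score, length = al$length,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(read_i = character(), read_j = character(),
                          i_start = integer(), i_end = integer(),
                          j_start = integer(), j_end = integer(),
                          score = numeric(), length = integer(),
                          stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

# consensus over member sequences placed at offsets: per-column majority
# vote, ties broken by the fixed base order A < C < G < T
consensusFromMembers <- function(seqs, offsets) {
    len <- max(offsets + nchar(seqs))
    counts <- matrix(0L, len, 4L)
    for (i in seq_along(seqs)) {
        ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
        idx <- match(ch, BASES)
        rows <- offsets[i] + seq_along(ch)
        keep <- !is.na(idx)
        tab <- cbind(rows[keep], idx[keep])
        counts[tab] <- counts[tab] + 1L
    }
    paste(BASES[max.col(counts, ties.method = "first")], collapse = "")
}

#' Lay out reads into contigs by greedy overlap merging
#'
#' Processes overlaps in descending score order (ties broken by the
#' lexicographic read-id pair) and greedily merges the contigs containing
#' the two reads, placing each read at the relative offset implied by the
#' overlap spans. Reads without any usable overlap remain singleton
#' contigs; every read belongs to exactly one contig. The contig sequence
#' is the per-column majority vote over its member reads.
#'
#' @param reads A [ReadSet-class].
#' @param overlaps Overlaps from [computeOverlaps()].
#' @return A list of contigs, each a list with `sequence` (character) and
#'   `members` (`data.frame` of `read_id`, `offset`).
#' @export
layoutContigs <- function(reads, overlaps) {
    ids <- names(reads@sequences)
    seqs <- as.character(reads@sequences)
    names(seqs) <- ids
    contigOf <- seq_along(ids)
    names(contigOf) <- ids
    offset <- integer(length(ids))
    names(offset) <- ids
    if (nrow(overlaps) > 0L) {
        ov <- overlaps[order(-overlaps$score, overlaps$read_i,
                             overlaps$read_j), , drop = FALSE]
        for (r in seq_len(nrow(ov))) {
            a <- ov$read_i[r]; b <- ov$read_j[r]
            ca <- contigOf[a]; cb <- contigOf[b]
            if (ca == cb) next
            # place b's contig so that the overlapping spans coincide
            delta <- offset[a] + ov$i_start[r] - (offset[b] + ov$j_start[r])
            inB <- contigOf == cb
            offset[inB] <- offset[inB] + delta
            contigOf[inB] <- ca
        }
    }
    lapply(split(ids, contigOf), function(members) {
        offs <- offset[members]
        offs <- offs - min(offs)
        ord <- order(offs, members)
        members <- members[ord]; offs <- offs[ord]
        list(sequence = consensusFromMembers(seqs[members], offs),
             members = data.frame(read_id = members, offset = unname(offs),
                                  stringsAsFactors = FALSE))
    })
}

#' Merge contigs that still overlap
#'
#' Repeats overlap detection on the contig sequences themselves and merges
#' overlapping contigs (deleting the originals) until no inter-contig
#' overlap remains. Original read members are carried through with adjusted
#' offsets.
#'
#' @param contigs Contigs from [layoutContigs()].
#' @param params An [assemblyParams()] list.
#' @param maxPasses Safety bound on merge passes.
#' @return The merged contig list, same layout as [layoutContigs()].
#' @export
mergeContigs <- function(contigs, params = assemblyParams(), maxPasses = 10L) {
    for (pass in seq_len(maxPasses)) {
        if (length(contigs) < 2L) break
        cs <- DNAStringSet(vapply(contigs, `[[`, "", "sequence"))
        names(cs) <- sprintf("ctg_%04d", seq_along(contigs))
        crs <- new("ReadSet", sequences = cs, truthSpans = emptyTruthSpans())
        ov <- computeOverlaps(crs, params)
        if (nrow(ov) == 0L) break
        lay <- layoutContigs(crs, ov)
        merged <- lapply(lay, function(group) {
            idx <- match(group$members$read_id, names(cs))
            mem <- do.call(rbind, lapply(seq_along(idx), function(j) {
                m <- contigs[[idx[j]]]$members
                m$offset <- m$offset + group$members$offset[j]
                m
            }))
            mem <- mem[order(mem$offset, mem$read_id), , drop = FALSE]
            rownames(mem) <- NULL
            list(sequence = group$sequence, members = mem)
        })
        if (length(merged) == length(contigs)) break
        contigs <- merged
    }
    unname(contigs)
}

#' Link contigs into a pseudo reference
#'
#' Concatenates the contigs in descending length order (ties by first member
#' read id), separated by runs of 50 `N` spacer bases. Spacer positions are
#' recorded in the mask and excluded from anchoring downstream.
#'
#' @param contigs Contigs from [layoutContigs()] or [mergeContigs()].
#' @param spacer Number of `N` bases between consecutive contigs.
#' @return A [PseudoReference-class].
#' @export
linkContigs <- function(contigs, spacer = 50L) {
    stopIfNot(length(contigs) > 0L, "cannot link an empty contig list")
    seqs <- vapply(contigs, `[[`, "", "sequence")
    firstMember <- vapply(contigs, function(ct) ct$members$read_id[1L], "")
    ord <- order(-nchar(seqs), firstMember)
    seqs <- seqs[ord]
    lens <- nchar(seqs)
    n <- length(seqs)
    starts <- cumsum(c(1L, (lens + spacer)[-n]))
    linked <- paste(seqs, collapse = strrep("N", spacer))
    spacers <- if (n > 1L)
        IRanges(start = starts[-1L] - spacer, width = spacer)
    else IRanges()
    new("PseudoReference", sequence = DNAString(linked),
        contigSpans = IRanges(start = starts, width = lens),
        spacerMask = spacers)
}

#' Assemble a pseudo reference from long reads
#'
#' The full four-step overlap-layout-consensus procedure: score pairwise
#' overlaps, greedily lay reads out into contigs, merge contigs that still
#' overlap, and link the final contigs into a single pseudo reference
#' sequence. The pseudo reference is a shared coordinate anchor for joint
#' pileups, not a biological truth sequence; any externally assembled
#' reference can be substituted at this seam.
#'
#' @param reads The long-read [ReadSet-class] (L).
#' @param params An [assemblyParams()] list.
#' @param spacer Spacer length between linked contigs.
#' @return A list with `reference` (a [PseudoReference-class]) and
#'   `contigs` (the final contig list).
#' @export
assemblePseudoReference <- function(reads, params = assemblyParams(),
                                    spacer = 50L) {
    ov <- computeOverlaps(reads, params)
    contigs <- layoutContigs(reads, ov)
    contigs <- mergeContigs(contigs, params)
    list(reference = linkContigs(contigs, spacer), contigs = contigs)
}
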