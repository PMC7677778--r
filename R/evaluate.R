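#' Heterozygosity retention of one pileup column
#'
#' A site retains heterozygosity when the balance between its two most
#' frequent alleles lies inside the heterozygous interval (inclusive). The
#' balance is the fraction of the top allele among the top two,
#' `count(top1) / (count(top1) + count(top2))`, so it always lies in
#' `[0.5, 1]`; a column showing a single allele has balance 1 and is lost
#' under any interval with `hi < 1`. Columns with depth below 2 count as
#' lost (heterozygosity cannot be exhibited by fewer than two reads). The
#' alternative `"majority"` mode uses the top-allele fraction over all
#' bases instead.
#'
#' @param counts Allele counts of the column (named vector, matrix row or
#'   [RankedCounts-class]).
#' @param interval Heterozygous interval `c(lo, hi)`; presets in the field
#'   are `[0.20,0.80]`, `[0.25,0.75]`, `[0.30,0.70]`, `[0.35,0.65]`.
#' @param mode `"balance"` (default) or `"majority"`.
#' @return A list with `retained` (logical) and `balance`.
#' @examples
#' retention(c(A = 5, C = 5))$retained          # TRUE everywhere
#' retention(c(A = 9, C = 1))$retained          # FALSE at [0.2, 0.8]
#' retention(c(A = 4, C = 1))$balance           # 0.8, inclusive boundary
#' @export
retention <- function(counts, interval = c(0.20, 0.80),
                      mode = c("balance", "majority")) {
    mode <- match.arg(mode)
    stopIfNot(length(interval) == 2L && interval[1L] < interval[2L],
              "interval must be c(lo, hi) with lo < hi")
    rc <- if (is(counts, "RankedCounts")) counts else rankAlleles(counts)
    if (rc@depth < 2L) return(list(retained = FALSE, balance = NA_real_))
    c1 <- rc@counts[1L]
    c2 <- if (rc@d >= 2L) rc@counts[2L] else 0L
    balance <- if (mode == "balance") c1 / (c1 + c2) else c1 / rc@depth
    list(retained = balance >= interval[1L] && balance <= interval[2L],
         balance = balance)
}

#' Heterozygosity quality (difference value) of one pileup column
#'
#' Compares the proportion of the two true heterozygous alleles against the
#' proportion of the other two bases at the site, over A/C/G/T counts only
#' (the null allele is excluded). A positive difference means the site is
#' still dominated by its true allele pair; the magnitude grades the
#' quality: `(0, 0.3]` is good, `(0.3, 1]` excellent, exactly 0 a draw,
#' negative values poor.
#'
#' @param counts Allele counts of the column.
#' @param alleles Character vector of the two true heterozygous alleles.
#' @return A list with `value` in `[-1, 1]` (`NA` when no A/C/G/T base
#'   covers the site) and `quality` in
#'   `negative`/`draw`/`good`/`excellent` (`NA` when value is `NA`).
#' @examples
#' differenceValue(c(A = 5, C = 4, T = 1), c("A", "C"))  # 0.8, excellent
#' @export
differenceValue <- function(counts, alleles) {
    stopIfNot(length(alleles) == 2L && all(alleles %in% BASES),
              "alleles must be two of A,C,G,T")
    rc <- rankAlleles(counts)
    v <- integer(4)
    names(v) <- BASES
    keep <- rc@alleles %in% BASES
    v[rc@alleles[keep]] <- rc@counts[keep]
    tot <- sum(v)
    if (tot == 0L) return(list(value = NA_real_, quality = NA_character_))
    value <- (sum(v[alleles]) - sum(v[setdiff(BASES, alleles)])) / tot
    quality <- if (value < 0) "negative"
        else if (value == 0) "draw"
        else if (value <= 0.3) "good"
        else "excellent"
    list(value = value, quality = quality)
}

#' Evaluate heterozygosity retention at the planted sites
#'
#' Re-maps the corrected long reads to the truth reference, builds the
#' post-correction pileup, and tests every planted heterozygous site for
#' retention under each requested heterozygous interval, along with its
#' difference value and quality grade. Sites covered by fewer than two
#' corrected reads are counted as lost.
#'
#' @param corrected The corrected long-read [ReadSet-class] (L').
#' @param genome The [DiploidGenome-class] the reads were simulated from.
#' @param intervals Numeric vector of lower interval bounds; each interval
#'   is `c(lo, 1 - lo)`.
#' @param mode Retention mode, see [retention()].
#' @param mapMode Mapping mode for the re-alignment, see [mapReads()].
#' @param alignments Optional precomputed alignments of `corrected` against
#'   the truth reference (skips the re-mapping).
#' @return A `data.frame` with one row per planted site: `position`,
#'   `allele_a`, `allele_b`, `depth`, `balance`, one logical
#'   `retained_<lo>` column per interval, `difference_value` and `quality`
#'   (`not_retained` when the site is lost at the widest interval).
#' @export
evaluateHetSites <- function(corrected, genome,
                             intervals = c(0.20, 0.25, 0.30, 0.35),
                             mode = c("balance", "majority"),
                             mapMode = "truth_anchored", alignments = NULL) {
    mode <- match.arg(mode)
    intervals <- sort(intervals)
    stopIfNot(all(intervals > 0 & intervals <= 0.5),
              "interval lower bounds must lie in (0, 0.5]")
    refChar <- as.character(genome@ref)
    if (is.null(alignments))
        alignments <- mapReads(corrected, refChar, mode = mapMode)
    pu <- buildPileup(alignments, corrected, nchar(refChar))
    hs <- genome@hetSites
    n <- nrow(hs)
    wide <- intervals[1L]
    res <- data.frame(position = hs$position, allele_a = hs$allele_a,
                      allele_b = hs$allele_b, depth = NA_integer_,
                      balance = NA_real_, stringsAsFactors = FALSE)
    retCols <- matrix(FALSE, n, length(intervals),
                      dimnames = list(NULL, sprintf("retained_%.2f", intervals)))
    dv <- numeric(n)
    quality <- character(n)
    for (i in seq_len(n)) {
        counts <- pu[hs$position[i] + 1L, ]
        rc <- rankAlleles(counts)
        res$depth[i] <- rc@depth
        for (j in seq_along(intervals)) {
            r <- retention(rc, c(intervals[j], 1 - intervals[j]), mode)
            retCols[i, j] <- r$retained
            if (j == 1L) res$balance[i] <- r$balance
        }
        q <- differenceValue(counts, c(hs$allele_a[i], hs$allele_b[i]))
        dv[i] <- if (is.na(q$value)) NA_real_ else q$value
        quality[i] <- if (!retCols[i, 1L]) "not_retained"
            else if (is.na(q$quality)) NA_character_ else q$quality
    }
    out <- cbind(res, as.data.frame(retCols))
    out$difference_value <- dv
    out$quality <- quality
    attr(out, "intervals") <- intervals
    attr(out, "widest") <- wide
    out
}

#' Retention accuracy over the planted heterozygous sites
#'
#' The fraction of planted heterozygous sites that retain heterozygosity
#' after correction, `TP / (TP + FN)`, equal to one minus the error rate.
#'
#' @param evals Site evaluations from [evaluateHetSites()].
#' @param interval Lower bound of the interval to read the accuracy at
#'   (must be one of the evaluated intervals).
#' @return A single numeric accuracy in `[0, 1]`.
#' @export
retentionAccuracy <- function(evals, interval = 0.20) {
    stopIfNot(nrow(evals) > 0L, "no evaluated sites")
    col <- sprintf("retained_%.2f", interval)
    stopIfNot(col %in% names(evals),
              paste("interval", interval, "was not evaluated"))
    mean(evals[[col]])
}

#' Summarise a site evaluation
#'
#' Per-interval retention accuracies plus the histogram of quality grades
#' (negative / draw / good / excellent / not_retained), optionally written
#' as TSV and JSON.
#'
#' @param evals Site evaluations from [evaluateHetSites()].
#' @param outdir Optional directory; writes `evaluation.tsv` and
#'   `summary.json` when given.
#' @return A list with `accuracy` (named numeric, one entry per interval),
#'   `quality` (named integer histogram), and `n_sites`.
#' @export
evaluationReport <- function(evals, outdir = NULL) {
    intervals <- attr(evals, "intervals")
    if (is.null(intervals))
        intervals <- as.numeric(sub("retained_", "",
            grep("^retained_", names(evals), value = TRUE)))
    acc <- vapply(intervals, function(lo) retentionAccuracy(evals, lo), 0)
    names(acc) <- sprintf("[%.2f,%.2f]", intervals, 1 - intervals)
    grades <- c("negative", "draw", "good", "excellent", "not_retained")
    qual <- table(factor(evals$quality, levels = grades))
    out <- list(accuracy = acc,
                quality = stats::setNames(as.integer(qual), grades),
                n_sites = nrow(evals))
    if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(evals, file.path(outdir, "evaluation.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(out, file.path(outdir, "summary.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    out
}
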