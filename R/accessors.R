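#' Accessors for the core classes
#'
#' Small accessor generics so that slot layout stays private: haplotype and
#' reference sequences and the planted-site table of a [DiploidGenome-class],
#' the sequences and truth spans of a [ReadSet-class], and the contig and
#' spacer layout of a [PseudoReference-class].
#'
#' @param x The object to access.
#' @return The corresponding component; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("hap1", function(x) standardGeneric("hap1"))
#' @rdname accessors
#' @export
setGeneric("hap2", function(x) standardGeneric("hap2"))
#' @rdname accessors
#' @export
setGeneric("refSequence", function(x) standardGeneric("refSequence"))
#' @rdname accessors
#' @export
setGeneric("hetSites", function(x) standardGeneric("hetSites"))
#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname accessors
#' @export
setGeneric("truthSpans", function(x) standardGeneric("truthSpans"))
#' @rdname accessors
#' @export
setGeneric("contigSpans", function(x) standardGeneric("contigSpans"))
#' @rdname accessors
#' @export
setGeneric("spacerMask", function(x) standardGeneric("spacerMask"))

#' @rdname accessors
setMethod("hap1", "DiploidGenome", function(x) x@hap1)
#' @rdname accessors
setMethod("hap2", "DiploidGenome", function(x) x@hap2)
#' @rdname accessors
setMethod("refSequence", "DiploidGenome", function(x) x@ref)
#' @rdname accessors
setMethod("hetSites", "DiploidGenome", function(x) x@hetSites)
#' @rdname accessors
setMethod("sequences", "ReadSet", function(x) x@sequences)
#' @rdname accessors
setMethod("truthSpans", "ReadSet", function(x) x@truthSpans)
#' @rdname accessors
setMethod("refSequence", "PseudoReference", function(x) x@sequence)
#' @rdname accessors
setMethod("contigSpans", "PseudoReference", function(x) x@contigSpans)
#' @rdname accessors
setMethod("spacerMask", "PseudoReference", function(x) x@spacerMask)

#' @rdname accessors
#' @export
setMethod("length", "ReadSet", function(x) length(x@sequences))

#' Subset a ReadSet
#'
#' @param x A [ReadSet-class].
#' @param i Index vector (integer, logical or read names).
#' @param j,...,drop Ignored.
#' @return A [ReadSet-class] with the selected reads (truth spans follow).
#' @export
setMethod("[", "ReadSet", function(x, i, j, ..., drop = FALSE) {
    ts <- x@truthSpans
    if (nrow(ts) > 0L) {
        if (is.character(i)) i <- match(i, names(x@sequences))
        if (is.logical(i)) i <- which(i)
        ts <- ts[i, , drop = FALSE]
        rownames(ts) <- NULL
        new("ReadSet", sequences = x@sequences[i], truthSpans = ts)
    } else {
        new("ReadSet", sequences = x@sequences[i], truthSpans = ts)
    }
})

#' Combine two ReadSets
#'
#' @param x,y [ReadSet-class] objects. Truth spans are kept only when both
#'   operands carry them.
#' @return A [ReadSet-class].
#' @export
setMethod("c", "ReadSet", function(x, ...) {
    all <- c(list(x), list(...))
    all <- Filter(function(y) length(y) > 0L, all)
    if (length(all) == 0L)
        return(new("ReadSet", sequences = DNAStringSet(),
                   truthSpans = emptyTruthSpans()))
    seqs <- do.call(c, lapply(all, slot, "sequences"))
    ts <- lapply(all, slot, "truthSpans")
    haveTS <- all(vapply(ts, nrow, 0L) > 0L)
    spans <- if (haveTS) do.call(rbind, ts) else emptyTruthSpans()
    rownames(spans) <- NULL
    new("ReadSet", sequences = seqs, truthSpans = spans)
})

setMethod("show", "DiploidGenome", function(object) {
    cat("DiploidGenome of length", length(object@ref), "with",
        nrow(object@hetSites), "heterozygous sites\n")
})

setMethod("show", "ReadSet", function(object) {
    n <- length(object@sequences)
    cat("ReadSet with", n, "reads")
    if (n > 0L)
        cat(" (total", sum(Biostrings::width(object@sequences)), "bases)")
    if (nrow(object@truthSpans) > 0L) cat(", truth spans recorded")
    cat("\n")
})

setMethod("show", "PseudoReference", function(object) {
    cat("PseudoReference of length", length(object@sequence), "linking",
        length(object@contigSpans), "contig(s);",
        sum(IRanges::width(object@spacerMask)), "spacer bases\n")
})

setMethod("show", "PriorSpec", function(object) {
    if (object@kind == "point") {
        cat("PriorSpec: point prior P(homozygous) =", object@pHomo, "\n")
    } else {
        cat("PriorSpec: Beta(", object@a, ",", object@b, ") prior, mode",
            object@betaMode, "\n")
    }
})

setMethod("show", "RankedCounts", function(object) {
    cat("RankedCounts: depth", object@depth, ", d =", object@d, "—",
        paste(sprintf("%s:%d", object@alleles, object@counts), collapse = " "),
        "\n")
})

setMethod("show", "ZygosityCall", function(object) {
    cat("ZygosityCall:", object@hypothesis,
        sprintf("(log post homo %.3f, het %.3f)",
                object@posteriorHomo, object@posteriorHet),
        "top:", paste(object@topAlleles, collapse = "/"), "\n")
})
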