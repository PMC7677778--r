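#' Error model for simulated reads
#'
#' Per-base error rates applied independently to every emitted base:
#' substitution to a uniformly chosen other base, deletion of the base, and
#' insertion of a uniformly chosen base after it. By default the total rate
#' is split equally across the three error types for long reads; short reads
#' are conventionally simulated substitution-only (see [simulateReads()]).
#'
#' @param total Total error rate; ignored when the three component rates are
#'   given explicitly.
#' @param sub,ins,del Component rates. Default `total/3` each.
#' @return A named list with elements `sub`, `ins`, `del`, `total`.
#' @examples
#' errorModel(0.15)
#' errorModel(sub = 0.05, ins = 0, del = 0)
#' @export
errorModel <- function(total = 0.15, sub = total / 3, ins = total / 3,
                       del = total / 3) {
    rates <- c(sub = sub, ins = ins, del = del)
    stopIfNot(all(rates >= 0) && all(rates < 1), "error rates must lie in [0,1)")
    tot <- sum(rates)
    stopIfNot(tot < 0.6,
        "total error rate must stay below 0.6 (above it a heterozygous allele is no more frequent than an error allele and ranks invert)")
    list(sub = unname(sub), ins = unname(ins), del = unname(del), total = tot)
}

#' Simulate a diploid genome with planted heterozygous SNPs
#'
#' Draws a uniform-random genome of the requested length and plants `nHet`
#' heterozygous SNPs at distinct, uniformly sampled positions: haplotype 1
#' keeps the reference base, haplotype 2 carries an alternate allele sampled
#' uniformly from the three non-reference bases.
#'
#' @param length Genome length in bases.
#' @param nHet Number of heterozygous sites to plant.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A [DiploidGenome-class].
#' @examples
#' g <- makeDiploidGenome(1000, 10, seed = 1)
#' nrow(hetSites(g))
#' @export
makeDiploidGenome <- function(length, nHet, seed = 1L) {
    stopIfNot(isSingleNumber(length) && length > 0, "length must be positive")
    stopIfNot(isSingleNumber(nHet) && nHet >= 0, "nHet must be non-negative")
    stopIfNot(nHet <= length, "cannot plant more het sites than genome positions")
    withSeed(seed, {
        refChars <- sample(BASES, length, replace = TRUE)
        pos <- sort(sample.int(length, nHet))
        altShift <- sample.int(3L, nHet, replace = TRUE)
        refIdx <- match(refChars[pos], BASES)
        altChars <- BASES[((refIdx - 1L + altShift) %% 4L) + 1L]
        hap2Chars <- refChars
        hap2Chars[pos] <- altChars
        hs <- data.frame(position = pos - 1L,
                         allele_a = refChars[pos],
                         allele_b = altChars,
                         stringsAsFactors = FALSE)
        refStr <- paste(refChars, collapse = "")
        new("DiploidGenome",
            hap1 = DNAString(refStr),
            hap2 = DNAString(paste(hap2Chars, collapse = "")),
            ref = DNAString(refStr),
            hetSites = hs)
    })
}

# apply the per-base error model to one read given as a character vector;
# returns the mutated character vector
mutateChars <- function(chars, sub, ins, del) {
    L <- length(chars)
    if (L == 0L) return(chars)
    u <- stats::runif(L)
    delMask <- u < del
    subMask <- !delMask & u < del + sub
    if (any(subMask)) {
        idx <- match(chars[subMask], BASES)
        shift <- sample.int(3L, sum(subMask), replace = TRUE)
        chars[subMask] <- BASES[((idx - 1L + shift) %% 4L) + 1L]
    }
    insMask <- stats::runif(L) < ins
    keep <- !delMask
    if (!any(insMask)) return(chars[keep])
    slotSize <- as.integer(keep) + as.integer(insMask)
    ends <- cumsum(slotSize)
    out <- character(ends[L])
    out[ends[keep] - as.integer(insMask[keep])] <- chars[keep]
    out[ends[insMask]] <- sample(BASES, sum(insMask), replace = TRUE)
    out
}

#' Simulate sequencing reads from a diploid genome
#'
#' Reads are drawn uniformly from the two haplotypes (expected 50/50 split),
#' with uniform start positions and lengths from a lognormal distribution
#' around `meanLen` (shape `sdlog = 0.3`), truncated to `[minLen, genome]`.
#' Reads are drawn until the total emitted bases reach
#' `coverage * length(genome)`. Every emitted base is then mutated
#' independently under the error model. The ground-truth placement of each
#' read (reference interval, strand, haplotype) is recorded in the returned
#' [ReadSet-class].
#'
#' @param genome A [DiploidGenome-class].
#' @param coverage Requested mean coverage (fold).
#' @param meanLen,minLen Mean and minimum read length in bases.
#' @param err An [errorModel()].
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param idPrefix Prefix for generated read identifiers.
#' @param revcompHalf If `TRUE`, a random half of the reads is emitted from
#'   the reverse strand (reverse-complemented); the mapper handles both
#'   orientations. Default `FALSE` (all forward).
#' @return A [ReadSet-class] with truth spans.
#' @examples
#' g <- makeDiploidGenome(2000, 5, seed = 1)
#' L <- simulateReads(g, coverage = 4, meanLen = 400, minLen = 100,
#'                    err = errorModel(0), seed = 2)
#' length(L)
#' @export
simulateReads <- function(genome, coverage, meanLen = 2000L, minLen = 200L,
                          err = errorModel(0.15), seed = 1L,
                          idPrefix = "read", revcompHalf = FALSE) {
    stopIfNot(coverage > 0, "coverage must be positive")
    stopIfNot(meanLen >= minLen && minLen >= 1, "need meanLen >= minLen >= 1")
    G <- length(genome@ref)
    stopIfNot(G > 0, "empty genome")
    stopIfNot(minLen <= G, "minLen exceeds genome length")
    hapChars <- c(as.character(genome@hap1), as.character(genome@hap2))
    withSeed(seed, {
        target <- coverage * G
        sdlog <- 0.3
        meanlog <- log(meanLen) - sdlog^2 / 2
        lens <- integer(0)
        while (sum(lens) < target) {
            n <- max(16L, ceiling((target - sum(lens)) / meanLen))
            draw <- round(stats::rlnorm(n, meanlog, sdlog))
            lens <- c(lens, pmin(pmax(draw, minLen), G))
        }
        nReads <- which(cumsum(lens) >= target)[1L]
        lens <- lens[seq_len(nReads)]
        haps <- sample(1:2, nReads, replace = TRUE)
        starts <- floor(stats::runif(nReads, 0, G - lens + 1))
        strands <- if (revcompHalf)
            sample(c("+", "-"), nReads, replace = TRUE) else rep("+", nReads)
        templates <- substring(hapChars[haps], starts + 1L, starts + lens)
        rc <- strands == "-"
        if (any(rc))
            templates[rc] <- as.character(
                reverseComplement(DNAStringSet(templates[rc])))
        noiseless <- err$sub == 0 && err$ins == 0 && err$del == 0
        seqs <- if (noiseless) {
            templates
        } else {
            charList <- strsplit(templates, "", fixed = TRUE)
            vapply(charList, function(ch)
                paste(mutateChars(ch, err$sub, err$ins, err$del), collapse = ""),
                character(1))
        }
        ids <- sprintf("%s_%0*d", idPrefix, nchar(as.character(nReads)),
                       seq_len(nReads))
        dss <- DNAStringSet(seqs)
        names(dss) <- ids
        new("ReadSet", sequences = dss,
            truthSpans = data.frame(read_id = ids, start = as.integer(starts),
                                    end = as.integer(starts + lens),
                                    strand = strands, hap = haps,
                                    stringsAsFactors = FALSE))
    })
}

#' Write a simulated dataset to disk
#'
#' Writes `ref.fasta`, `hap1.fasta`, `hap2.fasta`, `long.fastq`,
#' `short.fastq`, `het_truth.tsv` (position, allele_a, allele_b; 0-based) and
#' `truth_spans.tsv` (read_id, start, end, strand, hap; 0-based half-open).
#' FASTQ qualities are a constant Phred+33 'I'.
#'
#' @param genome A [DiploidGenome-class].
#' @param longReads,shortReads [ReadSet-class] objects (roles L and S).
#' @param outdir Output directory, created if missing.
#' @return Invisibly, the vector of file paths written.
#' @export
writeDataset <- function(genome, longReads, shortReads, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    stopIfNot(dir.exists(outdir), paste("cannot create", outdir))
    fa <- function(seq, name, file) {
        x <- DNAStringSet(as.character(seq))
        names(x) <- name
        writeXStringSet(x, file.path(outdir, file))
    }
    fa(genome@ref, "ref", "ref.fasta")
    fa(genome@hap1, "hap1", "hap1.fasta")
    fa(genome@hap2, "hap2", "hap2.fasta")
    fq <- function(rs, file) {
        q <- Biostrings::BStringSet(strrep("I", Biostrings::width(rs@sequences)))
        writeXStringSet(rs@sequences, file.path(outdir, file),
                        format = "fastq", qualities = q)
    }
    fq(longReads, "long.fastq")
    fq(shortReads, "short.fastq")
    tsv <- function(df, file) {
        path <- file.path(outdir, file)
        con <- file(path, "w")
        writeLines("# coordinates are 0-based (half-open intervals)", con)
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        close(con)
    }
    tsv(genome@hetSites, "het_truth.tsv")
    tsv(rbind(longReads@truthSpans, shortReads@truthSpans), "truth_spans.tsv")
    invisible(file.path(outdir, c("ref.fasta", "hap1.fasta", "hap2.fasta",
                                  "long.fastq", "short.fastq",
                                  "het_truth.tsv", "truth_spans.tsv")))
}

#' Read a FASTA/FASTQ file into a ReadSet
#'
#' @param file Path to a FASTA or FASTQ file (format inferred from the
#'   extension, override with `format`).
#' @param format `"fasta"` or `"fastq"`.
#' @param truthSpans Optional path to a `truth_spans.tsv` as written by
#'   [writeDataset()]; rows are matched to reads by identifier.
#' @return A [ReadSet-class].
#' @export
readReads <- function(file, format = c("auto", "fasta", "fastq"),
                      truthSpans = NULL) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.(fq|fastq)$", file, ignore.case = TRUE))
            "fastq" else "fasta"
    seqs <- readDNAStringSet(file, format = format)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    ts <- emptyTruthSpans()
    if (!is.null(truthSpans)) {
        tab <- utils::read.table(truthSpans, header = TRUE, sep = "\t",
                                 comment.char = "#", stringsAsFactors = FALSE)
        tab <- tab[match(names(seqs), tab$read_id), , drop = FALSE]
        stopIfNot(!anyNA(tab$start), "truth spans missing for some reads")
        rownames(tab) <- NULL
        ts <- tab
    }
    new("ReadSet", sequences = seqs, truthSpans = ts)
}

#' Read back a dataset written by writeDataset
#'
#' @param outdir Directory holding the files written by [writeDataset()].
#' @return A list with elements `genome` ([DiploidGenome-class]),
#'   `longReads` and `shortReads` ([ReadSet-class]).
#' @export
readDataset <- function(outdir) {
    hs <- utils::read.table(file.path(outdir, "het_truth.tsv"), header = TRUE,
                            sep = "\t", comment.char = "#",
                            stringsAsFactors = FALSE)
    h1 <- readDNAStringSet(file.path(outdir, "hap1.fasta"))[[1L]]
    h2 <- readDNAStringSet(file.path(outdir, "hap2.fasta"))[[1L]]
    genome <- new("DiploidGenome", hap1 = h1, hap2 = h2, ref = h1,
                  hetSites = hs)
    spans <- file.path(outdir, "truth_spans.tsv")
    list(genome = genome,
         longReads = readReads(file.path(outdir, "long.fastq"),
                               truthSpans = spans),
         shortReads = readReads(file.path(outdir, "short.fastq"),
                                truthSpans = spans))
}
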