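# shared fixtures and independent oracles

# a ReadSet from bare strings, optionally with truth spans
readSetFrom <- function(seqs, spans = NULL) {
    dss <- Biostrings::DNAStringSet(seqs)
    if (is.null(names(dss))) names(dss) <- sprintf("r%03d", seq_along(dss))
    ts <- if (is.null(spans)) {
        data.frame(read_id = character(), start = integer(), end = integer(),
                   strand = character(), hap = integer(),
                   stringsAsFactors = FALSE)
    } else {
        data.frame(read_id = names(dss), start = as.integer(spans$start),
                   end = as.integer(spans$end),
                   strand = if (is.null(spans$strand)) "+" else spans$strand,
                   hap = if (is.null(spans$hap)) 1L else spans$hap,
                   stringsAsFactors = FALSE)
    }
    new("ReadSet", sequences = dss, truthSpans = ts)
}

# independent likelihood oracle: multinomial pmf of the ranked counts under
# the per-rank category probabilities
multinomOracle <- function(counts, probs) {
    counts <- c(counts, rep(0L, 5L - length(counts)))
    stats::dmultinom(counts, prob = probs)
}

# brute-force classifier oracle built only on the multinomial pmf
bruteClassify <- function(counts, e, pHomo = 0.5) {
    counts <- sort(as.integer(counts), decreasing = TRUE)
    if (sum(counts > 0L) == 1L) return("homozygous")
    postH <- multinomOracle(counts, categoryProbs("homozygous", e)) * pHomo
    postA <- multinomOracle(counts, categoryProbs("heterozygous", e)) * (1 - pHomo)
    if (postA > postH) "heterozygous" else "homozygous"
}

# all non-increasing count vectors with <= 5 parts summing to n
rankedCountVectors <- function(n) {
    out <- list()
    recurse <- function(prefix, remaining, maxPart) {
        if (remaining == 0L) {
            out[[length(out) + 1L]] <<- prefix
            return()
        }
        if (length(prefix) == 5L) return()
        for (p in seq(min(maxPart, remaining), 1L)) {
            recurse(c(prefix, p), remaining - p, p)
        }
    }
    recurse(integer(0), n, n)
    out
}

# local-alignment score oracle via Biostrings
swScoreOracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                    mismatch = mismatch)
    Biostrings::pairwiseAlignment(a, b, type = "local",
                                  substitutionMatrix = mat,
                                  gapOpening = 0, gapExtension = -gap,
                                  scoreOnly = TRUE)
}

# a small noiseless diploid scenario reused across modules
noiselessScenario <- function(seed = 7L, genomeLength = 2000L, nHet = 8L,
                              longCov = 12, shortCov = 15) {
    g <- makeDiploidGenome(genomeLength, nHet, seed = seed)
    L <- simulateReads(g, longCov, meanLen = 400L, minLen = 200L,
                       err = errorModel(0), seed = seed + 1L, idPrefix = "L")
    S <- simulateReads(g, shortCov, meanLen = 100L, minLen = 60L,
                       err = errorModel(0), seed = seed + 2L, idPrefix = "S")
    list(genome = g, L = L, S = S)
}
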