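test_that("voting pools merge counts and break ties in fixed order", {
    pool <- votingPool(c(A = 4, C = 1), c(A = 6, C = 5))
    expect_identical(pool@alleles[1:2], c("A", "C"))
    expect_identical(pool@counts[1:2], c(10L, 6L))
    # short-only pool ignores the long counts
    poolS <- votingPool(c(A = 4, C = 1), c(G = 3, T = 3), pool = "short")
    expect_identical(poolS@alleles[1:2], c("G", "T"))   # tie: G before T
    expect_equal(poolS@depth, 6)
})

test_that("base correction follows the zygosity decision", {
    expect_identical(correctBase("C", "homozygous", rankAlleles(c(A = 5, C = 1))),
                     "A")
    expect_identical(correctBase("C", "heterozygous",
                                 rankAlleles(c(A = 5, C = 4, G = 1))), "C")
    expect_identical(correctBase("A", "heterozygous",
                                 rankAlleles(c(A = 5, C = 4))), "A")
    # a base outside the top two is randomly reassigned, reproducibly
    pick <- function(seed) {
        set.seed(seed)
        correctBase("G", "heterozygous", rankAlleles(c(A = 5, C = 4)))
    }
    expect_true(pick(1) %in% c("A", "C"))
    expect_identical(pick(1), pick(1))
    expect_error(correctBase("A", "homozygous", rankAlleles(c(A = 0))),
                 "empty voting pool")
})

test_that("mapped-read correction fixes a planted error and only that", {
    g <- makeDiploidGenome(400, 0, seed = 60)
    refc <- as.character(refSequence(g))
    clean <- substring(refc, 1, 400)
    bad <- clean
    wrong <- setdiff(c("A", "C", "G", "T"), substring(clean, 200, 200))[1]
    substring(bad, 200, 200) <- wrong
    seqs <- c(rep(clean, 5), bad)
    names(seqs) <- c(paste0("good", 1:5), "bad")
    reads <- readSetFrom(seqs, spans = list(start = rep(0, 6),
                                            end = rep(400, 6)))
    al <- mapReads(reads, refc, mode = "truth_anchored")
    pu <- buildPileup(al, reads, 400L)
    # a 5:1 column at e = 0.1 judges homozygous, so the outlier is replaced
    calls <- callZygosity(pu, e = 0.1)
    dec <- siteDecisions(calls, calls[0, ], pu, matrix(0L, 400, 5), "merged")
    out <- correctLongReads(reads, al, dec, 400L, seed = 1)
    expect_equal(nrow(out$edits), 1)
    expect_identical(out$edits$read_id, "bad")
    expect_equal(out$edits$read_pos, 199)
    expect_identical(out$edits$old, wrong)
    expect_identical(as.character(sequences(out$reads)[["bad"]]), clean)
    expect_identical(as.character(sequences(out$reads)[["good1"]]), clean)

    # idempotence: correcting the corrected set again changes nothing
    al2 <- mapReads(out$reads, refc, mode = "truth_anchored")
    out2 <- correctLongReads(out$reads, al2, dec, 400L, seed = 1)
    expect_equal(nrow(out2$edits), 0)
    expect_identical(as.character(sequences(out2$reads)),
                     as.character(sequences(out$reads)))
})

test_that("a winning null allele deletes the base", {
    target <- strrep("ACGT", 25)
    # site 10 deleted in a majority of reads
    del <- paste0(substring(target, 1, 10), substring(target, 12, 100))
    reads <- readSetFrom(c(d1 = del, d2 = del, d3 = del, d4 = del,
                           keep = target))
    al <- data.frame(read_id = c("d1", "d2", "d3", "d4", "keep"),
                     target_id = "t",
                     target_start = 0L, strand = "+", score = 1, pct_mapped = 1,
                     cigar = c(rep("10M1D89M", 4), "100M"),
                     read_length = c(rep(99L, 4), 100L),
                     stringsAsFactors = FALSE)
    pu <- buildPileup(al, reads, 100L)
    expect_equal(unname(pu[11, "N"]), 4)
    # a 4:1 column at e = 0.15 judges homozygous with the null on top
    calls <- callZygosity(pu, e = 0.15)
    dec <- siteDecisions(calls, calls[0, ], pu, matrix(0L, 100, 5), "merged")
    expect_identical(dec$top1[dec$site == 10], "N")
    out <- correctLongReads(reads, al, dec, 100L, seed = 2)
    kept <- as.character(sequences(out$reads)[["keep"]])
    expect_equal(nchar(kept), 99)
    expect_identical(kept, del)
    expect_true(any(out$edits$new == "deleted"))
})

test_that("unmapped reads are corrected from their short-read pileups only", {
    set.seed(63)
    luSeq <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
    bad <- luSeq
    substring(bad, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                      substring(luSeq, 50, 50))[1]
    lu <- readSetFrom(c(lu1 = bad), spans = list(start = 0, end = 100))
    sSeqs <- stats::setNames(rep(substring(luSeq, 31, 70), 5),
                             paste0("s", 1:5))
    sReads <- readSetFrom(sSeqs,
                          spans = list(start = rep(30, 5), end = rep(70, 5)))
    maps <- mapShortToLu(sReads, lu, mode = "truth_anchored")
    out <- correctUnmappedReads(lu, maps, eShort = 0.01, seed = 3)
    fixed <- as.character(sequences(out$reads)[["lu1"]])
    expect_identical(substring(fixed, 50, 50), substring(luSeq, 50, 50))
    # positions without short coverage stay untouched
    expect_identical(substring(fixed, 1, 30), substring(bad, 1, 30))
    expect_equal(nrow(out$edits), 1)
    expect_equal(out$edits$read_pos, 49)

    # a read with no short coverage passes through unchanged
    lone <- readSetFrom(c(lu2 = strrep("TTGCA", 12)),
                        spans = list(start = 900, end = 960))
    maps2 <- mapShortToLu(sReads, lone, mode = "truth_anchored")
    out2 <- correctUnmappedReads(lone, maps2, eShort = 0.01, seed = 3)
    expect_identical(as.character(sequences(out2$reads)[["lu2"]]),
                     strrep("TTGCA", 12))
    expect_equal(nrow(out2$edits), 0)
})

test_that("heterozygous sites keep both alleles during correction", {
    # two haplotype groups of reads over one 60 bp target with one het site
    h1 <- strrep("ACGTAC", 10)
    h2 <- h1
    substring(h2, 30, 30) <- "T"                       # A/T het at site 29
    reads <- readSetFrom(c(a1 = h1, a2 = h1, b1 = h2, b2 = h2),
                         spans = list(start = rep(0, 4), end = rep(60, 4)))
    al <- mapReads(reads, h1, mode = "truth_anchored")
    pu <- buildPileup(al, reads, 60L)
    calls <- callZygosity(pu, e = 0.05)
    dec <- siteDecisions(calls, calls[0, ], pu, matrix(0L, 60, 5), "merged")
    expect_identical(dec$H[dec$site == 29], "heterozygous")
    out <- correctLongReads(reads, al, dec, 60L, seed = 4)
    expect_equal(nrow(out$edits), 0)                   # both alleles in top two
    expect_identical(as.character(sequences(out$reads)[["b1"]]), h2)
})

test_that("correction is deterministic given the seed and accounts its edits", {
    sc <- noiselessScenario(seed = 61)
    g <- sc$genome
    L <- simulateReads(g, 8, meanLen = 300, minLen = 150,
                       err = errorModel(0.12), seed = 62, idPrefix = "L")
    refc <- as.character(refSequence(g))
    al <- mapReads(L, refc, mode = "truth_anchored")
    pu <- buildPileup(al, L, nchar(refc))
    calls <- callZygosity(pu, e = 0.12)
    dec <- siteDecisions(calls, calls[0, ], pu,
                         matrix(0L, nchar(refc), 5), "merged")
    o1 <- correctLongReads(L, al, dec, nchar(refc), seed = 9)
    o2 <- correctLongReads(L, al, dec, nchar(refc), seed = 9)
    expect_identical(as.character(sequences(o1$reads)),
                     as.character(sequences(o2$reads)))
    expect_identical(o1$edits, o2$edits)
    # edit accounting: every non-deletion edit changes exactly one base
    subEdits <- o1$edits[o1$edits$new != "deleted", ]
    for (id in unique(subEdits$read_id)) {
        orig <- strsplit(as.character(sequences(L)[[id]]), "")[[1]]
        corr <- strsplit(as.character(sequences(o1$reads)[[id]]), "")[[1]]
        if (length(orig) == length(corr))  # no deletions in this read
            expect_equal(sum(orig != corr),
                         sum(o1$edits$read_id == id))
    }
})
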