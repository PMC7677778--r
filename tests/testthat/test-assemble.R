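makeTilingReads <- function(refc, readLen, step) {
    starts <- seq(0, nchar(refc) - readLen, by = step)
    if (max(starts) + readLen < nchar(refc))
        starts <- c(starts, nchar(refc) - readLen)
    seqs <- substring(refc, starts + 1, starts + readLen)
    names(seqs) <- sprintf("t%03d", seq_along(starts))
    readSetFrom(seqs)
}

test_that("overlap scores match the Smith-Waterman oracle", {
    set.seed(50)
    g <- makeDiploidGenome(1200, 0, seed = 50)
    refc <- as.character(refSequence(g))
    # two reads sharing an exact 300 bp suffix/prefix
    rs <- readSetFrom(c(a = substring(refc, 1, 500),
                        b = substring(refc, 201, 700)))
    ov <- computeOverlaps(rs, assemblyParams(minLength = 100, theta = 100))
    expect_equal(nrow(ov), 1)
    expect_equal(ov$length, 300)
    expect_equal(ov$score, 300)
    expect_equal(ov$score, swScoreOracle(substring(refc, 1, 500),
                                         substring(refc, 201, 700)))
    expect_equal(ov$i_start, 200); expect_equal(ov$i_end, 500)
    expect_equal(ov$j_start, 0); expect_equal(ov$j_end, 300)

    # random noisy pairs: emitted scores equal the full-DP oracle
    for (i in 1:5) {
        a <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
        b <- paste0(substring(a, 51, 150),
                    paste(sample(c("A", "C", "G", "T"), 50, TRUE),
                          collapse = ""))
        ovi <- computeOverlaps(readSetFrom(c(x = a, y = b)),
                               assemblyParams(minLength = 10, theta = 20))
        if (nrow(ovi) == 1)
            expect_equal(ovi$score, swScoreOracle(a, b))
    }
})

test_that("pairs below the thresholds produce no overlap", {
    g <- makeDiploidGenome(800, 0, seed = 51)
    refc <- as.character(refSequence(g))
    # disjoint sequences: no shared 15-mer, no overlap
    rs <- readSetFrom(c(a = substring(refc, 1, 300),
                        b = substring(refc, 401, 700)))
    expect_equal(nrow(computeOverlaps(rs, assemblyParams())), 0)
    # a 50 bp overlap is below minLength = 100
    rs2 <- readSetFrom(c(a = substring(refc, 1, 300),
                         b = substring(refc, 251, 550)))
    expect_equal(nrow(computeOverlaps(
        rs2, assemblyParams(minLength = 100, theta = 20))), 0)
    # the same overlap is accepted once minLength admits it
    expect_equal(nrow(computeOverlaps(
        rs2, assemblyParams(minLength = 40, theta = 20))), 1)
    # maxLength caps the admissible overlap length
    rs3 <- readSetFrom(c(a = substring(refc, 1, 500),
                         b = substring(refc, 201, 700)))
    expect_equal(nrow(computeOverlaps(
        rs3, assemblyParams(minLength = 100, maxLength = 200, theta = 20))), 0)
})

test_that("the k-mer prefilter never changes established overlaps", {
    g <- makeDiploidGenome(1500, 0, seed = 52)
    refc <- as.character(refSequence(g))
    rs <- makeTilingReads(refc, 400, 250)
    p1 <- assemblyParams(minLength = 100, theta = 80, prefilter = TRUE)
    p2 <- assemblyParams(minLength = 100, theta = 80, prefilter = FALSE)
    o1 <- computeOverlaps(rs, p1)
    o2 <- computeOverlaps(rs, p2)
    key <- function(o) o[order(o$read_i, o$read_j),
                         c("read_i", "read_j", "score", "length")]
    expect_equal(key(o1), key(o2), ignore_attr = TRUE)
})

test_that("layout merges tiling reads into the genome sequence", {
    g <- makeDiploidGenome(5000, 0, seed = 53)
    refc <- as.character(refSequence(g))
    rs <- makeTilingReads(refc, 1000, 500)
    ov <- computeOverlaps(rs, assemblyParams(minLength = 100, theta = 100))
    contigs <- layoutContigs(rs, ov)
    expect_equal(length(contigs), 1)
    expect_identical(contigs[[1]]$sequence, refc)
    expect_equal(nrow(contigs[[1]]$members), length(rs))
    # without overlaps every read is its own contig
    single <- layoutContigs(rs, ov[0, ])
    expect_equal(length(single), length(rs))
})

test_that("consensus takes the per-column majority", {
    base <- paste(rep("ACGTT", 40), collapse = "")      # 200 bp
    mut <- base
    substring(mut, 100, 100) <- "A"                     # one disagreeing read
    rs <- readSetFrom(c(r1 = base, r2 = base, r3 = mut))
    ov <- computeOverlaps(rs, assemblyParams(minLength = 50, theta = 50))
    contigs <- layoutContigs(rs, ov)
    expect_equal(length(contigs), 1)
    expect_identical(contigs[[1]]$sequence, base)       # 2-vs-1 majority
})

test_that("contig merging reaches a fixpoint", {
    g <- makeDiploidGenome(3000, 0, seed = 54)
    refc <- as.character(refSequence(g))
    c1 <- list(sequence = substring(refc, 1, 1400),
               members = data.frame(read_id = "a", offset = 0L))
    c2 <- list(sequence = substring(refc, 1001, 2400),
               members = data.frame(read_id = "b", offset = 0L))
    c3 <- list(sequence = substring(refc, 2001, 3000),
               members = data.frame(read_id = "c", offset = 0L))
    merged <- mergeContigs(list(c1, c2, c3),
                           assemblyParams(minLength = 100, theta = 100))
    expect_equal(length(merged), 1)
    expect_identical(merged[[1]]$sequence, refc)
    expect_equal(sort(merged[[1]]$members$read_id), c("a", "b", "c"))
    # no inter-contig overlaps: input unchanged
    d1 <- list(sequence = substring(refc, 1, 800),
               members = data.frame(read_id = "a", offset = 0L))
    d2 <- list(sequence = substring(refc, 2001, 2800),
               members = data.frame(read_id = "b", offset = 0L))
    same <- mergeContigs(list(d1, d2), assemblyParams())
    expect_equal(length(same), 2)
})

test_that("linking orders contigs by length and masks the spacers", {
    g <- makeDiploidGenome(2000, 0, seed = 55)
    refc <- as.character(refSequence(g))
    cA <- list(sequence = substring(refc, 1, 800),
               members = data.frame(read_id = "a", offset = 0L))
    cB <- list(sequence = substring(refc, 1001, 2000),
               members = data.frame(read_id = "b", offset = 0L))
    ref1 <- linkContigs(list(cA, cB))
    ref2 <- linkContigs(list(cB, cA))     # input order must not matter
    expect_equal(length(refSequence(ref1)), 1850)
    expect_identical(as.character(refSequence(ref1)),
                     as.character(refSequence(ref2)))
    # longer contig first, spacer covers [1000, 1050) (0-based)
    expect_equal(IRanges::start(spacerMask(ref1)), 1001)
    expect_equal(IRanges::width(spacerMask(ref1)), 50)
    expect_identical(substring(as.character(refSequence(ref1)), 1, 1000),
                     substring(refc, 1001, 2000))
    # single contig: no spacer
    solo <- linkContigs(list(cA))
    expect_equal(length(spacerMask(solo)), 0)
    expect_identical(as.character(refSequence(solo)), cA$sequence)
    expect_error(linkContigs(list()), "empty")
})

test_that("assembly of error-free tiling reads reconstructs the genome and is idempotent", {
    g <- makeDiploidGenome(4000, 0, seed = 56)
    refc <- as.character(refSequence(g))
    rs <- makeTilingReads(refc, 900, 450)
    asm <- assemblePseudoReference(rs, assemblyParams(minLength = 100,
                                                      theta = 100))
    expect_identical(as.character(refSequence(asm$reference)), refc)
    # assembling the assembled contigs changes nothing
    again <- mergeContigs(asm$contigs, assemblyParams(minLength = 100,
                                                      theta = 100))
    expect_identical(vapply(again, `[[`, "", "sequence"),
                     vapply(asm$contigs, `[[`, "", "sequence"))
})
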