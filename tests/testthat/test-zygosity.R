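test_that("category probabilities follow the error-model construction", {
    expect_equal(categoryProbs("homozygous", 0.2), c(0.8, 0.05, 0.05, 0.05, 0.05))
    expect_equal(categoryProbs("heterozygous", 0.15),
                 c(0.425, 0.425, 0.05, 0.05, 0.05))
    expect_equal(sum(categoryProbs("homozygous", 0.37)), 1)
    expect_equal(sum(categoryProbs("heterozygous", 0.37)), 1)
    # noiseless limit: all mass on the true alleles
    expect_equal(categoryProbs("homozygous", 1e-9)[1], 1, tolerance = 1e-8)
    expect_error(categoryProbs("homozygous", 0.6), "rank")
    expect_error(categoryProbs("heterozygous", 0.7), "rank")
})

test_that("sequential likelihood reproduces frozen hand-checked values", {
    # both values verified against the multinomial pmf:
    # 10 * 0.8^3 * 0.05^2 and 10 * 0.4^3 * 0.4^2
    expect_equal(sequentialLikelihood(c(3, 2),
                                      categoryProbs("homozygous", 0.2),
                                      log = FALSE), 0.0128, tolerance = 1e-12)
    expect_equal(sequentialLikelihood(c(3, 2),
                                      categoryProbs("heterozygous", 0.2),
                                      log = FALSE), 0.1024, tolerance = 1e-12)
    # single observed allele reduces to pi_1^n
    p <- categoryProbs("homozygous", 0.15)
    expect_equal(sequentialLikelihood(c(6), p, log = FALSE), p[1]^6)
    expect_error(sequentialLikelihood(integer(0), p), "depth 0")
})

test_that("the binomial chain equals the multinomial pmf (small exhaustive)", {
    for (e in c(0.05, 0.2)) {
        for (hyp in c("homozygous", "heterozygous")) {
            p <- categoryProbs(hyp, e)
            for (n in c(1, 4, 7)) {
                for (cnt in rankedCountVectors(n)) {
                    expect_equal(sequentialLikelihood(cnt, p, log = FALSE),
                                 multinomOracle(cnt, p), tolerance = 1e-12)
                }
            }
        }
    }
})

test_that("priors evaluate to complementary probabilities", {
    expect_equal(priorValue(pointPrior(0.5), "homozygous"), 0.5)
    expect_equal(priorValue(pointPrior(0.5), "heterozygous"), 0.5)
    expect_equal(priorValue(pointPrior(0.3), "heterozygous"), 0.7)
    expect_equal(priorValue(betaPrior(300, 300), "homozygous"), 0.5)
    expect_equal(priorValue(betaPrior(10, 30), "homozygous"), 0.25)
    s1 <- priorValue(betaPrior(5, 5, mode = "sample", seed = 42), "homozygous")
    s2 <- priorValue(betaPrior(5, 5, mode = "sample", seed = 42), "homozygous")
    expect_identical(s1, s2)
    expect_gt(s1, 0); expect_lt(s1, 1)
    dH <- priorValue(betaPrior(8, 2, mode = "density_at_guess", guess = 0.7),
                     "homozygous")
    dA <- priorValue(betaPrior(8, 2, mode = "density_at_guess", guess = 0.7),
                     "heterozygous")
    expect_equal(dH + dA, 1)
    expect_error(priorValue(pointPrior(1.2), "homozygous"))
})

test_that("site classification matches the brute-force multinomial oracle", {
    # d = 1: judged homozygous directly
    z <- classifySite(rankAlleles(c(A = 7)), e = 0.2)
    expect_identical(z@hypothesis, "homozygous")
    expect_identical(z@topAlleles, "A")

    # frozen example: posteriors 0.1024 * 0.5 vs 0.0128 * 0.5
    z <- classifySite(rankAlleles(c(A = 3, C = 2)), e = 0.2)
    expect_identical(z@hypothesis, "heterozygous")
    expect_equal(exp(z@posteriorHet), 0.0512, tolerance = 1e-10)
    expect_equal(exp(z@posteriorHomo), 0.0064, tolerance = 1e-10)
    expect_identical(z@topAlleles, c("A", "C"))

    z <- classifySite(rankAlleles(c(A = 9, C = 1)), e = 0.15)
    expect_identical(z@hypothesis, "homozygous")

    # randomized agreement with the independent oracle
    set.seed(99)
    for (i in 1:60) {
        e <- runif(1, 0.03, 0.3)
        counts <- rmultinom(1, sample(2:15, 1), runif(5, 0.01, 1))[, 1]
        if (sum(counts) == 0) next
        names(counts) <- c("A", "C", "G", "T", "N")
        got <- classifySite(rankAlleles(counts), e = e)@hypothesis
        expect_identical(got, bruteClassify(counts, e))
    }
})

test_that("bulk calls agree with per-column classification", {
    set.seed(17)
    pu <- t(rmultinom(40, 9, c(0.45, 0.4, 0.05, 0.05, 0.05)))
    colnames(pu) <- c("A", "C", "G", "T", "N")
    pu[5, ] <- 0L   # an uncovered site must be dropped
    calls <- callZygosity(pu, e = 0.15)
    expect_false(4L %in% calls$site)
    expect_equal(nrow(calls), 39)
    for (i in seq_len(nrow(calls))) {
        z <- classifySite(rankAlleles(pu[calls$site[i] + 1L, ]), e = 0.15)
        expect_identical(calls$call[i], z@hypothesis)
        expect_equal(calls$logPostHomo[i], z@posteriorHomo)
        expect_equal(calls$logPostHet[i], z@posteriorHet)
    }
})

test_that("posterior ratio is monotone as counts move toward balance", {
    for (e in c(0.05, 0.15)) {
        pH <- categoryProbs("homozygous", e)
        pA <- categoryProbs("heterozygous", e)
        for (n in c(6, 11)) {
            ratio <- sapply(0:(n %/% 2), function(k) {
                cnt <- sort(c(n - k, k), decreasing = TRUE)
                cnt <- cnt[cnt > 0]
                sequentialLikelihood(cnt, pA) - sequentialLikelihood(cnt, pH)
            })
            expect_true(all(diff(ratio) > -1e-12))
        }
    }
})

test_that("decisions are monotone in the homozygosity prior", {
    rc <- rankAlleles(c(A = 4, C = 2))
    hyps <- sapply(c(0.05, 0.25, 0.5, 0.75, 0.95, 1 - 1e-12), function(p)
        classifySite(rc, e = 0.15, prior = pointPrior(p))@hypothesis)
    # once homozygous, homozygous for all larger priors
    firstHomo <- match("homozygous", hyps)
    expect_false(is.na(firstHomo))
    expect_true(all(hyps[firstHomo:length(hyps)] == "homozygous"))
    # an overwhelming prior forces homozygosity even on balanced columns
    expect_identical(classifySite(rankAlleles(c(A = 5, C = 5)), e = 0.15,
                                  prior = pointPrior(1 - 1e-12))@hypothesis,
                     "homozygous")
})

test_that("judgment combination prefers short reads, homozygosity on conflict", {
    expect_identical(combineCalls("heterozygous", "heterozygous"), "heterozygous")
    expect_identical(combineCalls("homozygous", "homozygous"), "homozygous")
    expect_identical(combineCalls("heterozygous", "homozygous"), "homozygous")
    expect_identical(combineCalls("homozygous", "heterozygous"), "homozygous")
    expect_identical(combineCalls(NULL, "heterozygous"), "heterozygous")
    expect_identical(combineCalls("heterozygous", NULL), "heterozygous")
    expect_error(combineCalls(NULL, NULL), "at least one")
    # ZygosityCall objects are accepted directly
    zh <- classifySite(rankAlleles(c(A = 5, C = 5)), e = 0.05)
    expect_identical(combineCalls(zh, "homozygous"), "homozygous")
    # vectorised form with absent judgments
    expect_identical(
        combineHypotheses(c("heterozygous", NA, "homozygous"),
                          c("heterozygous", "heterozygous", NA)),
        c("heterozygous", "heterozygous", "homozygous"))
})

test_that("classifier recovers zygosity on simulated columns (e = 0.05)", {
    set.seed(11)
    n <- 800; depth <- 12; e <- 0.05
    hetCols <- t(rmultinom(n, depth, categoryProbs("heterozygous", e)))
    homCols <- t(rmultinom(n, depth, categoryProbs("homozygous", e)))
    colnames(hetCols) <- colnames(homCols) <- c("A", "C", "G", "T", "N")
    sens <- mean(callZygosity(hetCols, e)$call == "heterozygous")
    spec <- mean(callZygosity(homCols, e)$call == "homozygous")
    expect_gt(sens, 0.9)
    expect_gt(spec, 0.9)
})
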