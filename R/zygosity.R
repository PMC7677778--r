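#' Per-allele category probabilities under each zygosity hypothesis
#'
#' The probability that a single read base at a site falls in each frequency
#' rank, given the hypothesis and the per-base error rate `e`. Under
#' homozygosity the single true allele receives `1 - e` and each of the four
#' error categories `e/4`; under heterozygosity the two true alleles receive
#' `(1 - e)/2` each and the three error categories `e/3` each. These
#' category probabilities, chained rank by rank, define the sequential
#' binomial likelihood of a ranked pileup column (see
#' [sequentialLikelihood()]).
#'
#' @param hypothesis `"homozygous"` or `"heterozygous"`.
#' @param e Per-base error rate, strictly between 0 and 0.6. At `e >= 0.6` a
#'   heterozygous allele (probability `(1-e)/2`) would be no more likely
#'   than an error allele (probability `e/3`) and the rank order on which
#'   the model is built inverts.
#' @return Numeric vector of 5 rank probabilities summing to 1.
#' @examples
#' categoryProbs("homozygous", 0.2)    # 0.80 0.05 0.05 0.05 0.05
#' categoryProbs("heterozygous", 0.15) # 0.425 0.425 0.05 0.05 0.05
#' @export
categoryProbs <- function(hypothesis = c("homozygous", "heterozygous"), e) {
    hypothesis <- match.arg(hypothesis)
    stopIfNot(isSingleNumber(e) && e > 0 && e < 0.6,
        "error rate must lie in (0, 0.6): at e >= 0.6 the heterozygous allele probability (1-e)/2 drops to the error probability e/3 and ranks invert")
    if (hypothesis == "homozygous") c(1 - e, rep(e / 4, 4))
    else c(rep((1 - e) / 2, 2), rep(e / 3, 3))
}

# vectorised sequential-binomial log likelihood over a matrix of ranked
# counts (rows = columns of a pileup, sorted descending); p is the 5-vector
# of category probabilities
chainLogLik <- function(sorted, p) {
    n <- nrow(sorted)
    ll <- numeric(n)
    D <- sorted[, 5L]
    Dmat <- matrix(0L, n, 5L)
    Dmat[, 5L] <- D
    for (q in 4:1) {
        D <- D + sorted[, q]
        Dmat[, q] <- D
    }
    psuf <- rev(cumsum(rev(p)))
    for (q in 1:5) {
        piq <- p[q] / psuf[q]
        X <- sorted[, q]
        Dq <- Dmat[, q]
        act <- Dq > 0L
        if (!any(act)) next
        if (piq >= 1 - 1e-12) {
            term <- ifelse(X == Dq, 0, -Inf)
        } else {
            term <- lchoose(Dq, X) + X * log(piq) + (Dq - X) * log1p(-piq)
        }
        ll[act] <- ll[act] + term[act]
    }
    ll
}

#' Sequential binomial likelihood of a ranked pileup column
#'
#' The likelihood of observing the ranked allele counts
#' \eqn{|X_1| \ge |X_2| \ge \dots} given a zygosity hypothesis: each rank
#' follows a binomial distribution whose size is the number of reads not yet
#' accounted for by earlier ranks, \eqn{D_q = \sum_{j \ge q} |X_j|}, and
#' whose success probability is the rank's category probability renormalised
#' over the remaining ranks, \eqn{\pi_q = p_q / \sum_{j \ge q} p_j}. Each
#' term is computed on the basis of the former terms; ranks with zero count
#' contribute nothing (their remaining size is zero). The product of the
#' chain is identical to the multinomial probability of the count vector
#' under the category probabilities, which serves as an independent oracle in
#' the test suite.
#'
#' @param rc A [RankedCounts-class] (see [rankAlleles()]) or an integer
#'   vector of counts sorted in decreasing order.
#' @param probs Category probabilities from [categoryProbs()].
#' @param log If `TRUE` (default) return the log likelihood.
#' @return A single numeric likelihood (or log likelihood).
#' @examples
#' sequentialLikelihood(c(3, 2), categoryProbs("homozygous", 0.2),
#'                      log = FALSE)  # 0.0128
#' @export
sequentialLikelihood <- function(rc, probs, log = TRUE) {
    counts <- if (is(rc, "RankedCounts")) rc@counts else as.integer(rc)
    stopIfNot(length(counts) >= 1L && sum(counts) >= 1L,
              "likelihood undefined for an empty column (depth 0)")
    stopIfNot(!is.unsorted(rev(counts)), "counts must be sorted decreasing")
    stopIfNot(length(counts) <= 5L, "at most 5 allele categories")
    padded <- matrix(c(counts, rep(0L, 5L - length(counts))), 1L, 5L)
    ll <- chainLogLik(padded, probs)
    if (log) ll else exp(ll)
}

#' Point and Beta priors for the zygosity classifier
#'
#' `pointPrior()` fixes the prior probability of homozygosity to a constant.
#' `betaPrior()` places a Beta(a, b) distribution on that probability and
#' reduces it to a usable prior in one of three modes: `"mean"` (the Beta
#' expected value `a/(a+b)`; default), `"sample"` (one reproducible draw
#' from the Beta), or `"density_at_guess"` (the Beta density evaluated at a
#' guess, renormalised against the density at the complementary guess so the
#' two hypothesis priors sum to one).
#'
#' @param pHomo Prior probability of homozygosity, in (0,1).
#' @param a,b Beta shape parameters, positive.
#' @param mode One of `"mean"`, `"density_at_guess"`, `"sample"`.
#' @param guess Guess at the homozygosity probability for
#'   `"density_at_guess"`.
#' @param seed Integer seed for the `"sample"` mode.
#' @return A [PriorSpec-class].
#' @examples
#' pointPrior(0.5)
#' betaPrior(300, 300)          # mean 0.5
#' @export
pointPrior <- function(pHomo = 0.5) {
    new("PriorSpec", kind = "point", pHomo = pHomo, a = NA_real_, b = NA_real_,
        thetaGuess = 0.5, betaMode = "mean", seed = NA_integer_)
}

#' @rdname pointPrior
#' @export
betaPrior <- function(a, b, mode = c("mean", "density_at_guess", "sample"),
                      guess = 0.5, seed = 1L) {
    mode <- match.arg(mode)
    new("PriorSpec", kind = "beta", pHomo = NA_real_, a = a, b = b,
        thetaGuess = guess, betaMode = mode, seed = as.integer(seed))
}

#' Evaluate a prior specification for one hypothesis
#'
#' @param prior A [PriorSpec-class].
#' @param hypothesis `"homozygous"` or `"heterozygous"`.
#' @return The prior probability of the hypothesis; the two hypotheses
#'   always sum to one.
#' @examples
#' priorValue(pointPrior(0.5), "heterozygous")
#' priorValue(betaPrior(300, 300), "homozygous")
#' @export
priorValue <- function(prior, hypothesis = c("homozygous", "heterozygous")) {
    hypothesis <- match.arg(hypothesis)
    validObject(prior)
    pHomo <- if (prior@kind == "point") {
        prior@pHomo
    } else if (prior@betaMode == "mean") {
        prior@a / (prior@a + prior@b)
    } else if (prior@betaMode == "sample") {
        withSeed(prior@seed, stats::rbeta(1L, prior@a, prior@b))
    } else {
        dH <- stats::dbeta(prior@thetaGuess, prior@a, prior@b)
        dA <- stats::dbeta(1 - prior@thetaGuess, prior@a, prior@b)
        stopIfNot(dH + dA > 0, "Beta density vanishes at both guesses")
        dH / (dH + dA)
    }
    if (hypothesis == "homozygous") pHomo else 1 - pHomo
}

#' Classify one pileup column as homozygous or heterozygous
#'
#' Computes the unnormalised posterior score (sequential-binomial likelihood
#' times prior) of both hypotheses and takes the larger. A column showing a
#' single allele (`d = 1`) is judged homozygous directly; ties are broken
#' toward homozygosity (the conservative choice: heterozygosity is never
#' fabricated from even evidence). A heterozygous call reports the top two
#' ranked alleles, a homozygous call the top one.
#'
#' @param rc A [RankedCounts-class] or an integer count vector sorted
#'   decreasing.
#' @param e Per-base error rate of the read source the column came from.
#' @param prior A [PriorSpec-class]. Default point 0.5/0.5.
#' @param site Optional 0-based anchor index stored in the call.
#' @return A [ZygosityCall-class].
#' @examples
#' classifySite(rankAlleles(c(A = 3, C = 2, G = 0, T = 0, N = 0)), e = 0.2)
#' @export
classifySite <- function(rc, e, prior = pointPrior(0.5), site = NA_integer_) {
    if (!is(rc, "RankedCounts")) {
        cv <- as.integer(rc)
        names(cv) <- names(rc)
        rc <- rankAlleles(cv)
    }
    stopIfNot(rc@depth >= 1L, "cannot classify an empty column (depth 0)")
    lpH <- sequentialLikelihood(rc, categoryProbs("homozygous", e)) +
        log(priorValue(prior, "homozygous"))
    lpA <- sequentialLikelihood(rc, categoryProbs("heterozygous", e)) +
        log(priorValue(prior, "heterozygous"))
    hyp <- if (rc@d == 1L) "homozygous"
           else if (lpA > lpH) "heterozygous" else "homozygous"
    top <- if (hyp == "heterozygous") rc@alleles[1:2] else rc@alleles[1L]
    new("ZygosityCall", hypothesis = hyp, posteriorHomo = lpH,
        posteriorHet = lpA, topAlleles = top, site = as.integer(site))
}

#' Classify every covered column of a pileup
#'
#' Vectorised version of [classifySite()] over a full pileup matrix. Columns
#' with zero depth are dropped (no call is possible there).
#'
#' @param pileup Integer matrix of allele counts, one row per target
#'   position (row `i` is 0-based site `i - 1`), columns `A,C,G,T,N`; see
#'   [buildPileup()].
#' @param e Per-base error rate of the read source.
#' @param prior A [PriorSpec-class].
#' @return A `data.frame` with one row per covered site: `site` (0-based),
#'   `depth`, `d`, `logPostHomo`, `logPostHet`, `call`, `top1`, `top2`
#'   (`NA` when fewer than two alleles were observed).
#' @export
callZygosity <- function(pileup, e, prior = pointPrior(0.5)) {
    stopIfNot(is.matrix(pileup) && ncol(pileup) == 5L,
              "pileup must be a matrix with columns A,C,G,T,N")
    depth <- as.integer(rowSums(pileup))
    covered <- which(depth > 0L)
    if (length(covered) == 0L)
        return(data.frame(site = integer(), depth = integer(), d = integer(),
                          logPostHomo = numeric(), logPostHet = numeric(),
                          call = character(), top1 = character(),
                          top2 = character(), stringsAsFactors = FALSE))
    ranked <- cpp_rank_counts(pileup[covered, , drop = FALSE])
    sorted <- ranked$sorted
    d <- as.integer(rowSums(sorted > 0L))
    llH <- chainLogLik(sorted, categoryProbs("homozygous", e))
    llA <- chainLogLik(sorted, categoryProbs("heterozygous", e))
    lpH <- llH + log(priorValue(prior, "homozygous"))
    lpA <- llA + log(priorValue(prior, "heterozygous"))
    call <- ifelse(d == 1L, "homozygous",
                   ifelse(lpA > lpH, "heterozygous", "homozygous"))
    data.frame(site = covered - 1L, depth = depth[covered], d = d,
               logPostHomo = lpH, logPostHet = lpA, call = call,
               top1 = ALLELES[ranked$order[, 1L]],
               top2 = ifelse(d >= 2L, ALLELES[ranked$order[, 2L]],
                             NA_character_),
               stringsAsFactors = FALSE)
}

#' Combine the long-read and short-read zygosity judgments
#'
#' When both judgments exist and agree, the short-read judgment is adopted
#' (short-read sequencing is far more accurate); when they disagree, the
#' homozygous judgment wins. When only one judgment exists (for example on
#' unmapped long reads, where only short-read evidence is available), that
#' judgment stands.
#'
#' @param callLong,callShort A [ZygosityCall-class], a hypothesis string, or
#'   `NULL`/`NA` when the source has no coverage at the site.
#' @return `"homozygous"` or `"heterozygous"`.
#' @examples
#' combineCalls("heterozygous", "heterozygous")  # heterozygous
#' combineCalls("heterozygous", "homozygous")    # homozygous
#' @export
combineCalls <- function(callLong, callShort) {
    hyp <- function(x) {
        if (is.null(x)) return(NA_character_)
        if (is(x, "ZygosityCall")) return(x@hypothesis)
        as.character(x)
    }
    out <- combineHypotheses(hyp(callLong), hyp(callShort))
    stopIfNot(!is.na(out), "at least one judgment must be present")
    out
}

#' @rdname combineCalls
#' @param hLong,hShort Character vectors of hypotheses (with `NA` for absent
#'   judgments) for the vectorised variant used across all anchor sites.
#' @export
combineHypotheses <- function(hLong, hShort) {
    n <- max(length(hLong), length(hShort))
    hLong <- rep_len(hLong, n)
    hShort <- rep_len(hShort, n)
    ifelse(is.na(hLong), hShort,
        ifelse(is.na(hShort), hLong,
            ifelse(hLong == hShort, hShort, "homozygous")))
}
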