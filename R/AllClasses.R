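#' @import methods
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom IRanges IRanges
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement writeXStringSet readDNAStringSet
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors isSingleNumber
#' @importFrom Rcpp sourceCpp
#' @useDynLib HetCorr, .registration = TRUE
NULL

BASES <- c("A", "C", "G", "T")
ALLELES <- c("A", "C", "G", "T", "N")

#' DiploidGenome: a two-haplotype genome with planted heterozygous SNPs
#'
#' Holds the two haplotype sequences of a simulated diploid individual, the
#' reference backbone (identical to haplotype 1), and the table of planted
#' heterozygous sites. The two haplotypes differ exactly at the planted
#' sites, each carrying one of two distinct alleles.
#'
#' @slot hap1 A [Biostrings::DNAString] with the first haplotype (the
#'   reference backbone).
#' @slot hap2 A [Biostrings::DNAString] with the second haplotype.
#' @slot ref A [Biostrings::DNAString], identical to `hap1`, playing the role
#'   of the truth reference that corrected reads are evaluated against.
#' @slot hetSites A `data.frame` with columns `position` (0-based),
#'   `allele_a` (the `hap1` base) and `allele_b` (the `hap2` base).
#'
#' @seealso [makeDiploidGenome()]
#' @export
setClass("DiploidGenome",
    representation(hap1 = "DNAString", hap2 = "DNAString", ref = "DNAString",
                   hetSites = "data.frame"))

setValidity("DiploidGenome", function(object) {
    h1 <- as.character(object@hap1)
    h2 <- as.character(object@hap2)
    if (nchar(h1) != nchar(h2) || nchar(h1) != length(object@ref))
        return("hap1, hap2 and ref must have equal length")
    hs <- object@hetSites
    need <- c("position", "allele_a", "allele_b")
    if (!all(need %in% names(hs)))
        return("hetSites needs columns position, allele_a, allele_b")
    if (anyDuplicated(hs$position))
        return("het site positions must be unique")
    if (any(hs$position < 0L | hs$position >= nchar(h1)))
        return("het site positions out of range")
    if (any(hs$allele_a == hs$allele_b))
        return("het site alleles must be distinct")
    diff <- which(charToRaw(h1) != charToRaw(h2)) - 1L
    if (!setequal(diff, hs$position))
        return("hap1 and hap2 must differ exactly at the het sites")
    TRUE
})

#' ReadSet: a named collection of sequencing reads
#'
#' A light container for a set of reads, optionally carrying the ground-truth
#' placement of each read on the genome it was simulated from. The truth span
#' records, per read, the 0-based half-open reference interval the read was
#' drawn from, the strand, and the haplotype of origin.
#'
#' @slot sequences A [Biostrings::DNAStringSet]; names are read identifiers.
#' @slot truthSpans A `data.frame` with zero rows (no truth available) or one
#'   row per read: `read_id`, `start`, `end` (0-based half-open), `strand`
#'   (`"+"`/`"-"`), `hap` (1 or 2).
#'
#' @seealso [simulateReads()]
#' @export
setClass("ReadSet",
    representation(sequences = "DNAStringSet", truthSpans = "data.frame"))

setValidity("ReadSet", function(object) {
    ts <- object@truthSpans
    if (nrow(ts) > 0L) {
        need <- c("read_id", "start", "end", "strand", "hap")
        if (!all(need %in% names(ts)))
            return("truthSpans needs columns read_id, start, end, strand, hap")
        if (nrow(ts) != length(object@sequences))
            return("truthSpans must have one row per read")
        if (!identical(as.character(ts$read_id), names(object@sequences)))
            return("truthSpans rows must follow read order")
    }
    TRUE
})

#' PseudoReference: a draft reference assembled from long reads
#'
#' The linked sequence of assembled contigs, used purely as a shared
#' coordinate system ("anchor points") for joint long-read and short-read
#' pileups, not as biological truth. Contigs are separated by runs of `N`
#' spacer bases; spacer positions are masked from anchoring.
#'
#' @slot sequence A [Biostrings::DNAString] with the linked contigs.
#' @slot contigSpans An [IRanges::IRanges] of the contig intervals (1-based,
#'   as usual for IRanges).
#' @slot spacerMask An [IRanges::IRanges] of the spacer intervals excluded
#'   from anchoring.
#'
#' @seealso [assemblePseudoReference()], [linkContigs()]
#' @export
setClass("PseudoReference",
    representation(sequence = "DNAString", contigSpans = "IRanges",
                   spacerMask = "IRanges"))

#' PriorSpec: prior probability specification for the zygosity classifier
#'
#' Either a point prior on homozygosity, or a Beta distribution over the
#' homozygosity probability ("a probability distribution of probabilities"),
#' reduced to a usable prior in one of three modes: the Beta mean, the Beta
#' density evaluated at a guess (renormalised against the complementary
#' hypothesis), or a reproducible random draw.
#'
#' @slot kind `"point"` or `"beta"`.
#' @slot pHomo Point prior probability of homozygosity (kind `"point"`).
#' @slot a,b Beta shape parameters (kind `"beta"`).
#' @slot thetaGuess Guess at the homozygosity probability used by the
#'   `density_at_guess` mode.
#' @slot betaMode `"mean"`, `"density_at_guess"` or `"sample"`.
#' @slot seed Integer seed used by the `"sample"` mode.
#'
#' @seealso [pointPrior()], [betaPrior()], [priorValue()]
#' @export
setClass("PriorSpec",
    representation(kind = "character", pHomo = "numeric", a = "numeric",
                   b = "numeric", thetaGuess = "numeric", betaMode = "character",
                   seed = "integer"))

setValidity("PriorSpec", function(object) {
    if (!object@kind %in% c("point", "beta")) return("kind must be point or beta")
    if (object@kind == "point") {
        if (object@pHomo <= 0 || object@pHomo >= 1)
            return("point prior must lie in (0,1)")
    } else {
        if (object@a <= 0 || object@b <= 0) return("Beta shapes must be positive")
        if (!object@betaMode %in% c("mean", "density_at_guess", "sample"))
            return("betaMode must be mean, density_at_guess or sample")
        if (object@thetaGuess <= 0 || object@thetaGuess >= 1)
            return("thetaGuess must lie in (0,1)")
    }
    TRUE
})

#' RankedCounts: allele counts of one pileup column, ranked by frequency
#'
#' Alleles sorted by observed count, descending, with ties broken by the
#' fixed allele order A < C < G < T < N; zero-count alleles are dropped. `d`
#' is the number of distinct observed alleles (the "bases distribution").
#'
#' @slot alleles Character vector of observed alleles, most frequent first.
#' @slot counts Integer counts parallel to `alleles`, non-increasing.
#' @slot d Integer, number of alleles with nonzero count.
#' @slot depth Integer, total count.
#'
#' @seealso [rankAlleles()]
#' @export
setClass("RankedCounts",
    representation(alleles = "character", counts = "integer", d = "integer",
                   depth = "integer"))

setValidity("RankedCounts", function(object) {
    if (length(object@alleles) != length(object@counts))
        return("alleles and counts must be parallel")
    if (is.unsorted(rev(object@counts)))
        return("counts must be non-increasing")
    if (object@d != sum(object@counts > 0L)) return("d must count nonzero alleles")
    if (object@depth != sum(object@counts)) return("depth must equal sum of counts")
    TRUE
})

#' ZygosityCall: the classifier decision for one pileup column
#'
#' The chosen hypothesis with both unnormalised log posterior scores and the
#' top-ranked allele(s): one allele for a homozygous call, the top two for a
#' heterozygous call.
#'
#' @slot hypothesis `"homozygous"` or `"heterozygous"`.
#' @slot posteriorHomo,posteriorHet Unnormalised log posterior scores.
#' @slot topAlleles Character vector of length 1 (homozygous) or 2
#'   (heterozygous).
#' @slot site 0-based anchor index, or `NA` when the column is free-standing.
#'
#' @seealso [classifySite()]
#' @export
setClass("ZygosityCall",
    representation(hypothesis = "character", posteriorHomo = "numeric",
                   posteriorHet = "numeric", topAlleles = "character",
                   site = "integer"))

setValidity("ZygosityCall", function(object) {
    if (!object@hypothesis %in% c("homozygous", "heterozygous"))
        return("hypothesis must be homozygous or heterozygous")
    n <- length(object@topAlleles)
    if (object@hypothesis == "homozygous" && n != 1L)
        return("homozygous calls carry one top allele")
    if (object@hypothesis == "heterozygous" && n != 2L)
        return("heterozygous calls carry two top alleles")
    TRUE
})
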