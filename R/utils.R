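# internal helpers shared across modules

# run expr under a temporary RNG state seeded with `seed`; the caller's RNG
# stream is left untouched
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(seed)
    }
    expr
}

emptyTruthSpans <- function() {
    data.frame(read_id = character(), start = integer(), end = integer(),
               strand = character(), hap = integer(),
               stringsAsFactors = FALSE)
}

# split a CIGAR over {M,I,D,S} into parallel op/length vectors
cigarToOps <- function(cigar) {
    lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
    ops <- regmatches(cigar, gregexpr("[A-Z]", cigar))[[1L]]
    data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

# number of read bases aligned to the target (M columns) in a CIGAR
cigarAlignedBases <- function(cigar) {
    ops <- cigarToOps(cigar)
    sum(ops$len[ops$op == "M"])
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
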