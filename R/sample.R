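#' Sample an annotation from a context-aware Markov chain
#'
#' Generates one realization of the null model: on each chromosome the state
#' at position -1 is drawn from the stationary distribution of the chain of
#' the class at position 0, and each subsequent position transitions under
#' the matrix of its own class.  The binary state sequence over positions
#' 0..L-1 is returned as an [Annotation-class].  Sampling is run-length
#' based (alternating geometric sojourn times), so the cost is proportional
#' to the number of state switches plus class boundaries, not to L.
#'
#' @param chain a [ContextChain-class]; must have a matrix for every label
#'   used by \code{context}.
#' @param context a [GenomeContext-class].
#' @param seed optional integer; when given, the caller's RNG state is left
#'   untouched and the draw is a deterministic function of the seed.
#' @return an [Annotation-class] on \code{seqlengths(context)}.
#' @examples
#' ctx <- uniformContext(c(chr1 = 1000))
#' ch <- new("ContextChain",
#'           matrices = list(background = rbind(c(0.99, 0.01), c(0.2, 0.8))),
#'           counts = list(), pseudocount = NA_real_)
#' sampleAnnotation(ch, ctx, seed = 7)
#' @export
sampleAnnotation <- function(chain, context, seed = NULL) {
    stopifnot(is(chain, "ContextChain"), is(context, "GenomeContext"))
    for (lab in contextLabels(context)) .chainMatrix(chain, lab)
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
    }
    ranges <- lapply(setNames(nm = names(context@seqlengths)), function(chrom)
        .sampleChrom(chain, context@runs[[chrom]],
                     context@seqlengths[[chrom]]))
    Annotation(ranges, context@seqlengths)
}

.sampleChrom <- function(chain, runs, L) {
    ## grow-by-doubling interval collectors
    cap <- 64L; n <- 0L
    bs <- numeric(cap); es <- numeric(cap)
    push <- function(b, e) {
        if (n == cap) { cap <<- cap * 2L; length(bs) <<- cap; length(es) <<- cap }
        n <<- n + 1L; bs[n] <<- b; es[n] <<- e
    }
    pi0 <- stationaryDistribution(.chainMatrix(chain, runs$label[1L]))
    state <- if (runif(1) < pi0[2L]) 1L else 0L
    pos <- 0                    # next position to assign
    open <- NA_real_            # begin of the currently open covered interval
    runEnd <- c(runs$start[-1L], L)
    for (r in seq_along(runs$start)) {
        Tm <- .chainMatrix(chain, runs$label[r])
        m <- runEnd[r] - runs$start[r]
        while (m > 0) {
            pSwitch <- Tm[state + 1L, 2L - state]
            g <- if (pSwitch <= 0) Inf else
                 if (pSwitch >= 1) 0 else rgeom(1L, pSwitch)
            if (g >= m) {       # state persists to the end of this class run
                if (state == 1L && is.na(open)) open <- pos
                pos <- pos + m
                m <- 0
            } else {
                if (state == 1L) {
                    if (is.na(open)) open <- pos
                    pos <- pos + g
                    if (pos > open) push(open, pos)
                    open <- NA_real_
                } else {
                    pos <- pos + g
                }
                state <- 1L - state
                if (state == 1L) open <- pos
                pos <- pos + 1
                m <- m - g - 1
            }
        }
    }
    if (!is.na(open) && pos > open) push(open, pos)
    cbind(begin = bs[seq_len(n)], end = es[seq_len(n)])
}
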