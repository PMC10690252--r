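#' Simulate an annotation with fixed-length intervals
#'
#' Places exactly \code{nIntervals} non-overlapping intervals of length
#' \code{intervalLength} on a single chromosome, each pair separated by at
#' least one base.  With \code{gapLayout = "uniform"} the configuration is
#' drawn uniformly at random among all valid placements (sorted uniform
#' draws over the free space); \code{"fixed"} spaces the intervals evenly.
#' Deterministic given the seed.
#'
#' This mirrors the synthetic benchmark design used throughout the package's
#' validation: a large chromosome, a dense query of fixed-length intervals,
#' and references of varying interval counts.
#'
#' @param L chromosome length (bp).
#' @param nIntervals number of intervals.
#' @param intervalLength length of every interval (bp).
#' @param gapLayout \code{"uniform"} or \code{"fixed"}.
#' @param seed integer seed (required for \code{"uniform"}).
#' @param chrom chromosome name.
#' @return an [Annotation-class] with one chromosome.
#' @examples
#' synthAnnotation(1e5, 50, 100, seed = 1)
#' @export
synthAnnotation <- function(L, nIntervals, intervalLength,
                            gapLayout = c("uniform", "fixed"), seed = NULL,
                            chrom = "chr1") {
    gapLayout <- match.arg(gapLayout)
    stopifnot(L >= 1, nIntervals >= 0, intervalLength >= 1)
    if (nIntervals * (intervalLength + 1) > L)
        stop("cannot pack ", nIntervals, " intervals of length ",
             intervalLength, " (plus >= 1 base separation) into L = ", L)
    if (nIntervals == 0)
        return(Annotation(list(), setNames(L, chrom)))
    if (gapLayout == "fixed") {
        slot <- L / nIntervals
        begin <- floor((seq_len(nIntervals) - 1) * slot)
    } else {
        if (is.null(seed)) stop("a seed is required for gapLayout = 'uniform'")
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
        ## free space after reserving n*(len+1) - 1 mandatory bases
        free <- L - nIntervals * (intervalLength + 1) + 1
        u <- sort(floor(runif(nIntervals, 0, free)))
        begin <- u + (seq_len(nIntervals) - 1) * (intervalLength + 1)
    }
    Annotation(list(cbind(begin = begin, end = begin + intervalLength)) |>
                   setNames(chrom),
               setNames(L, chrom))
}
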