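#' Number of intervals in an annotation
#'
#' @param x an [Annotation-class].
#' @param perChromosome return a named per-chromosome vector instead of the
#'   genome total.
#' @param ... ignored.
#' @return numeric count(s).
#' @examples
#' a <- Annotation(list(chr1 = cbind(c(0, 10), c(5, 20))), c(chr1 = 30))
#' intervalCount(a)
#' coveredBases(a)
#' @export
setMethod("intervalCount", "Annotation", function(x, perChromosome = FALSE, ...) {
    n <- vapply(x@ranges, nrow, 1L)
    if (perChromosome) n else sum(n)
})

#' Total bases covered by an annotation
#'
#' @inheritParams intervalCount
#' @return numeric count(s) of covered positions.
#' @export
setMethod("coveredBases", "Annotation", function(x, perChromosome = FALSE, ...) {
    b <- vapply(x@ranges, function(iv) sum(iv[, 2L] - iv[, 1L]), 0)
    if (perChromosome) b else sum(b)
})

#' Number of class boundaries in a genome context
#'
#' A class boundary is a position whose label differs from the label of the
#' previous position; chromosome starts are not boundaries.
#'
#' @param x a [GenomeContext-class].
#' @param perChromosome per-chromosome vector instead of the genome total.
#' @param ... ignored.
#' @return numeric boundary count(s).
#' @export
setMethod("boundaryCount", "GenomeContext", function(x, perChromosome = FALSE, ...) {
    b <- vapply(x@runs, function(r) length(r$start) - 1L, 1L)
    if (perChromosome) b else sum(b)
})

#' Label set of a genome context
#'
#' @param x a [GenomeContext-class].
#' @return sorted character vector of distinct class labels.
#' @export
setMethod("contextLabels", "GenomeContext", function(x) {
    sort(unique(unlist(lapply(x@runs, `[[`, "label"), use.names = FALSE)))
})

#' Transition matrices and training counts of a chain
#'
#' @param x a [ContextChain-class].
#' @return \code{transitionMatrices}: named list of 2x2 row-stochastic
#'   matrices; \code{trainingCounts}: named list of 2x2 count matrices
#'   (empty for chains not obtained by training).
#' @export
setMethod("transitionMatrices", "ContextChain", function(x) x@matrices)

#' @rdname transitionMatrices
#' @export
setMethod("trainingCounts", "ContextChain", function(x) x@counts)

#' Mean and variance of an exact null PMF
#'
#' @param x a [NullPmf-class].
#' @return numeric scalar.
#' @export
setMethod("pmfMean", "NullPmf", function(x) sum(x@support * x@prob))

#' @rdname pmfMean
#' @export
setMethod("pmfVariance", "NullPmf", function(x) {
    m <- sum(x@support * x@prob)
    sum((x@support - m)^2 * x@prob)
})

#' @importFrom GenomeInfoDb seqlengths
#' @export
setMethod("seqlengths", "Annotation", function(x) x@seqlengths)

#' @export
setMethod("seqlengths", "GenomeContext", function(x) x@seqlengths)

#' Flatten a test result to a one-row-per-chromosome table
#'
#' Returns the standard result table: one row per chromosome plus a
#' \code{"genome"} row, with columns \code{chrom}, \code{statistic},
#' \code{observed}, \code{null_mean}, \code{null_var}, \code{z},
#' \code{p_enrich}, \code{p_deplete}, \code{log10_p_enrich},
#' \code{log10_p_deplete}, \code{mode}, \code{status}.
#'
#' @param x a [ColocResult-class].
#' @param ... ignored.
#' @return data.frame.
#' @export
setMethod("resultTable", "ColocResult", function(x, ...) {
    genome <- data.frame(
        chrom = "genome", statistic = x@statistic, observed = x@observed,
        null_mean = x@nullMean, null_var = x@nullVariance, z = x@zScore,
        p_enrich = x@pEnrichment, p_deplete = x@pDepletion,
        log10_p_enrich = x@log10PEnrichment,
        log10_p_deplete = x@log10PDepletion,
        mode = x@mode, status = x@status, stringsAsFactors = FALSE)
    pc <- x@perChromosome
    if (nrow(pc)) {
        per <- data.frame(
            chrom = pc$chrom, statistic = x@statistic, observed = pc$observed,
            null_mean = pc$mean, null_var = pc$variance, z = NA_real_,
            p_enrich = NA_real_, p_deplete = NA_real_,
            log10_p_enrich = NA_real_, log10_p_deplete = NA_real_,
            mode = x@mode, status = x@status, stringsAsFactors = FALSE)
        rbind(genome, per)
    } else genome
})

#' @describeIn Annotation-class coerce to a \code{GRanges} (1-based closed
#'   coordinates, seqlengths carried over).
#' @name as
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
setAs("Annotation", "GRanges", function(from) {
    chroms <- names(from@ranges)
    parts <- lapply(chroms, function(chrom) {
        iv <- from@ranges[[chrom]]
        GenomicRanges::GRanges(chrom,
            IRanges::IRanges(start = iv[, 1L] + 1, end = iv[, 2L]))
    })
    gr <- do.call(c, parts)
    GenomeInfoDb::seqlevels(gr) <- chroms
    GenomeInfoDb::seqlengths(gr) <- from@seqlengths[chroms]
    gr
})

setAs("GRanges", "Annotation", function(from) {
    sl <- GenomeInfoDb::seqlengths(from)
    if (any(is.na(sl)))
        stop("GRanges must carry seqlengths to become an Annotation")
    red <- GenomicRanges::reduce(from, min.gapwidth = 1L)
    ranges <- lapply(setNames(nm = names(sl)), function(chrom) {
        r <- red[GenomeInfoDb::seqnames(red) == chrom]
        cbind(begin = GenomicRanges::start(r) - 1, end = GenomicRanges::end(r))
    })
    Annotation(ranges, setNames(as.numeric(sl), names(sl)))
})
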