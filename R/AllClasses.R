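#' @import methods
#' @importFrom stats pnorm rgeom runif setNames var
#' @importFrom utils head tail
NULL

## Coordinates are 0-based half-open throughout ([begin, end)), the native
## BED convention. Interval tables are numeric (not integer) so that
## chromosome lengths up to ~2^53 are representable without overflow.

#' Annotation: disjoint genomic intervals on named chromosomes
#'
#' An annotation is, per chromosome, an ordered set of half-open intervals
#' \eqn{[b, e)} with 0-based coordinates, each pair of intervals separated by
#' at least one uncovered base.  Equivalently it is a binary sequence over the
#' chromosome marking covered positions.  Both the query and the reference of
#' a colocalization test are annotations.
#'
#' @slot ranges named list, one element per chromosome: a numeric matrix with
#'   columns \code{begin}, \code{end} (0-based half-open), rows sorted.
#' @slot seqlengths named numeric vector of chromosome lengths (bp).
#'
#' @seealso [Annotation()], [readAnnotation()], [intervalCount()],
#'   [coveredBases()]
#' @export
setClass("Annotation",
         representation(ranges = "list", seqlengths = "numeric"))

setValidity("Annotation", function(object) {
    sl <- object@seqlengths
    if (is.null(names(sl)) || anyDuplicated(names(sl)) || any(names(sl) == ""))
        return("seqlengths must have unique non-empty names")
    if (any(!is.finite(sl)) || any(sl < 1))
        return("all chromosome lengths must be finite and >= 1")
    if (!identical(sort(names(object@ranges)), sort(names(sl))))
        return("ranges must have exactly one element per chromosome in seqlengths")
    for (chrom in names(object@ranges)) {
        iv <- object@ranges[[chrom]]
        if (!is.matrix(iv) || ncol(iv) != 2L || !is.numeric(iv))
            return(sprintf("ranges[['%s']] must be a 2-column numeric matrix", chrom))
        if (nrow(iv) == 0L) next
        if (any(iv[, 1L] < 0) || any(iv[, 2L] > sl[[chrom]]))
            return(sprintf("intervals on '%s' outside [0, L)", chrom))
        if (any(iv[, 2L] <= iv[, 1L]))
            return(sprintf("empty or inverted interval on '%s'", chrom))
        if (nrow(iv) > 1L && any(iv[-1L, 1L] <= iv[-nrow(iv), 2L]))
            return(sprintf(
                "intervals on '%s' must be sorted and separated by >= 1 base", chrom))
    }
    TRUE
})

#' GenomeContext: per-position class labels in run-length form
#'
#' A genome context assigns every genome position one label from a finite
#' label set; it stratifies the genome into classes (e.g. assembly gap
#' vs. non-gap, or GC-content bins) that each receive their own Markov chain
#' under the null model.  Stored as runs: per chromosome a vector of run
#' start positions (first always 0) and the label of each run; adjacent runs
#' always carry distinct labels.
#'
#' @slot runs named list, one element per chromosome: a list with components
#'   \code{start} (numeric, increasing, first element 0) and \code{label}
#'   (character, same length).
#' @slot seqlengths named numeric vector of chromosome lengths (bp).
#'
#' @seealso [GenomeContext()], [readContext()], [uniformContext()],
#'   [relativeContext()], [gcContext()], [boundaryCount()]
#' @export
setClass("GenomeContext",
         representation(runs = "list", seqlengths = "numeric"))

setValidity("GenomeContext", function(object) {
    sl <- object@seqlengths
    if (is.null(names(sl)) || anyDuplicated(names(sl)))
        return("seqlengths must have unique names")
    if (!identical(sort(names(object@runs)), sort(names(sl))))
        return("runs must have exactly one element per chromosome in seqlengths")
    for (chrom in names(object@runs)) {
        r <- object@runs[[chrom]]
        if (!is.list(r) || !all(c("start", "label") %in% names(r)))
            return(sprintf("runs[['%s']] needs 'start' and 'label'", chrom))
        s <- r$start; lab <- r$label
        if (length(s) != length(lab) || length(s) < 1L)
            return(sprintf("runs[['%s']]: start/label length mismatch", chrom))
        if (s[1L] != 0)
            return(sprintf("runs[['%s']]: first run must start at 0", chrom))
        if (length(s) > 1L && (any(diff(s) <= 0) || s[length(s)] >= sl[[chrom]]))
            return(sprintf("runs[['%s']]: starts must increase and stay below L", chrom))
        if (length(lab) > 1L && any(lab[-1L] == lab[-length(lab)]))
            return(sprintf("runs[['%s']]: adjacent runs must have distinct labels", chrom))
        if (any(is.na(lab)) || any(lab == ""))
            return(sprintf("runs[['%s']]: empty labels", chrom))
    }
    TRUE
})

#' ContextChain: the context-aware two-state Markov chain
#'
#' One 2x2 row-stochastic transition matrix per context class, plus (when
#' trained from data) the transition counts it came from.  State 1 means
#' "position covered by the query annotation", state 0 "not covered".  Rows
#' index the previous state, columns the next state; entry \code{[s+1, s'+1]}
#' is the probability of moving from state \code{s} to \code{s'}.
#'
#' @slot matrices named list (one per class label) of 2x2 numeric matrices.
#' @slot counts named list of 2x2 transition-count matrices (possibly empty
#'   for user-constructed chains).
#' @slot pseudocount the pseudocount added to every transition count during
#'   training (NA for user-constructed chains).
#'
#' @seealso [trainChain()], [sampleAnnotation()], [transitionMatrices()],
#'   [stationaryDistribution()]
#' @export
setClass("ContextChain",
         representation(matrices = "list", counts = "list",
                        pseudocount = "numeric"))

setValidity("ContextChain", function(object) {
    m <- object@matrices
    if (length(m) == 0L || is.null(names(m)) || anyDuplicated(names(m)))
        return("matrices must be a non-empty uniquely named list")
    for (lab in names(m)) {
        Tm <- m[[lab]]
        if (!is.matrix(Tm) || !all(dim(Tm) == 2L) || !is.numeric(Tm))
            return(sprintf("matrix for class '%s' must be 2x2 numeric", lab))
        if (any(Tm < 0) || any(Tm > 1))
            return(sprintf("matrix for class '%s' has entries outside [0,1]", lab))
        if (any(abs(rowSums(Tm) - 1) > 1e-8))
            return(sprintf("matrix for class '%s' rows do not sum to 1", lab))
    }
    if (length(object@counts) &&
        !all(names(object@counts) %in% names(m)))
        return("counts carry labels with no transition matrix")
    TRUE
})

#' NullPmf: exact null distribution of a test statistic
#'
#' Probability mass function of a colocalization statistic under the
#' context-aware Markov chain null, as computed by the exact
#' dynamic-programming mode or the brute-force enumeration oracle.
#'
#' @slot support numeric vector of attainable statistic values (0, 1, ...).
#' @slot prob probabilities, same length as \code{support}, summing to 1.
#' @slot statistic \code{"overlaps"} or \code{"bases"}.
#'
#' @seealso [exactNullPmf()], [bruteForcePmf()], [pmfMean()], [pmfTailP()]
#' @export
setClass("NullPmf",
         representation(support = "numeric", prob = "numeric",
                        statistic = "character"))

setValidity("NullPmf", function(object) {
    if (length(object@support) != length(object@prob))
        return("support and prob must have the same length")
    if (any(object@prob < -1e-12))
        return("negative probabilities")
    if (abs(sum(object@prob) - 1) > 1e-9)
        return("probabilities must sum to 1 (within 1e-9)")
    TRUE
})

#' MomentResult: exact null mean and variance of a statistic
#'
#' @slot statistic \code{"overlaps"} or \code{"bases"}.
#' @slot mean,variance genome-wide null moments (sums over chromosomes).
#' @slot perChromosome data.frame with columns \code{chrom}, \code{mean},
#'   \code{variance}.
#' @slot combineCalls number of pairwise summary-merge operations performed
#'   (exposed so the advertised complexity is testable).
#'
#' @seealso [nullMoments()]
#' @export
setClass("MomentResult",
         representation(statistic = "character", mean = "numeric",
                        variance = "numeric", perChromosome = "data.frame",
                        combineCalls = "numeric"))

setValidity("MomentResult", function(object) {
    if (object@variance < 0) return("negative variance")
    TRUE
})

#' TwoSidedPlumbus: conditional moments of an interval's contribution
#'
#' The O(1)-sized summary attached to a genomic interval \eqn{[i, j)}: for
#' every pair \eqn{(x, y)} of boundary states (the state at position
#' \eqn{i-1} and the state at position \eqn{j-1}) it stores the conditional
#' mean and variance of the interval's contribution to the test statistic,
#' and the probability \eqn{\Psi(x \to y)} of ending in state \eqn{y} given
#' the interval was entered from state \eqn{x}.  Merging two adjacent
#' summaries over their shared boundary state (law of total variance) is the
#' elementary step of the moment engine.
#'
#' @slot mu,var 2x2 matrices, entry \code{[x+1, y+1]} conditioned on boundary
#'   states \code{(x, y)}.
#' @slot psi 2x2 matrix of boundary transition probabilities (rows sum to 1).
#' @slot ok 2x2 logical; FALSE marks unreachable boundary pairs
#'   (\code{psi == 0}), whose mu/var are sentinels with zero downstream weight.
#' @slot span numeric length-2: the half-open genomic interval summarized.
#'
#' @seealso [gapPlumbus()], [overlapPlumbus()], [basesPlumbus()],
#'   [combinePlumbus()], [finalizePlumbus()]
#' @export
setClass("TwoSidedPlumbus",
         representation(mu = "matrix", var = "matrix", psi = "matrix",
                        ok = "matrix", span = "numeric"))

setValidity("TwoSidedPlumbus", function(object) {
    if (!all(dim(object@mu) == 2L) || !all(dim(object@var) == 2L) ||
        !all(dim(object@psi) == 2L))
        return("mu, var, psi must be 2x2")
    if (any(abs(rowSums(object@psi) - 1) > 1e-10))
        return("psi rows must sum to 1 (within 1e-10)")
    if (any(object@var < -1e-12))
        return("variance entries below -1e-12")
    if (length(object@span) != 2L || object@span[2L] < object@span[1L])
        return("span must be a half-open interval")
    TRUE
})

#' ColocResult: outcome of a colocalization significance test
#'
#' @slot statistic \code{"overlaps"} or \code{"bases"}.
#' @slot mode \code{"normal"} (moments + normal approximation) or
#'   \code{"exact"} (full null PMF).
#' @slot observed observed statistic value.
#' @slot nullMean,nullVariance exact null moments.
#' @slot zScore number of null standard deviations above the null mean.
#' @slot pEnrichment,pDepletion upper/lower tail p-values.
#' @slot log10PEnrichment,log10PDepletion the same on the log10 scale,
#'   evaluated stably so extreme Z-scores do not report \code{-Inf}
#'   spuriously.
#' @slot status \code{"ok"} or \code{"degenerate"} (zero null variance:
#'   p-values are omitted rather than guessed).
#' @slot perChromosome per-chromosome breakdown of observed statistic and
#'   null moments.
#' @slot chain the trained null [ContextChain-class] (for reproducibility).
#'
#' @seealso [colocTest()], [resultTable()]
#' @export
setClass("ColocResult",
         representation(statistic = "character", mode = "character",
                        observed = "numeric", nullMean = "numeric",
                        nullVariance = "numeric", zScore = "numeric",
                        pEnrichment = "numeric", pDepletion = "numeric",
                        log10PEnrichment = "numeric",
                        log10PDepletion = "numeric",
                        status = "character", perChromosome = "data.frame",
                        chain = "ContextChain"))
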