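#' Z-score of an observed statistic against its null moments
#'
#' @param observed observed statistic value.
#' @param mean,variance exact null mean and variance.
#' @return numeric Z; \code{NA} when the variance is zero (degenerate null).
#' @export
zScore <- function(observed, mean, variance) {
    stopifnot(variance >= 0)
    if (variance == 0) return(NA_real_)
    (observed - mean) / sqrt(variance)
}

#' Normal-approximation p-values from a Z-score
#'
#' Enrichment is the upper standard-normal tail \eqn{1 - \Phi(z)}, depletion
#' the lower tail \eqn{\Phi(z)}.  Log10 tails are evaluated through the
#' log-scale normal CDF, so extreme Z-scores (|z| > 38, where the linear
#' scale underflows to 0) still report a finite, correct magnitude.
#'
#' @param z finite Z-score.
#' @return list with \code{enrichment}, \code{depletion},
#'   \code{log10Enrichment}, \code{log10Depletion}.
#' @examples
#' normalPvalues(3)$enrichment   # 0.00135
#' @export
normalPvalues <- function(z) {
    stopifnot(is.finite(z))
    list(enrichment = pnorm(z, lower.tail = FALSE),
         depletion = pnorm(z),
         log10Enrichment = pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10),
         log10Depletion = pnorm(z, log.p = TRUE) / log(10))
}

#' Colocalization significance test
#'
#' The end-to-end test: trains the context-aware Markov chain from the query
#' (never from the reference), computes the observed statistic, and converts
#' the null mean/variance (mode \code{"normal"}) or the exact null PMF
#' (mode \code{"exact"}) into enrichment and depletion p-values.
#'
#' The normal approximation tightens as the number of reference intervals
#' grows; for references smaller than \code{smallReferenceWarn} intervals the
#' exact mode is recommended and a warning says so.
#'
#' @param query,reference [Annotation-class] objects on the same genome.
#' @param context optional [GenomeContext-class]; NULL means one class for
#'   the whole genome (the plain Markov chain null).
#' @param statistic \code{"overlaps"} or \code{"bases"}.
#' @param mode \code{"normal"} or \code{"exact"}.
#' @param pseudocount training pseudocount (default 1).
#' @param smallReferenceWarn warn in normal mode when \code{reference} has
#'   fewer intervals than this (default 500); set to 0 to disable.
#' @return a [ColocResult-class].
#' @examples
#' sl <- c(chr1 = 2000)
#' q <- synthAnnotation(2000, 20, 10, seed = 1)
#' r <- synthAnnotation(2000, 15, 12, seed = 2)
#' res <- colocTest(q, r, statistic = "overlaps", smallReferenceWarn = 0)
#' res
#' @export
colocTest <- function(query, reference, context = NULL,
                      statistic = c("overlaps", "bases"),
                      mode = c("normal", "exact"), pseudocount = 1,
                      smallReferenceWarn = 500) {
    statistic <- match.arg(statistic)
    mode <- match.arg(mode)
    stopifnot(is(query, "Annotation"), is(reference, "Annotation"))
    if (is.null(context))
        context <- uniformContext(query@seqlengths)
    .sharedChroms(query, context)
    .sharedChroms(query, reference)
    chain <- trainChain(query, context, pseudocount = pseudocount)
    observed <- observedStatistic(reference, query, statistic)
    obsPer <- observedStatistic(reference, query, statistic,
                                perChromosome = TRUE)
    mom <- nullMoments(chain, context, reference, statistic)
    per <- mom@perChromosome
    per$observed <- as.numeric(obsPer[per$chrom])
    per <- per[, c("chrom", "observed", "mean", "variance")]
    if (mode == "normal" && smallReferenceWarn > 0 &&
        intervalCount(reference) < smallReferenceWarn)
        warning("reference has only ", intervalCount(reference),
                " intervals; the normal tail can be conservative there -- ",
                "consider mode = 'exact'")
    if (mom@variance == 0) {
        return(new("ColocResult", statistic = statistic, mode = mode,
                   observed = observed, nullMean = mom@mean,
                   nullVariance = 0, zScore = NA_real_,
                   pEnrichment = NA_real_, pDepletion = NA_real_,
                   log10PEnrichment = NA_real_, log10PDepletion = NA_real_,
                   status = "degenerate", perChromosome = per,
                   chain = chain))
    }
    z <- zScore(observed, mom@mean, mom@variance)
    if (mode == "normal") {
        pv <- normalPvalues(z)
    } else {
        pmf <- exactNullPmf(chain, context, reference, statistic)
        tails <- pmfTailP(pmf, observed)
        pv <- list(enrichment = tails$enrichment,
                   depletion = tails$depletion,
                   log10Enrichment = log10(tails$enrichment),
                   log10Depletion = log10(tails$depletion))
    }
    new("ColocResult", statistic = statistic, mode = mode,
        observed = observed, nullMean = mom@mean,
        nullVariance = mom@variance, zScore = z,
        pEnrichment = pv$enrichment, pDepletion = pv$depletion,
        log10PEnrichment = pv$log10Enrichment,
        log10PDepletion = pv$log10Depletion,
        status = "ok", perChromosome = per, chain = chain)
}

#' Differential enrichment of a nested reference
#'
#' Tests enrichment of the query in \code{r1} relative to a superset
#' reference \code{r2} (every \code{r1} interval must lie within some
#' \code{r2} interval).  A two-class context labels positions covered by
#' \code{r2} "inside" and all others "outside", so the null chain inside r2
#' reflects the query's behaviour across all of r2; significance of the
#' query in r1 is then measured relative to r2 rather than to the genome.
#'
#' @param query the query [Annotation-class].
#' @param r1 nested reference of interest.
#' @param r2 superset reference defining the comparison stratum.
#' @inheritParams colocTest
#' @return a [ColocResult-class].
#' @importFrom IRanges IRanges countOverlaps
#' @export
differentialColocTest <- function(query, r1, r2,
                                  statistic = c("overlaps", "bases"),
                                  mode = c("normal", "exact"),
                                  pseudocount = 1, smallReferenceWarn = 500) {
    stopifnot(is(r1, "Annotation"), is(r2, "Annotation"))
    for (chrom in .sharedChroms(r1, r2)) {
        iv1 <- r1@ranges[[chrom]]
        if (!nrow(iv1)) next
        iv2 <- r2@ranges[[chrom]]
        a <- IRanges::IRanges(start = iv1[, 1L] + 1, end = iv1[, 2L])
        b <- IRanges::IRanges(start = iv2[, 1L] + 1, end = iv2[, 2L])
        within <- IRanges::countOverlaps(a, b, type = "within") > 0L
        if (!all(within)) {
            k <- which(!within)[1L]
            stop(sprintf("r1 interval %s:[%g,%g) is not contained in r2",
                         chrom, iv1[k, 1L], iv1[k, 2L]))
        }
    }
    ctx <- relativeContext(r2)
    colocTest(query, r1, ctx, statistic = statistic, mode = mode,
              pseudocount = pseudocount,
              smallReferenceWarn = smallReferenceWarn)
}
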