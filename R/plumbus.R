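## ---------------------------------------------------------------------------
## The moment engine.
##
## Internally a two-sided interval summary ("plumbus") is a plain list
## (mu, var, psi, ok, span) with 2x2 matrices indexed [x+1, y+1] by the
## boundary-state pair: x is the state just before the span, y the state at
## its last position.  Plain lists keep the per-merge cost tiny; the S4 face
## (TwoSidedPlumbus) wraps the same fields for user-level inspection.
## Unreachable boundary pairs (psi == 0) carry mu = var = 0 as sentinels and
## never receive weight downstream, which avoids 0/0 without branching.
## ---------------------------------------------------------------------------

.plIdentity <- function(at = 0) {
    list(mu = matrix(0, 2L, 2L), var = matrix(0, 2L, 2L), psi = diag(2),
         ok = diag(2) > 0, span = c(at, at))
}

.plWrap <- function(pl) {
    new("TwoSidedPlumbus", mu = pl$mu, var = pl$var, psi = pl$psi,
        ok = pl$ok, span = pl$span)
}

.plUnwrap <- function(x) {
    list(mu = x@mu, var = x@var, psi = x@psi, ok = x@ok, span = x@span)
}

## Boundary transition matrix across a span given its class runs:
## product of per-run n-step matrices.
.spanPsi <- function(chain, runs) {
    psi <- diag(2)
    for (k in seq_along(runs$label))
        psi <- psi %*% nStepMatrix(.chainMatrix(chain, runs$label[k]),
                                   runs$len[k])
    psi
}

.plGapRuns <- function(chain, runs, span) {
    if (span[2L] <= span[1L]) return(.plIdentity(span[1L]))
    psi <- .spanPsi(chain, runs)
    list(mu = matrix(0, 2L, 2L), var = matrix(0, 2L, 2L), psi = psi,
         ok = psi > 0, span = span)
}

## Pr[all states in the span are 0 | state before span = x], per x in {0,1}.
.allZeroAcross <- function(chain, runs) {
    z <- c(1, 1)
    prev0 <- FALSE                      # after first run the entry state is 0
    for (k in seq_along(runs$label)) {
        Tm <- .chainMatrix(chain, runs$label[k])
        len <- runs$len[k]
        if (!prev0) {
            z <- z * c(allZeroProbability(Tm, 0, len),
                       allZeroProbability(Tm, 1, len))
            prev0 <- TRUE
        } else {
            z <- z * allZeroProbability(Tm, 0, len)
        }
    }
    z
}

.plOverlapRuns <- function(chain, runs, span) {
    psi <- .spanPsi(chain, runs)
    z <- .allZeroAcross(chain, runs)
    mu <- matrix(1, 2L, 2L)             # y = 1 forces an overlap
    va <- matrix(0, 2L, 2L)
    for (x in 1:2) {
        if (psi[x, 1L] > 0) {
            m <- 1 - z[x] / psi[x, 1L]
            m <- max(0, min(1, m))
            mu[x, 1L] <- m
            va[x, 1L] <- m * (1 - m)
        }                                # else unreachable: sentinel mu = 1
    }
    list(mu = mu, var = va, psi = psi, ok = psi > 0, span = span)
}

## single-position summary for the shared-bases statistic: contribution = y
.plSingle <- function(Tm, at) {
    list(mu = rbind(c(0, 1), c(0, 1)), var = matrix(0, 2L, 2L), psi = Tm,
         ok = Tm > 0, span = c(at, at + 1))
}

## bases summary for a length-t stretch of one class, by binary doubling;
## `cache` persists ladders per class label across one chromosome pass
.plBasesRun <- function(chain, label, len, at, cache, cnt) {
    Tm <- .chainMatrix(chain, label)
    ladder <- cache[[label]]
    if (is.null(ladder)) ladder <- list(.plSingle(Tm, 0))
    need <- floor(log2(len)) + 1L
    while (length(ladder) < need) {
        top <- ladder[[length(ladder)]]
        ladder[[length(ladder) + 1L]] <- .plCombine(top, top, cnt)
    }
    cache[[label]] <- ladder
    acc <- NULL
    k <- 1L
    t <- len
    while (t > 0) {
        if (t %% 2 == 1)
            acc <- if (is.null(acc)) ladder[[k]] else
                .plCombine(acc, ladder[[k]], cnt)
        t <- t %/% 2
        k <- k + 1L
    }
    acc$span <- c(at, at + len)
    acc
}

.plBasesRuns <- function(chain, runs, span, cache, cnt) {
    at <- span[1L]
    acc <- NULL
    for (k in seq_along(runs$label)) {
        p <- .plBasesRun(chain, runs$label[k], runs$len[k], at, cache, cnt)
        acc <- if (is.null(acc)) p else .plCombine(acc, p, cnt)
        at <- at + runs$len[k]
    }
    acc
}

## Merge two adjacent summaries over the shared boundary state m = state at
## the last position of `a` (= state before `b`), using conditional
## independence given m and the law of total variance.
.plCombine <- function(a, b, cnt = NULL) {
    if (!is.null(cnt)) cnt$n <- cnt$n + 1
    psi <- a$psi %*% b$psi
    mu <- matrix(0, 2L, 2L)
    va <- matrix(0, 2L, 2L)
    ok <- psi > 0
    for (x in 1:2) for (y in 1:2) {
        tot <- psi[x, y]
        if (tot <= 0) next
        w <- a$psi[x, ] * b$psi[, y] / tot
        mm <- a$mu[x, ] + b$mu[, y]
        m <- w[1L] * mm[1L] + w[2L] * mm[2L]
        v <- w[1L] * (a$var[x, 1L] + b$var[1L, y] + mm[1L]^2) +
             w[2L] * (a$var[x, 2L] + b$var[2L, y] + mm[2L]^2) - m^2
        mu[x, y] <- m
        va[x, y] <- if (v > 0) v else 0
    }
    list(mu = mu, var = va, psi = psi, ok = ok, span = c(a$span[1L], b$span[2L]))
}

## Remove the conditioning on both boundary states using the initial
## distribution at position -1: joint weight p(x,y) = init_x * psi(x -> y).
.plFinalize <- function(pl, init) {
    p <- init * pl$psi                  # recycles init over rows: init[x] * psi[x, y]
    mean <- sum(p * pl$mu)
    v <- sum(p * pl$var) + sum(p * pl$mu^2) - mean^2
    c(mean = mean, variance = if (v > 0) v else 0)
}

## ---------------------------------------------------------------------------
## S4 face
## ---------------------------------------------------------------------------

#' Two-sided summary of a gap between reference intervals
#'
#' Gaps contribute nothing to a separable statistic; their summary carries
#' zero conditional mean and variance and only propagates the boundary-state
#' distribution across the span (a product of per-class n-step matrices, one
#' factor per maximal same-class run).
#'
#' @param chain a [ContextChain-class].
#' @param context a [GenomeContext-class].
#' @param chrom chromosome name.
#' @param begin,end half-open 0-based span; \code{begin == end} yields the
#'   identity summary.
#' @return a [TwoSidedPlumbus-class].
#' @export
gapPlumbus <- function(chain, context, chrom, begin, end) {
    stopifnot(end >= begin)
    .plWrap(.plGapRuns(chain, .runsWithin(context, chrom, begin, end),
                       c(begin, end)))
}

#' Two-sided summary of a reference interval, overlap statistic
#'
#' The contribution of a reference interval to the overlap count is the
#' indicator that at least one position inside it is covered.  Conditional
#' on the boundary states (x, y): ending covered (y = 1) forces an overlap;
#' for y = 0 the no-overlap probability is the all-zero stretch probability
#' divided by \eqn{\Psi(x \to 0)}.  Constant time per maximal same-class run.
#'
#' @inheritParams gapPlumbus
#' @return a [TwoSidedPlumbus-class].
#' @export
overlapPlumbus <- function(chain, context, chrom, begin, end) {
    stopifnot(end > begin)
    .plWrap(.plOverlapRuns(chain, .runsWithin(context, chrom, begin, end),
                           c(begin, end)))
}

#' Two-sided summary of a reference interval, shared-bases statistic
#'
#' Equals the fold of single-position summaries across the interval, but is
#' computed per maximal same-class run with a power-of-two doubling ladder,
#' i.e. O(log t) merges for a run of length t.
#'
#' @inheritParams gapPlumbus
#' @return a [TwoSidedPlumbus-class].
#' @export
basesPlumbus <- function(chain, context, chrom, begin, end) {
    stopifnot(end > begin)
    cache <- new.env(parent = emptyenv())
    .plWrap(.plBasesRuns(chain, .runsWithin(context, chrom, begin, end),
                         c(begin, end), cache, NULL))
}

#' Merge two adjacent two-sided summaries
#'
#' The spans must abut (\code{left} ends where \code{right} begins); the
#' shared boundary state is summed out with weights given by the boundary
#' transition probabilities, combining means linearly and variances by the
#' conditional-variance decomposition.
#'
#' @param left,right [TwoSidedPlumbus-class] objects with
#'   \code{left@span[2] == right@span[1]}.
#' @return a [TwoSidedPlumbus-class] over the concatenated span.
#' @export
combinePlumbus <- function(left, right) {
    stopifnot(is(left, "TwoSidedPlumbus"), is(right, "TwoSidedPlumbus"))
    if (left@span[2L] != right@span[1L])
        stop("plumbus spans do not abut: left ends at ", left@span[2L],
             ", right begins at ", right@span[1L])
    .plWrap(.plCombine(.plUnwrap(left), .plUnwrap(right)))
}

#' Unconditional mean and variance from a full-chromosome summary
#'
#' Removes the conditioning on both boundary states of a summary spanning a
#' whole chromosome, weighting by the initial (stationary) distribution at
#' position -1 and the boundary transition probabilities.
#'
#' @param plumbus a [TwoSidedPlumbus-class] spanning \eqn{[0, L)}.
#' @param init length-2 probability vector: the stationary distribution of
#'   the chain of the class at position 0.
#' @return named numeric: \code{mean}, \code{variance}.
#' @export
finalizePlumbus <- function(plumbus, init) {
    stopifnot(is(plumbus, "TwoSidedPlumbus"))
    if (abs(sum(init) - 1) > 1e-9 || any(init < 0))
        stop("init must be a probability vector summing to 1")
    .plFinalize(.plUnwrap(plumbus), init)
}

#' Exact null mean and variance of a colocalization statistic
#'
#' Computes, per chromosome, the exact mean and variance of the statistic
#' under the context-aware Markov chain null by folding gap and
#' reference-interval summaries left to right across the chromosome and
#' finalizing with that chromosome's initial distribution.  Chromosomes are
#' independent under the model, so genome totals are sums.  The number of
#' pairwise merges is O(|R| + c) for the overlap statistic and
#' O((|R| + c) log t) for shared bases (t = longest same-class stretch
#' within a reference interval), and is reported in the result.
#'
#' @param chain a [ContextChain-class] covering every label of
#'   \code{context}.
#' @param context a [GenomeContext-class].
#' @param reference an [Annotation-class] on the same genome.
#' @param statistic \code{"overlaps"} or \code{"bases"}.
#' @return a [MomentResult-class].
#' @examples
#' sl <- c(chr1 = 50)
#' ctx <- uniformContext(sl)
#' q <- Annotation(list(chr1 = cbind(c(3, 20), c(10, 30))), sl)
#' r <- Annotation(list(chr1 = cbind(c(5, 35), c(12, 40))), sl)
#' nullMoments(trainChain(q, ctx), ctx, r, "overlaps")
#' @export
nullMoments <- function(chain, context, reference,
                        statistic = c("overlaps", "bases")) {
    statistic <- match.arg(statistic)
    stopifnot(is(chain, "ContextChain"), is(context, "GenomeContext"),
              is(reference, "Annotation"))
    chroms <- sort(.sharedChroms(reference, context))
    for (lab in contextLabels(context)) .chainMatrix(chain, lab)
    cnt <- new.env(parent = emptyenv()); cnt$n <- 0
    rows <- lapply(chroms, function(chrom) {
        iv <- reference@ranges[[chrom]]
        if (!nrow(iv))
            return(data.frame(chrom = chrom, mean = 0, variance = 0))
        L <- context@seqlengths[[chrom]]
        cache <- new.env(parent = emptyenv())
        acc <- .plIdentity(0)
        pos <- 0
        for (k in seq_len(nrow(iv))) {
            b <- iv[k, 1L]; e <- iv[k, 2L]
            if (b > pos)
                acc <- .plCombine(acc, .plGapRuns(
                    chain, .runsWithin(context, chrom, pos, b), c(pos, b)), cnt)
            runs <- .runsWithin(context, chrom, b, e)
            ivpl <- if (statistic == "overlaps")
                .plOverlapRuns(chain, runs, c(b, e))
            else
                .plBasesRuns(chain, runs, c(b, e), cache, cnt)
            acc <- .plCombine(acc, ivpl, cnt)
            pos <- e
        }
        if (pos < L)
            acc <- .plCombine(acc, .plGapRuns(
                chain, .runsWithin(context, chrom, pos, L), c(pos, L)), cnt)
        init <- stationaryDistribution(
            .chainMatrix(chain, context@runs[[chrom]]$label[1L]))
        mv <- .plFinalize(acc, init)
        data.frame(chrom = chrom, mean = mv[["mean"]],
                   variance = mv[["variance"]])
    })
    per <- do.call(rbind, rows)
    new("MomentResult", statistic = statistic, mean = sum(per$mean),
        variance = sum(per$variance), perChromosome = per,
        combineCalls = cnt$n)
}
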