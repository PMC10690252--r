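## direct (non-FFT) convolution of small PMF vectors (index = value + 0)
.convolvePmf <- function(p, q) {
    if (length(p) == 1L && p[1L] == 1) return(q)
    out <- numeric(length(p) + length(q) - 1L)
    for (i in seq_along(p)) {
        if (p[i] == 0) next
        idx <- i:(i + length(q) - 1L)
        out[idx] <- out[idx] + p[i] * q
    }
    out
}

.exactChromOverlaps <- function(chain, context, chrom, iv) {
    init <- stationaryDistribution(
        .chainMatrix(chain, context@runs[[chrom]]$label[1L]))
    D <- matrix(0, 2L, nrow(iv) + 1L)
    D[, 1L] <- init
    pos <- 0
    for (k in seq_len(nrow(iv))) {
        b <- iv[k, 1L]; e <- iv[k, 2L]
        if (b > pos) {
            G <- .spanPsi(chain, .runsWithin(context, chrom, pos, b))
            D <- t(G) %*% D
        }
        runs <- .runsWithin(context, chrom, b, e)
        psi <- .spanPsi(chain, runs)
        z <- .allZeroAcross(chain, runs)
        ov0 <- pmax(psi[, 1L] - z, 0)   # end in 0 having overlapped, given x
        ov1 <- psi[, 2L]
        nc <- ncol(D)
        Dn <- matrix(0, 2L, nc)
        Dn[1L, ] <- z[1L] * D[1L, ] + z[2L] * D[2L, ]
        Dn[1L, -1L] <- Dn[1L, -1L] + ov0[1L] * D[1L, -nc] + ov0[2L] * D[2L, -nc]
        Dn[2L, -1L] <- ov1[1L] * D[1L, -nc] + ov1[2L] * D[2L, -nc]
        D <- Dn
        pos <- e
    }
    colSums(D)                          # trailing gap cannot change the count
}

.exactChromBases <- function(chain, context, chrom, iv) {
    init <- stationaryDistribution(
        .chainMatrix(chain, context@runs[[chrom]]$label[1L]))
    total <- sum(iv[, 2L] - iv[, 1L])
    D <- matrix(0, 2L, total + 1L)
    D[, 1L] <- init
    pos <- 0
    for (k in seq_len(nrow(iv))) {
        b <- iv[k, 1L]; e <- iv[k, 2L]
        if (b > pos) {
            G <- .spanPsi(chain, .runsWithin(context, chrom, pos, b))
            D <- t(G) %*% D
        }
        runs <- .runsWithin(context, chrom, b, e)
        nc <- ncol(D)
        for (r in seq_along(runs$label)) {
            Tm <- .chainMatrix(chain, runs$label[r])
            for (step in seq_len(runs$len[r])) {
                d0 <- Tm[1L, 1L] * D[1L, ] + Tm[2L, 1L] * D[2L, ]
                d1 <- Tm[1L, 2L] * D[1L, ] + Tm[2L, 2L] * D[2L, ]
                D[1L, ] <- d0
                D[2L, ] <- c(0, d1[-nc])   # covered base: count shifts by 1
            }
        }
        pos <- e
    }
    colSums(D)
}

#' Exact null distribution of a colocalization statistic
#'
#' Computes the full probability mass function of the statistic under the
#' context-aware Markov chain null by a left-to-right dynamic program that
#' carries the joint distribution of (state at the current boundary,
#' statistic so far).  Gap steps only propagate the state; reference
#' intervals branch on overlap/no-overlap (overlap statistic) or advance one
#' base at a time (shared-bases statistic, quadratic in the total reference
#' length).  Per-chromosome PMFs are convolved into the genome-level PMF.
#'
#' Intended for small references, where the normal approximation of the
#' tail is least accurate; use [nullMoments()] otherwise.
#'
#' @inheritParams nullMoments
#' @param overlapGuard warn when a chromosome has more reference intervals
#'   than this (quadratic support cost).
#' @param basesGuard error when the total reference length exceeds this.
#' @return a [NullPmf-class].
#' @examples
#' sl <- c(chr1 = 40)
#' ctx <- uniformContext(sl)
#' q <- Annotation(list(chr1 = cbind(c(4, 18), c(8, 25))), sl)
#' r <- Annotation(list(chr1 = cbind(c(10, 30), c(14, 33))), sl)
#' exactNullPmf(trainChain(q, ctx), ctx, r, "overlaps")
#' @export
exactNullPmf <- function(chain, context, reference,
                         statistic = c("overlaps", "bases"),
                         overlapGuard = 5e4, basesGuard = 1e4) {
    statistic <- match.arg(statistic)
    stopifnot(is(chain, "ContextChain"), is(context, "GenomeContext"),
              is(reference, "Annotation"))
    chroms <- sort(.sharedChroms(reference, context))
    for (lab in contextLabels(context)) .chainMatrix(chain, lab)
    if (statistic == "overlaps") {
        nmax <- max(vapply(reference@ranges, nrow, 1L))
        if (nmax > overlapGuard)
            warning("a chromosome carries ", nmax, " reference intervals; ",
                    "the exact PMF is quadratic -- consider nullMoments()")
    } else {
        if (coveredBases(reference) > basesGuard)
            stop("total reference length ", coveredBases(reference),
                 " exceeds the exact-mode guard (", basesGuard,
                 "); use nullMoments() for the shared-bases statistic")
    }
    pmf <- 1
    for (chrom in chroms) {
        iv <- reference@ranges[[chrom]]
        if (!nrow(iv)) next
        q <- if (statistic == "overlaps")
            .exactChromOverlaps(chain, context, chrom, iv)
        else
            .exactChromBases(chain, context, chrom, iv)
        pmf <- .convolvePmf(pmf, q)
    }
    if (identical(pmf, 1)) pmf <- c(1)
    pmf <- pmax(pmf, 0)
    new("NullPmf", support = seq_along(pmf) - 1, prob = pmf / sum(pmf),
        statistic = statistic)
}

#' Brute-force null distribution by state-sequence enumeration
#'
#' Enumerates all \eqn{2^{L+1}} state sequences (including the state at
#' position -1) of a single-chromosome instance, accumulating each
#' sequence's probability under the generative model and its statistic
#' value.  Exact by construction and independent of the dynamic programs
#' and the moment engine; only feasible for tiny chromosomes, which is all
#' a verification oracle needs.
#'
#' @inheritParams nullMoments
#' @param Lmax refuse chromosomes longer than this (default 16).
#' @return a [NullPmf-class].
#' @export
bruteForcePmf <- function(chain, context, reference,
                          statistic = c("overlaps", "bases"), Lmax = 16) {
    statistic <- match.arg(statistic)
    chroms <- .sharedChroms(reference, context)
    if (length(chroms) != 1L)
        stop("brute-force enumeration handles a single chromosome")
    chrom <- chroms[1L]
    L <- as.integer(context@seqlengths[[chrom]])
    if (L > Lmax) stop("chromosome length ", L, " exceeds Lmax = ", Lmax)
    n <- 2^(L + 1L)
    ints <- 0:(n - 1L)
    bits <- vapply(0:L, function(j) (ints %/% 2^j) %% 2, numeric(n))
    ## column j+1 holds state s_{j-1}: col 1 is s_{-1}, col i+2 is s_i
    init <- stationaryDistribution(
        .chainMatrix(chain, context@runs[[chrom]]$label[1L]))
    p <- init[bits[, 1L] + 1L]
    lab <- labelAt(context, chrom, 0:(L - 1L))
    for (i in 0:(L - 1L)) {
        Tm <- .chainMatrix(chain, lab[i + 1L])
        p <- p * Tm[cbind(bits[, i + 1L] + 1L, bits[, i + 2L] + 1L)]
    }
    iv <- reference@ranges[[chrom]]
    stat <- numeric(n)
    for (k in seq_len(nrow(iv))) {
        cols <- (iv[k, 1L]:(iv[k, 2L] - 1L)) + 2L
        inside <- rowSums(bits[, cols, drop = FALSE])
        stat <- stat + if (statistic == "overlaps") as.numeric(inside > 0)
                       else inside
    }
    maxStat <- if (statistic == "overlaps") nrow(iv) else
        sum(iv[, 2L] - iv[, 1L])
    pmf <- vapply(0:maxStat, function(v) sum(p[stat == v]), 0)
    new("NullPmf", support = 0:maxStat, prob = pmf / sum(pmf),
        statistic = statistic)
}

#' Tail p-values from an exact PMF
#'
#' Enrichment is the inclusive upper tail \eqn{\Pr[A' \ge A]}, depletion the
#' inclusive lower tail \eqn{\Pr[A' \le A]}.
#'
#' @param pmf a [NullPmf-class].
#' @param observed observed statistic value.
#' @return list with \code{enrichment} and \code{depletion}.
#' @export
pmfTailP <- function(pmf, observed) {
    stopifnot(is(pmf, "NullPmf"))
    list(enrichment = sum(pmf@prob[pmf@support >= observed]),
         depletion = sum(pmf@prob[pmf@support <= observed]))
}

#' Write a PMF as a two-column TSV (value, probability)
#'
#' @param pmf a [NullPmf-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writePmf <- function(pmf, path) {
    stopifnot(is(pmf, "NullPmf"))
    utils::write.table(
        data.frame(value = pmf@support, probability = pmf@prob),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
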