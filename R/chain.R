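#' Train the context-aware Markov chain from a query annotation
#'
#' Estimates, for every context class, the 2x2 transition matrix of the
#' two-state chain that generates the query: for each position
#' \eqn{i = 1, \dots, L-1} the state pair \eqn{(Q_{i-1}, Q_i)} is counted
#' towards the class of position \eqn{i}, a pseudocount is added to every
#' count to avoid zero probabilities, and rows are normalized.  Counting is
#' pooled over all chromosomes and done in run-length arithmetic, so the
#' cost is proportional to the number of query intervals plus the number of
#' class boundaries, not to the genome length.
#'
#' @param query an [Annotation-class].
#' @param context a [GenomeContext-class] on the same genome, or NULL for the
#'   single-class chain.
#' @param pseudocount nonnegative count added to every transition count
#'   (default 1).
#' @return a [ContextChain-class] carrying matrices and counts.
#' @examples
#' q <- Annotation(list(chr1 = cbind(1, 3)), c(chr1 = 5))
#' transitionMatrices(trainChain(q))  # all four transition counts equal 2
#' @export
trainChain <- function(query, context = NULL, pseudocount = 1) {
    stopifnot(is(query, "Annotation"), pseudocount >= 0)
    if (is.null(context))
        context <- uniformContext(query@seqlengths)
    chroms <- .sharedChroms(query, context)
    labels <- contextLabels(context)
    counts <- array(0, dim = c(length(labels), 2L, 2L),
                    dimnames = list(labels, NULL, NULL))
    for (chrom in chroms) {
        counts <- counts + .chromTransitionCounts(
            query@ranges[[chrom]], query@seqlengths[[chrom]],
            context@runs[[chrom]], labels)
    }
    counts <- counts + pseudocount
    mats <- lapply(setNames(nm = labels), function(lab) {
        cm <- counts[lab, , ]
        sweep(cm, 1L, rowSums(cm), "/")
    })
    cnts <- lapply(setNames(nm = labels), function(lab) counts[lab, , ])
    new("ContextChain", matrices = mats, counts = cnts,
        pseudocount = pseudocount)
}

## Raw (pseudocount-free) transition counts on one chromosome.
## Pairs (Q_{i-1}, Q_i) for i in [1, L-1] attributed to the class of
## position i (the destination position).  O(|Q| + c) via run-length sweeps.
.chromTransitionCounts <- function(iv, L, ctxRuns, labels) {
    cnt <- array(0, dim = c(length(labels), 2L, 2L),
                 dimnames = list(labels, NULL, NULL))
    if (L < 2) return(cnt)
    s <- ctxRuns$start
    runEnd <- c(s[-1L], L)
    labIdx <- match(ctxRuns$label, labels)
    b <- iv[, 1L]; e <- iv[, 2L]
    ## state-change transitions: i = begin gives (0,1), i = end gives (1,0)
    ch01 <- b[b >= 1 & b <= L - 1]
    ch10 <- e[e <= L - 1]
    if (length(ch01)) {
        t1 <- tabulate(labIdx[findInterval(ch01, s)], length(labels))
        cnt[, 1L, 2L] <- cnt[, 1L, 2L] + t1
    }
    if (length(ch10)) {
        t2 <- tabulate(labIdx[findInterval(ch10, s)], length(labels))
        cnt[, 2L, 1L] <- cnt[, 2L, 1L] + t2
    }
    ## self transitions: within a maximal constant-state run [a, b) the
    ## pairs (s, s) sit at i in [a+1, b); clip to [1, L-1] and split by class
    addSelf <- function(lo, hi, state) {
        ## spans are half-open [lo, hi) position sets of pair indices i
        for (k in seq_along(lo)) {
            l <- lo[k]; h <- hi[k]
            if (h <= l) next
            k1 <- findInterval(l, s); k2 <- findInterval(h - 1, s)
            for (r in k1:k2) {
                seg <- min(runEnd[r], h) - max(s[r], l)
                cnt[labIdx[r], state + 1L, state + 1L] <<-
                    cnt[labIdx[r], state + 1L, state + 1L] + seg
            }
        }
    }
    ## runs of state 1: the intervals themselves
    if (length(b))
        addSelf(pmax(b + 1, 1), pmin(e, L), 1L)
    ## runs of state 0: the gaps (including chromosome ends)
    g0 <- c(0, e); g1 <- c(b, L)
    addSelf(pmax(g0 + 1, 1), pmin(g1, L), 0L)
    cnt
}

#' Stationary distribution of a 2x2 transition matrix
#'
#' Closed form \eqn{\pi = (T_{10}, 1 - T_{00}) / (1 - T_{00} + T_{10})}.
#' The degenerate case \eqn{1 - T_{00} + T_{10} = 0} (state 0 absorbing and
#' unreachable from 1, i.e. the identity-like chain) is defined as
#' \eqn{(1, 0)}; with pseudocounted training it cannot arise.
#'
#' @param T 2x2 row-stochastic matrix.
#' @return numeric length-2 probability vector \eqn{(\pi_0, \pi_1)}.
#' @examples
#' stationaryDistribution(rbind(c(0.9, 0.1), c(0.5, 0.5)))  # (5/6, 1/6)
#' @export
stationaryDistribution <- function(T) {
    .checkT(T)
    den <- 1 - T[1L, 1L] + T[2L, 1L]
    if (den == 0) return(c(1, 0))
    c(T[2L, 1L], 1 - T[1L, 1L]) / den
}

.checkT <- function(T) {
    if (!is.matrix(T) || !all(dim(T) == 2L) || any(T < 0) || any(T > 1) ||
        any(abs(rowSums(T) - 1) > 1e-8))
        stop("T must be a 2x2 row-stochastic matrix")
    invisible(TRUE)
}

#' n-step transition matrix of a 2x2 chain in O(1)
#'
#' Uses the spectral closed form \eqn{T^n = \Pi + (1 - a - b)^n (I - \Pi)}
#' where \eqn{a = T_{01}}, \eqn{b = T_{10}} and \eqn{\Pi} has the stationary
#' vector in both rows.  This is what makes per-interval boundary
#' probabilities constant-time within a single context class.
#'
#' @param T 2x2 row-stochastic matrix.
#' @param n nonnegative integer step count.
#' @return 2x2 row-stochastic matrix equal to the n-fold product.
#' @export
nStepMatrix <- function(T, n) {
    .checkT(T)
    stopifnot(n >= 0, n == floor(n))
    if (n == 0) return(diag(2))
    pi <- stationaryDistribution(T)
    Pi <- rbind(pi, pi, deparse.level = 0)
    r <- 1 - T[1L, 2L] - T[2L, 1L]
    r <- max(-1, min(1, r))
    Tn <- Pi + r^n * (diag(2) - Pi)
    Tn[Tn < 0] <- 0; Tn[Tn > 1] <- 1
    Tn
}

#' Probability of an all-zero stretch
#'
#' \eqn{\Pr[S_{i+1} = \dots = S_{i+n} = 0 \mid S_i = x] = T_{x0} T_{00}^{n-1}}
#' within one context class; constant time.
#'
#' @param T 2x2 row-stochastic matrix.
#' @param x current state (0 or 1).
#' @param n stretch length, >= 1.
#' @return probability.
#' @export
allZeroProbability <- function(T, x, n) {
    .checkT(T)
    stopifnot(n >= 1, x %in% c(0, 1))
    T[x + 1L, 1L] * T[1L, 1L]^(n - 1)
}

#' Write / read a chain as a plain-text table
#'
#' One row per class label: the four transition probabilities (row-major:
#' t00 t01 t10 t11) and the four training counts (NA when the chain was not
#' trained).  The pseudocount is stored in a header comment.
#'
#' @param chain a [ContextChain-class].
#' @param path file path.
#' @return \code{writeChain}: invisibly \code{path}; \code{readChain}: a
#'   [ContextChain-class].
#' @export
writeChain <- function(chain, path) {
    stopifnot(is(chain, "ContextChain"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# pseudocount=%g", chain@pseudocount), con)
    writeLines("label\tt00\tt01\tt10\tt11\tc00\tc01\tc10\tc11", con)
    for (lab in names(chain@matrices)) {
        Tm <- chain@matrices[[lab]]
        cm <- chain@counts[[lab]]
        if (is.null(cm)) cm <- matrix(NA_real_, 2L, 2L)
        writeLines(paste(c(lab, format(c(t(Tm)), digits = 17),
                           format(c(t(cm)), digits = 17)),
                         collapse = "\t"), con)
    }
    invisible(path)
}

#' @rdname writeChain
#' @export
readChain <- function(path) {
    lines <- readLines(path)
    ps <- NA_real_
    hdr <- grep("^# pseudocount=", lines, value = TRUE)
    if (length(hdr)) ps <- as.numeric(sub("^# pseudocount=", "", hdr[1L]))
    tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
    mats <- list(); cnts <- list()
    for (k in seq_len(nrow(tab))) {
        lab <- as.character(tab$label[k])
        mats[[lab]] <- matrix(as.numeric(tab[k, 2:5]), 2L, 2L, byrow = TRUE)
        cm <- as.numeric(tab[k, 6:9])
        if (!anyNA(cm)) cnts[[lab]] <- matrix(cm, 2L, 2L, byrow = TRUE)
    }
    new("ContextChain", matrices = mats, counts = cnts, pseudocount = ps)
}

## chain matrix lookup with a clear error for unknown labels
.chainMatrix <- function(chain, label) {
    Tm <- chain@matrices[[label]]
    if (is.null(Tm))
        stop("chain has no transition matrix for context class '", label, "'")
    Tm
}
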