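# Fixture builders shared across the suite.  Everything is generated in
# code; no data files.

# 2x2 row-stochastic matrix with strictly positive entries
randomT <- function(lo = 0.05, hi = 0.95) {
    a <- runif(1, lo, hi); b <- runif(1, lo, hi)
    rbind(c(1 - a, a), c(b, 1 - b))
}

chainFor <- function(labels, Tlist = NULL) {
    if (is.null(Tlist))
        Tlist <- lapply(seq_along(labels), function(i) randomT())
    new("ContextChain", matrices = setNames(Tlist, labels),
        counts = list(), pseudocount = NA_real_)
}

singleChain <- function(T, label = "background") chainFor(label, list(T))

# random context on one chromosome with up to maxClasses classes
randomContext <- function(L, maxClasses = 3, chrom = "chr1") {
    nc <- sample(seq_len(maxClasses), 1L)
    starts <- if (nc == 1) 0 else c(0, sort(sample(seq_len(L - 1), nc - 1)))
    GenomeContext(setNames(list(list(start = starts,
                                     label = paste0("c", seq_along(starts)))),
                           chrom),
                  setNames(L, chrom))
}

# random valid reference with at most maxIv intervals (possibly fewer)
randomReference <- function(L, maxIv = 3, chrom = "chr1") {
    nr <- sample(seq_len(maxIv), 1L)
    pos <- sort(sample(0:L, min(2 * nr, L + 1)))
    iv <- matrix(pos[seq_len(2 * (length(pos) %/% 2))], ncol = 2, byrow = TRUE)
    iv <- iv[iv[, 2] > iv[, 1], , drop = FALSE]
    if (nrow(iv) > 1) {
        keep <- c(TRUE, iv[-1, 1] > iv[-nrow(iv), 2])
        iv <- iv[keep, , drop = FALSE]
    }
    Annotation(setNames(list(iv), chrom), setNames(L, chrom))
}

# a full random tiny instance; retries until the reference is non-empty
randomSmallInstance <- function(Lrange = 6:14, maxClasses = 3, maxIv = 3) {
    repeat {
        L <- sample(Lrange, 1L)
        R <- randomReference(L, maxIv)
        if (intervalCount(R) > 0) break
    }
    ctx <- randomContext(L, maxClasses)
    list(L = L, ctx = ctx, R = R,
         chain = chainFor(contextLabels(ctx)))
}

tmpBed <- function(lines) {
    f <- tempfile(fileext = ".bed")
    writeLines(lines, f)
    f
}
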