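test_that("training counts match manual transition enumeration", {
    ## L=5, Q=[1,3): states 0,1,1,0,0 -> pairs (0,1),(1,1),(1,0),(0,0),
    ## one each + pseudocount 1 = all counts 2
    q <- Annotation(list(chr1 = cbind(1, 3)), c(chr1 = 5))
    ch <- trainChain(q)
    expect_equal(trainingCounts(ch)$background, matrix(2, 2, 2))
    expect_equal(transitionMatrices(ch)$background, matrix(0.5, 2, 2))

    ## L=3, empty query: two (0,0) pairs + pseudocounts
    ch2 <- trainChain(Annotation(list(), c(chr1 = 3)))
    expect_equal(trainingCounts(ch2)$background,
                 rbind(c(3, 1), c(1, 1)))
    expect_equal(transitionMatrices(ch2)$background,
                 rbind(c(3 / 4, 1 / 4), c(1 / 2, 1 / 2)))

    ## per-class attribution: pair (Q_{i-1}, Q_i) belongs to the class of i
    ctx <- GenomeContext(list(chr1 = list(start = c(0, 2), label = c("A", "B"))),
                         c(chr1 = 4))
    ch3 <- trainChain(Annotation(list(chr1 = cbind(2, 4)), c(chr1 = 4)), ctx)
    expect_equal(transitionMatrices(ch3)$A,
                 rbind(c(2 / 3, 1 / 3), c(1 / 2, 1 / 2)))
    expect_equal(transitionMatrices(ch3)$B,
                 rbind(c(1 / 3, 2 / 3), c(1 / 3, 2 / 3)))
})

test_that("run-length training equals position-by-position counting", {
    set.seed(21)
    for (i in 1:20) {
        L <- sample(20:80, 1)
        ctx <- randomContext(L, maxClasses = 3)
        Q <- randomReference(L, maxIv = 4)
        ch <- trainChain(Q, ctx)
        ## naive oracle: expand states and labels, count pairs
        states <- numeric(L)
        iv <- Q@ranges$chr1
        for (k in seq_len(nrow(iv))) states[(iv[k, 1] + 1):iv[k, 2]] <- 1
        r <- ctx@runs$chr1
        labs <- rep(r$label, diff(c(r$start, L)))
        cnt <- lapply(setNames(nm = contextLabels(ctx)),
                      function(l) matrix(1, 2, 2))
        for (i2 in 2:L) {
            l <- labs[i2]
            s <- states[i2 - 1] + 1; s2 <- states[i2] + 1
            cnt[[l]][s, s2] <- cnt[[l]][s, s2] + 1
        }
        expect_equal(trainingCounts(ch), cnt)
    }
})

test_that("trained chains are pooled across chromosomes", {
    sl <- c(chr1 = 5, chr2 = 5)
    q <- Annotation(list(chr1 = cbind(1, 3), chr2 = cbind(1, 3)), sl)
    ch <- trainChain(q)
    expect_equal(trainingCounts(ch)$background, matrix(3, 2, 2))
    expect_error(trainChain(q, uniformContext(c(chr1 = 5, chr2 = 6))),
                 "disagree")
})

test_that("stationary distribution follows the closed form", {
    expect_equal(stationaryDistribution(rbind(c(0.9, 0.1), c(0.5, 0.5))),
                 c(5 / 6, 1 / 6))
    expect_equal(stationaryDistribution(matrix(0.5, 2, 2)), c(0.5, 0.5))
    expect_equal(stationaryDistribution(diag(2)), c(1, 0))
    ## fixed point
    set.seed(22)
    for (i in 1:25) {
        T <- randomT(0.01, 0.99)
        pi <- stationaryDistribution(T)
        expect_equal(as.numeric(pi %*% T), pi, tolerance = 1e-12)
        expect_equal(sum(pi), 1, tolerance = 1e-12)
    }
})

test_that("n-step closed form equals the matrix power and is a semigroup", {
    expect_equal(nStepMatrix(randomT(), 0), diag(2))
    T <- rbind(c(0.8, 0.2), c(0.3, 0.7))
    expect_equal(nStepMatrix(T, 2), T %*% T, tolerance = 1e-12)
    Ts <- matrix(0.5, 2, 2)
    expect_equal(nStepMatrix(Ts, 7), Ts)
    set.seed(23)
    for (i in 1:20) {
        T <- randomT(0.01, 0.99)
        m <- sample(0:1e6, 1); n <- sample(0:1e6, 1)
        expect_equal(nStepMatrix(T, m + n),
                     nStepMatrix(T, m) %*% nStepMatrix(T, n),
                     tolerance = 1e-10)
        ## direct 8-fold product
        P <- Reduce(`%*%`, rep(list(T), 8))
        expect_equal(nStepMatrix(T, 8), P, tolerance = 1e-12)
    }
})

test_that("all-zero stretch probability is T_x0 * T00^(n-1)", {
    T <- rbind(c(0.8, 0.2), c(0.3, 0.7))
    expect_equal(allZeroProbability(T, 0, 2), 0.64)
    expect_equal(allZeroProbability(T, 1, 1), 0.3)
    T0 <- rbind(c(0, 1), c(0.5, 0.5))
    expect_equal(allZeroProbability(T0, 0, 2), 0)
})

test_that("sampling is deterministic given the seed and leaves the RNG alone", {
    ctx <- uniformContext(c(chr1 = 2000))
    ch <- singleChain(rbind(c(0.97, 0.03), c(0.3, 0.7)))
    set.seed(99); before <- runif(1)
    a1 <- sampleAnnotation(ch, ctx, seed = 5)
    a2 <- sampleAnnotation(ch, ctx, seed = 5)
    expect_identical(a1@ranges, a2@ranges)
    a3 <- sampleAnnotation(ch, ctx, seed = 6)
    expect_false(identical(a1@ranges, a3@ranges))
    set.seed(99); expect_identical(runif(1), before)
    expect_error(sampleAnnotation(ch, randomContext(100), seed = 1),
                 "no transition matrix")
})

test_that("sampled state frequencies match the chain", {
    ## single class: coverage ~ pi_1; pair frequencies ~ T entries
    T <- rbind(c(0.99, 0.01), c(0.5, 0.5))
    pi1 <- stationaryDistribution(T)[2]
    L <- 1e6
    ctx <- uniformContext(c(chr1 = L))
    a <- sampleAnnotation(singleChain(T), ctx, seed = 31)
    cov <- coveredBases(a) / L
    tol <- 5 * 3 * sqrt(pi1 * (1 - pi1) / L)  # correlation-inflated
    expect_lt(abs(cov - pi1), tol)
    ## transition frequencies via retraining without pseudocount
    ch <- trainChain(a, ctx, pseudocount = 0)
    Themp <- transitionMatrices(ch)$background
    expect_lt(max(abs(Themp - T) / T), 0.05)
})

test_that("multi-class sampling respects each class' chain", {
    L <- 4e5
    ctx <- GenomeContext(list(chr1 = list(start = c(0, 2e5),
                                          label = c("A", "B"))),
                         c(chr1 = L))
    TA <- rbind(c(0.995, 0.005), c(0.05, 0.95))   # dense cover in A
    TB <- rbind(c(0.999, 0.001), c(0.5, 0.5))     # sparse in B
    a <- sampleAnnotation(chainFor(c("A", "B"), list(TA, TB)), ctx, seed = 8)
    ch <- trainChain(a, ctx, pseudocount = 0)
    expect_lt(max(abs(transitionMatrices(ch)$A - TA) / TA), 0.12)
    expect_lt(max(abs(transitionMatrices(ch)$B - TB) / TB), 0.12)
})

test_that("chain tables round-trip through the plain-text format", {
    q <- synthAnnotation(5000, 30, 40, seed = 2)
    ctx <- GenomeContext(list(chr1 = list(start = c(0, 2500),
                                          label = c("A", "B"))),
                         c(chr1 = 5000))
    ch <- trainChain(q, ctx)
    f <- tempfile(fileext = ".tsv")
    writeChain(ch, f)
    ch2 <- readChain(f)
    expect_equal(transitionMatrices(ch2), transitionMatrices(ch))
    expect_equal(trainingCounts(ch2), trainingCounts(ch))
    expect_equal(ch2@pseudocount, 1)
})
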