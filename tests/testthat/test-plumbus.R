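chainT <- function(T) singleChain(T)
uctx <- function(L) uniformContext(c(chr1 = L))

test_that("gap summaries propagate boundary states and contribute nothing", {
    T <- rbind(c(0.8, 0.2), c(0.3, 0.7))
    ch <- chainT(T)
    ctx <- uctx(100)
    p0 <- gapPlumbus(ch, ctx, "chr1", 10, 10)
    expect_equal(p0@psi, diag(2))
    expect_equal(p0@mu, matrix(0, 2, 2))

    pn <- gapPlumbus(ch, ctx, "chr1", 10, 17)
    expect_equal(pn@psi, nStepMatrix(T, 7), tolerance = 1e-12)
    expect_equal(pn@var, matrix(0, 2, 2))

    ## two class runs: product of the per-class powers
    ctx2 <- GenomeContext(list(chr1 = list(start = c(0, 12),
                                           label = c("A", "B"))),
                          c(chr1 = 100))
    TB <- rbind(c(0.6, 0.4), c(0.2, 0.8))
    ch2 <- chainFor(c("A", "B"), list(T, TB))
    g <- gapPlumbus(ch2, ctx2, "chr1", 10, 15)
    expect_equal(g@psi, (T %*% T) %*% (TB %*% TB %*% TB), tolerance = 1e-12)
})

test_that("overlap summary matches the direct conditional computation", {
    T <- rbind(c(0.8, 0.2), c(0.3, 0.7))
    ch <- chainT(T)
    ctx <- uctx(100)
    ## length-1 interval: mu(x,y) = y, psi = T
    p1 <- overlapPlumbus(ch, ctx, "chr1", 5, 6)
    expect_equal(p1@mu[, 2], c(1, 1))
    expect_equal(p1@mu[, 1], c(0, 0))
    expect_equal(p1@var, matrix(0, 2, 2))
    expect_equal(p1@psi, T)
    ## length-2, x=0, y=0: z = 0.64, psi(0->0) = 0.70
    p2 <- overlapPlumbus(ch, ctx, "chr1", 5, 7)
    expect_equal(p2@mu[1, 1], 1 - 0.64 / 0.70, tolerance = 1e-10)
    expect_equal(p2@var[1, 1], (1 - 0.64 / 0.70) * (0.64 / 0.70),
                 tolerance = 1e-10)
    expect_equal(p2@mu[, 2], c(1, 1))
})

test_that("bases summary equals the fold of single-position summaries", {
    set.seed(33)
    T <- randomT()
    ch <- chainT(T)
    ctx <- uctx(100)
    p1 <- basesPlumbus(ch, ctx, "chr1", 10, 11)
    expect_equal(p1@mu, rbind(c(0, 1), c(0, 1)))
    expect_equal(p1@psi, T)
    ## length-5 via doubling equals the 5-fold left fold of length-1 pieces
    p5 <- basesPlumbus(ch, ctx, "chr1", 10, 15)
    acc <- p1
    for (k in 1:4) {
        nxt <- basesPlumbus(ch, ctx, "chr1", 10 + k, 11 + k)
        acc <- combinePlumbus(acc, nxt)
    }
    expect_equal(p5@mu, acc@mu, tolerance = 1e-10)
    expect_equal(p5@var, acc@var, tolerance = 1e-10)
    expect_equal(p5@psi, acc@psi, tolerance = 1e-10)
    ## and combine(P4, P1) gives the same values
    p4 <- basesPlumbus(ch, ctx, "chr1", 10, 14)
    alt <- combinePlumbus(p4, basesPlumbus(ch, ctx, "chr1", 14, 15))
    expect_equal(p5@mu, alt@mu, tolerance = 1e-10)
    expect_equal(p5@var, alt@var, tolerance = 1e-10)
})

test_that("length-2 bases summary matches exhaustive two-state enumeration", {
    set.seed(34)
    T <- randomT()
    ch <- chainT(T)
    p <- basesPlumbus(ch, uctx(50), "chr1", 3, 5)
    ## enumerate the inner pair (s_3, s_4) given s_2 = x, condition on s_4 = y
    for (x in 0:1) for (y in 0:1) {
        pr <- T[x + 1, ] * T[, y + 1]          # over s_3
        vals <- c(0, 1) + y                    # contribution s_3 + s_4
        tot <- sum(pr)
        m <- sum(pr * vals) / tot
        v <- sum(pr * vals^2) / tot - m^2
        expect_equal(p@psi[x + 1, y + 1], tot, tolerance = 1e-12)
        expect_equal(p@mu[x + 1, y + 1], m, tolerance = 1e-12)
        expect_equal(p@var[x + 1, y + 1], v, tolerance = 1e-12)
    }
})

test_that("combine has the gap identity and is associative", {
    set.seed(35)
    ctx <- uctx(100)
    for (i in 1:10) {
        ch <- chainT(randomT())
        P <- basesPlumbus(ch, ctx, "chr1", 10, 14)
        idL <- gapPlumbus(ch, ctx, "chr1", 10, 10)
        expect_equal(combinePlumbus(idL, P)@mu, P@mu, tolerance = 1e-12)
        expect_equal(combinePlumbus(idL, P)@var, P@var, tolerance = 1e-12)
        P1 <- basesPlumbus(ch, ctx, "chr1", 10, 12)
        P2 <- overlapPlumbus(ch, ctx, "chr1", 12, 15)
        P3 <- gapPlumbus(ch, ctx, "chr1", 15, 20)
        a <- combinePlumbus(combinePlumbus(P1, P2), P3)
        b <- combinePlumbus(P1, combinePlumbus(P2, P3))
        expect_equal(a@mu, b@mu, tolerance = 1e-10)
        expect_equal(a@var, b@var, tolerance = 1e-10)
        expect_equal(a@psi, b@psi, tolerance = 1e-10)
    }
    expect_error(combinePlumbus(gapPlumbus(chainT(randomT()), ctx, "chr1", 0, 5),
                                gapPlumbus(chainT(randomT()), ctx, "chr1", 6, 8)),
                 "abut")
})

test_that("finalize recovers the stationary Bernoulli on one position", {
    T <- rbind(c(0.9, 0.1), c(0.5, 0.5))     # pi = (5/6, 1/6)
    ch <- chainT(T)
    ctx <- uctx(1)
    p <- basesPlumbus(ch, ctx, "chr1", 0, 1)
    mv <- finalizePlumbus(p, stationaryDistribution(T))
    expect_equal(mv[["mean"]], 1 / 6, tolerance = 1e-12)
    expect_equal(mv[["variance"]], 5 / 36, tolerance = 1e-12)
    ## constant summary has zero variance
    g <- gapPlumbus(ch, uctx(10), "chr1", 0, 10)
    mv0 <- finalizePlumbus(g, stationaryDistribution(T))
    expect_equal(mv0[["variance"]], 0)
    expect_error(finalizePlumbus(g, c(0.5, 0.6)), "summing to 1")
})

test_that("moments match brute-force enumeration on random tiny instances", {
    set.seed(36)
    for (i in 1:40) {
        inst <- randomSmallInstance()
        for (stat in c("overlaps", "bases")) {
            bf <- bruteForcePmf(inst$chain, inst$ctx, inst$R, stat)
            mom <- nullMoments(inst$chain, inst$ctx, inst$R, stat)
            expect_equal(mom@mean, pmfMean(bf), tolerance = 1e-9)
            expect_equal(mom@variance, pmfVariance(bf), tolerance = 1e-9)
            expect_gte(mom@variance, 0)
        }
    }
})

test_that("a fully covered chromosome at stationarity has mean L * pi1", {
    ## single class: every position is marginally Bernoulli(pi1)
    T <- rbind(c(0.9, 0.1), c(0.5, 0.5))
    ch <- chainT(T)
    ctx <- uctx(10)
    R <- Annotation(list(chr1 = cbind(0, 10)), c(chr1 = 10))
    mom <- nullMoments(ch, ctx, R, "bases")
    expect_equal(mom@mean, 10 / 6, tolerance = 1e-10)
})

test_that("genome moments are sums over independent chromosomes", {
    q <- synthAnnotation(3000, 20, 30, seed = 4)
    iv <- q@ranges$chr1
    two <- Annotation(list(chrA = iv, chrB = iv), c(chrA = 3000, chrB = 3000))
    ctxTwo <- uniformContext(c(chrA = 3000, chrB = 3000))
    rv <- synthAnnotation(3000, 10, 25, seed = 5)@ranges$chr1
    Rtwo <- Annotation(list(chrA = rv, chrB = rv), c(chrA = 3000, chrB = 3000))
    ch <- trainChain(two, ctxTwo)
    one <- Annotation(list(chrA = iv), c(chrA = 3000))
    Rone <- Annotation(list(chrA = rv), c(chrA = 3000))
    chOne <- trainChain(one)
    for (stat in c("overlaps", "bases")) {
        m2 <- nullMoments(ch, ctxTwo, Rtwo, stat)
        m1 <- nullMoments(chOne, uniformContext(c(chrA = 3000)), Rone, stat)
        ## the pooled chain differs slightly from the single-chromosome one,
        ## so compare doubling within the two-chromosome run itself
        expect_equal(m2@mean, 2 * m2@perChromosome$mean[1], tolerance = 1e-12)
        expect_equal(m2@variance, 2 * m2@perChromosome$variance[1],
                     tolerance = 1e-12)
        expect_equal(m2@perChromosome$mean[1], m2@perChromosome$mean[2])
    }
})

test_that("empty references yield zero moments", {
    ch <- chainT(randomT())
    mom <- nullMoments(ch, uctx(100), Annotation(list(), c(chr1 = 100)),
                       "overlaps")
    expect_equal(mom@mean, 0)
    expect_equal(mom@variance, 0)
})

test_that("combine-call counts scale with |R| (+ class boundaries)", {
    q <- synthAnnotation(2e5, 200, 100, seed = 6)
    ch <- trainChain(q)
    ctx <- uniformContext(c(chr1 = 2e5))
    counts <- vapply(c(50, 100, 200, 400), function(nr) {
        R <- synthAnnotation(2e5, nr, 100, seed = nr)
        nullMoments(ch, ctx, R, "overlaps")@combineCalls
    }, 0)
    ## doubling |R| should about double the combine count
    ratios <- counts[-1] / counts[-length(counts)]
    expect_true(all(ratios > 1.8 & ratios < 2.2))
})
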