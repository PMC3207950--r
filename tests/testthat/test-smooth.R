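test_that("tricube kernel takes its defining values", {
    sp <- KernelSpec(1, "tricube", "cM")
    w <- tricubeWeights(c(0, 0.5, 1), sp, normalize = FALSE)
    expect_equal(w, c(1, (1 - 0.5^3)^3, 0))
    expect_equal(w[2], 0.669921875)
    expect_error(tricubeWeights(c(0, 1.5), sp), "within the window")
})

test_that("normalized weights sum to one at every focal site", {
    set.seed(21)
    pos <- sort(runif(200, 0, 100))
    for (shape in c("tricube", "rectangular")) {
        sp <- KernelSpec(7, shape, "cM")
        ss <- kernelWeightSumsq(pos, sp)
        expect_true(all(ss > 0 & ss <= 1))
        # direct check on explicit windows (no reflection)
        i <- 100
        d <- pos[abs(pos - pos[i]) <= 7] - pos[i]
        expect_equal(sum(tricubeWeights(d, sp)), 1, tolerance = 1e-12)
    }
})

test_that("smoothing a constant is the identity, including at edges", {
    pos <- seq(0, 10, by = 0.25)
    g <- rep(3.7, length(pos))
    sp <- KernelSpec(2, "tricube", "cM")
    expect_equal(smoothGprime(pos, sp, g = g), g, tolerance = 1e-12)
})

test_that("degenerate windows return the raw statistic", {
    pos <- c(0, 10, 20, 30)
    g <- c(1, 5, 2, 8)
    sp <- KernelSpec(4, "rectangular", "cM")  # below inter-site spacing
    expect_equal(smoothGprime(pos, sp, g = g), g)
    expect_equal(kernelWeightSumsq(pos, sp), rep(1, 4))
})

test_that("rectangular kernel over 5 sites averages them", {
    pos <- 1:5
    g <- c(0, 0, 8, 0, 0)
    sp <- KernelSpec(2.4, "rectangular", "cM")
    gp <- smoothGprime(pos, sp, g = g, reflect = FALSE)
    expect_equal(gp[3], 1.6)
    # sum of squared weights: 1/m for m equally weighted sites
    sp20 <- KernelSpec(20.5, "rectangular", "cM")
    ss <- kernelWeightSumsq(as.numeric(1:20), sp20, reflect = FALSE)
    expect_equal(ss[10], 0.05)
})

test_that("tricube sum of squared weights exceeds the rectangular bound", {
    pos <- seq(-1, 1, by = 0.1)  # 21 sites spanning the window
    sp <- KernelSpec(1.000001, "tricube", "cM")
    ss <- kernelWeightSumsq(pos, sp, reflect = FALSE)
    mid <- 11
    # brute-force oracle: square and sum the normalized weight vector
    w <- (1 - abs(pos)^3)^3
    w <- w / sum(w)
    expect_equal(ss[mid], sum(w^2), tolerance = 1e-5)
    expect_gt(ss[mid], 1 / 21)
    expect_lt(ss[mid], 1)
})

test_that("G' is a convex combination of in-window G values", {
    set.seed(22)
    pos <- sort(runif(300, 0, 50))
    g <- rchisq(300, df = 1)
    sp <- KernelSpec(3, "tricube", "cM")
    gp <- smoothGprime(pos, sp, g = g)
    for (i in c(1, 50, 150, 300)) {
        win <- abs(pos - pos[i]) <= 3
        expect_gte(gp[i], min(g[win]) - 1e-12)
        expect_lte(gp[i], max(g[win]) + 1e-12)
    }
})

test_that("smoothing white noise shrinks variance by about sum k^2", {
    set.seed(23)
    pos <- seq_len(4000)
    g <- rchisq(length(pos), df = 1)
    sp <- KernelSpec(10, "tricube", "cM")
    gp <- smoothGprime(pos, sp, g = g)
    ss <- kernelWeightSumsq(pos, sp)
    interior <- 100:3900
    ratio <- var(gp[interior]) / var(g)
    expect_equal(ratio, mean(ss[interior]), tolerance = 0.15)
})

test_that("chromosomes are smoothed independently", {
    pos <- c(1:10, 1:10)
    chrom <- rep(c("a", "b"), each = 10)
    g <- c(rep(0, 10), rep(6, 10))
    sp <- KernelSpec(5, "tricube", "cM")
    gp <- smoothGprime(pos, sp, g = g, chrom = chrom)
    expect_equal(gp, c(rep(0, 10), rep(6, 10)))
})

test_that("unsorted positions within a chromosome are rejected", {
    sp <- KernelSpec(5, "tricube", "cM")
    expect_error(smoothGprime(c(3, 1, 2), sp, g = c(1, 2, 3)), "sorted")
})

test_that("matrix fast path agrees with the windowed smoother", {
    set.seed(24)
    pos <- seq(0, 10, by = 0.5)
    g <- rchisq(length(pos), df = 1)
    sp <- KernelSpec(3, "tricube", "cM")
    K <- gprimescan:::.kernelMatrix(pos, sp)
    expect_equal(as.vector(K %*% g), smoothGprime(pos, sp, g = g),
                 tolerance = 1e-12)
})

test_that("bandwidth recommendations follow the matched-filter guidance", {
    sp <- recommendBandwidth("single_peak", cmPerKb = 0.3)
    expect_equal(sp@halfWidth, 50000)          # 100 kb full width per 30 cM
    sp2 <- recommendBandwidth("single_peak", cmPerKb = 0.6)
    expect_equal(sp2@halfWidth, sp@halfWidth / 2)
    spNarrow <- recommendBandwidth("resolve_adjacent_peaks", cmPerKb = 0.3)
    expect_lt(spNarrow@halfWidth, sp@halfWidth)
    expect_error(recommendBandwidth("single_peak", cmPerKb = 0), "positive")
})

test_that("expected G' profile peaks at the QTL and decays to the null", {
    prof <- expectedGprimeProfile(0.5, 1.0, coverage = 50,
                                  effectiveAlleles = 300,
                                  distancesCm = c(0, 1, 5, 10, 30, 500))
    eg <- prof$profile$expectedG
    expect_equal(which.max(eg), 1)
    expect_true(all(diff(eg) < 0))
    # free recombination: the profile approaches the null expectation of G
    expect_equal(eg[length(eg)], 1 + 50 / 300, tolerance = 0.01)
    # half-width at half-maximum is a finite, positive map distance
    expect_gt(prof$hwhmCm, 5)
    expect_lt(prof$hwhmCm, 25)
    expect_error(expectedGprimeProfile(-0.1, 0.5), "frequencies")
})
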