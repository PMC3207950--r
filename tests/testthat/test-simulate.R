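test_that("truncation-selection theory reproduces the reference triple", {
    # standardized effect 0.1 at p0 = 0.5, truncating the top 20%, 10%, 1%
    dp <- vapply(c(0.20, 0.10, 0.01), function(f)
        unname(truncationSelectionTheory(0.1, 0.5, f)["expectedDp"]),
        numeric(1))
    expect_equal(100 * dp, c(3.5, 4.4, 6.7), tolerance = 0.015)
    expect_error(truncationSelectionTheory(0.1, 0.5, 0), "selectedFraction")
    expect_error(truncationSelectionTheory(0.1, 1.5, 0.1), "p0")
})

test_that("selection intensity grows far slower than 1/fraction", {
    i <- function(f) unname(truncationSelectionTheory(1, 0.5, f)[1])
    expect_gt(i(0.01), i(0.1))
    expect_gt(i(0.1), i(0.2))
    expect_lt(i(0.01) / i(0.2), 20 / 5)     # 20x stronger truncation, << 20x i
    # no selection limit: intensity (and dp) vanish
    expect_lt(i(0.9999), 0.01)
})

test_that("null simulations have frequency 0.5 at every marker", {
    set.seed(71)
    d <- SimDesign(popSize = 200, bulkSize = 30, coverage = 20,
                   snpDensity = 2, qtlEffect = 0)
    sim <- gprimescan:::.simulateCounts(d, 300)
    expect_equal(mean(sim$freqLow), 0.5, tolerance = 0.01)
    expect_equal(mean(sim$freqHigh), 0.5, tolerance = 0.01)
    mm <- colMeans(rbind(sim$freqLow, sim$freqHigh))
    expect_lt(max(abs(mm - 0.5)), 3 * sqrt(0.25 / (60 * 600)) * 4)
})

test_that("read depth per site and bulk is Poisson with mean C", {
    set.seed(72)
    d <- SimDesign(popSize = 200, bulkSize = 30, coverage = 25,
                   snpDensity = 2, qtlEffect = 0)
    sim <- gprimescan:::.simulateCounts(d, 200)
    depth <- as.vector(sim$nHiLow + sim$nLoLow)
    expect_equal(mean(depth), 25, tolerance = 0.02)
    # total of two independent Poissons at C p and C (1 - p): variance C
    expect_equal(var(depth), 25, tolerance = 0.1)
})

test_that("fixed seeds reproduce scans bit-identically", {
    d <- SimDesign(popSize = 100, bulkSize = 15, coverage = 20,
                   snpDensity = 4, qtlEffect = 0.8)
    a <- simulateF2Bulks(d, seed = 99)
    b <- simulateF2Bulks(d, seed = 99)
    expect_identical(alleleCounts(a$counts), alleleCounts(b$counts))
    expect_identical(a$freqHigh, b$freqHigh)
})

test_that("realized selection response matches i p q alpha", {
    set.seed(73)
    delta <- 0.3
    d <- SimDesign(popSize = 400, bulkSize = 40, coverage = 20,
                   snpDensity = 1, qtlEffect = delta)
    sim <- gprimescan:::.simulateCounts(d, 500)
    dpH <- sim$freqHigh[, sim$qtlIndex] - 0.5
    alpha <- (delta / 2) / sqrt(1 + delta^2 / 8)
    th <- truncationSelectionTheory(alpha, 0.5, 40 / 400)["expectedDp"]
    se <- sd(dpH) / sqrt(length(dpH))
    expect_lt(abs(mean(dpH) - th), 3 * se + 0.05 * th)
    # low bulk moves the opposite way by symmetry
    expect_lt(mean(sim$freqLow[, sim$qtlIndex]), 0.5)
})

test_that("linkage to the QTL decays with map distance in selected bulks", {
    set.seed(74)
    d <- SimDesign(popSize = 300, bulkSize = 40, coverage = 20,
                   snpDensity = 1, qtlEffect = 1.5)
    sim <- gprimescan:::.simulateCounts(d, 400)
    dp <- colMeans(sim$freqHigh) - 0.5
    qi <- sim$qtlIndex
    offsets <- c(0, 2, 5)  # markers at 0, 2, 5 cM from the QTL
    resp <- dp[qi + offsets]
    expect_true(all(diff(resp) < 0))
    # and the decay tracks the Haldane linkage coefficient
    expect_equal(resp[2] / resp[1], 1 - 2 * cmToRecomb(2), tolerance = 0.15)
})

test_that("homozygous designs halve the effective allele count", {
    expect_equal(SimDesign(homozygous = TRUE)@effectiveAlleles, 150)
    expect_equal(SimDesign()@effectiveAlleles, 300)
    set.seed(75)
    dHom <- SimDesign(popSize = 400, bulkSize = 60, coverage = 1000,
                      snpDensity = 1, qtlEffect = 0, homozygous = TRUE)
    dDip <- SimDesign(popSize = 400, bulkSize = 60, coverage = 1000,
                      snpDensity = 1, qtlEffect = 0)
    vHom <- var(gprimescan:::.simulateCounts(dHom, 600)$freqHigh[, 1])
    vDip <- var(gprimescan:::.simulateCounts(dDip, 600)$freqHigh[, 1])
    # binomial bulk variance p q / a: a = n vs 2n
    expect_equal(vHom / vDip, 2, tolerance = 0.3)
})

test_that("simulateF2Bulks returns a valid counts table with ground truth", {
    s <- simulateF2Bulks(SimDesign(popSize = 200, bulkSize = 30,
                                   coverage = 30, snpDensity = 4,
                                   qtlEffect = 1), seed = 7)
    expect_s4_class(s$counts, "BsaCounts")
    expect_true(validObject(s$counts))
    expect_equal(s$posCm[s$qtlIndex], 5)
    expect_equal(length(s$freqHigh), length(s$posCm))
    # simulated coordinates: 1 cM = 1 kb, first site at bp 1
    gr <- siteRanges(s$counts)
    expect_equal(GenomicRanges::start(gr)[1], 1)
})

test_that("null calibration rejects non-null designs and runs end to end", {
    expect_error(runNullCalibration(SimDesign(qtlEffect = 1), refKernel(),
                                    reps = 2), "qtlEffect = 0")
    cal <- runNullCalibration(
        SimDesign(popSize = 200, bulkSize = 30, coverage = 25,
                  snpDensity = 4), KernelSpec(3, "tricube", "cM"),
        reps = 60, seed = 5, robust = FALSE)
    expect_equal(length(cal$gFocal), 60)
    expect_true(all(cal$rates$naive >= 0 & cal$rates$naive <= 1))
    expect_gt(cal$momentsG["mean"], 0.5)
})

test_that("power increases with coverage up to the allele count", {
    set.seed(76)
    delta <- qtlEffectForVariance(0.05)
    designs <- lapply(c(5, 40), function(C)
        SimDesign(popSize = 300, bulkSize = 45, coverage = C,
                  snpDensity = 2, qtlEffect = delta))
    pw <- runPower(designs, KernelSpec(3, "tricube", "cM"), reps = 150)
    expect_gt(pw$powerGprime.0.05[2], pw$powerGprime.0.05[1])
    expect_gt(pw$meanGprime[2], pw$meanGprime[1])
    expect_error(runPower(list(), refKernel()), "empty")
})
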