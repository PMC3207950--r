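test_that("null moments of G converge on the chi-square values when C << a", {
    d <- BsaDesign(100000, 10000, 1)   # coverage tiny relative to 2n alleles
    m <- nullMomentsG(d)
    expect_equal(unname(m["mean"]), 1, tolerance = 1e-3)
    expect_equal(unname(m["var"]), 2, tolerance = 3e-3)
})

test_that("null moments of G match a two-level Monte-Carlo oracle", {
    # direct simulation of the hierarchical model: binomial bulk sampling of a
    # alleles, then independent Poisson counts at coverage C.  The closed
    # forms are leading-order approximations, so they are checked at their
    # accuracy scale (a few percent), not at Monte-Carlo precision.
    mcMoments <- function(a, C, p0 = 0.5, R = 2e5) {
        qL <- rbinom(R, a, p0) / a
        qH <- rbinom(R, a, p0) / a
        tab <- cbind(rpois(R, C * qL), rpois(R, C * (1 - qL)),
                     rpois(R, C * qH), rpois(R, C * (1 - qH)))
        ok <- (tab[, 1] + tab[, 2] > 0) & (tab[, 3] + tab[, 4] > 0)
        g <- gStatistic(tab[ok, ])
        c(mean(g), var(g))
    }
    set.seed(31)
    grid <- list(c(300, 50), c(200, 40), c(600, 60))
    for (ac in grid) {
        d <- BsaDesign(10 * ac[1], ac[1] / 2, ac[2])
        m <- nullMomentsG(d)
        mc <- mcMoments(ac[1], ac[2])
        expect_equal(unname(m["mean"]), mc[1], tolerance = 0.03)
        expect_equal(unname(m["var"]), mc[2], tolerance = 0.08)
    }
})

test_that("segregation distortion leaves the leading-order moments unchanged", {
    m5 <- nullMomentsG(BsaDesign(1000, 150, 50, p0 = 0.5))
    m3 <- nullMomentsG(BsaDesign(1000, 150, 50, p0 = 0.3))
    expect_equal(m5, m3)
    # and the Monte-Carlo oracle confirms the distorted null stays close
    set.seed(32)
    a <- 300; C <- 50; p0 <- 0.3; R <- 2e5
    qL <- rbinom(R, a, p0) / a; qH <- rbinom(R, a, p0) / a
    tab <- cbind(rpois(R, C * qL), rpois(R, C * (1 - qL)),
                 rpois(R, C * qH), rpois(R, C * (1 - qH)))
    ok <- (tab[, 1] + tab[, 2] > 0) & (tab[, 3] + tab[, 4] > 0)
    expect_equal(mean(gStatistic(tab[ok, ])), unname(m3["mean"]),
                 tolerance = 0.04)
})

test_that("moments are non-decreasing in coverage at fixed bulk size", {
    means <- vars <- numeric(0)
    for (C in c(10, 25, 50, 100, 200)) {
        m <- nullMomentsG(BsaDesign(1000, 150, C))
        means <- c(means, m["mean"]); vars <- c(vars, m["var"])
    }
    expect_true(all(diff(means) > 0))
    expect_true(all(diff(vars) > 0))
})

test_that("G' null moments: sequencing-only mode", {
    pos <- as.numeric(1:20)
    spec <- KernelSpec(20.5, "rectangular", "cM")
    nm <- nullMomentsGprime(BsaDesign(1000, 150, 50), pos, spec,
                            mode = "sequencing_only", reflect = FALSE)
    # rectangular kernel over m iid chi-square(1) terms: mean 1, var 2/m
    expect_equal(unname(nm[10, "mean"]), 1)
    expect_equal(unname(nm[10, "var"]), 2 / 20)
})

test_that("hierarchical G' variance dominates sequencing-only", {
    pos <- seq(0, 10, by = 0.25)
    spec <- KernelSpec(3, "tricube", "cM")
    d <- BsaDesign(1000, 150, 50)
    vh <- nullMomentsGprime(d, pos, spec)[, "var"]
    vs <- nullMomentsGprime(d, pos, spec, mode = "sequencing_only")[, "var"]
    expect_true(all(vh > vs))
    # E[G'] = E[G] since the weights sum to one
    expect_equal(unique(nullMomentsGprime(d, pos, spec)[, "mean"]),
                 unname(nullMomentsG(d)["mean"]))
})

test_that("linkage-decay refinement lowers the G' variance prediction", {
    pos <- seq(0, 10, by = 0.5)
    spec <- KernelSpec(2, "tricube", "cM")
    d <- BsaDesign(1000, 150, 50)
    v0 <- nullMomentsGprime(d, pos, spec)[, "var"]
    v1 <- nullMomentsGprime(d, pos, spec, linkageDecay = TRUE)[, "var"]
    interior <- pos > 2 & pos < 8   # reflection-free windows
    expect_true(all(v1[interior] < v0[interior]))
    expect_true(all(v1 > 0))
})

test_that("log-normal moment/parameter round trips hold to 1e-10", {
    set.seed(33)
    for (i in 1:50) {
        m <- runif(1, 0.5, 5); v <- runif(1, 0.001, 3)
        nm <- lognormalFromMoments(m, v)
        p <- lognormalParams(nm)
        expect_equal(exp(p["mu"] + p["sigma"]^2 / 2), m,
                     tolerance = 1e-10, ignore_attr = TRUE)
        expect_equal((exp(p["sigma"]^2) - 1) * exp(2 * p["mu"] + p["sigma"]^2),
                     v, tolerance = 1e-10, ignore_attr = TRUE)
    }
    # degenerate distribution
    nm0 <- lognormalFromMoments(3, 0)
    expect_equal(unname(lognormalParams(nm0)), c(log(3), 0))
    # direct evaluation at the reference moments
    p <- lognormalParams(lognormalFromMoments(1.17, 0.066))
    expect_equal(unname(p["mu"]), 0.1335, tolerance = 1e-3)
    expect_equal(unname(p["sigma"]), 0.2170, tolerance = 1e-3)
    expect_error(lognormalFromMoments(-1, 1), "positive")
})

test_that("log-normal sampling recovers the moments", {
    set.seed(34)
    nm <- lognormalFromMoments(1.6, 0.4)
    p <- lognormalParams(nm)
    x <- rlnorm(1e6, p["mu"], p["sigma"])
    expect_equal(mean(x), 1.6, tolerance = 3 * sd(x) / sqrt(1e6) / 1.6)
    expect_equal(var(x), 0.4, tolerance = 0.01)
})

test_that("log-normal p-values behave as an upper tail", {
    nm <- lognormalFromMoments(1.17, 0.066)
    p <- lognormalParams(nm)
    r <- pvaluesLognormal(c(exp(p["mu"]), exp(p["mu"] + p["sigma"]), 0), nm)
    expect_equal(r$pvalue[1], 0.5)
    expect_equal(r$zscore[1], 0)
    expect_equal(r$zscore[2], 1)
    expect_equal(r$pvalue[3], 1)
    # strictly decreasing in the value
    v <- seq(0.1, 5, by = 0.1)
    expect_true(all(diff(pvaluesLognormal(v, nm)$pvalue) < 0))
    # tail probability matches empirical exceedance of simulated deviates
    set.seed(35)
    x <- rlnorm(1e6, p["mu"], p["sigma"])
    thr <- 1.8
    emp <- mean(x > thr)
    expect_equal(pvaluesLognormal(thr, nm)$pvalue, emp,
                 tolerance = 3 * sqrt(emp * (1 - emp) / 1e6) / emp)
})

test_that("p-values are uniform under the fitted null", {
    set.seed(36)
    nm <- lognormalFromMoments(1.17, 0.066)
    p <- lognormalParams(nm)
    x <- rlnorm(1e5, p["mu"], p["sigma"])
    pv <- pvaluesLognormal(x, nm)$pvalue
    ks <- suppressWarnings(stats::ks.test(pv, "punif"))
    expect_gt(ks$p.value, 0.001)
})

test_that("NullModel validity enforces the moment identities", {
    expect_error(new("NullModel", meanG = 2, varG = 1, mu = 0, sigma = 1,
                     method = "x"), "inconsistent")
})
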