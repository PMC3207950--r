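# Independent oracles and shared fixtures for the test suite.

# Likelihood-ratio oracle for the 2x2 G statistic: twice the difference of
# multinomial log-likelihoods between the saturated model and the
# independence model, written directly from the definitions.
lrtOracle <- function(tab) {
    tot <- sum(tab)
    psat <- tab / tot
    r <- rowSums(tab) / tot
    cc <- colSums(tab) / tot
    pind <- outer(r, cc)
    ll <- function(p) sum(ifelse(tab == 0, 0, tab * log(p)))
    2 * (ll(psat) - ll(pind))
}

# random 2x2 allele-depth tables with positive bulk totals
randomTables <- function(n, lambda = 30) {
    m <- matrix(rpois(4 * n, lambda), n, 4)
    bad <- (m[, 1] + m[, 2] == 0) | (m[, 3] + m[, 4] == 0)
    m[bad, ] <- m[bad, ] + 1L
    m
}

# Monte-Carlo standard error of a sample variance
seVar <- function(x) {
    m4 <- mean((x - mean(x))^4)
    sqrt((m4 - var(x)^2) / length(x))
}

seProp <- function(p, n) sqrt(p * (1 - p) / n)

# Reference simulation conditions used by the calibration studies
refDesignNull <- function() SimDesign()
refDesignWeak <- function()
    SimDesign(qtlEffect = qtlEffectForVariance(0.02))
refKernel <- function() KernelSpec(5, "tricube", "cM", cmPerKb = 1)

# Shared, lazily computed simulation results for the acceptance tests
# (scaled-down replicate counts to stay within the test-time budget).
.acceptCache <- new.env(parent = emptyenv())

acceptNull <- function() {
    if (is.null(.acceptCache$null)) {
        .acceptCache$null <- runNullCalibration(
            refDesignNull(), refKernel(), reps = 1500,
            levels = c(0.05, 0.01), seed = 20260131, robust = TRUE)
    }
    .acceptCache$null
}

acceptWeak <- function() {
    if (is.null(.acceptCache$weak)) {
        .acceptCache$weak <- runPower(
            refDesignWeak(), refKernel(), reps = 400,
            levels = c(0.05, 0.01, 0.001), seed = 20260207)
    }
    .acceptCache$weak
}
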