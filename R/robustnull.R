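#' Hampel's outlier rule with the left MAD
#'
#' Flags observations exceeding median + g x (scaled left MAD).  The left
#' median absolute deviation is the median of |x - median(x)| taken over the
#' observations at or below the median only, multiplied by the normal
#' consistency constant 1.4826; using only the left half makes the spread
#' estimate insensitive to upper-tail contamination (QTL regions).  With
#' g = 5.2 and normally distributed data the rule is approximately a high-z
#' one-sided cut.  \code{side = "two_sided"} also flags observations below
#' median - g x spread.
#'
#' @param values numeric observations (log scale in the G' pipeline).
#' @param g outlier-limit constant (> 0), conventionally 5.2.
#' @param side \code{"upper"} (default, as used for G' scans) or
#'   \code{"two_sided"}.
#' @return logical mask, TRUE for outliers.
#' @export
hampelOutliers <- function(values, g = 5.2, side = c("upper", "two_sided")) {
    side <- match.arg(side)
    if (length(values) < 3) stop("need at least 3 observations")
    if (!is.finite(g) || g <= 0) stop("g must be positive")
    med <- median(values)
    spread <- leftMad(values)
    out <- values > med + g * spread
    if (side == "two_sided") out <- out | values < med - g * spread
    out
}

#' @describeIn hampelOutliers the scaled left MAD itself: 1.4826 x
#'   median(|x - median| : x <= median).
#' @export
leftMad <- function(values) {
    med <- median(values)
    1.4826 * median(med - values[values <= med])
}

#' Half-sample mode
#'
#' Robust mode estimator for continuous data by iterated shortest halves: at
#' each step the shortest interval containing ceiling(n/2) of the current
#' points is kept (the lower-indexed interval on ties), until three or fewer
#' points remain; the estimate is then the midpoint of the closest pair (or
#' the remaining point).  High breakdown and deterministic.
#'
#' @param x numeric vector.
#' @return the estimated mode.
#' @export
halfSampleMode <- function(x) {
    x <- sort(x[is.finite(x)])
    if (length(x) == 0) stop("no finite values")
    while (length(x) > 3) {
        n <- length(x)
        h <- ceiling(n / 2)
        width <- x[h:n] - x[seq_len(n - h + 1)]
        i <- which.min(width)           # lower-indexed shortest half on ties
        x <- x[i:(i + h - 1)]
    }
    if (length(x) == 3) {
        if (x[2] - x[1] <= x[3] - x[2]) mean(x[1:2]) else mean(x[2:3])
    } else mean(x)
}

# Kernel-density alternative mode estimator: argmax of a Gaussian KDE of the
# raw values; smoother than the HSM on small samples.
.kdeMode <- function(x) {
    d <- density(x)
    d$x[which.max(d$y)]
}

#' Robust non-parametric estimation of the G' null
#'
#' Estimates the log-normal null parameters from an observed genome-wide G'
#' vector assumed to be a mixture of the null (most sites) and right-shifted
#' contaminating components (QTL regions), in five steps: (1) take logs;
#' (2) compute the scaled left MAD of the logs (\code{\link{leftMad}}), a
#' spread estimate immune to the QTL tail; (3) flag upper outliers by Hampel's
#' rule with that spread (\code{\link{hampelOutliers}}, one-sided, g = 5.2);
#' (4) trim the flagged values; (5) estimate mu as the log of the median of the
#' trimmed (unlogged) values and sigma^2 from the log-normal identity
#' median/mode = exp(sigma^2), i.e. sigma^2 = ln(median) - ln(mode), with the
#' mode of the trimmed unlogged values estimated by the half-sample mode
#' (default) or a kernel-density mode.  Because the median of the contaminated
#' data lies at or right of the null median, the resulting estimates are
#' conservative.
#'
#' Zero G' values (possible on empty-ish windows) are dropped with a count
#' before taking logs.  If the mode estimate is not below the median (so the
#' identity gives sigma^2 <= 0, which happens routinely on short, strongly
#' autocorrelated scans where the sample carries little shape information),
#' the estimator falls back to the scaled left MAD of the trimmed logs as
#' sigma.  A sample in which all values are equal is un-estimable and raises
#' an error.
#'
#' @param gprime per-site G' values from a scan.
#' @param modeEstimator \code{"hsm"} (half-sample mode) or \code{"kde"}.
#' @param g Hampel constant for the trimming step.
#' @param minSites warn below this number of usable sites.
#' @return a \code{\link{NullModel}} with \code{method = "robust"}.
#' @export
estimateNullRobust <- function(gprime, modeEstimator = c("hsm", "kde"),
                               g = 5.2, minSites = 100) {
    modeEstimator <- match.arg(modeEstimator)
    nzero <- sum(gprime == 0, na.rm = TRUE)
    x <- gprime[is.finite(gprime) & gprime > 0]
    if (nzero > 0)
        message(nzero, " zero G' value(s) dropped before log transform")
    if (length(x) < 3) stop("too few usable sites to estimate a null")
    if (length(x) < minSites)
        warning("fewer than ", minSites,
                " sites: robust null estimate will be unstable")
    if (diff(range(x)) == 0)
        stop("degenerate input: all G' values equal; null not estimable")
    z <- log(x)
    keep <- !hampelOutliers(z, g = g, side = "upper")
    tr <- x[keep]
    mu <- log(median(tr))
    mode <- switch(modeEstimator, hsm = halfSampleMode(tr), kde = .kdeMode(tr))
    s2 <- mu - log(mode)
    if (!is.finite(s2) || s2 <= 0) {
        ztr <- log(tr)
        s2 <- leftMad(ztr)^2
    }
    if (!is.finite(s2) || s2 <= 0)
        stop("degenerate input: no usable spread; null not estimable")
    m <- exp(mu + s2 / 2)
    v <- (exp(s2) - 1) * exp(2 * mu + s2)
    new("NullModel", meanG = m, varG = v, mu = mu, sigma = sqrt(s2),
        method = "robust")
}
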