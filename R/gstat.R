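#' The G statistic on 2x2 allele-depth tables
#'
#' The likelihood-ratio goodness-of-fit statistic
#' \deqn{G = 2 \sum_{cells} O \, \ln(O / E)}
#' on the per-site 2x2 table of allele depths (rows: high/low-parent allele;
#' columns: low/high bulk), with expected counts from the usual independence
#' model, E = (row margin) x (column margin) / (grand total).  Under the
#' convention 0 ln 0 = 0, G >= 0, with G = 0 exactly when the observed allele
#' frequencies agree between bulks.  A site that is monomorphic across both
#' bulks (an allele-margin of zero) yields G = 0 rather than NaN, keeping scans
#' dense for smoothing.  No continuity or Williams correction is applied.
#'
#' @param x a \code{\link{BsaCounts}} object, or a numeric matrix/data.frame
#'   with columns \code{nHiLow, nLoLow, nHiHigh, nLoHigh} (one row per site).
#' @return numeric vector of per-site G values.
#' @examples
#' gStatistic(rbind(c(10, 10, 10, 10)))            # 0: equal frequencies
#' gStatistic(rbind(c(30, 10, 10, 30)))            # about 20.93
#' @export
setGeneric("gStatistic", function(x) standardGeneric("gStatistic"))

.gstat <- function(nHiLow, nLoLow, nHiHigh, nLoHigh) {
    cLow <- nHiLow + nLoLow
    cHigh <- nHiHigh + nLoHigh
    if (any(cLow == 0 | cHigh == 0))
        stop("zero total depth in a bulk: sites must be depth-filtered first")
    tot <- cLow + cHigh
    rHi <- nHiLow + nHiHigh
    rLo <- nLoLow + nLoHigh
    term <- function(o, e) {
        out <- o * log(o / e)
        out[o == 0] <- 0
        out
    }
    g <- 2 * (term(nHiLow, rHi * cLow / tot) +
              term(nLoLow, rLo * cLow / tot) +
              term(nHiHigh, rHi * cHigh / tot) +
              term(nLoHigh, rLo * cHigh / tot))
    g[rHi == 0 | rLo == 0] <- 0      # monomorphic across both bulks
    pmax(g, 0)                       # clip tiny negative rounding error
}

#' @rdname gStatistic
#' @export
setMethod("gStatistic", "BsaCounts", function(x) {
    cnt <- alleleCounts(x)
    .gstat(cnt[, 1], cnt[, 2], cnt[, 3], cnt[, 4])
})

#' @rdname gStatistic
#' @export
setMethod("gStatistic", "ANY", function(x) {
    m <- as.matrix(x)
    if (ncol(m) != 4) stop("expected 4 count columns")
    .gstat(m[, 1], m[, 2], m[, 3], m[, 4])
})

#' Observed bulk allele frequencies
#'
#' The observed frequency of the high-parent allele in each bulk:
#' p.Low = nHiLow / (nHiLow + nLoLow) and analogously p.High.
#'
#' @inheritParams gStatistic
#' @return a two-column matrix with columns \code{pLow}, \code{pHigh}.
#' @export
setGeneric("alleleFreqs", function(x) standardGeneric("alleleFreqs"))

.afreq <- function(m) {
    cLow <- m[, 1] + m[, 2]
    cHigh <- m[, 3] + m[, 4]
    if (any(cLow == 0 | cHigh == 0))
        stop("zero total depth in a bulk: sites must be depth-filtered first")
    cbind(pLow = m[, 1] / cLow, pHigh = m[, 3] / cHigh)
}

#' @rdname alleleFreqs
#' @export
setMethod("alleleFreqs", "BsaCounts", function(x) .afreq(alleleCounts(x)))

#' @rdname alleleFreqs
#' @export
setMethod("alleleFreqs", "ANY", function(x) .afreq(as.matrix(x)))
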