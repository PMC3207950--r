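#' Benjamini-Hochberg FDR control
#'
#' The step-up procedure at target FDR q: with sorted p-values p(1) <= ... <=
#' p(m), find the largest k with p(k) <= k q / m; all p-values up to p(k) are
#' significant.  q-values are the standard monotone-adjusted values (computed
#' with \code{stats::p.adjust}); the significance mask is computed by the
#' explicit step-up rule, which coincides with \code{qvalue <= q}.
#'
#' @param pvalues numeric p-values in [0, 1].
#' @param q target false discovery rate in (0, 1).
#' @return list with \code{qvalues} and logical \code{significant}.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.5), q = 0.05)$significant  # T T T F
#' @export
bhFdr <- function(pvalues, q = 0.01) {
    if (length(pvalues) == 0) stop("empty p-value vector")
    if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
        stop("p-values must lie in [0, 1]")
    if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
    m <- length(pvalues)
    o <- order(pvalues)
    ps <- pvalues[o]
    ok <- which(ps <= seq_len(m) * q / m)
    thr <- if (length(ok)) ps[max(ok)] else -Inf
    list(qvalues = p.adjust(pvalues, method = "BH"),
         significant = pvalues <= thr)
}

#' Call QTL regions from a significance mask
#'
#' Maximal runs of consecutive significant sites within a chromosome become
#' candidate QTL regions; a run is broken by any interleaved non-significant
#' site unless \code{maxGapSites > 0} allows that many to be bridged.  Each
#' region records its site count, and its peak: the position of the maximum G'
#' in the run (leftmost on ties), called as the QTL point estimate.
#'
#' @param chrom chromosome per site.
#' @param pos position per site (sorted within chromosome).
#' @param significant logical mask per site.
#' @param gprime per-site G' values.
#' @param maxGapSites non-significant sites tolerated inside a run (default 0).
#' @return a \code{GRanges}, one range per region spanning [start site, end
#'   site] (1-based inclusive), with metadata columns \code{nSites},
#'   \code{peakPos}, \code{peakGprime}.
#' @export
callRegions <- function(chrom, pos, significant, gprime, maxGapSites = 0) {
    stopifnot(length(chrom) == length(pos), length(pos) == length(significant),
              length(pos) == length(gprime))
    if (length(pos) == 0 || !any(significant))
        return(GenomicRanges::GRanges(nSites = integer(), peakPos = integer(),
                                      peakGprime = numeric()))
    out <- list()
    for (idx in split(seq_along(pos), factor(chrom, unique(chrom)))) {
        sig <- significant[idx]
        if (!any(sig)) next
        r <- rle(sig)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        keep <- r$values
        if (maxGapSites > 0 && sum(keep) > 1) {
            # merge significant runs separated by short non-significant gaps
            gap <- !r$values & r$lengths <= maxGapSites
            gap[1] <- gap[length(gap)] <- FALSE
            runs <- which(keep)
            merged <- list(c(starts[runs[1]], ends[runs[1]]))
            for (k in runs[-1]) {
                between <- seq(which(runs == k) - 1, which(runs == k) - 1)
                prev <- merged[[length(merged)]]
                gapidx <- which(starts > prev[2] & ends < starts[k])
                if (length(gapidx) && all(gap[gapidx]))
                    merged[[length(merged)]] <- c(prev[1], ends[k])
                else merged[[length(merged) + 1]] <- c(starts[k], ends[k])
            }
            spans <- merged
        } else {
            spans <- Map(c, starts[keep], ends[keep])
        }
        for (sp in spans) {
            ii <- idx[sp[1]:sp[2]]
            ii <- ii[significant[ii] | maxGapSites > 0]
            pk <- ii[which.max(gprime[ii])]   # leftmost maximum
            out[[length(out) + 1]] <- data.frame(
                chrom = chrom[ii[1]], start = pos[ii[1]],
                end = pos[ii[length(ii)]], nSites = sum(significant[ii]),
                peakPos = pos[pk], peakGprime = gprime[pk])
        }
    }
    df <- do.call(rbind, out)
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end))
    S4Vectors::mcols(gr)$nSites <- df$nSites
    S4Vectors::mcols(gr)$peakPos <- df$peakPos
    S4Vectors::mcols(gr)$peakGprime <- df$peakGprime
    gr
}
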