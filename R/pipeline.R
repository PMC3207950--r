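#' Run the full G' QTL scan pipeline
#'
#' Executes the recommended analysis in order: (1) per-site G from the allele
#' depths; (2) G' by kernel smoothing within each chromosome; (3) null model,
#' either the robust empirical estimate from the observed genome-wide G'
#' (default for real data) or the theoretical log-normal null from the
#' experimental design; (4) upper-tail log-normal p-values and z-scores;
#' (5) Benjamini-Hochberg FDR at target \code{fdr}; (6) candidate QTL regions
#' as maximal runs of significant sites, with their peaks.
#'
#' @param counts a \code{\link{BsaCounts}}.
#' @param spec a \code{\link{KernelSpec}} with \code{unit = "bp"} (positions
#'   of \code{counts} are physical); see \code{\link{recommendBandwidth}}.
#' @param nullMethod \code{"robust"} (default) or \code{"theoretical"}.
#' @param design a \code{\link{BsaDesign}}; required for the theoretical null.
#' @param fdr target false discovery rate (default 0.01).
#' @param maxGapSites gap tolerance for region calling (default 0).
#' @param modeEstimator mode estimator for the robust null.
#' @param verbose log effective configuration and progress via
#'   \code{message()}.
#' @return list with \code{scan} (data.frame: chrom, pos, pLow, pHigh, G,
#'   Gprime, pvalue, zscore, qvalue, significant), \code{regions}
#'   (\code{GRanges} from \code{\link{callRegions}}), \code{nullModel}, and
#'   \code{config} (the effective parameters).
#' @export
runGprimeScan <- function(counts, spec, nullMethod = c("robust",
                                                       "theoretical"),
                          design = NULL, fdr = 0.01, maxGapSites = 0,
                          modeEstimator = c("hsm", "kde"), verbose = TRUE) {
    stopifnot(is(counts, "BsaCounts"), is(spec, "KernelSpec"))
    nullMethod <- match.arg(nullMethod)
    modeEstimator <- match.arg(modeEstimator)
    gr <- siteRanges(counts)
    chrom <- as.character(GenomicRanges::seqnames(gr))
    pos <- GenomicRanges::start(gr)
    if (verbose)
        message(sprintf(
            "gprime scan: %d sites on %d chromosome(s); %s kernel W=%g %s; %s null; FDR q=%g",
            length(pos), length(unique(chrom)), spec@shape, spec@halfWidth,
            spec@unit, nullMethod, fdr))
    freqs <- alleleFreqs(counts)
    g <- gStatistic(counts)
    gp <- smoothGprime(counts, spec, g = g)
    if (nullMethod == "robust") {
        model <- estimateNullRobust(gp, modeEstimator = modeEstimator)
    } else {
        if (is.null(design))
            stop("theoretical null requires a BsaDesign")
        nm <- nullMomentsGprime(design, pos, spec, chrom = chrom)
        # one model per scan: moments are site-independent for a uniform
        # design, take the focal (median-variance) site
        model <- lognormalFromMoments(nm[1, "mean"], stats::median(nm[, "var"]))
    }
    if (verbose)
        message(sprintf("null model (%s): mu=%.4f sigma=%.4f",
                        model@method, model@mu, model@sigma))
    pz <- pvaluesLognormal(gp, model)
    bh <- bhFdr(pz$pvalue, q = fdr)
    regions <- callRegions(chrom, pos, bh$significant, gp,
                           maxGapSites = maxGapSites)
    if (verbose)
        message(sprintf("%d significant site(s) in %d region(s)",
                        sum(bh$significant), length(regions)))
    scan <- data.frame(chrom = chrom, pos = pos,
                       pLow = freqs[, "pLow"], pHigh = freqs[, "pHigh"],
                       G = g, Gprime = gp, pvalue = pz$pvalue,
                       zscore = pz$zscore, qvalue = bh$qvalues,
                       significant = bh$significant)
    config <- list(nSites = length(pos), kernel = spec@shape,
                   halfWidth = spec@halfWidth, unit = spec@unit,
                   cmPerKb = spec@cmPerKb, nullMethod = nullMethod,
                   fdr = fdr, maxGapSites = maxGapSites,
                   modeEstimator = modeEstimator)
    list(scan = scan, regions = regions, nullModel = model, config = config)
}
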