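#' Haldane map function
#'
#' Converts genetic map distance to recombination fraction under no
#' interference: r = (1 - exp(-2 x / 100)) / 2 for x in centimorgans, and its
#' inverse x = -50 log(1 - 2 r).  This is the conversion used throughout the
#' package whenever genetic distances must be turned into recombination
#' fractions (expected G' profiles, simulator, null covariances).
#'
#' @param cm map distance in centimorgans.
#' @param r recombination fraction in [0, 0.5).
#' @return \code{cmToRecomb}: recombination fraction; \code{recombToCm}: map
#'   distance in cM.
#' @export
cmToRecomb <- function(cm) (1 - exp(-2 * cm / 100)) / 2

#' @rdname cmToRecomb
#' @export
recombToCm <- function(r) -50 * log(1 - 2 * r)

.kernelShape <- function(D, shape) {
    if (shape == "tricube") ifelse(abs(D) < 1, (1 - abs(D)^3)^3, 0)
    else as.numeric(abs(D) <= 1)   # rectangular, boundary sites included
}

#' Tricube kernel weights
#'
#' Weights of the Nadaraya-Watson smoother for a window of sites at signed
#' offsets from the focal site.  The unnormalized tricube weight at
#' standardized distance D = |offset| / W is (1 - D^3)^3, equal to 1 at the
#' focal position and 0 at the window edge; the rectangular kernel gives every
#' in-window site weight 1.  Normalized weights sum to one over the window.
#'
#' @param distances signed offsets of in-window sites from the focal site, in
#'   the unit of \code{spec}; all must satisfy |distance| <= W.
#' @param spec a \code{\link{KernelSpec}}.
#' @param normalize return weights normalized to sum to 1 (default) or the raw
#'   kernel values.
#' @return numeric weight per site.
#' @examples
#' sp <- KernelSpec(1, "tricube", "cM")
#' tricubeWeights(c(0, 0.5, 1), sp, normalize = FALSE)  # 1, 0.6699..., 0
#' @export
tricubeWeights <- function(distances, spec, normalize = TRUE) {
    W <- spec@halfWidth
    if (any(abs(distances) > W + 1e-9 * W))
        stop("all supplied sites must lie within the window (|distance| <= W)")
    w <- .kernelShape(distances / W, spec@shape)
    if (normalize) w / sum(w) else w
}

# Reflect (pos, value) pairs about the terminal sites of one chromosome so the
# smoother sees a symmetric neighbourhood at the boundaries; appended values
# are never reported (the smoother only evaluates at original sites).
.reflectAugment <- function(pos, val, W) {
    n <- length(pos)
    li <- which(pos > pos[1] & pos <= pos[1] + W)
    ri <- which(pos >= pos[n] - W & pos < pos[n])
    ap <- c(2 * pos[1] - pos[li], pos, 2 * pos[n] - pos[ri])
    av <- c(val[li], val, val[ri])
    o <- order(ap)
    list(pos = ap[o], val = av[o])
}

# Core windowed pass over one sorted chromosome; returns G' and/or sum of
# squared normalized weights at each original site.
.smoothOne <- function(pos, g, spec, reflect = TRUE) {
    W <- spec@halfWidth
    aug <- if (reflect && length(pos) > 1) .reflectAugment(pos, g, W)
           else list(pos = pos, val = g)
    lo <- findInterval(pos - W, aug$pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + W, aug$pos)
    gp <- numeric(length(pos))
    ss <- numeric(length(pos))
    for (i in seq_along(pos)) {
        j <- lo[i]:hi[i]
        w <- .kernelShape((aug$pos[j] - pos[i]) / W, spec@shape)
        w <- w / sum(w)
        gp[i] <- sum(w * aug$val[j])
        ss[i] <- sum(w * w)
    }
    list(gprime = gp, sumsq = ss)
}

.perChrom <- function(chrom, pos, g, spec, reflect, what) {
    if (is.unsorted(pos, strictly = FALSE)) {
        # positions must be sorted within each chromosome
        bych <- split(seq_along(pos), chrom)
        if (any(vapply(bych, function(i) is.unsorted(pos[i]), logical(1))))
            stop("sites must be sorted by position within each chromosome")
    }
    out <- numeric(length(pos))
    for (idx in split(seq_along(pos), factor(chrom, unique(chrom)))) {
        r <- .smoothOne(pos[idx], g[idx], spec, reflect)
        out[idx] <- r[[what]]
    }
    out
}

#' Smoothed G statistic (G')
#'
#' Nadaraya-Watson kernel regression of per-site G values over position: the
#' G' value at each site is the weighted average of G over all sites within
#' +/- W, with tricube (or rectangular) weights normalized to sum to one.
#' Chromosomes are smoothed independently.  At each chromosome end the series
#' is extended by reflecting the (position, G) pairs that fall within the
#' half-bandwidth about the terminal site, the smoother is run as usual, and
#' the appended values are trimmed, which removes the edge bias of an
#' asymmetric window (a constant series stays exactly constant).
#'
#' @param x a \code{\link{BsaCounts}} object (positions taken from its ranges,
#'   G computed via \code{\link{gStatistic}}) or a numeric vector of sorted
#'   positions.
#' @param spec a \code{\link{KernelSpec}} in the same unit as the positions.
#' @param g per-site G values (required when \code{x} is a position vector).
#' @param chrom chromosome identifier per site (optional for the numeric
#'   method; a single chromosome is assumed when missing).
#' @param reflect apply boundary reflection (default TRUE).
#' @return numeric vector of per-site G'.
#' @export
setGeneric("smoothGprime",
           function(x, spec, ...) standardGeneric("smoothGprime"))

#' @rdname smoothGprime
#' @export
setMethod("smoothGprime", "BsaCounts", function(x, spec, g = NULL,
                                                reflect = TRUE) {
    gr <- siteRanges(x)
    if (is.null(g)) g <- gStatistic(x)
    .perChrom(as.character(GenomicRanges::seqnames(gr)),
              GenomicRanges::start(gr), g, spec, reflect, "gprime")
})

#' @rdname smoothGprime
#' @export
setMethod("smoothGprime", "numeric", function(x, spec, g, chrom = NULL,
                                              reflect = TRUE) {
    if (missing(g) || length(g) != length(x))
        stop("g must be supplied with one value per position")
    if (is.null(chrom)) chrom <- rep("chr", length(x))
    .perChrom(chrom, x, g, spec, reflect, "gprime")
})

#' Sum of squared kernel weights per site
#'
#' For each focal site, the sum over its window of the squared normalized
#' kernel weights (often written k').  For a rectangular kernel over m sites
#' this equals 1/m; the tricube value is larger (the weights are less even).
#' 2 k' is the sequencing-only null variance of G'.
#'
#' @inheritParams smoothGprime
#' @return numeric vector of per-site sums of squared weights.
#' @export
setGeneric("kernelWeightSumsq",
           function(x, spec, ...) standardGeneric("kernelWeightSumsq"))

#' @rdname kernelWeightSumsq
#' @export
setMethod("kernelWeightSumsq", "BsaCounts", function(x, spec, reflect = TRUE) {
    gr <- siteRanges(x)
    .perChrom(as.character(GenomicRanges::seqnames(gr)),
              GenomicRanges::start(gr), numeric(length(gr)), spec, reflect,
              "sumsq")
})

#' @rdname kernelWeightSumsq
#' @export
setMethod("kernelWeightSumsq", "numeric", function(x, spec, chrom = NULL,
                                                   reflect = TRUE) {
    if (is.null(chrom)) chrom <- rep("chr", length(x))
    .perChrom(chrom, x, numeric(length(x)), spec, reflect, "sumsq")
})

# Dense smoothing matrix K with reflection folded back onto original site
# indices: gprime = K %*% g.  Only for small site sets (simulation scans).
.kernelMatrix <- function(pos, spec, reflect = TRUE) {
    W <- spec@halfWidth
    n <- length(pos)
    idx <- seq_len(n)
    li <- which(pos > pos[1] & pos <= pos[1] + W)
    ri <- which(pos >= pos[n] - W & pos < pos[n])
    if (reflect && n > 1) {
        apos <- c(2 * pos[1] - pos[li], pos, 2 * pos[n] - pos[ri])
        aidx <- c(idx[li], idx, idx[ri])
    } else {
        apos <- pos; aidx <- idx
    }
    K <- matrix(0, n, n)
    for (i in idx) {
        w <- .kernelShape((apos - pos[i]) / W, spec@shape)
        w <- w / sum(w)
        for (j in which(w > 0)) K[i, aidx[j]] <- K[i, aidx[j]] + w[j]
    }
    K
}

#' Expected G' profile around a QTL
#'
#' The expected shape of the smoothed statistic around a single causal site.
#' If the true high-allele frequencies in the two bulks at the QTL are
#' (freqLow, freqHigh), then at map distance x the expected marker frequency in
#' each bulk is attenuated toward 0.5 through the recombination fraction
#' r(x): p(x) = 0.5 + (p - 0.5)(1 - 2 r(x)).  The expected G at that
#' divergence is evaluated by plugging the expected allele depths (per-bulk
#' coverage times frequency) into the G formula, and the hierarchical null
#' expectation 1 + C/a (a = effective alleles) is added as the baseline the
#' profile decays to, so that the profile approaches the null expectation of G
#' at large distances.  The returned half-width at half-maximum of the excess
#' over baseline is the natural scale for matched-filter bandwidth choice.
#'
#' @param freqLow,freqHigh true bulk frequencies of the high allele at the QTL.
#' @param coverage mean per-bulk sequencing coverage.
#' @param effectiveAlleles alleles sampled per bulk (2n diploid, n homozygous).
#' @param distancesCm non-negative map distances (cM) at which to evaluate.
#' @param mapFunction cM -> recombination fraction (default Haldane).
#' @return list with \code{profile} (data.frame: distanceCm, expectedG) and
#'   \code{hwhmCm}, the half-width at half-maximum.
#' @export
expectedGprimeProfile <- function(freqLow, freqHigh, coverage = 50,
                                  effectiveAlleles = 300,
                                  distancesCm = seq(0, 50, by = 0.05),
                                  mapFunction = cmToRecomb) {
    if (any(c(freqLow, freqHigh) < 0 | c(freqLow, freqHigh) > 1))
        stop("frequencies must lie in [0, 1]")
    if (any(distancesCm < 0)) stop("distances must be >= 0")
    base <- 1 + coverage / effectiveAlleles
    expg <- function(x) {
        att <- 1 - 2 * mapFunction(x)
        pL <- 0.5 + (freqLow - 0.5) * att
        pH <- 0.5 + (freqHigh - 0.5) * att
        .expectedPluginG(pL, pH, coverage) + base
    }
    prof <- expg(distancesCm)
    peak <- expg(0)
    half <- base + (peak - base) / 2
    hw <- NA_real_
    if (peak > base) {
        f <- function(x) expg(x) - half
        up <- 200
        if (f(up) < 0)
            hw <- stats::uniroot(f, c(0, up), tol = 1e-8)$root
    }
    list(profile = data.frame(distanceCm = distancesCm, expectedG = prof),
         hwhmCm = hw)
}

# Plug-in G at expected counts: per-bulk depth C, frequencies pL, pH.
.expectedPluginG <- function(pL, pH, C) {
    pbar <- (pL + pH) / 2
    term <- function(p, m) ifelse(p == 0, 0, p * log(p / m))
    2 * C * (term(pL, pbar) + term(1 - pL, 1 - pbar) +
             term(pH, pbar) + term(1 - pH, 1 - pbar))
}

#' Recommended smoothing bandwidth
#'
#' Practical kernel-width guidance.  For locating single QTL peaks
#' (\code{"single_peak"}) the recommended kernel corresponds to a full width of
#' about 30 cM (the middle of the 25-40 cM range that gives smoothing ratios
#' near 1-1.5 relative to the expected peak width), converted to physical
#' distance with the supplied cM/kb rate.  To resolve adjacent peaks
#' (\code{"resolve_adjacent_peaks"}) a markedly narrower kernel with a
#' smoothing ratio near 0.7 of the expected full width at half maximum of the
#' G' peak is returned (computed from \code{\link{expectedGprimeProfile}} for a
#' locus fixed in one bulk at frequency 0.5 in the other).
#'
#' @param target \code{"single_peak"} or \code{"resolve_adjacent_peaks"}.
#' @param cmPerKb average recombination rate, centimorgans per kilobase (> 0).
#' @param shape kernel shape for the returned spec.
#' @return a \code{\link{KernelSpec}} with \code{halfWidth} in bp.
#' @export
recommendBandwidth <- function(target = c("single_peak",
                                          "resolve_adjacent_peaks"),
                               cmPerKb, shape = "tricube") {
    target <- match.arg(target)
    if (!is.finite(cmPerKb) || cmPerKb <= 0)
        stop("cmPerKb must be a positive conversion rate")
    fullCm <- if (target == "single_peak") 30 else {
        prof <- expectedGprimeProfile(0.5, 1.0)
        0.7 * 2 * prof$hwhmCm
    }
    halfBp <- (fullCm / 2) / cmPerKb * 1000
    KernelSpec(halfWidth = halfBp, shape = shape, unit = "bp",
               cmPerKb = cmPerKb)
}
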