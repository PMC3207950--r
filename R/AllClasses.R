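#' @import methods
#' @importFrom stats dnorm qnorm pnorm rnorm rbinom rpois runif median mad
#'   plnorm qlnorm qchisq pchisq p.adjust quantile var density setNames
#' @importFrom utils read.delim write.table
NULL

#' Per-site two-bulk allele depths
#'
#' \code{BsaCounts} holds the data of a bulk segregant sequencing experiment:
#' one row per biallelic polymorphic site, with the read depth of the
#' high-parent and low-parent allele in each of the two bulks.  Sites live on a
#' \link[GenomicRanges]{GRanges} (width-1 ranges, 1-based coordinates) whose
#' metadata columns are the four cells of the per-site 2x2 contingency table:
#' \describe{
#'   \item{nHiLow}{reads carrying the high-parent allele in the low bulk}
#'   \item{nLoLow}{reads carrying the low-parent allele in the low bulk}
#'   \item{nHiHigh}{high-parent-allele reads in the high bulk}
#'   \item{nLoHigh}{low-parent-allele reads in the high bulk}
#' }
#' An optional \code{cm} column carries genetic-map coordinates in centimorgans.
#' Validity requires non-negative integer counts, positive total depth in each
#' bulk at every site, and sites sorted by (chromosome, position) with unique
#' positions per chromosome.
#'
#' @slot sites a \code{GRanges} as described above.
#' @seealso \code{\link{readSiteCounts}}, \code{\link{gStatistic}},
#'   \code{\link{smoothGprime}}
#' @export
setClass("BsaCounts", representation(sites = "GRanges"))

.countCols <- c("nHiLow", "nLoLow", "nHiHigh", "nLoHigh")

setValidity("BsaCounts", function(object) {
    gr <- object@sites
    mc <- S4Vectors::mcols(gr)
    msg <- character()
    if (!all(.countCols %in% colnames(mc)))
        return(paste("missing count columns:",
                     paste(setdiff(.countCols, colnames(mc)), collapse = ", ")))
    cnt <- as.matrix(as.data.frame(mc[, .countCols]))
    if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
        msg <- c(msg, "counts must be non-negative integers")
    else {
        if (any(cnt[, "nHiLow"] + cnt[, "nLoLow"] == 0) ||
            any(cnt[, "nHiHigh"] + cnt[, "nLoHigh"] == 0))
            msg <- c(msg, "every site needs positive total depth in both bulks")
    }
    if (length(gr) > 1) {
        o <- order(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr))
        if (!identical(o, seq_along(gr)))
            msg <- c(msg, "sites must be sorted by (chrom, pos)")
        key <- paste(GenomicRanges::seqnames(gr), GenomicRanges::start(gr))
        if (anyDuplicated(key))
            msg <- c(msg, "positions must be unique within a chromosome")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn BsaCounts construct from vectors of coordinates and counts.
#' @param chrom chromosome identifiers.
#' @param pos 1-based physical positions (bp).
#' @param nHiLow,nLoLow,nHiHigh,nLoHigh per-site allele depths (see class
#'   description).
#' @param cm optional genetic-map coordinates (cM).
#' @return a \code{BsaCounts} object with sites sorted by (chrom, pos).
#' @export
BsaCounts <- function(chrom, pos, nHiLow, nLoLow, nHiHigh, nLoHigh, cm = NULL) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
    S4Vectors::mcols(gr)$nHiLow <- as.integer(nHiLow)
    S4Vectors::mcols(gr)$nLoLow <- as.integer(nLoLow)
    S4Vectors::mcols(gr)$nHiHigh <- as.integer(nHiHigh)
    S4Vectors::mcols(gr)$nLoHigh <- as.integer(nLoHigh)
    if (!is.null(cm)) S4Vectors::mcols(gr)$cm <- as.numeric(cm)
    o <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr))
    new("BsaCounts", sites = gr[o])
}

#' @describeIn BsaCounts the underlying \code{GRanges}.
#' @param x,object a \code{BsaCounts}.
#' @export
siteRanges <- function(x) x@sites

#' @describeIn BsaCounts the four allele-depth columns as an integer matrix
#'   (one row per site).
#' @export
alleleCounts <- function(x) {
    as.matrix(as.data.frame(S4Vectors::mcols(x@sites)[, .countCols]))
}

#' @describeIn BsaCounts number of sites.
#' @export
setMethod("length", "BsaCounts", function(x) length(x@sites))

setMethod("show", "BsaCounts", function(object) {
    gr <- object@sites
    cat("BsaCounts with", length(gr), "biallelic sites on",
        length(unique(as.character(GenomicRanges::seqnames(gr)))),
        "chromosome(s)\n")
    cnt <- alleleCounts(object)
    cat(sprintf("  mean depth: low bulk %.1f, high bulk %.1f\n",
                mean(cnt[, 1] + cnt[, 2]), mean(cnt[, 3] + cnt[, 4])))
})

#' Smoothing kernel specification
#'
#' Defines the moving window used by the Nadaraya-Watson smoother that turns
#' per-site G values into G'.  \code{halfWidth} is the half-bandwidth W: a site
#' j enters the window of site i when |pos_j - pos_i| <= W.  The tricube kernel
#' gives weight (1 - D^3)^3 at standardized distance D = |pos_j - pos_i|/W
#' (zero at D >= 1); the rectangular kernel weighs all in-window sites equally.
#' Positions and \code{halfWidth} must share a unit (\code{"bp"} or
#' \code{"cM"}); \code{cmPerKb} is the constant genetic/physical conversion
#' rate used when genetic distances are needed for bp positions.
#'
#' @slot halfWidth half-bandwidth W (> 0), in \code{unit}.
#' @slot shape \code{"tricube"} or \code{"rectangular"}.
#' @slot unit \code{"bp"} or \code{"cM"}.
#' @slot cmPerKb centimorgans per kilobase (NA if not needed).
#' @seealso \code{\link{smoothGprime}}, \code{\link{recommendBandwidth}}
#' @export
setClass("KernelSpec", representation(halfWidth = "numeric",
                                      shape = "character",
                                      unit = "character",
                                      cmPerKb = "numeric"))

setValidity("KernelSpec", function(object) {
    msg <- character()
    if (length(object@halfWidth) != 1 || !is.finite(object@halfWidth) ||
        object@halfWidth <= 0)
        msg <- c(msg, "halfWidth must be a single positive number")
    if (!object@shape %in% c("tricube", "rectangular"))
        msg <- c(msg, "shape must be 'tricube' or 'rectangular'")
    if (!object@unit %in% c("bp", "cM"))
        msg <- c(msg, "unit must be 'bp' or 'cM'")
    if (length(msg)) msg else TRUE
})

#' @describeIn KernelSpec constructor.
#' @param halfWidth half-bandwidth W (> 0).
#' @param shape kernel shape.
#' @param unit coordinate unit of \code{halfWidth}.
#' @param cmPerKb optional cM/kb conversion rate.
#' @export
KernelSpec <- function(halfWidth, shape = c("tricube", "rectangular"),
                       unit = c("bp", "cM"), cmPerKb = NA_real_) {
    new("KernelSpec", halfWidth = as.numeric(halfWidth),
        shape = match.arg(shape), unit = match.arg(unit),
        cmPerKb = as.numeric(cmPerKb))
}

setMethod("show", "KernelSpec", function(object) {
    cat(sprintf("KernelSpec: %s kernel, half-bandwidth W = %g %s\n",
                object@shape, object@halfWidth, object@unit))
})

#' Experimental design of a BSA sequencing experiment
#'
#' The design parameters that determine the null distribution of G under the
#' two-level hierarchical sampling model: an F2 (or comparable segregant)
#' population of \code{popSize} individuals, \code{bulkSize} individuals
#' selected into each tail bulk, mean sequencing coverage \code{coverage} per
#' site for each bulk (length-2 vector low/high; their mean enters the null
#' formulas), the effective number of alleles sampled per bulk
#' (\code{2 * bulkSize} for diploid F2 segregants, \code{bulkSize} for
#' homozygous diploid segregants), and the null frequency \code{p0} of the
#' high-parent allele (0.5 absent segregation distortion).
#'
#' @slot popSize F2 population size N.
#' @slot bulkSize individuals per tail bulk, n.
#' @slot coverage length-2 numeric, mean per-site coverage of (low, high) bulk.
#' @slot effectiveAlleles alleles sampled per bulk (n or 2n).
#' @slot p0 expected null frequency of the high allele.
#' @seealso \code{\link{nullMomentsG}}, \code{\link{nullMomentsGprime}}
#' @export
setClass("BsaDesign", representation(popSize = "numeric",
                                     bulkSize = "numeric",
                                     coverage = "numeric",
                                     effectiveAlleles = "numeric",
                                     p0 = "numeric"))

setValidity("BsaDesign", function(object) {
    msg <- character()
    n <- object@bulkSize; N <- object@popSize
    if (!(n > 0 && 2 * n <= N))
        msg <- c(msg, "need 0 < 2*bulkSize <= popSize")
    if (length(object@coverage) != 2 || any(object@coverage <= 0))
        msg <- c(msg, "coverage must be two positive values (low, high)")
    if (!object@effectiveAlleles %in% c(n, 2 * n))
        msg <- c(msg, "effectiveAlleles must be bulkSize or 2*bulkSize")
    if (object@p0 <= 0 || object@p0 >= 1)
        msg <- c(msg, "p0 must be in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' @describeIn BsaDesign constructor. A scalar \code{coverage} is recycled to
#'   both bulks; \code{homozygous = TRUE} sets effective alleles to
#'   \code{bulkSize} instead of \code{2 * bulkSize}.
#' @param popSize,bulkSize,coverage,p0 see slots.
#' @param homozygous are segregants homozygous diploids?
#' @export
BsaDesign <- function(popSize, bulkSize, coverage, p0 = 0.5,
                      homozygous = FALSE) {
    if (length(coverage) == 1) coverage <- rep(coverage, 2)
    new("BsaDesign", popSize = as.numeric(popSize),
        bulkSize = as.numeric(bulkSize), coverage = as.numeric(coverage),
        effectiveAlleles = if (homozygous) as.numeric(bulkSize) else
            2 * as.numeric(bulkSize),
        p0 = as.numeric(p0))
}

setMethod("show", "BsaDesign", function(object) {
    cat(sprintf(paste0("BsaDesign: N = %g, n = %g per bulk, coverage = ",
                       "(%g, %g), %g effective alleles, p0 = %g\n"),
                object@popSize, object@bulkSize, object@coverage[1],
                object@coverage[2], object@effectiveAlleles, object@p0))
})

#' Log-normal null model for G or G'
#'
#' Stores the null mean and variance of the scan statistic together with the
#' log-normal parameters (mu, sigma) they imply through the moment identities
#' mean = exp(mu + sigma^2/2) and var = (exp(sigma^2) - 1) exp(2 mu + sigma^2).
#' Upper-tail p-values of a scan are computed from this distribution.
#'
#' @slot meanG null mean of the statistic.
#' @slot varG null variance of the statistic.
#' @slot mu,sigma log-normal parameters.
#' @slot method \code{"theoretical"} or \code{"robust"}.
#' @seealso \code{\link{lognormalFromMoments}}, \code{\link{pvaluesLognormal}},
#'   \code{\link{estimateNullRobust}}
#' @export
setClass("NullModel", representation(meanG = "numeric", varG = "numeric",
                                     mu = "numeric", sigma = "numeric",
                                     method = "character"))

setValidity("NullModel", function(object) {
    msg <- character()
    if (object@meanG <= 0) msg <- c(msg, "meanG must be positive")
    if (object@varG < 0) msg <- c(msg, "varG must be non-negative")
    if (object@sigma < 0) msg <- c(msg, "sigma must be non-negative")
    m <- exp(object@mu + object@sigma^2 / 2)
    v <- (exp(object@sigma^2) - 1) * exp(2 * object@mu + object@sigma^2)
    if (abs(m - object@meanG) > 1e-10 * max(1, object@meanG))
        msg <- c(msg, "mu/sigma inconsistent with meanG")
    if (abs(v - object@varG) > 1e-10 * max(1, object@varG))
        msg <- c(msg, "mu/sigma inconsistent with varG")
    if (length(msg)) msg else TRUE
})

setMethod("show", "NullModel", function(object) {
    cat(sprintf(paste0("NullModel (%s): mean = %.4g, var = %.4g ",
                       "(log-normal mu = %.4g, sigma = %.4g)\n"),
                object@method, object@meanG, object@varG, object@mu,
                object@sigma))
})

#' @describeIn NullModel null mean of the statistic.
#' @param x a \code{NullModel}.
#' @export
nullMean <- function(x) x@meanG

#' @describeIn NullModel null variance of the statistic.
#' @export
nullVar <- function(x) x@varG

#' @describeIn NullModel log-normal parameters as c(mu, sigma).
#' @export
lognormalParams <- function(x) c(mu = x@mu, sigma = x@sigma)

#' Specification of one simulated F2 BSA experiment
#'
#' Extends \code{\link{BsaDesign}} with the genetic geometry and effect size of
#' a simulated experiment: a single chromosome of \code{chromLengthCm}
#' centimorgans carrying uniformly spaced markers at \code{snpDensity} SNPs per
#' cM, a biallelic additive QTL at \code{qtlPosCm} whose alternative
#' homozygotes differ by \code{qtlEffect} phenotypic units
#' (\code{qtlEffect = 0} encodes the null hypothesis), and a residual
#' (within-genotype) phenotypic standard deviation \code{residualSd}.
#'
#' The defaults reproduce the simulation conditions used throughout the
#' package's calibration studies: N = 1000 F2 individuals, n = 150 per tail
#' bulk, coverage 50 per bulk, a 10 cM chromosome at 40 SNPs/cM with the QTL at
#' its center, and residual SD 1.
#'
#' @slot chromLengthCm simulated chromosome length (cM).
#' @slot snpDensity markers per cM.
#' @slot qtlEffect difference between alternative QTL homozygotes (phenotypic
#'   units); 0 for the null.
#' @slot residualSd within-genotype phenotypic SD.
#' @slot qtlPosCm QTL position (cM).
#' @slot homozygous homozygous diploid segregants? (effective alleles n vs 2n)
#' @seealso \code{\link{simulateF2Bulks}}, \code{\link{runNullCalibration}},
#'   \code{\link{runPower}}
#' @export
setClass("SimDesign", contains = "BsaDesign",
         representation(chromLengthCm = "numeric", snpDensity = "numeric",
                        qtlEffect = "numeric", residualSd = "numeric",
                        qtlPosCm = "numeric", homozygous = "logical"))

setValidity("SimDesign", function(object) {
    msg <- character()
    if (object@chromLengthCm <= 0) msg <- c(msg, "chromLengthCm must be > 0")
    if (object@snpDensity <= 0) msg <- c(msg, "snpDensity must be > 0")
    if (object@residualSd <= 0) msg <- c(msg, "residualSd must be > 0")
    if (object@qtlPosCm < 0 || object@qtlPosCm > object@chromLengthCm)
        msg <- c(msg, "qtlPosCm must lie on the chromosome")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimDesign constructor with the package's reference simulation
#'   conditions as defaults.
#' @param popSize,bulkSize,coverage,p0 see \code{\link{BsaDesign}}.
#' @param chromLengthCm,snpDensity,qtlEffect,residualSd,qtlPosCm,homozygous
#'   see slots; \code{qtlPosCm = NULL} places the QTL at the chromosome center.
#' @export
SimDesign <- function(popSize = 1000, bulkSize = 150, coverage = 50,
                      chromLengthCm = 10, snpDensity = 40, qtlEffect = 0,
                      residualSd = 1, qtlPosCm = NULL, homozygous = FALSE,
                      p0 = 0.5) {
    if (is.null(qtlPosCm)) qtlPosCm <- chromLengthCm / 2
    if (length(coverage) == 1) coverage <- rep(coverage, 2)
    new("SimDesign", popSize = as.numeric(popSize),
        bulkSize = as.numeric(bulkSize), coverage = as.numeric(coverage),
        effectiveAlleles = if (homozygous) as.numeric(bulkSize) else
            2 * as.numeric(bulkSize),
        p0 = as.numeric(p0), chromLengthCm = as.numeric(chromLengthCm),
        snpDensity = as.numeric(snpDensity), qtlEffect = as.numeric(qtlEffect),
        residualSd = as.numeric(residualSd), qtlPosCm = as.numeric(qtlPosCm),
        homozygous = isTRUE(homozygous))
}

setMethod("show", "SimDesign", function(object) {
    callNextMethod()
    cat(sprintf(paste0("  chromosome %g cM, %g SNPs/cM, QTL at %g cM, ",
                       "effect delta = %g (residual SD %g)%s\n"),
                object@chromLengthCm, object@snpDensity, object@qtlPosCm,
                object@qtlEffect, object@residualSd,
                if (object@homozygous) ", homozygous segregants" else ""))
})
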