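#' Null moments of G under hierarchical sampling
#'
#' Closed-form approximations to the null mean and variance of the per-site G
#' statistic when allele frequencies are subject to two levels of sampling:
#' binomial sampling of a = effective alleles into each bulk (variance
#' p0 q0 / a per bulk) on top of Poisson read sampling at mean coverage C
#' (variance about p0 q0 / C on the frequency scale).  The G-test calibrates
#' itself against the read-sampling level only, so the statistic is inflated by
#' the variance ratio
#' \deqn{E[G] \approx (1/a + 1/C) / (1/C) = 1 + C/a,}
#' and, G being approximately a scaled chi-square with 1 df,
#' \deqn{Var[G] \approx 2 (1 + C/a)^2.}
#' The bulk-level and read-level variances are both proportional to
#' p0 (1 - p0), so the inflation factor -- and with it both moments -- is
#' unchanged under segregation distortion (p0 != 0.5) to this order; the
#' distorted case therefore nests the p0 = 0.5 base case.  In the limit
#' C << a the moments converge on (1, 2), the chi-square(1) values.  When the
#' two bulks were sequenced at different depths the mean of the two coverages
#' is used.
#'
#' @param design a \code{\link{BsaDesign}} (or \code{\link{SimDesign}}).
#' @return named numeric vector \code{c(mean, var)}.
#' @examples
#' nullMomentsG(BsaDesign(1000, 150, 50))   # c(1.1667, 2.7222)
#' @export
nullMomentsG <- function(design) {
    stopifnot(is(design, "BsaDesign"))
    validObject(design)
    C <- mean(design@coverage)
    a <- design@effectiveAlleles
    lambda <- 1 + C / a
    c(mean = lambda, var = 2 * lambda^2)
}

#' Null moments of G' per site
#'
#' Null mean and variance of the smoothed statistic.  Because the kernel
#' weights sum to one, E[G'] = E[G] at every site.  The variance combines the
#' per-site variance of G with the covariance between SNPs sharing a window:
#' \deqn{Var[G'_i] = \sum_j k_j^2 Var[G] + \sum_{j \ne l} k_j k_l Cov[G_j, G_l].}
#' Two modes are available:
#' \describe{
#'   \item{\code{hierarchical}}{the full two-level model.  The read-sampling
#'   noise is independent between sites, but all sites in a window share the
#'   bulk-composition draw, giving \eqn{Cov[G_j, G_l] \approx 2 (C/a)^2} for
#'   in-window pairs (in-window SNPs treated as tightly linked).  With
#'   \code{linkageDecay = TRUE} the covariance is attenuated by
#'   \eqn{(1 - 2 r)^2} with r the Haldane recombination fraction for the pair's
#'   map separation -- a refinement that lowers the prediction slightly for
#'   windows spanning several centimorgans.}
#'   \item{\code{sequencing_only}}{bulks fixed, only read sampling varies (e.g.
#'   technical replicates of the same pools): G is approximately chi-square(1),
#'   and by a weighted central limit argument G' is approximately normal with
#'   mean 1 and variance 2 k', where k' is the sum of squared kernel weights
#'   (\code{\link{kernelWeightSumsq}}); for a rectangular kernel over m sites,
#'   2/m.}
#' }
#'
#' @param design a \code{\link{BsaDesign}}.
#' @param pos sorted site positions.
#' @param spec a \code{\link{KernelSpec}} in the unit of \code{pos}.
#' @param mode \code{"hierarchical"} or \code{"sequencing_only"}.
#' @param chrom optional chromosome per site (single chromosome assumed).
#' @param linkageDecay attenuate in-window covariances by the squared Haldane
#'   linkage coefficient (hierarchical mode only).  Requires genetic distances:
#'   positions in cM, or a \code{cmPerKb} rate in \code{spec}.
#' @param reflect boundary reflection, as in \code{\link{smoothGprime}}.
#' @return two-column matrix, one row per site: \code{mean}, \code{var}.
#' @export
nullMomentsGprime <- function(design, pos, spec,
                              mode = c("hierarchical", "sequencing_only"),
                              chrom = NULL, linkageDecay = FALSE,
                              reflect = TRUE) {
    mode <- match.arg(mode)
    if (is.null(chrom)) chrom <- rep("chr", length(pos))
    ss <- kernelWeightSumsq(as.numeric(pos), spec, chrom = chrom,
                            reflect = reflect)
    if (mode == "sequencing_only")
        return(cbind(mean = rep(1, length(pos)), var = 2 * ss))
    m <- nullMomentsG(design)
    C <- mean(design@coverage)
    a <- design@effectiveAlleles
    covFull <- 2 * (C / a)^2
    if (!linkageDecay) {
        # sum_{j != l} k_j k_l = 1 - sum k^2 since weights sum to one
        v <- ss * m["var"] + (1 - ss) * covFull
    } else {
        toCm <- function(x) {
            if (spec@unit == "cM") x
            else {
                if (!is.finite(spec@cmPerKb))
                    stop("linkageDecay with bp positions needs cmPerKb")
                x / 1000 * spec@cmPerKb
            }
        }
        v <- numeric(length(pos))
        for (idx in split(seq_along(pos), factor(chrom, unique(chrom)))) {
            K <- .kernelMatrix(pos[idx], spec, reflect = reflect)
            dcm <- abs(outer(toCm(pos[idx]), toCm(pos[idx]), "-"))
            att <- (1 - 2 * cmToRecomb(dcm))^2
            for (i in seq_along(idx)) {
                k <- K[i, ]
                cc <- covFull * (tcrossprod(k) * att)
                diag(cc) <- k^2 * m["var"]
                v[idx[i]] <- sum(cc)
            }
        }
    }
    cbind(mean = rep(unname(m["mean"]), length(pos)), var = unname(v))
}

#' Log-normal parameters from moments
#'
#' Solves mean = exp(mu + sigma^2/2), var = (exp(sigma^2) - 1)
#' exp(2 mu + sigma^2) for (mu, sigma):
#' mu = ln(mean^2 / sqrt(var + mean^2)), sigma^2 = ln(1 + var / mean^2).
#'
#' @param mean positive mean of the statistic under the null.
#' @param var non-negative variance.
#' @param method label stored in the returned model.
#' @return a \code{\link{NullModel}}.
#' @examples
#' lognormalParams(lognormalFromMoments(1.17, 0.066))  # mu 0.1335, sigma 0.2170
#' @export
lognormalFromMoments <- function(mean, var, method = "theoretical") {
    if (!is.finite(mean) || mean <= 0) stop("mean must be positive")
    if (!is.finite(var) || var < 0) stop("var must be non-negative")
    s2 <- log(1 + var / mean^2)
    mu <- log(mean^2 / sqrt(var + mean^2))
    new("NullModel", meanG = mean, varG = var, mu = mu, sigma = sqrt(s2),
        method = method)
}

#' Upper-tail log-normal p-values for a G' scan
#'
#' p-values and z-scores of observed G' values under a fitted log-normal null:
#' p = P(LN(mu, sigma) > value) and z = (ln value - mu)/sigma.  A value of 0
#' gets p = 1 (and z = -Inf); p is strictly decreasing in the value.
#'
#' @param values non-negative per-site G' values.
#' @param model a \code{\link{NullModel}}.
#' @return data.frame with columns \code{pvalue} and \code{zscore}.
#' @export
pvaluesLognormal <- function(values, model) {
    stopifnot(is(model, "NullModel"))
    validObject(model)
    if (any(values < 0)) stop("G' values must be non-negative")
    if (model@sigma == 0) {
        p <- as.numeric(values <= exp(model@mu))
        z <- ifelse(values > exp(model@mu), Inf,
                    ifelse(values < exp(model@mu), -Inf, 0))
        return(data.frame(pvalue = p, zscore = z))
    }
    p <- plnorm(values, meanlog = model@mu, sdlog = model@sigma,
                lower.tail = FALSE)
    z <- ifelse(values == 0, -Inf, (log(values) - model@mu) / model@sigma)
    data.frame(pvalue = p, zscore = z)
}
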