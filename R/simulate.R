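#' QTL effect size from heritability
#'
#' The homozygote difference delta for a biallelic additive locus (genotypic
#' values -delta/2, 0, +delta/2 at frequencies 1/4, 1/2, 1/4) that explains a
#' fraction \code{h2} of the phenotypic variance when the residual SD is
#' \code{residualSd}: the locus variance is delta^2/8, so
#' delta = sqrt(8 h2 / (1 - h2)) x residualSd.
#'
#' @param h2 fraction of phenotypic variance explained, in [0, 1).
#' @param residualSd residual (within-genotype) phenotypic SD.
#' @return the homozygote difference delta.
#' @examples
#' qtlEffectForVariance(0.02)   # a weak QTL: delta ~ 0.404
#' @export
qtlEffectForVariance <- function(h2, residualSd = 1) {
    stopifnot(h2 >= 0, h2 < 1, residualSd > 0)
    sqrt(8 * h2 / (1 - h2)) * residualSd
}

# Simulate `reps` independent F2 BSA experiments under `design`, fully
# vectorized across replicates.  Steps per replicate:
#   1. N individuals get QTL genotypes with Mendelian probabilities
#      (1/4, 1/2, 1/4) (homozygous designs: two classes at (1/2, 1/2)) and
#      additive genotypic values; phenotype = value + Normal(0, residualSd).
#   2. Rank by phenotype; the n lowest and n highest form the bulks
#      (measure-zero ties broken by individual index via order()).
#   3. Selected individuals contribute their gametes (two independent gametes
#      for diploid F2; one gamete, doubled, for homozygous designs).  Marker
#      haplotypes are built outward from the QTL allele, recombining between
#      adjacent markers with the Haldane fraction for their cM spacing,
#      independently per interval and per gamete.
#   4. Per SNP and bulk, the two allele counts are independent Poisson draws
#      with means C p and C (1 - p), p the realized bulk allele frequency.
# Returns per-site count matrices (reps x M), realized bulk frequencies,
# marker positions (cM) and the causal index.
.simulateCounts <- function(design, reps) {
    stopifnot(is(design, "SimDesign"))
    N <- design@popSize; n <- design@bulkSize
    Clow <- design@coverage[1]; Chigh <- design@coverage[2]
    d <- design@snpDensity; L <- design@chromLengthCm
    delta <- design@qtlEffect
    pos <- seq(0, L, by = 1 / d)
    qidx <- which.min(abs(pos - design@qtlPosCm))
    M <- length(pos)
    rstep <- cmToRecomb(1 / d)

    if (design@homozygous) {
        gg <- matrix(rbinom(reps * N, 1, 0.5), reps, N)      # 0/1 homozygotes
        geno <- 2L * gg
        value <- (gg - 0.5) * delta
    } else {
        geno <- matrix(rbinom(reps * N, 2, 0.5), reps, N)
        value <- (geno - 1) * delta / 2
    }
    pheno <- value + matrix(rnorm(reps * N, sd = design@residualSd), reps, N)

    selIdx <- function(decreasing) {
        t(apply(pheno, 1, function(x) {
            o <- order(x, decreasing = decreasing)
            o[seq_len(n)]
        }))
    }
    selL <- selIdx(FALSE)
    selH <- selIdx(TRUE)

    # QTL alleles of the gametes of the selected individuals (reps x G2)
    gameteAlleles <- function(sel) {
        gg <- matrix(geno[cbind(rep(seq_len(reps), each = n),
                                as.vector(t(sel)))], reps, n, byrow = TRUE)
        if (design@homozygous) (gg == 2) * 1L
        else cbind((gg >= 1) * 1L, (gg == 2) * 1L)
    }

    bulkFreqs <- function(sel) {
        A <- gameteAlleles(sel)
        G2 <- ncol(A)
        cnt <- matrix(0L, reps, M)
        cnt[, qidx] <- rowSums(A)
        cur <- A
        if (qidx > 1) for (j in (qidx - 1):1) {
            cur <- abs(cur - matrix(rbinom(reps * G2, 1, rstep), reps, G2))
            cnt[, j] <- rowSums(cur)
        }
        cur <- A
        if (qidx < M) for (j in (qidx + 1):M) {
            cur <- abs(cur - matrix(rbinom(reps * G2, 1, rstep), reps, G2))
            cnt[, j] <- rowSums(cur)
        }
        cnt / G2
    }
    qL <- bulkFreqs(selL)
    qH <- bulkFreqs(selH)
    list(posCm = pos, qtlIndex = qidx, freqLow = qL, freqHigh = qH,
         nHiLow = matrix(rpois(reps * M, Clow * qL), reps, M),
         nLoLow = matrix(rpois(reps * M, Clow * (1 - qL)), reps, M),
         nHiHigh = matrix(rpois(reps * M, Chigh * qH), reps, M),
         nLoHigh = matrix(rpois(reps * M, Chigh * (1 - qH)), reps, M))
}

# G matrix (reps x M) from a .simulateCounts result, with zero-depth sites
# (possible at very low coverage) given G = 0.
.gMatrix <- function(sim) {
    cLow <- sim$nHiLow + sim$nLoLow
    cHigh <- sim$nHiHigh + sim$nLoHigh
    g <- matrix(0, nrow(cLow), ncol(cLow))
    ok <- cLow > 0 & cHigh > 0
    if (any(ok))
        g[ok] <- .gstat(sim$nHiLow[ok], sim$nLoLow[ok],
                        sim$nHiHigh[ok], sim$nLoHigh[ok])
    g
}

#' Simulate one F2 BSA sequencing experiment
#'
#' Runs the full generative model once (genotypes, phenotypes, truncation
#' selection of the tail bulks, recombinant haplotypes outward from the QTL,
#' independent Poisson read counts per allele and bulk) and packages the
#' result as a \code{\link{BsaCounts}} table.  Simulated coordinates place
#' 1 cM = 1 kb (positions in bp = cM x 1000 + 1, chromosome \code{"sim1"},
#' so a \code{\link{KernelSpec}} with \code{cmPerKb = 1} matches).  Sites
#' where either bulk received zero reads carry no information and are dropped
#' from the counts table (their number is reported).
#'
#' @param design a \code{\link{SimDesign}}.
#' @param seed optional RNG seed for reproducibility.
#' @return list: \code{counts} (\code{BsaCounts}), \code{posCm},
#'   \code{qtlIndex} (index into \code{posCm}), \code{freqLow}/\code{freqHigh}
#'   (realized bulk allele frequencies at every marker), \code{nDropped}.
#' @export
simulateF2Bulks <- function(design, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    sim <- .simulateCounts(design, 1)
    keep <- (sim$nHiLow[1, ] + sim$nLoLow[1, ] > 0) &
            (sim$nHiHigh[1, ] + sim$nLoHigh[1, ] > 0)
    counts <- BsaCounts(chrom = "sim1",
                        pos = round(sim$posCm[keep] * 1000) + 1,
                        nHiLow = sim$nHiLow[1, keep],
                        nLoLow = sim$nLoLow[1, keep],
                        nHiHigh = sim$nHiHigh[1, keep],
                        nLoHigh = sim$nLoHigh[1, keep],
                        cm = sim$posCm[keep])
    list(counts = counts, posCm = sim$posCm, qtlIndex = sim$qtlIndex,
         freqLow = sim$freqLow[1, ], freqHigh = sim$freqHigh[1, ],
         nDropped = sum(!keep))
}

#' Truncation-selection theory
#'
#' For truncation selection retaining a fraction phi of a normally distributed
#' phenotype, the selection intensity is i = dnorm(x)/phi with x the upper
#' phi-quantile of the standard normal, and the expected change of allele
#' frequency at an additive locus with standardized effect alpha (= half the
#' homozygote difference in phenotypic SD units) and frequency p0 is
#' approximately delta-p = i p0 (1 - p0) alpha.
#'
#' @param alpha standardized locus effect a / sigma.
#' @param p0 allele frequency before selection.
#' @param selectedFraction retained proportion phi in (0, 1).
#' @return named vector \code{c(selectionIntensity, expectedDp)}.
#' @examples
#' truncationSelectionTheory(0.1, 0.5, 0.20)  # dp ~ 3.5%
#' truncationSelectionTheory(0.1, 0.5, 0.01)  # dp ~ 6.7%
#' @export
truncationSelectionTheory <- function(alpha, p0, selectedFraction) {
    if (selectedFraction <= 0 || selectedFraction >= 1)
        stop("selectedFraction must be in (0, 1)")
    if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
    x <- qnorm(selectedFraction, lower.tail = FALSE)
    i <- dnorm(x) / selectedFraction
    c(selectionIntensity = i, expectedDp = i * p0 * (1 - p0) * alpha)
}

#' Null calibration of the G and G' tests by simulation
#'
#' Repeats the full F2 BSA simulation under the null (no QTL), scans each
#' replicate, and summarizes the behaviour of the statistics at the focal
#' (central) SNP: observed moments of G and G', and empirical type-I error
#' rates at the given nominal levels under (a) the naive chi-square(1) cutoff
#' applied to raw G, (b) the theoretical log-normal null for G' from
#' \code{\link{nullMomentsG}} / \code{\link{nullMomentsGprime}}, and (c) the
#' robust empirical null re-estimated from each replicate's own G' scan
#' (\code{\link{estimateNullRobust}}).
#'
#' @param design a \code{\link{SimDesign}} with \code{qtlEffect = 0}.
#' @param spec a \code{\link{KernelSpec}} with \code{unit = "cM"}.
#' @param reps number of simulated experiments.
#' @param levels nominal significance levels.
#' @param seed optional RNG seed.
#' @param robust also run the (slower) per-replicate robust estimation.
#' @param modeEstimator mode estimator for the robust fits.
#' @param chunkSize replicates simulated per memory chunk.
#' @return list with \code{momentsG}, \code{momentsGprime} (observed mean/var
#'   at the focal SNP), \code{rates} (data.frame: level, naive, lognormal,
#'   robust), \code{theoreticalModel} (the \code{\link{NullModel}} used in (b)),
#'   \code{gFocal}, \code{gprimeFocal} (per-replicate statistics), \code{reps}.
#' @export
runNullCalibration <- function(design, spec, reps = 1000,
                               levels = c(0.05, 0.01), seed = NULL,
                               robust = TRUE,
                               modeEstimator = c("hsm", "kde"),
                               chunkSize = 250) {
    stopifnot(is(design, "SimDesign"), is(spec, "KernelSpec"))
    modeEstimator <- match.arg(modeEstimator)
    if (design@qtlEffect != 0)
        stop("null calibration requires a design with qtlEffect = 0")
    if (spec@unit != "cM")
        stop("simulation smoothing uses genetic distance; spec unit must be cM")
    if (!is.null(seed)) set.seed(seed)
    pos <- seq(0, design@chromLengthCm, by = 1 / design@snpDensity)
    qidx <- which.min(abs(pos - design@qtlPosCm))
    K <- .kernelMatrix(pos, spec)
    gF <- numeric(0); gpF <- numeric(0); probF <- numeric(0)
    left <- reps
    while (left > 0) {
        r <- min(chunkSize, left)
        sim <- .simulateCounts(design, r)
        G <- .gMatrix(sim)
        GP <- G %*% t(K)
        gF <- c(gF, G[, qidx])
        gpF <- c(gpF, GP[, qidx])
        if (robust) {
            pv <- apply(GP, 1, function(gp) {
                fit <- suppressWarnings(suppressMessages(
                    estimateNullRobust(gp, modeEstimator = modeEstimator)))
                pvaluesLognormal(gp[qidx], fit)$pvalue
            })
            probF <- c(probF, pv)
        }
        left <- left - r
    }
    nmgp <- nullMomentsGprime(design, pos, spec)[qidx, ]
    model <- lognormalFromMoments(nmgp["mean"], nmgp["var"])
    pTheory <- pvaluesLognormal(gpF, model)$pvalue
    rates <- data.frame(
        level = levels,
        naive = vapply(levels, function(a)
            mean(gF > qchisq(1 - a, df = 1)), numeric(1)),
        lognormal = vapply(levels, function(a) mean(pTheory < a), numeric(1)),
        robust = if (robust) vapply(levels, function(a)
            mean(probF < a), numeric(1)) else NA_real_)
    list(momentsG = c(mean = mean(gF), var = var(gF)),
         momentsGprime = c(mean = mean(gpF), var = var(gpF)),
         rates = rates, theoreticalModel = model,
         gFocal = gF, gprimeFocal = gpF, reps = reps)
}

#' Power analysis over a design grid
#'
#' Simulates each design (typically varying bulk size, coverage, population
#' size and QTL effect), and reports for every grid cell the mean G' at the
#' causal SNP together with detection power at the causal SNP: the fraction of
#' replicates exceeding the naive chi-square(1) cutoff on raw G, and the
#' fraction significant under the theoretical log-normal G' null, at each
#' requested level.
#'
#' @param designs a \code{\link{SimDesign}} or list of them (non-empty).
#' @param spec a \code{\link{KernelSpec}} (unit cM).
#' @param reps replicates per design (>= 100 recommended).
#' @param levels nominal significance levels.
#' @param seed optional RNG seed.
#' @param chunkSize replicates per memory chunk.
#' @return data.frame: one row per design with its parameters, meanGprime, and
#'   \code{powerNaive.*} / \code{powerGprime.*} columns per level.
#' @export
runPower <- function(designs, spec, reps = 1000,
                     levels = c(0.05, 0.01, 0.001), seed = NULL,
                     chunkSize = 250) {
    if (is(designs, "SimDesign")) designs <- list(designs)
    if (length(designs) == 0) stop("empty design grid")
    if (!is.null(seed)) set.seed(seed)
    rows <- lapply(designs, function(design) {
        pos <- seq(0, design@chromLengthCm, by = 1 / design@snpDensity)
        qidx <- which.min(abs(pos - design@qtlPosCm))
        K <- .kernelMatrix(pos, spec)
        nmgp <- nullMomentsGprime(design, pos, spec)[qidx, ]
        model <- lognormalFromMoments(nmgp["mean"], nmgp["var"])
        gF <- numeric(0); gpF <- numeric(0)
        left <- reps
        while (left > 0) {
            r <- min(chunkSize, left)
            sim <- .simulateCounts(design, r)
            G <- .gMatrix(sim)
            gF <- c(gF, G[, qidx])
            gpF <- c(gpF, (G %*% K[qidx, ])[, 1])
            left <- left - r
        }
        pv <- pvaluesLognormal(gpF, model)$pvalue
        res <- data.frame(popSize = design@popSize, bulkSize = design@bulkSize,
                          coverage = mean(design@coverage),
                          qtlEffect = design@qtlEffect,
                          meanGprime = mean(gpF))
        for (a in levels) {
            res[[paste0("powerNaive.", a)]] <-
                mean(gF > qchisq(1 - a, df = 1))
            res[[paste0("powerGprime.", a)]] <- mean(pv < a)
        }
        res
    })
    do.call(rbind, rows)
}
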