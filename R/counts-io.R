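#' Read per-site allele counts
#'
#' Reads the two-bulk allele-depth table from either a tab-separated file with
#' header columns \code{chrom pos n_hi_L n_lo_L n_hi_H n_lo_H} or a VCF 4.x
#' file with per-sample AD-style allele depths for the two pooled samples.
#' Sites failing checks are skipped with a warning and counted: non-biallelic
#' records, rows that do not parse (reported with their line number), and
#' sites with zero total depth in either bulk (they carry no information and
#' make G undefined).  Which VCF allele is the "high-parent allele" is not
#' decidable from a VCF alone, so it is set by \code{highAllele}; G is
#' invariant to the choice (swapping alleles permutes table rows), only the
#' sign convention of the reported frequencies changes.  Output is sorted by
#' (chrom, pos); internal coordinates are 1-based.
#'
#' @param source path to the input file.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @param samples for VCF: character vector of length 2 naming the (low, high)
#'   bulk samples.
#' @param highAllele for VCF: which allele carries the high-parent label,
#'   \code{"alt"} (default) or \code{"ref"}.
#' @return a \code{\link{BsaCounts}}; the number of skipped sites is available
#'   as \code{attr(, "nSkipped")}.
#' @export
readSiteCounts <- function(source, format = c("tsv", "vcf"), samples = NULL,
                           highAllele = c("alt", "ref")) {
    format <- match.arg(format)
    highAllele <- match.arg(highAllele)
    if (!file.exists(source)) stop("file not found: ", source)
    if (format == "tsv") .readCountsTsv(source) else
        .readCountsVcf(source, samples, highAllele)
}

.finishCounts <- function(df, nSkipped) {
    keep <- (df$n_hi_L + df$n_lo_L > 0) & (df$n_hi_H + df$n_lo_H > 0)
    nzero <- sum(!keep)
    if (nzero > 0) {
        warning(nzero, " site(s) with zero depth in a bulk excluded")
        df <- df[keep, , drop = FALSE]
    }
    if (nrow(df) == 0) stop("zero usable sites after filtering")
    out <- BsaCounts(df$chrom, df$pos, df$n_hi_L, df$n_lo_L,
                     df$n_hi_H, df$n_lo_H)
    attr(out, "nSkipped") <- nSkipped + nzero
    out
}

.readCountsTsv <- function(source) {
    need <- c("chrom", "pos", "n_hi_L", "n_lo_L", "n_hi_H", "n_lo_H")
    df <- read.delim(source, header = TRUE, stringsAsFactors = FALSE)
    if (!all(need %in% names(df)))
        stop("TSV must have header columns: ", paste(need, collapse = " "))
    df <- df[need]
    num <- c("pos", "n_hi_L", "n_lo_L", "n_hi_H", "n_lo_H")
    bad <- rep(FALSE, nrow(df))
    for (cl in num) {
        v <- suppressWarnings(as.numeric(df[[cl]]))
        bad <- bad | !is.finite(v) | v < 0 | v != round(v)
        df[[cl]] <- v
    }
    if (any(bad))
        warning(sum(bad), " malformed row(s) skipped (data line ",
                paste(utils::head(which(bad), 5), collapse = ", "),
                if (sum(bad) > 5) ", ..." else "", ")")
    .finishCounts(df[!bad, , drop = FALSE], sum(bad))
}

.readCountsVcf <- function(source, samples, highAllele) {
    if (is.null(samples) || length(samples) != 2)
        stop("VCF input needs samples = c(lowBulk, highBulk)")
    v <- vcfR::read.vcfR(source, verbose = FALSE)
    have <- colnames(v@gt)[-1]
    if (!all(samples %in% have))
        stop("sample(s) missing from VCF: ",
             paste(setdiff(samples, have), collapse = ", "))
    fix <- vcfR::getFIX(v)
    alt <- fix[, "ALT"]
    biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE)
    nSkipped <- sum(!biallelic)
    if (nSkipped)
        warning(nSkipped, " non-biallelic VCF record(s) skipped")
    ad <- vcfR::extract.gt(v, element = "AD")
    parseAd <- function(x) {
        parts <- strsplit(x, ",", fixed = TRUE)
        ref <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
        altd <- suppressWarnings(as.numeric(vapply(parts, function(p)
            if (length(p) >= 2) p[2] else NA_character_, "")))
        cbind(ref, altd)
    }
    adL <- parseAd(ad[, samples[1]])
    adH <- parseAd(ad[, samples[2]])
    ok <- biallelic & rowSums(is.na(adL)) == 0 & rowSums(is.na(adH)) == 0
    nbad <- sum(biallelic) - sum(ok)
    if (nbad) warning(nbad, " VCF record(s) with unparseable AD skipped")
    hi <- if (highAllele == "alt") 2L else 1L
    lo <- 3L - hi
    df <- data.frame(chrom = fix[ok, "CHROM"],
                     pos = as.integer(fix[ok, "POS"]),
                     n_hi_L = adL[ok, hi], n_lo_L = adL[ok, lo],
                     n_hi_H = adH[ok, hi], n_lo_H = adH[ok, lo],
                     stringsAsFactors = FALSE)
    .finishCounts(df, nSkipped + nbad)
}

#' Write and re-read scan results
#'
#' \code{writeScan} writes the per-site scan table (chrom, pos, observed bulk
#' frequencies, G, G', p-value, q-value, significance flag) as TSV with 12
#' significant digits; \code{readScan} reads it back.  \code{writeRegions}
#' writes called QTL regions both as BED (0-based half-open intervals, with a
#' commented header line; score = peak G') and as a companion TSV
#' (\code{<dest>.peaks.tsv}) carrying 1-based inclusive coordinates, the site
#' count, and the peak coordinate and peak G' of each region.  An empty region
#' set yields a BED file holding only the header comment.
#'
#' @param scan non-empty data.frame as produced by \code{\link{runGprimeScan}}.
#' @param source path of a scan TSV written by \code{writeScan}.
#' @param dest output path (for \code{writeRegions}, the BED path).
#' @param regions \code{GRanges} from \code{\link{callRegions}}.
#' @return \code{writeScan}/\code{writeRegions}: the path, invisibly;
#'   \code{readScan}: the scan data.frame.
#' @export
writeScan <- function(scan, dest) {
    stopifnot(is.data.frame(scan), nrow(scan) > 0)
    df <- scan
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
    tryCatch(
        write.table(df, dest, sep = "\t", quote = FALSE, row.names = FALSE),
        error = function(e) stop("cannot write scan to ", dest, ": ",
                                 conditionMessage(e)))
    invisible(dest)
}

#' @rdname writeScan
#' @export
readScan <- function(source) {
    read.delim(source, header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname writeScan
#' @export
writeRegions <- function(regions, dest) {
    header <- "#chrom\tstart\tend\tname\tscore\tstrand"
    peakPath <- paste0(sub("\\.bed$", "", dest), ".peaks.tsv")
    writeLines(header, dest)
    if (length(regions) == 0) {
        peaks <- data.frame(chrom = character(), startPos = integer(),
                            endPos = integer(), nSites = integer(),
                            peakPos = integer(), peakGprime = numeric())
    } else {
        df <- data.frame(
            chrom = as.character(GenomicRanges::seqnames(regions)),
            start0 = GenomicRanges::start(regions) - 1L,  # BED half-open
            end = GenomicRanges::end(regions),
            name = paste0("QTL_", seq_along(regions)),
            score = sprintf("%.6g", S4Vectors::mcols(regions)$peakGprime),
            strand = ".")
        write.table(df, dest, sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE, append = TRUE)
        peaks <- data.frame(
            chrom = df$chrom, startPos = GenomicRanges::start(regions),
            endPos = df$end, nSites = S4Vectors::mcols(regions)$nSites,
            peakPos = S4Vectors::mcols(regions)$peakPos,
            peakGprime = S4Vectors::mcols(regions)$peakGprime)
    }
    write.table(peaks, peakPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dest)
}
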