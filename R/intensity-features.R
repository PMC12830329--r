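#' Histogram of masked intensities with uniform bin width
#'
#' Bins span the masked value range with constant width; edges are aligned
#' to multiples of the bin width so that binning is stable under affine
#' shifts that preserve bin assignment. Every masked voxel is counted
#' exactly once (values on the upper edge fall in the last bin).
#'
#' @param volume an [ImageVolume-class] (or [DoseGrid-class] for dose
#'   histograms).
#' @param mask a non-empty [StructureMask-class]; alternatively pass a
#'   numeric vector of values as `volume` and omit `mask`.
#' @param binWidth positive bin width (HU for CT, Gy for dose). Default
#'   25 HU, the conventional first-order radiomics discretization.
#' @return an [IntensityHistogram-class].
#' @examples
#' h <- computeHistogram(c(0, 10, 20, 30), binWidth = 10)
#' h@counts
#' @export
computeHistogram <- function(volume, mask = NULL, binWidth = 25) {
    if (binWidth <= 0)
        stop("binWidth must be positive")
    v <- if (is.numeric(volume) && is.null(dim(volume))) {
        if (!length(volume)) stop("no values to bin")
        volume
    } else {
        maskedValues(volume, mask)
    }
    e0 <- floor(min(v) / binWidth) * binWidth
    nb <- max(1L, as.integer(ceiling((max(v) - e0) / binWidth)))
    # value exactly on the top edge must land in the last bin
    if (max(v) >= e0 + nb * binWidth) nb <- nb + 1L
    idx <- pmin(as.integer(floor((v - e0) / binWidth)) + 1L, nb)
    counts <- tabulate(idx, nbins = nb)
    new("IntensityHistogram",
        binEdges = e0 + (0:nb) * binWidth,
        counts = as.integer(counts), nTotal = length(v))
}

#' Uniformity of a histogram
#'
#' The first-order uniformity statistic: the sum of squared bin
#' probabilities, `sum(p_i^2)` with `p_i = counts_i / nTotal`. It is 1 when
#' all mass sits in one bin and `1/n` for `n` equally populated bins. The
#' same statistic is applied to HU histograms (density characterisation)
#' and to dose histograms (dose homogeneity).
#'
#' @param x an [IntensityHistogram-class], or a numeric vector of counts.
#' @param percent if TRUE, return the value as a percentage.
#' @return uniformity in (0, 1] (or (0, 100] with `percent = TRUE`).
#' @export
uniformityIndex <- function(x, percent = FALSE) {
    counts <- if (is(x, "IntensityHistogram")) x@counts else x
    n <- sum(counts)
    if (n <= 0) stop("empty histogram")
    p <- counts / n
    stopifnot(abs(sum(p) - 1) < 1e-12)
    u <- sum(p^2)
    if (percent) 100 * u else u
}

#' First-order intensity features of a masked region
#'
#' The three features driving the global density classification: median and
#' interquartile range of the raw masked voxel values (linear-interpolation
#' quantiles, R type 7), and histogram uniformity at the given bin width.
#'
#' @inheritParams computeHistogram
#' @return a one-row data.frame: `n_voxels`, `median_hu`, `iqr_hu`,
#'   `uniformity`.
#' @examples
#' vol <- ImageVolume(array(rnorm(1000, -80, 30), dim = c(10, 10, 10)))
#' msk <- StructureMask("breast", array(TRUE, dim = c(10, 10, 10)),
#'                      reference = vol)
#' firstOrderFeatures(vol, msk)
#' @export
firstOrderFeatures <- function(volume, mask = NULL, binWidth = 25) {
    v <- if (is.numeric(volume) && is.null(dim(volume))) volume
         else maskedValues(volume, mask)
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    u <- uniformityIndex(computeHistogram(v, binWidth = binWidth))
    data.frame(n_voxels = length(v), median_hu = q[2], iqr_hu = q[3] - q[1],
               uniformity = u)
}

#' Feature table for a set of structures
#'
#' Convenience wrapper producing the cohort feature CSV layout: one row per
#' (patient, structure).
#'
#' @param volume an [ImageVolume-class].
#' @param masks a list of [StructureMask-class] objects.
#' @param patientId identifier copied into every row.
#' @param binWidth histogram bin width in HU.
#' @return a data.frame with columns patient_id, structure, n_voxels,
#'   median_hu, iqr_hu, uniformity.
#' @export
featureTable <- function(volume, masks, patientId, binWidth = 25) {
    rows <- lapply(masks, function(m) {
        cbind(data.frame(patient_id = patientId, structure = m@name,
                         stringsAsFactors = FALSE),
              firstOrderFeatures(volume, m, binWidth = binWidth))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
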