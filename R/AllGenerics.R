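#' Accessors for voxel-grid objects
#'
#' `voxels()` returns the raw 3-D array, `spacing()` the per-axis voxel
#' spacing in mm, `origin()` the world coordinate (mm) of the centre of the
#' first voxel, and `nVoxels()` the number of voxels (for masks, the number
#' of TRUE voxels).
#'
#' @param x an [ImageVolume], [StructureMask] or [DoseGrid].
#' @return `voxels()`: an array; `spacing()`, `origin()`: numeric(3);
#'   `nVoxels()`: a count.
#' @name grid-accessors
#' @aliases voxels spacing origin nVoxels
NULL

#' @rdname grid-accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname grid-accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname grid-accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname grid-accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname grid-accessors
#' @export
setMethod("voxels", "ImageVolume", function(x) x@voxels)
#' @rdname grid-accessors
#' @export
setMethod("voxels", "StructureMask", function(x) x@voxels)
#' @rdname grid-accessors
#' @export
setMethod("voxels", "DoseGrid", function(x) x@voxels)

for (cl in c("ImageVolume", "StructureMask", "DoseGrid")) {
    setMethod("spacing", cl, function(x) x@spacing)
    setMethod("origin", cl, function(x) x@origin)
}

#' @rdname grid-accessors
#' @export
setMethod("nVoxels", "ImageVolume", function(x) length(x@voxels))
#' @rdname grid-accessors
#' @export
setMethod("nVoxels", "StructureMask", function(x) sum(x@voxels))
#' @rdname grid-accessors
#' @export
setMethod("nVoxels", "DoseGrid", function(x) length(x@voxels))

#' Fraction count of a dose grid or fractionation scheme
#' @param x a [DoseGrid] or [FractionationScheme].
#' @return integer fraction count.
#' @export
setGeneric("nFractions", function(x) standardGeneric("nFractions"))
#' @rdname nFractions
#' @export
setMethod("nFractions", "DoseGrid", function(x) x@fractions)
#' @rdname nFractions
#' @export
setMethod("nFractions", "FractionationScheme", function(x) x@nFractions)

#' Mixture-parameter accessors for a [GMMFit]
#'
#' @param x a [GMMFit].
#' @return numeric(2): fat component first.
#' @name gmm-accessors
NULL

#' @rdname gmm-accessors
#' @export
setGeneric("mixWeights", function(x) standardGeneric("mixWeights"))
#' @rdname gmm-accessors
#' @export
setGeneric("mixMeans", function(x) standardGeneric("mixMeans"))
#' @rdname gmm-accessors
#' @export
setGeneric("mixSDs", function(x) standardGeneric("mixSDs"))
#' @rdname gmm-accessors
#' @export
setMethod("mixWeights", "GMMFit", function(x) x@weights)
#' @rdname gmm-accessors
#' @export
setMethod("mixMeans", "GMMFit", function(x) x@means)
#' @rdname gmm-accessors
#' @export
setMethod("mixSDs", "GMMFit", function(x) x@sds)

#' Composition percentages of a tissue segmentation
#'
#' @param x a [TissueSegmentation].
#' @return named numeric(3): fat, fibroglandular, unclassified percentages
#'   of the complete breast volume (they sum to 100).
#' @export
setGeneric("compositionPct", function(x) standardGeneric("compositionPct"))
#' @rdname compositionPct
#' @export
setMethod("compositionPct", "TissueSegmentation", function(x)
    c(fat = x@fatPct, fibroglandular = x@fibroPct,
      unclassified = x@unclassifiedPct))

setMethod("show", "ImageVolume", function(object) {
    d <- dim(object@voxels)
    cat(sprintf("ImageVolume %d x %d x %d, spacing (%.3g, %.3g, %.3g) mm\n",
                d[1], d[2], d[3], object@spacing[1], object@spacing[2],
                object@spacing[3]))
    cat(sprintf("  HU range [%.1f, %.1f], origin (%.1f, %.1f, %.1f) mm\n",
                min(object@voxels), max(object@voxels),
                object@origin[1], object@origin[2], object@origin[3]))
})

setMethod("show", "StructureMask", function(object) {
    d <- dim(object@voxels)
    cat(sprintf("StructureMask '%s': %d voxels on a %d x %d x %d grid\n",
                object@name, sum(object@voxels), d[1], d[2], d[3]))
})

setMethod("show", "DoseGrid", function(object) {
    d <- dim(object@voxels)
    cat(sprintf("DoseGrid %d x %d x %d, %d fractions, dose [%.2f, %.2f] Gy\n",
                d[1], d[2], d[3], object@fractions,
                min(object@voxels), max(object@voxels)))
})

setMethod("show", "GMMFit", function(object) {
    cat("Two-component Gaussian mixture (HU)\n")
    cat(sprintf("  fat:            weight %.3f, mean %7.1f, SD %5.2f\n",
                object@weights[1], object@means[1], object@sds[1]))
    cat(sprintf("  fibroglandular: weight %.3f, mean %7.1f, SD %5.2f\n",
                object@weights[2], object@means[2], object@sds[2]))
    cat(sprintf("  window [%.0f, %.0f] HU, n = %d, logLik %.1f, %s (%d iter)\n",
                object@window[1], object@window[2], object@nVoxels,
                object@logLik,
                if (object@converged) "converged" else "NOT converged",
                object@nIter))
})

setMethod("show", "TissueThresholds", function(object) {
    cat(sprintf("Tissue HU intervals (+/- %g SD):\n", object@nSD))
    cat(sprintf("  fat            [%.1f, %.1f]\n", object@fat[1],
                object@fat[2]))
    cat(sprintf("  fibroglandular [%.1f, %.1f]\n", object@fibroglandular[1],
                object@fibroglandular[2]))
    if (object@fat[2] >= object@fibroglandular[1])
        cat("  (intervals overlap; fat takes priority at segmentation)\n")
})

setMethod("show", "TissueSegmentation", function(object) {
    cat(sprintf(
        "TissueSegmentation: fat %.1f%%, fibroglandular %.1f%%, unclassified %.1f%%\n",
        object@fatPct, object@fibroPct, object@unclassifiedPct))
})

setMethod("show", "ClusterModel", function(object) {
    cat("4-cluster breast-density model (k-means on z-scored features)\n")
    hu <- object@centers[, "median_hu"] * object@featureSDs["median_hu"] +
        object@featureMeans["median_hu"]
    ord <- object@labelOrder
    for (i in seq_along(ord))
        cat(sprintf("  %-22s centroid median %7.1f HU\n",
                    .DENSITY_LABELS[i], hu[ord[i]]))
})

setMethod("show", "OrdinalFit", function(object) {
    cat(sprintf("Proportional-odds fit: %s\n", object@formula))
    cat(sprintf("  n = %d, logLik = %.2f, AIC = %.2f%s\n", object@nUsed,
                object@logLik, object@aic,
                if (object@converged) "" else " (NOT converged)"))
    if (nrow(object@coefficients)) {
        cf <- object@coefficients
        for (i in seq_len(nrow(cf)))
            cat(sprintf("  %-24s %8.3f (SE %.3f, p = %.3g)\n",
                        cf$term[i], cf$estimate[i], cf$se[i], cf$p[i]))
    }
})
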