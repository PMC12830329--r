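#' @import methods
#' @importFrom stats quantile sd var cor median kmeans rnorm runif rbinom
#'   rlogis dnorm plogis qlogis pnorm setNames complete.cases as.formula
#'   fft logLik AIC coef vcov dist
#' @importFrom utils write.csv read.csv modifyList head
#' @importFrom tools md5sum
#' @useDynLib breastCompRT, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.validGeometry <- function(object) {
    msg <- character()
    v <- object@voxels
    if (length(dim(v)) != 3L)
        msg <- c(msg, "voxels must be a 3-D array")
    if (any(dim(v) < 1L))
        msg <- c(msg, "voxel grid must have shape >= (1,1,1)")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be three finite positive values (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        msg <- c(msg, "origin must be three finite values (mm)")
    msg
}

#' ImageVolume: a CT volume in Hounsfield units
#'
#' A 3-D scalar grid with voxel spacing and world origin (patient-based mm,
#' LPS). Arrays are stored in NIfTI order: axis 1 = x (column), axis 2 = y
#' (row), axis 3 = z (slice). The world coordinate of voxel (i, j, k)
#' (1-based) is \code{origin + (c(i, j, k) - 1) * spacing}, i.e. voxel-centre
#' coordinates.
#'
#' @slot voxels 3-D numeric array of HU values (finite).
#' @slot spacing numeric(3), voxel spacing in mm, all positive.
#' @slot origin numeric(3), world coordinate of the centre of voxel (1,1,1).
#'
#' @aliases ImageVolume
#' @exportClass ImageVolume
setClass("ImageVolume",
    representation(voxels = "array", spacing = "numeric", origin = "numeric"),
    validity = function(object) {
        msg <- .validGeometry(object)
        if (!length(msg) && any(!is.finite(object@voxels)))
            msg <- c(msg, "voxel values must be finite")
        if (length(msg)) msg else TRUE
    })

#' StructureMask: a named boolean region on a reference grid
#'
#' @slot name character scalar, the structure name.
#' @slot voxels 3-D logical array, congruent with its reference volume.
#' @slot spacing,origin geometry, identical to the reference volume's.
#'
#' @aliases StructureMask
#' @exportClass StructureMask
setClass("StructureMask",
    representation(name = "character", voxels = "array",
                   spacing = "numeric", origin = "numeric"),
    validity = function(object) {
        msg <- .validGeometry(object)
        if (!is.logical(object@voxels))
            msg <- c(msg, "mask voxels must be logical")
        if (length(object@name) != 1L || is.na(object@name))
            msg <- c(msg, "mask must carry a single non-NA name")
        if (length(msg)) msg else TRUE
    })

#' DoseGrid: a 3-D dose distribution in Gy
#'
#' Carries its own geometry (which may differ from the CT grid until
#' resampled) plus the delivered fraction count. The \code{outside} slot
#' flags voxels that fell outside the original dose extent during
#' resampling (their dose is zero by construction).
#'
#' @slot voxels 3-D numeric array of dose in Gy, non-negative.
#' @slot spacing,origin geometry in mm.
#' @slot fractions integer, number of delivered fractions (>= 1).
#' @slot outside logical array flagging extrapolated voxels (may be empty).
#'
#' @aliases DoseGrid
#' @exportClass DoseGrid
setClass("DoseGrid",
    representation(voxels = "array", spacing = "numeric", origin = "numeric",
                   fractions = "integer", outside = "array"),
    validity = function(object) {
        msg <- .validGeometry(object)
        if (!length(msg) && any(object@voxels < 0, na.rm = TRUE))
            msg <- c(msg, "dose must be non-negative")
        if (length(object@fractions) != 1L || is.na(object@fractions) ||
            object@fractions < 1L)
            msg <- c(msg, "fractions must be a single integer >= 1")
        if (length(object@outside) &&
            !identical(dim(object@outside), dim(object@voxels)))
            msg <- c(msg, "outside flag must match the dose grid shape")
        if (length(msg)) msg else TRUE
    })

#' FractionationScheme: fraction count and alpha/beta ratio
#'
#' The linear-quadratic parameters used for EQD2 conversion. The default
#' alpha/beta of 1.7 Gy is the value used for late breast effects.
#'
#' @slot nFractions integer >= 1.
#' @slot alphaBeta positive numeric, Gy.
#'
#' @aliases FractionationScheme
#' @exportClass FractionationScheme
setClass("FractionationScheme",
    representation(nFractions = "integer", alphaBeta = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@nFractions) != 1L || is.na(object@nFractions) ||
            object@nFractions < 1L)
            msg <- c(msg, "nFractions must be a single integer >= 1")
        if (length(object@alphaBeta) != 1L || !is.finite(object@alphaBeta) ||
            object@alphaBeta <= 0)
            msg <- c(msg, "alphaBeta must be a single positive value (Gy)")
        if (length(msg)) msg else TRUE
    })

#' IntensityHistogram: a uniform-width value histogram
#'
#' @slot binEdges strictly increasing numeric edges with constant width.
#' @slot counts non-negative integer counts, one per bin.
#' @slot nTotal total number of values binned; equals \code{sum(counts)}.
#'
#' @aliases IntensityHistogram
#' @exportClass IntensityHistogram
setClass("IntensityHistogram",
    representation(binEdges = "numeric", counts = "integer",
                   nTotal = "integer"),
    validity = function(object) {
        msg <- character()
        ne <- length(object@binEdges)
        if (ne < 2L || any(diff(object@binEdges) <= 0))
            msg <- c(msg, "bin edges must be strictly increasing")
        w <- diff(object@binEdges)
        if (ne >= 3L && max(abs(w - w[1])) > 1e-9 * max(w))
            msg <- c(msg, "bins must have constant width")
        if (length(object@counts) != ne - 1L)
            msg <- c(msg, "need one count per bin")
        if (any(object@counts < 0L))
            msg <- c(msg, "counts must be non-negative")
        if (sum(object@counts) != object@nTotal)
            msg <- c(msg, "counts must sum to nTotal")
        if (length(msg)) msg else TRUE
    })

#' GMMFit: a two-component Gaussian mixture fitted to a HU histogram
#'
#' Components are sorted by ascending mean, so component 1 is the fat peak
#' and component 2 the fibroglandular peak.
#'
#' @slot weights,means,sds numeric(2) mixture parameters; weights sum to 1,
#'   SDs positive, mean 1 < mean 2.
#' @slot logLik log-likelihood of the (histogram-weighted) data.
#' @slot converged logical, EM convergence flag.
#' @slot nIter number of EM iterations run.
#' @slot window numeric(2), the HU fitting window actually used.
#' @slot nVoxels number of in-window voxels fitted.
#'
#' @aliases GMMFit
#' @exportClass GMMFit
setClass("GMMFit",
    representation(weights = "numeric", means = "numeric", sds = "numeric",
                   logLik = "numeric", converged = "logical",
                   nIter = "integer", window = "numeric",
                   nVoxels = "integer"),
    validity = function(object) {
        msg <- character()
        if (length(object@weights) != 2L || any(object@weights <= 0) ||
            abs(sum(object@weights) - 1) > 1e-8)
            msg <- c(msg, "weights must be two positives summing to 1")
        if (length(object@sds) != 2L || any(object@sds <= 0))
            msg <- c(msg, "SDs must be positive")
        if (length(object@means) != 2L ||
            object@means[1] >= object@means[2])
            msg <- c(msg, "component means must be ordered (fat first)")
        if (length(msg)) msg else TRUE
    })

#' TissueThresholds: patient-specific HU intervals for fat and
#' fibroglandular tissue
#'
#' Closed intervals mean +/- nSD * SD derived from a [GMMFit]. Overlap is
#' permitted; it is resolved at segmentation time with fat priority.
#'
#' @slot fat,fibroglandular numeric(2) closed HU intervals (lo, hi).
#' @slot nSD the SD multiple used (default 2).
#'
#' @aliases TissueThresholds
#' @exportClass TissueThresholds
setClass("TissueThresholds",
    representation(fat = "numeric", fibroglandular = "numeric",
                   nSD = "numeric"),
    validity = function(object) {
        msg <- character()
        ok <- function(x) length(x) == 2L && all(is.finite(x)) && x[1] <= x[2]
        if (!ok(object@fat)) msg <- c(msg, "fat interval invalid")
        if (!ok(object@fibroglandular))
            msg <- c(msg, "fibroglandular interval invalid")
        if (!length(msg) &&
            mean(object@fat) >= mean(object@fibroglandular))
            msg <- c(msg, "fat interval must be centred below fibroglandular")
        if (length(msg)) msg else TRUE
    })

#' TissueSegmentation: the three-way tissue partition of a breast mask
#'
#' The fat, fibroglandular and unclassified masks are pairwise disjoint and
#' their union is exactly the breast mask; the three percentages (relative
#' to the complete breast volume) sum to 100.
#'
#' @slot fat,fibroglandular,unclassified [StructureMask] objects.
#' @slot fatPct,fibroPct,unclassifiedPct percentages of breast volume.
#'
#' @aliases TissueSegmentation
#' @exportClass TissueSegmentation
setClass("TissueSegmentation",
    representation(fat = "StructureMask", fibroglandular = "StructureMask",
                   unclassified = "StructureMask",
                   fatPct = "numeric", fibroPct = "numeric",
                   unclassifiedPct = "numeric"),
    validity = function(object) {
        msg <- character()
        f <- object@fat@voxels; g <- object@fibroglandular@voxels
        u <- object@unclassified@voxels
        if (!identical(dim(f), dim(g)) || !identical(dim(f), dim(u)))
            msg <- c(msg, "tissue masks must share one grid")
        else if (any((f & g) | (f & u) | (g & u)))
            msg <- c(msg, "tissue masks must be pairwise disjoint")
        pct <- object@fatPct + object@fibroPct + object@unclassifiedPct
        if (abs(pct - 100) > 1e-9)
            msg <- c(msg, "percentages must sum to 100")
        if (length(msg)) msg else TRUE
    })

#' ClusterModel: a fitted 4-cluster BI-RADS-like density model
#'
#' K-means centroids in standardized (z-scored) feature space, together
#' with the standardization parameters so new feature vectors can be
#' projected, and the label order mapping raw cluster indices to density
#' class names by ascending centroid median HU.
#'
#' @slot centers 4 x 3 matrix of standardized centroids
#'   (median_hu, iqr_hu, uniformity).
#' @slot featureMeans,featureSDs standardization parameters per feature.
#' @slot seed,restarts reproducibility parameters of the k-means fit.
#' @slot inertia total within-cluster sum of squares of the kept fit.
#' @slot labelOrder integer(4), raw cluster indices ordered fatty ->
#'   extremely dense.
#'
#' @aliases ClusterModel
#' @exportClass ClusterModel
setClass("ClusterModel",
    representation(centers = "matrix", featureMeans = "numeric",
                   featureSDs = "numeric", seed = "integer",
                   restarts = "integer", inertia = "numeric",
                   labelOrder = "integer"),
    validity = function(object) {
        msg <- character()
        if (nrow(object@centers) != 4L)
            msg <- c(msg, "exactly 4 centroids required")
        if (any(object@featureSDs <= 0))
            msg <- c(msg, "standardization SDs must be positive")
        if (length(object@labelOrder) &&
            !setequal(object@labelOrder, 1:4))
            msg <- c(msg, "labelOrder must be a permutation of 1:4")
        if (length(msg)) msg else TRUE
    })

#' OrdinalFit: a proportional-odds ordinal regression fit
#'
#' @slot coefficients data.frame with columns term, estimate, se, z, p.
#' @slot zeta named numeric, cutpoint intercepts (strictly increasing).
#' @slot logLik,aic model fit statistics; aic = 2 * nPar - 2 * logLik.
#' @slot nUsed complete cases used.
#' @slot converged logical.
#' @slot formula character representation of the model formula.
#'
#' @aliases OrdinalFit
#' @exportClass OrdinalFit
setClass("OrdinalFit",
    representation(coefficients = "data.frame", zeta = "numeric",
                   logLik = "numeric", aic = "numeric", nUsed = "integer",
                   converged = "logical", formula = "character"),
    validity = function(object) {
        msg <- character()
        if (length(object@zeta) > 1L && any(diff(object@zeta) <= 0))
            msg <- c(msg, "cutpoints must be strictly increasing")
        k <- nrow(object@coefficients) + length(object@zeta)
        if (is.finite(object@aic) &&
            abs(object@aic - (2 * k - 2 * object@logLik)) > 1e-6)
            msg <- c(msg, "AIC identity violated")
        if (length(msg)) msg else TRUE
    })

.DENSITY_LABELS <- c("fatty", "scattered", "heterogeneously_dense",
                     "extremely_dense")

.ENDPOINTS <- c("pain", "oedema", "atrophy", "induration")
.TIMEPOINTS <- c("post", "y1", "y2")
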