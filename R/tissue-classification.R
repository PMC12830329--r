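#' Fit a two-component Gaussian mixture to breast HU values
#'
#' The per-patient composition model: breast voxels are expected to form
#' two intensity peaks, fat (lower HU, narrower) and fibroglandular tissue
#' (higher HU, broader). A two-component univariate Gaussian mixture is
#' fitted by EM to the voxel values inside a restricted HU window, so air,
#' lung and high-HU outliers such as surgical clips or calcifications never
#' enter the fit. For speed the EM runs on a 1-HU-resolution weighted
#' histogram of the in-window values, making the fit invariant to voxel
#' order.
#'
#' Initialization is deterministic: component means at the weighted 25th
#' and 75th percentiles, equal weights, pooled SD. After the first fit the
#' window is refined once to `[mu_fat - 2*sd_fat, mu_fg + 2*sd_fg]`
#' (intersected with the initial window) and the mixture refitted, so the
#' effective window is per-case.
#'
#' @param x an [ImageVolume-class], or directly a numeric vector of HU
#'   values.
#' @param mask breast [StructureMask-class] (when `x` is a volume).
#' @param window initial HU fitting window, default `c(-200, 100)`.
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param maxIter EM iteration cap (default 500); hitting it flags the fit
#'   as non-converged rather than failing.
#' @param sdFloor component-collapse guard in HU (default 1): an SD
#'   shrinking below it aborts with an error suggesting a single-population
#'   input.
#' @param minVoxels minimum number of in-window voxels (default 1000).
#' @param refine logical; run the one-pass per-case window refinement
#'   (default TRUE).
#' @return a [GMMFit-class] with components sorted by mean (fat first).
#' @examples
#' set.seed(1)
#' hu <- c(rnorm(7000, -110, 5), rnorm(3000, -52, 12))
#' fitTwoComponentGMM(hu)
#' @export
setGeneric("fitTwoComponentGMM",
    function(x, ...) standardGeneric("fitTwoComponentGMM"))

#' @rdname fitTwoComponentGMM
#' @param ... passed through to the numeric method.
#' @export
setMethod("fitTwoComponentGMM", "ImageVolume",
    function(x, mask, ...) fitTwoComponentGMM(maskedValues(x, mask), ...))

#' @rdname fitTwoComponentGMM
#' @export
setMethod("fitTwoComponentGMM", "numeric",
    function(x, window = c(-200, 100), tol = 1e-6, maxIter = 500,
             sdFloor = 1, minVoxels = 1000, refine = TRUE) {
        v <- x[x >= window[1] & x <= window[2]]
        if (length(v) < minVoxels)
            stop("only ", length(v), " voxels inside the HU window [",
                 window[1], ", ", window[2], "]; need >= ", minVoxels)
        fit <- .emHistogram(v, window, tol, maxIter, sdFloor)
        if (refine) {
            w2 <- c(max(window[1], fit@means[1] - 2 * fit@sds[1]),
                    min(window[2], fit@means[2] + 2 * fit@sds[2]))
            v2 <- x[x >= w2[1] & x <= w2[2]]
            if (length(v2) >= minVoxels)
                fit <- .emHistogram(v2, w2, tol, maxIter, sdFloor)
        }
        fit
    })

# weighted EM for a 2-component univariate Gaussian mixture on a 1-HU
# histogram; deterministic quantile-based initialization
.emHistogram <- function(v, window, tol, maxIter, sdFloor) {
    h <- round(v)
    lo <- min(h)
    w <- tabulate(h - lo + 1L)
    xs <- lo + seq_along(w) - 1
    keep <- w > 0
    xs <- xs[keep]; w <- w[keep]
    n <- sum(w)

    q <- .weightedQuantile(xs, w, c(0.25, 0.75))
    mu <- q
    xbar <- sum(w * xs) / n
    s0 <- sqrt(sum(w * (xs - xbar)^2) / n)
    sdv <- c(s0, s0)
    pi1 <- 0.5

    logdens <- function(x, m, s) dnorm(x, m, s, log = TRUE)
    ll <- -Inf
    converged <- FALSE
    it <- 0L
    while (it < maxIter) {
        it <- it + 1L
        l1 <- log(pi1) + logdens(xs, mu[1], sdv[1])
        l2 <- log(1 - pi1) + logdens(xs, mu[2], sdv[2])
        m <- pmax(l1, l2)
        lse <- m + log(exp(l1 - m) + exp(l2 - m))
        r1 <- exp(l1 - lse)
        newll <- sum(w * lse)

        n1 <- sum(w * r1); n2 <- n - n1
        if (n1 < 1e-8 || n2 < 1e-8)
            stop("component collapse (vanishing weight); ",
                 "input may be a single population")
        mu <- c(sum(w * r1 * xs) / n1, sum(w * (1 - r1) * xs) / n2)
        sdv <- c(sqrt(sum(w * r1 * (xs - mu[1])^2) / n1),
                 sqrt(sum(w * (1 - r1) * (xs - mu[2])^2) / n2))
        if (any(sdv < sdFloor))
            stop("component collapse (SD below ", sdFloor, " HU); ",
                 "input may be a single population")
        pi1 <- n1 / n

        if (is.finite(ll) && abs(newll - ll) < tol * abs(ll)) {
            ll <- newll
            converged <- TRUE
            break
        }
        ll <- newll
    }

    ord <- order(mu)
    new("GMMFit",
        weights = c(pi1, 1 - pi1)[ord], means = mu[ord], sds = sdv[ord],
        logLik = ll, converged = converged, nIter = it,
        window = as.numeric(window), nVoxels = as.integer(n))
}

.weightedQuantile <- function(x, w, probs) {
    o <- order(x)
    x <- x[o]; w <- w[o]
    cw <- cumsum(w) / sum(w)
    vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Derive patient-specific tissue HU intervals
#'
#' Closed intervals mean +/- `nSD` * SD around each mixture component; the
#' default two SDs defines the patient-specific fat and fibroglandular
#' intensity ranges. Overlap between the intervals is permitted (and
#' common); it is resolved at segmentation with fat priority.
#'
#' @param fit a converged, non-collapsed [GMMFit-class].
#' @param nSD SD multiple (default 2).
#' @return a [TissueThresholds-class].
#' @export
deriveThresholds <- function(fit, nSD = 2) {
    if (!fit@converged)
        stop("refusing to derive thresholds from a non-converged fit")
    new("TissueThresholds",
        fat = c(fit@means[1] - nSD * fit@sds[1],
                fit@means[1] + nSD * fit@sds[1]),
        fibroglandular = c(fit@means[2] - nSD * fit@sds[2],
                           fit@means[2] + nSD * fit@sds[2]),
        nSD = nSD)
}

#' Segment breast voxels into fat / fibroglandular / unclassified
#'
#' Binary thresholding with the patient-specific intervals: a voxel inside
#' the fat interval is fat even when it also lies in the fibroglandular
#' interval (fat priority — the fat peak is the narrower, more distinct
#' one); otherwise a voxel inside the fibroglandular interval is
#' fibroglandular; anything else (seroma-like water HU above the window,
#' clips, streaks) stays unclassified. The three masks partition the breast
#' mask exactly and the percentages are relative to the complete breast
#' volume, so they always sum to 100.
#'
#' @param volume the CT [ImageVolume-class].
#' @param breast the (cropped) breast [StructureMask-class].
#' @param thresholds a [TissueThresholds-class].
#' @return a [TissueSegmentation-class].
#' @export
segmentTissues <- function(volume, breast, thresholds) {
    hu <- maskedValues(volume, breast)   # errors on empty mask
    inFat <- hu >= thresholds@fat[1] & hu <= thresholds@fat[2]
    inFg <- hu >= thresholds@fibroglandular[1] &
        hu <= thresholds@fibroglandular[2]
    lab <- ifelse(inFat, 1L, ifelse(inFg, 2L, 3L))

    mk <- function(code, nm) {
        m <- array(FALSE, dim = dim(volume@voxels))
        m[breast@voxels] <- lab == code
        StructureMask(nm, m, spacing = breast@spacing,
                      origin = breast@origin)
    }
    nb <- length(hu)
    pct <- tabulate(lab, 3L) / nb * 100
    pct[3] <- 100 - pct[1] - pct[2]   # exact partition of 100
    new("TissueSegmentation",
        fat = mk(1L, "fat"), fibroglandular = mk(2L, "fibroglandular"),
        unclassified = mk(3L, "unclassified"),
        fatPct = pct[1], fibroPct = pct[2], unclassifiedPct = pct[3])
}

#' Per-patient composition in one call
#'
#' Convenience wrapper: GMM fit, threshold derivation and segmentation.
#'
#' @inheritParams segmentTissues
#' @param ... passed to [fitTwoComponentGMM()].
#' @param nSD SD multiple for [deriveThresholds()].
#' @return list with `fit`, `thresholds`, `segmentation`.
#' @export
classifyBreastTissue <- function(volume, breast, nSD = 2, ...) {
    fit <- fitTwoComponentGMM(volume, breast, ...)
    thr <- deriveThresholds(fit, nSD = nSD)
    list(fit = fit, thresholds = thr,
         segmentation = segmentTissues(volume, breast, thr))
}

#' Write a tissue segmentation as a NIfTI label map
#'
#' Labels: 0 background, 1 fat, 2 fibroglandular, 3 unclassified.
#'
#' @param segmentation a [TissueSegmentation-class].
#' @param path output NIfTI path.
#' @return the path, invisibly.
#' @export
writeSegmentation <- function(segmentation, path) {
    lab <- array(0L, dim = dim(segmentation@fat@voxels))
    lab[segmentation@fat@voxels] <- 1L
    lab[segmentation@fibroglandular@voxels] <- 2L
    lab[segmentation@unclassified@voxels] <- 3L
    img <- RNifti::asNifti(lab,
                           reference = .niftiRef(segmentation@fat@spacing,
                                                 segmentation@fat@origin),
                           datatype = "uint8")
    RNifti::writeNifti(img, path)
    invisible(path)
}
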