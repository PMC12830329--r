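#' Archetype calibration table
#'
#' Per-archetype tissue HU parameters (ipsilateral calibration) together
#' with invented-but-realistic defaults for fat fraction, breast radius and
#' tissue correlation length. The HU means/SDs are the cohort-calibrated
#' values; fraction, radius and texture scale are generator defaults chosen
#' so that archetypes reproduce the expected feature ordering (fatty:
#' largest volume, lowest median HU, highest uniformity; heterogeneously
#' dense: widest IQR).
#'
#' @return data.frame, one row per archetype.
#' @export
archetypeDefaults <- function() {
    data.frame(
        archetype = .DENSITY_LABELS,
        fat_mean = c(-110, -105, -101, -76),
        fat_sd = c(5, 7, 7, 25),
        fg_mean = c(-52, -33, -13, 9),
        fg_sd = c(12, 10, 11, 15),
        fat_fraction = c(0.85, 0.68, 0.50, 0.32),
        radius_mm = c(62, 55, 48, 42),
        corr_len_mm = c(12, 5, 9, 7),
        stringsAsFactors = FALSE)
}

#' Specify a synthetic breast phantom
#'
#' Defaults for any field not given are taken from [archetypeDefaults()]
#' for the chosen archetype.
#'
#' @param archetype one of fatty, scattered, heterogeneously_dense,
#'   extremely_dense.
#' @param gridDim integer(3) grid shape (default 64 x 64 x 40).
#' @param spacing numeric(3) voxel spacing in mm (default 2.5 mm
#'   isotropic).
#' @param breastRadiusMm hemisphere radius.
#' @param fatFraction target fat volume fraction in (0, 1).
#' @param fatHU,fgHU numeric(2) mean/SD per tissue; fat mean must lie below
#'   fibroglandular mean.
#' @param corrLenMm correlation length of the tissue texture field.
#' @param clipVoxels number of surgical-clip voxels (default 0).
#' @param clipHU clip intensity (default +800).
#' @return a validated list of class `PhantomSpec`.
#' @export
phantomSpec <- function(archetype = "fatty", gridDim = c(64, 64, 40),
                        spacing = c(2.5, 2.5, 2.5), breastRadiusMm = NULL,
                        fatFraction = NULL, fatHU = NULL, fgHU = NULL,
                        corrLenMm = NULL, clipVoxels = 0, clipHU = 800) {
    archetype <- match.arg(archetype, .DENSITY_LABELS)
    a <- archetypeDefaults()
    a <- a[a$archetype == archetype, ]
    spec <- list(
        archetype = archetype,
        gridDim = as.integer(gridDim), spacing = as.numeric(spacing),
        breastRadiusMm = if (is.null(breastRadiusMm)) a$radius_mm
                         else breastRadiusMm,
        fatFraction = if (is.null(fatFraction)) a$fat_fraction
                      else fatFraction,
        fatHU = if (is.null(fatHU)) c(a$fat_mean, a$fat_sd) else fatHU,
        fgHU = if (is.null(fgHU)) c(a$fg_mean, a$fg_sd) else fgHU,
        corrLenMm = if (is.null(corrLenMm)) a$corr_len_mm else corrLenMm,
        clipVoxels = as.integer(clipVoxels), clipHU = clipHU)
    if (spec$fatFraction <= 0 || spec$fatFraction >= 1)
        stop("fatFraction must lie strictly in (0, 1)")
    if (spec$fatHU[2] <= 0 || spec$fgHU[2] <= 0)
        stop("tissue SDs must be positive")
    if (spec$fatHU[1] >= spec$fgHU[1])
        stop("fat mean HU must lie below fibroglandular mean HU")
    class(spec) <- "PhantomSpec"
    spec
}

# smooth standard-normal random field via FFT (circular) Gaussian filtering,
# rescaled to unit variance
.smoothField <- function(dims, spacing, corrLenMm) {
    noise <- array(rnorm(prod(dims)), dim = dims)
    if (corrLenMm <= 0) return(noise)
    g1 <- function(n, dx) {
        # frequency response of a Gaussian kernel with sd = corrLenMm
        f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1) / (n * dx)
        exp(-2 * (pi * corrLenMm * f)^2)
    }
    tx <- g1(dims[1], spacing[1])
    ty <- g1(dims[2], spacing[2])
    tz <- g1(dims[3], spacing[3])
    transfer <- outer(outer(tx, ty), tz)
    sm <- Re(fft(fft(noise) * transfer, inverse = TRUE)) / prod(dims)
    (sm - mean(sm)) / sd(sm)
}

#' Generate a synthetic breast CT phantom
#'
#' A hemispherical breast protruding anteriorly from a body slab. Tissue
#' labels come from a smoothed Gaussian random field thresholded at the
#' fat-fraction quantile, so the correlation length controls whether the
#' fibroglandular component is finely scattered or coarsely heterogeneous.
#' HU values are drawn per tissue from the spec's Gaussians; optional
#' surgical-clip voxels are set to the clip HU. Fully deterministic given
#' the seed.
#'
#' @param spec a [phantomSpec()].
#' @param seed integer RNG seed.
#' @return list: `ct` ([ImageVolume-class]), `body`, `breast`, `fatTruth`,
#'   `fgTruth` ([StructureMask-class]es; the truths partition the breast),
#'   `spec`, `seed`.
#' @export
generateBreastPhantom <- function(spec, seed = 1) {
    stopifnot(inherits(spec, "PhantomSpec"))
    set.seed(seed)
    dims <- spec$gridDim
    sp <- spec$spacing
    xs <- (seq_len(dims[1]) - 1) * sp[1]
    ys <- (seq_len(dims[2]) - 1) * sp[2]
    zs <- (seq_len(dims[3]) - 1) * sp[3]

    # chest wall plane at 60% of the y extent; breast points toward -y
    chestY <- ys[1] + 0.6 * (ys[length(ys)] - ys[1])
    cx <- mean(range(xs)); cz <- mean(range(zs))
    R <- spec$breastRadiusMm

    X <- array(rep(xs, times = dims[2] * dims[3]), dim = dims)
    Y <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dim = dims)
    Z <- array(rep(zs, each = dims[1] * dims[2]), dim = dims)

    r2 <- (X - cx)^2 + (Y - chestY)^2 + (Z - cz)^2
    breast <- r2 <= R^2 & Y <= chestY
    slab <- Y >= chestY
    body <- slab | breast
    nb <- sum(breast)
    if (nb < 50)
        stop("breast hemisphere too small for this grid (", nb, " voxels)")

    field <- .smoothField(dims, sp, spec$corrLenMm)
    fb <- field[breast]
    kFat <- round(spec$fatFraction * nb)
    if (kFat < 1 || kFat > nb - 1)
        stop("fat fraction ", spec$fatFraction,
             " unreachable with ", nb, " breast voxels")
    thr <- sort(fb, partial = kFat)[kFat]
    fat <- breast & (field <= thr)
    # duplicated field values could overshoot the target count; the field is
    # continuous so ties are measure-zero, but guard anyway
    if (abs(sum(fat[breast]) - kFat) > 0.005 * nb)
        stop("tissue threshold could not hit the target fat fraction ",
             "(correlation length too coarse for this grid)")
    fg <- breast & !fat

    hu <- array(-1000, dim = dims)
    hu[slab & !breast] <- rnorm(sum(slab & !breast), 30, 15)
    hu[fat] <- rnorm(sum(fat), spec$fatHU[1], spec$fatHU[2])
    hu[fg] <- rnorm(sum(fg), spec$fgHU[1], spec$fgHU[2])
    if (spec$clipVoxels > 0) {
        idx <- sample(which(breast), min(spec$clipVoxels, nb))
        hu[idx] <- spec$clipHU
    }

    ct <- ImageVolume(hu, spacing = sp, origin = c(0, 0, 0))
    list(ct = ct,
         body = StructureMask("body", body, reference = ct),
         breast = StructureMask("breast", breast, reference = ct),
         fatTruth = StructureMask("fat_truth", fat, reference = ct),
         fgTruth = StructureMask("fg_truth", fg, reference = ct),
         spec = spec, seed = seed)
}

#' Generate a dose field for a phantom
#'
#' Prescribed base dose plus an optional linear gradient (centred on the
#' breast centroid) and an optional Gaussian boost hotspot centred in a
#' chosen tissue-truth mask. The field is evaluated analytically at voxel
#' centres of the target geometry, which may be the CT grid (default) or a
#' coarser grid for resampling exercises.
#'
#' @param breast breast [StructureMask-class] (defines default geometry and
#'   the gradient centre).
#' @param baseGy prescribed dose (default 40.05 Gy).
#' @param nFractions fraction count (default 15).
#' @param gradientGyPerMm linear gradient along `gradientAxis` (default 0).
#' @param gradientAxis axis index 1..3 (default 1).
#' @param boost NULL, or `list(amplitudeGy=, sigmaMm=)`.
#' @param boostIn [StructureMask-class] locating the boost: the hotspot is
#'   centred at the mask voxel nearest the mask centroid. Required when
#'   `boost` is given; the centre must lie inside the breast.
#' @param grid optional object with geometry (e.g. a coarser
#'   [ImageVolume-class]) on which to evaluate the dose.
#' @return a [DoseGrid-class].
#' @export
generateDose <- function(breast, baseGy = 40.05, nFractions = 15,
                         gradientGyPerMm = 0, gradientAxis = 1,
                         boost = NULL, boostIn = NULL, grid = NULL) {
    target <- if (is.null(grid)) breast else grid
    dims <- dim(target@voxels)
    coords <- lapply(1:3, function(a) .axisCoords(target, a))

    idx <- which(breast@voxels, arr.ind = TRUE)
    ctr <- vapply(1:3, function(a)
        mean(.axisCoords(breast, a)[idx[, a]]), numeric(1))

    D <- array(baseGy, dim = dims)
    if (gradientGyPerMm != 0) {
        ax <- coords[[gradientAxis]] - ctr[gradientAxis]
        per <- array(0, dim = dims)
        perm <- c(gradientAxis, setdiff(1:3, gradientAxis))
        per <- aperm(array(rep(ax, times = prod(dims[-gradientAxis])),
                           dim = dims[perm]), order(perm))
        D <- D + gradientGyPerMm * per
    }
    if (!is.null(boost)) {
        if (is.null(boostIn) || !any(boostIn@voxels))
            stop("boost requested but boostIn mask is missing or empty")
        bi <- which(boostIn@voxels, arr.ind = TRUE)
        bc <- vapply(1:3, function(a)
            mean(.axisCoords(boostIn, a)[bi[, a]]), numeric(1))
        d2 <- rowSums(sweep(bi, 2, vapply(1:3, function(a)
            (bc[a] - boostIn@origin[a]) / boostIn@spacing[a] + 1,
            numeric(1)), "-")^2)
        cvox <- bi[which.min(d2), ]
        centre <- vapply(1:3, function(a)
            .axisCoords(boostIn, a)[cvox[a]], numeric(1))
        # hotspot centre must fall inside the breast
        bidx <- vapply(1:3, function(a)
            which.min(abs(.axisCoords(breast, a) - centre[a])), numeric(1))
        if (!breast@voxels[bidx[1], bidx[2], bidx[3]])
            stop("boost hotspot centre lies outside the breast mask")
        r2 <- outer(outer((coords[[1]] - centre[1])^2,
                          (coords[[2]] - centre[2])^2, "+"),
                    (coords[[3]] - centre[3])^2, "+")
        D <- D + boost$amplitudeGy * exp(-r2 / (2 * boost$sigmaMm^2))
    }
    D[D < 0] <- 0
    DoseGrid(D, spacing = target@spacing, origin = target@origin,
             fractions = nFractions)
}

## ---- cohort generation -----------------------------------------------------

.defaultOutcomeBetas <- function() {
    list(pain = c(fat_mean_gy = 1.0, age = 0.2),
         oedema = c(breast_volume_cm3 = 0.5, fat_uniformity = -0.6),
         atrophy = c(fg_volume_cm3 = 0.6, fg_mean_gy = 0.5),
         induration = c(fg_mean_gy = 1.0, boost = 0.3))
}

.drawGrades <- function(eta, cutpoints = c(0.4, 1.7, 3.0)) {
    latent <- eta + stats::rlogis(length(eta))
    rowSums(outer(latent, cutpoints, ">"))
}

.misgrade <- function(g, prob, missProb) {
    n <- length(g)
    flip <- runif(n) < prob
    g[flip] <- pmin(3, pmax(0, g[flip] + sample(c(-1, 1), sum(flip),
                                                replace = TRUE)))
    g[runif(n) < missProb] <- NA
    as.integer(g)
}

#' Generate a synthetic patient cohort
#'
#' Patients are drawn across the four density archetypes with
#' volume-density coupling (fattier archetypes are larger). Ordinal
#' toxicity grades are drawn from a proportional-odds latent model whose
#' coefficients (on z-scored covariates) are user-specified and returned as
#' machine-readable truth; clinician and patient reports are two noisy
#' observations of the same underlying grade.
#'
#' Two modes are provided. With `imaging = FALSE` (the default, suitable
#' for large association studies) per-patient first-order features are
#' computed from a direct HU sample of the archetype mixture and dose
#' metrics are drawn from a closed-form model around the prescription.
#' With `imaging = TRUE` every patient gets a full voxel phantom and dose
#' field; features, composition and dose metrics are then *measured* by
#' the pipeline stages themselves, and outcomes are coupled to the
#' measured ground-truth dose metrics.
#'
#' @param nPatients cohort size.
#' @param seed integer RNG seed.
#' @param archetypeProbs probabilities of the four archetypes (sum to 1).
#' @param outcomeBetas named list per endpoint of named coefficient
#'   vectors; names refer to covariate columns. Defaults couple fat dose
#'   to pain, fibroglandular dose to induration, volume/uniformity to
#'   oedema and fibroglandular volume and dose to atrophy.
#' @param timeAttenuation multiplies the linear predictor at the three
#'   timepoints post/y1/y2 (late effects weaken in the default model).
#' @param baseGy,nFractions prescription.
#' @param misgradeProb probability a report mis-grades by one level.
#' @param missingProb probability a report is missing.
#' @param imaging build full voxel phantoms (slower; see above).
#' @param nSample HU sample size per breast in tabular mode.
#' @param pvFraction fraction of tabular-mode voxels treated as partial
#'   volume (a uniform random mix of the two tissue intensities). Real
#'   breast voxels straddle tissue boundaries, which widens the IQR and
#'   lowers uniformity relative to pure tissue draws; 0.35 calibrates the
#'   fatty archetype to the observed cluster profile (uniformity near
#'   40 %, IQR in the tens of HU).
#' @param gridDim,spacing phantom geometry in imaging mode.
#' @return list: `records` (one row per patient: covariates, dose metrics,
#'   `<endpoint>_<timepoint>_cro/_pro` grade columns), `truth` (betas,
#'   cutpoints, per-patient archetype and fat fraction), and in imaging
#'   mode `phantoms` (list of [generateBreastPhantom()] outputs plus dose).
#' @export
generateCohort <- function(nPatients, seed = 1,
                           archetypeProbs = rep(0.25, 4),
                           outcomeBetas = .defaultOutcomeBetas(),
                           timeAttenuation = c(post = 1, y1 = 0.75,
                                               y2 = 0.55),
                           baseGy = 40.05, nFractions = 15,
                           misgradeProb = 0.15, missingProb = 0.05,
                           imaging = FALSE, nSample = 4000,
                           pvFraction = 0.35,
                           gridDim = c(48, 48, 32),
                           spacing = c(3.5, 3.5, 3.5)) {
    if (abs(sum(archetypeProbs) - 1) > 1e-8 || any(archetypeProbs < 0) ||
        max(archetypeProbs) == 0)
        stop("archetype proportions must be non-negative and sum to 1")
    set.seed(seed)
    arch <- archetypeDefaults()
    ai <- sample.int(4, nPatients, replace = TRUE, prob = archetypeProbs)

    rows <- vector("list", nPatients)
    phantoms <- if (imaging) vector("list", nPatients) else NULL
    fatFrac <- numeric(nPatients)

    for (p in seq_len(nPatients)) {
        a <- arch[ai[p], ]
        f <- min(0.95, max(0.05, a$fat_fraction + rnorm(1, 0, 0.04)))
        fatFrac[p] <- f
        radius <- max(25, a$radius_mm + rnorm(1, 0, 4))
        age <- round(rnorm(1, 60, 8))
        boostFlag <- rbinom(1, 1, 0.4)

        if (imaging) {
            spc <- phantomSpec(a$archetype, gridDim = gridDim,
                               spacing = spacing, breastRadiusMm = radius,
                               fatFraction = f)
            ph <- generateBreastPhantom(spc, seed = seed * 1000L + p)
            boost <- if (boostFlag)
                list(amplitudeGy = 8, sigmaMm = 12) else NULL
            dose <- generateDose(ph$breast, baseGy = baseGy,
                                 nFractions = nFractions,
                                 gradientGyPerMm = 0.02, gradientAxis = 2,
                                 boost = boost,
                                 boostIn = if (boostFlag) ph$fgTruth)
            ph$dose <- dose
            phantoms[[p]] <- ph
            feat <- firstOrderFeatures(ph$ct, ph$breast)
            mFat <- doseMetrics(dose, ph$fatTruth)
            mFg <- doseMetrics(dose, ph$fgTruth)
            mAll <- doseMetrics(dose, ph$breast)
            vxCm3 <- prod(spacing) / 1000
            rows[[p]] <- data.frame(
                patient_id = sprintf("P%04d", p),
                archetype = a$archetype, age = age,
                breast_volume_cm3 = nVoxels(ph$breast) * vxCm3,
                fat_volume_cm3 = nVoxels(ph$fatTruth) * vxCm3,
                fg_volume_cm3 = nVoxels(ph$fgTruth) * vxCm3,
                boost = boostFlag,
                median_hu = feat$median_hu, iqr_hu = feat$iqr_hu,
                uniformity = feat$uniformity,
                breast_mean_gy = mAll$mean_gy, breast_max_gy = mAll$max_gy,
                breast_uniformity = mAll$uniformity,
                fat_mean_gy = mFat$mean_gy, fat_max_gy = mFat$max_gy,
                fat_uniformity = mFat$uniformity,
                fg_mean_gy = mFg$mean_gy, fg_max_gy = mFg$max_gy,
                fg_uniformity = mFg$uniformity,
                stringsAsFactors = FALSE)
        } else {
            drawHU <- function() {
                nPv <- round(nSample * pvFraction)
                nt <- nSample - nPv
                nf <- round(nt * f)
                w <- runif(nPv)
                c(rnorm(nf, a$fat_mean, a$fat_sd),
                  rnorm(nt - nf, a$fg_mean, a$fg_sd),
                  w * rnorm(nPv, a$fat_mean, a$fat_sd) +
                      (1 - w) * rnorm(nPv, a$fg_mean, a$fg_sd))
            }
            feat <- firstOrderFeatures(drawHU())
            featC <- firstOrderFeatures(drawHU())
            vol <- 2 / 3 * pi * radius^3 / 1000
            e1 <- rnorm(1, 0, 1.5); e2 <- rnorm(1, 0, 1.5)
            meanBreast <- baseGy + rnorm(1, 0, 1.2)
            rows[[p]] <- data.frame(
                patient_id = sprintf("P%04d", p),
                archetype = a$archetype, age = age,
                breast_volume_cm3 = vol,
                fat_volume_cm3 = vol * f, fg_volume_cm3 = vol * (1 - f),
                boost = boostFlag,
                median_hu = feat$median_hu, iqr_hu = feat$iqr_hu,
                uniformity = feat$uniformity,
                median_hu_contra = featC$median_hu,
                iqr_hu_contra = featC$iqr_hu,
                uniformity_contra = featC$uniformity,
                breast_mean_gy = meanBreast,
                breast_max_gy = meanBreast + abs(rnorm(1, 3, 1)),
                breast_uniformity = min(1, max(0.05,
                    0.6 + rnorm(1, 0, 0.1))),
                fat_mean_gy = meanBreast + e1,
                fat_max_gy = meanBreast + e1 + abs(rnorm(1, 2, 1)),
                fat_uniformity = min(1, max(0.05,
                    0.6 + 0.5 * rnorm(1, 0, 0.1) + rnorm(1, 0, 0.08))),
                fg_mean_gy = meanBreast + 0.5 * e1 + e2 + 1.5 * boostFlag,
                fg_max_gy = meanBreast + e2 + abs(rnorm(1, 3, 1)),
                fg_uniformity = min(1, max(0.05,
                    0.55 + rnorm(1, 0, 0.1))),
                stringsAsFactors = FALSE)
        }
    }
    records <- do.call(rbind, rows)
    rownames(records) <- NULL

    # ordinal outcomes from the latent proportional-odds model
    cutpoints <- c(0.4, 1.7, 3.0)
    zsc <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x)
                       else rep(0, length(x))
    for (ep in names(outcomeBetas)) {
        beta <- outcomeBetas[[ep]]
        bad <- setdiff(names(beta), names(records))
        if (length(bad))
            stop("outcome coefficients refer to unknown covariates: ",
                 paste(bad, collapse = ", "))
        eta0 <- if (length(beta))
            as.numeric(as.matrix(
                vapply(names(beta), function(v) zsc(records[[v]]),
                       numeric(nPatients))) %*% beta)
        else rep(0, nPatients)
        for (tp in names(timeAttenuation)) {
            g <- .drawGrades(eta0 * timeAttenuation[[tp]], cutpoints)
            records[[paste(ep, tp, "cro", sep = "_")]] <-
                .misgrade(g, misgradeProb, missingProb)
            records[[paste(ep, tp, "pro", sep = "_")]] <-
                .misgrade(g, misgradeProb, missingProb)
        }
    }

    truth <- list(outcomeBetas = outcomeBetas, cutpoints = cutpoints,
                  timeAttenuation = as.list(timeAttenuation),
                  archetype = arch$archetype[ai], fatFraction = fatFrac,
                  seed = seed)
    out <- list(records = records, truth = truth)
    if (imaging) out$phantoms <- phantoms
    out
}

#' Merge all CRO/PRO outcome columns of a cohort table
#'
#' Applies [mergeOutcomes()] to every `<endpoint>_<timepoint>_cro`/`_pro`
#' pair and adds the merged `<endpoint>_<timepoint>` column. With
#' `maxOverTime = TRUE` an additional `<endpoint>_max` column holds the
#' maximum merged severity across timepoints, the summary used when a
#' single per-endpoint score is wanted.
#'
#' @param records cohort data.frame.
#' @param endpoints,timepoints names scanned for grade columns.
#' @param maxOverTime also add per-endpoint maximum-over-time columns.
#' @return `records` with merged columns added.
#' @export
mergeCohortOutcomes <- function(records, endpoints = .ENDPOINTS,
                                timepoints = .TIMEPOINTS,
                                maxOverTime = FALSE) {
    for (ep in endpoints) {
        merged <- list()
        for (tp in timepoints) {
            croCol <- paste(ep, tp, "cro", sep = "_")
            proCol <- paste(ep, tp, "pro", sep = "_")
            if (!croCol %in% names(records) ||
                !proCol %in% names(records)) next
            m <- suppressMessages(
                mergeOutcomes(records[[croCol]], records[[proCol]]))
            records[[paste(ep, tp, sep = "_")]] <- m$grade
            merged[[tp]] <- m$grade
        }
        if (maxOverTime && length(merged)) {
            mm <- do.call(pmax, c(merged, list(na.rm = TRUE)))
            mm[Reduce(`&`, lapply(merged, is.na))] <- NA
            records[[paste(ep, "max", sep = "_")]] <- mm
        }
    }
    records
}

#' Simulate a feature-space cohort with known archetype labels
#'
#' Draws first-order feature vectors directly around the four archetype
#' feature centroids, with within-group spread set by a separation factor:
#' the isotropic within-group SD (in standardized feature space) is the
#' minimum between-centroid distance divided by `separation`. At the
#' default separation of 10 the groups are well separated and k-means
#' recovers them exactly.
#'
#' @param nPatients cohort size.
#' @param seed RNG seed.
#' @param separation between/within distance ratio (default 10).
#' @param probs archetype proportions.
#' @return data.frame: patient_id, archetype (truth), median_hu, iqr_hu,
#'   uniformity.
#' @export
simulateFeatureCohort <- function(nPatients, seed = 1, separation = 10,
                                  probs = rep(0.25, 4)) {
    set.seed(seed)
    cent <- rbind(fatty = c(-108, 25, 0.40),
                  scattered = c(-88, 42, 0.30),
                  heterogeneously_dense = c(-55, 62, 0.18),
                  extremely_dense = c(-20, 45, 0.24))
    colnames(cent) <- .FEATURES
    sc <- apply(cent, 2, sd)
    cz <- scale(cent, center = colMeans(cent), scale = sc)
    dmin <- min(dist(cz))
    sdz <- dmin / separation
    ai <- sample.int(4, nPatients, replace = TRUE, prob = probs)
    z <- cz[ai, ] + matrix(rnorm(3 * nPatients, 0, sdz), ncol = 3)
    x <- sweep(sweep(z, 2, sc, "*"), 2, colMeans(cent), "+")
    data.frame(patient_id = sprintf("P%04d", seq_len(nPatients)),
               archetype = factor(.DENSITY_LABELS[ai],
                                  levels = .DENSITY_LABELS),
               median_hu = x[, 1], iqr_hu = x[, 2], uniformity = x[, 3],
               stringsAsFactors = FALSE)
}
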