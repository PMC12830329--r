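test_that("EM recovers calibrated two-Gaussian mixtures", {
    set.seed(101)
    hu <- c(rnorm(7e4, -110, 5), rnorm(3e4, -52, 12))
    fit <- fitTwoComponentGMM(hu, refine = FALSE)
    expect_true(fit@converged)
    expect_lt(abs(mixMeans(fit)[1] - (-110)), 1)
    expect_lt(abs(mixMeans(fit)[2] - (-52)), 1)
    expect_lt(abs(mixSDs(fit)[1] - 5), 0.5)
    expect_lt(abs(mixSDs(fit)[2] - 12), 0.5)
    expect_lt(abs(mixWeights(fit)[1] - 0.7), 0.02)
    # the per-case window refinement preserves means and weights
    fitR <- fitTwoComponentGMM(hu)
    expect_lt(abs(mixMeans(fitR)[1] - (-110)), 1)
    expect_lt(abs(mixMeans(fitR)[2] - (-52)), 1)
    expect_lt(abs(mixWeights(fitR)[1] - 0.7), 0.02)
})

test_that("EM agrees with an independent mixture fitter", {
    set.seed(55)
    hu <- c(rnorm(3e4, -108, 6), rnorm(2e4, -40, 14))
    fit <- fitTwoComponentGMM(hu, refine = FALSE)
    mclustBIC <- mclust::mclustBIC   # Mclust resolves this in caller scope
    mc <- mclust::Mclust(hu, G = 2, modelNames = "V", verbose = FALSE)
    expect_lt(max(abs(sort(mc$parameters$mean) - mixMeans(fit))), 1.5)
    expect_lt(max(abs(sort(mc$parameters$pro) - sort(mixWeights(fit)))),
              0.02)
})

test_that("single-population input triggers the collapse guard", {
    set.seed(3)
    expect_error(fitTwoComponentGMM(rnorm(5000, -100, 0.4)), "collapse")
})

test_that("the fit depends only on the histogram, not voxel order", {
    set.seed(9)
    hu <- c(rnorm(2e4, -110, 5), rnorm(1e4, -52, 12))
    a <- fitTwoComponentGMM(hu)
    b <- fitTwoComponentGMM(sample(hu))
    expect_equal(mixMeans(a), mixMeans(b))
    expect_equal(mixWeights(a), mixWeights(b))
    expect_equal(a@logLik, b@logLik)
})

test_that("out-of-window values (clips, air) never enter the fit", {
    set.seed(13)
    hu <- c(rnorm(2e4, -110, 5), rnorm(1e4, -52, 12))
    contaminated <- c(hu, rep(800, 500), rep(-1000, 500))
    a <- fitTwoComponentGMM(hu)
    b <- fitTwoComponentGMM(contaminated)
    expect_equal(mixMeans(a), mixMeans(b))
    expect_equal(a@nVoxels, b@nVoxels)
    expect_error(fitTwoComponentGMM(rnorm(500, -100, 10)), "window")
})

test_that("thresholds are mean +/- nSD arithmetic", {
    fit <- new("GMMFit", weights = c(0.7, 0.3), means = c(-110, -52),
               sds = c(5, 12), logLik = 0, converged = TRUE,
               nIter = 1L, window = c(-200, 100), nVoxels = 1000L)
    thr <- deriveThresholds(fit)
    expect_equal(thr@fat, c(-120, -100))
    expect_equal(thr@fibroglandular, c(-76, -28))
    thr0 <- deriveThresholds(fit, nSD = 0)
    expect_equal(thr0@fat, c(-110, -110))
    expect_equal(thr0@fibroglandular, c(-52, -52))
    fit@converged <- FALSE
    expect_error(deriveThresholds(fit), "non-converged")
})

test_that("fat priority decides overlapping intervals", {
    thr <- new("TissueThresholds", fat = c(-120, -50),
               fibroglandular = c(-76, -28), nSD = 2)
    vol <- ImageVolume(array(-60, dim = c(4, 4, 4)))
    breast <- StructureMask("breast", array(TRUE, dim = c(4, 4, 4)),
                            reference = vol)
    seg <- segmentTissues(vol, breast, thr)
    expect_equal(seg@fatPct, 100)
    expect_equal(seg@fibroPct, 0)
    # a voxel in the fat interval is never fibroglandular, whatever the
    # overlap
    set.seed(8)
    vol2 <- ImageVolume(array(runif(64, -130, -20), dim = c(4, 4, 4)))
    seg2 <- segmentTissues(vol2, breast, thr)
    inFat <- voxels(vol2) >= -120 & voxels(vol2) <= -50
    expect_false(any(voxels(seg2@fibroglandular)[inFat]))
})

test_that("values outside both intervals stay unclassified", {
    thr <- new("TissueThresholds", fat = c(-120, -100),
               fibroglandular = c(-76, -28), nSD = 2)
    vol <- ImageVolume(array(200, dim = c(3, 3, 3)))
    breast <- StructureMask("breast", array(TRUE, dim = c(3, 3, 3)),
                            reference = vol)
    seg <- segmentTissues(vol, breast, thr)
    expect_equal(seg@unclassifiedPct, 100)
})

test_that("segmentation partitions the breast mask on every input", {
    for (a in c("fatty", "extremely_dense")) {
        ph <- generateBreastPhantom(
            phantomSpec(a, gridDim = c(36, 36, 22), spacing = c(2.5, 2.5, 2.5),
                        breastRadiusMm = 30), seed = 17)
        seg <- classifyBreastTissue(ph$ct, ph$breast,
                                    minVoxels = 500)$segmentation
        u <- voxels(seg@fat) | voxels(seg@fibroglandular) |
            voxels(seg@unclassified)
        expect_identical(u, voxels(ph$breast))
        expect_false(any(voxels(seg@fat) & voxels(seg@fibroglandular)))
        pct <- compositionPct(seg)
        expect_equal(sum(pct), 100)
    }
})

test_that("segmentation recovers phantom ground truth at calibrated
           separations", {
    ph <- generateBreastPhantom(phantomSpec("fatty"), seed = 23)
    seg <- classifyBreastTissue(ph$ct, ph$breast)$segmentation
    expect_gte(diceCoef(seg@fat, ph$fatTruth), 0.95)
    expect_gte(diceCoef(seg@fibroglandular, ph$fgTruth), 0.95)
})

test_that("enlarging nSD never shrinks classified coverage", {
    ph <- generateBreastPhantom(
        phantomSpec("scattered", gridDim = c(36, 36, 22),
                    spacing = c(2.5, 2.5, 2.5), breastRadiusMm = 30),
        seed = 31)
    fit <- fitTwoComponentGMM(ph$ct, ph$breast, minVoxels = 500)
    cov <- vapply(c(0.5, 1, 2, 3), function(ns) {
        seg <- segmentTissues(ph$ct, ph$breast,
                              deriveThresholds(fit, nSD = ns))
        100 - seg@unclassifiedPct
    }, numeric(1))
    expect_true(all(diff(cov) >= 0))
})

test_that("fat fraction is recovered across the composition range", {
    # the mixture weight of the fat component is the fat-fraction estimate
    fracs <- seq(0.2, 0.9, length.out = 50)
    err <- vapply(seq_along(fracs), function(i) {
        set.seed(400 + i)
        n <- 2e4
        nf <- round(n * fracs[i])
        hu <- c(rnorm(nf, -110, 5), rnorm(n - nf, -52, 12))
        fit <- fitTwoComponentGMM(hu)
        abs(mixWeights(fit)[1] - fracs[i])
    }, numeric(1))
    expect_lt(mean(err) * 100, 2)   # mean abs error below 2 pct points
})

test_that("label maps round trip through NIfTI", {
    ph <- generateBreastPhantom(
        phantomSpec("fatty", gridDim = c(26, 26, 16), spacing = c(2, 2, 2),
                    breastRadiusMm = 18), seed = 2)
    seg <- classifyBreastTissue(ph$ct, ph$breast,
                                minVoxels = 200)$segmentation
    f <- withr::local_tempfile(fileext = ".nii")
    writeSegmentation(seg, f)
    lab <- voxels(readVolume(f))
    expect_equal(sum(lab == 1), nVoxels(seg@fat))
    expect_equal(sum(lab == 2), nVoxels(seg@fibroglandular))
    expect_equal(sum(lab == 3), nVoxels(seg@unclassified))
})
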