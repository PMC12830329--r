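test_that("NIfTI round trip preserves voxels and geometry", {
    set.seed(11)
    vol <- ImageVolume(array(rnorm(4 * 5 * 6, -80, 40), dim = c(4, 5, 6)),
                       spacing = c(1.5, 2, 2.5), origin = c(-10, -20, 5))
    f <- withr::local_tempfile(fileext = ".nii")
    writeVolume(vol, f)
    back <- readVolume(f)
    expect_equal(voxels(back), voxels(vol))
    expect_equal(spacing(back), spacing(vol))
    expect_equal(origin(back), origin(vol))

    msk <- StructureMask("breast",
                         array(runif(4 * 5 * 6) > 0.5, dim = c(4, 5, 6)),
                         reference = vol)
    fm <- withr::local_tempfile(fileext = ".nii")
    writeMask(msk, fm)
    backM <- readMask(fm, name = "breast", reference = vol)
    expect_identical(voxels(backM), voxels(msk))

    dg <- DoseGrid(array(runif(4 * 5 * 6, 0, 50), dim = c(4, 5, 6)),
                   spacing = c(1.5, 2, 2.5), origin = c(-10, -20, 5),
                   fractions = 15)
    fd <- withr::local_tempfile(fileext = ".nii")
    writeDose(dg, fd)
    expect_equal(voxels(readDose(fd, fractions = 15)), voxels(dg))
    expect_error(readDose(fd), "fractions")
})

test_that("grid objects validate geometry invariants", {
    expect_error(ImageVolume(array(0, dim = c(2, 2, 2)),
                             spacing = c(1, 0, 1)), "spacing")
    expect_error(ImageVolume(array(c(NA, rep(0, 7)), dim = c(2, 2, 2))),
                 "finite")
    expect_error(DoseGrid(array(-1, dim = c(2, 2, 2)), fractions = 1),
                 "non-negative")
    expect_error(DoseGrid(array(1, dim = c(2, 2, 2)), fractions = 0),
                 "fractions")
    expect_error(StructureMask("m", array(TRUE, dim = c(2, 2, 2)),
                               reference = ImageVolume(
                                   array(0, dim = c(3, 3, 3)))),
                 "does not match")
})

test_that("square contour rasterizes to its analytic voxel count", {
    ref <- ImageVolume(array(0, dim = c(30, 30, 5)))
    sq <- data.frame(structure = "sq", contour_id = 1,
                     x_mm = c(4.5, 14.5, 14.5, 4.5),
                     y_mm = c(4.5, 4.5, 14.5, 14.5), z_mm = 2)
    m <- rasterizeContours(sq, ref)$sq
    expect_equal(nVoxels(m), 100)
    expect_equal(sum(voxels(m)[, , 3]), 100)   # z = 2 mm is slice 3
})

test_that("mask -> contours -> mask round trip is near-lossless", {
    ph <- generateBreastPhantom(
        phantomSpec("scattered", gridDim = c(36, 36, 20),
                    spacing = c(2, 2, 2), breastRadiusMm = 28),
        seed = 4)
    ct <- maskToContours(ph$breast)
    m2 <- rasterizeContours(ct, ph$ct)$breast
    expect_gte(diceCoef(m2, ph$breast), 0.99)
})

test_that("off-grid contours clip to an empty mask with warnings", {
    ref <- ImageVolume(array(0, dim = c(10, 10, 3)))
    off <- data.frame(structure = "off", contour_id = 1,
                      x_mm = c(100, 110, 110, 100),
                      y_mm = c(100, 100, 110, 110), z_mm = 1)
    expect_warning(expect_warning(r <- rasterizeContours(off, ref),
                                  "clipped"), "empty")
    expect_equal(nVoxels(r$off), 0)
})

test_that("resampling is exact for identity, constants and planes", {
    ct <- ImageVolume(array(0, dim = c(10, 12, 8)), spacing = c(2, 2, 2))
    # identity: dose already on the CT grid
    set.seed(2)
    dv <- array(runif(10 * 12 * 8, 10, 50), dim = c(10, 12, 8))
    dg <- DoseGrid(dv, spacing = c(2, 2, 2), fractions = 15)
    expect_equal(voxels(resampleDoseToCT(dg, ct)), dv)
    # constant field on a coarser grid
    cg <- DoseGrid(array(40, dim = c(6, 7, 5)), spacing = c(4, 4, 4),
                   fractions = 15)
    rs <- resampleDoseToCT(cg, ct)
    expect_true(all(voxels(rs)[!rs@outside] == 40))
    # linear plane interpolates exactly (trilinear reproduces affine fields)
    plane <- function(x, y, z) 10 + 0.3 * x + 0.2 * y + 0.1 * z
    dvp <- array(0, dim = c(6, 7, 5))
    for (i in 1:6) for (j in 1:7) for (k in 1:5)
        dvp[i, j, k] <- plane((i - 1) * 4, (j - 1) * 4, (k - 1) * 4)
    pg <- DoseGrid(dvp, spacing = c(4, 4, 4), fractions = 15)
    rp <- resampleDoseToCT(pg, ct)
    want <- array(0, dim = c(10, 12, 8))
    for (i in 1:10) for (j in 1:12) for (k in 1:8)
        want[i, j, k] <- plane((i - 1) * 2, (j - 1) * 2, (k - 1) * 2)
    expect_lt(max(abs(voxels(rp)[!rp@outside] - want[!rp@outside])), 1e-6)
})

test_that("resampling flags voxels outside the dose extent and rejects
           disjoint grids", {
    ct <- ImageVolume(array(0, dim = c(10, 10, 10)), spacing = c(2, 2, 2))
    small <- DoseGrid(array(40, dim = c(3, 3, 3)), spacing = c(2, 2, 2),
                      origin = c(4, 4, 4), fractions = 5)
    rs <- resampleDoseToCT(small, ct)
    expect_true(any(rs@outside))
    expect_true(all(voxels(rs)[rs@outside] == 0))
    far <- DoseGrid(array(40, dim = c(3, 3, 3)), origin = c(500, 500, 500),
                    fractions = 5)
    expect_error(resampleDoseToCT(far, ct), "disjoint")
})

test_that("slab crop removes exactly the layers nearest the surface", {
    sl <- slabPhantom(dims = c(12, 12, 10), bodyZ = 8)
    cr <- cropFromSkin(sl$breast, sl$body, marginMm = 5)
    perSlice <- apply(voxels(cr), 3, sum)
    # body occupies z-slices 1..8; exterior starts at slice 9, so slices
    # 4..8 (distance 5..1 mm) go, slices 1..3 stay
    expect_equal(perSlice, c(144, 144, 144, rep(0, 7)))
    # margin 0 is the identity on a valid input
    cr0 <- cropFromSkin(sl$breast, sl$body, marginMm = 0)
    expect_identical(voxels(cr0), voxels(sl$breast))
    # a margin deeper than the slab kills the structure
    expect_error(cropFromSkin(sl$breast, sl$body, marginMm = 20),
                 "unusable")
})

test_that("hemisphere crop matches an exhaustive distance computation", {
    ph <- generateBreastPhantom(
        phantomSpec("heterogeneously_dense", gridDim = c(26, 26, 16),
                    spacing = c(2, 2, 2), breastRadiusMm = 18), seed = 9)
    margin <- 5
    cr <- cropFromSkin(ph$breast, ph$body, marginMm = margin)
    d <- bruteDistance(!voxels(ph$body), spacing(ph$body))
    keepBrute <- voxels(ph$breast) & (d > margin)
    expect_identical(voxels(cr), keepBrute)
})

test_that("cropping is monotone in the margin", {
    ph <- generateBreastPhantom(
        phantomSpec("fatty", gridDim = c(26, 26, 16), spacing = c(2, 2, 2),
                    breastRadiusMm = 20), seed = 3)
    margins <- c(0, 2, 4, 6)
    masks <- lapply(margins, function(m)
        voxels(cropFromSkin(ph$breast, ph$body, marginMm = m)))
    for (i in seq_along(margins)[-1])
        expect_true(all(masks[[i]] <= masks[[i - 1]]))
})

test_that("breast voxels outside the body are dropped with a warning", {
    sl <- slabPhantom(bodyZ = 7)
    bad <- voxels(sl$breast)
    bad[1, 1, 9] <- TRUE   # above the body slab
    breast <- StructureMask("breast", bad, reference = sl$ct)
    expect_warning(cr <- cropFromSkin(breast, sl$body, marginMm = 0),
                   "outside the body")
    expect_false(voxels(cr)[1, 1, 9])
})
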