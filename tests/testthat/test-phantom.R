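test_that("phantoms are deterministic and hit the target fat fraction", {
    spec <- phantomSpec("fatty", fatFraction = 0.70)
    a <- generateBreastPhantom(spec, seed = 5)
    b <- generateBreastPhantom(spec, seed = 5)
    expect_identical(voxels(a$ct), voxels(b$ct))
    expect_identical(voxels(a$fatTruth), voxels(b$fatTruth))
    frac <- nVoxels(a$fatTruth) / nVoxels(a$breast)
    expect_lt(abs(frac - 0.70), 0.005)
    # truths partition the breast
    expect_identical(voxels(a$fatTruth) | voxels(a$fgTruth),
                     voxels(a$breast))
    expect_false(any(voxels(a$fatTruth) & voxels(a$fgTruth)))
})

test_that("generated HU mixtures match their calibration", {
    ph <- generateBreastPhantom(phantomSpec("fatty",
                                            gridDim = c(96, 96, 64),
                                            spacing = c(1.5, 1.5, 1.5)),
                                seed = 12)
    expect_gte(nVoxels(ph$breast), 1e5)
    fatHU <- voxels(ph$ct)[voxels(ph$fatTruth)]
    fgHU <- voxels(ph$ct)[voxels(ph$fgTruth)]
    expect_lt(abs(mean(fatHU) - (-110)), 1)
    expect_lt(abs(mean(fgHU) - (-52)), 1)
    expect_lt(abs(sd(fatHU) - 5), 0.5)
    expect_lt(abs(sd(fgHU) - 12), 0.5)
})

test_that("clip voxels appear at the clip HU inside the breast", {
    ph <- generateBreastPhantom(phantomSpec("fatty", clipVoxels = 20),
                                seed = 3)
    clips <- voxels(ph$ct) == 800
    expect_equal(sum(clips), 20)
    expect_true(all(voxels(ph$breast)[clips]))
})

test_that("degenerate specs are rejected", {
    expect_error(phantomSpec("fatty", fatFraction = 0), "strictly")
    expect_error(phantomSpec("fatty", fatHU = c(-50, 5),
                             fgHU = c(-110, 12)), "below")
    expect_error(phantomSpec("fatty", fatHU = c(-110, 0)), "positive")
})

test_that("dose generator produces the stated analytic fields", {
    ph <- generateBreastPhantom(
        phantomSpec("fatty", gridDim = c(36, 36, 22),
                    spacing = c(2.5, 2.5, 2.5), breastRadiusMm = 30),
        seed = 7)
    # constant field
    flat <- generateDose(ph$breast, baseGy = 40.05)
    expect_true(all(voxels(flat) == 40.05))
    expect_equal(doseMetrics(flat, ph$breast)$uniformity, 1)
    expect_equal(nFractions(flat), 15L)
    # gradient centred on the breast: breast mean equals the base dose
    # within discretization error of the hemisphere's symmetry
    gr <- generateDose(ph$breast, baseGy = 40, gradientGyPerMm = 0.05,
                       gradientAxis = 1)
    m <- doseMetrics(gr, ph$breast)$mean_gy
    expect_lt(abs(m - 40), 0.05)
    # boost must land inside the breast
    outside <- array(FALSE, dim = dim(voxels(ph$ct)))
    outside[1, 1, 1] <- TRUE
    om <- StructureMask("elsewhere", outside, reference = ph$ct)
    expect_error(generateDose(ph$breast, boost = list(amplitudeGy = 8,
                                                      sigmaMm = 10),
                              boostIn = om), "outside the breast")
    expect_error(generateDose(ph$breast, boost = list(amplitudeGy = 8,
                                                      sigmaMm = 10)),
                 "missing or empty")
})

test_that("cohorts are deterministic and carry machine-readable truth", {
    a <- generateCohort(40, seed = 9)
    b <- generateCohort(40, seed = 9)
    expect_identical(a$records, b$records)
    expect_named(a$truth,
                 c("outcomeBetas", "cutpoints", "timeAttenuation",
                   "archetype", "fatFraction", "seed"))
    expect_equal(length(a$truth$archetype), 40L)
    grades <- unlist(a$records[grep("_(cro|pro)$", names(a$records))])
    expect_true(all(is.na(grades) | grades %in% 0:3))
})

test_that("null outcome coefficients leave grades unlinked to dose", {
    coh <- generateCohort(800, seed = 13,
                          outcomeBetas = list(pain = numeric()),
                          missingProb = 0)
    rec <- mergeCohortOutcomes(coh$records, endpoints = "pain",
                               timepoints = "post")
    f <- fitOrdinal(rec, "pain_post", "fat_mean_gy")
    expect_lt(abs(f@coefficients$estimate), 0.15)
    expect_gt(f@coefficients$p, 0.01)
})

test_that("imaging cohorts couple outcomes to measured phantom dosimetry", {
    coh <- generateCohort(12, seed = 15, imaging = TRUE,
                          gridDim = c(32, 32, 22),
                          spacing = c(4, 4, 4))
    expect_length(coh$phantoms, 12L)
    ph <- coh$phantoms[[1]]
    expect_s4_class(ph$dose, "DoseGrid")
    # the record's dose metrics are those measured on the phantom truth
    m <- doseMetrics(ph$dose, ph$fatTruth)
    expect_equal(coh$records$fat_mean_gy[1], m$mean_gy)
    # volume-density coupling across archetypes
    v <- tapply(coh$records$breast_volume_cm3, coh$records$archetype,
                mean)
    if (all(c("fatty", "extremely_dense") %in% names(v)))
        expect_gt(v[["fatty"]], v[["extremely_dense"]])
})

test_that("separated feature cohorts expose the archetype geometry", {
    fc <- simulateFeatureCohort(160, seed = 21, separation = 10)
    cen <- aggregate(fc[c("median_hu", "iqr_hu", "uniformity")],
                     list(archetype = fc$archetype), mean)
    # fatty: lowest median, highest uniformity; heterogeneously dense:
    # widest IQR, lowest uniformity
    expect_equal(as.character(cen$archetype[which.min(cen$median_hu)]),
                 "fatty")
    expect_equal(as.character(cen$archetype[which.max(cen$uniformity)]),
                 "fatty")
    expect_equal(as.character(cen$archetype[which.max(cen$iqr_hu)]),
                 "heterogeneously_dense")
    expect_equal(as.character(cen$archetype[which.min(cen$uniformity)]),
                 "heterogeneously_dense")
})
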