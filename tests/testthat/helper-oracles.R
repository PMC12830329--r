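# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force loops and closed forms only.

diceCoef <- function(a, b) {
    if (is(a, "StructureMask")) a <- voxels(a)
    if (is(b, "StructureMask")) b <- voxels(b)
    2 * sum(a & b) / (sum(a) + sum(b))
}

# exhaustive anisotropic distance from every voxel centre to the nearest
# seed voxel centre (O(N * nseed); small fixtures only)
bruteDistance <- function(seed, spacing) {
    idx <- which(seed, arr.ind = TRUE)
    d <- array(Inf, dim = dim(seed))
    all <- which(array(TRUE, dim = dim(seed)), arr.ind = TRUE)
    for (r in seq_len(nrow(all))) {
        dd <- ((all[r, 1] - idx[, 1]) * spacing[1])^2 +
              ((all[r, 2] - idx[, 2]) * spacing[2])^2 +
              ((all[r, 3] - idx[, 3]) * spacing[3])^2
        d[all[r, 1], all[r, 2], all[r, 3]] <- sqrt(min(dd))
    }
    d
}

# brute-force sum of squared bin probabilities over an explicit histogram
bruteUniformity <- function(values, width) {
    e0 <- floor(min(values) / width) * width
    breaks <- seq(e0, max(values) + width, by = width)
    cnt <- as.vector(table(cut(values, breaks, right = FALSE)))
    stopifnot(sum(cnt) == length(values))
    sum((cnt / length(values))^2)
}

# tiny slab-phantom builder shared by io/dosimetry tests
slabPhantom <- function(dims = c(12, 12, 10), spacing = c(1, 1, 1),
                        bodyZ = 7) {
    body <- array(FALSE, dim = dims)
    body[, , seq_len(bodyZ)] <- TRUE
    ct <- ImageVolume(array(-50, dim = dims), spacing = spacing)
    list(ct = ct,
         body = StructureMask("body", body, reference = ct),
         breast = StructureMask("breast", body, reference = ct))
}
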