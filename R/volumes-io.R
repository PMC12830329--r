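#' Construct an ImageVolume
#'
#' @param voxels 3-D numeric array of HU values.
#' @param spacing numeric(3), voxel spacing in mm (x, y, z).
#' @param origin numeric(3), world coordinate (mm) of the centre of voxel
#'   (1,1,1). Defaults to (0,0,0).
#' @return an [ImageVolume-class] object.
#' @examples
#' vol <- ImageVolume(array(-100, dim = c(4, 4, 2)), spacing = c(1, 1, 2))
#' spacing(vol)
#' @export
ImageVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    storage.mode(voxels) <- "double"
    new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' Construct a StructureMask
#'
#' @param name structure name.
#' @param voxels 3-D logical array.
#' @param reference an [ImageVolume-class] (or other grid object) providing
#'   geometry; alternatively pass `spacing` and `origin` directly.
#' @param spacing,origin geometry if no reference is given.
#' @return a [StructureMask-class] object.
#' @export
StructureMask <- function(name, voxels, reference = NULL,
                          spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    if (!is.null(reference)) {
        if (!identical(dim(voxels), dim(reference@voxels)))
            stop("mask shape ", paste(dim(voxels), collapse = "x"),
                 " does not match reference grid ",
                 paste(dim(reference@voxels), collapse = "x"))
        spacing <- reference@spacing
        origin <- reference@origin
    }
    new("StructureMask", name = as.character(name),
        voxels = array(as.logical(voxels), dim = dim(voxels)),
        spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' Construct a DoseGrid
#'
#' @param voxels 3-D numeric array of dose in Gy.
#' @param spacing,origin grid geometry in mm.
#' @param fractions delivered fraction count (>= 1).
#' @param outside optional logical array flagging voxels outside the
#'   original dose extent (set by [resampleDoseToCT()]).
#' @return a [DoseGrid-class] object.
#' @export
DoseGrid <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     fractions, outside = array(FALSE, dim = dim(voxels))) {
    storage.mode(voxels) <- "double"
    new("DoseGrid", voxels = voxels, spacing = as.numeric(spacing),
        origin = as.numeric(origin), fractions = as.integer(fractions),
        outside = array(as.logical(outside), dim = dim(outside)))
}

#' Construct a FractionationScheme
#'
#' @param nFractions delivered fraction count.
#' @param alphaBeta linear-quadratic alpha/beta ratio in Gy; the default
#'   1.7 Gy is the late-breast-effects value.
#' @return a [FractionationScheme-class] object.
#' @export
FractionationScheme <- function(nFractions, alphaBeta = 1.7) {
    if (missing(nFractions) || is.null(nFractions) || is.na(nFractions))
        stop("nFractions is required; there is no silent default")
    new("FractionationScheme", nFractions = as.integer(nFractions),
        alphaBeta = as.numeric(alphaBeta))
}

# geometry congruence check used everywhere two grids must align
.sameGeometry <- function(a, b, tol = 1e-6) {
    identical(dim(a@voxels), dim(b@voxels)) &&
        max(abs(a@spacing - b@spacing)) < tol &&
        max(abs(a@origin - b@origin)) < tol
}

.stopIfIncongruent <- function(a, b, what = "grids") {
    if (!.sameGeometry(a, b))
        stop(what, " are not geometry-congruent (shape/spacing/origin differ)")
    invisible(TRUE)
}

# world coordinates of voxel centres along one axis
.axisCoords <- function(obj, axis) {
    obj@origin[axis] + (seq_len(dim(obj@voxels)[axis]) - 1) * obj@spacing[axis]
}

## ---- NIfTI I/O -------------------------------------------------------------

.niftiRef <- function(spacing, origin) {
    list(pixdim = c(1, spacing, 1, 1, 1, 1),
         qoffset_x = origin[1], qoffset_y = origin[2], qoffset_z = origin[3],
         qform_code = 1L)
}

.readNiftiGrid <- function(path) {
    img <- RNifti::readNifti(path)
    arr <- array(as.vector(img), dim = dim(img))
    if (length(dim(arr)) != 3L)
        stop("expected a 3-D NIfTI volume, got ",
             length(dim(arr)), "-D: ", path)
    sp <- RNifti::pixdim(img)[1:3]
    xf <- RNifti::xform(img)
    if (any(abs(diag(xf)[1:3] - sp) > 1e-4))
        warning("non-axis-aligned or flipped NIfTI orientation in ", path,
                "; voxel geometry taken from pixdim/offset as-is")
    list(voxels = arr, spacing = abs(sp), origin = xf[1:3, 4])
}

#' Read a CT volume from NIfTI
#'
#' NIfTI is the array+metadata interchange format accepted everywhere in
#' this package; voxel values are taken as Hounsfield units as stored.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return an [ImageVolume-class].
#' @seealso [writeVolume()], [readMask()]
#' @export
readVolume <- function(path) {
    g <- .readNiftiGrid(path)
    ImageVolume(g$voxels, spacing = g$spacing, origin = g$origin)
}

#' Write a CT volume to NIfTI
#'
#' @param volume an [ImageVolume-class].
#' @param path output `.nii` or `.nii.gz` path.
#' @return the path, invisibly.
#' @export
writeVolume <- function(volume, path) {
    img <- RNifti::asNifti(volume@voxels,
                           reference = .niftiRef(volume@spacing,
                                                 volume@origin),
                           datatype = "double")
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Read a structure mask from NIfTI
#'
#' Non-zero voxels become mask members.
#'
#' @param path NIfTI path.
#' @param name structure name to attach; defaults to the file stem.
#' @param reference optional [ImageVolume-class] whose geometry the mask
#'   must match (checked).
#' @return a [StructureMask-class].
#' @export
readMask <- function(path, name = NULL, reference = NULL) {
    g <- .readNiftiGrid(path)
    if (is.null(name))
        name <- sub("\\.nii(\\.gz)?$", "", basename(path))
    m <- StructureMask(name, g$voxels != 0, spacing = g$spacing,
                       origin = g$origin)
    if (!is.null(reference))
        .stopIfIncongruent(m, reference, "mask and reference CT")
    m
}

#' Write a structure mask to NIfTI (uint8, 0/1)
#'
#' @param mask a [StructureMask-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
    img <- RNifti::asNifti(array(as.integer(mask@voxels),
                                 dim = dim(mask@voxels)),
                           reference = .niftiRef(mask@spacing, mask@origin),
                           datatype = "uint8")
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Read a dose grid from NIfTI
#'
#' @param path NIfTI path with dose in Gy.
#' @param fractions delivered fraction count; required (no silent default).
#' @return a [DoseGrid-class].
#' @export
readDose <- function(path, fractions) {
    if (missing(fractions))
        stop("fractions is required when reading a dose grid")
    g <- .readNiftiGrid(path)
    DoseGrid(g$voxels, spacing = g$spacing, origin = g$origin,
             fractions = fractions)
}

#' Write a dose grid to NIfTI
#'
#' The fraction count is not representable in NIfTI and must be carried in
#' configuration; [readDose()] requires it back explicitly.
#'
#' @param dose a [DoseGrid-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDose <- function(dose, path) {
    img <- RNifti::asNifti(dose@voxels,
                           reference = .niftiRef(dose@spacing, dose@origin),
                           datatype = "double")
    RNifti::writeNifti(img, path)
    invisible(path)
}

## ---- contour rasterization -------------------------------------------------

#' Read a plain-text contour table
#'
#' The contour interchange format is a CSV with columns `structure`,
#' `contour_id` (integer; one closed polygon per id), `x_mm`, `y_mm`,
#' `z_mm` (world coordinates of the polygon vertices, in order). Each
#' contour lies in a single axial plane (constant `z_mm`).
#'
#' @param path CSV path.
#' @return a data.frame with the columns above.
#' @export
readContourTable <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("structure", "contour_id", "x_mm", "y_mm", "z_mm")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("contour table lacks columns: ", paste(miss, collapse = ", "))
    df
}

# even-odd (crossing-number) test of points against one polygon;
# px, py vectors; vx, vy polygon vertices (closed implicitly)
.pointInPolygon <- function(px, py, vx, vy) {
    n <- length(vx)
    inside <- logical(length(px))
    j <- n
    for (i in seq_len(n)) {
        crosses <- ((vy[i] > py) != (vy[j] > py))
        if (any(crosses)) {
            xint <- vx[i] + (py[crosses] - vy[i]) / (vy[j] - vy[i]) *
                (vx[j] - vx[i])
            inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
        }
        j <- i
    }
    inside
}

#' Rasterize planar contours onto a reference grid
#'
#' Each closed polygon is rasterized per axial slice with a
#' voxel-centre-in-polygon (even-odd) rule; multiple polygons of one
#' structure on a slice combine by exclusive-or, so nested contours create
#' holes. Contour vertices outside the grid are clipped with a warning;
#' a structure with no in-grid voxels yields an empty mask with a warning.
#'
#' @param contours a contour table as from [readContourTable()].
#' @param reference the [ImageVolume-class] defining the target grid.
#' @return a named list of [StructureMask-class] objects, one per structure.
#' @export
rasterizeContours <- function(contours, reference) {
    xs <- .axisCoords(reference, 1)
    ys <- .axisCoords(reference, 2)
    zs <- .axisCoords(reference, 3)
    dz <- reference@spacing[3]
    dims <- dim(reference@voxels)
    out <- list()
    for (sname in unique(contours$structure)) {
        sdf <- contours[contours$structure == sname, , drop = FALSE]
        mk <- array(FALSE, dim = dims)
        clipped <- FALSE
        for (cid in unique(sdf$contour_id)) {
            poly <- sdf[sdf$contour_id == cid, , drop = FALSE]
            if (nrow(poly) < 3L) next
            zc <- poly$z_mm[1]
            k <- which.min(abs(zs - zc))
            if (abs(zs[k] - zc) > dz / 2 + 1e-9) {
                clipped <- TRUE
                next
            }
            ix <- which(xs >= min(poly$x_mm) - 1e-9 &
                        xs <= max(poly$x_mm) + 1e-9)
            iy <- which(ys >= min(poly$y_mm) - 1e-9 &
                        ys <= max(poly$y_mm) + 1e-9)
            hx <- reference@spacing[1] / 2
            hy <- reference@spacing[2] / 2
            if (min(poly$x_mm) < xs[1] - hx - 1e-9 ||
                max(poly$x_mm) > xs[length(xs)] + hx + 1e-9 ||
                min(poly$y_mm) < ys[1] - hy - 1e-9 ||
                max(poly$y_mm) > ys[length(ys)] + hy + 1e-9)
                clipped <- TRUE
            if (!length(ix) || !length(iy)) next
            gp <- expand.grid(ix = ix, iy = iy)
            inside <- .pointInPolygon(xs[gp$ix], ys[gp$iy],
                                      poly$x_mm, poly$y_mm)
            sel <- cbind(gp$ix[inside], gp$iy[inside], k)
            mk[sel] <- xor(mk[sel], TRUE)
        }
        if (clipped)
            warning("structure '", sname,
                    "' extends beyond the reference grid; clipped")
        if (!any(mk))
            warning("structure '", sname, "' rasterized to an empty mask")
        out[[sname]] <- StructureMask(sname, mk, reference = reference)
    }
    out
}

#' Extract planar contours from a mask (marching per slice)
#'
#' The inverse of [rasterizeContours()] for simply-connected regions:
#' traces the boundary of each slice's connected voxel set as the outline
#' of its voxel squares is approximated by the convex-free row-run
#' outline. Intended for round-trip testing; contours are returned at
#' voxel-boundary resolution.
#'
#' @param mask a [StructureMask-class].
#' @return a contour table (see [readContourTable()]).
#' @keywords internal
#' @export
maskToContours <- function(mask) {
    xs <- .axisCoords(mask, 1)
    ys <- .axisCoords(mask, 2)
    zs <- .axisCoords(mask, 3)
    hx <- mask@spacing[1] / 2
    hy <- mask@spacing[2] / 2
    rows <- list()
    cid <- 0L
    for (k in seq_along(zs)) {
        sl <- mask@voxels[, , k]
        if (!any(sl)) next
        # one rectilinear polygon per contiguous row-run, XOR-combined
        for (j in seq_along(ys)) {
            runs <- rle(sl[, j])
            ends <- cumsum(runs$lengths)
            starts <- ends - runs$lengths + 1L
            for (r in which(runs$values)) {
                cid <- cid + 1L
                x0 <- xs[starts[r]] - hx
                x1 <- xs[ends[r]] + hx
                y0 <- ys[j] - hy
                y1 <- ys[j] + hy
                rows[[length(rows) + 1L]] <- data.frame(
                    structure = mask@name, contour_id = cid,
                    x_mm = c(x0, x1, x1, x0), y_mm = c(y0, y0, y1, y1),
                    z_mm = zs[k])
            }
        }
    }
    if (!length(rows))
        return(data.frame(structure = character(), contour_id = integer(),
                          x_mm = numeric(), y_mm = numeric(),
                          z_mm = numeric()))
    do.call(rbind, rows)
}

## ---- dose resampling -------------------------------------------------------

#' Resample a dose grid onto the CT grid (trilinear)
#'
#' Dose is interpolated trilinearly at every CT voxel centre. CT voxels
#' outside the dose extent receive zero dose and are flagged in the
#' `outside` slot; interpolation never extrapolates.
#'
#' @param dose a [DoseGrid-class] on its own geometry.
#' @param ct the target [ImageVolume-class].
#' @return a [DoseGrid-class] congruent with `ct`.
#' @export
resampleDoseToCT <- function(dose, ct) {
    dd <- dim(dose@voxels)
    # continuous (0-based) dose-grid coordinates of CT voxel centres, per axis
    u <- lapply(1:3, function(a)
        (.axisCoords(ct, a) - dose@origin[a]) / dose@spacing[a])
    lo <- vapply(u, min, 0); hi <- vapply(u, max, 0)
    if (any(hi < 0) || any(lo > dd - 1))
        stop("dose and CT extents are disjoint; cannot resample")
    dims <- dim(ct@voxels)
    ux <- u[[1]]; uy <- u[[2]]; uz <- u[[3]]
    inx <- ux >= 0 & ux <= dd[1] - 1
    iny <- uy >= 0 & uy <= dd[2] - 1
    inz <- uz >= 0 & uz <= dd[3] - 1
    out <- array(0, dim = dims)
    outside <- array(TRUE, dim = dims)
    ii <- which(inx); jj <- which(iny); kk <- which(inz)
    if (length(ii) && length(jj) && length(kk)) {
        gx <- ux[ii]; gy <- uy[jj]; gz <- uz[kk]
        fx0 <- pmin(floor(gx), dd[1] - 2); fx0 <- pmax(fx0, 0)
        fy0 <- pmin(floor(gy), dd[2] - 2); fy0 <- pmax(fy0, 0)
        fz0 <- pmin(floor(gz), dd[3] - 2); fz0 <- pmax(fz0, 0)
        if (dd[1] == 1) fx0 <- rep(0, length(gx))
        if (dd[2] == 1) fy0 <- rep(0, length(gy))
        if (dd[3] == 1) fz0 <- rep(0, length(gz))
        tx <- gx - fx0; ty <- gy - fy0; tz <- gz - fz0
        g <- expand.grid(a = seq_along(ii), b = seq_along(jj),
                         c = seq_along(kk))
        i0 <- fx0[g$a] + 1L; j0 <- fy0[g$b] + 1L; k0 <- fz0[g$c] + 1L
        wx <- tx[g$a]; wy <- ty[g$b]; wz <- tz[g$c]
        i1 <- pmin(i0 + 1L, dd[1]); j1 <- pmin(j0 + 1L, dd[2])
        k1 <- pmin(k0 + 1L, dd[3])
        dv <- dose@voxels
        val <-
            dv[cbind(i0, j0, k0)] * (1 - wx) * (1 - wy) * (1 - wz) +
            dv[cbind(i1, j0, k0)] * wx       * (1 - wy) * (1 - wz) +
            dv[cbind(i0, j1, k0)] * (1 - wx) * wy       * (1 - wz) +
            dv[cbind(i1, j1, k0)] * wx       * wy       * (1 - wz) +
            dv[cbind(i0, j0, k1)] * (1 - wx) * (1 - wy) * wz +
            dv[cbind(i1, j0, k1)] * wx       * (1 - wy) * wz +
            dv[cbind(i0, j1, k1)] * (1 - wx) * wy       * wz +
            dv[cbind(i1, j1, k1)] * wx       * wy       * wz
        idx <- cbind(ii[g$a], jj[g$b], kk[g$c])
        out[idx] <- val
        outside[idx] <- FALSE
    }
    DoseGrid(out, spacing = ct@spacing, origin = ct@origin,
             fractions = dose@fractions, outside = outside)
}

## ---- skin cropping ---------------------------------------------------------

#' Distance to the body exterior
#'
#' Exact anisotropic Euclidean distance (mm) from each voxel centre to the
#' nearest voxel centre outside the body mask, computed with a separable
#' distance transform at native spacing.
#'
#' @param body a [StructureMask-class] of the body/skin outline.
#' @return a 3-D numeric array of distances in mm (0 outside the body).
#' @export
skinDistance <- function(body) {
    d <- .edt3d(as.logical(!body@voxels), dim(body@voxels), body@spacing)
    array(d, dim = dim(body@voxels))
}

#' Crop a breast mask away from the skin surface
#'
#' Removes breast voxels within `marginMm` of the body exterior so that
#' unreliable superficial dose (and skin itself) is excluded from
#' composition and dosimetry. A voxel is removed when its Euclidean
#' distance to the nearest exterior voxel centre is `<= marginMm`; on a
#' 1 mm grid with the default 5 mm margin this removes exactly the five
#' voxel layers nearest the surface. Cropping is monotone in the margin.
#'
#' @param breast breast [StructureMask-class].
#' @param body body [StructureMask-class] on the same grid. Breast voxels
#'   outside the body are dropped with a warning.
#' @param marginMm crop margin in mm (default 5).
#' @return the cropped [StructureMask-class].
#' @export
cropFromSkin <- function(breast, body, marginMm = 5) {
    .stopIfIncongruent(breast, body, "breast and body masks")
    bx <- breast@voxels
    stray <- bx & !body@voxels
    if (any(stray)) {
        warning(sum(stray), " breast voxels lie outside the body mask; ",
                "dropped")
        bx <- bx & body@voxels
    }
    if (marginMm > 0) {
        d <- skinDistance(body)
        bx <- bx & (d > marginMm)
    }
    if (!any(bx))
        stop("margin of ", marginMm,
             " mm removed the whole breast mask; structure unusable")
    StructureMask(breast@name, bx, spacing = breast@spacing,
                  origin = breast@origin)
}

#' Extract masked voxel values
#'
#' @param volume an [ImageVolume-class] or [DoseGrid-class].
#' @param mask a congruent, non-empty [StructureMask-class].
#' @return numeric vector of the masked voxel values.
#' @export
maskedValues <- function(volume, mask) {
    .stopIfIncongruent(volume, mask, "volume and mask")
    if (!any(mask@voxels))
        stop("mask '", mask@name, "' is empty")
    volume@voxels[mask@voxels]
}
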