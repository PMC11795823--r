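#' 2D single-channel image
#'
#' The unit every registration step operates on: an `H x W` matrix of
#' intensities in `[0, 1]` plus the physical pixel spacing in millimetres.
#'
#' @param pixels Numeric matrix of intensities.
#' @param spacing Length-2 numeric, `(row_mm, col_mm)` pixel spacing.
#'   Defaults to 0.7 mm isotropic, the in-plane resolution typical of the
#'   mid-sagittal T2 acquisitions this pipeline targets.
#' @return An object of class `image2d`.
#' @export
image2d <- function(pixels, spacing = c(0.7, 0.7)) {
    pixels <- as.matrix(pixels)
    if (nrow(pixels) < 16L || ncol(pixels) < 16L)
        stop("image2d: image must be at least 16 x 16 pixels")
    if (!all(is.finite(pixels)))
        stop("image2d: intensities must be finite")
    stopifnot(length(spacing) == 2L, all(spacing > 0))
    structure(list(pixels = pixels, spacing = as.numeric(spacing)),
              class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
    cat(sprintf("<image2d %d x %d, spacing %.3g x %.3g mm, range [%.3g, %.3g]>\n",
                nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
                min(x$pixels), max(x$pixels)))
    invisible(x)
}

#' @export
dim.image2d <- function(x) dim(x$pixels)

as_image2d <- function(x, spacing = c(0.7, 0.7)) {
    if (inherits(x, "image2d")) x else image2d(x, spacing)
}

# Min-max scale a matrix to [0, 1]; a constant image maps to all zeros.
minmax01 <- function(m) {
    rng <- range(m)
    if (rng[2] - rng[1] < .Machine$double.eps) return(m * 0)
    (m - rng[1]) / (rng[2] - rng[1])
}

#' Per-pixel dense displacement field
#'
#' Displacements live on the reference grid and follow the pull convention:
#' `warped_query(x) = query(x + d(x))`, with `d = (drow, dcol)` in pixels.
#'
#' @param drow,dcol Numeric matrices of identical dimensions holding the
#'   row- and column-displacement components in pixels.
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(drow, dcol) {
    drow <- as.matrix(drow); dcol <- as.matrix(dcol)
    if (!identical(dim(drow), dim(dcol)))
        stop("deformation_field: component dimensions differ")
    if (!all(is.finite(drow)) || !all(is.finite(dcol)))
        stop("deformation_field: displacement components must be finite")
    structure(list(drow = drow, dcol = dcol), class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
    m <- field_magnitude(x)
    cat(sprintf("<deformation_field %d x %d, mean |d| %.3g px, max |d| %.3g px>\n",
                nrow(x$drow), ncol(x$drow), mean(m), max(m)))
    invisible(x)
}

#' @export
dim.deformation_field <- function(x) dim(x$drow)

#' Per-pixel displacement magnitude
#'
#' @param field A [deformation_field()].
#' @return `H x W` matrix of Euclidean norms `sqrt(drow^2 + dcol^2)`, pixels.
#' @export
field_magnitude <- function(field) {
    stopifnot(inherits(field, "deformation_field"))
    sqrt(field$drow^2 + field$dcol^2)
}

#' Warp an image through a displacement field
#'
#' Pull warping with bilinear interpolation and edge clamping:
#' `out(x) = img(x + d(x))`.
#'
#' @param img An [image2d()] (or plain matrix).
#' @param field A [deformation_field()] on the same grid.
#' @return An [image2d()] with the same spacing.
#' @export
warp_image <- function(img, field) {
    img <- as_image2d(img)
    stopifnot(inherits(field, "deformation_field"))
    if (!identical(dim(img$pixels), dim(field$drow)))
        stop("warp_image: image and field dimensions differ")
    image2d(warp_bilinear_cpp(img$pixels, field$drow, field$dcol),
            spacing = img$spacing)
}

#' Read / write 2D NIfTI images
#'
#' Thin wrappers over RNifti keeping the `image2d` contract (2D matrix,
#' spacing in mm).
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param img An [image2d()].
#' @return `read_image2d` returns an [image2d()]; `write_image2d` returns
#'   `path` invisibly.
#' @export
read_image2d <- function(path) {
    nii <- RNifti::readNifti(path)
    px <- drop(as.array(nii))
    if (length(dim(px)) != 2L)
        stop("read_image2d: expected a single-slice 2D image: ", path)
    sp <- tryCatch(RNifti::pixdim(nii)[1:2], error = function(e) c(0.7, 0.7))
    if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(0.7, 0.7)
    image2d(px, spacing = sp)
}

#' @rdname read_image2d
#' @export
write_image2d <- function(img, path) {
    img <- as_image2d(img)
    nii <- RNifti::asNifti(img$pixels)
    RNifti::pixdim(nii) <- img$spacing
    RNifti::writeNifti(nii, path)
    invisible(path)
}

#' Read / write displacement fields as two-volume NIfTI
#'
#' Volume 0 holds the row displacement, volume 1 the column displacement,
#' both in pixels on the reference grid.
#'
#' @param field A [deformation_field()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_field` returns a [deformation_field()]; `write_field`
#'   returns `path` invisibly.
#' @export
write_field <- function(field, path) {
    stopifnot(inherits(field, "deformation_field"))
    arr <- array(0, c(dim(field$drow), 2L))
    arr[, , 1] <- field$drow
    arr[, , 2] <- field$dcol
    RNifti::writeNifti(RNifti::asNifti(arr), path)
    invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) != 3L || dim(arr)[3] != 2L)
        stop("read_field: expected a two-volume displacement NIfTI: ", path)
    deformation_field(arr[, , 1], arr[, , 2])
}
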