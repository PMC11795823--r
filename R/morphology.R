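#' Angular separation between two 2-vectors
#'
#' @param v1,v2 Nonzero numeric 2-vectors.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
angular_separation <- function(v1, v2) {
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 < 1e-12 || n2 < 1e-12)
        stop("angular_separation: vectors must be nonzero")
    acos(pmin(pmax(sum(v1 * v2) / (n1 * n2), -1), 1)) * 180 / pi
}

#' Exemplar pixel of a region
#'
#' The member pixel nearest the region's coordinate centroid; ties broken
#' by raster order.
#'
#' @param region A [dbm_region()].
#' @return Integer (row, col).
#' @export
exemplar_pixel <- function(region) {
    stopifnot(inherits(region, "dbm_region"))
    px <- region$pixels       # already raster-sorted
    ctr <- colMeans(px)
    d2 <- (px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2
    as.integer(px[which.min(d2), ])
}

#' Stack per-subject displacement vectors over region pixels
#'
#' Subject i becomes a flattened vector of length `2 * total pixels`
#' holding `(drow, dcol)` pairs in a fixed pixel ordering (region id, then
#' raster within region), so rows are comparable across subjects.
#'
#' @param regions List of [dbm_region()] objects.
#' @param fields Named list of [deformation_field()] per subject.
#' @return Matrix subjects x (2 * n_pixels) with rownames = subject ids;
#'   attribute `pixel_table` records the (region, row, col) of each pair.
#' @export
collect_roi_vectors <- function(regions, fields) {
    stopifnot(length(regions) > 0, length(fields) > 0)
    H <- dim(fields[[1]])[1]
    pixel_table <- do.call(rbind, lapply(seq_along(regions), function(i)
        cbind(region = i, regions[[i]]$pixels)))
    idx <- (pixel_table[, "col"] - 1L) * H + pixel_table[, "row"]
    vecs <- t(vapply(names(fields), function(id) {
        f <- fields[[id]]
        if (is.null(f))
            stop("collect_roi_vectors: missing field for subject ", id)
        as.numeric(rbind(f$drow[idx], f$dcol[idx]))
    }, numeric(2 * length(idx))))
    rownames(vecs) <- names(fields)
    attr(vecs, "pixel_table") <- pixel_table
    vecs
}

#' Pooled PCA of stacked ROI displacement vectors
#'
#' PCA on the mean-centered subject vectors; orthonormal components with
#' nonincreasing explained-variance ratios summing to 1 (rank-deficient
#' trailing components get ratio 0).
#'
#' @param vectors Subjects x d matrix from [collect_roi_vectors()].
#' @return List with `components` (d x k orthonormal),
#'   `explained_variance_ratio`, `scores`.
#' @export
pooled_pca <- function(vectors) {
    if (nrow(vectors) < 3L)
        stop("pooled_pca: at least 3 subjects are required")
    pc <- prcomp(vectors, center = TRUE, scale. = FALSE)
    v <- pc$sdev^2
    list(components = unname(pc$rotation),
         explained_variance_ratio = v / sum(v),
         scores = unname(pc$x))
}

#' Class-wise morphology at an exemplar pixel
#'
#' For each class: the mean `(drow, dcol)` displacement at the pixel and
#' the class's prominent displacement direction — the first singular
#' vector of the (uncentered) stack of 2D displacements there, the axis
#' most deformations point along — sign-aligned with the class mean
#' (nonnegative dot product). A single-subject class gets its mean but an
#' undefined-direction flag.
#'
#' @param fields Named list of [deformation_field()] per subject.
#' @param labels Named labels (0/1 or control/disease) covering `fields`.
#' @param pixel Integer (row, col) exemplar position.
#' @return List with per-class `mean` and `direction` (unit 2-vectors),
#'   plus `direction_defined` flags.
#' @export
class_morphology <- function(fields, labels, pixel) {
    lab <- if (is.data.frame(labels))
        stats::setNames(labels$label, labels$subject_id) else labels
    y <- as_binary_labels(lab[names(fields)])
    if (length(unique(y)) < 2L)
        stop("class_morphology: both classes must be present")
    disp <- t(vapply(fields, function(f)
        c(f$drow[pixel[1], pixel[2]], f$dcol[pixel[1], pixel[2]]),
        numeric(2)))
    per_class <- function(cl) {
        d <- disp[y == cl, , drop = FALSE]
        m <- colMeans(d)
        if (nrow(d) < 2L)
            return(list(mean = m, direction = c(NA_real_, NA_real_),
                        defined = FALSE))
        # dominant direction of the displacements themselves (uncentered
        # first singular vector): the axis most deformations point along,
        # not the axis of scatter about the class mean
        if (max(abs(d)) < 1e-12)
            return(list(mean = m, direction = c(NA_real_, NA_real_),
                        defined = FALSE))
        dir <- svd(d, nu = 0, nv = 2)$v[, 1]
        if (sum(dir * m) < 0) dir <- -dir
        list(mean = m, direction = unname(dir), defined = TRUE)
    }
    ctl <- per_class(0L); dis <- per_class(1L)
    list(control_mean = ctl$mean, disease_mean = dis$mean,
         control_direction = ctl$direction,
         disease_direction = dis$direction,
         direction_defined = c(control = ctl$defined,
                               disease = dis$defined))
}

#' Morphology summary of the winning regions
#'
#' Per region: the exemplar pixel, class mean displacement vectors, class
#' principal directions and the angular separation between them; plus the
#' pooled PCA explained-variance ratios over all region pixels jointly.
#' Displacements of all subjects (train and test) are used, since this
#' stage characterizes rather than classifies.
#'
#' @param regions List of [dbm_region()] objects.
#' @param fields Named list of [deformation_field()] per subject.
#' @param labels Labels data frame or named vector.
#' @return An object of class `morphology_summary`: `regions` (list of
#'   per-region records), `explained_variance_ratio` (pooled).
#' @export
morphology_summary <- function(regions, fields, labels) {
    vecs <- collect_roi_vectors(regions, fields)
    pca <- pooled_pca(vecs)
    recs <- lapply(seq_along(regions), function(i) {
        ex <- exemplar_pixel(regions[[i]])
        cm <- class_morphology(fields, labels, ex)
        sep <- if (all(cm$direction_defined))
            angular_separation(cm$control_direction, cm$disease_direction)
        else NA_real_
        c(list(region = i, exemplar_pixel = ex,
               angular_separation_deg = sep), cm)
    })
    structure(list(regions = recs,
                   explained_variance_ratio = pca$explained_variance_ratio),
              class = "morphology_summary")
}

#' @export
print.morphology_summary <- function(x, ...) {
    cat(sprintf("<morphology_summary: %d regions, first PC %.1f%% of variance>\n",
                length(x$regions), 100 * x$explained_variance_ratio[1]))
    for (r in x$regions)
        cat(sprintf("  region %d @ (%d, %d): separation %.1f deg\n",
                    r$region, r$exemplar_pixel[1], r$exemplar_pixel[2],
                    r$angular_separation_deg))
    invisible(x)
}

#' Write a morphology summary to JSON and a vector-overlay PNG
#'
#' Solid lines would be class means and dashed lines principal directions
#' in the figure convention; the PNG renders mean vectors as bright pixel
#' traces over the reference image, which is enough for a visual sanity
#' check without a plotting device.
#'
#' @param summary A `morphology_summary`.
#' @param path JSON output path.
#' @param reference Optional [image2d()] for the overlay PNG.
#' @param png_path Optional overlay output path.
#' @return `path`, invisibly.
#' @export
write_morphology <- function(summary, path, reference = NULL,
                             png_path = NULL) {
    jsonlite::write_json(
        list(regions = lapply(summary$regions, function(r)
            list(region = r$region, exemplar_pixel = r$exemplar_pixel,
                 control_mean = r$control_mean,
                 disease_mean = r$disease_mean,
                 control_direction = r$control_direction,
                 disease_direction = r$disease_direction,
                 angular_separation_deg = r$angular_separation_deg)),
            explained_variance_ratio = summary$explained_variance_ratio),
        path, auto_unbox = TRUE, digits = NA)
    if (!is.null(reference)) {
        png_path <- png_path %||% sub("\\.json$", "_overlay.png", path)
        bg <- minmax01(as_image2d(reference)$pixels)
        rgb <- array(rep(bg, 3), c(dim(bg), 3))
        draw_vec <- function(rgb, p0, v, ch, scale = 6) {
            if (any(!is.finite(v)) || sum(v^2) < 1e-12) return(rgb)
            v <- v / sqrt(sum(v^2))
            for (t in seq(0, scale, by = 0.25)) {
                r <- round(p0[1] + t * v[1]); c <- round(p0[2] + t * v[2])
                if (r >= 1 && r <= nrow(bg) && c >= 1 && c <= ncol(bg)) {
                    rgb[r, c, ] <- 0
                    rgb[r, c, ch] <- 1
                }
            }
            rgb
        }
        for (r in summary$regions) {
            rgb <- draw_vec(rgb, r$exemplar_pixel, r$control_mean, 3)
            rgb <- draw_vec(rgb, r$exemplar_pixel, r$disease_mean, 1)
        }
        png::writePNG(rgb, png_path)
    }
    invisible(path)
}
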