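#' Rigid landmark alignment of a query image to the reference
#'
#' The translation maps the query's point 1 onto the reference's point 1;
#' the rotation about that center is the least-squares (orthogonal
#' Procrustes, restricted to pure rotation) fit of the remaining six
#' landmark pairs. The query is resampled onto the reference grid with
#' bilinear interpolation and edge clamping. If the query landmarks are
#' degenerate (all coincident with point 1), alignment falls back to
#' translation only with a warning flag.
#'
#' @param query An [image2d()].
#' @param query_landmarks,ref_landmarks [landmark_set()] objects.
#' @return List with `image` (resampled [image2d()]) and `transform`
#'   (class `rigid_transform`: `rotation_deg`, `translation` = (drow, dcol)
#'   mapping query point 1 to reference point 1, `center` = reference point
#'   1, `degenerate`).
#' @export
rigid_align <- function(query, query_landmarks, ref_landmarks) {
    query <- as_image2d(query)
    stopifnot(inherits(query_landmarks, "landmark_set"),
              inherits(ref_landmarks, "landmark_set"))
    q1 <- query_landmarks$points[1, ]
    r1 <- ref_landmarks$points[1, ]
    qc <- sweep(query_landmarks$points[-1, , drop = FALSE], 2, q1)
    rc <- sweep(ref_landmarks$points[-1, , drop = FALSE], 2, r1)
    ss <- sum(qc^2)
    degenerate <- FALSE
    # optimal 2D rotation angle: atan2 of summed cross/dot products
    num <- sum(qc[, 1] * rc[, 2] - qc[, 2] * rc[, 1])
    den <- sum(qc[, 1] * rc[, 1] + qc[, 2] * rc[, 2])
    if (ss < 1e-9 || (abs(num) < 1e-12 && abs(den) < 1e-12)) {
        warning("rigid_align: degenerate landmarks; translation-only alignment")
        degenerate <- TRUE
        theta <- 0
    } else {
        theta <- atan2(num, den)
    }
    # resample: for each reference-grid pixel x, look up
    # query(R^{-1}(x - r1) + q1)
    H <- nrow(query$pixels); W <- ncol(query$pixels)
    r <- matrix(seq_len(H), H, W) - r1[1]
    c <- matrix(seq_len(W), H, W, byrow = TRUE) - r1[2]
    ct <- cos(-theta); st <- sin(-theta)
    src_r <- ct * r - st * c + q1[1]
    src_c <- st * r + ct * c + q1[2]
    px <- matrix(sample_bilinear_cpp(query$pixels, as.numeric(src_r) - 1,
                                     as.numeric(src_c) - 1), H, W)
    transform <- structure(list(rotation_deg = theta * 180 / pi,
                                translation = r1 - q1, center = r1,
                                degenerate = degenerate),
                           class = "rigid_transform")
    list(image = image2d(px, spacing = query$spacing), transform = transform)
}

#' @export
print.rigid_transform <- function(x, ...) {
    cat(sprintf("<rigid_transform: %.3f deg about (%.1f, %.1f), translation (%.2f, %.2f)%s>\n",
                x$rotation_deg, x$center[1], x$center[2], x$translation[1],
                x$translation[2], if (x$degenerate) ", degenerate" else ""))
    invisible(x)
}

#' Demons registration parameters
#'
#' Classic Thirion demons defaults: field-smoothing sigma 1.5 px, a
#' three-level coarse-to-fine pyramid (downsampling factors 4, 2, 1), up to
#' 100 iterations per level, stopping when the relative SSD improvement
#' over a 5-iteration window falls below 1e-4.
#'
#' @param smoothing_sigma Gaussian sigma (pixels) applied to the field
#'   after every update.
#' @param pyramid_levels Integer downsampling factors, coarse to fine; must
#'   end in 1.
#' @param max_iter Maximum iterations per pyramid level.
#' @param tol Relative SSD improvement threshold for convergence.
#' @param window Iteration window over which improvement is measured.
#' @return A list of class `demons_params`.
#' @export
demons_params <- function(smoothing_sigma = 1.5, pyramid_levels = c(4, 2, 1),
                          max_iter = 100L, tol = 1e-4, window = 5L) {
    stopifnot(smoothing_sigma > 0, max_iter >= 1, tol > 0, window >= 1,
              pyramid_levels[length(pyramid_levels)] == 1,
              all(diff(pyramid_levels) < 0))
    structure(list(smoothing_sigma = smoothing_sigma,
                   pyramid_levels = as.integer(pyramid_levels),
                   max_iter = as.integer(max_iter), tol = tol,
                   window = as.integer(window)),
              class = "demons_params")
}

#' Thirion demons non-rigid registration
#'
#' Estimates the dense displacement field mapping the (rigidly pre-aligned)
#' moving image onto the fixed image, under the pull convention
#' `warped_moving(x) = moving(x + d(x))`. Both images are min-max scaled to
#' `[0, 1]` before registration. The per-iteration force is the classic
#' normalized intensity difference times the fixed-image gradient, the
#' accumulated field is Gaussian-smoothed after every update, and a
#' coarse-to-fine pyramid with bilinear field prolongation provides capture
#' range. The best-SSD field seen at the finest level is returned.
#'
#' @param fixed,moving [image2d()] objects of identical dimensions.
#' @param params A [demons_params()] list.
#' @return A [deformation_field()] with attributes `ssd_initial`,
#'   `ssd_final` and `ssd_history` (finest level).
#' @export
demons_register <- function(fixed, moving, params = demons_params()) {
    fixed <- as_image2d(fixed); moving <- as_image2d(moving)
    if (!identical(dim(fixed$pixels), dim(moving$pixels)))
        stop("demons_register: fixed and moving images differ in shape")
    stopifnot(inherits(params, "demons_params"))
    f0 <- minmax01(fixed$pixels)
    m0 <- minmax01(moving$pixels)
    H <- nrow(f0); W <- ncol(f0)
    drow <- NULL; dcol <- NULL
    hist <- NULL
    for (fac in params$pyramid_levels) {
        h <- max(16L, as.integer(round(H / fac)))
        w <- max(16L, as.integer(round(W / fac)))
        f <- if (fac == 1) f0 else resize_bilinear_cpp(f0, h, w)
        m <- if (fac == 1) m0 else resize_bilinear_cpp(m0, h, w)
        if (is.null(drow)) {
            drow <- matrix(0, h, w); dcol <- matrix(0, h, w)
        } else {
            # prolong the coarse field: resize and rescale displacements
            sr <- h / nrow(drow); sc <- w / ncol(dcol)
            drow <- resize_bilinear_cpp(drow, h, w) * sr
            dcol <- resize_bilinear_cpp(dcol, h, w) * sc
        }
        res <- demons_level_cpp(f, m, drow, dcol, params$smoothing_sigma,
                                params$max_iter, params$tol, params$window)
        drow <- res$drow; dcol <- res$dcol
        hist <- res$ssd
    }
    field <- deformation_field(drow, dcol)
    attr(field, "ssd_initial") <- sum((m0 - f0)^2)
    warped <- warp_bilinear_cpp(m0, drow, dcol)
    attr(field, "ssd_final") <- sum((warped - f0)^2)
    attr(field, "ssd_history") <- hist
    field
}

#' Register a whole cohort to a reference subject
#'
#' Rigidly aligns every subject to the reference on landmarks, then runs
#' demons registration, returning the per-subject deformation fields on
#' the reference grid.
#'
#' @param images Named list of [image2d()] (includes the reference id).
#' @param landmarks Named list of [landmark_set()] covering all subjects.
#' @param reference_id Subject id used as the fixed image.
#' @param params [demons_params()].
#' @param verbose Print per-subject progress.
#' @return List with `fields` (named list of [deformation_field()]),
#'   `transforms` (named list of `rigid_transform`) and `reference_id`.
#' @export
register_cohort <- function(images, landmarks, reference_id,
                            params = demons_params(), verbose = FALSE) {
    if (!reference_id %in% names(images))
        stop("register_cohort: reference id not found: ", reference_id)
    fixed <- as_image2d(images[[reference_id]])
    ref_lm <- landmarks[[reference_id]]
    if (is.null(ref_lm))
        stop("register_cohort: no landmarks for reference ", reference_id)
    fields <- list(); transforms <- list()
    for (id in names(images)) {
        lm <- landmarks[[id]]
        if (is.null(lm))
            stop("register_cohort: no landmarks for subject ", id)
        al <- rigid_align(as_image2d(images[[id]]), lm, ref_lm)
        fields[[id]] <- demons_register(fixed, al$image, params)
        transforms[[id]] <- al$transform
        if (verbose)
            message(sprintf("registered %s: SSD %.4g -> %.4g", id,
                            attr(fields[[id]], "ssd_initial"),
                            attr(fields[[id]], "ssd_final")))
    }
    list(fields = fields, transforms = transforms,
         reference_id = reference_id)
}
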