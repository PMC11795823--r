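#' Phantom specification for the synthetic reference anatomy
#'
#' The reference "anatomy" is a sum of Gaussian intensity blobs, giving the
#' smooth, gradient-rich structures that intensity-driven registration
#' needs, plus seven ordered landmark positions mimicking the anatomical
#' annotation convention (point 1 plays the role of the image center used
#' by the rigid alignment).
#'
#' @param image_height,image_width Image dimensions in pixels (>= 64).
#' @param blob_centers n x 2 matrix of (row, col) blob centers.
#' @param blob_amplitudes Length-n intensity amplitudes.
#' @param blob_sigmas Length-n Gaussian widths in pixels (> 0).
#' @param landmark_positions 7 x 2 matrix of (row, col) landmark positions,
#'   all strictly inside the image.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_height, image_width, blob_centers,
                         blob_amplitudes, blob_sigmas, landmark_positions) {
    if (image_height < 64L || image_width < 64L)
        stop("phantom_spec: image dimensions must be at least 64")
    blob_centers <- matrix(as.numeric(blob_centers), ncol = 2L)
    n <- nrow(blob_centers)
    if (length(blob_amplitudes) != n || length(blob_sigmas) != n)
        stop("phantom_spec: blob parameter lengths differ")
    if (n > 0L && any(blob_sigmas <= 0))
        stop("phantom_spec: blob sigmas must be positive")
    lm <- matrix(as.numeric(landmark_positions), ncol = 2L)
    if (nrow(lm) != 7L)
        stop("phantom_spec: exactly 7 landmarks are required")
    if (any(lm[, 1] <= 1 | lm[, 1] >= image_height |
            lm[, 2] <= 1 | lm[, 2] >= image_width))
        stop("phantom_spec: landmarks must lie strictly inside the image")
    structure(list(image_height = as.integer(image_height),
                   image_width = as.integer(image_width),
                   blob_centers = blob_centers,
                   blob_amplitudes = as.numeric(blob_amplitudes),
                   blob_sigmas = as.numeric(blob_sigmas),
                   landmark_positions = lm),
              class = "phantom_spec")
}

#' Localized class-specific displacement effect
#'
#' One ground-truth "morphology": a Gaussian displacement envelope at a
#' known locus whose direction and amplitude differ between classes. The
#' control/disease directions stand in for the class-specific deformation
#' behaviors the morphology stage is meant to recover.
#'
#' @param locus_center (row, col) center of the effect envelope.
#' @param locus_sigma Envelope width in pixels (> 0).
#' @param control_direction,disease_direction Unit 2-vectors (drow, dcol).
#' @param control_amplitude,disease_amplitude Peak displacement in pixels
#'   (>= 0).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(locus_center, locus_sigma, control_direction,
                        disease_direction, control_amplitude,
                        disease_amplitude) {
    norm2 <- function(v) sqrt(sum(v^2))
    if (abs(norm2(control_direction) - 1) > 1e-8 ||
        abs(norm2(disease_direction) - 1) > 1e-8)
        stop("effect_spec: direction vectors must have unit norm")
    if (control_amplitude < 0 || disease_amplitude < 0)
        stop("effect_spec: amplitudes must be nonnegative")
    if (locus_sigma <= 0)
        stop("effect_spec: locus_sigma must be positive")
    structure(list(locus_center = as.numeric(locus_center),
                   locus_sigma = as.numeric(locus_sigma),
                   control_direction = as.numeric(control_direction),
                   disease_direction = as.numeric(disease_direction),
                   control_amplitude = as.numeric(control_amplitude),
                   disease_amplitude = as.numeric(disease_amplitude)),
              class = "effect_spec")
}

#' Cohort specification for the synthetic study
#'
#' Each subject receives a smooth random "nuisance" deformation (smoothed
#' white noise rescaled to a target RMS magnitude) plus every effect's
#' class-dependent displacement, and the reference is warped through the
#' resulting field with additive Gaussian intensity noise.
#'
#' @param n_control,n_disease Subject counts (>= 2 each).
#' @param effects List of [effect_spec()] objects (possibly empty).
#' @param background_field_sigma Smoothness of the nuisance deformation in
#'   pixels.
#' @param background_field_amplitude Target RMS magnitude of the nuisance
#'   deformation in pixels (>= 0).
#' @param intensity_noise_sd SD of additive intensity noise (image is
#'   clipped back to `[0, 1]`).
#' @param seed Integer seed; a fixed seed makes the rendered cohort
#'   bit-reproducible.
#' @param include_template Add one extra control subject (`C000`) with
#'   zero deformation — the idealized average anatomy. Because implanted
#'   effects are displacements relative to the template, measuring class
#'   morphology requires the registration reference to *be* the template;
#'   the landmark-PCA medoid rule identifies `C000` on its own (its
#'   landmark configuration is the population mean), so direction-recovery
#'   experiments stay honest end to end.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control, n_disease, effects = list(),
                        background_field_sigma = 8,
                        background_field_amplitude = 1,
                        intensity_noise_sd = 0.02, seed = 1L,
                        include_template = FALSE) {
    if (n_control < 2L || n_disease < 2L)
        stop("cohort_spec: at least 2 subjects per class are required")
    if (background_field_amplitude < 0)
        stop("cohort_spec: background amplitude must be nonnegative")
    if (background_field_sigma <= 0)
        stop("cohort_spec: background sigma must be positive")
    if (intensity_noise_sd < 0)
        stop("cohort_spec: intensity noise SD must be nonnegative")
    stopifnot(all(vapply(effects, inherits, TRUE, "effect_spec")))
    structure(list(n_control = as.integer(n_control),
                   n_disease = as.integer(n_disease),
                   effects = effects,
                   background_field_sigma = as.numeric(background_field_sigma),
                   background_field_amplitude = as.numeric(background_field_amplitude),
                   intensity_noise_sd = as.numeric(intensity_noise_sd),
                   seed = as.integer(seed),
                   include_template = isTRUE(include_template)),
              class = "cohort_spec")
}

#' Render the reference anatomy image
#'
#' Deterministically evaluates the sum of Gaussian blobs on the pixel grid
#' and min-max scales it to `[0, 1]` (a zero-blob spec yields a uniform
#' zero image).
#'
#' @param spec A [phantom_spec()].
#' @return An [image2d()].
#' @export
make_reference <- function(spec) {
    stopifnot(inherits(spec, "phantom_spec"))
    H <- spec$image_height; W <- spec$image_width
    img <- matrix(0, H, W)
    if (nrow(spec$blob_centers) > 0L) {
        r <- matrix(seq_len(H), H, W)
        c <- matrix(seq_len(W), H, W, byrow = TRUE)
        for (i in seq_len(nrow(spec$blob_centers))) {
            d2 <- (r - spec$blob_centers[i, 1])^2 + (c - spec$blob_centers[i, 2])^2
            img <- img + spec$blob_amplitudes[i] *
                exp(-d2 / (2 * spec$blob_sigmas[i]^2))
        }
        img <- minmax01(img)
    }
    image2d(img)
}

# Deterministic Gaussian envelope of one effect on the (H, W) grid.
effect_envelope <- function(effect, H, W) {
    r <- matrix(seq_len(H), H, W)
    c <- matrix(seq_len(W), H, W, byrow = TRUE)
    d2 <- (r - effect$locus_center[1])^2 + (c - effect$locus_center[2])^2
    exp(-d2 / (2 * effect$locus_sigma^2))
}

#' Sample one subject's ground-truth displacement field
#'
#' The field is the sum of a smoothed-white-noise background (rescaled so
#' its RMS magnitude equals `background_field_amplitude` exactly) and, for
#' each effect, `amplitude(label) * direction(label) * envelope`. Random
#' draws come from the session RNG, so wrap calls in a seeded context for
#' reproducibility (as [render_cohort()] does).
#'
#' @param spec A [phantom_spec()] (defines the grid).
#' @param cohort A [cohort_spec()].
#' @param label `"control"` or `"disease"`.
#' @return A [deformation_field()].
#' @export
sample_subject_field <- function(spec, cohort, label) {
    stopifnot(inherits(spec, "phantom_spec"), inherits(cohort, "cohort_spec"))
    label <- match.arg(label, c("control", "disease"))
    H <- spec$image_height; W <- spec$image_width
    drow <- matrix(0, H, W); dcol <- matrix(0, H, W)
    if (cohort$background_field_amplitude > 0) {
        br <- gaussian_blur_cpp(matrix(rnorm(H * W), H, W),
                                cohort$background_field_sigma)
        bc <- gaussian_blur_cpp(matrix(rnorm(H * W), H, W),
                                cohort$background_field_sigma)
        rms <- sqrt(mean(br^2 + bc^2))
        if (rms > 0) {
            s <- cohort$background_field_amplitude / rms
            drow <- br * s; dcol <- bc * s
        }
    }
    for (ef in cohort$effects) {
        amp <- if (label == "control") ef$control_amplitude else ef$disease_amplitude
        dir <- if (label == "control") ef$control_direction else ef$disease_direction
        if (amp > 0) {
            env <- effect_envelope(ef, H, W)
            drow <- drow + amp * dir[1] * env
            dcol <- dcol + amp * dir[2] * env
        }
    }
    deformation_field(drow, dcol)
}

# Transport a reference-grid point p through the rendering warp
# subject(x) = reference(x - d(x)): solve x - d(x) = p by fixed-point
# iteration (d is smooth, so a handful of iterations suffices).
transport_point <- function(field, p, iters = 8L) {
    x <- p
    for (i in seq_len(iters)) {
        dr <- sample_bilinear_cpp(field$drow, x[1] - 1, x[2] - 1)
        dc <- sample_bilinear_cpp(field$dcol, x[1] - 1, x[2] - 1)
        x <- c(p[1] + dr, p[2] + dc)
    }
    x
}

#' Render a labeled synthetic cohort
#'
#' Each subject image is the reference warped through that subject's
#' sampled ground-truth field, `subject(x) = reference(x - d(x))` with
#' bilinear interpolation (so registering a subject back to the reference
#' recovers approximately `+d`), plus i.i.d. Gaussian intensity noise,
#' clipped to `[0, 1]`. Landmarks are transported through the exact field;
#' `landmark_jitter_sd` optionally adds annotation noise.
#'
#' @param spec A [phantom_spec()].
#' @param cohort A [cohort_spec()].
#' @param out_dir Optional directory; when given, the bundle is written as
#'   `images/<id>.nii.gz`, `labels.csv`, `landmarks.csv`,
#'   `truth/fields/<id>.nii.gz` and `truth/effects.json`.
#' @param landmark_jitter_sd SD in pixels of optional landmark annotation
#'   jitter (default 0: exact transport).
#' @return A list with `reference` ([image2d()]), `images` (named list of
#'   [image2d()]), `labels` (data.frame `subject_id,label`), `landmarks`
#'   (data.frame `subject_id,landmark_index,row,col`), `fields` (named list
#'   of ground-truth [deformation_field()]s) and the two specs.
#' @export
render_cohort <- function(spec, cohort, out_dir = NULL,
                          landmark_jitter_sd = 0) {
    stopifnot(inherits(spec, "phantom_spec"), inherits(cohort, "cohort_spec"))
    ref <- make_reference(spec)
    ids <- c(if (cohort$include_template) "C000",
             sprintf("C%03d", seq_len(cohort$n_control)),
             sprintf("D%03d", seq_len(cohort$n_disease)))
    labels <- c(rep("control", cohort$n_control + cohort$include_template),
                rep("disease", cohort$n_disease))
    images <- vector("list", length(ids)); names(images) <- ids
    fields <- vector("list", length(ids)); names(fields) <- ids
    lm_rows <- vector("list", length(ids))
    H <- spec$image_height; W <- spec$image_width
    with_seed(cohort$seed, {
        for (i in seq_along(ids)) {
            fld <- if (cohort$include_template && ids[i] == "C000")
                deformation_field(matrix(0, H, W), matrix(0, H, W))
            else sample_subject_field(spec, cohort, labels[i])
            # subject(x) = reference(x - d(x))
            px <- warp_bilinear_cpp(ref$pixels, -fld$drow, -fld$dcol)
            if (cohort$intensity_noise_sd > 0)
                px <- px + matrix(rnorm(length(px), sd = cohort$intensity_noise_sd),
                                  nrow(px), ncol(px))
            px <- pmin(pmax(px, 0), 1)
            images[[i]] <- image2d(px, spacing = ref$spacing)
            fields[[i]] <- fld
            lm <- t(apply(spec$landmark_positions, 1,
                          function(p) transport_point(fld, p)))
            if (landmark_jitter_sd > 0)
                lm <- lm + matrix(rnorm(length(lm), sd = landmark_jitter_sd),
                                  nrow(lm), ncol(lm))
            lm_rows[[i]] <- data.frame(subject_id = ids[i],
                                       landmark_index = 1:7,
                                       row = lm[, 1], col = lm[, 2])
        }
    })
    bundle <- list(reference = ref, images = images,
                   labels = data.frame(subject_id = ids, label = labels),
                   landmarks = do.call(rbind, lm_rows),
                   fields = fields, phantom = spec, cohort = cohort)
    if (!is.null(out_dir)) write_cohort_bundle(bundle, out_dir)
    bundle
}

# Serialize a rendered bundle in the on-disk cohort layout.
write_cohort_bundle <- function(bundle, out_dir) {
    img_dir <- file.path(out_dir, "images")
    fld_dir <- file.path(out_dir, "truth", "fields")
    for (d in c(img_dir, fld_dir))
        if (!dir.create(d, recursive = TRUE, showWarnings = FALSE) &&
            !dir.exists(d))
            stop("render_cohort: cannot create output directory: ", d)
    ok <- function(path, expr) {
        tryCatch(expr, error = function(e)
            stop("render_cohort: failed writing ", path, ": ",
                 conditionMessage(e)))
    }
    for (id in names(bundle$images)) {
        p <- file.path(img_dir, paste0(id, ".nii.gz"))
        ok(p, write_image2d(bundle$images[[id]], p))
        p <- file.path(fld_dir, paste0(id, ".nii.gz"))
        ok(p, write_field(bundle$fields[[id]], p))
    }
    write.csv(bundle$labels, file.path(out_dir, "labels.csv"),
              row.names = FALSE)
    write.csv(bundle$landmarks, file.path(out_dir, "landmarks.csv"),
              row.names = FALSE)
    ref_path <- file.path(out_dir, "reference_phantom.nii.gz")
    ok(ref_path, write_image2d(bundle$reference, ref_path))
    co <- bundle$cohort
    effects <- lapply(co$effects, function(ef) ef[])
    jsonlite::write_json(
        list(n_control = co$n_control, n_disease = co$n_disease,
             effects = effects,
             background_field_sigma = co$background_field_sigma,
             background_field_amplitude = co$background_field_amplitude,
             intensity_noise_sd = co$intensity_noise_sd, seed = co$seed),
        file.path(out_dir, "truth", "effects.json"),
        auto_unbox = TRUE, digits = NA)
    invisible(out_dir)
}

#' Default synthetic study conditions
#'
#' `default_phantom()` is a 128 x 128 anatomy of 12 Gaussian blobs with the
#' seven landmarks placed on distinctive structures (landmark 1 central).
#' `default_cohort()` is the single-locus study: 30 controls + 30 diseased,
#' one effect at a blob boundary with disease amplitude 3 px versus control
#' 0 px, background nuisance deformation of 1 px RMS and intensity noise SD
#' 0.02. `two_locus_cohort()` adds a second well-separated locus and gives
#' controls their own 1.5 px directions so that class-specific morphology
#' directions exist for both classes (implanted separations 90 and 135
#' degrees). `null_cohort()` makes the two classes statistically identical
#' (equal effect parameters) for calibration checks.
#'
#' @param seed Integer cohort seed.
#' @param n_control,n_disease Subject counts.
#' @return A [phantom_spec()] or [cohort_spec()].
#' @export
default_phantom <- function() {
    centers <- rbind(
        c(64, 64), c(40, 40), c(36, 86), c(88, 40), c(92, 88),
        c(64, 24), c(24, 64), c(64, 104), c(104, 64), c(44, 64),
        c(84, 64), c(64, 44))
    amps <- c(1.0, 0.8, 0.9, 0.7, 0.85, 0.6, 0.65, 0.7, 0.6, 0.5, 0.55, 0.45)
    sigmas <- c(14, 8, 9, 8, 9, 6, 6, 7, 7, 5, 5, 4)
    landmarks <- rbind(
        c(64, 64),   # 1: central structure, rigid-alignment center
        c(40, 40), c(36, 86), c(88, 40), c(92, 88), c(64, 24), c(24, 64))
    phantom_spec(128, 128, centers, amps, sigmas, landmarks)
}

#' @rdname default_phantom
#' @export
default_cohort <- function(seed = 1234L, n_control = 30L, n_disease = 30L) {
    eff <- effect_spec(locus_center = c(36, 76), locus_sigma = 6,
                       control_direction = c(0, 1),
                       disease_direction = c(0, 1),
                       control_amplitude = 0, disease_amplitude = 3)
    cohort_spec(n_control, n_disease, effects = list(eff),
                background_field_sigma = 8, background_field_amplitude = 1,
                intensity_noise_sd = 0.02, seed = seed)
}

#' @rdname default_phantom
#' @export
two_locus_cohort <- function(seed = 1234L, n_control = 30L, n_disease = 30L) {
    s2 <- sqrt(2) / 2
    eff1 <- effect_spec(locus_center = c(36, 76), locus_sigma = 6,
                        control_direction = c(0, 1),
                        disease_direction = c(1, 0),
                        control_amplitude = 1.5, disease_amplitude = 3)
    eff2 <- effect_spec(locus_center = c(92, 50), locus_sigma = 6,
                        control_direction = c(-1, 0),
                        disease_direction = c(s2, s2),
                        control_amplitude = 1.5, disease_amplitude = 3)
    cohort_spec(n_control, n_disease, effects = list(eff1, eff2),
                background_field_sigma = 8, background_field_amplitude = 1,
                intensity_noise_sd = 0.02, seed = seed,
                include_template = TRUE)
}

#' @rdname default_phantom
#' @export
null_cohort <- function(seed = 1234L, n_control = 30L, n_disease = 30L) {
    eff <- effect_spec(locus_center = c(36, 76), locus_sigma = 6,
                       control_direction = c(0, 1),
                       disease_direction = c(0, 1),
                       control_amplitude = 1.5, disease_amplitude = 1.5)
    cohort_spec(n_control, n_disease, effects = list(eff),
                background_field_sigma = 8, background_field_amplitude = 1,
                intensity_noise_sd = 0.02, seed = seed)
}
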