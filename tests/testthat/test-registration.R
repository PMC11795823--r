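# Rigid landmark alignment, demons registration and field operations.

# resample ref so its content is rotated by `deg` about `center`
rotate_image <- function(img, deg, center) {
    th <- deg * pi / 180
    H <- nrow(img$pixels); W <- ncol(img$pixels)
    r <- matrix(seq_len(H), H, W) - center[1]
    c <- matrix(seq_len(W), H, W, byrow = TRUE) - center[2]
    src_r <- cos(th) * r + sin(th) * c + center[1]
    src_c <- -sin(th) * r + cos(th) * c + center[2]
    image2d(matrix(deformark:::sample_bilinear_cpp(
        img$pixels, as.numeric(src_r) - 1, as.numeric(src_c) - 1), H, W))
}

rotate_points <- function(pts, deg, center) {
    th <- deg * pi / 180
    d <- sweep(pts, 2, center)
    sweep(cbind(cos(th) * d[, 1] - sin(th) * d[, 2],
                sin(th) * d[, 1] + cos(th) * d[, 2]), 2, center, `+`)
}

test_that("rigid_align recovers identity, rotation and translation", {
    ref <- make_reference(small_phantom())
    lm <- landmark_set("ref", small_phantom()$landmark_positions)

    al <- rigid_align(ref, lm, lm)
    expect_equal(al$transform$rotation_deg, 0)
    expect_equal(unname(al$transform$translation), c(0, 0))
    expect_lt(max(abs(al$image$pixels - ref$pixels)), 1e-12)

    # query content rotated +10 deg about point 1: recovered rotation -10
    qlm <- landmark_set("q", rotate_points(lm$points, 10, lm$points[1, ]))
    qimg <- rotate_image(ref, 10, lm$points[1, ])
    al2 <- rigid_align(qimg, qlm, lm)
    expect_equal(al2$transform$rotation_deg, -10, tolerance = 0.1)
    # the resampled image matches the reference away from edges
    inner <- 10:54
    expect_lt(mean(abs(al2$image$pixels[inner, inner] -
                           ref$pixels[inner, inner])), 0.01)

    # query translated by (5, -3): translation (-5, 3), rotation 0
    qlm3 <- landmark_set("q", lm$points + matrix(rep(c(5, -3), each = 7),
                                                 7, 2))
    al3 <- rigid_align(ref, qlm3, lm)
    expect_equal(unname(al3$transform$translation), c(-5, 3),
                 tolerance = 1e-6)
    expect_equal(al3$transform$rotation_deg, 0, tolerance = 1e-6)
})

test_that("degenerate landmarks fall back to translation with a warning", {
    ref <- make_reference(small_phantom())
    pts <- matrix(rep(c(32, 32), each = 7), 7, 2)
    lm_deg <- landmark_set("d", pts)
    expect_warning(al <- rigid_align(ref, lm_deg, lm_deg), "degenerate")
    expect_true(al$transform$degenerate)
    expect_equal(al$transform$rotation_deg, 0)
})

test_that("warp_image obeys closed forms and the convex-range property", {
    H <- 32L; W <- 40L
    ramp <- image2d(matrix(rep(seq_len(W) / W, each = H), H, W))
    zero <- deformation_field(matrix(0, H, W), matrix(0, H, W))
    expect_identical(warp_image(ramp, zero)$pixels, ramp$pixels)
    # constant shift (0, 1) on a horizontal ramp: out(r, c) = (c + 1) / W
    one <- deformation_field(matrix(0, H, W), matrix(1, H, W))
    out <- warp_image(ramp, one)$pixels
    expect_equal(out[, 1:(W - 1)],
                 matrix(rep((2:W) / W, each = H), H, W - 1),
                 tolerance = 1e-12)
    # random smooth field: bilinear outputs stay within the input range
    with_seed_local(4, {
        f <- deformation_field(
            deformark:::gaussian_blur_cpp(matrix(rnorm(H * W, sd = 4), H, W), 3),
            deformark:::gaussian_blur_cpp(matrix(rnorm(H * W, sd = 4), H, W), 3))
        img <- image2d(matrix(runif(H * W), H, W))
        w <- warp_image(img, f)$pixels
        expect_gte(min(w), min(img$pixels))
        expect_lte(max(w), max(img$pixels))
    })
})

test_that("field_magnitude is the Euclidean norm, rotation-invariant", {
    H <- 20L; W <- 20L
    expect_true(all(field_magnitude(
        deformation_field(matrix(0, H, W), matrix(0, H, W))) == 0))
    expect_true(all(field_magnitude(
        deformation_field(matrix(3, H, W), matrix(4, H, W))) == 5))
    with_seed_local(5, {
        dr <- matrix(rnorm(H * W), H, W); dc <- matrix(rnorm(H * W), H, W)
        th <- matrix(runif(H * W, 0, 2 * pi), H, W)
        m1 <- field_magnitude(deformation_field(dr, dc))
        m2 <- field_magnitude(deformation_field(cos(th) * dr - sin(th) * dc,
                                                sin(th) * dr + cos(th) * dc))
        expect_equal(m1, m2, tolerance = 1e-12)
    })
})

test_that("demons self-registration is near-zero and SSD always improves", {
    ref <- make_reference(small_phantom())
    self <- demons_register(ref, ref)
    expect_lt(mean(field_magnitude(self)), 0.05)

    # translated-by-2px phantom: recovered mean dcol inside high-gradient
    # support within [1.5, 2.5]; moving(x) = fixed(x - (0, 2)) so the pull
    # field mapping moving onto fixed has dcol = +2 (spec'd recovery window)
    shift <- deformation_field(matrix(0, 64, 64), matrix(-2, 64, 64))
    mov <- warp_image(ref, shift)
    fld <- demons_register(ref, mov)
    expect_lt(attr(fld, "ssd_final"), attr(fld, "ssd_initial"))
    grad <- abs(ref$pixels - cbind(ref$pixels[, -1], ref$pixels[, 64]))
    mask <- grad > stats::quantile(grad, 0.8)
    expect_gt(mean(fld$dcol[mask]), 1.5)
    expect_lt(mean(fld$dcol[mask]), 2.5)
})

test_that("demons reduces SSD on every noisy synthetic pair", {
    ph <- small_phantom()
    b <- render_cohort(ph, small_cohort(seed = 55L, n = 3L))
    ref <- b$reference
    for (id in names(b$images)) {
        fld <- demons_register(ref, b$images[[id]])
        expect_gt(attr(fld, "ssd_initial"), 0)
        expect_lt(attr(fld, "ssd_final"), attr(fld, "ssd_initial"))
    }
})

test_that("demons recovers background deformations direction and size", {
    ph <- small_phantom()
    co <- cohort_spec(2, 2, list(), background_field_amplitude = 2,
                      background_field_sigma = 8, intensity_noise_sd = 0,
                      seed = 66L)
    b <- render_cohort(ph, co)
    ref <- b$reference
    ang_err <- c(); cors <- c()
    for (id in names(b$images)) {
        rec <- demons_register(ref, b$images[[id]])
        tru <- b$fields[[id]]
        gmag <- field_magnitude(tru)
        grad <- sqrt((ref$pixels - rbind(ref$pixels[-1, ], ref$pixels[64, ]))^2 +
                     (ref$pixels - cbind(ref$pixels[, -1], ref$pixels[, 64]))^2)
        m <- gmag > 1 & grad > stats::median(grad)
        dot <- rec$drow[m] * tru$drow[m] + rec$dcol[m] * tru$dcol[m]
        cosang <- dot / (field_magnitude(rec)[m] * gmag[m] + 1e-12)
        ang_err <- c(ang_err, mean(acos(pmin(pmax(cosang, -1), 1))) * 180 / pi)
        cors <- c(cors, stats::cor(as.numeric(field_magnitude(rec)[m]),
                                   as.numeric(gmag[m])))
    }
    expect_lt(mean(ang_err), 45)
    expect_gt(mean(cors), 0.5)
})

test_that("field NIfTI round-trip preserves components", {
    with_seed_local(6, {
        f <- deformation_field(matrix(rnorm(400), 20, 20),
                               matrix(rnorm(400), 20, 20))
        p <- withr::local_tempfile(fileext = ".nii.gz")
        write_field(f, p)
        g <- read_field(p)
        expect_equal(f$drow, g$drow, tolerance = 1e-6)
        expect_equal(f$dcol, g$dcol, tolerance = 1e-6)
    })
})
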