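# Synthetic cohort generator: reference rendering, ground-truth fields,
# cohort rendering and its reproducibility contract.

test_that("make_reference renders symmetric, bounded, deterministic images", {
    lm <- rbind(c(64, 64), c(40, 40), c(36, 86), c(88, 40), c(92, 88),
                c(64, 24), c(24, 64))
    # single centered blob: maximum at the center pixel
    sp1 <- phantom_spec(128, 128, rbind(c(64, 64)), 1, 8, lm)
    img1 <- make_reference(sp1)
    expect_equal(as.integer(which(img1$pixels == max(img1$pixels),
                                  arr.ind = TRUE)[1, ]), c(64L, 64L))
    # zero blobs: uniform zero image
    sp0 <- phantom_spec(128, 128, matrix(numeric(0), 0, 2), numeric(0),
                        numeric(0), lm)
    expect_true(all(make_reference(sp0)$pixels == 0))
    # two blobs mirrored about the vertical midline: image equals its own
    # left-right mirror (compare against explicitly mirrored evaluation)
    sp2 <- phantom_spec(128, 128, rbind(c(50, 30), c(50, 99)), c(1, 1),
                        c(7, 7), lm)
    img2 <- make_reference(sp2)$pixels
    expect_lt(max(abs(img2 - img2[, ncol(img2):1])), 1e-12)
    expect_true(all(img2 >= 0 & img2 <= 1))
    expect_identical(img2, make_reference(sp2)$pixels)
})

test_that("spec constructors validate their invariants", {
    lm7 <- cbind(rep(30, 7), 10 * (1:7))
    expect_error(phantom_spec(32, 128, rbind(c(10, 10)), 1, 5, lm7),
                 "at least 64")
    expect_error(phantom_spec(128, 128, rbind(c(10, 10)), 1, 5, lm7[1:6, ]),
                 "exactly 7")
    expect_error(phantom_spec(128, 128, rbind(c(10, 10)), 1, -2, lm7),
                 "sigmas")
    expect_error(effect_spec(c(10, 10), 4, c(1, 1), c(0, 1), 1, 1),
                 "unit norm")
    expect_error(effect_spec(c(10, 10), 4, c(0, 1), c(0, 1), -1, 1),
                 "amplitudes")
    expect_error(cohort_spec(1, 5), "at least 2")
})

test_that("sample_subject_field honors its additive contract", {
    ph <- small_phantom()
    eff <- effect_spec(c(20, 42), 4, c(0, 1), c(0, 1), 0, 3)
    co <- cohort_spec(4, 4, list(eff), background_field_amplitude = 0,
                      intensity_noise_sd = 0)
    fld <- sample_subject_field(ph, co, "disease")
    # envelope peak equals 1 at its center: displacement is exactly (0, 3)
    expect_equal(fld$drow[20, 42], 0)
    expect_equal(fld$dcol[20, 42], 3)
    # controls have amplitude 0: zero field
    fld0 <- sample_subject_field(ph, co, "control")
    expect_true(all(fld0$drow == 0) && all(fld0$dcol == 0))
    # background rescaling contract: RMS magnitude matches the requested
    # amplitude (Monte-Carlo over repeated draws)
    co2 <- cohort_spec(4, 4, list(), background_field_amplitude = 2,
                       background_field_sigma = 6)
    rms <- with_seed_local(5, replicate(50, {
        f <- sample_subject_field(ph, co2, "control")
        sqrt(mean(f$drow^2 + f$dcol^2))
    }))
    expect_true(all(abs(rms - 2) < 0.1))
})

test_that("ground-truth field equals background plus effect terms", {
    ph <- small_phantom()
    eff1 <- effect_spec(c(20, 42), 4, c(0, 1), c(1, 0), 1, 2)
    eff2 <- effect_spec(c(45, 20), 5, c(-1, 0), c(0, -1), 0.5, 1.5)
    co_full <- cohort_spec(4, 4, list(eff1, eff2),
                           background_field_amplitude = 0)
    co_e1 <- cohort_spec(4, 4, list(eff1), background_field_amplitude = 0)
    co_e2 <- cohort_spec(4, 4, list(eff2), background_field_amplitude = 0)
    for (lab in c("control", "disease")) {
        full <- sample_subject_field(ph, co_full, lab)
        p1 <- sample_subject_field(ph, co_e1, lab)
        p2 <- sample_subject_field(ph, co_e2, lab)
        expect_lt(max(abs(full$drow - p1$drow - p2$drow)), 1e-10)
        expect_lt(max(abs(full$dcol - p1$dcol - p2$dcol)), 1e-10)
    }
})

test_that("identical class effects make locus magnitudes label-independent", {
    ph <- small_phantom()
    eff <- effect_spec(c(20, 42), 4, c(0, 1), c(0, 1), 1.5, 1.5)
    co <- cohort_spec(4, 4, list(eff), background_field_amplitude = 1,
                      background_field_sigma = 6)
    mags <- with_seed_local(31, {
        sapply(rep(c("control", "disease"), each = 250), function(lab) {
            f <- sample_subject_field(ph, co, lab)
            sqrt(f$drow[20, 42]^2 + f$dcol[20, 42]^2)
        })
    })
    ks <- stats::ks.test(mags[1:250], mags[251:500])
    expect_gt(ks$p.value, 0.01)
})

test_that("render_cohort bookkeeping, identity limit and reproducibility", {
    ph <- small_phantom()
    # zero noise, zero fields: every subject equals the reference
    co0 <- cohort_spec(3, 4, list(), background_field_amplitude = 0,
                       intensity_noise_sd = 0, seed = 7L)
    b0 <- render_cohort(ph, co0)
    expect_equal(nrow(b0$labels), 7L)
    expect_equal(sum(b0$labels$label == "control"), 3L)
    expect_equal(sum(b0$labels$label == "disease"), 4L)
    for (img in b0$images)
        expect_lt(max(abs(img$pixels - b0$reference$pixels)), 1e-12)
    # undeformed landmarks transport to themselves
    lm <- b0$landmarks[b0$landmarks$subject_id == "C001", ]
    expect_equal(cbind(lm$row, lm$col), unname(ph$landmark_positions))

    # fixed seed: byte-identical files on disk
    co <- small_cohort(seed = 123L, n = 3L)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    render_cohort(ph, co, out_dir = d1)
    render_cohort(ph, co, out_dir = d2)
    f1 <- list.files(d1, recursive = TRUE)
    expect_true(length(f1) > 8)
    expect_identical(f1, list.files(d2, recursive = TRUE))
    sums1 <- unname(tools::md5sum(file.path(d1, f1)))
    sums2 <- unname(tools::md5sum(file.path(d2, f1)))
    expect_identical(sums1, sums2)
})
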