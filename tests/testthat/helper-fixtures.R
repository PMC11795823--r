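# Shared fixtures, all generated in code. Heavy end-to-end runs used by the
# acceptance tests are memoized here so several test blocks can interrogate
# one run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
    if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
    .fixture_cache[[key]]
}

# small 64x64 phantom for fast unit and determinism tests
small_phantom <- function() {
    phantom_spec(64, 64,
                 blob_centers = rbind(c(32, 32), c(18, 20), c(20, 46),
                                      c(46, 18), c(46, 46), c(32, 12)),
                 blob_amplitudes = c(1, 0.7, 0.8, 0.6, 0.75, 0.5),
                 blob_sigmas = c(8, 5, 5, 4, 5, 3),
                 landmark_positions = rbind(c(32, 32), c(18, 20), c(20, 46),
                                            c(46, 18), c(46, 46), c(32, 12),
                                            c(12, 32)))
}

small_cohort <- function(seed = 99L, n = 8L, disease_amp = 2.5,
                         control_amp = 0) {
    eff <- effect_spec(locus_center = c(20, 42), locus_sigma = 4,
                       control_direction = c(0, 1),
                       disease_direction = c(0, 1),
                       control_amplitude = control_amp,
                       disease_amplitude = disease_amp)
    cohort_spec(n, n, effects = list(eff), background_field_sigma = 6,
                background_field_amplitude = 0.75,
                intensity_noise_sd = 0.02, seed = seed)
}

# hand-built cohort_features with a known informative pixel block:
# disease subjects get elevated magnitudes inside `block`, plus noise.
toy_cohort_features <- function(n_per_class = 12L, H = 24L, W = 24L,
                                block_rows = 10:12, block_cols = 10:12,
                                effect = 3, seed = 42L) {
    ids <- c(sprintf("C%02d", seq_len(n_per_class)),
             sprintf("D%02d", seq_len(n_per_class)))
    labels <- data.frame(subject_id = ids,
                         label = rep(c("control", "disease"),
                                     each = n_per_class))
    fields <- withr_seed_fields(ids, labels$label, H, W, block_rows,
                                block_cols, effect, seed)
    cohort_features(fields, labels, split_ratio = 0.8, n_folds = 4L,
                    split_seed = 1L, fold_seed = 2L)
}

withr_seed_fields <- function(ids, labels, H, W, block_rows, block_cols,
                              effect, seed) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    fields <- lapply(seq_along(ids), function(i) {
        m <- matrix(abs(rnorm(H * W, sd = 0.5)), H, W)
        if (labels[i] == "disease")
            m[block_rows, block_cols] <- m[block_rows, block_cols] + effect
        deformation_field(m, matrix(0, H, W))
    })
    names(fields) <- ids
    fields
}

# landmark sets of a rendered bundle, as register_cohort wants them
bundle_landmarks <- function(bundle) read_landmarks(bundle$landmarks)

# run code under a fixed seed, restoring the caller's RNG state
with_seed_local <- function(seed, code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    force(code)
}

# brute-force pairwise AUC oracle (ties count one half)
auc_bruteforce <- function(scores, labels) {
    sd_ <- scores[labels == 1]
    sc <- scores[labels == 0]
    tot <- 0
    for (a in sd_) for (b in sc)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(sd_) * length(sc))
}
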