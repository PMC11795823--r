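# Locale extraction, splits, AUC computation and the searchlight map.

test_that("auc_from_scores equals the pairwise Mann-Whitney oracle", {
    expect_equal(auc_from_scores(c(0.9, 0.8, 0.1, 0.7), c(1, 1, 0, 0)), 1.0)
    # (3 concordant + 1 tie) / 4 pairs
    expect_equal(auc_from_scores(c(0.8, 0.5, 0.5, 0.2), c(1, 1, 0, 0)), 0.875)
    expect_equal(auc_from_scores(rep(1, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
    expect_error(auc_from_scores(1:3, c(1, 1, 1)), "both classes")
    with_seed_local(8, {
        for (i in 1:50) {
            n <- sample(4:30, 1)
            y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
            s <- sample(round(rnorm(n), 1))  # coarse values force ties
            expect_equal(auc_from_scores(s, y), auc_bruteforce(s, y),
                         tolerance = 1e-12)
        }
    })
})

test_that("stratified_split draws round(ratio * class size) per class", {
    y <- c(rep(0, 34), rep(1, 51))
    sp <- stratified_split(y, 0.8, seed = 3L)
    expect_equal(sum(sp == "train" & y == 0), 27L)   # round(0.8 * 34)
    expect_equal(sum(sp == "train" & y == 1), 41L)   # round(0.8 * 51)
    expect_identical(sp, stratified_split(y, 0.8, seed = 3L))
    expect_true(all(stratified_split(y, 1.0, seed = 1L) == "train"))
    expect_error(stratified_split(c(0, 1, 1, 1), 0.8), "at least 2")
})

test_that("direct libsvm call agrees exactly with e1071::svm", {
    with_seed_local(9, {
        for (i in 1:5) {
            n <- sample(20:40, 1); p <- sample(5:30, 1)
            X <- matrix(rnorm(n * p), n, p)
            y <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
            fit <- deformark:::svm_linear_fit(X, y)
            ref <- e1071::svm(X, factor(y, levels = c("0", "1")),
                              kernel = "linear", cost = 1, scale = FALSE)
            dv <- attr(predict(ref, X, decision.values = TRUE),
                       "decision.values")
            oriented <- if (colnames(dv)[1] == "1/0") dv[, 1] else -dv[, 1]
            expect_equal(deformark:::svm_disease_scores(fit, X),
                         unname(oriented), tolerance = 1e-10)
        }
    })
})

test_that("cv_auc handles separable, null and degenerate inputs", {
    y <- rep(c(0, 1), each = 12)
    # perfectly separable: label duplicated across all columns
    X <- matrix(rep(y, 81), ncol = 81)
    expect_equal(cv_auc(X, y, n_folds = 4), 1.0)
    # all-identical features: degenerate contract
    expect_equal(cv_auc(matrix(2, 24, 5), y, n_folds = 4), 0.5)
    # permutation null: mean of mean-AUCs stays near 0.5
    with_seed_local(10, {
        Xn <- matrix(rnorm(24 * 6), 24, 6)
        aucs <- replicate(60, cv_auc(Xn, sample(y), n_folds = 4,
                                     seed = sample.int(1e6, 1)))
        expect_lt(abs(mean(aucs) - 0.5), 0.05)
    })
})

test_that("locale extraction is row-major and validates bounds", {
    cf <- toy_cohort_features()
    X <- extract_locale(cf, c(12, 12), k = 9)
    expect_equal(ncol(X), 81L)
    expect_equal(nrow(X), 24L)
    # k = 1: single column equal to the magnitude at the seed
    X1 <- extract_locale(cf, c(12, 12), k = 1)
    expect_equal(as.numeric(X1), unname(cf$magnitudes[, (12 - 1) * 24 + 12]))
    # row-major flattening: feature (wr, wc) sits at (wr-1)*k + wc
    k <- 3L
    X3 <- extract_locale(cf, c(12, 12), k = k)
    for (wr in 1:3) for (wc in 1:3) {
        px_r <- 12 + wr - 2L; px_c <- 12 + wc - 2L
        expect_equal(unname(X3[, (wr - 1L) * k + wc]),
                     unname(cf$magnitudes[, (px_c - 1L) * 24L + px_r]))
    }
    expect_error(extract_locale(cf, c(2, 12), k = 9), "exits the image")
    # constant stack: every feature equals the constant
    cfc <- cf
    cfc$magnitudes[] <- 2
    expect_true(all(extract_locale(cfc, c(12, 12), k = 9) == 2))
})

test_that("searchlight map finds the implanted block and masks borders", {
    cf <- toy_cohort_features()
    map <- screen_all_seeds(cf, k = 9)
    # 4-px invalid frame for k = 9
    expect_false(any(map$valid_mask[1:4, ]))
    expect_false(any(map$valid_mask[, 21:24]))
    expect_true(all(map$valid_mask[5:20, 5:20]))
    expect_true(all(is.na(map$auc[!map$valid_mask])))
    v <- map$auc[map$valid_mask]
    expect_true(all(v >= 0 & v <= 1))
    # argmax adjacent to the implanted 10:12 x 10:12 block
    am <- which(map$auc == max(v), arr.ind = TRUE)[1, ]
    expect_true(all(abs(am - 11) <= 5))
    # screening agrees with extract_locale + cv over the same folds
    tr <- cf$split == "train"
    direct <- deformark:::cv_auc_folds(
        extract_locale(cf, c(11, 11), k = 9, subjects = tr),
        cf$labels[tr], cf$folds[tr])
    expect_equal(map$auc[11, 11], direct)
})

test_that("AUC map is invariant to a global positive magnitude rescale", {
    cf <- toy_cohort_features(n_per_class = 8L, H = 16L, W = 16L,
                              block_rows = 8:9, block_cols = 8:9)
    map1 <- screen_all_seeds(cf, k = 5)
    cf2 <- cf
    cf2$magnitudes <- cf$magnitudes * 7.3
    map2 <- screen_all_seeds(cf2, k = 5)
    expect_equal(map1$auc, map2$auc, tolerance = 1e-6)
})
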