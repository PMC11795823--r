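# ROC construction, operating points and the exhaustive subset search.

test_that("roc_curve has proper endpoints and vertices", {
    roc <- roc_curve(c(0.9, 0.8, 0.4, 0.6, 0.3, 0.2), c(1, 1, 1, 0, 0, 0))
    expect_equal(roc$fpr[1], 0)
    expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1)
    expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    # AUC by trapezoid equals the Mann-Whitney value
    trap <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                     utils::tail(roc$tpr, -1)) / 2)
    expect_equal(trap, auc_from_scores(c(0.9, 0.8, 0.4, 0.6, 0.3, 0.2),
                                       c(1, 1, 1, 0, 0, 0)))
})

test_that("operating_point maximizes Youden's J with sensitivity ties", {
    # perfect separation
    roc <- roc_curve(c(3, 2, 1, 0), c(1, 1, 0, 0))
    op <- operating_point(roc)
    expect_equal(op$sensitivity, 1.0)
    expect_equal(op$specificity, 1.0)
    # degenerate all-equal scores: J = 0 everywhere, tie rule picks the
    # all-positive vertex
    opd <- operating_point(roc_curve(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)))
    expect_equal(opd$sensitivity, 1.0)
    expect_equal(opd$specificity, 0.0)
    # enumeration oracle on a mixed instance: every threshold's J computed
    # by brute force, maximum taken with the higher-sensitivity tie rule
    s <- c(0.9, 0.8, 0.4, 0.6, 0.3, 0.2); y <- c(1, 1, 1, 0, 0, 0)
    thr <- c(Inf, sort(unique(s), decreasing = TRUE))
    sens <- vapply(thr, function(t) mean(s[y == 1] >= t), 1)
    spec <- vapply(thr, function(t) mean(s[y == 0] < t), 1)
    j <- sens + spec - 1
    cand <- which(j >= max(j) - 1e-12)
    cand <- cand[order(-sens[cand])][1]
    op2 <- operating_point(roc_curve(s, y))
    expect_equal(op2$sensitivity, sens[cand])
    expect_equal(op2$specificity, spec[cand])
})

test_that("evaluate_combination is consistent and idempotent", {
    cf <- toy_cohort_features()
    map <- screen_all_seeds(cf, k = 9)
    regs <- refine_all(map, cf, threshold = 0.60)
    expect_gt(length(regs), 0L)
    a1 <- evaluate_combination(regs, 1L, cf)
    expect_equal(a1, regs[[1]]$train_auc)
    # duplicated member: pixel-set union makes it idempotent
    expect_equal(evaluate_combination(regs, c(1L, 1L), cf), a1)
    expect_error(evaluate_combination(regs, integer(0), cf), "nonempty")
})

test_that("search_combinations enumerates all subsets and matches an oracle", {
    cf <- toy_cohort_features()
    map <- screen_all_seeds(cf, k = 9)
    # build 4 small synthetic regions around the informative block
    regs <- list(dbm_region(cbind(10:12, 10L)), dbm_region(cbind(10:12, 11L)),
                 dbm_region(cbind(10:12, 12L)), dbm_region(cbind(6:7, 6L)))
    regs <- lapply(regs, function(r) {
        r$train_auc <- evaluate_combination(list(r), 1L, cf)
        r
    })
    res <- search_combinations(regs, cf)
    expect_equal(nrow(res$all_subsets), 15L)    # 2^4 - 1
    # independent second enumeration
    oracle_best <- -Inf; oracle_set <- NULL
    for (size in 1:4) {
        combos <- combn(4, size)
        for (j in seq_len(ncol(combos))) {
            a <- evaluate_combination(regs, combos[, j], cf)
            if (a > oracle_best) {
                oracle_best <- a
                oracle_set <- combos[, j]
            }
        }
    }
    expect_equal(res$train_auc, oracle_best)
    expect_equal(res$region_indices, oracle_set)
    # the winner beats (or ties) every singleton
    singles <- vapply(1:4, function(i) evaluate_combination(regs, i, cf), 1)
    expect_gte(res$train_auc, max(singles))
    # test metrics live in [0, 1] with coherent ROC endpoints
    expect_true(res$test_auc >= 0 && res$test_auc <= 1)
    expect_equal(res$roc$fpr[1], 0)
    expect_equal(res$roc$tpr[nrow(res$roc)], 1)
    # rerunning reproduces the test metrics bit-identically
    res2 <- search_combinations(regs, cf)
    expect_identical(res$test_auc, res2$test_auc)
    expect_identical(res$roc, res2$roc)
})

test_that("search_combinations refuses unsearchably many regions", {
    cf <- toy_cohort_features()
    regs <- lapply(1:23, function(i) dbm_region(cbind(5L + i %% 10, 5L + i %/% 10)))
    expect_error(search_combinations(regs, cf), "raise the AUC threshold")
    expect_error(search_combinations(list(), cf), "at least one")
})

test_that("crosscheck scores an external cohort with the frozen model", {
    cf <- toy_cohort_features()
    map <- screen_all_seeds(cf, k = 9)
    regs <- refine_all(map, cf, threshold = 0.60)
    res <- search_combinations(regs, cf)
    # a fresh all-control cohort: most subjects classified negative
    flds <- withr_seed_fields(sprintf("X%02d", 1:20), rep("control", 20),
                              24L, 24L, 10:12, 10:12, 3, seed = 77L)
    cc <- crosscheck_cohort(res, flds)
    expect_equal(cc$n, 20L)
    expect_true(cc$fraction_negative >= 0 && cc$fraction_negative <= 1)
    expect_gt(cc$fraction_negative, 0.5)
    expect_error(crosscheck_cohort(res, list()), "empty")
    bad <- list(B1 = deformation_field(matrix(0, 10, 10), matrix(0, 10, 10)))
    expect_error(crosscheck_cohort(res, bad), "reference grid")
})
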