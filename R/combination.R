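#' ROC curve from decision scores
#'
#' Vertices are generated at every distinct score threshold (predicted
#' positive iff score >= threshold) and always include the endpoints
#' (0, 0) and (1, 1).
#'
#' @param scores Numeric decision scores (larger = more disease-like).
#' @param labels 0/1 (or control/disease) labels.
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
    y <- as_binary_labels(labels)
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    if (n1 == 0L || n0 == 0L)
        stop("roc_curve: both classes must be present")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; yo <- y[ord]
    keep <- !duplicated(s, fromLast = TRUE)
    data.frame(threshold = c(Inf, s[keep]),
               fpr = c(0, cumsum(yo == 0)[keep] / n0),
               tpr = c(0, cumsum(yo == 1)[keep] / n1))
}

#' ROC operating point by Youden's J
#'
#' Picks the ROC vertex maximizing `J = sensitivity + specificity - 1`;
#' ties go to the vertex with higher sensitivity (then to the first such
#' vertex).
#'
#' @param roc Data frame from [roc_curve()].
#' @return List with `sensitivity`, `specificity`, `threshold`.
#' @export
operating_point <- function(roc) {
    stopifnot(is.data.frame(roc), nrow(roc) > 0)
    j <- roc$tpr - roc$fpr
    best <- which(j >= max(j) - 1e-12)
    best <- best[order(-roc$tpr[best])][1]
    list(sensitivity = roc$tpr[best], specificity = 1 - roc$fpr[best],
         threshold = roc$threshold[best])
}

# union of member regions' pixels as linear indices, deduplicated, in
# (region order, then raster) order
combination_idx <- function(regions, subset, H) {
    idx <- unlist(lapply(regions[subset], function(r)
        px_to_idx(r$pixels, H)))
    unique(idx)
}

#' Training AUC of a region combination
#'
#' The feature vector of a combination is the concatenation of its member
#' regions' per-pixel magnitudes (union of pixel sets: a duplicated region
#' is idempotent); the score is the cross-validated AUC on the training
#' subjects, over the same folds every other stage uses.
#'
#' @param regions List of [dbm_region()] objects.
#' @param subset Integer indices of the member regions (nonempty).
#' @param cohort A [cohort_features()] object.
#' @return Mean cross-validated training AUC.
#' @export
evaluate_combination <- function(regions, subset, cohort) {
    if (length(subset) == 0L)
        stop("evaluate_combination: subset must be nonempty")
    region_cv_auc(cohort, combination_idx(regions, subset, cohort$dims[1]))
}

#' Exhaustive search over all region combinations
#'
#' Evaluates all `2^n - 1` nonempty subsets of the refined regions on the
#' training subjects and selects the one with maximal training AUC (ties:
#' smallest subset, then lexicographic). The winner is then refit on the
#' full training set and scored exactly once on the reserved test
#' subjects, yielding the test AUC, the ROC curve and the Youden operating
#' point.
#'
#' @param regions List of [dbm_region()] objects (1 to 22 regions; more
#'   refuses with guidance to raise the AUC threshold).
#' @param cohort A [cohort_features()] object.
#' @param verbose Print progress.
#' @return An object of class `combination_result`: `region_indices`,
#'   `train_auc`, `test_auc`, `roc`, `sensitivity`, `specificity`,
#'   `operating_threshold`, `all_subsets` (data.frame of every evaluated
#'   subset), and `model` (frozen classifier for cross-checking).
#' @export
search_combinations <- function(regions, cohort, verbose = FALSE) {
    n <- length(regions)
    if (n < 1L) stop("search_combinations: need at least one region")
    if (n > 22L)
        stop("search_combinations: ", n, " regions give 2^", n,
             " subsets; raise the AUC threshold to reduce the region count")
    H <- cohort$dims[1]
    subsets <- list(); auc <- numeric(0)
    # size-ascending, lexicographic enumeration makes strict-greater
    # selection implement the tie-break for free
    for (size in seq_len(n)) {
        cols <- combn(n, size)
        for (j in seq_len(ncol(cols))) {
            subsets[[length(subsets) + 1L]] <- cols[, j]
            auc[length(auc) + 1L] <-
                evaluate_combination(regions, cols[, j], cohort)
        }
        if (verbose) message("evaluated all subsets of size ", size)
    }
    best <- which.max(auc)   # first max: smallest size, then lexicographic
    winner <- subsets[[best]]

    # refit on the full training set, score the reserved test set once
    idx <- combination_idx(regions, winner, H)
    ord_idx <- raster_order(idx, H)
    tr <- cohort$split == "train"
    Xtr <- cohort$magnitudes[tr, ord_idx, drop = FALSE]
    Xte <- cohort$magnitudes[!tr, ord_idx, drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, sd)
    sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
    fit <- svm_linear_fit(t((t(Xtr) - mu) / sdv), cohort$labels[tr])
    te_scores <- svm_disease_scores(fit, t((t(Xte) - mu) / sdv))
    roc <- roc_curve(te_scores, cohort$labels[!tr])
    op <- operating_point(roc)
    structure(list(
        region_indices = winner,
        train_auc = auc[best],
        test_auc = auc_from_scores(te_scores, cohort$labels[!tr]),
        roc = roc,
        sensitivity = op$sensitivity,
        specificity = op$specificity,
        operating_threshold = op$threshold,
        all_subsets = data.frame(
            subset = vapply(subsets, paste, character(1), collapse = "+"),
            size = lengths(subsets), train_auc = auc),
        model = list(pixels_idx = ord_idx, w = fit$w, rho = fit$rho,
                     pos_label = fit$pos_label, center = mu, scale = sdv,
                     dims = cohort$dims)),
        class = "combination_result")
}

#' @export
print.combination_result <- function(x, ...) {
    cat(sprintf("<combination_result: regions {%s}, train AUC %.3f, test AUC %.3f, sens %.2f / spec %.2f>\n",
                paste(x$region_indices, collapse = ","), x$train_auc,
                x$test_auc, x$sensitivity, x$specificity))
    invisible(x)
}

# Decision scores of a frozen combination model on new magnitude rows
frozen_model_scores <- function(model, magnitudes) {
    X <- magnitudes[, model$pixels_idx, drop = FALSE]
    X <- t((t(X) - model$center) / model$scale)
    s <- as.numeric(X %*% model$w) - model$rho
    if (model$pos_label == 1L) s else -s
}

#' Cross-check a frozen model against a second cohort
#'
#' Scores every subject of an independently registered cohort with the
#' frozen combined classifier and its operating threshold and reports the
#' fraction classified negative (score below threshold) — the external
#' consistency check against a cohort expected to be negative for the
#' trained condition.
#'
#' @param result A `combination_result`.
#' @param fields Named list of [deformation_field()] objects for the
#'   second cohort, on the same reference grid.
#' @return List with `fraction_negative`, `n`, and the per-subject
#'   `scores`.
#' @export
crosscheck_cohort <- function(result, fields) {
    stopifnot(inherits(result, "combination_result"))
    if (length(fields) == 0L)
        stop("crosscheck_cohort: empty cohort")
    dims <- result$model$dims
    bad <- names(fields)[!vapply(fields, function(f)
        identical(dim(f), dims), logical(1))]
    if (length(bad))
        stop("crosscheck_cohort: fields not on the reference grid: ",
             paste(bad, collapse = ", "))
    M <- t(vapply(fields, function(f) as.numeric(field_magnitude(f)),
                  numeric(prod(dims))))
    s <- frozen_model_scores(result$model, M)
    list(fraction_negative = mean(s < result$operating_threshold),
         n = length(s), scores = stats::setNames(s, names(fields)))
}

#' Write a combination result to JSON (and optionally a ROC plot)
#'
#' @param result A `combination_result`.
#' @param path JSON output path.
#' @param roc_png Optional PNG path for a rendered ROC curve.
#' @return `path`, invisibly.
#' @export
write_combination_result <- function(result, path, roc_png = NULL) {
    jsonlite::write_json(
        list(region_indices = result$region_indices,
             train_auc = result$train_auc, test_auc = result$test_auc,
             sensitivity = result$sensitivity,
             specificity = result$specificity,
             operating_threshold = result$operating_threshold,
             roc = result$roc, all_subsets = result$all_subsets),
        path, auto_unbox = TRUE, digits = NA)
    if (!is.null(roc_png)) {
        tryCatch({
            grDevices::png(roc_png, width = 480, height = 480)
            on.exit(grDevices::dev.off(), add = TRUE)
            graphics::plot(result$roc$fpr, result$roc$tpr, type = "s", lwd = 2,
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("combined ROIs: test AUC %.2f",
                                result$test_auc))
            graphics::abline(0, 1, lty = 3)
            graphics::points(1 - result$specificity, result$sensitivity,
                             pch = 19, col = 2)
        }, error = function(e)
            message("ROC plot skipped: ", conditionMessage(e)))
    }
    invisible(path)
}
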