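#' Cohort feature container for locale screening
#'
#' Stacks every subject's deformation-magnitude map, the class labels, the
#' train/test split (stratified, approximately 80/20) and the stratified
#' cross-validation fold assignment of the training subjects. The split and
#' folds are drawn once here so that every downstream stage (searchlight,
#' region refinement, combination search) scores candidates against the
#' identical partition, and the reserved test subjects are never touched
#' before final evaluation.
#'
#' @param fields Named list of [deformation_field()] objects, one per
#'   subject, all on the same grid.
#' @param labels Data frame with `subject_id` and `label`
#'   (`control`/`disease`), or a named character/numeric vector.
#' @param split_ratio Training fraction (default 0.8).
#' @param n_folds Number of cross-validation folds (default 8).
#' @param split_seed,fold_seed Integer seeds for the split and fold draws.
#' @return An object of class `cohort_features`: `magnitudes` (subjects x
#'   (H*W) matrix, column-major pixel indexing), `dims` (H, W), `labels`
#'   (0 = control, 1 = disease), `subject_ids`, `split` (factor
#'   `train`/`test`), `folds` (fold id per training subject, NA for test).
#' @export
cohort_features <- function(fields, labels, split_ratio = 0.8, n_folds = 8L,
                            split_seed = 1L, fold_seed = 2L) {
    if (is.data.frame(labels)) {
        lab <- stats::setNames(labels$label, labels$subject_id)
    } else lab <- labels
    ids <- names(fields)
    if (is.null(ids) || !all(ids %in% names(lab)))
        stop("cohort_features: every field needs a labeled subject id")
    y <- as_binary_labels(lab[ids])
    dims <- dim(fields[[1]])
    mags <- t(vapply(fields, function(f) {
        if (!identical(dim(f), dims))
            stop("cohort_features: field grids differ across subjects")
        as.numeric(field_magnitude(f))
    }, numeric(prod(dims))))
    rownames(mags) <- ids
    split <- stratified_split(y, ratio = split_ratio, seed = split_seed)
    folds <- rep(NA_integer_, length(ids))
    tr <- split == "train"
    folds[tr] <- make_folds(y[tr], n_folds = n_folds, seed = fold_seed)
    structure(list(magnitudes = mags, dims = dims, labels = y,
                   subject_ids = ids, split = split, folds = folds,
                   n_folds = as.integer(n_folds)),
              class = "cohort_features")
}

#' @export
print.cohort_features <- function(x, ...) {
    cat(sprintf("<cohort_features: %d subjects (%d control / %d disease), %d x %d grid, %d train / %d test, %d folds>\n",
                length(x$labels), sum(x$labels == 0), sum(x$labels == 1),
                x$dims[1], x$dims[2], sum(x$split == "train"),
                sum(x$split == "test"), x$n_folds))
    invisible(x)
}

# Coerce labels to 0 (control) / 1 (disease).
as_binary_labels <- function(labels) {
    if (is.numeric(labels)) {
        if (!all(labels %in% c(0, 1)))
            stop("labels must be 0/1 or control/disease")
        return(as.integer(labels))
    }
    l <- as.character(labels)
    if (!all(l %in% c("control", "disease")))
        stop("labels must be 0/1 or control/disease")
    as.integer(l == "disease")
}

#' Stratified train/test split
#'
#' Draws `round(ratio * n_class)` training subjects per class,
#' deterministically for a given seed.
#'
#' @param labels 0/1 (or control/disease) label vector.
#' @param ratio Training fraction.
#' @param seed Integer seed.
#' @return Factor with levels `train`, `test`.
#' @export
stratified_split <- function(labels, ratio = 0.8, seed = 1L) {
    y <- as_binary_labels(labels)
    if (min(table(y)) < 2L)
        stop("stratified_split: each class needs at least 2 subjects")
    stopifnot(ratio > 0, ratio <= 1)
    out <- rep("test", length(y))
    with_seed(seed, {
        for (cl in c(0L, 1L)) {
            idx <- which(y == cl)
            n_tr <- round(ratio * length(idx))
            out[sample(idx, n_tr)] <- "train"
        }
    })
    factor(out, levels = c("train", "test"))
}

# Stratified fold ids 1..n_folds: shuffle within class, assign round-robin.
make_folds <- function(labels, n_folds = 8L, seed = 2L) {
    y <- as_binary_labels(labels)
    folds <- integer(length(y))
    with_seed(seed, {
        for (cl in c(0L, 1L)) {
            idx <- which(y == cl)
            folds[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
        }
    })
    folds
}

#' AUC from decision scores (Mann-Whitney statistic)
#'
#' Fraction of (disease, control) pairs with the disease score higher,
#' ties counting one half; computed from average ranks.
#'
#' @param scores Numeric decision scores (larger = more disease-like).
#' @param labels 0/1 (or control/disease) labels.
#' @return AUC scalar in `[0, 1]`.
#' @export
auc_from_scores <- function(scores, labels) {
    y <- as_binary_labels(labels)
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    if (n1 == 0L || n0 == 0L)
        stop("auc_from_scores: both classes must be present")
    r <- rank(scores, ties.method = "average")
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Direct call into e1071's registered libsvm trainer (C-classification,
# linear kernel, cost as given, libsvm defaults otherwise). Avoids the R
# wrapper overhead, which dominates at searchlight scale; exact agreement
# with e1071::svm() is asserted in the test suite.
.svmtrain_cache <- new.env(parent = emptyenv())

svmtrain_symbol <- function() {
    if (is.null(.svmtrain_cache$sym)) {
        loadNamespace("e1071")   # ensures the libsvm DLL is loaded
        .svmtrain_cache$sym <- getNativeSymbolInfo("svmtrain",
                                                   PACKAGE = "e1071")
    }
    .svmtrain_cache$sym
}

svm_linear_fit <- function(X, y01, cost = 1) {
    n <- nrow(X); p <- ncol(X)
    err <- paste(rep(" ", 255), collapse = "")
    cret <- .C(svmtrain_symbol(),
               as.double(t(X)), as.integer(n), as.integer(p),
               as.double(y01 + 1), as.integer(0), as.integer(0),
               as.integer(0),              # type: C-classification
               as.integer(0),              # kernel: linear
               as.integer(3), as.double(1 / p), as.double(0),
               as.double(cost), as.double(0.5),
               integer(0), double(0), as.integer(0),
               as.double(40), as.double(0.001), as.double(0.1),
               as.integer(1), as.integer(0), as.integer(0), as.integer(0),
               nclasses = integer(1), nr = integer(1), index = integer(n),
               labels = integer(2), nSV = integer(2), rho = double(1),
               coefs = double(n), sigma = double(1), probA = double(1),
               probB = double(1), cresults = double(0), ctotal1 = double(1),
               ctotal2 = double(1), error = err)
    if (cret$error != err)
        stop("svm_linear_fit: libsvm error: ", trimws(cret$error))
    idx <- cret$index[seq_len(cret$nr)]
    w <- as.numeric(crossprod(X[idx, , drop = FALSE],
                              cret$coefs[seq_len(cret$nr)]))
    # decision value x.w - rho is positive for libsvm's first stored class
    list(w = w, rho = cret$rho[1], pos_label = cret$labels[1] - 1L)
}

# Decision scores oriented so that larger = disease (label 1).
svm_disease_scores <- function(fit, X) {
    s <- as.numeric(X %*% fit$w) - fit$rho
    if (fit$pos_label == 1L) s else -s
}

# Core CV engine over a fixed fold assignment. Standardizes features by
# fold-train statistics only; folds whose validation part has a single
# class are skipped and the mean renormalized; a degenerate problem
# (constant features, or no usable fold) scores 0.5.
cv_auc_folds <- function(X, y, folds, cost = 1) {
    if (max(X) - min(X) < 1e-12) return(0.5)
    uf <- sort(unique(folds))
    aucs <- rep(NA_real_, length(uf))
    for (i in seq_along(uf)) {
        va <- folds == uf[i]
        yva <- y[va]
        if (length(unique(yva)) < 2L) next
        ytr <- y[!va]
        if (length(unique(ytr)) < 2L) next
        Xtr <- X[!va, , drop = FALSE]
        mu <- colMeans(Xtr)
        sdv <- sqrt(pmax(colMeans(Xtr^2) - mu^2, 0) *
                        nrow(Xtr) / max(nrow(Xtr) - 1, 1))
        sdv[sdv < 1e-12] <- 1
        Xtr <- t((t(Xtr) - mu) / sdv)
        Xva <- t((t(X[va, , drop = FALSE]) - mu) / sdv)
        fit <- tryCatch(svm_linear_fit(Xtr, ytr, cost = cost),
                        error = function(e) NULL)
        if (is.null(fit)) next
        aucs[i] <- auc_from_scores(svm_disease_scores(fit, Xva), yva)
    }
    if (all(is.na(aucs))) 0.5 else mean(aucs, na.rm = TRUE)
}

#' Cross-validated AUC of a feature matrix
#'
#' Stratified `n_folds` partition; per fold, features are standardized by
#' the fold-train statistics, a linear-kernel maximum-margin classifier
#' (unit cost) is fitted, and the held-out fold is scored by its decision
#' values; the mean AUC over folds is returned. Folds whose validation
#' part contains a single class are skipped and the mean renormalized.
#' All-constant features return 0.5.
#'
#' @param features Subjects x p numeric matrix.
#' @param labels 0/1 (or control/disease) labels.
#' @param n_folds Number of folds (default 8).
#' @param seed Integer seed for the fold draw.
#' @return Mean cross-validated AUC.
#' @export
cv_auc <- function(features, labels, n_folds = 8L, seed = 2L) {
    y <- as_binary_labels(labels)
    if (length(unique(y)) < 2L)
        stop("cv_auc: both classes must be present")
    folds <- make_folds(y, n_folds = n_folds, seed = seed)
    cv_auc_folds(as.matrix(features), y, folds)
}

#' Extract the k x k locale feature matrix at a seed pixel
#'
#' Row i is the row-major flattening of subject i's `k x k` window of
#' deformation magnitudes centered on the seed (81 features for the
#' default 9 x 9 locale).
#'
#' @param cohort A [cohort_features()] object (or a subjects x H x W
#'   magnitude array).
#' @param seed_pixel Integer (row, col) seed position.
#' @param k Odd window size, default 9.
#' @param subjects Optional logical/integer subject subset.
#' @return Subjects x k^2 feature matrix.
#' @export
extract_locale <- function(cohort, seed_pixel, k = 9L, subjects = NULL) {
    stopifnot(k %% 2 == 1, k >= 1)
    h <- (k - 1L) %/% 2L
    if (inherits(cohort, "cohort_features")) {
        H <- cohort$dims[1]; W <- cohort$dims[2]
        M <- cohort$magnitudes
    } else {
        a <- as.array(cohort)
        H <- dim(a)[2]; W <- dim(a)[3]
        M <- matrix(a, dim(a)[1], H * W)
    }
    r <- seed_pixel[1]; c <- seed_pixel[2]
    if (r - h < 1 || r + h > H || c - h < 1 || c + h > W)
        stop("extract_locale: locale exits the image at seed (", r, ", ", c, ")")
    idx <- as.integer(outer(seq(r - h, r + h), (seq(c - h, c + h) - 1L) * H,
                            `+`))
    # row-major flattening: row varies slowest within the window
    idx <- idx[as.integer(t(matrix(seq_len(k * k), k, k)))]
    X <- M[, idx, drop = FALSE]
    if (!is.null(subjects)) X <- X[subjects, , drop = FALSE]
    X
}

#' Searchlight AUC map over every valid seed pixel
#'
#' For each pixel whose `k x k` locale stays inside the image, computes the
#' cross-validated AUC of the locale's magnitude features on the training
#' subjects only (the reserved test subjects are never touched). The
#' result is the per-pixel map that region refinement thresholds.
#'
#' @param cohort A [cohort_features()] object.
#' @param k Odd locale size (default 9).
#' @param verbose Print progress every 2000 seeds.
#' @return An object of class `auc_map`: `auc` (H x W matrix, NA where
#'   invalid), `valid_mask` (H x W logical), `k`.
#' @export
screen_all_seeds <- function(cohort, k = 9L, verbose = FALSE) {
    stopifnot(inherits(cohort, "cohort_features"), k %% 2 == 1)
    H <- cohort$dims[1]; W <- cohort$dims[2]
    h <- (k - 1L) %/% 2L
    tr <- cohort$split == "train"
    y <- cohort$labels[tr]
    folds <- cohort$folds[tr]
    M <- cohort$magnitudes[tr, , drop = FALSE]
    auc <- matrix(NA_real_, H, W)
    valid <- matrix(FALSE, H, W)
    valid[(h + 1):(H - h), (h + 1):(W - h)] <- TRUE
    # precomputed window offsets in column-major pixel indexing
    offs <- as.integer(outer(-h:h, (-h:h) * H, `+`))
    n_done <- 0L
    for (c in (h + 1):(W - h)) {
        base <- (c - 1L) * H
        for (r in (h + 1):(H - h)) {
            X <- M[, base + r + offs, drop = FALSE]
            auc[r, c] <- cv_auc_folds(X, y, folds)
            n_done <- n_done + 1L
            if (verbose && n_done %% 2000L == 0L)
                message("screened ", n_done, " seeds")
        }
    }
    structure(list(auc = auc, valid_mask = valid, k = as.integer(k)),
              class = "auc_map")
}

#' @export
print.auc_map <- function(x, ...) {
    v <- x$auc[x$valid_mask]
    cat(sprintf("<auc_map %d x %d (k = %d): mean %.3f, max %.3f>\n",
                nrow(x$auc), ncol(x$auc), x$k, mean(v), max(v)))
    invisible(x)
}

#' Write an AUC map as NIfTI plus a display heatmap PNG
#'
#' The PNG emulates the usual presentation: the reference image in gray
#' with AUC values above 0.5 blended in as a hot colormap.
#'
#' @param map An `auc_map`.
#' @param path Output NIfTI path (`.nii` / `.nii.gz`).
#' @param reference Optional [image2d()] used as the PNG underlay.
#' @param png_path Optional PNG path (default: alongside `path`).
#' @return `path`, invisibly.
#' @export
write_auc_map <- function(map, path, reference = NULL, png_path = NULL) {
    a <- map$auc
    a[!map$valid_mask] <- 0
    RNifti::writeNifti(RNifti::asNifti(a), path)
    if (!is.null(reference)) {
        png_path <- png_path %||% sub("\\.nii(\\.gz)?$", "_heatmap.png", path)
        bg <- minmax01(as_image2d(reference)$pixels)
        v <- pmin(pmax((map$auc - 0.5) / 0.5, 0), 1)
        v[!map$valid_mask] <- 0
        rgb <- array(0, c(dim(bg), 3))
        # hot overlay: red ramps first, then green
        rgb[, , 1] <- pmin(1, bg * (1 - v) + 2 * v)
        rgb[, , 2] <- bg * (1 - v) + pmax(0, 2 * v - 1)
        rgb[, , 3] <- bg * (1 - v)
        png::writePNG(rgb, png_path)
    }
    invisible(path)
}
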