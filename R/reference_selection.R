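#' Ordered 7-landmark configuration of one subject
#'
#' Landmarks follow a fixed anatomical numbering; point 1 is the central
#' structure on which the rigid alignment is centered.
#'
#' @param subject_id Subject identifier.
#' @param points 7 x 2 numeric matrix of (row, col) positions in pixels.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(subject_id, points) {
    points <- matrix(as.numeric(points), ncol = 2L)
    if (nrow(points) != 7L)
        stop("landmark_set: subject ", subject_id,
             " must have exactly 7 landmarks, got ", nrow(points))
    if (!all(is.finite(points)))
        stop("landmark_set: subject ", subject_id,
             " has non-finite landmark coordinates")
    structure(list(subject_id = as.character(subject_id), points = points),
              class = "landmark_set")
}

#' Read landmark sets from the cohort CSV layout
#'
#' Expects columns `subject_id, landmark_index, row, col` with indices
#' 1 to 7 per subject.
#'
#' @param path CSV file path, or a data.frame in the same layout.
#' @return Named list of [landmark_set()] objects.
#' @export
read_landmarks <- function(path) {
    df <- if (is.data.frame(path)) path else read.csv(path)
    need <- c("subject_id", "landmark_index", "row", "col")
    if (!all(need %in% names(df)))
        stop("read_landmarks: missing columns: ",
             paste(setdiff(need, names(df)), collapse = ", "))
    sets <- lapply(split(df, df$subject_id), function(s) {
        s <- s[order(s$landmark_index), ]
        landmark_set(s$subject_id[1], cbind(s$row, s$col))
    })
    sets[order(names(sets))]
}

#' Subjects x 14 landmark configuration matrix
#'
#' Each configuration is centered on its own point 1 (translation removal)
#' and flattened as (row1, col1, ..., row7, col7); positions 1-2 are
#' therefore always zero.
#'
#' @param sets List of [landmark_set()] objects (>= 3 subjects).
#' @return Numeric matrix with one row per subject, rownames = subject ids.
#' @export
landmark_matrix <- function(sets) {
    stopifnot(all(vapply(sets, inherits, TRUE, "landmark_set")))
    if (length(sets) < 3L)
        stop("landmark_matrix: at least 3 subjects are required")
    m <- t(vapply(sets, function(s) {
        p <- sweep(s$points, 2, s$points[1, ])
        as.numeric(t(p))
    }, numeric(14)))
    rownames(m) <- vapply(sets, `[[`, character(1), "subject_id")
    m
}

#' Select the reference subject by landmark PCA
#'
#' Runs PCA on the centered configuration matrix and picks the subject
#' whose scores lie nearest the group mean (the medoid) in the subspace of
#' leading components explaining at least 95% cumulative variance. Ties are
#' broken by lexicographic subject id. A degenerate cohort (all
#' configurations identical) returns the first id with distance 0 and a
#' `degenerate` flag.
#'
#' @param sets List of [landmark_set()] objects (>= 3 subjects).
#' @param variance_target Cumulative explained-variance fraction defining
#'   the score subspace (default 0.95).
#' @return An object of class `reference_choice`: `subject_id`,
#'   `pc_scores` (subjects x components), `distance_to_mean` (named vector,
#'   all subjects), `explained_variance_ratio`, `n_components`,
#'   `degenerate`.
#' @export
select_reference <- function(sets, variance_target = 0.95) {
    m <- landmark_matrix(sets)
    ids <- rownames(m)
    total_var <- sum(apply(m, 2, stats::var))
    if (total_var < 1e-12) {
        warning("select_reference: all landmark configurations identical")
        d <- stats::setNames(rep(0, nrow(m)), ids)
        return(structure(list(subject_id = sort(ids)[1],
                              pc_scores = matrix(0, nrow(m), 1,
                                                 dimnames = list(ids, "PC1")),
                              distance_to_mean = d,
                              explained_variance_ratio = 1,
                              n_components = 1L, degenerate = TRUE),
                         class = "reference_choice"))
    }
    pc <- prcomp(m, center = TRUE, scale. = FALSE)
    evr <- pc$sdev^2 / sum(pc$sdev^2)
    k <- which(cumsum(evr) >= variance_target)[1]
    scores <- pc$x[, seq_len(k), drop = FALSE]
    # prcomp centers on the column mean, so the group mean sits at the origin
    d <- sqrt(rowSums(scores^2))
    names(d) <- ids
    best <- unname(sort(ids[d <= min(d) + 1e-12])[1])
    structure(list(subject_id = best, pc_scores = pc$x,
                   distance_to_mean = d, explained_variance_ratio = evr,
                   n_components = k, degenerate = FALSE),
              class = "reference_choice")
}

#' @export
print.reference_choice <- function(x, ...) {
    cat(sprintf("<reference_choice: %s (distance %.4g, %d PC%s for %.1f%% variance)>\n",
                x$subject_id, x$distance_to_mean[x$subject_id],
                x$n_components, if (x$n_components > 1) "s" else "",
                100 * sum(x$explained_variance_ratio[seq_len(x$n_components)])))
    invisible(x)
}

#' Write a reference choice to JSON
#'
#' @param choice A `reference_choice`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reference_choice <- function(choice, path) {
    jsonlite::write_json(
        list(subject_id = choice$subject_id,
             distance_to_mean = as.list(choice$distance_to_mean),
             explained_variance_ratio = choice$explained_variance_ratio,
             n_components = choice$n_components,
             degenerate = choice$degenerate),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
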