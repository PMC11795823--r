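#' Candidate region of interest
#'
#' A set of reference-grid pixels with the training AUC of its pooled
#' per-pixel magnitude features and the audit trail of every refinement
#' step.
#'
#' @param pixels m x 2 integer matrix of (row, col) coordinates.
#' @param train_auc Cross-validated training AUC of the region's features.
#' @param history Data frame of `(step, n_pixels, auc)` records.
#' @return An object of class `dbm_region`.
#' @export
dbm_region <- function(pixels, train_auc = NA_real_, history = NULL) {
    pixels <- matrix(as.integer(pixels), ncol = 2L,
                     dimnames = list(NULL, c("row", "col")))
    if (nrow(pixels) == 0L) stop("dbm_region: region must be nonempty")
    pixels <- pixels[order(pixels[, 1], pixels[, 2]), , drop = FALSE]
    structure(list(pixels = pixels, train_auc = train_auc,
                   history = history %||%
                       data.frame(step = character(), n_pixels = integer(),
                                  auc = numeric())),
              class = "dbm_region")
}

#' @export
print.dbm_region <- function(x, ...) {
    cat(sprintf("<dbm_region: %d pixels, train AUC %.3f, %d history steps>\n",
                nrow(x$pixels), x$train_auc, nrow(x$history)))
    invisible(x)
}

# --- pixel-set helpers (column-major linear indices on the H x W grid) ---

px_to_idx <- function(pixels, H) (pixels[, 2] - 1L) * H + pixels[, 1]

idx_to_px <- function(idx, H) {
    cbind(row = ((idx - 1L) %% H) + 1L, col = ((idx - 1L) %/% H) + 1L)
}

# raster (row-major) ordering of linear indices
raster_order <- function(idx, H) {
    px <- idx_to_px(idx, H)
    idx[order(px[, 1], px[, 2])]
}

# 8-neighborhood ring around a pixel-index set, restricted to valid mask
ring_idx <- function(idx, H, W, valid) {
    px <- idx_to_px(idx, H)
    offs <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
    offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
    nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
        cbind(px[, 1] + offs[i, 1], px[, 2] + offs[i, 2])))
    ok <- nb[, 1] >= 1 & nb[, 1] <= H & nb[, 2] >= 1 & nb[, 2] <= W
    nb <- nb[ok, , drop = FALSE]
    cand <- unique((nb[, 2] - 1L) * H + nb[, 1])
    cand <- setdiff(cand, idx)
    cand[valid[cand]]
}

# region pixels having at least one 8-neighbor outside the region
boundary_idx <- function(idx, H, W) {
    inset <- logical(H * W)
    inset[idx] <- TRUE
    px <- idx_to_px(idx, H)
    is_b <- vapply(seq_along(idx), function(i) {
        r <- px[i, 1]; c <- px[i, 2]
        for (dr in -1:1) for (dc in -1:1) {
            if (dr == 0 && dc == 0) next
            rr <- r + dr; cc <- c + dc
            if (rr < 1 || rr > H || cc < 1 || cc > W) return(TRUE)
            if (!inset[(cc - 1L) * H + rr]) return(TRUE)
        }
        FALSE
    }, logical(1))
    idx[is_b]
}

# training-subject CV AUC of a pixel-index set (raster feature order)
region_cv_auc <- function(cohort, idx) {
    tr <- cohort$split == "train"
    X <- cohort$magnitudes[tr, raster_order(idx, cohort$dims[1]),
                           drop = FALSE]
    cv_auc_folds(X, cohort$labels[tr], cohort$folds[tr])
}

# 8-connected component labeling by flood fill
label_components8 <- function(mask) {
    H <- nrow(mask); W <- ncol(mask)
    lab <- matrix(0L, H, W)
    nextlab <- 0L
    todo <- which(mask)
    for (s in todo) {
        if (lab[s] > 0L) next
        nextlab <- nextlab + 1L
        queue <- s
        lab[s] <- nextlab
        while (length(queue)) {
            cur <- queue[length(queue)]
            queue <- queue[-length(queue)]
            r <- ((cur - 1L) %% H) + 1L
            c <- ((cur - 1L) %/% H) + 1L
            for (dr in -1:1) for (dc in -1:1) {
                rr <- r + dr; cc <- c + dc
                if (rr < 1 || rr > H || cc < 1 || cc > W) next
                j <- (cc - 1L) * H + rr
                if (mask[j] && lab[j] == 0L) {
                    lab[j] <- nextlab
                    queue <- c(queue, j)
                }
            }
        }
    }
    lab
}

#' Threshold the AUC map into connected candidate regions
#'
#' Takes the 8-connected components of `{valid pixels with AUC >
#' threshold}`, scores each by the cross-validated training AUC of its
#' pooled per-pixel magnitude features, and returns them sorted by
#' descending size.
#'
#' @param map An `auc_map` from [screen_all_seeds()].
#' @param cohort The [cohort_features()] object the map was computed from.
#' @param threshold AUC threshold (default 0.62).
#' @return List of [dbm_region()] objects (possibly empty).
#' @export
threshold_regions <- function(map, cohort, threshold = 0.62) {
    stopifnot(inherits(map, "auc_map"), inherits(cohort, "cohort_features"))
    mask <- map$valid_mask & !is.na(map$auc) & map$auc > threshold
    if (!any(mask)) return(list())
    lab <- label_components8(mask)
    H <- nrow(lab)
    regions <- lapply(seq_len(max(lab)), function(l) {
        idx <- which(lab == l)
        auc <- region_cv_auc(cohort, idx)
        dbm_region(idx_to_px(idx, H), train_auc = auc,
                   history = data.frame(step = "threshold",
                                        n_pixels = length(idx), auc = auc))
    })
    regions[order(-vapply(regions, function(r) nrow(r$pixels), numeric(1)))]
}

#' Grow a region by dilation until its AUC plateaus
#'
#' Repeatedly adds the full one-pixel 8-neighborhood ring (inside the
#' valid mask) and rescores; stops once the improvement over the best
#' state stays below `plateau_eps` for `patience` consecutive dilations or
#' the AUC drops below the best seen, then rolls back to the best-scoring
#' state. Every step is recorded in the history.
#'
#' @param region A [dbm_region()].
#' @param cohort A [cohort_features()] object.
#' @param map The `auc_map` providing the valid mask.
#' @param plateau_eps Minimum improvement that resets the plateau counter.
#' @param patience Number of consecutive sub-`plateau_eps` dilations
#'   tolerated before stopping.
#' @param max_dilations Hard cap on dilation steps.
#' @return The grown [dbm_region()] (rolled back to its best state).
#' @export
grow_region <- function(region, cohort, map, plateau_eps = 1e-3,
                        patience = 2L, max_dilations = 50L) {
    stopifnot(inherits(region, "dbm_region"))
    H <- cohort$dims[1]; W <- cohort$dims[2]
    valid <- as.logical(map$valid_mask)
    idx <- px_to_idx(region$pixels, H)
    hist <- region$history
    if (is.na(region$train_auc)) {
        region$train_auc <- region_cv_auc(cohort, idx)
        hist <- rbind(hist, data.frame(step = "rescore",
                                       n_pixels = length(idx),
                                       auc = region$train_auc))
    }
    best_auc <- region$train_auc
    best_idx <- idx
    stale <- 0L
    for (i in seq_len(max_dilations)) {
        ring <- ring_idx(idx, H, W, valid)
        if (!length(ring)) break
        idx <- c(idx, ring)
        auc <- region_cv_auc(cohort, idx)
        hist <- rbind(hist, data.frame(step = "dilate",
                                       n_pixels = length(idx), auc = auc))
        if (auc - best_auc >= plateau_eps) {
            best_auc <- auc
            best_idx <- idx
            stale <- 0L
        } else {
            if (auc > best_auc) {       # tiny gain: keep, but count as stale
                best_auc <- auc
                best_idx <- idx
            }
            stale <- stale + 1L
            if (auc < best_auc || stale >= patience) break
        }
    }
    hist <- rbind(hist, data.frame(step = "rollback",
                                   n_pixels = length(best_idx),
                                   auc = best_auc))
    dbm_region(idx_to_px(best_idx, H), train_auc = best_auc, history = hist)
}

#' Optimize a region boundary by per-pixel inclusion/exclusion sweeps
#'
#' In raster order, every exterior 8-neighbor is tested for inclusion
#' (kept iff the training AUC strictly increases) and every boundary pixel
#' for exclusion (removed iff the AUC strictly increases and the region
#' stays nonempty). Passes repeat until one changes nothing or
#' `max_passes` is reached; the result never scores below the input.
#'
#' @param region A [dbm_region()].
#' @param cohort A [cohort_features()] object.
#' @param map The `auc_map` providing the valid mask.
#' @param max_passes Maximum full sweeps (default 10).
#' @return The optimized [dbm_region()].
#' @export
boundary_sweep <- function(region, cohort, map, max_passes = 10L) {
    stopifnot(inherits(region, "dbm_region"))
    H <- cohort$dims[1]; W <- cohort$dims[2]
    valid <- as.logical(map$valid_mask)
    idx <- px_to_idx(region$pixels, H)
    auc <- if (is.na(region$train_auc)) region_cv_auc(cohort, idx)
           else region$train_auc
    hist <- region$history
    for (pass in seq_len(max_passes)) {
        changed <- FALSE
        for (cand in raster_order(ring_idx(idx, H, W, valid), H)) {
            trial <- region_cv_auc(cohort, c(idx, cand))
            if (trial > auc) {
                idx <- c(idx, cand)
                auc <- trial
                changed <- TRUE
                hist <- rbind(hist, data.frame(step = "include",
                                               n_pixels = length(idx),
                                               auc = auc))
            }
        }
        for (cand in raster_order(boundary_idx(idx, H, W), H)) {
            if (length(idx) <= 1L) break
            if (!cand %in% idx) next   # may have been restructured
            trial <- region_cv_auc(cohort, setdiff(idx, cand))
            if (trial > auc) {
                idx <- setdiff(idx, cand)
                auc <- trial
                changed <- TRUE
                hist <- rbind(hist, data.frame(step = "exclude",
                                               n_pixels = length(idx),
                                               auc = auc))
            }
        }
        if (!changed) break
    }
    dbm_region(idx_to_px(idx, H), train_auc = auc, history = hist)
}

#' Threshold, grow, sweep and merge all regions
#'
#' Runs the full refinement: threshold the AUC map, grow each component to
#' its plateau, sweep its boundary, then merge any refined regions that
#' share or 8-touch pixels (rescoring merged regions once). Returns the
#' final regions sorted by descending training AUC.
#'
#' @inheritParams threshold_regions
#' @param plateau_eps,patience,max_passes Refinement controls, see
#'   [grow_region()] and [boundary_sweep()].
#' @param verbose Print per-region progress.
#' @return List of refined [dbm_region()] objects.
#' @export
refine_all <- function(map, cohort, threshold = 0.62, plateau_eps = 1e-3,
                       patience = 2L, max_passes = 10L, verbose = FALSE) {
    regions <- threshold_regions(map, cohort, threshold)
    if (!length(regions)) return(list())
    H <- cohort$dims[1]
    refined <- vector("list", length(regions))
    for (i in seq_along(regions)) {
        g <- grow_region(regions[[i]], cohort, map, plateau_eps, patience)
        refined[[i]] <- boundary_sweep(g, cohort, map, max_passes)
        if (verbose)
            message(sprintf("region %d: %d -> %d px, AUC %.3f -> %.3f", i,
                            nrow(regions[[i]]$pixels),
                            nrow(refined[[i]]$pixels),
                            regions[[i]]$train_auc,
                            refined[[i]]$train_auc))
    }
    # merge regions that overlap or touch (8-adjacency), transitively
    n <- length(refined)
    if (n > 1L) {
        idxs <- lapply(refined, function(r) px_to_idx(r$pixels, H))
        adj <- diag(TRUE, n)
        for (i in seq_len(n - 1)) for (j in (i + 1):n) {
            pi <- refined[[i]]$pixels; pj <- refined[[j]]$pixels
            touch <- FALSE
            for (a in seq_len(nrow(pi))) {
                if (any(abs(pj[, 1] - pi[a, 1]) <= 1 &
                        abs(pj[, 2] - pi[a, 2]) <= 1)) {
                    touch <- TRUE
                    break
                }
            }
            adj[i, j] <- adj[j, i] <- touch
        }
        comp <- components_from_adjacency(adj)
        merged <- lapply(unique(comp), function(g) {
            members <- which(comp == g)
            if (length(members) == 1L) return(refined[[members]])
            idx <- unique(unlist(idxs[members]))
            auc <- region_cv_auc(cohort, idx)
            hist <- do.call(rbind, lapply(refined[members], `[[`, "history"))
            hist <- rbind(hist, data.frame(step = "merge",
                                           n_pixels = length(idx), auc = auc))
            dbm_region(idx_to_px(idx, H), train_auc = auc, history = hist)
        })
        refined <- merged
    }
    refined[order(-vapply(refined, `[[`, numeric(1), "train_auc"))]
}

# connected components of a logical adjacency matrix (tiny n; BFS)
components_from_adjacency <- function(adj) {
    n <- nrow(adj)
    comp <- integer(n)
    cur <- 0L
    for (s in seq_len(n)) {
        if (comp[s] > 0L) next
        cur <- cur + 1L
        queue <- s
        comp[s] <- cur
        while (length(queue)) {
            v <- queue[1]
            queue <- queue[-1]
            nb <- which(adj[v, ] & comp == 0L)
            comp[nb] <- cur
            queue <- c(queue, nb)
        }
    }
    comp
}

#' Write regions as a labeled mask NIfTI plus JSON
#'
#' @param regions List of [dbm_region()] objects.
#' @param dims (H, W) grid dimensions.
#' @param nii_path Labeled-mask NIfTI output path.
#' @param json_path JSON output path (pixels, AUC, history per region).
#' @return `nii_path`, invisibly.
#' @export
write_regions <- function(regions, dims, nii_path, json_path) {
    lab <- matrix(0L, dims[1], dims[2])
    for (i in seq_along(regions))
        lab[px_to_idx(regions[[i]]$pixels, dims[1])] <- i
    RNifti::writeNifti(RNifti::asNifti(lab), nii_path)
    jsonlite::write_json(
        lapply(regions, function(r)
            list(pixels = unname(as.matrix(r$pixels)),
                 train_auc = r$train_auc, history = r$history)),
        json_path, auto_unbox = TRUE, digits = NA)
    invisible(nii_path)
}
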