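#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end run with validation. Unknown
#' arguments are rejected so parameter-sweep typos fail loudly. Either
#' `synth` (phantom + cohort specs for a generated study) or `inputs`
#' (paths to an existing cohort in the on-disk layout) must be given.
#'
#' @param out Output directory.
#' @param synth Optional list with `phantom` ([phantom_spec()]) and
#'   `cohort` ([cohort_spec()]).
#' @param inputs Optional list with `images` (directory of
#'   `<id>.nii(.gz)` files), `labels` (CSV path), `landmarks` (CSV path).
#' @param k Odd locale size >= 3 (default 9).
#' @param folds Cross-validation folds >= 2 (default 8).
#' @param split_ratio Training fraction (default 0.8).
#' @param auc_threshold Region threshold in (0.5, 1) (default 0.62).
#' @param max_regions Cap on candidate regions entering refinement and the
#'   exhaustive combination search (default 12, at most 22): the pipeline
#'   raises the working threshold in 0.02 steps while more components than
#'   this survive, mirroring the step-down used when none do.
#' @param demons [demons_params()].
#' @param split_seed,fold_seed Integer seeds for split and folds.
#' @param experiment Experiment name recorded in the manifest.
#' @param ... Unknown keys: rejected.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out, synth = NULL, inputs = NULL, k = 9L,
                       folds = 8L, split_ratio = 0.8, auc_threshold = 0.62,
                       max_regions = 12L, demons = demons_params(),
                       split_seed = 11L, fold_seed = 12L,
                       experiment = "default", ...) {
    extra <- list(...)
    if (length(extra))
        stop("run_config: unknown configuration keys: ",
             paste(names(extra), collapse = ", "))
    if (is.null(synth) == is.null(inputs))
        stop("run_config: exactly one of `synth` or `inputs` is required")
    stopifnot(k %% 2 == 1, k >= 3, folds >= 2,
              auc_threshold > 0.5, auc_threshold < 1,
              split_ratio > 0, split_ratio < 1,
              max_regions >= 1, max_regions <= 22)
    if (!is.null(synth))
        stopifnot(inherits(synth$phantom, "phantom_spec"),
                  inherits(synth$cohort, "cohort_spec"))
    structure(list(out = out, synth = synth, inputs = inputs,
                   k = as.integer(k), folds = as.integer(folds),
                   split_ratio = split_ratio, auc_threshold = auc_threshold,
                   max_regions = as.integer(max_regions),
                   demons = demons, split_seed = as.integer(split_seed),
                   fold_seed = as.integer(fold_seed),
                   experiment = experiment),
              class = "run_config")
}

load_cohort_inputs <- function(inputs) {
    for (p in c(inputs$labels, inputs$landmarks))
        if (!file.exists(p)) stop("pipeline: missing input file: ", p)
    if (!dir.exists(inputs$images))
        stop("pipeline: missing image directory: ", inputs$images)
    labels <- read.csv(inputs$labels)
    imgs <- lapply(stats::setNames(nm = labels$subject_id), function(id) {
        for (ext in c(".nii.gz", ".nii")) {
            p <- file.path(inputs$images, paste0(id, ext))
            if (file.exists(p)) return(read_image2d(p))
        }
        stop("pipeline: missing image for subject ", id)
    })
    list(images = imgs, labels = labels,
         landmarks = read.csv(inputs$landmarks))
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes, in order: cohort synthesis (or loading), reference selection,
#' rigid + demons registration of every subject, searchlight AUC
#' screening, region refinement, exhaustive combination search with final
#' test-set evaluation, and morphology inference; every intermediate
#' artifact is written under `config$out` and summarized in a manifest
#' with per-artifact MD5 checksums. Re-running an identical config
#' reproduces all numeric outputs (and hence checksums) bit-identically.
#' If no region survives the AUC threshold, the threshold is stepped down
#' by 0.02 (not below 0.52) until one does.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return An object of class `pipeline_run`: all stage results plus the
#'   `manifest` (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
    stopifnot(inherits(config, "run_config"))
    out <- config$out
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    t_stage <- c()
    tick <- function(name, expr) {
        t0 <- proc.time()[["elapsed"]]
        r <- tryCatch(force(expr), error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
        t_stage[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
        if (verbose) message(sprintf("stage %-16s %8.1fs", name,
                                     t_stage[[name]]))
        r
    }

    # 1. cohort
    cohort_data <- tick("cohort", {
        if (!is.null(config$synth))
            render_cohort(config$synth$phantom, config$synth$cohort,
                          out_dir = file.path(out, "cohort"))
        else load_cohort_inputs(config$inputs)
    })
    labels <- cohort_data$labels
    landmarks <- read_landmarks(cohort_data$landmarks %||%
                                config$inputs$landmarks)

    # 2. reference selection (controls only)
    choice <- tick("select_reference", {
        ctl <- labels$subject_id[labels$label == "control"]
        ch <- select_reference(landmarks[names(landmarks) %in% ctl])
        write_reference_choice(ch, file.path(out, "reference_choice.json"))
        ch
    })

    # 3. registration
    reg <- tick("register", {
        r <- register_cohort(cohort_data$images, landmarks,
                             choice$subject_id, config$demons,
                             verbose = verbose)
        fdir <- file.path(out, "fields")
        dir.create(fdir, showWarnings = FALSE)
        for (id in names(r$fields))
            write_field(r$fields[[id]], file.path(fdir, paste0(id, ".nii.gz")))
        jsonlite::write_json(lapply(r$transforms, function(tr)
            list(rotation_deg = tr$rotation_deg,
                 translation = tr$translation, center = tr$center,
                 degenerate = tr$degenerate)),
            file.path(out, "rigid_transforms.json"),
            auto_unbox = TRUE, digits = NA)
        r
    })

    # 4. searchlight screening (features, split and folds drawn here)
    reference_img <- cohort_data$images[[choice$subject_id]]
    cohort <- NULL
    map <- tick("screen", {
        cohort <- cohort_features(
            reg$fields, labels, split_ratio = config$split_ratio,
            n_folds = config$folds, split_seed = config$split_seed,
            fold_seed = config$fold_seed)
        m <- screen_all_seeds(cohort, k = config$k, verbose = verbose)
        write_auc_map(m, file.path(out, "auc_map.nii.gz"),
                      reference = reference_img)
        m
    })

    # 5. refinement; the working threshold steps down when no component
    # survives and up when more than max_regions do (an unsearchable
    # threshold is as unusable as an empty one)
    refine <- tick("refine", {
        thr <- config$auc_threshold
        n_comp <- function(t) {
            mask <- map$valid_mask & !is.na(map$auc) & map$auc > t
            if (!any(mask)) 0L else max(label_components8(mask))
        }
        for (i in 1:30) {
            n <- n_comp(thr)
            if (n == 0L && thr > 0.52) thr <- thr - 0.02
            else if (n > config$max_regions && thr < 0.98) thr <- thr + 0.02
            else break
        }
        if (n_comp(thr) == 0L)
            stop("no region exceeds the AUC threshold floor of 0.52")
        regions <- refine_all(map, cohort, threshold = thr,
                              verbose = verbose)
        write_regions(regions, cohort$dims,
                      file.path(out, "regions.nii.gz"),
                      file.path(out, "regions.json"))
        list(regions = regions, threshold_used = thr)
    })

    # 6. combination search + reserved-test evaluation
    combo <- tick("combine", {
        cr <- search_combinations(refine$regions, cohort,
                                  verbose = verbose)
        write_combination_result(cr, file.path(out, "combination_result.json"),
                                 roc_png = file.path(out, "roc.png"))
        cr
    })

    # 7. morphology of the winning regions
    morph <- tick("morphology", {
        winning <- refine$regions[combo$region_indices]
        ms <- morphology_summary(winning, reg$fields, labels)
        write_morphology(ms, file.path(out, "morphology.json"),
                         reference = reference_img)
        ms
    })

    files <- sort(setdiff(list.files(out, recursive = TRUE),
                          c("manifest.json", "roc.png")))
    manifest <- list(
        experiment = config$experiment,
        config = config_echo(config),
        stages = names(t_stage),
        reference_id = choice$subject_id,
        threshold_used = refine$threshold_used,
        n_regions = length(refine$regions),
        winning_regions = combo$region_indices,
        train_auc = combo$train_auc, test_auc = combo$test_auc,
        sensitivity = combo$sensitivity, specificity = combo$specificity,
        checksums = as.list(tools::md5sum(file.path(out, files))) |>
            stats::setNames(files),
        wall_clock_s = as.list(t_stage))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    structure(list(config = config, reference = choice,
                   registration = reg, cohort = cohort, auc_map = map,
                   regions = refine$regions, combination = combo,
                   morphology = morph, manifest = manifest,
                   cohort_data = cohort_data),
              class = "pipeline_run")
}

# JSON-serializable echo of a run_config
config_echo <- function(config) {
    ech <- list(schema_version = 1L, k = config$k, folds = config$folds,
                split_ratio = config$split_ratio,
                auc_threshold = config$auc_threshold,
                max_regions = config$max_regions,
                demons = unclass(config$demons),
                split_seed = config$split_seed,
                fold_seed = config$fold_seed,
                experiment = config$experiment)
    if (!is.null(config$synth)) {
        co <- config$synth$cohort
        ech$synth <- list(n_control = co$n_control,
                          n_disease = co$n_disease, seed = co$seed,
                          n_effects = length(co$effects))
    } else ech$inputs <- config$inputs
    ech
}

#' @export
print.pipeline_run <- function(x, ...) {
    cat(sprintf("<pipeline_run '%s': reference %s, %d regions, winner {%s}, train AUC %.3f, test AUC %.3f>\n",
                x$config$experiment, x$reference$subject_id,
                length(x$regions),
                paste(x$combination$region_indices, collapse = ","),
                x$combination$train_auc, x$combination$test_auc))
    invisible(x)
}

#' Cross-check a pipeline's frozen model against another cohort
#'
#' Registers a second labeled cohort to the same reference subject and
#' scores it with the frozen combined classifier at its operating
#' threshold, reporting the fraction classified negative.
#'
#' @param run A `pipeline_run`.
#' @param images Named list of [image2d()] for the second cohort.
#' @param landmarks Named list of [landmark_set()] for the second cohort.
#' @param verbose Print registration progress.
#' @return See [crosscheck_cohort()].
#' @export
pipeline_crosscheck <- function(run, images, landmarks, verbose = FALSE) {
    stopifnot(inherits(run, "pipeline_run"))
    ref_id <- run$reference$subject_id
    imgs <- c(run$cohort_data$images[ref_id], images)
    lms <- c(read_landmarks(run$cohort_data$landmarks)[ref_id], landmarks)
    reg <- register_cohort(imgs, lms, ref_id, run$config$demons,
                           verbose = verbose)
    crosscheck_cohort(run$combination, reg$fields[names(images)])
}
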