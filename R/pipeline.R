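.defaultConfig <- function() {
    list(seed = 1, n_patients = 50, out_dir = "breastcomp-run",
         margin_mm = 5, bin_width_hu = 25, dose_bin_width_gy = 0.25,
         gmm_window = c(-200, 100), gmm_tol = 1e-6, gmm_max_iter = 500,
         gmm_min_voxels = 1000,
         kmeans_seed = 20140, kmeans_restarts = 10,
         alpha_beta = 1.7, n_fractions = NULL,
         base_gy = 40.05,
         baseline_vars = c("age", "breast_volume_cm3", "boost"),
         candidate_vars = c("median_hu", "fat_volume_cm3",
                            "fg_volume_cm3", "fat_mean_gy", "fat_max_gy",
                            "fat_uniformity", "fg_mean_gy", "fg_max_gy",
                            "fg_uniformity"),
         endpoints = .ENDPOINTS, timepoints = .TIMEPOINTS,
         grid_dim = c(48, 48, 32), grid_spacing = c(3.5, 3.5, 3.5))
}

#' Read and validate a pipeline configuration
#'
#' Configuration is a YAML file (or an R list) of the keys in
#' `.defaultConfig`; unknown keys are an error and `n_fractions` is
#' mandatory — the fraction count must never be assumed. Validation runs
#' before any computation.
#'
#' @param config path to a YAML file, or a named list.
#' @return the completed, validated configuration list.
#' @export
readRunConfig <- function(config) {
    if (is.character(config)) {
        if (!file.exists(config))
            stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    def <- .defaultConfig()
    unknown <- setdiff(names(config), names(def))
    if (length(unknown))
        stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(def, config)
    if (is.null(cfg$n_fractions))
        stop("config validation failed: n_fractions is required ",
             "(no silent default)")
    stopifnot(cfg$n_fractions >= 1, cfg$alpha_beta > 0,
              cfg$margin_mm >= 0, cfg$bin_width_hu > 0,
              cfg$dose_bin_width_gy > 0, cfg$n_patients >= 4)
    cfg
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in order — simulate, crop from skin, intensity
#' features, density clustering, per-patient tissue segmentation,
#' substructure dosimetry (physical and EQD2), outcome merging and the
#' association sweep — writing one artifact per stage into the run
#' directory. The run is deterministic given the configuration: a rerun
#' with the same config reproduces byte-identical CSV outputs. A
#' `manifest.json` records the MD5 of the config file so every artifact in
#' the directory is traceable to its configuration.
#'
#' @param config a YAML path or named list (see [readRunConfig()]).
#' @return invisibly, a list with the run directory, the cohort records,
#'   the cluster model and the sweep result.
#' @export
runPipeline <- function(config) {
    cfg <- readRunConfig(config)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    outfile <- function(f) file.path(cfg$out_dir, f)
    log <- function(...) {
        msg <- sprintf(...)
        cat(msg, "\n", sep = "", file = outfile("run.log"), append = TRUE)
        message(msg)
    }
    cat("", file = outfile("run.log"))
    yaml::write_yaml(cfg, outfile("config.yaml"))
    cfgHash <- unname(tools::md5sum(outfile("config.yaml")))
    log("run config hash %s", cfgHash)

    log("stage simulate: %d patients, seed %d", cfg$n_patients, cfg$seed)
    coh <- generateCohort(cfg$n_patients, seed = cfg$seed, imaging = TRUE,
                          baseGy = cfg$base_gy,
                          nFractions = cfg$n_fractions,
                          gridDim = cfg$grid_dim,
                          spacing = cfg$grid_spacing)
    records <- coh$records
    scheme <- FractionationScheme(cfg$n_fractions,
                                  alphaBeta = cfg$alpha_beta)

    log("stage crop/features/segment/dosimetry (margin %g mm)",
        cfg$margin_mm)
    featRows <- list(); segRows <- list(); doseRows <- list()
    for (p in seq_along(coh$phantoms)) {
        ph <- coh$phantoms[[p]]
        pid <- records$patient_id[p]
        cropped <- cropFromSkin(ph$breast, ph$body,
                                marginMm = cfg$margin_mm)
        featRows[[p]] <- featureTable(ph$ct, list(cropped), pid,
                                      binWidth = cfg$bin_width_hu)
        res <- classifyBreastTissue(ph$ct, cropped,
                                    window = cfg$gmm_window,
                                    tol = cfg$gmm_tol,
                                    maxIter = cfg$gmm_max_iter,
                                    minVoxels = min(cfg$gmm_min_voxels,
                                                    nVoxels(cropped) %/% 2))
        pct <- compositionPct(res$segmentation)
        segRows[[p]] <- data.frame(
            patient_id = pid,
            fat_weight = mixWeights(res$fit)[1],
            fat_mean_hu = mixMeans(res$fit)[1],
            fat_sd_hu = mixSDs(res$fit)[1],
            fg_mean_hu = mixMeans(res$fit)[2],
            fg_sd_hu = mixSDs(res$fit)[2],
            fat_pct = pct[["fat"]],
            fibroglandular_pct = pct[["fibroglandular"]],
            unclassified_pct = pct[["unclassified"]],
            stringsAsFactors = FALSE)
        dm <- withCallingHandlers(
            substructureDoseReport(ph$dose, res$segmentation, cropped,
                                   scheme,
                                   binWidthGy = cfg$dose_bin_width_gy),
            warning = function(w) invokeRestart("muffleWarning"))
        dm$patient_id <- pid
        doseRows[[p]] <- dm
    }
    features <- do.call(rbind, featRows)
    segs <- do.call(rbind, segRows)
    doseTab <- do.call(rbind, doseRows)
    write.csv(features, outfile("features.csv"), row.names = FALSE)
    write.csv(segs, outfile("segmentations.csv"), row.names = FALSE)
    write.csv(doseTab, outfile("dosimetry.csv"), row.names = FALSE)

    log("stage cluster (seed %d, %d restarts)", cfg$kmeans_seed,
        cfg$kmeans_restarts)
    cl <- clusterCohort(features, seed = cfg$kmeans_seed,
                        restarts = cfg$kmeans_restarts)
    write.csv(cl$assignments, outfile("assignments.csv"),
              row.names = FALSE)
    .writeClusterModel(cl$model, outfile("cluster-model.txt"))

    log("stage associate")
    records$density_label <- cl$assignments$label[
        match(records$patient_id, cl$assignments$patient_id)]
    records <- mergeCohortOutcomes(records, endpoints = cfg$endpoints,
                                   timepoints = cfg$timepoints)
    sweep <- endpointSweep(records, baseline = cfg$baseline_vars,
                           candidates = cfg$candidate_vars,
                           endpoints = cfg$endpoints,
                           timepoints = cfg$timepoints)
    write.csv(sweep$summary, outfile("models-summary.csv"),
              row.names = FALSE)
    modelJson <- lapply(sweep$details, function(d) list(
        coefficients = d$coefficients,
        selected = d$forward$selected,
        baseline_aic = d$forward$baselineAIC,
        final_aic = d$forward$finalAIC,
        trace = d$forward$trace,
        backward_selected = if (!is.null(d$backward))
            d$backward$selected else NULL))
    jsonlite::write_json(modelJson, outfile("models.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(records, outfile("cohort.csv"), row.names = FALSE)

    artifacts <- c("config.yaml", "features.csv", "segmentations.csv",
                   "dosimetry.csv", "assignments.csv", "cluster-model.txt",
                   "models-summary.csv", "models.json", "cohort.csv")
    jsonlite::write_json(list(config_hash = cfgHash, artifacts = artifacts),
                         outfile("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    log("run complete: %s", cfg$out_dir)
    invisible(list(dir = cfg$out_dir, records = records, model = cl$model,
                   sweep = sweep))
}

# plain-text persistence of a cluster model (centroids, standardization,
# seed); human-readable and diff-friendly
.writeClusterModel <- function(model, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        "# breastCompRT cluster model",
        paste("seed:", model@seed),
        paste("restarts:", model@restarts),
        paste("inertia:", format(model@inertia, digits = 17)),
        paste("feature_means:",
              paste(format(model@featureMeans, digits = 17),
                    collapse = " ")),
        paste("feature_sds:",
              paste(format(model@featureSDs, digits = 17),
                    collapse = " ")),
        paste("label_order:", paste(model@labelOrder, collapse = " ")),
        "centers:"), con)
    for (i in 1:4)
        writeLines(paste(format(model@centers[i, ], digits = 17),
                         collapse = " "), con)
    invisible(path)
}

#' Read back a persisted cluster model
#'
#' @param path file written by the pipeline's cluster stage.
#' @return a [ClusterModel-class].
#' @export
readClusterModel <- function(path) {
    ln <- readLines(path)
    val <- function(key) {
        x <- sub(paste0("^", key, ": *"), "",
                 grep(paste0("^", key, ":"), ln, value = TRUE))
        as.numeric(strsplit(x, " +")[[1]])
    }
    ci <- which(ln == "centers:")
    centers <- do.call(rbind, lapply(ln[(ci + 1):(ci + 4)], function(s)
        as.numeric(strsplit(trimws(s), " +")[[1]])))
    colnames(centers) <- .FEATURES
    new("ClusterModel", centers = centers,
        featureMeans = setNames(val("feature_means"), .FEATURES),
        featureSDs = setNames(val("feature_sds"), .FEATURES),
        seed = as.integer(val("seed")),
        restarts = as.integer(val("restarts")),
        inertia = val("inertia"),
        labelOrder = as.integer(val("label_order")))
}
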