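.FEATURES <- c("median_hu", "iqr_hu", "uniformity")

.checkFeatureFrame <- function(features) {
    miss <- setdiff(c("patient_id", .FEATURES), names(features))
    if (length(miss))
        stop("feature table lacks columns: ", paste(miss, collapse = ", "))
    bad <- !stats::complete.cases(features[.FEATURES]) |
        !apply(is.finite(as.matrix(features[.FEATURES])), 1, all)
    if (any(bad))
        stop(sum(bad), " patients have non-finite features")
    invisible(TRUE)
}

#' Cluster a cohort into four BI-RADS-like density classes
#'
#' K-means (k = 4) on z-scored first-order features (median HU, IQR,
#' uniformity). Four clusters are used by design, mirroring the four
#' BI-RADS density categories. The fit is deterministic given the seed and
#' restart count; the best-inertia solution over the restarts is kept.
#'
#' @param features data.frame with columns `patient_id`, `median_hu`,
#'   `iqr_hu`, `uniformity` (one row per patient-side).
#' @param seed RNG seed for the k-means initializations (default 20140).
#' @param restarts number of random restarts (default 10).
#' @return a list with `model` (a [ClusterModel-class], label order filled
#'   by ascending centroid median HU) and `assignments` (data.frame:
#'   patient_id, cluster, label).
#' @seealso [nameClusters()], [projectClusters()], [compareClusterings()]
#' @export
clusterCohort <- function(features, seed = 20140, restarts = 10) {
    .checkFeatureFrame(features)
    if (nrow(features) < 4L)
        stop("need at least 4 patients to form 4 clusters, got ",
             nrow(features))
    x <- as.matrix(features[.FEATURES])
    mu <- colMeans(x)
    sdv <- apply(x, 2, sd)
    if (any(sdv == 0))
        stop("degenerate (zero-variance) feature: ",
             paste(.FEATURES[sdv == 0], collapse = ", "))
    z <- scale(x, center = mu, scale = sdv)
    set.seed(seed)
    km <- kmeans(z, centers = 4, nstart = restarts, iter.max = 100)
    model <- new("ClusterModel",
                 centers = km$centers,
                 featureMeans = setNames(mu, .FEATURES),
                 featureSDs = setNames(sdv, .FEATURES),
                 seed = as.integer(seed), restarts = as.integer(restarts),
                 inertia = km$tot.withinss,
                 labelOrder = integer(0))
    model <- .orderClusterLabels(model)
    assignments <- data.frame(patient_id = features$patient_id,
                              cluster = km$cluster,
                              stringsAsFactors = FALSE)
    assignments$label <- .labelFor(model, assignments$cluster)
    list(model = model, assignments = assignments)
}

# centroid features back on the HU scale
.centroidFeatures <- function(model) {
    sweep(sweep(model@centers, 2, model@featureSDs, "*"),
          2, model@featureMeans, "+")
}

.orderClusterLabels <- function(model) {
    cf <- .centroidFeatures(model)
    med <- cf[, "median_hu"]
    if (max(med) - min(med) < 1e-9 &&
        max(cf[, "uniformity"]) - min(cf[, "uniformity"]) < 1e-12)
        stop("degenerate model: all centroids identical; cannot name clusters")
    if (anyDuplicated(med)) {
        message("tied centroid median HU; breaking tie by descending ",
                "uniformity")
        ord <- order(med, -cf[, "uniformity"])
    } else {
        ord <- order(med)
    }
    model@labelOrder <- as.integer(ord)
    validObject(model)
    model
}

.labelFor <- function(model, cluster) {
    rank <- match(cluster, model@labelOrder)
    factor(.DENSITY_LABELS[rank], levels = .DENSITY_LABELS)
}

#' Name clusters by ascending centroid median HU
#'
#' Density names are attached in order of ascending centroid median HU:
#' the lowest-median cluster is `fatty` (fat is the lowest-HU breast
#' tissue) through to `extremely_dense`. Ties are broken by descending
#' centroid uniformity (the fattier cluster is the more uniform one) and
#' reported.
#'
#' @param model a fitted [ClusterModel-class].
#' @param assignments data.frame with a `cluster` column of raw indices.
#' @return `assignments` with a `label` factor column added/replaced.
#' @export
nameClusters <- function(model, assignments) {
    model <- .orderClusterLabels(model)
    assignments$label <- .labelFor(model, assignments$cluster)
    assignments
}

#' Assign new feature vectors through a fitted model
#'
#' Projects feature vectors (e.g. contralateral breasts) onto the fitted
#' ipsilateral model: z-score with the model's standardization, then
#' nearest centroid. The alternative — an independent refit on the
#' contralateral features — is [clusterCohort()] applied to those features;
#' reproducibility analysis uses two independent fits.
#'
#' @param model a [ClusterModel-class].
#' @param features feature data.frame (see [clusterCohort()]).
#' @return assignments data.frame (patient_id, cluster, label).
#' @export
projectClusters <- function(model, features) {
    .checkFeatureFrame(features)
    z <- scale(as.matrix(features[.FEATURES]),
               center = model@featureMeans, scale = model@featureSDs)
    d2 <- vapply(seq_len(nrow(model@centers)), function(k)
        rowSums(sweep(z, 2, model@centers[k, ], "-")^2),
        numeric(nrow(z)))
    cl <- max.col(-matrix(d2, nrow = nrow(z)))
    out <- data.frame(patient_id = features$patient_id, cluster = cl,
                      stringsAsFactors = FALSE)
    out$label <- .labelFor(model, out$cluster)
    out
}

#' Compare two labelled clusterings of the same patients
#'
#' Used for the ipsilateral-versus-contralateral reproducibility analysis:
#' a 4 x 4 confusion matrix (rows = `a` labels, columns = `b` labels),
#' per-class agreement (diagonal / row total) and overall accuracy.
#'
#' @param a,b assignment data.frames with `patient_id` and `label` columns
#'   over the same patient set.
#' @return a list: `confusion` (4 x 4 table), `perClass` (named numeric),
#'   `accuracy` (scalar), `n`.
#' @export
compareClusterings <- function(a, b) {
    if (!setequal(a$patient_id, b$patient_id) ||
        nrow(a) != nrow(b) || anyDuplicated(a$patient_id))
        stop("patient sets differ: only in a: ",
             paste(setdiff(a$patient_id, b$patient_id), collapse = ", "),
             "; only in b: ",
             paste(setdiff(b$patient_id, a$patient_id), collapse = ", "))
    b <- b[match(a$patient_id, b$patient_id), ]
    la <- factor(a$label, levels = .DENSITY_LABELS)
    lb <- factor(b$label, levels = .DENSITY_LABELS)
    cm <- table(a = la, b = lb)
    rowTot <- rowSums(cm)
    perClass <- ifelse(rowTot > 0, diag(cm) / rowTot, NA_real_)
    names(perClass) <- .DENSITY_LABELS
    list(confusion = cm, perClass = perClass,
         accuracy = sum(diag(cm)) / sum(cm), n = sum(cm))
}
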