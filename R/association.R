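#' Merge clinician- and patient-reported toxicity grades
#'
#' The per-patient merged grade is the maximum of the available reports,
#' so the more severe observation always wins; when only one source is
#' present it is used as-is. Provenance records which source supplied the
#' merged value.
#'
#' @param cro,pro integer vectors of grades in 0..3, NA allowed.
#' @return data.frame with columns `grade` (merged, NA when both sources
#'   are missing) and `source` in {"cro", "pro", "tie", "cro_only",
#'   "pro_only", "missing"}.
#' @examples
#' mergeOutcomes(c(1, 0, 3, NA), c(2, 0, NA, NA))
#' @export
mergeOutcomes <- function(cro, pro) {
    if (length(cro) != length(pro))
        stop("cro and pro must have equal length")
    ok <- function(x) all(is.na(x) | (x %in% 0:3))
    if (!ok(cro) || !ok(pro))
        stop("grades must lie in 0..3 (or NA)")
    grade <- pmax(cro, pro, na.rm = TRUE)
    grade[is.na(cro) & is.na(pro)] <- NA
    source <- rep("missing", length(grade))
    source[!is.na(cro) & is.na(pro)] <- "cro_only"
    source[is.na(cro) & !is.na(pro)] <- "pro_only"
    both <- !is.na(cro) & !is.na(pro)
    source[both & cro > pro] <- "cro"
    source[both & pro > cro] <- "pro"
    source[both & cro == pro] <- "tie"
    nmiss <- sum(source == "missing")
    if (nmiss)
        message(nmiss, " records missing from both sources")
    data.frame(grade = grade, source = source, stringsAsFactors = FALSE)
}

#' Fit a proportional-odds ordinal regression
#'
#' Maximum-likelihood proportional-odds (ordinal logistic) model of a
#' 0..3 toxicity grade on covariates, via [MASS::polr()]. Complete cases
#' only; a warning is raised when there are fewer than 10 complete cases
#' per estimated parameter. Wald standard errors, z and p values come from
#' the observed information.
#'
#' @param records data.frame, one row per patient.
#' @param outcome name of the grade column (values in 0..3).
#' @param covariates character vector of covariate column names (may be
#'   empty for the cutpoints-only null model).
#' @return an [OrdinalFit-class]; non-convergence or an unstable Hessian is
#'   flagged in `converged` rather than raising.
#' @export
fitOrdinal <- function(records, outcome, covariates = character()) {
    cols <- c(outcome, covariates)
    miss <- setdiff(cols, names(records))
    if (length(miss))
        stop("records lack columns: ", paste(miss, collapse = ", "))
    d <- records[stats::complete.cases(records[cols]), cols, drop = FALSE]
    y <- d[[outcome]]
    if (!all(y %in% 0:3))
        stop("outcome '", outcome, "' must contain grades 0..3")
    lev <- sort(unique(y))
    if (length(lev) < 2L)
        stop("outcome '", outcome, "' has a single observed level")
    d[[outcome]] <- factor(y, levels = lev, ordered = TRUE)

    rhs <- if (length(covariates))
        paste(covariates, collapse = " + ") else "1"
    fml <- as.formula(paste(outcome, "~", rhs))
    nPar <- length(covariates) + length(lev) - 1L
    if (nrow(d) < 10 * nPar)
        warning("only ", nrow(d), " complete cases for ", nPar,
                " parameters (", outcome, ")")

    fit <- tryCatch(
        suppressWarnings(MASS::polr(fml, data = d, Hess = TRUE,
                                    method = "logistic")),
        error = function(e) e)
    if (inherits(fit, "error"))
        return(new("OrdinalFit",
                   coefficients = data.frame(term = character(),
                                             estimate = numeric(),
                                             se = numeric(), z = numeric(),
                                             p = numeric()),
                   zeta = numeric(), logLik = NA_real_, aic = NA_real_,
                   nUsed = nrow(d), converged = FALSE,
                   formula = deparse(fml)))

    est <- coef(fit)
    se <- rep(NA_real_, length(est))
    hessOk <- TRUE
    if (length(est)) {
        vc <- tryCatch(vcov(fit), error = function(e) NULL)
        if (is.null(vc) || any(!is.finite(diag(vc)[seq_along(est)])) ||
            any(diag(vc)[seq_along(est)] <= 0)) {
            hessOk <- FALSE
        } else {
            se <- sqrt(diag(vc)[seq_along(est)])
        }
    }
    z <- est / se
    cf <- data.frame(term = names(est), estimate = unname(est),
                     se = unname(se), z = unname(z),
                     p = 2 * pnorm(-abs(unname(z))),
                     stringsAsFactors = FALSE)
    ll <- as.numeric(logLik(fit))
    new("OrdinalFit",
        coefficients = cf, zeta = fit$zeta, logLik = ll,
        aic = 2 * (length(est) + length(fit$zeta)) - 2 * ll,
        nUsed = nrow(d), converged = (fit$convergence == 0) && hessOk,
        formula = deparse(fml))
}

#' Screen covariates for collinearity
#'
#' Pairs of candidate variables with |Pearson r| at or above the threshold
#' are reduced to one variable. Within a flagged pair the variable with the
#' better (lower-AIC) univariable proportional-odds fit for the given
#' outcome is kept; without an outcome the earlier-listed variable is kept.
#' Zero-variance variables are dropped up front with a warning. Pairs are
#' resolved in order of descending |r|.
#'
#' @param records data.frame of covariates.
#' @param vars character vector of candidate column names.
#' @param outcome optional outcome column driving the keep rule.
#' @param threshold absolute-correlation cutoff (default 0.9).
#' @return list: `retained` (character), `dropped` (data.frame with
#'   dropped, kept, r).
#' @export
collinearityFilter <- function(records, vars, outcome = NULL,
                               threshold = 0.9) {
    dropped <- data.frame(dropped = character(), kept = character(),
                          r = numeric(), stringsAsFactors = FALSE)
    x <- records[vars]
    zv <- vapply(x, function(col) var(col, na.rm = TRUE) == 0 ||
                     all(is.na(col)), logical(1))
    if (any(zv)) {
        warning("zero-variance variables dropped: ",
                paste(vars[zv], collapse = ", "))
        for (v in vars[zv])
            dropped[nrow(dropped) + 1L, ] <- list(v, NA_character_,
                                                  NA_real_)
        vars <- vars[!zv]
    }
    uniAic <- function(v) {
        if (is.null(outcome)) return(NA_real_)
        f <- fitOrdinal(records, outcome, v)
        if (f@converged) f@aic else Inf
    }
    repeat {
        if (length(vars) < 2L) break
        cm <- suppressWarnings(
            abs(cor(records[vars], use = "pairwise.complete.obs")))
        diag(cm) <- 0
        if (all(cm < threshold, na.rm = TRUE)) break
        ij <- which(cm == max(cm, na.rm = TRUE), arr.ind = TRUE)[1, ]
        a <- vars[ij[1]]; b <- vars[ij[2]]
        keepA <- if (is.null(outcome)) {
            match(a, vars) < match(b, vars)
        } else {
            aicA <- suppressWarnings(uniAic(a))
            aicB <- suppressWarnings(uniAic(b))
            if (aicA == aicB) match(a, vars) < match(b, vars)
            else aicA < aicB
        }
        drop <- if (keepA) b else a
        keep <- if (keepA) a else b
        dropped[nrow(dropped) + 1L, ] <-
            list(drop, keep, cm[ij[1], ij[2]])
        vars <- setdiff(vars, drop)
    }
    list(retained = vars, dropped = dropped)
}

#' AIC-stepwise selection over candidate variables with a fixed baseline
#'
#' Forward: starting from the baseline (clinical/demographic) model, the
#' candidate giving the largest AIC decrease is added greedily; selection
#' stops when no candidate decreases the AIC. Baseline variables are never
#' removed. Backward: starting from baseline plus all candidates,
#' candidates are greedily removed while removal decreases AIC. Complete
#' cases are fixed over the union of all variables up front so every AIC in
#' a run is computed on the same records. The trace records every
#' comparison made. The selection path is deterministic given the data.
#'
#' @param records data.frame.
#' @param outcome grade column name.
#' @param baseline character vector of always-included covariates.
#' @param candidates character vector of candidate covariates.
#' @param direction "forward" or "backward".
#' @return list: `trace` (data.frame: step, variable, aic_before,
#'   aic_after, accepted), `fit` (final [OrdinalFit-class]), `selected`
#'   (candidates in the final model), `baselineAIC`, `finalAIC`,
#'   `direction`.
#' @export
stepwiseAIC <- function(records, outcome, baseline = character(),
                        candidates = character(),
                        direction = c("forward", "backward")) {
    direction <- match.arg(direction)
    allVars <- c(outcome, baseline, candidates)
    d <- records[stats::complete.cases(records[allVars]), , drop = FALSE]

    base <- fitOrdinal(d, outcome, baseline)
    if (!base@converged)
        stop("baseline model did not converge for outcome '", outcome,
             "'; cannot run selection")
    baselineAIC <- base@aic

    trace <- data.frame(step = integer(), variable = character(),
                        aic_before = numeric(), aic_after = numeric(),
                        accepted = logical(), stringsAsFactors = FALSE)
    inSet <- if (direction == "forward") character() else candidates
    cur <- if (direction == "forward") base
           else fitOrdinal(d, outcome, c(baseline, candidates))
    if (!cur@converged && direction == "backward")
        stop("full model did not converge; cannot run backward selection")
    step <- 0L
    repeat {
        step <- step + 1L
        pool <- if (direction == "forward") setdiff(candidates, inSet)
                else inSet
        if (!length(pool)) break
        aics <- vapply(pool, function(v) {
            vars <- if (direction == "forward") c(baseline, inSet, v)
                    else c(baseline, setdiff(inSet, v))
            f <- suppressWarnings(fitOrdinal(d, outcome, vars))
            if (f@converged) f@aic else NA_real_
        }, numeric(1))
        best <- if (all(is.na(aics))) 0L else which.min(aics)
        accepted <- best > 0L && is.finite(aics[best]) &&
            aics[best] < cur@aic
        for (i in seq_along(pool))
            trace[nrow(trace) + 1L, ] <-
                list(step, pool[i], cur@aic, aics[i],
                     accepted && i == best)
        if (!accepted) break
        v <- pool[best]
        inSet <- if (direction == "forward") c(inSet, v)
                 else setdiff(inSet, v)
        cur <- suppressWarnings(fitOrdinal(d, outcome, c(baseline, inSet)))
    }
    list(trace = trace, fit = cur, selected = inSet,
         baselineAIC = baselineAIC, finalAIC = cur@aic,
         direction = direction)
}

#' Sweep all endpoint/timepoint cells
#'
#' For every requested endpoint and timepoint: screen candidates for
#' collinearity (keeping the variable with the better univariable fit),
#' run forward and backward AIC-stepwise selection around the fixed
#' baseline, and tabulate the result. Outcome columns are named
#' `<endpoint>_<timepoint>`. Cells whose outcome is missing, constant, or
#' too sparse are skipped with a reason. Coefficients of the forward final
#' model carry two significance tiers (p < 0.05, p < 0.001), reported
#' without multiplicity correction.
#'
#' @param records cohort data.frame with merged grade columns.
#' @param baseline baseline covariate names (e.g. age, breast volume,
#'   boost).
#' @param candidates candidate composition/dose variable names.
#' @param endpoints endpoint names (default pain, oedema, atrophy,
#'   induration).
#' @param timepoints timepoint suffixes (default post, y1, y2).
#' @param threshold collinearity cutoff passed to [collinearityFilter()].
#' @return list: `summary` (one row per cell: n, baseline_aic, best_aic,
#'   selected, agreement, skipped, reason), `details` (per-cell list with
#'   the forward/backward runs and the collinearity report).
#' @export
endpointSweep <- function(records, baseline, candidates,
                          endpoints = .ENDPOINTS,
                          timepoints = .TIMEPOINTS, threshold = 0.9) {
    summ <- list()
    details <- list()
    for (ep in endpoints) for (tp in timepoints) {
        cell <- paste(ep, tp, sep = "_")
        row <- data.frame(endpoint = ep, timepoint = tp, n = NA_integer_,
                          baseline_aic = NA_real_, best_aic = NA_real_,
                          selected = NA_character_, agreement = NA,
                          skipped = FALSE, reason = "",
                          stringsAsFactors = FALSE)
        skip <- function(why) {
            row$skipped <<- TRUE
            row$reason <<- why
        }
        if (!cell %in% names(records)) {
            skip("outcome column absent")
        } else {
            cc <- stats::complete.cases(
                records[c(cell, baseline, candidates)])
            y <- records[[cell]][cc]
            if (sum(cc) < 20) skip("fewer than 20 complete cases")
            else if (length(unique(y)) < 2L) skip("single level")
        }
        if (!row$skipped) {
            scr <- collinearityFilter(records, candidates, outcome = cell,
                                      threshold = threshold)
            fwd <- tryCatch(
                stepwiseAIC(records, cell, baseline, scr$retained,
                            "forward"),
                error = function(e) e)
            if (inherits(fwd, "error")) {
                skip(conditionMessage(fwd))
            } else {
                bwd <- tryCatch(
                    stepwiseAIC(records, cell, baseline, scr$retained,
                                "backward"),
                    error = function(e) NULL)
                cf <- fwd$fit@coefficients
                cf$sig <- ifelse(cf$p < 0.001, "**",
                                 ifelse(cf$p < 0.05, "*", ""))
                row$n <- fwd$fit@nUsed
                row$baseline_aic <- fwd$baselineAIC
                row$best_aic <- fwd$finalAIC
                row$selected <- paste(fwd$selected, collapse = ",")
                row$agreement <- !is.null(bwd) &&
                    setequal(fwd$selected, bwd$selected)
                details[[cell]] <- list(screen = scr, forward = fwd,
                                        backward = bwd, coefficients = cf)
            }
        }
        summ[[cell]] <- row
    }
    out <- do.call(rbind, summ)
    rownames(out) <- NULL
    list(summary = out, details = details)
}
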