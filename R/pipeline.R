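#' Default pipeline configuration
#'
#' A single nested list drives an end-to-end run; every threshold the
#' analysis depends on is visible here and recorded in the run manifest.
#'
#' @param seed RNG seed for the run
#' @param stages character vector of stages to execute, in order, among
#'   \code{"simulate"}, \code{"qc"}, \code{"normalize"}, \code{"fit"},
#'   \code{"evaluate"}, \code{"bridge"}
#' @param ... named overrides of the per-stage sub-lists (\code{simulate},
#'   \code{qc}, \code{normalize}, \code{fit}, \code{evaluate}, \code{bridge})
#' @return a config list
#' @export
pipelineConfig <- function(seed = 1L,
                           stages = c("simulate", "qc", "normalize", "fit",
                                      "evaluate", "bridge"), ...) {
    cfg <- list(
        seed = as.integer(seed),
        stages = stages,
        simulate = list(timepoint = "D1"),
        qc = list(ctLimit = 37, hemolysisThreshold = 7, spikeinMaxDev = 2,
                  minDetectionRate = 0.75),
        normalize = list(k = 3L),
        fit = list(ncompGrid = 1:3, keepXGrid = c(3, 5, 7, 10, 15, 20, 30),
                   designWeight = 0.1, similarityCutoff = 0.5),
        evaluate = list(resubstitution = FALSE),
        bridge = list(chains = 2L, keep = 2500L, burnin = 2000L,
                      outcomes = c("injury_score", "perfusion_ratio")))
    ov <- list(...)
    for (nm in names(ov))
        cfg[[nm]] <- utils::modifyList(cfg[[nm]], ov[[nm]])
    cfg
}

#' Read a pipeline configuration from JSON
#' @param path JSON file of overrides; merged over the defaults
#' @return a config list
#' @export
readPipelineConfig <- function(path) {
    ov <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- pipelineConfig(seed = ov$seed %||% 1L)
    known <- names(cfg)
    bad <- setdiff(names(ov), known)
    if (length(bad))
        stop("unknown config key(s): ", paste(bad, collapse = ", "))
    for (nm in intersect(names(ov), known))
        cfg[[nm]] <- if (is.list(cfg[[nm]]))
            utils::modifyList(cfg[[nm]], as.list(ov[[nm]])) else ov[[nm]]
    cfg
}

#' Run the pipeline end-to-end
#'
#' Executes the enabled stages in order — simulate a cohort (or read one),
#' QC, adaptive normalization, signature fitting with LOO tuning and
#' stability selection, cross-validated ROC evaluation, and the Bayesian
#' bridge against a day-14 outcome cohort — writing all tabular artifacts
#' and a reproducible run manifest (config snapshot, seed, stage timings,
#' file digests) to \code{outDir}. Input files are never mutated; identical
#' config + seed reproduce identical digests for deterministic stages.
#'
#' @param config list from \code{\link{pipelineConfig}} /
#'   \code{\link{readPipelineConfig}}
#' @param outDir output directory (created)
#' @param ctPath,clinicalPath,metaPath optional input files consumed instead
#'   of the simulate stage (Ct table, clinical table, sample metadata)
#' @param d14Path optional day-14 outcomes CSV (sample, dose, injury score,
#'   perfusion ratio); when absent and the bridge stage is enabled, a
#'   synthetic day-14 cohort is generated
#' @return the run manifest, invisibly; artifacts on disk
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = "radiomir_run",
                        ctPath = NULL, clinicalPath = NULL, metaPath = NULL,
                        d14Path = NULL) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(config = config, seed = config$seed,
                     timings = list(), warnings = character())
    files <- character()
    note <- function(f) files <<- union(files, f)
    timed <- function(stage, expr) {
        t0 <- proc.time()[["elapsed"]]
        v <- withCallingHandlers(expr, warning = function(w) {
            manifest$warnings <<- c(manifest$warnings,
                                    paste0(stage, ": ", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
        manifest$timings[[stage]] <<- round(
            proc.time()[["elapsed"]] - t0, 3)
        v
    }
    stages <- config$stages
    ct <- clinical <- truth <- NULL

    if ("simulate" %in% stages) {
        sim <- timed("simulate", {
            p <- simulationParams(seed = config$seed)
            simulateCohort(p, timepoint = config$simulate$timepoint)
        })
        ct <- sim$ct; clinical <- sim$clinical; truth <- sim$truth
        f <- file.path(outDir, c("ct.csv", "sample_meta.csv",
                                 "clinical.csv", "ground_truth.json"))
        writeCtTable(ct, f[1], metaPath = f[2])
        utils::write.csv(clinical, f[3], row.names = FALSE)
        writeGroundTruth(truth, f[4])
        note(f)
    } else if (!is.null(ctPath)) {
        ct <- readCtTable(ctPath, sampleData = metaPath)
        if (!is.null(clinicalPath)) clinical <- readClinicalTable(clinicalPath)
    }

    qcRes <- NULL
    if ("qc" %in% stages) {
        if (is.null(ct)) stop("qc stage needs a Ct table ",
                              "(simulate stage or ctPath)")
        qcRes <- timed("qc", do.call(applyQC, c(list(ct), config$qc)))
        ct <- qcRes$ct
        note(writeQCReport(qcRes$report, file.path(outDir, "qc")))
    }

    ne <- NULL
    if ("normalize" %in% stages) {
        if (is.null(ct)) stop("normalize stage needs a QC'd Ct table")
        ne <- timed("normalize", {
            ns <- findNormalizerSet(ct, k = config$normalize$k)
            toNegDeltaCt(ct, ns)
        })
        f <- file.path(outDir, c("normalized.csv", "normalizer_audit.json"))
        utils::write.csv(data.frame(assay = rownames(negDeltaCt(ne)),
                                    negDeltaCt(ne), check.names = FALSE),
                         f[1], row.names = FALSE)
        jsonlite::write_json(list(
            normalizer_set = normalizerSet(ne),
            dispersion = metadata(ne)$dispersion,
            candidates = metadata(ne)$dendrogram_audit,
            dropped_samples = metadata(ne)$dropped_samples),
            f[2], auto_unbox = TRUE, digits = NA, dataframe = "rows")
        note(f)
    }

    model <- bdRaw <- NULL
    if ("fit" %in% stages) {
        if (is.null(ne)) stop("fit stage needs normalized expression")
        bdRaw <- assembleBlocks(ne, clinical, config$fit$designWeight)
        model <- timed("fit",
            fitSignatureModel(bdRaw, expression = ne,
                              ncompGrid = config$fit$ncompGrid,
                              keepXGrid = config$fit$keepXGrid))
        f <- file.path(outDir, c("signature.csv", "tuning_trace.csv",
                                 "scores_miR.csv", "loadings_miR.csv",
                                 "similarity.csv"))
        writeSignatureReport(model, f[1])
        utils::write.csv(tuningTrace(model), f[2], row.names = FALSE)
        utils::write.csv(data.frame(sample_id = rownames(model@blocks[[1]]),
                                    blockScores(model)), f[3],
                         row.names = FALSE)
        utils::write.csv(data.frame(feature = rownames(blockLoadings(model)),
                                    blockLoadings(model)), f[4],
                         row.names = FALSE)
        if (length(model@blocks) >= 2) {
            sim <- crossBlockSimilarity(model,
                                        cutoff = config$fit$similarityCutoff)
            utils::write.csv(sim$pairs, f[5], row.names = FALSE)
        }
        note(f[file.exists(f)])
    }

    rocRes <- NULL
    if ("evaluate" %in% stages && !is.null(model)) {
        rocRes <- timed("evaluate", {
            kx <- model@keepX
            sparseBlock <- if ("miR" %in% names(kx)) "miR" else names(kx)[1]
            if (isTRUE(config$evaluate$resubstitution)) {
                oneVsRestRoc(.resubScores(model), model@outcome)
            } else {
                loo <- looGroupScores(bdRaw, model@ncomp,
                                      kx[[sparseBlock]][1],
                                      sparseBlock = sparseBlock)
                oneVsRestRoc(loo$scores, outcomeGroups(bdRaw))
            }
        })
        f <- file.path(outDir, "roc.csv")
        utils::write.csv(rocRes, f, row.names = FALSE)
        note(f)
    }

    if ("bridge" %in% stages && !is.null(model)) {
        bres <- timed("bridge", {
            d14 <- if (!is.null(d14Path)) readClinicalTable(d14Path)
                   else simulateD14Cohort(
                       simulationParams(seed = config$seed))$clinical
            lapply(seq_len(model@ncomp), function(h) {
                prior <- summarizeCoordinates(model, component = h)
                stats::setNames(lapply(config$bridge$outcomes, function(oc)
                    fitBridge(prior, d14, outcome = oc,
                              mcmc = config$bridge,
                              seed = config$seed + 17L * h)),
                    config$bridge$outcomes)
            })
        })
        f <- file.path(outDir, "bridge.json")
        jsonlite::write_json(lapply(bres, function(perComp)
            lapply(perComp, function(b) list(
                summary = posteriorSummary(b), tail_probability = b@tailProb,
                converged = b@converged))),
            f, auto_unbox = TRUE, digits = NA, dataframe = "rows")
        note(f)
    }

    manifest$files <- lapply(stats::setNames(files, basename(files)),
                             function(f) unname(tools::md5sum(f)))
    mf <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    invisible(manifest)
}

#' Assemble miR + clinical blocks from pipeline objects
#'
#' Convenience constructor: transposes the normalized expression into a
#' samples x assays miR block, drops excluded samples, aligns the numeric
#' clinical fields on sample id, and builds the \linkS4class{BlockDataset}
#' with the dose group as outcome.
#'
#' @param ne a \linkS4class{NormalizedExpression}
#' @param clinical optional clinical data.frame with a \code{sample_id}
#'   column; numeric fields (except \code{dose_gy}) become the clinical
#'   block
#' @param designWeight inter-block design weight (default 0.1)
#' @return a raw \linkS4class{BlockDataset}
#' @export
assembleBlocks <- function(ne, clinical = NULL, designWeight = 0.1) {
    miR <- t(negDeltaCt(ne))
    keep <- !colData(ne)$excluded
    miR <- miR[keep, , drop = FALSE]
    outcome <- colData(ne)$dose_gy[keep]
    blocks <- list(miR = miR)
    if (!is.null(clinical)) {
        m <- match(rownames(miR), clinical$sample_id)
        num <- vapply(clinical, is.numeric, logical(1))
        cl <- as.matrix(clinical[m, num & names(clinical) != "dose_gy",
                                 drop = FALSE])
        rownames(cl) <- rownames(miR)
        blocks$clinical <- cl
    }
    B <- length(blocks)
    design <- matrix(designWeight, B, B,
                     dimnames = list(names(blocks), names(blocks)))
    diag(design) <- 0
    blockDataset(blocks, outcome, design = design)
}

# training (resubstitution) per-group scores from a fitted model
.resubScores <- function(model) {
    Tavg <- Reduce(`+`, model@scores) / length(model@scores)
    lev <- rownames(model@centroids)
    d <- vapply(lev, function(g)
        sqrt(rowSums(sweep(Tavg, 2L, model@centroids[g, ])^2)), numeric(nrow(Tavg)))
    -d
}
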