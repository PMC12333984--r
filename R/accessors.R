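#' Extract the raw Ct matrix
#' @param x a \linkS4class{CtExperiment}
#' @return numeric matrix, assays x samples
#' @export
ctValues <- function(x) {
    stopifnot(is(x, "CtExperiment"))
    assay(x, "ct")
}

#' Control-assay mapping of a CtExperiment
#' @param x a \linkS4class{CtExperiment}
#' @return named list of control roles -> assay names
#' @export
controlAssays <- function(x) metadata(x)$controls

#' Extract the (-)delta-Ct matrix
#' @param x a \linkS4class{NormalizedExpression}
#' @return numeric matrix, assays x samples, log2-expression scale
#' @export
negDeltaCt <- function(x) {
    stopifnot(is(x, "NormalizedExpression"))
    assay(x, "negDeltaCt")
}

#' Selected normalizer assays
#' @param x a \linkS4class{NormalizedExpression}
#' @return character vector of assay names
#' @export
normalizerSet <- function(x) metadata(x)$normalizer_set

#' Per-sample section of a QC report
#' @param x a \linkS4class{QCReport}
#' @return data.frame
#' @export
sampleQC <- function(x) x@sampleQC

#' Per-assay section of a QC report
#' @param x a \linkS4class{QCReport}
#' @return data.frame
#' @export
assayQC <- function(x) x@assayQC

#' Block matrices of a BlockDataset
#' @param x a \linkS4class{BlockDataset}
#' @return named list of samples x features matrices
#' @export
dataBlocks <- function(x) x@blocks

#' Outcome factor of a BlockDataset or SplsdaModel
#' @param x a \linkS4class{BlockDataset} or \linkS4class{SplsdaModel}
#' @return factor of group labels
#' @export
outcomeGroups <- function(x) x@outcome

#' Per-block component scores of a fitted model
#' @param x a \linkS4class{SplsdaModel}
#' @param block block name; default the first block
#' @return n x ncomp score matrix
#' @export
blockScores <- function(x, block = names(x@scores)[1]) x@scores[[block]]

#' Per-block sparse loadings of a fitted model
#' @param x a \linkS4class{SplsdaModel}
#' @param block block name; default the first block
#' @return p x ncomp loading matrix (unit L2 norm columns)
#' @export
blockLoadings <- function(x, block = names(x@loadings)[1]) x@loadings[[block]]

#' Selected-signature table of a fitted model
#' @param x a \linkS4class{SplsdaModel}
#' @return data.frame with columns component, miRNA, stability, loading and,
#'   when computed, the dose group of maximal median expression
#' @export
signatureTable <- function(x) x@signature

#' Leave-one-out tuning trace
#' @param x a \linkS4class{SplsdaModel}
#' @return data.frame: one row per (ncomp, keepX) grid point with its
#'   balanced error rate
#' @export
tuningTrace <- function(x) x@tuningTrace

#' Per-feature stability scores
#' @param x a \linkS4class{SplsdaModel}
#' @return data.frame (block, component, feature, stability)
#' @export
featureStability <- function(x) x@stability

#' Posterior draws of a bridge fit
#' @param x a \linkS4class{BridgeResult}
#' @return matrix of draws (alpha, beta, sigma_y, r)
#' @export
posteriorDraws <- function(x) x@draws

#' Posterior summary of a bridge fit
#' @param x a \linkS4class{BridgeResult}
#' @return data.frame of posterior mean, median and 95% credible interval
#' @export
posteriorSummary <- function(x) x@summary

#' @describeIn ctExperiment show method
#' @param object a CtExperiment
#' @export
setMethod("show", "CtExperiment", function(object) {
    cat(sprintf("CtExperiment: %d assays x %d samples\n",
                nrow(object), ncol(object)))
    ct <- assay(object, "ct")
    cat(sprintf("  missing Ct: %d (%.1f%%)\n", sum(is.na(ct)),
                100 * mean(is.na(ct))))
    ctr <- metadata(object)$controls
    if (length(ctr))
        cat("  controls:", paste(names(ctr), unlist(ctr), sep = "=",
                                 collapse = ", "), "\n")
    tb <- table(colData(object)$dose_gy)
    cat("  dose groups:", paste(names(tb), tb, sep = " Gy: n=",
                                collapse = ", "), "\n")
})

setMethod("show", "QCReport", function(object) {
    cat("QCReport\n")
    cat(sprintf("  Ct > %g discarded: %d\n", object@ctLimit,
                object@nDiscardedHighCt))
    sq <- object@sampleQC
    if (nrow(sq))
        cat(sprintf("  samples: %d flagged hemolysis, %d flagged spike-in, %d excluded\n",
                    sum(sq$hemolysis_flag, na.rm = TRUE),
                    sum(sq$spikein_flag, na.rm = TRUE),
                    sum(sq$excluded, na.rm = TRUE)))
    aq <- object@assayQC
    if (nrow(aq))
        cat(sprintf("  assays: %d/%d retained\n", sum(aq$retained), nrow(aq)))
})

setMethod("show", "BlockDataset", function(object) {
    cat("BlockDataset:",
        paste(sprintf("%s[%d x %d]", names(object@blocks),
                      vapply(object@blocks, nrow, 1L),
                      vapply(object@blocks, ncol, 1L)), collapse = ", "), "\n")
    tb <- table(object@outcome)
    cat("  outcome:", paste(names(tb), tb, sep = ": n=", collapse = ", "), "\n")
    cat("  preprocessed:", object@preprocessed, "\n")
})

setMethod("show", "SplsdaModel", function(object) {
    cat(sprintf("SplsdaModel: %d component(s), blocks %s\n", object@ncomp,
                paste(names(object@loadings), collapse = ", ")))
    for (b in names(object@keepX))
        cat(sprintf("  keepX[%s]: %s\n", b,
                    paste(object@keepX[[b]], collapse = ", ")))
    if (nrow(object@signature))
        cat(sprintf("  signature: %d selected feature(s)\n",
                    nrow(object@signature)))
    if (!all(object@converged))
        cat("  warning: some components did not converge\n")
})

setMethod("show", "BridgeResult", function(object) {
    cat("BridgeResult\n")
    s <- object@summary
    r <- s[s$parameter == "r", ]
    cat(sprintf("  posterior r: mean %.3f, 95%% CrI [%.3f, %.3f]\n",
                r$mean, r$lower95, r$upper95))
    cat(sprintf("  two-sided tail probability: %.4f\n", object@tailProb))
    cat(sprintf("  converged (all split-Rhat <= 1.05): %s\n",
                object@converged))
})
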