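#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' Container for raw RT-qPCR Ct panels
#'
#' A \code{CtExperiment} holds a raw cycle-threshold (Ct) matrix with assays
#' (miRNAs) in rows and samples in columns, sample metadata (cohort,
#' timepoint, dose group, exclusion flags) as \code{colData}, and the mapping
#' of control assays (endogenous reference, hemolysis indicator, exogenous
#' spike-in) in \code{metadata(x)$controls}. Missing Ct values (undetected
#' reactions) are \code{NA}.
#'
#' @slot ... inherits all slots from \linkS4class{SummarizedExperiment};
#'   the single assay is named \code{"ct"}.
#' @seealso \code{\link{ctExperiment}}, \code{\link{readCtTable}}
#' @export
setClass("CtExperiment", contains = "SummarizedExperiment")

setValidity("CtExperiment", function(object) {
    msg <- NULL
    if (!"ct" %in% assayNames(object))
        msg <- c(msg, "assay 'ct' is required")
    else {
        ct <- assay(object, "ct")
        if (any(ct[!is.na(ct)] <= 0))
            msg <- c(msg, "all non-missing Ct values must be > 0")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "assay (row) names must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample (column) names must be unique")
    req <- c("cohort", "timepoint", "dose_gy", "excluded")
    miss <- setdiff(req, colnames(colData(object)))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
    else {
        dg <- colData(object)$dose_gy
        if (!all(is.na(dg) | dg %in% c(0, 20, 40, 80)))
            msg <- c(msg, "dose_gy must be one of 0, 20, 40, 80")
    }
    ctr <- metadata(object)$controls
    if (!is.null(ctr) && !is.list(ctr))
        msg <- c(msg, "metadata 'controls' must be a named list")
    if (is.null(msg)) TRUE else msg
})

#' Construct a CtExperiment
#'
#' @param ct numeric matrix of Ct values, assays in rows, samples in columns;
#'   \code{NA} marks undetected reactions. Dimnames are required.
#' @param sampleData data.frame (or DataFrame) with one row per sample and at
#'   least columns \code{cohort} (\code{"broad"} or \code{"targeted"}),
#'   \code{timepoint} (\code{"D1"}, \code{"D7"} or \code{"D14"}) and
#'   \code{dose_gy} (0, 20, 40 or 80). Columns \code{excluded} /
#'   \code{exclusion_reason} are added when absent.
#' @param controls named list mapping control roles to assay names; defaults
#'   to the conventional plasma-panel controls: reference miR-23a-3p,
#'   hemolysis indicator miR-451a, spike-in cel-miR-39.
#' @return a \linkS4class{CtExperiment}
#' @examples
#' ct <- matrix(c(25, 30, 26, 31), 2,
#'              dimnames = list(c("miR-a", "miR-b"), c("s1", "s2")))
#' meta <- data.frame(cohort = "targeted", timepoint = "D1",
#'                    dose_gy = c(0, 80))
#' ctExperiment(ct, meta, controls = list())
#' @export
ctExperiment <- function(ct, sampleData,
                         controls = list(reference = "miR-23a-3p",
                                         hemolysis = "miR-451a",
                                         spikein   = "cel-miR-39")) {
    if (is.null(rownames(ct)) || is.null(colnames(ct)))
        stop("'ct' must have assay row names and sample column names")
    sampleData <- as.data.frame(sampleData)
    if (nrow(sampleData) != ncol(ct))
        stop("one sampleData row per sample required")
    if (is.null(sampleData$excluded)) sampleData$excluded <- FALSE
    if (is.null(sampleData$exclusion_reason))
        sampleData$exclusion_reason <- NA_character_
    se <- SummarizedExperiment(assays = list(ct = ct),
                               colData = DataFrame(sampleData,
                                                   row.names = colnames(ct)))
    obj <- new("CtExperiment", se)
    present <- vapply(controls, function(a) a %in% rownames(ct), logical(1))
    metadata(obj)$controls <- controls
    metadata(obj)$controls_absent <- names(controls)[!present]
    obj
}

#' Normalized (-)delta-Ct expression values
#'
#' Holds the (-)delta-Ct matrix (log2-expression scale: higher value, higher
#' abundance) produced by adaptive normalization, together with the selected
#' normalizer assay set, its dispersion, and the full candidate-cluster audit
#' trail in \code{metadata(x)}.
#'
#' @seealso \code{\link{findNormalizerSet}}, \code{\link{toNegDeltaCt}}
#' @export
setClass("NormalizedExpression", contains = "SummarizedExperiment")

setValidity("NormalizedExpression", function(object) {
    msg <- NULL
    if (!"negDeltaCt" %in% assayNames(object))
        msg <- c(msg, "assay 'negDeltaCt' is required")
    ns <- metadata(object)$normalizer_set
    if (is.null(ns) || !length(ns))
        msg <- c(msg, "metadata 'normalizer_set' is required")
    else if (!all(ns %in% rownames(object)))
        msg <- c(msg, "normalizer assays must appear among the rows")
    else {
        m <- assay(object, "negDeltaCt")[ns, , drop = FALSE]
        cm <- colMeans(m)
        if (any(is.na(cm)) || max(abs(cm)) > 1e-8)
            msg <- c(msg,
                "per-sample mean of (-)delta-Ct over the normalizer set must be 0")
    }
    if (is.null(msg)) TRUE else msg
})

#' Quality-control report
#'
#' Per-sample hemolysis/spike-in deltas and flags, per-assay detection rates
#' and retention, and the count of Ct values discarded by the detection-limit
#' rule.
#'
#' @slot sampleQC data.frame: per-sample hemolysis_delta, hemolysis_flag,
#'   spikein_deviation, spikein_flag, excluded, reason
#' @slot assayQC data.frame: per-assay detection_rate, retained, is_control
#' @slot nDiscardedHighCt integer, Ct entries set missing by the limit rule
#' @slot ctLimit numeric, the limit used
#' @export
setClass("QCReport",
    representation(sampleQC = "data.frame", assayQC = "data.frame",
                   nDiscardedHighCt = "integer", ctLimit = "numeric"))

setValidity("QCReport", function(object) {
    msg <- NULL
    aq <- object@assayQC
    if (nrow(aq) && ("detection_rate" %in% names(aq))) {
        dr <- aq$detection_rate
        if (any(dr < 0 | dr > 1, na.rm = TRUE))
            msg <- c(msg, "detection_rate must lie in [0, 1]")
    }
    sq <- object@sampleQC
    if (nrow(sq) && all(c("excluded", "hemolysis_flag", "spikein_flag")
                        %in% names(sq))) {
        bad <- sq$excluded &
            !(sq$hemolysis_flag %in% c(TRUE, NA) |
              sq$spikein_flag %in% c(TRUE, NA))
        if (any(bad, na.rm = TRUE))
            msg <- c(msg, "excluded samples must carry at least one QC flag")
    }
    if (is.null(msg)) TRUE else msg
})

#' Aligned multi-block dataset for supervised integration
#'
#' Named blocks (samples x features matrices sharing row order), a categorical
#' outcome (dose group), and the inter-block design matrix. Preprocessing
#' state (per-column centers/scales) is carried so new samples can be
#' projected with training statistics.
#'
#' @slot blocks named list of numeric matrices (samples x features)
#' @slot outcome factor of group labels, one per sample
#' @slot design numeric matrix (blocks x blocks) of connection weights in
#'   [0, 1]; the outcome block is connected to every block with weight 1
#' @slot preprocessed logical
#' @slot centers,scales named lists of per-column statistics (after
#'   preprocessing)
#' @slot log character vector of preprocessing messages (dropped columns,
#'   imputations)
#' @export
setClass("BlockDataset",
    representation(blocks = "list", outcome = "factor", design = "matrix",
                   preprocessed = "logical", centers = "list",
                   scales = "list", log = "character"))

setValidity("BlockDataset", function(object) {
    msg <- NULL
    b <- object@blocks
    if (!length(b) || is.null(names(b)) || any(names(b) == ""))
        msg <- c(msg, "blocks must be a non-empty named list")
    n <- unique(vapply(b, nrow, integer(1)))
    if (length(n) > 1)
        msg <- c(msg, "all blocks must have the same number of samples")
    else if (length(object@outcome) != n)
        msg <- c(msg, "outcome length must equal the number of samples")
    tb <- table(droplevels(object@outcome))
    if (length(tb) < 2 || any(tb < 2))
        msg <- c(msg, "outcome needs >= 2 levels with >= 2 samples each")
    d <- object@design
    if (!all(dim(d) == length(b)))
        msg <- c(msg, "design must be blocks x blocks")
    else if (any(d < 0 | d > 1))
        msg <- c(msg, "design weights must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Fitted sparse multiblock PLS-DA model
#'
#' Per-block sparse loadings (unit L2 norm) and scores per component,
#' outcome-block loadings, the tuning trace, per-feature stability scores and
#' the selected signature table.
#'
#' @slot blocks preprocessed (undeflated) training blocks, for similarity and
#'   prediction diagnostics
#' @slot loadings named list, per block a p x ncomp matrix of sparse loadings
#' @slot scores named list, per block an n x ncomp score matrix
#' @slot projLoadings named list of p x ncomp regression (deflation) loadings
#' @slot outcomeLoadings G x ncomp loadings of the outcome indicator block
#' @slot outcomeScores n x ncomp outcome-block scores
#' @slot keepX named list, per block an integer vector (length ncomp)
#' @slot ncomp integer, number of components
#' @slot outcome training outcome factor
#' @slot centroids per-class centroid matrix (G x ncomp) of averaged scores
#' @slot centers,scales training preprocessing statistics per block
#' @slot design inter-block design matrix
#' @slot converged logical per component
#' @slot tuningTrace data.frame of the leave-one-out tuning grid (may be
#'   empty when the model was fitted at fixed parameters)
#' @slot stability data.frame (block, component, feature, stability); empty
#'   until \code{\link{stabilityScores}} is run
#' @slot signature data.frame (component, miRNA, stability, loading, ...)
#' @export
setClass("SplsdaModel",
    representation(blocks = "list", loadings = "list", scores = "list",
                   projLoadings = "list", outcomeLoadings = "matrix",
                   outcomeScores = "matrix", keepX = "list",
                   ncomp = "integer", outcome = "factor",
                   centroids = "matrix", centers = "list", scales = "list",
                   design = "matrix", converged = "logical",
                   tuningTrace = "data.frame", stability = "data.frame",
                   signature = "data.frame"))

setValidity("SplsdaModel", function(object) {
    msg <- NULL
    for (b in names(object@loadings)) {
        A <- object@loadings[[b]]
        nrm <- sqrt(colSums(A^2))
        if (any(abs(nrm - 1) > 1e-6))
            msg <- c(msg, sprintf("loadings of block '%s' must be unit-norm", b))
    }
    if (nrow(object@stability) &&
        any(object@stability$stability < 0 | object@stability$stability > 1))
        msg <- c(msg, "stability scores must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Posterior summary of the latent-variable bridge correlation
#'
#' Posterior draws and summaries for the slope, residual SD, and the implied
#' correlation r between a signature component (measured on one cohort) and a
#' clinical outcome (measured on another), linked only through dose groups.
#'
#' @slot draws matrix of retained posterior draws (columns alpha, beta,
#'   sigma_y, r), chains stacked
#' @slot chains integer, number of chains
#' @slot summary data.frame of per-parameter mean, median and 95% credible
#'   interval
#' @slot rhat,ess named numerics of split-Rhat and effective sample size
#' @slot tailProb two-sided posterior tail probability of r
#' @slot converged logical, TRUE when all split-Rhat <= 1.05
#' @slot settings list of MCMC settings and seed
#' @export
setClass("BridgeResult",
    representation(draws = "matrix", chains = "integer",
                   summary = "data.frame", rhat = "numeric", ess = "numeric",
                   tailProb = "numeric", converged = "logical",
                   settings = "list"))

setValidity("BridgeResult", function(object) {
    msg <- NULL
    if ("r" %in% colnames(object@draws)) {
        r <- object@draws[, "r"]
        if (any(abs(r) > 1 + 1e-12))
            msg <- c(msg, "every posterior draw of r must lie in [-1, 1]")
    }
    if (is.null(msg)) TRUE else msg
})
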