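#' Discard Ct values above the detection limit
#'
#' Reactions with Ct strictly above \code{limit} (default 37) are
#' uninformative at the 40-cycle ceiling and are set missing. The count of
#' discarded entries accumulates in \code{metadata(x)$qc_log}.
#'
#' @param x a \linkS4class{CtExperiment}
#' @param limit Ct cutoff (strict inequality; default 37)
#' @return the filtered \linkS4class{CtExperiment}
#' @export
discardHighCt <- function(x, limit = 37) {
    stopifnot(is(x, "CtExperiment"), limit > 0)
    ct <- ctValues(x)
    hi <- !is.na(ct) & ct > limit
    ct[hi] <- NA
    assay(x, "ct") <- ct
    lg <- metadata(x)$qc_log
    if (is.null(lg)) lg <- list(n_discarded_high_ct = 0L, ct_limit = limit)
    lg$n_discarded_high_ct <- lg$n_discarded_high_ct + sum(hi)
    lg$ct_limit <- limit
    metadata(x)$qc_log <- lg
    x
}

#' Per-sample hemolysis score
#'
#' The hemolysis delta is Ct(reference) - Ct(hemolysis indicator), i.e.
#' Ct(miR-23a-3p) - Ct(miR-451a) under the default control mapping. Red-cell
#' contamination boosts miR-451a (lowers its Ct) and drives the delta up; a
#' sample is flagged when the delta exceeds \code{threshold}.
#'
#' @param x a \linkS4class{CtExperiment} with both controls present
#' @param threshold flag cutoff in cycles (default 7)
#' @return data.frame: sample_id, hemolysis_delta, hemolysis_flag (logical,
#'   \code{NA} = indeterminate when either control Ct is missing)
#' @export
hemolysisScore <- function(x, threshold = 7) {
    ctr <- controlAssays(x)
    ct <- ctValues(x)
    if (is.null(ctr$reference) || !ctr$reference %in% rownames(ct) ||
        is.null(ctr$hemolysis) || !ctr$hemolysis %in% rownames(ct))
        stop("both the reference and hemolysis control assays are required")
    delta <- ct[ctr$reference, ] - ct[ctr$hemolysis, ]
    data.frame(sample_id = colnames(ct), hemolysis_delta = unname(delta),
               hemolysis_flag = unname(delta > threshold))
}

#' Spike-in extraction-efficiency check
#'
#' Flags samples whose exogenous spike-in Ct deviates from the cohort median
#' by more than \code{maxDev} cycles. Being median-relative, the check is
#' invariant to a uniform shift of all samples.
#'
#' @param x a \linkS4class{CtExperiment}
#' @param maxDev maximal tolerated absolute deviation in cycles (default 2)
#' @return data.frame: sample_id, spikein_deviation, spikein_flag (all
#'   \code{NA}/indeterminate when the spike-in assay is absent)
#' @export
spikeinCheck <- function(x, maxDev = 2) {
    ctr <- controlAssays(x)
    ct <- ctValues(x)
    out <- data.frame(sample_id = colnames(ct),
                      spikein_deviation = NA_real_, spikein_flag = NA)
    if (is.null(ctr$spikein) || !ctr$spikein %in% rownames(ct))
        return(out)
    s <- ct[ctr$spikein, ]
    dev <- s - stats::median(s, na.rm = TRUE)
    out$spikein_deviation <- unname(dev)
    out$spikein_flag <- unname(abs(dev) > maxDev)
    out
}

#' Filter assays by detection rate
#'
#' Removes assays detected (non-missing Ct) in fewer than \code{minRate} of
#' the non-excluded samples. Control assays are always retained in the matrix
#' (they are never used as features downstream) but their detection rate is
#' reported.
#'
#' @param x a \linkS4class{CtExperiment}
#' @param minRate minimal detection rate in (0, 1] (default 0.75)
#' @return list with elements \code{ct} (filtered
#'   \linkS4class{CtExperiment}) and \code{assayQC} (data.frame: assay,
#'   detection_rate, retained, is_control)
#' @export
assayDetectionFilter <- function(x, minRate = 0.75) {
    stopifnot(is(x, "CtExperiment"))
    if (!(minRate > 0 && minRate <= 1))
        stop("minRate must lie in (0, 1]")
    ct <- ctValues(x)
    keepSamp <- !colData(x)$excluded
    rate <- rowMeans(!is.na(ct[, keepSamp, drop = FALSE]))
    isCtr <- rownames(ct) %in% unlist(controlAssays(x))
    retained <- rate >= minRate | isCtr
    if (!any(retained & !isCtr))
        stop("detection filter removed every feature assay")
    aq <- data.frame(assay = rownames(ct), detection_rate = unname(rate),
                     retained = unname(retained), is_control = unname(isCtr))
    list(ct = x[retained, ], assayQC = aq)
}

#' Run the full sample- and assay-level QC chain
#'
#' Applies, in order: the high-Ct discard rule, hemolysis scoring, the
#' spike-in check, and the assay detection filter. Flags never auto-exclude;
#' with \code{exclude = TRUE} samples flagged for hemolysis OR spike-in
#' deviation are marked excluded in the metadata (with a reason), mirroring
#' explicit, logged exclusion decisions. The chain is idempotent.
#'
#' @param x a \linkS4class{CtExperiment}
#' @param ctLimit detection-limit cutoff (default 37)
#' @param hemolysisThreshold hemolysis-delta cutoff in cycles (default 7)
#' @param spikeinMaxDev spike-in deviation cutoff in cycles (default 2)
#' @param minDetectionRate assay detection-rate cutoff (default 0.75)
#' @param exclude mark flagged samples excluded (default TRUE)
#' @return list with elements \code{ct} (QC'd \linkS4class{CtExperiment})
#'   and \code{report} (a \linkS4class{QCReport})
#' @export
applyQC <- function(x, ctLimit = 37, hemolysisThreshold = 7,
                    spikeinMaxDev = 2, minDetectionRate = 0.75,
                    exclude = TRUE) {
    x <- discardHighCt(x, ctLimit)
    hem <- tryCatch(hemolysisScore(x, hemolysisThreshold),
                    error = function(e) data.frame(
                        sample_id = colnames(x),
                        hemolysis_delta = NA_real_, hemolysis_flag = NA))
    spk <- spikeinCheck(x, spikeinMaxDev)
    sq <- merge(hem, spk, by = "sample_id", sort = FALSE)
    sq <- sq[match(colnames(x), sq$sample_id), ]
    flagged <- (sq$hemolysis_flag %in% TRUE) | (sq$spikein_flag %in% TRUE)
    sq$excluded <- exclude & flagged
    sq$reason <- ifelse(sq$excluded,
        paste0(ifelse(sq$hemolysis_flag %in% TRUE, "hemolysis;", ""),
               ifelse(sq$spikein_flag %in% TRUE, "spikein;", "")), "")
    if (exclude) {
        prev <- colData(x)$excluded
        colData(x)$excluded <- prev | sq$excluded
        colData(x)$exclusion_reason <- ifelse(
            sq$excluded & !prev, sub(";$", "", sq$reason),
            colData(x)$exclusion_reason)
    }
    flt <- assayDetectionFilter(x, minDetectionRate)
    rep <- new("QCReport", sampleQC = sq, assayQC = flt$assayQC,
               nDiscardedHighCt =
                   as.integer(metadata(x)$qc_log$n_discarded_high_ct),
               ctLimit = ctLimit)
    validObject(rep)
    list(ct = flt$ct, report = rep)
}
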