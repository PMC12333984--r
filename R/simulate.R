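#' Simulation parameters for synthetic plasma-miRNA cohorts
#'
#' Defaults emulate the study conditions the pipeline is designed for: four
#' dose groups (0/20/40/80 Gy) of 15 animals, ~300 detected assays, a planted
#' dose-responsive signature, a tight housekeeping cluster, per-sample
#' extraction-efficiency offsets, occasional hemolysis, and Ct truncation at
#' the detection limit.
#'
#' @param nPerGroup samples per dose group (default 15)
#' @param nAssays number of panel assays, controls excluded (default 300)
#' @param nSignature number of planted dose-responsive assays (default 15)
#' @param effectRange magnitude range (cycles at 80 Gy) of planted Ct shifts;
#'   shifts are linear in log2(dose + 1) with random sign (default
#'   c(0.75, 1.5), i.e. moderate, detectable effects with max |shift| 1.5)
#' @param housekeepingSize size of the low-variance housekeeping cluster
#'   (default 3, minimum 3)
#' @param housekeepingSd biological SD of housekeeping assays (default 0.05
#'   cycles)
#' @param sigmaTech technical Ct SD (default 0.25)
#' @param sigmaBio biological per-sample, per-assay SD (default 0.5)
#' @param sampleOffsetSd SD of per-sample extraction-efficiency offsets
#'   (default 0.3 cycles)
#' @param pHemolysis probability a sample is hemolysed (default 0.05)
#' @param detectionLimit Ct above which a reaction is undetected (default 37)
#' @param lymphocyteEffects additive shifts (10^9/L) of the lymphocyte mean
#'   per dose group; the default is significant only at 80 Gy
#' @param perfusionEffect80 additive shift of the D7 perfusion ratio at
#'   80 Gy (default 0.4)
#' @param severitySlope slope of the latent severity in log2(dose + 1),
#'   rescaled so 80 Gy maps to slope x 1 (default 1)
#' @param nPerGroupD14 per-group sizes of the day-14 outcome cohort
#'   (default c(15, 13, 11, 9): attrition grows with dose)
#' @param seed RNG seed
#' @return a list of class \code{SimulationParams}
#' @export
simulationParams <- function(nPerGroup = 15L, nAssays = 300L,
                             nSignature = 15L, effectRange = c(0.75, 1.5),
                             housekeepingSize = 3L, housekeepingSd = 0.05,
                             sigmaTech = 0.25, sigmaBio = 0.5,
                             sampleOffsetSd = 0.3, pHemolysis = 0.05,
                             detectionLimit = 37,
                             lymphocyteEffects = c(0, -0.2, -0.5, -1.8),
                             perfusionEffect80 = 0.4, severitySlope = 1,
                             nPerGroupD14 = c(15L, 13L, 11L, 9L),
                             seed = 1L) {
    p <- list(nPerGroup = as.integer(nPerGroup), nAssays = as.integer(nAssays),
              nSignature = as.integer(nSignature), effectRange = effectRange,
              housekeepingSize = as.integer(housekeepingSize),
              housekeepingSd = housekeepingSd, sigmaTech = sigmaTech,
              sigmaBio = sigmaBio, sampleOffsetSd = sampleOffsetSd,
              pHemolysis = pHemolysis, detectionLimit = detectionLimit,
              lymphocyteEffects = lymphocyteEffects,
              perfusionEffect80 = perfusionEffect80,
              severitySlope = severitySlope,
              nPerGroupD14 = as.integer(nPerGroupD14), seed = as.integer(seed))
    if (p$housekeepingSize < 3L)
        stop("housekeepingSize must be >= 3")
    if (p$nSignature + p$housekeepingSize > p$nAssays)
        stop("nSignature + housekeepingSize must not exceed nAssays")
    if (!all(is.finite(unlist(p[vapply(p, is.numeric, TRUE)]))))
        stop("all parameters must be finite")
    class(p) <- "SimulationParams"
    p
}

.doses <- c(0, 20, 40, 80)
.doseScale <- function(dose) log2(dose + 1) / log2(81)

#' Simulate a synthetic RT-qPCR cohort with planted ground truth
#'
#' Generates Ct values as baseline + per-sample extraction offset +
#' dose effect (planted signature assays only) + biological + technical
#' noise, truncated to missing above the detection limit. Hemolysed samples
#' get the miR-451a control boosted (Ct lowered) by 4 to 8 cycles. The
#' clinical table carries a dose-dependent lymphocyte decrease and, at D7, an
#' elevated perfusion ratio at 80 Gy. Ground truth (planted assays, effect
#' curves, latent severity, hemolysed samples) is returned for recovery
#' testing.
#'
#' @param params a \code{\link{simulationParams}} list
#' @param timepoint \code{"D1"} or \code{"D7"}; D7 adds the injury score
#' @param cohort cohort label recorded in the metadata
#' @return list with elements \code{ct} (a \linkS4class{CtExperiment}),
#'   \code{clinical} (data.frame) and \code{truth} (list)
#' @export
simulateCohort <- function(params = simulationParams(),
                           timepoint = c("D1", "D7"), cohort = "targeted") {
    timepoint <- match.arg(timepoint)
    set.seed(params$seed)
    n <- params$nPerGroup * 4L
    dose <- rep(.doses, each = params$nPerGroup)
    ids <- sprintf("s%03d", seq_len(n))

    assays <- sprintf("miR-sim-%03d", seq_len(params$nAssays))
    hk <- assays[seq_len(params$housekeepingSize)]
    sig <- sample(setdiff(assays, hk), params$nSignature)

    baseline <- stats::runif(params$nAssays, 22, 36)
    names(baseline) <- assays
    baseline[hk] <- 24 + stats::rnorm(length(hk), 0, 0.1)

    magnitude <- stats::runif(params$nSignature, params$effectRange[1],
                              params$effectRange[2])
    sign_i <- sample(c(-1, 1), params$nSignature, replace = TRUE)
    effect <- matrix(0, params$nAssays, 4L,
                     dimnames = list(assays, as.character(.doses)))
    effect[sig, ] <- outer(sign_i * magnitude, .doseScale(.doses))

    offset <- stats::rnorm(n, 0, params$sampleOffsetSd)
    bioSd <- rep(params$sigmaBio, params$nAssays)
    names(bioSd) <- assays
    bioSd[hk] <- params$housekeepingSd

    ct <- baseline +
        matrix(stats::rnorm(params$nAssays * n, 0, bioSd),
               params$nAssays, n) +
        matrix(stats::rnorm(params$nAssays * n, 0, params$sigmaTech),
               params$nAssays, n)
    ct <- ct + effect[, as.character(dose)]
    ct <- sweep(ct, 2L, offset, `+`)
    dimnames(ct) <- list(assays, ids)

    # control assays: endogenous reference, hemolysis indicator, spike-in
    hemolysed <- ids[stats::runif(n) < params$pHemolysis]
    boost <- stats::runif(length(hemolysed), 4, 8)
    ct23 <- 24 + offset + stats::rnorm(n, 0, params$sigmaTech)
    ct451 <- 21 + offset + stats::rnorm(n, 0, params$sigmaTech)
    ct451[match(hemolysed, ids)] <- ct451[match(hemolysed, ids)] - boost
    ct39 <- 19 + offset + stats::rnorm(n, 0, 0.1)
    ct <- rbind(ct, `miR-23a-3p` = ct23, `miR-451a` = ct451,
                `cel-miR-39` = ct39)

    ct[ct > params$detectionLimit] <- NA

    severity <- params$severitySlope * .doseScale(dose) +
        stats::rnorm(n, 0, 0.25)

    lym <- pmax(0.1, 4.2 + params$lymphocyteEffects[match(dose, .doses)] +
                          stats::rnorm(n, 0, 0.7))
    neu <- pmax(0.1, stats::rnorm(n, 1.5, 0.4))
    mono <- pmax(0.02, stats::rnorm(n, 0.2, 0.06))
    clin <- data.frame(
        sample_id = ids, dose_gy = dose,
        lymphocytes = lym, neutrophils = neu, monocytes = mono,
        wbc = lym + neu + mono,
        rbc = stats::rnorm(n, 9, 0.6),
        hemoglobin = stats::rnorm(n, 14, 1),
        hematocrit = stats::rnorm(n, 45, 3),
        platelets = stats::rnorm(n, 1000, 150),
        crp = pmax(0.5, stats::rnorm(n, 10, 3)),
        tewl_diff = stats::rnorm(n, 0, 1.5),
        perfusion_ratio = pmax(0.2, stats::rnorm(n, 1, 0.15) +
            if (timepoint == "D7")
                ifelse(dose == 80, params$perfusionEffect80, 0) else 0))
    # at D7 only a handful of high-dose animals show mild erythema
    if (timepoint == "D7")
        clin$injury_score <- ifelse(dose >= 40 & severity > 1.2, 1L, 0L)

    meta <- data.frame(sample_id = ids, cohort = cohort,
                       timepoint = timepoint, dose_gy = dose)
    ctx <- ctExperiment(ct, meta)
    truth <- list(signature_assays = sort(sig),
                  housekeeping_assays = hk,
                  effect_curves = effect[sig, , drop = FALSE],
                  severity = stats::setNames(severity, ids),
                  hemolysed_samples = hemolysed,
                  hemolysis_boost = stats::setNames(boost, hemolysed),
                  sample_offsets = stats::setNames(offset, ids),
                  baseline = baseline)
    list(ct = ctx, clinical = clin, truth = truth)
}

#' Simulate a day-14 outcome cohort
#'
#' Day-14 injury scores and perfusion ratios driven by a latent severity
#' variable that is a noisy monotone function of dose. Used as the
#' independent outcome cohort for the Bayesian bridge.
#'
#' @param params a \code{\link{simulationParams}} list
#' @param severityLink optional function dose -> latent severity mean; the
#'   default is \code{3 * severitySlope * log2(dose + 1) / log2(81)}. A
#'   non-monotone link triggers a warning only.
#' @return list with elements \code{clinical} (data.frame: sample_id,
#'   dose_gy, injury_score, perfusion_ratio) and \code{truth}
#' @export
simulateD14Cohort <- function(params = simulationParams(),
                              severityLink = NULL) {
    set.seed(params$seed + 1000003L)
    if (is.null(severityLink))
        severityLink <- function(dose)
            3 * params$severitySlope * .doseScale(dose)
    mu <- severityLink(.doses)
    if (is.unsorted(mu, strictly = FALSE))
        warning("severityLink is not monotone non-decreasing in dose")
    ng <- rep(params$nPerGroupD14, length.out = 4L)
    dose <- rep(.doses, times = ng)
    n <- length(dose)
    ids <- sprintf("d14_%03d", seq_len(n))
    severity <- severityLink(dose) + stats::rnorm(n, 0, 0.5)
    injury <- pmin(4L, pmax(0L, as.integer(round(
        severity + stats::rnorm(n, 0, 0.3)))))
    perf <- pmax(0.2, 1 + 0.25 * severity + stats::rnorm(n, 0, 0.15))
    clin <- data.frame(sample_id = ids, dose_gy = dose,
                       injury_score = injury, perfusion_ratio = perf)
    truth <- list(severity = stats::setNames(severity, ids),
                  severity_means = stats::setNames(mu, .doses))
    list(clinical = clin, truth = truth)
}

#' Export ground truth as JSON
#' @param truth the \code{truth} element of a simulated cohort
#' @param path output JSON path
#' @return \code{path}, invisibly
#' @export
writeGroundTruth <- function(truth, path) {
    tr <- truth
    if (!is.null(tr$effect_curves))
        tr$effect_curves <- as.data.frame(tr$effect_curves)
    jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    invisible(path)
}
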