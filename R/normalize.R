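#' Select a data-driven normalizer set by Ward clustering
#'
#' Assays that are complete (no missing Ct) across all retained samples are
#' clustered on their per-sample Ct coordinates with Euclidean distance and
#' Ward's minimum-variance linkage. Walking the merge tree bottom-up, every
#' first-formed cluster of size >= k (a merge whose children are both smaller
#' than k) is a candidate; within each candidate the k-subset minimizing the
#' sum of member-to-centroid Euclidean distances is evaluated, and the
#' overall minimum-dispersion subset is selected as the normalizer set.
#' Dispersion ties break on lexicographic assay-name order. Control assays
#' are never candidates.
#'
#' @param x a \linkS4class{CtExperiment}
#' @param k number of normalizer assays (default 3)
#' @return list with elements \code{normalizers} (character, sorted),
#'   \code{dispersion} (sum of member distances to the subset centroid) and
#'   \code{audit} (data.frame of every candidate subset and its dispersion,
#'   selection flagged)
#' @export
findNormalizerSet <- function(x, k = 3L) {
    stopifnot(is(x, "CtExperiment"), k >= 2)
    ct <- ctValues(x)[, !colData(x)$excluded, drop = FALSE]
    ctr <- unlist(controlAssays(x))
    cand <- rownames(ct)[rowSums(is.na(ct)) == 0 & !rownames(ct) %in% ctr]
    if (length(cand) < k)
        stop("fewer than ", k, " assays with complete Ct across retained ",
             "samples; relax the detection filter or impute upstream")
    X <- ct[cand, , drop = FALSE]
    hc <- stats::hclust(stats::dist(X), method = "ward.D2")
    members <- .mergeMembers(hc$merge, length(cand))
    sizes <- lengths(members)
    childSize <- function(v) {
        out <- rep(1L, length(v))
        out[v > 0] <- sizes[v[v > 0]]
        out
    }
    firstFormed <- which(sizes >= k &
        childSize(hc$merge[, 1]) < k & childSize(hc$merge[, 2]) < k)
    audit <- NULL
    for (node in firstFormed) {
        mem <- cand[members[[node]]]
        subs <- utils::combn(sort(mem), k, simplify = FALSE)
        for (s in subs) {
            audit <- rbind(audit, data.frame(
                cluster = node, cluster_size = length(mem),
                subset = paste(s, collapse = "|"),
                dispersion = .centroidDispersion(X[s, , drop = FALSE])))
        }
    }
    audit <- audit[order(audit$dispersion, audit$subset), , drop = FALSE]
    rownames(audit) <- NULL
    audit$selected <- seq_len(nrow(audit)) == 1L
    sel <- strsplit(audit$subset[1L], "|", fixed = TRUE)[[1L]]
    list(normalizers = sort(sel), dispersion = audit$dispersion[1L],
         audit = audit)
}

# membership (leaf indices) of every internal node of an hclust merge matrix
.mergeMembers <- function(merge, nLeaves) {
    members <- vector("list", nrow(merge))
    for (i in seq_len(nrow(merge))) {
        take <- function(v) if (v < 0) -v else members[[v]]
        members[[i]] <- c(take(merge[i, 1]), take(merge[i, 2]))
    }
    members
}

# sum of Euclidean distances from rows of X to their centroid
.centroidDispersion <- function(X) {
    ctr <- colMeans(X)
    sum(sqrt(rowSums(sweep(X, 2L, ctr)^2)))
}

#' Compute (-)delta-Ct expression values
#'
#' For each sample, (-)delta-Ct(assay) = -(Ct(assay) - mean Ct over the
#' normalizer set), a log2-expression-scale value increasing with abundance.
#' Per-sample extraction-efficiency offsets cancel exactly. Samples with any
#' missing normalizer Ct cannot be normalized and are dropped with a log
#' entry; control assays are dropped from the output (they are QC-only).
#'
#' @param x a \linkS4class{CtExperiment}
#' @param normalizers character vector of normalizer assay names (e.g. from
#'   \code{\link{findNormalizerSet}}), or the list that function returns
#' @param dropControls drop control assays from the output (default TRUE)
#' @return a \linkS4class{NormalizedExpression}
#' @export
toNegDeltaCt <- function(x, normalizers, dropControls = TRUE) {
    stopifnot(is(x, "CtExperiment"))
    audit <- NULL
    if (is.list(normalizers)) {
        audit <- normalizers$audit
        dispersion <- normalizers$dispersion
        normalizers <- normalizers$normalizers
    } else dispersion <- NA_real_
    if (!length(normalizers))
        stop("empty normalizer set")
    ct <- ctValues(x)
    if (!all(normalizers %in% rownames(ct)))
        stop("normalizer assays missing from the Ct matrix")
    normMean <- colMeans(ct[normalizers, , drop = FALSE])
    ok <- !is.na(normMean)
    dropped <- colnames(ct)[!ok]
    vals <- -sweep(ct[, ok, drop = FALSE], 2L, normMean[ok], `-`)
    if (dropControls) {
        ctr <- setdiff(unlist(controlAssays(x)), normalizers)
        vals <- vals[!rownames(vals) %in% ctr, , drop = FALSE]
    }
    se <- SummarizedExperiment(
        assays = list(negDeltaCt = vals),
        colData = colData(x)[ok, , drop = FALSE],
        metadata = list(normalizer_set = normalizers,
                        dispersion = dispersion,
                        dendrogram_audit = audit,
                        dropped_samples = dropped))
    obj <- new("NormalizedExpression", se)
    if (length(dropped))
        message("dropped ", length(dropped),
                " sample(s) with missing normalizer Ct: ",
                paste(dropped, collapse = ", "))
    validObject(obj)
    obj
}

#' Adaptive normalization in one step
#'
#' Convenience wrapper: \code{\link{findNormalizerSet}} followed by
#' \code{\link{toNegDeltaCt}}.
#'
#' @param x a \linkS4class{CtExperiment}
#' @param k normalizer-set size (default 3)
#' @return a \linkS4class{NormalizedExpression}
#' @export
normalizeCt <- function(x, k = 3L) {
    toNegDeltaCt(x, findNormalizerSet(x, k))
}
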