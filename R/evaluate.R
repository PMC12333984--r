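#' One-vs-rest ROC curves with Mann-Whitney p-values
#'
#' For each group, the ROC of that group's continuous score with positives =
#' samples of the group. The AUC is the Mann-Whitney U statistic divided by
#' n1*n0, computed with midranks; the p-value is the two-sided
#' normal-approximated Mann-Whitney test with tie correction. An AUC below
#' 0.5 is reported as-is (orientation is never flipped).
#'
#' @param scores samples x groups matrix of continuous per-group scores
#'   (higher = more group-like), column names = group labels; typically
#'   cross-validated held-out scores from \code{\link{looGroupScores}}
#' @param labels true group labels, one per sample
#' @return data.frame with one row per group: auc, p_value, n_pos, n_neg;
#'   attribute \code{"curves"} holds per-group lists of thresholds, TPR and
#'   FPR arrays (curves run from (0,0) to (1,1), monotone)
#' @export
oneVsRestRoc <- function(scores, labels) {
    scores <- as.matrix(scores)
    labels <- as.character(labels)
    groups <- colnames(scores)
    if (is.null(groups)) stop("scores must have group column names")
    curves <- list()
    res <- do.call(rbind, lapply(groups, function(g) {
        s <- scores[, g]
        pos <- labels == g
        n1 <- sum(pos); n0 <- sum(!pos)
        if (n1 < 1 || n0 < 1)
            stop("group '", g, "' is degenerate (needs >=1 positive and ",
                 ">=1 negative)")
        r <- rank(s)                       # midranks
        auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
        p <- if (length(unique(s)) == 1L) 1 else
            suppressWarnings(stats::wilcox.test(
                s[pos], s[!pos], exact = FALSE, correct = FALSE)$p.value)
        thr <- sort(unique(s), decreasing = TRUE)
        tpr <- c(0, vapply(thr, function(t) mean(s[pos] >= t), 1))
        fpr <- c(0, vapply(thr, function(t) mean(s[!pos] >= t), 1))
        curves[[g]] <<- list(thresholds = c(Inf, thr), tpr = tpr, fpr = fpr)
        data.frame(group = g, auc = auc, p_value = p, n_pos = n1, n_neg = n0)
    }))
    rownames(res) <- NULL
    attr(res, "curves") <- curves
    res
}

#' Cross-validated held-out group scores
#'
#' Leave-one-out loop at fixed model parameters: each sample's per-group
#' scores (negative centroid distances) come from a model fitted without it.
#' These held-out scores are the honest input for ROC evaluation of a tuned
#' model.
#'
#' @param bd a raw \linkS4class{BlockDataset}
#' @param ncomp,keepX chosen model parameters
#' @param sparseBlock block carrying the sparsity constraint (default as in
#'   \code{\link{looTune}})
#' @return list with \code{scores} (samples x groups matrix) and
#'   \code{class} (held-out predicted labels)
#' @export
looGroupScores <- function(bd, ncomp, keepX, sparseBlock = NULL) {
    stopifnot(is(bd, "BlockDataset"), !bd@preprocessed)
    bn <- names(bd@blocks)
    sparseBlock <- sparseBlock %||% if ("miR" %in% bn) "miR" else bn[1L]
    n <- length(bd@outcome)
    lev <- levels(bd@outcome)
    scores <- matrix(NA_real_, n, length(lev),
                     dimnames = list(rownames(bd@blocks[[1]]), lev))
    cls <- rep(NA_character_, n)
    for (i in seq_len(n)) {
        bdTrain <- blockDataset(
            lapply(bd@blocks, function(X) X[-i, , drop = FALSE]),
            bd@outcome[-i], design = bd@design, impute = FALSE)
        if (any(table(bdTrain@outcome) < 2L)) next
        fit <- fitBlockSplsda(bdTrain, ncomp = ncomp,
                              keepX = stats::setNames(list(keepX),
                                                      sparseBlock))
        pr <- predictGroup(fit, lapply(bd@blocks, function(X)
            X[i, , drop = FALSE]))
        scores[i, ] <- pr$scores[1L, lev]
        cls[i] <- as.character(pr$class)
    }
    list(scores = scores, class = factor(cls, levels = lev))
}

#' Kruskal-Wallis rank test
#'
#' H statistic with tie correction and chi-square p-value (G - 1 degrees of
#' freedom). All-tied input returns H = 0, p = 1 rather than an error.
#'
#' @param values numeric vector
#' @param groups group labels (>= 2 groups with >= 2 samples each)
#' @return list with \code{H}, \code{p}, \code{df}
#' @export
kruskalWallis <- function(values, groups) {
    groups <- as.factor(groups)
    tb <- table(groups[!is.na(values)])
    if (length(tb) < 2 || any(tb < 2))
        stop("need >= 2 groups with >= 2 non-missing samples each")
    if (length(unique(values[!is.na(values)])) == 1L)
        return(list(H = 0, p = 1, df = length(tb) - 1L))
    kt <- stats::kruskal.test(values, groups)
    list(H = unname(kt$statistic), p = kt$p.value,
         df = unname(kt$parameter))
}
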