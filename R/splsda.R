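#' Assemble a multi-block dataset
#'
#' Aligns named feature blocks (samples x features) with a categorical
#' outcome and an inter-block design matrix. Missing values in clinical-type
#' blocks can be median-imputed (logged); the outcome block is connected to
#' every data block with weight 1 during fitting.
#'
#' @param blocks named list of numeric matrices, samples in rows (shared
#'   order); row names, when present, must agree across blocks
#' @param outcome vector/factor of group labels (e.g. dose group), one per
#'   sample
#' @param design optional blocks x blocks matrix of connection weights in
#'   [0, 1]; default: 0.1 between every pair of data blocks (weak inter-block
#'   coupling, prioritizing outcome association)
#' @param impute median-impute missing block values, with a log entry
#'   (default TRUE)
#' @return a \linkS4class{BlockDataset}
#' @export
blockDataset <- function(blocks, outcome, design = NULL, impute = TRUE) {
    stopifnot(is.list(blocks), length(blocks) >= 1)
    blocks <- lapply(blocks, as.matrix)
    logs <- character()
    rn <- Filter(Negate(is.null), lapply(blocks, rownames))
    if (length(rn) > 1 && !all(vapply(rn[-1], identical, TRUE, rn[[1]])))
        stop("blocks must share an identical sample order")
    if (impute)
        for (b in names(blocks)) {
            X <- blocks[[b]]
            for (j in which(colSums(is.na(X)) > 0)) {
                med <- stats::median(X[, j], na.rm = TRUE)
                n_imp <- sum(is.na(X[, j]))
                X[is.na(X[, j]), j] <- med
                logs <- c(logs, sprintf(
                    "imputed %d value(s) of %s/%s with median %.4g",
                    n_imp, b, colnames(X)[j], med))
            }
            blocks[[b]] <- X
        }
    if (is.null(design)) {
        B <- length(blocks)
        design <- matrix(0.1, B, B,
                         dimnames = list(names(blocks), names(blocks)))
        diag(design) <- 0
    }
    obj <- new("BlockDataset", blocks = blocks,
               outcome = droplevels(as.factor(outcome)), design = design,
               preprocessed = FALSE, centers = list(), scales = list(),
               log = logs)
    validObject(obj)
    obj
}

#' Center and scale all blocks
#'
#' Each column is centered and scaled to unit (sample) variance;
#' zero-variance columns are dropped with a log entry. Any missing value
#' remaining after construction is an error naming the sample and feature.
#'
#' @param bd a \linkS4class{BlockDataset}
#' @return the preprocessed \linkS4class{BlockDataset} (idempotent)
#' @export
preprocessBlocks <- function(bd) {
    stopifnot(is(bd, "BlockDataset"))
    if (bd@preprocessed) return(bd)
    for (b in names(bd@blocks)) {
        X <- bd@blocks[[b]]
        if (anyNA(X)) {
            idx <- which(is.na(X), arr.ind = TRUE)[1L, ]
            stop(sprintf("missing value in block '%s' (sample %s, feature %s)",
                         b, rownames(X)[idx[1]] %||% idx[1],
                         colnames(X)[idx[2]] %||% idx[2]))
        }
        ctr <- colMeans(X)
        scl <- apply(X, 2L, stats::sd)
        zero <- scl < .Machine$double.eps^0.5
        if (any(zero)) {
            bd@log <- c(bd@log, sprintf(
                "dropped zero-variance column(s) in block '%s': %s", b,
                paste(colnames(X)[zero], collapse = ", ")))
            X <- X[, !zero, drop = FALSE]
            ctr <- ctr[!zero]; scl <- scl[!zero]
        }
        if (!ncol(X)) stop("block '", b, "' has no variable columns")
        bd@blocks[[b]] <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
        bd@centers[[b]] <- ctr
        bd@scales[[b]] <- scl
    }
    bd@preprocessed <- TRUE
    bd
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# centered class-indicator matrix
.indicatorMatrix <- function(outcome) {
    lev <- levels(outcome)
    Y <- outer(as.character(outcome), lev, `==`) * 1
    colnames(Y) <- lev
    scale(Y, center = TRUE, scale = FALSE)
}

# keep the keepX largest-magnitude entries, soft-shrunk by the (keepX+1)-th
# largest absolute value; signs preserved
.softSelect <- function(u, keepX) {
    p <- length(u)
    if (keepX >= p) return(u)
    a <- abs(u)
    ord <- order(a, decreasing = TRUE)
    thr <- a[ord[keepX + 1L]]
    out <- numeric(p)
    keep <- ord[seq_len(keepX)]
    out[keep] <- sign(u[keep]) * (a[keep] - thr)
    out
}

.unitNorm <- function(v) {
    n <- sqrt(sum(v^2))
    if (n < .Machine$double.eps) v else v / n
}

# deterministic sign convention for an initial vector
.fixSign <- function(v) if (v[which.max(abs(v))] < 0) -v else v

#' Fit a sparse multiblock PLS-DA model
#'
#' DIABLO-style supervised integration: per component, each block's loading
#' is iteratively updated as the (sparsified, unit-norm) image of the
#' design-weighted sum of the other blocks' scores plus the outcome-block
#' score; the outcome indicator block participates with full connectivity and
#' no sparsity. Sparsity is rank-based soft-thresholding keeping exactly
#' \code{keepX} features per block per component. Blocks are deflated on
#' their own scores, making successive within-block scores orthogonal. The
#' fit is deterministic: SVD-based initialization with a fixed sign
#' convention and fixed tie-breaks.
#'
#' @param bd a \linkS4class{BlockDataset} (preprocessed automatically)
#' @param ncomp number of components
#' @param keepX named list: per block, an integer vector (length ncomp,
#'   scalars recycled) of features to retain; blocks not named keep all
#'   features
#' @param deflateY also deflate the outcome block (default TRUE)
#' @param tol convergence tolerance on the maximal loading change
#'   (default 1e-6)
#' @param maxIter maximal iterations per component (default 100); a
#'   non-converged component yields a warning and is flagged
#' @return a \linkS4class{SplsdaModel}
#' @export
fitBlockSplsda <- function(bd, ncomp, keepX = list(), deflateY = TRUE,
                           tol = 1e-6, maxIter = 100L) {
    bd <- preprocessBlocks(bd)
    blocks <- bd@blocks
    bn <- names(blocks)
    n <- nrow(blocks[[1L]])
    ncomp <- as.integer(ncomp)
    stopifnot(ncomp >= 1L, ncomp < n)
    kx <- lapply(bn, function(b) {
        p <- ncol(blocks[[b]])
        v <- keepX[[b]] %||% p
        v <- as.integer(rep(v, length.out = ncomp))
        if (any(v < 1L | v > p))
            stop("keepX for block '", b, "' must lie in [1, ", p, "]")
        v
    })
    names(kx) <- bn
    Y <- .indicatorMatrix(bd@outcome)
    design <- bd@design[bn, bn, drop = FALSE]

    X <- blocks
    loadings <- lapply(blocks, function(B)
        matrix(0, ncol(B), ncomp, dimnames = list(colnames(B), NULL)))
    proj <- loadings
    scores <- lapply(blocks, function(B) matrix(0, n, ncomp))
    aYm <- matrix(0, ncol(Y), ncomp, dimnames = list(colnames(Y), NULL))
    tYm <- matrix(0, n, ncomp)
    converged <- logical(ncomp)

    for (h in seq_len(ncomp)) {
        a <- lapply(bn, function(b)
            .fixSign(svd(crossprod(X[[b]], Y), nu = 1L, nv = 0L)$u[, 1L]))
        names(a) <- bn
        tB <- lapply(bn, function(b) drop(X[[b]] %*% a[[b]]))
        names(tB) <- bn
        aY <- .unitNorm(drop(crossprod(Y, Reduce(`+`, tB) / length(tB))))
        tY <- drop(Y %*% aY)
        it <- 0L; delta <- Inf
        while (it < maxIter && delta >= tol) {
            it <- it + 1L
            delta <- 0
            for (b in bn) {
                w <- tY
                for (k in setdiff(bn, b))
                    if (design[b, k] > 0) w <- w + design[b, k] * tB[[k]]
                u <- drop(crossprod(X[[b]], w))
                aNew <- .unitNorm(.softSelect(u, kx[[b]][h]))
                delta <- max(delta, max(abs(aNew - a[[b]])))
                a[[b]] <- aNew
                tB[[b]] <- drop(X[[b]] %*% aNew)
            }
            uY <- drop(crossprod(Y, Reduce(`+`, tB)))
            aYnew <- .unitNorm(uY)
            delta <- max(delta, max(abs(aYnew - aY)))
            aY <- aYnew
            tY <- drop(Y %*% aY)
        }
        converged[h] <- delta < tol
        if (!converged[h])
            warning("component ", h, " did not converge after ", maxIter,
                    " iterations")
        for (b in bn) {
            loadings[[b]][, h] <- a[[b]]
            scores[[b]][, h] <- tB[[b]]
            cb <- drop(crossprod(X[[b]], tB[[b]])) / sum(tB[[b]]^2)
            proj[[b]][, h] <- cb
            X[[b]] <- X[[b]] - tcrossprod(tB[[b]], cb)
        }
        aYm[, h] <- aY
        tYm[, h] <- tY
        if (deflateY) {
            cy <- drop(crossprod(Y, tY)) / sum(tY^2)
            Y <- Y - tcrossprod(tY, cy)
        }
    }

    Tavg <- Reduce(`+`, scores) / length(scores)
    lev <- levels(bd@outcome)
    centroids <- do.call(rbind, lapply(lev, function(g)
        colMeans(Tavg[bd@outcome == g, , drop = FALSE])))
    rownames(centroids) <- lev

    sigBlock <- if ("miR" %in% bn) "miR" else bn[1L]
    sig <- do.call(rbind, lapply(seq_len(ncomp), function(h) {
        sup <- which(loadings[[sigBlock]][, h] != 0)
        if (!length(sup)) return(NULL)
        data.frame(component = h,
                   miRNA = colnames(blocks[[sigBlock]])[sup],
                   stability = NA_real_,
                   loading = loadings[[sigBlock]][sup, h])
    }))
    if (is.null(sig))
        sig <- data.frame(component = integer(), miRNA = character(),
                          stability = numeric(), loading = numeric())
    rownames(sig) <- NULL

    obj <- new("SplsdaModel", blocks = blocks, loadings = loadings,
               scores = scores, projLoadings = proj, outcomeLoadings = aYm,
               outcomeScores = tYm, keepX = kx, ncomp = ncomp,
               outcome = bd@outcome, centroids = centroids,
               centers = bd@centers, scales = bd@scales, design = design,
               converged = converged, tuningTrace = data.frame(),
               stability = data.frame(), signature = sig)
    validObject(obj)
    obj
}

#' Predict dose groups for new samples
#'
#' New samples are preprocessed with the training centers/scales, projected
#' through the model's components (with deflation replayed), block score
#' vectors are averaged with equal weights, and each sample is assigned the
#' group whose training-score centroid is nearest in Euclidean distance.
#' Exact centroid ties break to the lexicographically first group and are
#' flagged. Continuous per-group scores (negative distances) support ROC
#' analysis.
#'
#' @param model a fitted \linkS4class{SplsdaModel}
#' @param newBlocks named list of raw (unpreprocessed) sample x feature
#'   matrices; features must match the training features by name
#' @param ncomp number of components to use (default: all fitted)
#' @return list with \code{class} (factor), \code{scores} (samples x groups
#'   matrix of negative centroid distances), \code{components} (samples x
#'   ncomp averaged component scores) and \code{tied} (logical)
#' @export
predictGroup <- function(model, newBlocks, ncomp = model@ncomp) {
    stopifnot(is(model, "SplsdaModel"), ncomp >= 1, ncomp <= model@ncomp)
    bn <- names(model@loadings)
    miss <- setdiff(bn, names(newBlocks))
    if (length(miss))
        stop("missing block(s): ", paste(miss, collapse = ", "))
    Tnew <- NULL
    for (b in bn) {
        X <- as.matrix(newBlocks[[b]])
        feats <- names(model@centers[[b]])
        if (!all(feats %in% colnames(X)))
            stop("block '", b, "' lacks training features")
        X <- X[, feats, drop = FALSE]
        X <- sweep(sweep(X, 2L, model@centers[[b]]), 2L,
                   model@scales[[b]], `/`)
        Tb <- matrix(0, nrow(X), ncomp)
        for (h in seq_len(ncomp)) {
            th <- drop(X %*% model@loadings[[b]][, h])
            Tb[, h] <- th
            X <- X - tcrossprod(th, model@projLoadings[[b]][, h])
        }
        Tnew <- if (is.null(Tnew)) Tb else Tnew + Tb
    }
    Tnew <- Tnew / length(bn)
    lev <- rownames(model@centroids)
    Tavg <- Reduce(`+`, model@scores) / length(model@scores)
    ctr <- do.call(rbind, lapply(lev, function(g)
        colMeans(Tavg[model@outcome == g, seq_len(ncomp), drop = FALSE])))
    d2 <- outer(rowSums(Tnew^2), rep(1, length(lev))) -
        2 * Tnew %*% t(ctr) + outer(rep(1, nrow(Tnew)), rowSums(ctr^2))
    dist <- sqrt(pmax(d2, 0))
    colnames(dist) <- lev
    best <- apply(dist, 1L, function(d) which(d == min(d))[1L])
    tied <- apply(dist, 1L, function(d) sum(d == min(d)) > 1L)
    list(class = factor(lev[best], levels = lev), scores = -dist,
         components = Tnew, tied = tied)
}

#' Tune model size by leave-one-out cross-validation
#'
#' For every grid point (number of components x keepX for the sparse block),
#' each sample is held out in turn, the model is refitted on the remainder
#' (preprocessing recomputed inside the fold), and the held-out sample's
#' group is predicted. The score is the balanced error rate (mean of
#' per-class error rates); the minimizer is chosen, with ties broken toward
#' fewer components, then smaller total keepX, then grid order. Classes with
#' a single sample make their own fold unevaluable; such folds are skipped
#' with a warning.
#'
#' @param bd a raw (unpreprocessed) \linkS4class{BlockDataset}
#' @param ncompGrid candidate component counts (default 1:3)
#' @param keepXGrid candidate keepX values for the sparse block (default
#'   c(3, 5, 7, 10, 15, 20, 30)); values above the block width are clamped
#' @param sparseBlock name of the block tuned for sparsity (default
#'   \code{"miR"} when present, else the first block); other blocks keep all
#'   features
#' @return list with \code{ncomp}, \code{keepX} (chosen value for the sparse
#'   block), \code{ber} and \code{trace} (data.frame over the grid)
#' @export
looTune <- function(bd, ncompGrid = 1:3,
                    keepXGrid = c(3, 5, 7, 10, 15, 20, 30),
                    sparseBlock = NULL) {
    stopifnot(is(bd, "BlockDataset"), length(ncompGrid) > 0,
              length(keepXGrid) > 0)
    if (bd@preprocessed)
        stop("looTune needs raw blocks: preprocessing is refitted per fold")
    bn <- names(bd@blocks)
    sparseBlock <- sparseBlock %||% if ("miR" %in% bn) "miR" else bn[1L]
    p <- ncol(bd@blocks[[sparseBlock]])
    keepXGrid <- sort(unique(pmin(as.integer(keepXGrid), p)))
    ncompGrid <- sort(unique(as.integer(ncompGrid)))
    hmax <- max(ncompGrid)
    n <- length(bd@outcome)
    lev <- levels(bd@outcome)
    classN <- table(bd@outcome)
    skipClasses <- names(classN)[classN < 2L]
    if (length(skipClasses))
        warning("class(es) with a single sample skipped in LOO: ",
                paste(skipClasses, collapse = ", "))

    # preds[[kx]][fold, h] = predicted label
    preds <- lapply(keepXGrid, function(k)
        matrix(NA_character_, n, hmax))
    names(preds) <- as.character(keepXGrid)
    evaluated <- rep(TRUE, n)
    for (i in seq_len(n)) {
        if (as.character(bd@outcome[i]) %in% skipClasses) {
            evaluated[i] <- FALSE
            next
        }
        bdTrain <- blockDataset(
            lapply(bd@blocks, function(X) X[-i, , drop = FALSE]),
            bd@outcome[-i], design = bd@design, impute = FALSE)
        newB <- lapply(bd@blocks, function(X) X[i, , drop = FALSE])
        for (k in keepXGrid) {
            fit <- fitBlockSplsda(bdTrain, ncomp = hmax,
                                  keepX = stats::setNames(list(k),
                                                          sparseBlock))
            for (h in ncompGrid) {
                pr <- predictGroup(fit, newB, ncomp = h)
                preds[[as.character(k)]][i, h] <- as.character(pr$class)
            }
        }
    }

    trace <- do.call(rbind, lapply(keepXGrid, function(k)
        do.call(rbind, lapply(ncompGrid, function(h) {
            pd <- preds[[as.character(k)]][, h]
            perClass <- vapply(setdiff(lev, skipClasses), function(g) {
                idx <- evaluated & bd@outcome == g
                mean(pd[idx] != g)
            }, numeric(1))
            data.frame(ncomp = h, keepX = k, ber = mean(perClass),
                       n_folds = sum(evaluated))
        }))))
    rownames(trace) <- NULL
    ord <- order(trace$ber, trace$ncomp, trace$ncomp * trace$keepX,
                 seq_len(nrow(trace)))
    best <- trace[ord[1L], ]
    list(ncomp = best$ncomp, keepX = best$keepX, ber = best$ber,
         trace = trace, sparseBlock = sparseBlock)
}

#' Leave-one-out stability scores and final signature
#'
#' Refits the model within each leave-one-out fold at the chosen parameters;
#' a feature's stability for a component is the fraction of folds in which
#' it carried a nonzero loading on that component. The final signature is
#' the support of the full-data fit, annotated with stability.
#'
#' @param bd a raw \linkS4class{BlockDataset}
#' @param ncomp chosen number of components
#' @param keepX chosen keepX for the sparse block
#' @param sparseBlock block tuned for sparsity (default as in
#'   \code{\link{looTune}})
#' @return the full-data \linkS4class{SplsdaModel} with slots
#'   \code{stability} and \code{signature} filled
#' @export
stabilityScores <- function(bd, ncomp, keepX, sparseBlock = NULL) {
    stopifnot(is(bd, "BlockDataset"), !bd@preprocessed)
    bn <- names(bd@blocks)
    sparseBlock <- sparseBlock %||% if ("miR" %in% bn) "miR" else bn[1L]
    kxArg <- stats::setNames(list(keepX), sparseBlock)
    n <- length(bd@outcome)
    feats <- colnames(bd@blocks[[sparseBlock]])
    counts <- matrix(0L, length(feats), ncomp,
                     dimnames = list(feats, NULL))
    nFolds <- 0L
    for (i in seq_len(n)) {
        bdTrain <- blockDataset(
            lapply(bd@blocks, function(X) X[-i, , drop = FALSE]),
            bd@outcome[-i], design = bd@design, impute = FALSE)
        if (any(table(bdTrain@outcome) < 2L)) next
        fit <- fitBlockSplsda(bdTrain, ncomp = ncomp, keepX = kxArg)
        A <- fit@loadings[[sparseBlock]]
        counts[rownames(A), ] <- counts[rownames(A), ] +
            (A[, seq_len(ncomp), drop = FALSE] != 0)
        nFolds <- nFolds + 1L
    }
    stab <- counts / nFolds
    full <- fitBlockSplsda(bd, ncomp = ncomp, keepX = kxArg)
    stabDf <- do.call(rbind, lapply(seq_len(ncomp), function(h)
        data.frame(block = sparseBlock, component = h, feature = feats,
                   stability = stab[, h])))
    rownames(stabDf) <- NULL
    sig <- full@signature
    sig$stability <- stab[cbind(match(sig$miRNA, feats), sig$component)]
    full@stability <- stabDf
    full@signature <- sig
    validObject(full)
    full
}

#' Dose group of maximal median expression
#'
#' For each feature, the group in which its median expression is maximal;
#' exact ties resolve to the higher dose and are flagged.
#'
#' @param expression a \linkS4class{NormalizedExpression} or a features x
#'   samples matrix
#' @param features feature names to evaluate (default: all rows)
#' @param groups group labels per sample; taken from \code{dose_gy} in the
#'   colData when \code{expression} is a NormalizedExpression
#' @return data.frame: miRNA, max_median_group, tied
#' @export
maxMedianGroup <- function(expression, features = NULL, groups = NULL) {
    if (is(expression, "NormalizedExpression")) {
        groups <- groups %||% colData(expression)$dose_gy
        expression <- negDeltaCt(expression)
    }
    stopifnot(!is.null(groups), ncol(expression) == length(groups))
    features <- features %||% rownames(expression)
    glev <- sort(unique(as.numeric(groups)))
    out <- do.call(rbind, lapply(features, function(f) {
        med <- vapply(glev, function(g)
            stats::median(expression[f, groups == g], na.rm = TRUE),
            numeric(1))
        mx <- which(med == max(med))
        data.frame(miRNA = f, max_median_group = glev[max(mx)],
                   tied = length(mx) > 1L)
    }))
    rownames(out) <- NULL
    out
}

#' Cross-block variable similarities
#'
#' The similarity between variable x of block a and variable y of block b is
#' the sum over components of cor(x, t_a,h) * cor(y, t_b,h), computed on the
#' preprocessed training data — the quantity rendered in correlation circle
#' plots and clustered heatmaps. Pairs at or above \code{cutoff} in absolute
#' value are listed; the full matrix is also returned. Zero-variance
#' variables are skipped with a log attribute.
#'
#' @param model a fitted \linkS4class{SplsdaModel} with >= 1 component
#' @param cutoff absolute-similarity cutoff for the pair list (default 0.5)
#' @param blocks pair of block names (default: the first two blocks)
#' @return list with \code{pairs} (data.frame var_a, var_b, similarity,
#'   sorted by |similarity| descending) and \code{matrix} (p_a x p_b)
#' @export
crossBlockSimilarity <- function(model, cutoff = 0.5,
                                 blocks = names(model@blocks)[1:2]) {
    stopifnot(is(model, "SplsdaModel"), model@ncomp >= 1L,
              length(blocks) == 2L, all(blocks %in% names(model@blocks)))
    corsWith <- function(b) {
        X <- model@blocks[[b]]
        Tb <- model@scores[[b]]
        C <- suppressWarnings(stats::cor(X, Tb))
        C
    }
    Ca <- corsWith(blocks[1L]); Cb <- corsWith(blocks[2L])
    skipA <- rownames(Ca)[!stats::complete.cases(Ca)]
    skipB <- rownames(Cb)[!stats::complete.cases(Cb)]
    Ca <- Ca[stats::complete.cases(Ca), , drop = FALSE]
    Cb <- Cb[stats::complete.cases(Cb), , drop = FALSE]
    M <- tcrossprod(Ca, Cb)
    idx <- which(abs(M) >= cutoff, arr.ind = TRUE)
    pairs <- data.frame(var_a = rownames(M)[idx[, 1L]],
                        var_b = colnames(M)[idx[, 2L]],
                        similarity = M[idx])
    pairs <- pairs[order(-abs(pairs$similarity), pairs$var_a, pairs$var_b), ]
    rownames(pairs) <- NULL
    out <- list(pairs = pairs, matrix = M)
    if (length(c(skipA, skipB)))
        attr(out, "skipped") <- c(skipA, skipB)
    out
}

#' Tune, fit and stability-annotate in one call
#'
#' Runs \code{\link{looTune}}, refits on the full data at the chosen
#' parameters via \code{\link{stabilityScores}}, and annotates the signature
#' with the dose group of maximal median expression.
#'
#' @param bd a raw \linkS4class{BlockDataset}
#' @param expression optional \linkS4class{NormalizedExpression} for the
#'   max-median-group annotation
#' @param ncompGrid,keepXGrid tuning grids (see \code{\link{looTune}})
#' @return a fitted \linkS4class{SplsdaModel} with tuning trace, stability
#'   scores and annotated signature
#' @export
fitSignatureModel <- function(bd, expression = NULL, ncompGrid = 1:3,
                              keepXGrid = c(3, 5, 7, 10, 15, 20, 30)) {
    tune <- looTune(bd, ncompGrid, keepXGrid)
    model <- stabilityScores(bd, tune$ncomp, tune$keepX,
                             sparseBlock = tune$sparseBlock)
    model@tuningTrace <- tune$trace
    if (!is.null(expression) && nrow(model@signature)) {
        mmg <- maxMedianGroup(expression,
                              features = unique(model@signature$miRNA))
        model@signature$max_median_group <-
            mmg$max_median_group[match(model@signature$miRNA, mmg$miRNA)]
    }
    model
}
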