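test_that("preprocessing centers, scales, drops constants and reports NAs", {
    X <- cbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5), c = rnorm(4))
    rownames(X) <- paste0("s", 1:4)
    bd <- blockDataset(list(blk = X), factor(c("A", "A", "B", "B")))
    pp <- preprocessBlocks(bd)
    expect_false("b" %in% colnames(dataBlocks(pp)$blk))
    expect_match(paste(pp@log, collapse = " "), "zero-variance")
    Z <- dataBlocks(pp)$blk
    expect_equal(colMeans(Z), c(a = 0, c = 0), tolerance = 1e-12)
    expect_equal(apply(Z, 2, sd), c(a = 1, c = 1), tolerance = 1e-12)
    expect_identical(preprocessBlocks(pp), pp)   # idempotent
    Xna <- X; Xna[2, 1] <- NA
    bdNa <- blockDataset(list(blk = Xna), factor(c("A", "A", "B", "B")),
                         impute = FALSE)
    expect_error(preprocessBlocks(bdNa), "sample s2, feature a")
    # with imputation the gap is median-filled and logged
    bdImp <- blockDataset(list(blk = Xna), factor(c("A", "A", "B", "B")))
    expect_match(paste(bdImp@log, collapse = " "), "imputed 1 value")
})

test_that("single-block no-sparsity fit matches an independent NIPALS oracle", {
    for (s in 1:20) {
        set.seed(s)
        n <- sample(12:20, 1); p <- sample(5:15, 1)
        grp <- factor(sample(c("A", "B", "C"), n, replace = TRUE,
                             prob = c(.4, .3, .3)))
        while (min(table(grp)) < 2)
            grp <- factor(sample(c("A", "B", "C"), n, replace = TRUE))
        X <- matrix(rnorm(n * p), n, p,
                    dimnames = list(paste0("s", 1:n), paste0("f", 1:p)))
        X[, 1] <- X[, 1] + 2 * (grp == "B")
        bd <- blockDataset(list(miR = X), grp)
        fit <- fitBlockSplsda(bd, ncomp = 1)
        oracle <- nipalsFirstScore(X, grp)
        expect_gte(cosineSim(blockScores(fit)[, 1], oracle), 0.999)
    }
})

test_that("support size equals keepX exactly and keepX = 1 selects one feature", {
    sep <- makeSeparableBlocks()
    for (k in c(1, 3, 7, 20)) {
        fit <- suppressWarnings(
            fitBlockSplsda(sep$bd, ncomp = 2, keepX = list(miR = k)))
        expect_equal(colSums(blockLoadings(fit, "miR") != 0), c(k, k))
    }
    expect_error(fitBlockSplsda(sep$bd, ncomp = 1, keepX = list(miR = 0)))
})

test_that("well-separated classes give perfect component-1 separation", {
    sep <- makeSeparableBlocks(shift = 8)
    fit <- fitBlockSplsda(sep$bd, ncomp = 1, keepX = list(miR = 5))
    sc <- blockScores(fit)[, 1]
    auc <- oneVsRestRoc(cbind(A = -sc, B = sc)[, , drop = FALSE][, c("A", "B")],
                        sep$outcome)
    expect_true(all(auc$auc %in% c(0, 1)))
    expect_true(any(auc$auc == 1))
    # resubstitution on a separable fit is perfect
    pr <- predictGroup(fit, dataBlocks(sep$bd))
    expect_equal(as.character(pr$class), as.character(sep$outcome))
})

test_that("predictions are invariant to feature order and flag exact ties", {
    sep <- makeSeparableBlocks(seed = 5)
    fit <- fitBlockSplsda(sep$bd, ncomp = 2, keepX = list(miR = 5))
    newB <- dataBlocks(sep$bd)
    p1 <- predictGroup(fit, newB)
    perm <- lapply(newB, function(X) X[, sample(ncol(X)), drop = FALSE])
    p2 <- predictGroup(fit, perm)
    expect_identical(p1$class, p2$class)
    expect_equal(p1$scores, p2$scores, tolerance = 1e-12)
    # a sample projecting to the exact midpoint of two centroids ties and
    # breaks to the lexicographically first group, flagged
    Xs <- matrix(c(-2, -1, -1.5, 1, 2, 1.5), 6, 1,
                 dimnames = list(paste0("s", 1:6), "f1"))
    bdS <- blockDataset(list(miR = Xs), factor(rep(c("A", "B"), each = 3)))
    fs <- fitBlockSplsda(bdS, ncomp = 1)
    tie <- predictGroup(fs, list(miR = matrix(0, 1, 1,
                                              dimnames = list("t", "f1"))))
    expect_equal(as.character(tie$class), "A")
    expect_true(tie$tied[1])
})

test_that("scaling a raw feature column changes nothing downstream", {
    sep <- makeSeparableBlocks(seed = 9)
    raw <- dataBlocks(sep$bd)
    raw2 <- raw
    raw2$miR[, 3] <- raw2$miR[, 3] * 17
    bd2 <- blockDataset(raw2, sep$outcome)
    f1 <- fitBlockSplsda(sep$bd, ncomp = 2, keepX = list(miR = 6))
    f2 <- fitBlockSplsda(bd2, ncomp = 2, keepX = list(miR = 6))
    expect_equal(blockLoadings(f1), blockLoadings(f2), tolerance = 1e-9)
    expect_equal(blockScores(f1), blockScores(f2), tolerance = 1e-9)
})

test_that("the fit is deterministic and successive scores are orthogonal", {
    sep <- makeSeparableBlocks(seed = 12)
    f1 <- suppressWarnings(fitBlockSplsda(sep$bd, 3, keepX = list(miR = 8)))
    f2 <- suppressWarnings(fitBlockSplsda(sep$bd, 3, keepX = list(miR = 8)))
    expect_identical(blockLoadings(f1), blockLoadings(f2))
    for (b in names(f1@scores)) {
        S <- f1@scores[[b]]
        G <- crossprod(S)
        expect_lt(max(abs(G[upper.tri(G)])), 1e-6 * max(diag(G)))
    }
})

test_that("leave-one-out tuning finds zero error on separable data", {
    sep <- makeSeparableBlocks(n_per = 8, shift = 8, seed = 3)
    tune <- suppressWarnings(looTune(sep$bd, ncompGrid = 1:2,
                                     keepXGrid = c(2, 5)))
    expect_equal(min(tune$trace$ber), 0)
    expect_equal(tune$ber, 0)
    # trace bookkeeping: one row per grid point
    expect_equal(nrow(tune$trace), 2 * 2)
    expect_true(all(tune$trace$n_folds == 16))
    # ties break toward fewer components then smaller keepX
    zero <- tune$trace[tune$trace$ber == 0, ]
    expect_equal(tune$ncomp, min(zero$ncomp))
})

test_that("stability scores bracket always- and never-selected features", {
    sep <- makeSeparableBlocks(n_per = 8, shift = 10, seed = 6)
    model <- suppressWarnings(stabilityScores(sep$bd, ncomp = 1, keepX = 5))
    st <- featureStability(model)
    expect_true(all(st$stability >= 0 & st$stability <= 1))
    # the 5 planted features dominate: each should be selected in every fold
    planted <- sprintf("f%02d", 1:5)
    expect_true(all(st$stability[st$feature %in% planted] >= 0.9))
    expect_true(all(st$stability[!st$feature %in% planted] <= 0.5))
    sig <- signatureTable(model)
    expect_setequal(sig$miRNA, planted)
    expect_true(all(sig$stability >= 0.9))
})

test_that("max-median group identification follows medians with high-dose ties", {
    expr <- rbind(up = c(1, 1, 2, 2, 3, 3, 4, 4),
                  down = c(4, 4, 3, 3, 2, 2, 1, 1),
                  flat = rep(1, 8))
    colnames(expr) <- paste0("s", 1:8)
    groups <- rep(c(0, 20, 40, 80), each = 2)
    mm <- maxMedianGroup(expr, groups = groups)
    expect_equal(mm$max_median_group[mm$miRNA == "up"], 80)
    expect_equal(mm$max_median_group[mm$miRNA == "down"], 0)
    expect_equal(mm$max_median_group[mm$miRNA == "flat"], 80)
    expect_true(mm$tied[mm$miRNA == "flat"])
    expect_false(any(mm$tied[mm$miRNA != "flat"]))
})

test_that("cross-block similarities match the defining formula", {
    sep <- makeSeparableBlocks(seed = 15)
    fit <- suppressWarnings(fitBlockSplsda(sep$bd, 2, keepX = list(miR = 6)))
    sim <- crossBlockSimilarity(fit, cutoff = 0)
    # direct recomputation from definitions
    Xa <- fit@blocks$miR; Xb <- fit@blocks$clinical
    for (i in sample(nrow(sim$pairs), 10)) {
        row <- sim$pairs[i, ]
        manual <- sum(vapply(1:2, function(h)
            cor(Xa[, row$var_a], fit@scores$miR[, h]) *
            cor(Xb[, row$var_b], fit@scores$clinical[, h]), numeric(1)))
        expect_equal(row$similarity, manual, tolerance = 1e-10)
    }
    expect_equal(nrow(crossBlockSimilarity(fit, cutoff = 1.01)$pairs), 0L)
    # a variable identical to a block's component-1 score has correlation 1
    # with it; paired with its counterpart the similarity is 1 (1 component)
    fit1 <- fitBlockSplsda(sep$bd, 1, keepX = list(miR = 6))
    m2 <- fit1
    m2@blocks$miR <- cbind(m2@blocks$miR, syn_a = fit1@scores$miR[, 1])
    m2@blocks$clinical <- cbind(m2@blocks$clinical,
                                syn_b = fit1@scores$clinical[, 1])
    sim2 <- crossBlockSimilarity(m2, cutoff = 0.99)
    hit <- sim2$pairs[sim2$pairs$var_a == "syn_a" &
                      sim2$pairs$var_b == "syn_b", ]
    expect_equal(hit$similarity, 1, tolerance = 1e-9)
})
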