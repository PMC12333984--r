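test_that("AUC hits the textbook limits", {
    lab <- rep(c("A", "B"), each = 4)
    sep <- cbind(A = c(4, 3, 5, 6, 0, 1, -1, 2),
                 B = -c(4, 3, 5, 6, 0, 1, -1, 2))
    r <- oneVsRestRoc(sep, lab)
    expect_equal(r$auc, c(1, 1))
    flat <- cbind(A = rep(1, 8), B = rep(1, 8))
    r0 <- oneVsRestRoc(flat, lab)
    expect_equal(r0$auc, c(0.5, 0.5))
    expect_equal(r0$p_value, c(1, 1))
})

test_that("AUC equals hand-enumerated concordant pairs, midranks for ties", {
    lab <- c("A", "A", "A", "B", "B", "B")
    s <- c(3.2, 1.1, 2.0, 0.4, 2.5, 1.1)   # one tie across groups
    # brute force: P(score_A > score_B) + 0.5 P(tie) over all 9 pairs
    pos <- s[1:3]; neg <- s[4:6]
    conc <- sum(outer(pos, neg, `>`)) + 0.5 * sum(outer(pos, neg, `==`))
    r <- oneVsRestRoc(cbind(A = s, B = -s), lab)
    expect_equal(r$auc[r$group == "A"], conc / 9)
    # curve endpoints and monotonicity
    cv <- attr(r, "curves")$A
    expect_equal(c(cv$tpr[1], cv$fpr[1]), c(0, 0))
    expect_equal(c(rev(cv$tpr)[1], rev(cv$fpr)[1]), c(1, 1))
    expect_true(all(diff(cv$tpr) >= 0) && all(diff(cv$fpr) >= 0))
})

test_that("AUC is invariant under strictly monotone score transforms", {
    set.seed(4)
    lab <- sample(rep(c("A", "B", "C"), each = 7))
    sc <- matrix(rnorm(21 * 3), 21, 3, dimnames = list(NULL, c("A", "B", "C")))
    r1 <- oneVsRestRoc(sc, lab)
    r2 <- oneVsRestRoc(exp(3 * sc + 1), lab)
    expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
})

test_that("AUC and p agree with the pROC / wilcox references", {
    skip_if_not_installed("pROC")
    set.seed(10)
    lab <- rep(c("A", "B"), c(9, 12))
    s <- rnorm(21) + (lab == "A")
    r <- oneVsRestRoc(cbind(A = s, B = -s), lab)
    ref <- as.numeric(suppressMessages(
        pROC::auc(pROC::roc(lab == "A", s, direction = "<", quiet = TRUE))))
    expect_equal(r$auc[r$group == "A"], ref, tolerance = 1e-12)
    pw <- stats::wilcox.test(s[lab == "A"], s[lab == "B"],
                             exact = FALSE, correct = FALSE)$p.value
    expect_equal(r$p_value[r$group == "A"], pw, tolerance = 1e-12)
})

test_that("degenerate groups raise an informative error", {
    expect_error(oneVsRestRoc(cbind(A = 1:3, B = 3:1), c("A", "A", "A")),
                 "degenerate")
})

test_that("Kruskal-Wallis matches a hand-ranked oracle and handles ties", {
    v <- c(27, 2, 4, 18, 7, 9, 1, 30, 3, 6, 10, 12)
    g <- rep(c("x", "y", "z"), each = 4)
    got <- kruskalWallis(v, g)
    expect_equal(got$H, handKruskalH(v, g), tolerance = 1e-12)
    expect_equal(got$df, 2L)
    expect_equal(got$p, stats::pchisq(got$H, 2, lower.tail = FALSE),
                 tolerance = 1e-12)
    vt <- c(1, 1, 2, 2, 3, 3, 1, 2, 3)
    gt <- rep(c("x", "y", "z"), each = 3)
    expect_equal(kruskalWallis(vt, gt)$H, handKruskalH(vt, gt),
                 tolerance = 1e-12)
    expect_equal(kruskalWallis(rep(5, 9), gt), list(H = 0, p = 1, df = 2L))
    expect_error(kruskalWallis(1:3, c("x", "x", "y")), ">= 2")
})

test_that("simulated lymphocyte depression is detectable at default effects", {
    sig <- vapply(1:10, function(s) {
        sim <- simulateCohort(simulationParams(seed = s))
        kruskalWallis(sim$clinical$lymphocytes, sim$clinical$dose_gy)$p
    }, numeric(1))
    expect_true(all(sig < 0.05))
})

test_that("held-out LOO scores support honest ROC evaluation", {
    sep <- makeSeparableBlocks(n_per = 8, shift = 8, seed = 20)
    loo <- suppressWarnings(looGroupScores(sep$bd, ncomp = 1, keepX = 5))
    expect_false(anyNA(loo$scores))
    r <- oneVsRestRoc(loo$scores, sep$outcome)
    expect_true(all(r$auc > 0.95))
    # held-out predictions on noisy data need not be perfect
    expect_gte(mean(as.character(loo$class) == as.character(sep$outcome)),
               0.9)
})
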