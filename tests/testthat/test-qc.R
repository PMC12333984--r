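test_that("the high-Ct rule is a strict inequality at the limit", {
    ct <- matrix(c(36.9, 37.0, 37.1, 20), 4, 1,
                 dimnames = list(paste0("m", 1:4), "s1"))
    x <- makeCtFixture(ct)
    out <- ctValues(discardHighCt(x))
    expect_equal(out["m1", 1], 36.9)
    expect_equal(out["m2", 1], 37.0)      # 37 itself is retained
    expect_true(is.na(out["m3", 1]))
})

test_that("a matrix with no high Ct is unchanged and counts match brute force", {
    sim <- simulateCohort(simulationParams(nAssays = 60, nSignature = 5,
                                           nPerGroup = 5,
                                           detectionLimit = 60, seed = 5))
    raw <- ctValues(sim$ct)
    expected <- sum(raw > 37, na.rm = TRUE)
    filtered <- discardHighCt(sim$ct, 37)
    expect_equal(metadata(filtered)$qc_log$n_discarded_high_ct, expected)
    low <- sim$ct
    assay(low, "ct") <- pmin(raw, 30)
    expect_equal(ctValues(discardHighCt(low, 37)), pmin(raw, 30))
})

test_that("hemolysis delta is Ct(reference) - Ct(indicator) with threshold 7", {
    ct <- matrix(c(25, 20, 28, 19, NA, 20), 2,
                 dimnames = list(c("miR-23a-3p", "miR-451a"),
                                 c("s1", "s2", "s3")))
    x <- makeCtFixture(ct, controls = list(reference = "miR-23a-3p",
                                           hemolysis = "miR-451a"))
    h <- hemolysisScore(x)
    expect_equal(h$hemolysis_delta, c(5, 9, NA))
    expect_equal(h$hemolysis_flag, c(FALSE, TRUE, NA))
})

test_that("hemolysis flag sensitivity matches a ground-truth recount", {
    p <- simulationParams(pHemolysis = 0.25, seed = 13)
    sim <- simulateCohort(p)
    h <- hemolysisScore(sim$ct)
    truthIds <- sim$truth$hemolysed_samples
    # brute force: which hemolysed samples actually have delta > 7
    shouldFlag <- h$sample_id[h$sample_id %in% truthIds &
                              !is.na(h$hemolysis_delta) &
                              h$hemolysis_delta > 7]
    flagged <- h$sample_id[h$hemolysis_flag %in% TRUE]
    expect_true(all(shouldFlag %in% flagged))
    sens <- mean(truthIds %in% flagged)
    expect_gte(sens, length(shouldFlag) / length(truthIds))
})

test_that("spike-in check is median-relative", {
    ct <- matrix(20, 1, 5, dimnames = list("cel-miR-39", paste0("s", 1:5)))
    x <- makeCtFixture(ct, controls = list(spikein = "cel-miR-39"))
    expect_true(all(spikeinCheck(x)$spikein_flag == FALSE))
    ct2 <- ct; ct2[1, 5] <- 23
    x2 <- makeCtFixture(ct2, controls = list(spikein = "cel-miR-39"))
    expect_equal(spikeinCheck(x2)$spikein_flag, c(rep(FALSE, 4), TRUE))
    x3 <- makeCtFixture(ct2 + 1, controls = list(spikein = "cel-miR-39"))
    expect_equal(spikeinCheck(x3)$spikein_flag, spikeinCheck(x2)$spikein_flag)
    # spike-in absent: all indeterminate
    x4 <- makeCtFixture(ct, controls = list())
    expect_true(all(is.na(spikeinCheck(x4)$spikein_flag)))
})

test_that("detection filter removes sparse assays and matches a recount", {
    set.seed(3)
    ct <- matrix(rnorm(20 * 12, 28), 20, 12,
                 dimnames = list(sprintf("m%02d", 1:20),
                                 sprintf("s%02d", 1:12)))
    ct[1, 1:10] <- NA                      # detected 2/12 < 0.75
    ct[2, 1:2] <- NA                       # detected 10/12 >= 0.75
    x <- makeCtFixture(ct)
    res <- assayDetectionFilter(x, 0.75)
    expect_false("m01" %in% rownames(res$ct))
    expect_true("m02" %in% rownames(res$ct))
    brute <- rownames(ct)[rowMeans(!is.na(ct)) >= 0.75]
    expect_setequal(rownames(res$ct), brute)
    expect_error(assayDetectionFilter(x, 0), "\\(0, 1\\]")
    allMiss <- makeCtFixture(matrix(NA_real_, 2, 3,
        dimnames = list(c("a", "b"), c("s1", "s2", "s3"))))
    expect_error(assayDetectionFilter(allMiss), "every feature")
})

test_that("the full QC chain is idempotent", {
    sim <- simulateCohort(simulationParams(pHemolysis = 0.2, seed = 17))
    r1 <- applyQC(sim$ct)
    r2 <- applyQC(r1$ct)
    expect_identical(ctValues(r2$ct), ctValues(r1$ct))
    expect_identical(colData(r2$ct)$excluded, colData(r1$ct)$excluded)
    expect_identical(assayQC(r2$report)$retained,
                     assayQC(r1$report)$retained[
                         assayQC(r1$report)$retained])
    expect_equal(r2$report@nDiscardedHighCt, 0L)  # nothing new to discard
})

test_that("flags exclude samples only through the explicit decision", {
    sim <- simulateCohort(simulationParams(pHemolysis = 0.3, seed = 19))
    res <- applyQC(sim$ct, exclude = FALSE)
    expect_false(any(colData(res$ct)$excluded))
    resEx <- applyQC(sim$ct, exclude = TRUE)
    sq <- sampleQC(resEx$report)
    expect_true(all(sq$excluded == (sq$hemolysis_flag %in% TRUE |
                                    sq$spikein_flag %in% TRUE)))
})
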