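test_that("coordinate summaries equal direct group aggregation", {
    sep <- makeSeparableBlocks(seed = 30)
    fit <- fitBlockSplsda(sep$bd, ncomp = 1, keepX = list(miR = 5))
    pri <- summarizeCoordinates(fit, 1)
    sc <- blockScores(fit)[, 1]
    for (g in levels(sep$outcome)) {
        v <- sc[sep$outcome == g]
        expect_equal(pri$mean[pri$group == g], mean(v))
        expect_equal(pri$sd[pri$group == g], sd(v))
        expect_equal(pri$n[pri$group == g], length(v))
    }
    expect_error(summarizeCoordinates(fit, 5), "component")
    # averaged-block mode
    priAvg <- summarizeCoordinates(fit, 1, block = "average")
    avg <- (fit@scores$miR[, 1] + fit@scores$clinical[, 1]) / 2
    expect_equal(priAvg$mean,
                 as.numeric(tapply(avg, sep$outcome, mean)[priAvg$group]))
})

test_that("summaries are invariant to sample order", {
    set.seed(31)
    sc <- rnorm(20)
    grp <- factor(rep(c("0", "20", "40", "80"), each = 5))
    mkModel <- function(ord) {
        new("SplsdaModel", scores = list(miR = matrix(sc[ord], ncol = 1)),
            outcome = grp[ord], ncomp = 1L, loadings = list(),
            stability = data.frame(), signature = data.frame(),
            tuningTrace = data.frame())
    }
    p1 <- summarizeCoordinates(mkModel(1:20))
    p2 <- summarizeCoordinates(mkModel(sample(20)))
    expect_equal(p1, p2)
})

test_that("groups with a single sample make the prior SD undefined", {
    m <- new("SplsdaModel", scores = list(miR = matrix(rnorm(5), ncol = 1)),
             outcome = factor(c("a", "a", "b", "b", "c")), ncomp = 1L,
             loadings = list(), stability = data.frame(),
             signature = data.frame(), tuningTrace = data.frame())
    expect_error(summarizeCoordinates(m), "fewer than 2")
})

test_that("bridge draws are valid, deterministic and affine-invariant", {
    prior <- data.frame(group = c(0, 20, 40, 80), mean = c(0, 0.5, 1.2, 2),
                        sd = c(0.4, 0.5, 0.6, 0.5), n = 15)
    set.seed(2)
    d14 <- data.frame(dose_gy = rep(c(0, 20, 40, 80), each = 8))
    d14$y <- 0.6 * prior$mean[match(d14$dose_gy, prior$group)] + rnorm(32, 0, 0.5)
    mc <- list(keep = 1200, burnin = 600)
    b1 <- fitBridge(prior, d14, "y", mcmc = mc, seed = 42)
    b2 <- fitBridge(prior, d14, "y", mcmc = mc, seed = 42)
    expect_identical(posteriorDraws(b1), posteriorDraws(b2))
    r <- posteriorDraws(b1)[, "r"]
    expect_true(all(r >= -1 & r <= 1))
    s <- posteriorSummary(b1)
    expect_true(all(s$mean >= apply(posteriorDraws(b1), 2, min) - 1e-12))
    expect_true(all(s$mean <= apply(posteriorDraws(b1), 2, max) + 1e-12))
    expect_true(all(c("alpha", "beta", "sigma_y", "r") %in% s$parameter))
    expect_true(all(is.finite(s$rhat)))
    # affine outcome transform: internal standardization makes draws identical
    d14b <- d14; d14b$y <- 3.5 * d14$y + 11
    b3 <- fitBridge(prior, d14b, "y", mcmc = mc, seed = 42)
    expect_equal(posteriorDraws(b3), posteriorDraws(b1), tolerance = 1e-12)
})

test_that("bridge input validation catches unusable outcomes", {
    prior <- data.frame(group = c(0, 20), mean = c(0, 1), sd = c(1, 1), n = 5)
    d14 <- data.frame(dose_gy = c(0, 0, 20, 20), y = c(1, 1, 1, 1))
    expect_error(fitBridge(prior, d14, "y"), "constant")
    d14$y <- rnorm(4)
    d14$dose_gy[1] <- 40
    expect_error(fitBridge(prior, d14, "y"), "not covered")
    expect_error(fitBridge(prior, d14, "missing_col"), "outcome column")
    badPrior <- prior; badPrior$sd[1] <- 0
    expect_error(fitBridge(badPrior, d14, "y"), "> 0")
})

test_that("strong alignment between prior means and outcome recovers r near 1", {
    prior <- data.frame(group = c(0, 20, 40, 80), mean = c(0, 1, 2, 3),
                        sd = 0.05, n = 15)
    set.seed(3)
    d14 <- data.frame(dose_gy = rep(c(0, 20, 40, 80), each = 10))
    d14$y <- prior$mean[match(d14$dose_gy, prior$group)] + rnorm(40, 0, 0.01)
    b <- fitBridge(prior, d14, "y", mcmc = list(keep = 1500, burnin = 800),
                   seed = 4)
    expect_gt(mean(posteriorDraws(b)[, "r"]), 0.95)
    expect_lt(b@tailProb, 0.01)
    # near-deterministic outcomes couple the latents and slope tightly; the
    # split-Rhat flag honestly reports the slow mixing rather than hiding it
    expect_true(all(is.finite(b@rhat)))
})

test_that("posterior mean r grows along an effect-size ladder", {
    prior <- data.frame(group = c(0, 20, 40, 80), mean = c(0, 1, 2, 3),
                        sd = 0.5, n = 15)
    rbar <- vapply(c(0, 0.5, 2), function(slope) {
        set.seed(5)
        d14 <- data.frame(dose_gy = rep(c(0, 20, 40, 80), each = 8))
        d14$y <- slope * prior$mean[match(d14$dose_gy, prior$group)] +
            rnorm(32)
        mean(posteriorDraws(fitBridge(prior, d14, "y",
            mcmc = list(keep = 1000, burnin = 500), seed = 6))[, "r"])
    }, numeric(1))
    expect_true(all(diff(rbar) > 0))
})

test_that("null tail probabilities are roughly uniform", {
    prior <- data.frame(group = c(0, 20, 40, 80), mean = c(0, 1, 2, 3),
                        sd = 0.5, n = 15)
    pv <- vapply(1:40, function(s) {
        set.seed(1000 + s)
        d14 <- data.frame(dose_gy = rep(c(0, 20, 40, 80), each = 8),
                          y = rnorm(32))
        fitBridge(prior, d14, "y", mcmc = list(keep = 800, burnin = 400),
                  seed = s)@tailProb
    }, numeric(1))
    expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})
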