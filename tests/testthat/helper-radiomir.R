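# Fixture builders and independent oracles shared across tests.

# small CtExperiment fixture with explicit values
makeCtFixture <- function(ct, dose = rep(0, ncol(ct)),
                          controls = list()) {
    meta <- data.frame(cohort = "targeted", timepoint = "D1",
                       dose_gy = dose)
    ctExperiment(ct, meta, controls = controls)
}

# two well-separated classes in a miR-like block plus a weak clinical block
makeSeparableBlocks <- function(n_per = 10, p = 20, shift = 6, seed = 42) {
    set.seed(seed)
    grp <- factor(rep(c("A", "B"), each = n_per))
    X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p,
                dimnames = list(sprintf("s%02d", seq_len(2 * n_per)),
                                sprintf("f%02d", seq_len(p))))
    X[grp == "B", 1:5] <- X[grp == "B", 1:5] + shift
    C <- matrix(rnorm(2 * n_per * 3), 2 * n_per, 3,
                dimnames = list(rownames(X), c("c1", "c2", "c3")))
    list(bd = blockDataset(list(miR = X, clinical = C), grp), outcome = grp)
}

# independent NIPALS PLS2 oracle: first component score of X against the
# centered class-indicator matrix
nipalsFirstScore <- function(X, outcome, tol = 1e-12, maxit = 5000) {
    X <- scale(X)
    lev <- levels(factor(outcome))
    Y <- outer(as.character(outcome), lev, `==`) * 1
    Y <- scale(Y, center = TRUE, scale = FALSE)
    u <- Y[, 1L]
    w <- rep(0, ncol(X))
    for (i in seq_len(maxit)) {
        wNew <- drop(crossprod(X, u))
        wNew <- wNew / sqrt(sum(wNew^2))
        tt <- drop(X %*% wNew)
        q <- drop(crossprod(Y, tt))
        q <- q / sqrt(sum(q^2))
        u <- drop(Y %*% q)
        if (max(abs(wNew - w)) < tol) break
        w <- wNew
    }
    drop(X %*% wNew)
}

cosineSim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# brute-force normalizer oracle: walk the Ward merge tree independently,
# enumerate every triple inside each first-formed cluster of size >= k,
# and pick the minimum-dispersion triple (lexicographic tie-break)
bruteNormalizerOracle <- function(X, k = 3) {
    hc <- stats::hclust(stats::dist(X), method = "ward.D2")
    nodes <- list()
    sizes <- integer(nrow(hc$merge))
    for (i in seq_len(nrow(hc$merge))) {
        get <- function(v) if (v < 0) -v else nodes[[v]]
        nodes[[i]] <- c(get(hc$merge[i, 1]), get(hc$merge[i, 2]))
        sizes[i] <- length(nodes[[i]])
    }
    sz <- function(v) if (v < 0) 1L else sizes[v]
    best <- NULL; bestDisp <- Inf; bestKey <- ""
    for (i in seq_len(nrow(hc$merge))) {
        if (sizes[i] < k) next
        if (sz(hc$merge[i, 1]) >= k || sz(hc$merge[i, 2]) >= k) next
        for (tri in utils::combn(sort(rownames(X)[nodes[[i]]]), k,
                                 simplify = FALSE)) {
            M <- X[tri, , drop = FALSE]
            ctr <- colMeans(M)
            disp <- sum(sqrt(rowSums(sweep(M, 2, ctr)^2)))
            key <- paste(tri, collapse = "|")
            if (disp < bestDisp - 1e-12 ||
                (abs(disp - bestDisp) <= 1e-12 && key < bestKey)) {
                best <- tri; bestDisp <- disp; bestKey <- key
            }
        }
    }
    list(normalizers = best, dispersion = bestDisp)
}

# hand-computed Kruskal-Wallis H with tie correction, from the definition
handKruskalH <- function(values, groups) {
    r <- rank(values)
    N <- length(values)
    H <- 12 / (N * (N + 1)) *
        sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) -
        3 * (N + 1)
    ties <- table(values)
    H / (1 - sum(ties^3 - ties) / (N^3 - N))
}
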