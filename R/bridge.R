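#' Group-wise summary of signature component coordinates
#'
#' Mean, SD and size of a fitted component's sample scores per dose group —
#' the prior carried into the latent-variable bridge linking two cohorts that
#' share only dose-group labels.
#'
#' @param model a fitted \linkS4class{SplsdaModel}
#' @param component component index (default 1)
#' @param block \code{"miR"}-style block name, or \code{"average"} for the
#'   equal-weight average of block scores (default the miR block when
#'   present)
#' @return data.frame of class \code{CoordinatePrior}: group, mean, sd, n
#' @export
summarizeCoordinates <- function(model, component = 1L, block = NULL) {
    stopifnot(is(model, "SplsdaModel"),
              component >= 1L, component <= model@ncomp)
    bn <- names(model@scores)
    block <- block %||% if ("miR" %in% bn) "miR" else bn[1L]
    sc <- if (identical(block, "average"))
        (Reduce(`+`, model@scores) / length(model@scores))[, component]
    else model@scores[[block]][, component]
    out <- do.call(rbind, lapply(levels(model@outcome), function(g) {
        v <- sc[model@outcome == g]
        if (length(v) < 2L)
            stop("group '", g, "' has fewer than 2 samples; SD undefined")
        data.frame(group = g, mean = mean(v), sd = stats::sd(v),
                   n = length(v))
    }))
    rownames(out) <- NULL
    class(out) <- c("CoordinatePrior", "data.frame")
    out
}

#' Bayesian latent-variable bridge between cohorts
#'
#' Estimates the correlation between a signature component (summarized per
#' dose group on one cohort) and a clinical outcome measured on animals of
#' another cohort, when no animal carries both measurements. For outcome
#' animal j in group g(j): latent coordinate x_j ~ Normal(mu_g, s_g^2)
#' (plug-in group prior), outcome y_j ~ Normal(alpha + beta x_j, sigma_y^2),
#' with alpha, beta ~ Normal(0, 10^2) on the standardized outcome scale and
#' sigma_y ~ Half-Normal(5). Sampling is Metropolis-within-Gibbs: conjugate
#' normal updates for the latent coordinates and (alpha, beta), random-walk
#' Metropolis on log sigma_y. Each retained draw maps to a correlation
#' r = beta sd_x / sqrt(beta^2 var_x + sigma_y^2), with var_x the
#' latent-coordinate mixture variance implied by the prior and the outcome
#' cohort's group sizes — so every draw of r lies in [-1, 1]. Split-Rhat and
#' effective sample size are reported; Rhat > 1.05 on any parameter flags
#' the result non-converged.
#'
#' @param prior a \code{CoordinatePrior} (see
#'   \code{\link{summarizeCoordinates}}) or data.frame with columns group,
#'   mean, sd, n
#' @param d14 data.frame of the outcome cohort with a \code{dose_gy} (or
#'   \code{group}) column and the outcome field
#' @param outcome name of the outcome column (e.g. \code{"injury_score"},
#'   \code{"perfusion_ratio"}); standardized internally, so r is invariant
#'   to positive affine transforms of the outcome
#' @param mcmc list of settings: \code{chains} (default 2), \code{keep}
#'   (kept draws per chain after burn-in, default 2500), \code{burnin}
#'   (default 2000), \code{proposalSd} (log-sigma random-walk SD, default
#'   0.3)
#' @param seed integer seed; chain c uses \code{seed + c}
#' @return a \linkS4class{BridgeResult}
#' @export
fitBridge <- function(prior, d14, outcome = "injury_score",
                      mcmc = list(), seed = 1L) {
    prior <- as.data.frame(prior)
    stopifnot(all(c("group", "mean", "sd") %in% names(prior)))
    if (any(prior$sd <= 0)) stop("prior SDs must be > 0")
    set <- utils::modifyList(list(chains = 2L, keep = 2500L, burnin = 2000L,
                                  proposalSd = 0.3), mcmc)
    if (set$chains < 2L) stop("at least 2 chains are required")
    grp <- as.character(d14$dose_gy %||% d14$group)
    if (is.null(grp)) stop("d14 needs a 'dose_gy' or 'group' column")
    if (!outcome %in% names(d14)) stop("no outcome column '", outcome, "'")
    y <- d14[[outcome]]
    keep <- !is.na(y) & !is.na(grp)
    y <- y[keep]; grp <- grp[keep]
    if (!all(grp %in% as.character(prior$group)))
        stop("outcome animals in groups not covered by the prior: ",
             paste(setdiff(grp, prior$group), collapse = ", "))
    if (stats::sd(y) == 0) stop("outcome is constant; r is undefined")
    y <- as.numeric(scale(y))
    m <- match(grp, as.character(prior$group))
    mu <- prior$mean[m]
    s2 <- prior$sd[m]^2
    nj <- length(y)
    # latent-coordinate mixture variance implied by the prior over this cohort
    varX <- mean(s2) + mean((mu - mean(mu))^2)
    sdX <- sqrt(varX)

    runChain <- function(chainSeed) {
        set.seed(chainSeed)
        x <- mu
        alpha <- 0; beta <- 0; sigma <- 1
        nIter <- set$burnin + set$keep
        out <- matrix(NA_real_, set$keep, 4L,
                      dimnames = list(NULL,
                                      c("alpha", "beta", "sigma_y", "r")))
        for (it in seq_len(nIter)) {
            # latent coordinates: conjugate normal
            prec <- 1 / s2 + beta^2 / sigma^2
            mn <- (mu / s2 + beta * (y - alpha) / sigma^2) / prec
            x <- stats::rnorm(nj, mn, sqrt(1 / prec))
            # (alpha, beta): conjugate bivariate normal, prior N(0, 10^2 I)
            Z <- cbind(1, x)
            V <- solve(crossprod(Z) / sigma^2 + diag(1 / 100, 2L))
            mAB <- V %*% (crossprod(Z, y) / sigma^2)
            ab <- drop(mAB + t(chol(V)) %*% stats::rnorm(2L))
            alpha <- ab[1L]; beta <- ab[2L]
            # sigma_y: random walk on log scale, Half-Normal(5) prior
            lsig <- log(sigma)
            lprop <- lsig + stats::rnorm(1L, 0, set$proposalSd)
            sprop <- exp(lprop)
            resid <- y - alpha - beta * x
            logpost <- function(s, ls)
                sum(stats::dnorm(resid, 0, s, log = TRUE)) +
                    stats::dnorm(s, 0, 5, log = TRUE) + ls
            if (log(stats::runif(1L)) <
                logpost(sprop, lprop) - logpost(sigma, lsig))
                sigma <- sprop
            if (!is.finite(alpha + beta + sigma))
                stop("sampler produced non-finite values")
            if (it > set$burnin) {
                r <- beta * sdX / sqrt(beta^2 * varX + sigma^2)
                out[it - set$burnin, ] <- c(alpha, beta, sigma, r)
            }
        }
        out
    }
    chains <- lapply(seq_len(set$chains), function(ch) runChain(seed + ch))
    if (any(vapply(chains, function(ch) any(!is.finite(ch)), logical(1))))
        stop("MCMC chains contain non-finite draws")

    params <- colnames(chains[[1L]])
    rhat <- vapply(params, function(p)
        .splitRhat(lapply(chains, function(ch) ch[, p])), numeric(1))
    ess <- vapply(params, function(p)
        .splitEss(lapply(chains, function(ch) ch[, p])), numeric(1))
    draws <- do.call(rbind, chains)
    qs <- apply(draws, 2L, stats::quantile, c(0.025, 0.5, 0.975))
    summ <- data.frame(parameter = params, mean = colMeans(draws),
                       median = qs[2L, ], lower95 = qs[1L, ],
                       upper95 = qs[3L, ], rhat = rhat[params],
                       ess = ess[params])
    rownames(summ) <- NULL
    r <- draws[, "r"]
    tail <- 2 * min(mean(r > 0), mean(r < 0))
    obj <- new("BridgeResult", draws = draws, chains = set$chains,
               summary = summ, rhat = rhat, ess = ess, tailProb = tail,
               converged = all(rhat <= 1.05, na.rm = TRUE),
               settings = c(set, list(seed = seed, outcome = outcome,
                                      var_x = varX, n = nj)))
    validObject(obj)
    obj
}

# split-Rhat (each chain halved) per Gelman et al.
.splitRhat <- function(chainList) {
    halves <- unlist(lapply(chainList, function(v) {
        n2 <- floor(length(v) / 2)
        list(v[seq_len(n2)], v[seq_len(n2) + n2])
    }), recursive = FALSE)
    n <- length(halves[[1L]])
    m <- length(halves)
    means <- vapply(halves, mean, numeric(1))
    vars <- vapply(halves, stats::var, numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W < .Machine$double.eps) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size over split chains (paired-lag truncation)
.splitEss <- function(chainList) {
    halves <- unlist(lapply(chainList, function(v) {
        n2 <- floor(length(v) / 2)
        list(v[seq_len(n2)], v[seq_len(n2) + n2])
    }), recursive = FALSE)
    n <- length(halves[[1L]])
    m <- length(halves)
    means <- vapply(halves, mean, numeric(1))
    vars <- vapply(halves, stats::var, numeric(1))
    W <- mean(vars)
    varPlus <- (n - 1) / n * W + stats::var(means)
    if (varPlus < .Machine$double.eps) return(m * n)
    maxLag <- min(n - 1L, 1000L)
    acovs <- vapply(halves, function(v)
        stats::acf(v, lag.max = maxLag, type = "covariance",
                   plot = FALSE, demean = TRUE)$acf[, 1L, 1L],
        numeric(maxLag + 1L))
    rho <- 1 - (W - rowMeans(acovs)[-1L]) / varPlus
    # Geyer initial positive sequence on paired sums
    s <- 0
    t <- 1L
    while (t + 1L <= length(rho)) {
        pair <- rho[t] + rho[t + 1L]
        if (pair <= 0) break
        s <- s + pair
        t <- t + 2L
    }
    max(m * n / (1 + 2 * s), 1)
}
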