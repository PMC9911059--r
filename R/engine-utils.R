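#' Eigen-decomposition of a relationship kernel
#'
#' Decomposes a symmetric positive-definite kernel as K = V diag(d) V'
#' after adding a small diagonal jitter (1e-8 x mean diagonal) that
#' guards factorizations under near-duplicate genotypes.  All Gibbs
#' updates for kernel-structured effects work in this eigenbasis, where
#' the kernel is diagonal.
#'
#' @param K symmetric numeric matrix or a [TetraKinship-class].
#' @param jitter relative diagonal jitter (default 1e-8).
#' @return list with \code{vectors}, \code{values} (descending) and the
#'   jittered matrix \code{K}.
#' @export
eigenKernel <- function(K, jitter = 1e-8) {
    if (is(K, "TetraKinship")) K <- kinshipMatrix(K)
    if (!all(is.finite(K))) stop("kernel contains non-finite entries")
    K <- (K + t(K)) / 2
    diag(K) <- diag(K) + jitter * mean(diag(K))
    e <- eigen(K, symmetric = TRUE)
    if (min(e$values) <= 0)
        stop("kernel is not positive definite after jitter")
    list(vectors = e$vectors, values = e$values, K = K)
}

#' Inverse-Wishart sampler
#'
#' Draws from IW(df, S): if X ~ Wishart(df, S^{-1}) then X^{-1} ~
#' IW(df, S).  For dimension 1 this reduces to the scaled inverse
#' chi-squared distribution scale/chisq(df).
#'
#' @param df degrees of freedom (> d - 1).
#' @param S positive-definite scale matrix.
#' @return one draw, a d x d symmetric positive-definite matrix.
#' @export
rInvWishart <- function(df, S) {
    S <- as.matrix(S)
    d <- nrow(S)
    Sinv <- chol2inv(chol(S))
    W <- stats::rWishart(1L, df, Sinv)[, , 1L]
    out <- chol2inv(chol(W))
    (out + t(out)) / 2
}

# scaled-inverse-chi-squared: df * scale / chisq_df
rScaledInvChisq <- function(df, scale) df * scale / stats::rchisq(1L, df)

# Deterministic substream derivation from a master seed: keeps every
# derived seed a positive 32-bit integer so folds/chains are
# independent and replayable.
deriveSeed <- function(master, ...) {
    ks <- c(as.numeric(master), as.numeric(unlist(list(...))))
    s <- 0
    for (k in ks) s <- (s * 69069 + k + 1) %% 2147483647
    as.integer(s %% 2147483646) + 1L
}

# Split-chain potential scale reduction (Rhat) on a vector of retained
# draws; > ~1.1 suggests the chain has not mixed.
splitRhat <- function(x) {
    x <- x[is.finite(x)]
    n <- length(x)
    if (n < 8L) return(NA_real_)
    half <- floor(n / 2)
    chains <- cbind(x[seq_len(half)], x[(n - half + 1):n])
    m <- ncol(chains); nn <- nrow(chains)
    mu <- colMeans(chains)
    B <- nn * var(mu)
    Wv <- mean(apply(chains, 2L, var))
    if (Wv <= 0) return(1)
    sqrt(((nn - 1) / nn * Wv + B / nn) / Wv)
}

#' Default MCMC settings
#'
#' @param nIter total iterations (default 30000).
#' @param burnIn burn-in iterations discarded (default 5000).
#' @param thin thinning interval (default 5).
#' @param seed RNG seed for the chain.
#' @return a list of settings for [fitGEModel()].
#' @export
mcmcSettings <- function(nIter = 30000L, burnIn = 5000L, thin = 5L,
                         seed = 1L) {
    stopifnot(burnIn < nIter, thin >= 1L)
    list(nIter = as.integer(nIter), burnIn = as.integer(burnIn),
         thin = as.integer(thin), seed = as.integer(seed))
}

# Weakly-informative default priors.
# Scalar variances: scaled-inv-chisq(df = 5, scale s.t. prior mode =
# half the sample variance of the observed responses).
# Covariances: inverse-Wishart(df = d + 4,
# scale = 0.5 * sample covariance * (df - d - 1)).
priorScalar <- function(sampleVar) {
    df <- 5
    s <- max(sampleVar, 1e-8)
    list(df = df, scale = 0.5 * s * (df + 2) / df)
}

priorCovariance <- function(sampleCov) {
    d <- nrow(sampleCov)
    df <- d + 4
    S <- 0.5 * sampleCov * (df - d - 1)
    # keep the scale matrix safely positive definite
    S <- S + diag(1e-6 * mean(diag(sampleCov)) + 1e-10, d)
    list(df = df, S = S)
}

# Running mean/variance accumulator (Welford) for predictive summaries.
welfordInit <- function(n) list(n = 0L, mean = numeric(n), m2 = numeric(n))
welfordAdd <- function(w, x) {
    w$n <- w$n + 1L
    delta <- x - w$mean
    w$mean <- w$mean + delta / w$n
    w$m2 <- w$m2 + delta * (x - w$mean)
    w
}
welfordSd <- function(w) {
    if (w$n < 2L) rep(NA_real_, length(w$mean))
    else sqrt(w$m2 / (w$n - 1L))
}

# draw from MN(mean, I, Sigma) for a block of rows: mean + Z %*% chol(Sigma)
rMatrixRows <- function(mean, cholSigma) {
    n <- nrow(mean); t <- ncol(mean)
    mean + matrix(stats::rnorm(n * t), n, t) %*% cholSigma
}
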