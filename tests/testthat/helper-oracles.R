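# Independent oracles used across the suite.  These deliberately avoid
# the package's own linear-algebra shortcuts: the kinship oracle loops
# over the printed formulas term by term, the covariance oracle builds
# the marginal covariance entry by entry from the distributional
# statements, and the prediction oracle is a dense GLS + Gaussian
# conditioning solve.

# brute-force kinship: expand 5-class indicators and evaluate the two
# printed formulas column by column
bruteKinship <- function(dosageMatrix) {
    d <- dosageMatrix
    n <- nrow(d); S <- ncol(d)
    X <- matrix(0, n, 5 * S)
    for (j in seq_len(n)) for (s in seq_len(S))
        X[j, (s - 1) * 5 + d[j, s] + 1] <- 1
    p <- colMeans(X)
    keep <- which(p > 0 & p < 1)
    M <- length(keep)
    K <- matrix(0, n, n)
    for (j in seq_len(n)) for (k in seq_len(n)) {
        acc <- 0
        for (i in keep) {
            if (j == k)
                acc <- acc + (X[j, i]^2 - 2 * p[i] * X[j, i] + p[i]^2) /
                    (p[i] * (1 - p[i]))
            else
                acc <- acc + (X[j, i] - p[i]) * (X[k, i] - p[i]) /
                    (p[i] * (1 - p[i]))
        }
        K[j, k] <- acc / M + (j == k)
    }
    K
}

# entry-by-entry marginal covariance from each model's distributional
# statements, over records laid out env-major (and trait-major blocks
# for M4), all cultivars per environment
entrywiseCovariance <- function(model, K, m, pars, t = 1) {
    n <- nrow(K)
    N <- n * m
    rec <- expand.grid(line = seq_len(n), env = seq_len(m),
                       trait = seq_len(t))
    Ntot <- nrow(rec)
    C <- matrix(0, Ntot, Ntot)
    for (a in seq_len(Ntot)) for (b in seq_len(Ntot)) {
        j <- rec$line[a]; k <- rec$line[b]
        e <- rec$env[a];  f <- rec$env[b]
        u <- rec$trait[a]; v <- rec$trait[b]
        C[a, b] <- switch(model,
            M1 = pars$sigma2_g * K[j, k] +
                 pars$sigma2_ge * K[j, k] * (e == f) +
                 pars$sigma2_e * (a == b),
            M2 = pars$UE[e, f] * K[j, k] +
                 (a == b) * pars$sigma2[e],
            M3 = pars$UE[e, f] * K[j, k] +
                 pars$FE[e, f] * (j == k) +
                 (a == b) * pars$sigma2[e],
            M4 = pars$Ug[u, v] * K[j, k] +
                 pars$Uge[u, v] * K[j, k] * (e == f) +
                 pars$Sigma[u, v] * (j == k) * (e == f))
    }
    C
}

# GLS fixed-effect estimate plus Gaussian conditioning: the exact
# posterior predictive mean under clamped variances and flat priors on
# the group means
glsConditionalPredict <- function(C, X, y, observed) {
    o <- which(observed); p <- which(!observed)
    Ci <- solve(C[o, o])
    XtCi <- t(X[o, , drop = FALSE]) %*% Ci
    bhat <- solve(XtCi %*% X[o, , drop = FALSE], XtCi %*% y[o])
    drop(X[p, , drop = FALSE] %*% bhat +
         C[p, o] %*% Ci %*% (y[o] - X[o, , drop = FALSE] %*% bhat))
}

# random toy dosage panel; guarantees no SNP is entirely missing
randomPanel <- function(n, S, seed, missingRate = 0) {
    set.seed(seed)
    q <- runif(S, 0.1, 0.9)
    d <- matrix(rbinom(n * S, 4, rep(q, each = n)), n, S)
    if (missingRate > 0) {
        d[runif(n * S) < missingRate] <- NA
        allMiss <- colSums(!is.na(d)) == 0
        d[1, allMiss] <- 2
    }
    DosagePanel(d)
}

# balanced fully observed single/multi trait table on a grid
gridTable <- function(lines, envs, traits, values) {
    rec <- expand.grid(cultivar = lines, environment = envs,
                       trait = traits, stringsAsFactors = FALSE)
    rec$value <- values
    TrialTable(rec, environments = envs, traits = traits)
}

# align oracle predictions (in record order of `table`) to a
# predictions data.frame
alignOracle <- function(pred, records, maskedPos, oracleValues) {
    key <- paste(records$cultivar, records$environment, records$trait,
                 sep = "\r")[maskedPos]
    oracleValues[match(paste(pred$cultivar, pred$environment, pred$trait,
                             sep = "\r"), key)]
}

# correlation matrix with given pairwise correlations (lower triangle,
# (2,1), (3,1), (3,2) order)
corMatT <- function(m, pairCor) {
    S <- diag(m)
    S[lower.tri(S)] <- rep_len(pairCor, m * (m - 1L) / 2L)
    S[upper.tri(S)] <- t(S)[upper.tri(S)]
    S
}

# records of a table re-laid-out in oracle order: cultivar fastest,
# then environment, then trait (matching entrywiseCovariance /
# marginalCovariance row order)
oracleRecords <- function(table, lines, envs, traits) {
    rec <- expand.grid(cultivar = lines, environment = envs,
                       trait = traits, stringsAsFactors = FALSE)
    r <- tetraGP::trialRecords(table)
    key <- paste(r$cultivar, r$environment, r$trait, sep = "\r")
    i <- match(paste(rec$cultivar, rec$environment, rec$trait, sep = "\r"),
               key)
    rec$value <- r$value[i]
    rec$observed <- r$observed[i] & !is.na(r$value[i])
    rec
}

# design matrix of environment(-by-trait) means in record order
meanDesign <- function(records, envs, traits = NULL) {
    if (length(envs) == 1L && (is.null(traits) || length(traits) == 1L))
        matrix(1, nrow(records), 1L)
    else if (is.null(traits) || length(traits) == 1L)
        stats::model.matrix(~ 0 + factor(records$environment,
                                         levels = envs))
    else
        stats::model.matrix(~ 0 + interaction(
            factor(records$environment, levels = envs),
            factor(records$trait, levels = traits)))
}
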