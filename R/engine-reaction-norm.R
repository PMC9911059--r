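# Gibbs sampler for the reaction-norm family (models M1 and M4).
#
# Data layout: complete cultivar x environment x trait grid, held as an
# array Y of dim (nL, m, t) with NA for masked cells (imputed by data
# augmentation each sweep).  The model is
#   Y[, e, ] = mu[e, ] + Ag + Age[, e, ] + eps,   eps rows ~ N(0, Sigma)
# with Ag ~ MN(0, K, Ug) shared across environments and the interaction
# array Age separable over (K, E, Uge), E the environment relationship
# (identity by default, giving independent within-environment blocks).
# For a single trait this is the conventional reaction-norm model with
# scalar variances and homogeneous error; for t traits it is the
# multitrait G x E model with unstructured Ug, Uge and Sigma.
#
# All updates are conjugate and fully vectorized: cultivar structure is
# diagonalized once through the kernel eigenbasis, the environment
# relation through its own eigenbasis, and the trait dimension through
# joint diagonalization of the effect covariance against the residual
# covariance, so each sweep costs a handful of BLAS calls.

# joint diagonalization of prior covariance U against residual Sigma:
# returns forward map Tmat (apply to data rows), back map tLQ, and the
# diagonal prior variances dvals so that in the rotated basis the noise
# is white and the prior diagonal.
jointDiag <- function(U, cholSigma) {
    L <- t(cholSigma)                       # lower, Sigma = L L'
    A1 <- forwardsolve(L, U)
    B <- forwardsolve(L, t(A1))
    B <- (B + t(B)) / 2
    e <- eigen(B, symmetric = TRUE)
    d <- pmax(e$values, 0)
    Q <- e$vectors
    Tmat <- backsolve(t(L), Q)              # L^{-T} Q : forward transform
    tLQ <- t(L %*% Q)                       # back transform (right-multiply)
    list(Tmat = Tmat, tLQ = tLQ, d = d)
}

# rotate an (nL, m, t) array: rows by Vt, envs by P (right), traits by M
rotateArr <- function(arr, Vt = NULL, Pright = NULL, Mright = NULL) {
    dm <- dim(arr)
    nL <- dm[1L]; m <- dm[2L]; t <- dm[3L]
    if (!is.null(Vt))
        arr <- array(Vt %*% matrix(arr, nrow = nL), c(nL, m, t))
    if (!is.null(Mright)) {
        a2 <- aperm(arr, c(1L, 3L, 2L))     # (nL, t, m)
        a2 <- array(apply(a2, 3L, function(x) x %*% Mright), c(nL, t, m))
        arr <- aperm(a2, c(1L, 3L, 2L))
    }
    if (!is.null(Pright)) {
        a2 <- aperm(arr, c(1L, 3L, 2L))     # (nL, t, m): env last
        a2m <- matrix(a2, ncol = m) %*% Pright
        arr <- aperm(array(a2m, c(nL, t, m)), c(1L, 3L, 2L))
    }
    arr
}

gibbsReactionNorm <- function(Yobs, eig, settings, E = NULL, fixed = NULL,
                              trackExternal = FALSE) {
    nL <- dim(Yobs)[1L]; m <- dim(Yobs)[2L]; t <- dim(Yobs)[3L]
    V <- eig$vectors; Vt <- t(V); lam <- eig$values
    if (is.null(E)) E <- diag(m)
    eE <- eigen((E + t(E)) / 2, symmetric = TRUE)
    P <- eE$vectors; phi <- pmax(eE$values, 1e-12)
    obs <- !is.na(Yobs)
    nObsTot <- sum(obs)
    set.seed(settings$seed)

    # empirical moments of observed cells for priors / initialization
    obsVarTrait <- vapply(seq_len(t), function(j) {
        v <- Yobs[, , j][obs[, , j]]
        if (length(v) > 1) stats::var(v) else 1
    }, 0)
    obsVarTrait[!is.finite(obsVarTrait) | obsVarTrait <= 0] <- 1
    # identical weakly-informative priors for all three components:
    # mode at half the sample phenotypic (co)variance, so the split
    # between them is decided by the likelihood alone
    Spheno <- diag(obsVarTrait, t)
    prG <- priorCovariance(Spheno)
    prGE <- priorCovariance(Spheno)
    prS <- priorCovariance(Spheno)

    clamp <- !is.null(fixed)
    Ug  <- if (clamp) as.matrix(fixed$Ug)  else diag(obsVarTrait / 3, t)
    Uge <- if (clamp) as.matrix(fixed$Uge) else diag(obsVarTrait / 3, t)
    Sigma <- if (clamp) as.matrix(fixed$Sigma) else diag(obsVarTrait / 2, t)

    # initialize: masked cells at the env x trait mean of observed cells
    Yaug <- Yobs
    for (e in seq_len(m)) for (j in seq_len(t)) {
        v <- Yobs[, e, j]
        mn <- mean(v, na.rm = TRUE)
        if (!is.finite(mn)) mn <- mean(Yobs[, , j], na.rm = TRUE)
        if (!is.finite(mn)) mn <- 0
        Yaug[is.na(v), e, j] <- mn
    }
    mu <- matrix(0, m, t)
    for (e in seq_len(m))
        mu[e, ] <- colMeans(matrix(Yaug[, e, ], nL, t))
    Ag <- matrix(0, nL, t)
    Age <- array(0, c(nL, m, t))

    # missingness pattern groups per environment (fixed over the run)
    patGroups <- lapply(seq_len(m), function(e) {
        om <- matrix(obs[, e, ], nL, t)
        pat <- apply(!om, 1L, function(z) paste(as.integer(z), collapse = ""))
        rowsWithMiss <- which(rowSums(!om) > 0L)
        split(rowsWithMiss, pat[rowsWithMiss])
    })

    nKeep <- (settings$nIter - settings$burnIn) %/% settings$thin
    maskedIdx <- which(!obs)
    wMask <- welfordInit(length(maskedIdx))
    wMaskRB <- welfordInit(length(maskedIdx))
    wExt <- if (trackExternal) welfordInit(nL * t) else NULL
    wExtRB <- if (trackExternal) welfordInit(nL * t) else NULL
    varNames <- c(outer(seq_len(t), seq_len(t),
                        function(i, j) sprintf("Ug[%d,%d]", i, j))[lower.tri(diag(t), TRUE)],
                  outer(seq_len(t), seq_len(t),
                        function(i, j) sprintf("Uge[%d,%d]", i, j))[lower.tri(diag(t), TRUE)],
                  outer(seq_len(t), seq_len(t),
                        function(i, j) sprintf("Sigma[%d,%d]", i, j))[lower.tri(diag(t), TRUE)])
    varDraws <- matrix(NA_real_, nKeep, length(varNames),
                       dimnames = list(NULL, varNames))
    muSum <- matrix(0, m, t); AgSum <- matrix(0, nL, t)
    keep <- 0L
    ltri <- lower.tri(diag(t), TRUE)

    for (iter in seq_len(settings$nIter)) {
        cholS <- chol(Sigma)

        # --- environment(-trait) means, flat prior
        for (e in seq_len(m)) {
            Re <- matrix(Yaug[, e, ], nL, t) - Ag - matrix(Age[, e, ], nL, t)
            mu[e, ] <- colMeans(Re) +
                drop(matrix(stats::rnorm(t), 1L) %*% cholS) / sqrt(nL)
        }

        # --- genetic main effects Ag ~ MN(0, K, Ug)
        Rbar <- matrix(0, nL, t)
        for (e in seq_len(m))
            Rbar <- Rbar + matrix(Yaug[, e, ], nL, t) -
                matrix(Age[, e, ], nL, t) - matrix(mu[e, ], nL, t, byrow = TRUE)
        Rbar <- Rbar / m
        jd <- jointDiag(Ug, cholS)
        Smat <- (Vt %*% Rbar) %*% jd$Tmat
        pv <- outer(lam, jd$d)                       # prior variances
        Vpost <- 1 / (1 / pv + m)
        Bmean <- Vpost * (m * Smat)
        Bdraw <- Bmean + sqrt(Vpost) * matrix(stats::rnorm(nL * t), nL, t)
        Xg <- Bdraw %*% jd$tLQ
        Ag <- V %*% Xg
        AgCond <- V %*% (Bmean %*% jd$tLQ)   # Rao-Blackwellized mean

        # --- interaction effects Age separable over (K, E, Uge)
        Rarr <- Yaug
        for (e in seq_len(m))
            Rarr[, e, ] <- matrix(Yaug[, e, ], nL, t) - Ag -
                matrix(mu[e, ], nL, t, byrow = TRUE)
        jd2 <- jointDiag(Uge, cholS)
        Sarr <- rotateArr(Rarr, Vt = Vt, Pright = P, Mright = jd2$Tmat)
        pv2 <- outer(lam, outer(phi, jd2$d))         # (nL, m, t)
        Vp2 <- 1 / (1 / pv2 + 1)
        BarrMean <- Vp2 * Sarr
        Barr <- BarrMean +
            sqrt(Vp2) * array(stats::rnorm(nL * m * t), c(nL, m, t))
        # back-transform: traits, then envs, then rows
        Age <- rotateArr(rotateArr(Barr, Pright = t(P), Mright = jd2$tLQ),
                         Vt = V)
        AgeCond <- rotateArr(rotateArr(BarrMean, Pright = t(P),
                                       Mright = jd2$tLQ), Vt = V)

        # --- residuals & augmentation of masked cells
        Fit <- Age
        FitRB <- Age                    # low-noise predictor tracker
        for (e in seq_len(m)) {
            Fit[, e, ] <- matrix(Age[, e, ], nL, t) + Ag +
                matrix(mu[e, ], nL, t, byrow = TRUE)
            FitRB[, e, ] <- matrix(AgeCond[, e, ], nL, t) + AgCond +
                matrix(mu[e, ], nL, t, byrow = TRUE)
        }
        # masked-cell predictive means must include the residual's
        # cross-trait conditional mean for rows with observed traits
        Adj <- array(0, c(nL, m, t))
        for (e in seq_len(m)) {
            grp <- patGroups[[e]]
            if (!length(grp)) next
            Fe <- matrix(Fit[, e, ], nL, t)
            Ye <- matrix(Yaug[, e, ], nL, t)
            Ae <- matrix(0, nL, t)
            for (g in seq_along(grp)) {
                rows <- grp[[g]]
                miss <- as.logical(as.integer(strsplit(names(grp)[g],
                                                       "")[[1]]))
                if (all(miss)) {
                    Ye[rows, ] <- rMatrixRows(Fe[rows, , drop = FALSE], cholS)
                } else {
                    o <- which(!miss); mi <- which(miss)
                    Soo <- Sigma[o, o, drop = FALSE]
                    A <- Sigma[mi, o, drop = FALSE] %*% chol2inv(chol(Soo))
                    Cc <- Sigma[mi, mi, drop = FALSE] -
                        A %*% Sigma[o, mi, drop = FALSE]
                    Cc <- (Cc + t(Cc)) / 2
                    resCond <- (Ye[rows, o, drop = FALSE] -
                                Fe[rows, o, drop = FALSE]) %*% t(A)
                    mn <- Fe[rows, mi, drop = FALSE] + resCond
                    Ae[rows, mi] <- resCond
                    Ye[rows, mi] <- rMatrixRows(mn, chol(Cc))
                }
            }
            Yaug[, e, ] <- Ye
            Adj[, e, ] <- Ae
        }

        # --- (co)variance updates
        if (!clamp) {
            Sg <- crossprod(Xg, Xg / lam)
            Ug <- rInvWishart(prG$df + nL, prG$S + Sg)
            Xtil <- rotateArr(Age, Vt = Vt, Pright = P)
            w <- sqrt(1 / outer(lam, phi))           # (nL, m)
            Xm <- matrix(Xtil, nrow = nL * m) * as.vector(w)
            Sge <- crossprod(Xm)
            Uge <- rInvWishart(prGE$df + nL * m, prGE$S + Sge)
            SSE <- matrix(0, t, t)
            for (e in seq_len(m)) {
                Ee <- matrix(Yaug[, e, ], nL, t) - matrix(Fit[, e, ], nL, t)
                SSE <- SSE + crossprod(Ee)
            }
            Sigma <- rInvWishart(prS$df + nL * m, prS$S + SSE)
        }

        if (!all(is.finite(mu)) || !all(is.finite(Ag)))
            stop("sampler diverged (non-finite state) at iteration ", iter)

        # --- bookkeeping
        if (iter > settings$burnIn &&
            (iter - settings$burnIn) %% settings$thin == 0L) {
            keep <- keep + 1L
            varDraws[keep, ] <- c(Ug[ltri], Uge[ltri], Sigma[ltri])
            wMask <- welfordAdd(wMask, Fit[maskedIdx] + Adj[maskedIdx])
            wMaskRB <- welfordAdd(wMaskRB,
                                  FitRB[maskedIdx] + Adj[maskedIdx])
            if (trackExternal) {
                gm <- colMeans(mu)
                wExt <- welfordAdd(wExt,
                    as.vector(sweep(Ag, 2L, gm, "+")))
                wExtRB <- welfordAdd(wExtRB,
                    as.vector(sweep(AgCond, 2L, gm, "+")))
            }
            muSum <- muSum + mu
            AgSum <- AgSum + Ag
        }
    }

    rhat <- apply(varDraws, 2L, splitRhat)
    list(maskedIdx = maskedIdx, maskedMean = wMaskRB$mean,
         maskedSd = welfordSd(wMask),
         externalMean = if (trackExternal) matrix(wExtRB$mean, nL, t)
                        else NULL,
         externalSd = if (trackExternal) matrix(welfordSd(wExt), nL, t)
                      else NULL,
         varDraws = varDraws, muMean = muSum / max(keep, 1L),
         AgMean = AgSum / max(keep, 1L), rhat = rhat,
         nRetained = keep)
}
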