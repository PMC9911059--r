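# Gibbs sampler for the Kronecker-structured single-trait models
# (M2 and M3).
#
# Data layout: cultivar x environment matrix Y (nL x m) for one trait,
# NA cells imputed by data augmentation.  The model is
#   Y = 1 mu' + Au (+ F) + eps
# with Au ~ MN(0, K, UE): joint genomic main and G x E effects with an
# unstructured m x m environmental covariance UE ("Kronecker" because
# vec(Au) ~ N(0, UE x K)); optionally F ~ MN(0, I, FE), an
# identity-kernel environment-covariant effect capturing nonadditive
# variation not in K; and heteroscedastic residuals
# eps[, e] ~ N(0, sigma2[e]).
#
# Updates are conjugate: Au rows are diagonalized through the kernel
# eigenbasis and the environment dimension through joint
# diagonalization of UE (or FE) against diag(sigma2); UE and FE get
# inverse-Wishart updates, sigma2 per-environment scaled-inv-chisq.

gibbsKronecker <- function(Yobs, eig, settings, withF = FALSE,
                           fixed = NULL) {
    nL <- nrow(Yobs); m <- ncol(Yobs)
    V <- eig$vectors; Vt <- t(V); lam <- eig$values
    obs <- !is.na(Yobs)
    if (any(colSums(obs) == 0L))
        stop("an environment has no observed cells; the ",
             "environment-covariance models cannot predict full ",
             "environments")
    set.seed(settings$seed)

    envVar <- apply(Yobs, 2L, function(v) stats::var(v[!is.na(v)]))
    envVar[!is.finite(envVar) | envVar <= 0] <- 1
    # pairwise-complete phenotypic covariance between environments
    Sph <- stats::cov(Yobs, use = "pairwise.complete.obs")
    Sph[!is.finite(Sph)] <- 0
    diag(Sph) <- envVar
    ev <- eigen((Sph + t(Sph)) / 2, symmetric = TRUE, only.values = TRUE)
    if (min(ev$values) < 1e-8 * max(envVar))
        Sph <- Sph + diag(1e-6 + abs(min(ev$values)), m)
    # identical prior scaling for every covariance component (mean at
    # half the sample phenotypic covariance) and error-variance priors
    # with mode at half the sample variance
    prU <- priorCovariance(Sph)
    prF <- priorCovariance(Sph)
    prE <- lapply(envVar, function(v) priorScalar(v))

    clamp <- !is.null(fixed)
    UE <- if (clamp) as.matrix(fixed$UE) else diag(envVar / 2, m)
    FE <- if (clamp && withF) as.matrix(fixed$FE)
          else if (withF) diag(envVar / 4, m) else matrix(0, m, m)
    sig2 <- if (clamp) rep_len(fixed$sigma2, m) else envVar / 2

    Yaug <- Yobs
    for (e in seq_len(m))
        Yaug[is.na(Yobs[, e]), e] <- mean(Yobs[, e], na.rm = TRUE)
    mu <- colMeans(Yaug)
    Au <- matrix(0, nL, m)
    Fm <- matrix(0, nL, m)

    nKeep <- (settings$nIter - settings$burnIn) %/% settings$thin
    maskedIdx <- which(!obs)
    wMask <- welfordInit(length(maskedIdx))
    wMaskRB <- welfordInit(length(maskedIdx))
    varNames <- c(outer(seq_len(m), seq_len(m),
                        function(i, j) sprintf("UE[%d,%d]", i, j))[lower.tri(diag(m), TRUE)],
                  if (withF)
                      outer(seq_len(m), seq_len(m),
                            function(i, j) sprintf("FE[%d,%d]", i, j))[lower.tri(diag(m), TRUE)],
                  sprintf("sigma2[%d]", seq_len(m)))
    varDraws <- matrix(NA_real_, nKeep, length(varNames),
                       dimnames = list(NULL, varNames))
    muSum <- numeric(m); AuSum <- matrix(0, nL, m)
    keep <- 0L
    ltri <- lower.tri(diag(m), TRUE)

    for (iter in seq_len(settings$nIter)) {
        # --- environment means
        R0 <- Yaug - Au - Fm
        mu <- colMeans(R0) + stats::rnorm(m) * sqrt(sig2 / nL)

        # --- Au ~ MN(0, K, UE) against diag(sig2) noise
        R <- sweep(Yaug - Fm, 2L, mu, "-")
        sh <- sqrt(sig2)
        Bm <- (UE / sh) / rep(sh, each = m)          # D^{-1/2} UE D^{-1/2}
        Bm <- (Bm + t(Bm)) / 2
        eB <- eigen(Bm, symmetric = TRUE)
        d <- pmax(eB$values, 0); Q <- eB$vectors
        Tmat <- (1 / sh) * Q                         # D^{-1/2} Q
        Smat <- (Vt %*% R) %*% Tmat
        pv <- outer(lam, d)
        Vp <- 1 / (1 / pv + 1)
        Bmean <- Vp * Smat
        Bdraw <- Bmean + sqrt(Vp) * matrix(stats::rnorm(nL * m), nL, m)
        Xu <- Bdraw %*% t(sh * Q)                    # back: (D^{1/2} Q)'
        Au <- V %*% Xu
        AuCond <- V %*% (Bmean %*% t(sh * Q))   # Rao-Blackwellized mean

        # --- F ~ MN(0, I, FE), identity cultivar kernel
        if (withF) {
            R2 <- sweep(Yaug - Au, 2L, mu, "-")
            B2 <- (FE / sh) / rep(sh, each = m)
            B2 <- (B2 + t(B2)) / 2
            e2 <- eigen(B2, symmetric = TRUE)
            d2 <- pmax(e2$values, 0); Q2 <- e2$vectors
            S2 <- R2 %*% ((1 / sh) * Q2)
            v2 <- d2 / (d2 + 1)
            B2mean <- sweep(S2, 2L, v2, "*")
            B2draw <- B2mean +
                matrix(stats::rnorm(nL * m), nL, m) *
                    rep(sqrt(v2), each = nL)
            Fm <- B2draw %*% t(sh * Q2)
            FmCond <- B2mean %*% t(sh * Q2)
        } else FmCond <- Fm

        Fit <- sweep(Au + Fm, 2L, mu, "+")
        FitRB <- sweep(AuCond + FmCond, 2L, mu, "+")

        # --- augmentation (residuals independent given diagonal Sigma)
        for (e in seq_len(m)) {
            mi <- which(!obs[, e])
            if (length(mi))
                Yaug[mi, e] <- Fit[mi, e] +
                    stats::rnorm(length(mi)) * sqrt(sig2[e])
        }

        # --- (co)variance updates
        if (!clamp) {
            Xt <- Vt %*% Au
            SU <- crossprod(Xt / sqrt(lam))
            UE <- rInvWishart(prU$df + nL, prU$S + SU)
            if (withF)
                FE <- rInvWishart(prF$df + nL, prF$S + crossprod(Fm))
            Eres <- Yaug - Fit
            for (e in seq_len(m)) {
                sse <- sum(Eres[, e]^2)
                dfp <- prE[[e]]$df + nL
                sig2[e] <- rScaledInvChisq(dfp,
                    (prE[[e]]$df * prE[[e]]$scale + sse) / dfp)
            }
        }

        if (!all(is.finite(mu)) || !all(is.finite(Au)))
            stop("sampler diverged (non-finite state) at iteration ", iter)

        if (iter > settings$burnIn &&
            (iter - settings$burnIn) %% settings$thin == 0L) {
            keep <- keep + 1L
            varDraws[keep, ] <- c(UE[ltri], if (withF) FE[ltri], sig2)
            wMask <- welfordAdd(wMask, Fit[maskedIdx])
            wMaskRB <- welfordAdd(wMaskRB, FitRB[maskedIdx])
            muSum <- muSum + mu
            AuSum <- AuSum + Au
        }
    }

    rhat <- apply(varDraws, 2L, splitRhat)
    list(maskedIdx = maskedIdx, maskedMean = wMaskRB$mean,
         maskedSd = welfordSd(wMask), varDraws = varDraws,
         muMean = muSum / max(keep, 1L), AuMean = AuSum / max(keep, 1L),
         rhat = rhat, nRetained = keep)
}
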