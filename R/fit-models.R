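#' Fit a Bayesian genome-based G x E prediction model
#'
#' Fits one of four genomic prediction models for multi-environment
#' trials of a tetraploid crop, by Gibbs sampling:
#' \describe{
#'   \item{M1}{single-trait reaction-norm model
#'     \eqn{y = Z_E \mu_E + g + ge + \epsilon} with
#'     \eqn{g \sim N(0, \sigma_g^2 Z_g K Z_g')}, interaction
#'     \eqn{ge \sim N(0, \sigma_{ge}^2\, Z_g K Z_g' \# Z_E E Z_E')}
#'     (Hadamard product; E defaults to the identity so interaction
#'     effects are independent between environments) and homogeneous
#'     error variance.}
#'   \item{M2}{single-trait model
#'     \eqn{y = Z_E \mu_E + u + \epsilon} with
#'     \eqn{u \sim N(0, U_E \otimes K)}, an unstructured m x m genomic
#'     covariance between environments, and heteroscedastic
#'     per-environment error variances (diagonal \eqn{\Sigma}).}
#'   \item{M3}{M2 plus an extra independent random vector
#'     \eqn{f \sim N(0, F_E \otimes I)} whose cultivar kernel is the
#'     identity, capturing environment-covariant nonadditive variation
#'     not represented in K.}
#'   \item{M4}{multitrait multi-environment model
#'     \eqn{Y = 1\mu' + Z_E \mu_E + g + ge + \epsilon} with
#'     matrix-normal effects \eqn{g \sim MN(0, Z_g K Z_g', U_g)},
#'     \eqn{ge \sim MN(0, Z_g K Z_g' \# Z_E Z_E', U_{ge})} and
#'     \eqn{\epsilon \sim MN(0, I, \Sigma_t)}, the three t x t trait
#'     covariances sampled unstructured.}
#' }
#'
#' Masked cells of the trial table are imputed by data augmentation,
#' which is what lets the models predict different numbers of cultivars
#' in different environments (and, for M4, cultivars observed for some
#' traits but masked for others).  Environments with no observed cell
#' at all are dropped from the sampling grid under M1/M4 and predicted
#' by the grand-mean convention (mean of the observed-environment means
#' plus the genomic main effect); M2/M3 reject them, since the
#' corresponding rows of the environmental covariance cannot be
#' estimated.  The global intercept of M4 is absorbed into the
#' environment means during sampling and reported separately as their
#' average.
#'
#' @param table a [TrialTable-class].
#' @param kinship a [TetraKinship-class] (or plain symmetric matrix)
#'   covering every cultivar of the table.
#' @param model "M1", "M2", "M3" (single trait) or "M4" (multitrait).
#' @param traits traits to fit; defaults to all traits of the table.
#'   M1-M3 require exactly one, M4 at least two.
#' @param settings MCMC settings from [mcmcSettings()].
#' @param environmentRelation optional m x m environment relationship
#'   matrix E for the M1/M4 interaction kernel (default identity),
#'   rows/columns ordered as the table's environments.
#' @param fixedVariances optional named list clamping all (co)variance
#'   parameters (no variance updates): for M1
#'   \code{list(sigma2_g, sigma2_ge, sigma2_e)}; for M2
#'   \code{list(UE, sigma2)}; for M3 additionally \code{FE}; for M4
#'   \code{list(Ug, Uge, Sigma)}.
#' @param rhatThreshold split-chain potential-scale-reduction threshold
#'   above which a convergence warning (not an error) is raised.
#'
#' @return a [GEModelFit-class] with predictions for every masked cell.
#' @examples
#' set.seed(1)
#' panel <- simulateDosages(scenarioConfig(nCultivars = 30, nSnps = 80))
#' K <- tetraKinship(panel)
#' sim <- simulateTrial(panel, scenarioConfig(nCultivars = 30,
#'     nEnvironments = 2, nTraits = 1, model = "M1"))
#' tt <- maskCells(sim$table, data.frame(cultivar = cultivarIds(K)[1:5],
#'     environment = environmentNames(sim$table)[2],
#'     trait = traitNames(sim$table)[1]))
#' fit <- fitGEModel(tt, K, "M1", settings = mcmcSettings(300, 100, 2))
#' head(predictions(fit))
#' @export
fitGEModel <- function(table, kinship, model = c("M1", "M2", "M3", "M4"),
                       traits = NULL, settings = mcmcSettings(),
                       environmentRelation = NULL, fixedVariances = NULL,
                       rhatThreshold = 1.1) {
    model <- match.arg(model)
    stopifnot(is(table, "TrialTable"))
    if (is.matrix(kinship))
        kinship <- new("TetraKinship", K = kinship, nMarkersUsed = NA_integer_)
    if (is.null(traits)) traits <- traitNames(table)
    if (model %in% c("M1", "M2", "M3") && length(traits) != 1L)
        stop(model, " is a single-trait model; select exactly one trait")
    if (model == "M4" && length(traits) < 2L)
        stop("M4 is a multitrait model and requires at least 2 traits")

    r <- trialRecords(table)
    r <- r[r$trait %in% traits, , drop = FALSE]
    if (!nrow(r)) stop("no records for the requested traits")
    lines <- sort(unique(r$cultivar))
    kin <- subsetKinship(kinship, lines)
    envs <- environmentNames(table)
    envs <- envs[envs %in% unique(r$environment)]
    m <- length(envs); t <- length(traits); nL <- length(lines)
    if (model == "M1" && m < 2L)
        stop("M1 needs at least 2 environments (the interaction term is ",
             "inestimable in a single environment)")
    if (!any(r$observed)) stop("no observed responses")

    # complete grid as an (nL, m, t) array
    Y <- array(NA_real_, c(nL, m, t), dimnames = list(lines, envs, traits))
    obsRec <- r[r$observed, , drop = FALSE]
    Y[cbind(match(obsRec$cultivar, lines), match(obsRec$environment, envs),
            match(obsRec$trait, traits))] <- obsRec$value

    obsPerEnv <- apply(!is.na(Y), 2L, sum)
    obsPerTrait <- apply(!is.na(Y), 3L, sum)
    if (any(obsPerTrait == 0L))
        stop("trait(s) with no observed cells: ",
             paste(traits[obsPerTrait == 0L], collapse = ", "))
    emptyEnvs <- envs[obsPerEnv == 0L]
    if (model %in% c("M2", "M3") && length(emptyEnvs))
        stop("environment(s) with no observed cells: ",
             paste(emptyEnvs, collapse = ", "),
             "; ", model, " cannot predict full environments because ",
             "their environmental covariances are inestimable")
    fitEnvs <- setdiff(envs, emptyEnvs)

    eig <- eigenKernel(kin)
    fixed <- canonicalFixed(model, fixedVariances, t)

    if (model %in% c("M1", "M4")) {
        E <- environmentRelation
        if (!is.null(E)) {
            E <- as.matrix(E)
            if (!identical(dim(E), c(m, m)))
                stop("environmentRelation must be ", m, " x ", m)
            E <- E[match(fitEnvs, envs), match(fitEnvs, envs), drop = FALSE]
        }
        Yfit <- Y[, match(fitEnvs, envs), , drop = FALSE]
        res <- gibbsReactionNorm(Yfit, eig, settings, E = E, fixed = fixed,
                                 trackExternal = length(emptyEnvs) > 0L)
        pred <- predFromArray(res, lines, fitEnvs, traits)
        if (length(emptyEnvs)) {
            ext <- expand.grid(cultivar = lines, environment = emptyEnvs,
                               trait = traits, stringsAsFactors = FALSE)
            li <- match(ext$cultivar, lines)
            tj <- match(ext$trait, traits)
            ext$predictive_mean <- res$externalMean[cbind(li, tj)]
            ext$predictive_sd <- res$externalSd[cbind(li, tj)]
            pred <- rbind(pred, ext)
        }
        post <- list(varDraws = res$varDraws, muMean = res$muMean,
                     geneticMean = res$AgMean, nRetained = res$nRetained)
        rhat <- res$rhat
        if (model == "M1") {
            colnames(post$varDraws) <-
                c("sigma2_g", "sigma2_ge", "sigma2_e")
            names(rhat) <- colnames(post$varDraws)
        }
        if (model == "M4")
            post$traitMeans <- colMeans(res$muMean)
    } else {
        res <- gibbsKronecker(matrix(Y[, , 1L], nL, m), eig, settings,
                              withF = model == "M3", fixed = fixed)
        pred <- predFromMatrix(res, lines, envs, traits)
        post <- list(varDraws = res$varDraws, muMean = res$muMean,
                     geneticMean = res$AuMean, nRetained = res$nRetained)
        rhat <- res$rhat
    }

    # keep only cells that are masked records of the (completed) table
    maskKey <- {
        rAll <- trialRecords(completeGrid(table))
        rAll <- rAll[rAll$trait %in% traits & !rAll$observed, , drop = FALSE]
        paste(rAll$cultivar, rAll$environment, rAll$trait, sep = "\r")
    }
    pkey <- paste(pred$cultivar, pred$environment, pred$trait, sep = "\r")
    pred <- pred[pkey %in% maskKey, , drop = FALSE]
    rownames(pred) <- NULL

    conv <- rhat
    if (any(is.finite(conv) & conv > rhatThreshold))
        warning("possible non-convergence (split-Rhat > ", rhatThreshold,
                ") for: ",
                paste(names(conv)[is.finite(conv) & conv > rhatThreshold],
                      collapse = ", "))

    new("GEModelFit", model = model, traits = traits, environments = envs,
        predictions = pred, posterior = post,
        settings = settings, convergence = conv)
}

# map user-facing clamped-variance names onto engine-internal ones
canonicalFixed <- function(model, fv, t) {
    if (is.null(fv)) return(NULL)
    switch(model,
        M1 = list(Ug = matrix(fv$sigma2_g, 1, 1),
                  Uge = matrix(fv$sigma2_ge, 1, 1),
                  Sigma = matrix(fv$sigma2_e, 1, 1)),
        M4 = list(Ug = as.matrix(fv$Ug), Uge = as.matrix(fv$Uge),
                  Sigma = as.matrix(fv$Sigma)),
        M2 = list(UE = as.matrix(fv$UE), sigma2 = fv$sigma2),
        M3 = list(UE = as.matrix(fv$UE), sigma2 = fv$sigma2,
                  FE = as.matrix(fv$FE)))
}

predFromArray <- function(res, lines, envs, traits) {
    nL <- length(lines); m <- length(envs); t <- length(traits)
    idx <- arrayInd(res$maskedIdx, c(nL, m, t))
    data.frame(cultivar = lines[idx[, 1L]], environment = envs[idx[, 2L]],
               trait = traits[idx[, 3L]],
               predictive_mean = res$maskedMean,
               predictive_sd = res$maskedSd)
}

predFromMatrix <- function(res, lines, envs, traits) {
    idx <- arrayInd(res$maskedIdx, c(length(lines), length(envs)))
    data.frame(cultivar = lines[idx[, 1L]], environment = envs[idx[, 2L]],
               trait = rep(traits[1L], nrow(idx)),
               predictive_mean = res$maskedMean,
               predictive_sd = res$maskedSd)
}

#' @rdname predictions
#' @export
setMethod("predictions", "GEModelFit", function(object) object@predictions)

#' @rdname posteriorSummary
#' @export
setMethod("posteriorSummary", "GEModelFit", function(object) {
    vd <- object@posterior$varDraws
    list(model = object@model,
         variance = data.frame(parameter = colnames(vd),
                               mean = colMeans(vd),
                               sd = apply(vd, 2L, stats::sd),
                               rhat = object@convergence,
                               row.names = NULL),
         environmentMeans = object@posterior$muMean,
         nRetained = object@posterior$nRetained)
})

setMethod("show", "GEModelFit", function(object) {
    cat("GEModelFit:", object@model, "|",
        length(object@traits), "trait(s),",
        length(object@environments), "environment(s)\n")
    cat("  retained draws:", object@posterior$nRetained,
        "| masked cells predicted:", nrow(object@predictions), "\n")
    vd <- object@posterior$varDraws
    vs <- colMeans(vd)
    cat("  posterior mean (co)variances:\n")
    print(round(vs, 4))
})

#' Marginal phenotypic covariance implied by a model
#'
#' Assembles the full marginal covariance matrix of the stacked
#' response vector implied by each model's distributional assumptions,
#' for a balanced grid in canonical order (environment-major for
#' M1-M3; for M4, trait-major blocks of environment-major cells, i.e.
#' the covariance of \code{vec(Y)}).  Intended for small instances:
#' the Hadamard (M1) and Kronecker (M2) forms can be compared directly,
#' and clamped-variance Gibbs predictions can be checked against exact
#' Gaussian conditioning on this matrix.
#'
#' @param model "M1", "M2", "M3" or "M4".
#' @param K cultivar relationship matrix (n x n) or [TetraKinship-class].
#' @param nEnv number of environments m.
#' @param params named list of the model's (co)variance parameters, as
#'   in the \code{fixedVariances} argument of [fitGEModel()].
#' @param E optional environment relationship for the M1/M4 interaction
#'   kernel (default identity).
#' @return a covariance matrix of order n*m (times t for M4).
#' @export
marginalCovariance <- function(model = c("M1", "M2", "M3", "M4"), K, nEnv,
                               params, E = NULL) {
    model <- match.arg(model)
    if (is(K, "TetraKinship")) K <- kinshipMatrix(K)
    n <- nrow(K); m <- nEnv
    if (is.null(E)) E <- diag(m)
    J <- matrix(1, m, m)
    switch(model,
        M1 = params$sigma2_g * kronecker(J, K) +
             params$sigma2_ge * kronecker(E, K) +
             params$sigma2_e * diag(n * m),
        M2 = kronecker(as.matrix(params$UE), K) +
             kronecker(diag(rep_len(params$sigma2, m), m), diag(n)),
        M3 = kronecker(as.matrix(params$UE), K) +
             kronecker(as.matrix(params$FE), diag(n)) +
             kronecker(diag(rep_len(params$sigma2, m), m), diag(n)),
        M4 = kronecker(as.matrix(params$Ug), kronecker(J, K)) +
             kronecker(as.matrix(params$Uge), kronecker(E, K)) +
             kronecker(as.matrix(params$Sigma), diag(n * m)))
}
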