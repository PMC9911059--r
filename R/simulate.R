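#' Scenario configuration for the synthetic trial generator
#'
#' Describes a synthetic multi-environment potato-style trial: panel
#' dimensions, environment and trait inventories, the generative model
#' and its true (co)variance parameters.  The default emulates the
#' structure of a Nordic potato testing program: 253 cultivars
#' genotyped at 2,000 SNPs and phenotyped for 7 traits in 3 locations
#' over 2 years (6 location-year environments), with per-trait
#' between-environment genetic correlations spanning high (0.85),
#' moderate (0.5) and near-zero/negative (-0.1) regimes and
#' heritability about 0.5.
#'
#' @param nCultivars,nSnps panel dimensions.
#' @param nLocations,nYears used to label default environments
#'   (LOC1Y1 style) when \code{environments} is not given.
#' @param nEnvironments number of environments (default
#'   \code{nLocations * nYears}).
#' @param nTraits number of traits.
#' @param environments,traits optional explicit labels.
#' @param model generative structure: \code{"M1"}, \code{"M2"},
#'   \code{"M3"}, \code{"M4"} (each trait or trait set drawn from that
#'   model's own equations) or \code{"study"} (per-trait environmental
#'   covariances plus cross-trait genetic correlation).
#' @param truth named list of true parameters; missing entries get
#'   model-specific defaults (see Details).
#' @param missingRate genotype missing-call rate for
#'   [simulateDosages()].
#' @param alleleFreqShape Beta shape parameters for the B-allele
#'   frequency distribution (default Beta(2, 2)).
#' @param mafBound allele-frequency truncation bound (default 0.05,
#'   echoing a MAF > 0.05 marker filter).
#' @param nFamilies 0 (default) for an unstructured random-mating
#'   panel; a positive value groups cultivars into that many full-sib
#'   families (two random-mating parents each, tetrasomic bivalent
#'   gametes), giving the panel the relatedness structure of a
#'   breeding program.
#' @param seed default seed used by the generators.
#'
#' @details Default truth values: M1 uses
#'   \code{sigma2_g = 1, sigma2_ge = 0.5, sigma2_e = 0.5}; M2/M3 use a
#'   unit-variance \code{UE} with correlations 0.8/0.5/0.2 and
#'   per-environment error variances 0.5/1.0/1.5 (recycled), M3 adding
#'   \code{FE} with correlation 0.6 and variance 0.5; M4 uses
#'   compound-symmetric trait covariances \code{Ug} (variance 1,
#'   correlation 0.5), \code{Uge} (variance 0.5, correlation 0.2) and
#'   diagonal \code{Sigma} (variance 1).  The \code{"study"} model uses
#'   per-trait environment correlations
#'   (0.5, 0.2, -0.1, 0.5, 0.5, 0.85, 0.35 recycled over traits),
#'   cross-trait genetic correlation 0.5, genetic variance 1 and
#'   environment error-variance scales spread around 1.
#'
#' @return a list of class \code{ScenarioConfig}.
#' @seealso [defaultStudyScenario()], [simulateDosages()],
#'   [simulateTrial()]
#' @export
scenarioConfig <- function(nCultivars = 253L, nSnps = 2000L,
                           nLocations = 3L, nYears = 2L,
                           nEnvironments = NULL, nTraits = 7L,
                           environments = NULL, traits = NULL,
                           model = c("study", "M1", "M2", "M3", "M4"),
                           truth = list(), missingRate = 0,
                           alleleFreqShape = c(2, 2), mafBound = 0.05,
                           nFamilies = 0L, seed = 1L) {
    model <- match.arg(model)
    if (is.null(environments)) {
        if (is.null(nEnvironments)) nEnvironments <- nLocations * nYears
        environments <- if (nEnvironments == nLocations * nYears)
            as.vector(outer(sprintf("LOC%d", seq_len(nLocations)),
                            sprintf("Y%d", seq_len(nYears)), paste0))
        else sprintf("ENV%d", seq_len(nEnvironments))
    }
    m <- length(environments)
    if (is.null(traits))
        traits <- sprintf("trait%d", seq_len(nTraits))
    t <- length(traits)
    truth <- fillTruth(model, truth, m, t)
    cfg <- list(nCultivars = as.integer(nCultivars),
                nSnps = as.integer(nSnps),
                environments = environments, traits = traits,
                model = model, truth = truth,
                missingRate = missingRate,
                alleleFreqShape = alleleFreqShape, mafBound = mafBound,
                nFamilies = as.integer(nFamilies),
                seed = as.integer(seed))
    class(cfg) <- "ScenarioConfig"
    cfg
}

compoundSym <- function(d, variance, correlation) {
    S <- matrix(variance * correlation, d, d)
    diag(S) <- variance
    S
}

fillTruth <- function(model, truth, m, t) {
    dft <- switch(model,
        M1 = list(sigma2_g = 1, sigma2_ge = 0.5, sigma2_e = 0.5),
        M2 = list(UE = corMat(m, c(0.8, 0.5, 0.2)),
                  sigma2 = rep_len(c(0.5, 1.0, 1.5), m)),
        M3 = list(UE = corMat(m, c(0.8, 0.5, 0.2)),
                  sigma2 = rep_len(c(0.5, 1.0, 1.5), m),
                  FE = compoundSym(m, 0.5, 0.6)),
        M4 = list(Ug = compoundSym(t, 1, 0.5),
                  Uge = compoundSym(t, 0.5, 0.2),
                  Sigma = diag(1, t)),
        study = list(
            envCorrByTrait = rep_len(c(0.5, 0.2, -0.1, 0.5, 0.5, 0.85,
                                       0.35), t),
            traitCor = 0.5, geneticVar = rep_len(1, t),
            errorVar = rep_len(1, t),
            envErrorScale = rep_len(seq(0.8, 1.2,
                                        length.out = max(m, 2L)), m)))
    for (nm in names(dft)) if (is.null(truth[[nm]])) truth[[nm]] <- dft[[nm]]
    for (nm in c("UE", "FE", "Ug", "Uge", "Sigma")) {
        if (!is.null(truth[[nm]])) {
            S <- as.matrix(truth[[nm]])
            if (min(eigen(S, symmetric = TRUE,
                          only.values = TRUE)$values) <= 0)
                stop("truth covariance ", nm, " is not positive definite")
            truth[[nm]] <- S
        }
    }
    truth
}

# correlation matrix with distinct pairwise correlations, recycled over
# the lower triangle in (2,1), (3,1), (3,2), ... order
corMat <- function(m, pairCor) {
    S <- diag(m)
    S[lower.tri(S)] <- rep_len(pairCor, m * (m - 1L) / 2L)
    S[upper.tri(S)] <- t(S)[upper.tri(S)]
    ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-8) S <- (S + diag(m) * (abs(ev) + 1e-6)) / (1 + abs(ev))
    S
}

#' The default study-structured scenario
#'
#' Returns the 253-cultivar, 2,000-SNP configuration with the 3
#' locations x 2 years environment inventory (HEL2020 ... UM2021) and
#' the seven tuber traits (five weight classes, starch, sugar).
#'
#' @param ... overrides passed to [scenarioConfig()].
#' @return a \code{ScenarioConfig}.
#' @export
defaultStudyScenario <- function(...) {
    args <- list(
        nCultivars = 253L, nSnps = 2000L,
        environments = c("HEL2020", "MOS2020", "UM2020",
                         "HEL2021", "MOS2021", "UM2021"),
        traits = c("<40 mm", "40-50 mm", "50-60 mm", ">60 mm",
                   "Total", "Starch", "Sugar"),
        model = "study")
    over <- list(...)
    args[names(over)] <- over
    do.call(scenarioConfig, args)
}

#' Simulate a tetraploid SNP dosage panel
#'
#' Per SNP a B-allele frequency q is drawn from a Beta distribution
#' truncated to [mafBound, 1 - mafBound]; each cultivar's dosage is
#' then Binomial(4, q) -- tetrasomic random mating (polysomic
#' Hardy-Weinberg).  Optional missing calls are placed uniformly at
#' random.
#'
#' @param config a \code{ScenarioConfig}.
#' @param seed RNG seed (default: the config's).
#' @return a [DosagePanel-class].
#' @export
simulateDosages <- function(config, seed = config$seed) {
    stopifnot(inherits(config, "ScenarioConfig"))
    set.seed(seed)
    n <- config$nCultivars; S <- config$nSnps
    sh <- config$alleleFreqShape
    lo <- stats::pbeta(config$mafBound, sh[1], sh[2])
    hi <- stats::pbeta(1 - config$mafBound, sh[1], sh[2])
    q <- stats::qbeta(stats::runif(S, lo, hi), sh[1], sh[2])
    nFam <- config$nFamilies
    if (is.null(nFam) || nFam < 1L) {
        d <- matrix(stats::rbinom(n * S, 4L, rep(q, each = n)), n, S)
    } else {
        # full-sib families: two HWE parents per family, each offspring
        # the sum of two bivalent gametes (2 of the parent's 4 alleles,
        # drawn without replacement)
        fam <- sort(rep_len(seq_len(nFam), n))
        gamete <- function(par) {
            # par: vector of parental dosages; returns gamete B-counts
            v <- integer(length(par))
            for (dd in 1:4) {
                i <- which(par == dd)
                if (length(i))
                    v[i] <- stats::rhyper(length(i), dd, 4L - dd, 2L)
            }
            v
        }
        d <- matrix(0L, n, S)
        for (f in seq_len(nFam)) {
            rows <- which(fam == f)
            p1 <- stats::rbinom(S, 4L, q)
            p2 <- stats::rbinom(S, 4L, q)
            for (r in rows)
                d[r, ] <- gamete(p1) + gamete(p2)
        }
    }
    if (config$missingRate > 0)
        d[stats::runif(n * S) < config$missingRate] <- NA_integer_
    dimnames(d) <- list(sprintf("G%03d", seq_len(n)),
                        sprintf("snp%d", seq_len(S)))
    DosagePanel(d)
}

#' Simulate a multi-environment trial with known truth
#'
#' Draws phenotypes from the exact generative equations of the chosen
#' model, using the full-tetrasomic kinship computed from the panel, so
#' every fitted model can be checked against recorded truth.
#'
#' For \code{model = "study"} each trait k has its own
#' between-environment genetic covariance (compound-symmetric with the
#' trait's correlation regime), traits share a cross-trait genetic
#' correlation, and error variances are heteroscedastic across
#' environments; the implied between-environment phenotypic correlation
#' for trait k and environments e, f is
#' \eqn{\bar K U_k[e,f] / \sqrt{(\bar K U_k[e,e] + v_e)(\bar K U_k[f,f] + v_f)}}
#' with \eqn{\bar K} the mean kinship diagonal.
#'
#' @param panel a [DosagePanel-class].
#' @param config a \code{ScenarioConfig}.
#' @param seed RNG seed (default: the config's, advanced by one so the
#'   panel and the trial use distinct streams).
#' @param kinship optional precomputed [TetraKinship-class] for the
#'   panel.
#' @return list with \code{table} (a fully observed [TrialTable-class])
#'   and \code{truth} (true parameters, true genetic values, seed).
#' @export
simulateTrial <- function(panel, config, seed = config$seed + 1L,
                          kinship = NULL) {
    stopifnot(inherits(config, "ScenarioConfig"))
    if (is.null(kinship)) kinship <- tetraKinship(panel)
    K <- kinshipMatrix(kinship)
    lines <- rownames(K)
    n <- length(lines)
    envs <- config$environments; m <- length(envs)
    traits <- config$traits; t <- length(traits)
    tr <- config$truth
    set.seed(seed)
    e <- eigen(K, symmetric = TRUE)
    Ksqrt <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))

    Yg <- array(0, c(n, m, t))      # genetic values (all genetic terms)
    Y <- array(0, c(n, m, t))
    if (config$model == "M1") {
        for (j in seq_len(t)) {
            g <- sqrt(tr$sigma2_g) * (Ksqrt %*% stats::rnorm(n))
            for (eI in seq_len(m)) {
                ge <- sqrt(tr$sigma2_ge) * (Ksqrt %*% stats::rnorm(n))
                Yg[, eI, j] <- g + ge
                Y[, eI, j] <- Yg[, eI, j] +
                    stats::rnorm(n, 0, sqrt(tr$sigma2_e))
            }
        }
    } else if (config$model %in% c("M2", "M3")) {
        Lu <- t(chol(tr$UE))
        for (j in seq_len(t)) {
            A <- Ksqrt %*% matrix(stats::rnorm(n * m), n, m) %*% t(Lu)
            if (config$model == "M3")
                A <- A + matrix(stats::rnorm(n * m), n, m) %*%
                    chol(tr$FE)
            Yg[, , j] <- A
            Y[, , j] <- A + matrix(stats::rnorm(n * m), n, m) *
                rep(sqrt(rep_len(tr$sigma2, m)), each = n)
        }
    } else if (config$model == "M4") {
        G <- Ksqrt %*% matrix(stats::rnorm(n * t), n, t) %*% chol(tr$Ug)
        cholSig <- chol(tr$Sigma)
        for (eI in seq_len(m)) {
            GE <- Ksqrt %*% matrix(stats::rnorm(n * t), n, t) %*%
                chol(tr$Uge)
            Yg[, eI, ] <- G + GE
            Y[, eI, ] <- Yg[, eI, ] +
                matrix(stats::rnorm(n * t), n, t) %*% cholSig
        }
    } else {                       # "study"
        Ct <- compoundSym(t, 1, tr$traitCor)
        cholCt <- chol(Ct)
        UEk <- lapply(seq_len(t), function(j)
            compoundSym(m, tr$geneticVar[j], tr$envCorrByTrait[j]))
        Z <- array(stats::rnorm(n * m * t), c(n, m, t))
        Z <- array(Ksqrt %*% matrix(Z, n), c(n, m, t))
        for (eI in seq_len(m))
            Z[, eI, ] <- matrix(Z[, eI, ], n, t) %*% cholCt
        for (j in seq_len(t)) {
            Lk <- t(chol(UEk[[j]]))
            Yg[, , j] <- matrix(Z[, , j], n, m) %*% t(Lk)
            sdE <- sqrt(tr$errorVar[j] * rep_len(tr$envErrorScale, m))
            Y[, , j] <- Yg[, , j] +
                matrix(stats::rnorm(n * m), n, m) *
                    rep(sdE, each = n)
        }
        tr$UEk <- UEk
        tr$meanKinshipDiag <- mean(diag(K))
    }

    recs <- expand.grid(cultivar = lines, environment = envs,
                        trait = traits, stringsAsFactors = FALSE)
    recs$value <- as.vector(Y)
    tbl <- TrialTable(recs, environments = envs, traits = traits)
    list(table = tbl,
         truth = c(tr, list(geneticValues = Yg, seed = seed,
                            model = config$model)))
}
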