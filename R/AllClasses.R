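#' @import methods
#' @importFrom stats cor rchisq rnorm runif rWishart sd var quantile setNames aggregate complete.cases cov
#' @importFrom utils read.csv write.csv packageVersion
#' @importFrom tools md5sum
NULL

#' Tetraploid SNP dosage panel
#'
#' Container for a cultivar-by-SNP matrix of tetraploid allele dosages.
#' Each entry counts copies of the B allele in a tetrasomic genotype and
#' must lie in \{0, 1, 2, 3, 4\}; \code{NA} marks a missing genotype call.
#' Row names are cultivar identifiers, column names are SNP identifiers.
#'
#' @slot dosages integer matrix (cultivars x SNPs) with values 0-4 or NA.
#'
#' @seealso [DosagePanel()], [tetraKinship()], [simulateDosages()]
#' @exportClass DosagePanel
setClass("DosagePanel", representation(dosages = "matrix"))

setValidity("DosagePanel", function(object) {
    d <- object@dosages
    msg <- character()
    if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
        msg <- c(msg, "cultivar ids (rownames) must be present and unique")
    if (nrow(d) < 2L)
        msg <- c(msg, "a panel needs at least 2 cultivars")
    v <- d[!is.na(d)]
    if (length(v) && (any(v != round(v)) || any(v < 0) || any(v > 4)))
        msg <- c(msg, "non-missing dosages must be integers in [0, 4]")
    if (length(msg)) msg else TRUE
})

#' Tetrasomic genomic relationship matrix
#'
#' Symmetric positive-definite cultivar-by-cultivar relationship matrix
#' built from the five-class genotype indicator coding.  The diagonal is
#' \eqn{\ge 1} by construction (a normalized Gram matrix plus the
#' identity), which keeps the matrix positive definite.
#'
#' @slot K symmetric numeric matrix with cultivar ids as dimnames.
#' @slot nMarkersUsed integer, number of polymorphic indicator columns
#'   (the divisor M of the relationship formulas).
#'
#' @seealso [tetraKinship()], [kinshipMatrix()]
#' @exportClass TetraKinship
setClass("TetraKinship",
    representation(K = "matrix", nMarkersUsed = "integer"))

setValidity("TetraKinship", function(object) {
    K <- object@K
    msg <- character()
    if (nrow(K) != ncol(K)) msg <- c(msg, "K must be square")
    if (is.null(rownames(K)) || !identical(rownames(K), colnames(K)))
        msg <- c(msg, "K needs identical row/column cultivar ids")
    if (max(abs(K - t(K))) > 1e-12)
        msg <- c(msg, "K must be symmetric to within 1e-12")
    if (any(diag(K) < 1 - 1e-12))
        msg <- c(msg, "every diagonal entry of K must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Multi-environment multi-trait phenotype table
#'
#' Long-format container of trial records: one row per
#' (cultivar, environment, trait) cell with a numeric value and an
#' observed flag.  Masked cells (\code{observed = FALSE}) are the
#' prediction targets of the cross-validation schemes.  Within a model
#' fit the records are kept in canonical order: environment, then
#' cultivar, then trait.
#'
#' @slot records data.frame with columns \code{cultivar},
#'   \code{environment}, \code{trait}, \code{value}, \code{observed}.
#' @slot environments character vector of environment labels (order kept).
#' @slot traits character vector of trait labels (order kept).
#'
#' @seealso [TrialTable()], [maskCells()], [fitGEModel()]
#' @exportClass TrialTable
setClass("TrialTable",
    representation(records = "data.frame", environments = "character",
                   traits = "character"))

setValidity("TrialTable", function(object) {
    r <- object@records
    msg <- character()
    need <- c("cultivar", "environment", "trait", "value", "observed")
    if (!all(need %in% names(r)))
        msg <- c(msg, paste("records needs columns:",
                            paste(need, collapse = ", ")))
    else {
        key <- paste(r$cultivar, r$environment, r$trait, sep = "\r")
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate (cultivar, environment, trait) records")
        if (!all(r$environment %in% object@environments))
            msg <- c(msg, "records contain environments missing from the inventory")
        if (!all(r$trait %in% object@traits))
            msg <- c(msg, "records contain traits missing from the inventory")
        if (any(r$observed & is.na(r$value)))
            msg <- c(msg, "observed records cannot have NA values")
    }
    if (length(msg)) msg else TRUE
})

#' Fitted Bayesian G x E prediction model
#'
#' Posterior summaries and predictions from one of the four
#' genome-based prediction models (see [fitGEModel()]).  Predictions
#' exist for exactly the masked cells of the fitted [TrialTable].
#'
#' @slot model one of "M1", "M2", "M3", "M4".
#' @slot traits traits the fit covers.
#' @slot environments environments in the fit (including fully masked
#'   ones predicted by the grand-mean convention).
#' @slot predictions data.frame: cultivar, environment, trait,
#'   predictive_mean, predictive_sd for every masked cell.
#' @slot posterior named list of posterior summaries (means, sds,
#'   retained draws of variance parameters).
#' @slot settings the MCMC settings used.
#' @slot convergence named numeric vector of split-chain potential
#'   scale reduction factors for the variance parameters.
#'
#' @exportClass GEModelFit
setClass("GEModelFit",
    representation(model = "character", traits = "character",
                   environments = "character", predictions = "data.frame",
                   posterior = "list", settings = "list",
                   convergence = "numeric"))

#' Cross-validation plan for the seven prediction schemes
#'
#' Reproducible masking partitions for one scheme.  For the
#' whole-environment schemes (\code{M1Sa}, \code{M4Ma}) there is a
#' single fold masking every cell of the target environments; for the
#' 70-percent schemes each fold masks a seeded random sample of
#' cultivars in the target environments (all traits jointly, or
#' independently per trait for \code{M4Mp*}).
#'
#' @slot scheme scheme id, one of M1Sa, M4Ma, M1Sp, M2Sp, M3Sp, M4Mp, M4Mp*.
#' @slot model the model the scheme uses.
#' @slot targetEnvironments environments whose cells are masked.
#' @slot trainEnvironments environments never masked.
#' @slot fraction fraction of cultivars masked per target environment.
#' @slot seed master seed the folds were derived from.
#' @slot folds list of data.frames (cultivar, environment, trait) of
#'   masked cells, one per fold.
#'
#' @seealso [makeCVPlan()], [runScheme()]
#' @exportClass CVPlan
setClass("CVPlan",
    representation(scheme = "character", model = "character",
                   targetEnvironments = "character",
                   trainEnvironments = "character",
                   fraction = "numeric", seed = "numeric", folds = "list"))

setValidity("CVPlan", function(object) {
    ok <- c("M1Sa", "M4Ma", "M1Sp", "M2Sp", "M3Sp", "M4Mp", "M4Mp*")
    msg <- character()
    if (!(object@scheme %in% ok))
        msg <- c(msg, paste("unknown scheme:", object@scheme))
    if (length(intersect(object@targetEnvironments,
                         object@trainEnvironments)))
        msg <- c(msg, "target and training environments must be disjoint")
    if (length(msg)) msg else TRUE
})
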