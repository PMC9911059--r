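schemeModelMap <- c(M1Sa = "M1", M4Ma = "M4", M1Sp = "M1", M2Sp = "M2",
                    M3Sp = "M3", M4Mp = "M4", `M4Mp*` = "M4")

#' Build a cross-validation plan for one prediction scheme
#'
#' Generates the reproducible masking partitions of the seven
#' sparse-testing schemes.  The whole-environment schemes (\code{M1Sa},
#' \code{M4Ma}) mask every cell of the target environments in a single
#' fold.  The 70-percent schemes draw, per fold, a seeded random sample
#' of \code{round(fraction * n)} cultivars (ties round up, i.e. toward
#' masking more) and mask them in every target environment: for
#' \code{M1Sp}/\code{M2Sp}/\code{M3Sp}/\code{M4Mp} the same cultivars
#' are masked for all traits, while for \code{M4Mp*} an independent
#' cultivar sample is drawn for each trait, so a cultivar can be
#' observed for some traits and masked for others.  Identical seeds
#' give identical folds, so the same partitions can be reused across
#' the models being compared.
#'
#' @param scheme one of M1Sa, M4Ma, M1Sp, M2Sp, M3Sp, M4Mp, M4Mp*.
#' @param table a [TrialTable-class].
#' @param targetEnvironments environments whose cells are masked (e.g.
#'   all location-years of the prediction year).
#' @param fraction fraction of cultivars masked per target environment
#'   (default 0.70); must be 1 for the *a* schemes (their whole-
#'   environment masking is expressed as fraction 1).
#' @param nRepeats number of folds for the *p* schemes (default 10).
#' @param seed master seed; per-fold (and per-trait for M4Mp*)
#'   substreams are derived deterministically from it.
#' @param traits traits the plan covers (default: all in the table).
#'
#' @return a [CVPlan-class].
#' @examples
#' tt <- TrialTable(expand.grid(cultivar = sprintf("g%02d", 1:10),
#'     environment = c("E2020", "E2021"), trait = "yield",
#'     stringsAsFactors = FALSE) |> transform(value = rnorm(20)))
#' plan <- makeCVPlan("M1Sp", tt, "E2021", nRepeats = 3, seed = 7)
#' nrow(cvFolds(plan)[[1]])   # 7 cultivars masked
#' @export
makeCVPlan <- function(scheme, table, targetEnvironments, fraction = 0.70,
                       nRepeats = 10L, seed = 1L, traits = NULL) {
    stopifnot(is(table, "TrialTable"))
    if (!scheme %in% names(schemeModelMap))
        stop("unknown scheme: ", scheme)
    if (is.null(traits)) traits <- traitNames(table)
    envs <- environmentNames(table)
    if (!length(targetEnvironments) ||
        !all(targetEnvironments %in% envs))
        stop("target environments must be a nonempty subset of the table's")
    trainEnvs <- setdiff(envs, targetEnvironments)
    isA <- scheme %in% c("M1Sa", "M4Ma")
    if (isA && fraction != 1)
        stop("whole-environment schemes mask all cultivars; use fraction = 1")
    if (!isA && (fraction <= 0 || fraction >= 1))
        stop("fraction must be in (0, 1) for the 70%-style schemes")

    r <- trialRecords(table)
    cultivars <- sort(unique(r$cultivar[r$environment %in%
                                        targetEnvironments]))
    n <- length(cultivars)
    if (isA) {
        folds <- list(expand.grid(cultivar = cultivars,
                                  environment = targetEnvironments,
                                  trait = traits,
                                  stringsAsFactors = FALSE))
    } else {
        nMask <- floor(fraction * n + 0.5)   # ties round toward masking more
        folds <- lapply(seq_len(nRepeats), function(f) {
            if (scheme == "M4Mp*") {
                do.call(rbind, lapply(seq_along(traits), function(j) {
                    set.seed(deriveSeed(seed, f, j))
                    masked <- sample(cultivars, nMask)
                    expand.grid(cultivar = masked,
                                environment = targetEnvironments,
                                trait = traits[j], stringsAsFactors = FALSE)
                }))
            } else {
                set.seed(deriveSeed(seed, f, 0L))
                masked <- sample(cultivars, nMask)
                expand.grid(cultivar = masked,
                            environment = targetEnvironments,
                            trait = traits, stringsAsFactors = FALSE)
            }
        })
    }
    new("CVPlan", scheme = scheme,
        model = unname(schemeModelMap[scheme]),
        targetEnvironments = as.character(targetEnvironments),
        trainEnvironments = trainEnvs,
        fraction = fraction, seed = as.numeric(seed), folds = folds)
}

#' @rdname CVPlan-class
#' @export
setMethod("cvFolds", "CVPlan", function(x) x@folds)

setMethod("show", "CVPlan", function(object) {
    cat("CVPlan:", object@scheme, "( model", object@model, ")\n")
    cat("  target:", paste(object@targetEnvironments, collapse = ", "),
        "| training:", paste(object@trainEnvironments, collapse = ", "),
        "\n")
    cat("  folds:", length(object@folds), "| fraction:", object@fraction,
        "| seed:", object@seed, "\n")
})

#' Prediction accuracy: Pearson correlation and mean squared error
#'
#' COR is the Pearson correlation between observed and predicted
#' values; PMSE is the mean of squared differences.  When either
#' vector has zero variance the correlation is undefined and returned
#' as NA with a warning; PMSE is still returned.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return named numeric vector \code{c(COR = ..., PMSE = ...)}.
#' @examples
#' scorePredictions(c(1, 2, 3), c(2, 4, 6))   # COR 1, PMSE 14/3
#' @export
scorePredictions <- function(observed, predicted) {
    stopifnot(length(observed) == length(predicted))
    pmse <- mean((observed - predicted)^2)
    if (length(observed) < 2L || stats::sd(observed) == 0 ||
        stats::sd(predicted) == 0) {
        warning("zero variance in observed or predicted values; ",
                "COR is undefined")
        return(c(COR = NA_real_, PMSE = pmse))
    }
    c(COR = stats::cor(observed, predicted), PMSE = pmse)
}

#' Run one cross-validation scheme
#'
#' For each fold of the plan: masks the fold's cells, fits the scheme's
#' model, predicts the masked cells, and scores COR and PMSE per
#' (target environment, trait) over the fold's masked cells that have
#' an observed truth value.  Metrics are aggregated as mean and SD over
#' folds (single-fold schemes report no SD).  Folds in which some
#' (environment, trait) has fewer than 3 scoreable cells are skipped
#' with a warning.
#'
#' @param table a fully observed (or partially observed) [TrialTable-class]
#'   holding the truth values; the plan's masked cells must have values
#'   to score against.
#' @param kinship a [TetraKinship-class].
#' @param plan a [CVPlan-class] from [makeCVPlan()].
#' @param settings MCMC settings for the per-fold fits.
#' @param ... passed to [fitGEModel()].
#' @return list with \code{metrics} (data.frame: scheme, model,
#'   environment, trait, metric, mean, sd, n_folds), \code{perFold}
#'   (long data.frame of per-fold scores) and \code{predictions}
#'   (per-fold prediction records).
#' @export
runScheme <- function(table, kinship, plan, settings = mcmcSettings(),
                      ...) {
    stopifnot(is(plan, "CVPlan"))
    model <- plan@model
    traits <- sort(unique(plan@folds[[1L]]$trait))
    perFold <- list(); predRecs <- list(); varPost <- list()
    for (f in seq_along(plan@folds)) {
        fold <- plan@folds[[f]]
        masked <- maskCells(table, fold)
        foldSettings <- settings
        foldSettings$seed <- deriveSeed(settings$seed, 1000L + f)
        scores <- list()
        if (model %in% c("M2", "M3", "M4")) {
            fit <- fitGEModel(masked, kinship, model,
                              traits = if (model == "M4") traits
                                       else traits[1L],
                              settings = foldSettings, ...)
            pred <- predictions(fit)
            vs <- posteriorSummary(fit)$variance
            vs$fold <- f; vs$trait <- NA_character_
            varPost[[length(varPost) + 1L]] <- vs
        } else {
            pred <- do.call(rbind, lapply(seq_along(traits), function(j) {
                fs <- foldSettings
                fs$seed <- deriveSeed(foldSettings$seed, j)
                fitj <- fitGEModel(masked, kinship, "M1",
                                   traits = traits[j], settings = fs, ...)
                vs <- posteriorSummary(fitj)$variance
                vs$fold <- f; vs$trait <- traits[j]
                varPost[[length(varPost) + 1L]] <<- vs
                predictions(fitj)
            }))
        }
        truth <- trialRecords(table)
        tkey <- paste(truth$cultivar, truth$environment, truth$trait,
                      sep = "\r")
        pkey <- paste(pred$cultivar, pred$environment, pred$trait,
                      sep = "\r")
        fkey <- paste(fold$cultivar, fold$environment, fold$trait,
                      sep = "\r")
        pred <- pred[pkey %in% fkey, , drop = FALSE]
        pred$observed_value <- truth$value[match(
            paste(pred$cultivar, pred$environment, pred$trait, sep = "\r"),
            tkey)]
        sc <- pred[!is.na(pred$observed_value), , drop = FALSE]
        wanted <- expand.grid(environment = plan@targetEnvironments,
                              trait = traits, stringsAsFactors = FALSE)
        nCells <- mapply(function(e, tr)
            sum(sc$environment == e & sc$trait == tr),
            wanted$environment, wanted$trait)
        if (any(nCells < 3L)) {
            warning("fold ", f, " skipped: fewer than 3 scoreable cells ",
                    "for some (environment, trait)")
            next
        }
        for (i in seq_len(nrow(wanted))) {
            e <- wanted$environment[i]; tr <- wanted$trait[i]
            sub <- sc[sc$environment == e & sc$trait == tr, ]
            s <- suppressWarnings(
                scorePredictions(sub$observed_value, sub$predictive_mean))
            scores[[i]] <- data.frame(fold = f, environment = e,
                                      trait = tr, COR = s[["COR"]],
                                      PMSE = s[["PMSE"]])
        }
        pred$fold <- f; pred$scheme <- plan@scheme; pred$model <- model
        predRecs[[length(predRecs) + 1L]] <- pred
        perFold[[length(perFold) + 1L]] <- do.call(rbind, scores)
    }
    if (!length(perFold)) stop("all folds were skipped")
    pf <- do.call(rbind, perFold)
    long <- rbind(
        data.frame(pf[c("fold", "environment", "trait")], metric = "COR",
                   value = pf$COR),
        data.frame(pf[c("fold", "environment", "trait")], metric = "PMSE",
                   value = pf$PMSE))
    agg <- aggregate(value ~ environment + trait + metric, long,
                     function(v) c(mean = mean(v, na.rm = TRUE),
                                   sd = if (length(v) > 1L)
                                       stats::sd(v, na.rm = TRUE)
                                       else NA_real_,
                                   n = sum(is.finite(v))))
    metrics <- data.frame(scheme = plan@scheme, model = model,
                          environment = agg$environment, trait = agg$trait,
                          metric = agg$metric,
                          mean = agg$value[, "mean"],
                          sd = agg$value[, "sd"],
                          n_folds = agg$value[, "n"])
    list(metrics = metrics, perFold = pf,
         predictions = do.call(rbind, predRecs),
         variancePosteriors = do.call(rbind, varPost))
}

#' Between-environment phenotypic correlations
#'
#' Pearson correlation, per trait, of the observed values of cultivars
#' shared between pairs of environments -- the quantity that largely
#' drives how predictable a target environment is from a training one.
#'
#' @param table a [TrialTable-class].
#' @param targetEnvironments rows of the output (e.g. the prediction
#'   year's location-years).
#' @param trainEnvironments environments each target is correlated with
#'   (default: all others).
#' @param minShared minimum number of shared observed cultivars
#'   (default 3); pairs below it give NA.
#' @return data.frame: target, train, one column per trait.
#' @export
phenotypicCorrelations <- function(table, targetEnvironments,
                                   trainEnvironments = NULL,
                                   minShared = 3L) {
    stopifnot(is(table, "TrialTable"))
    if (is.null(trainEnvironments))
        trainEnvironments <- setdiff(environmentNames(table),
                                     targetEnvironments)
    r <- trialRecords(table)
    r <- r[r$observed, , drop = FALSE]
    traits <- traitNames(table)
    out <- expand.grid(target = targetEnvironments,
                       train = trainEnvironments,
                       stringsAsFactors = FALSE)
    for (tr in traits) out[[tr]] <- NA_real_
    for (i in seq_len(nrow(out))) {
        for (tr in traits) {
            a <- r[r$environment == out$target[i] & r$trait == tr, ]
            b <- r[r$environment == out$train[i] & r$trait == tr, ]
            shared <- intersect(a$cultivar, b$cultivar)
            if (length(shared) >= minShared)
                out[[tr]][i] <- stats::cor(
                    a$value[match(shared, a$cultivar)],
                    b$value[match(shared, b$cultivar)])
        }
    }
    out
}
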