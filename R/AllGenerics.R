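#' @rdname DosagePanel-class
#' @param object,x a \code{DosagePanel}.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname DosagePanel-class
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' Cultivar identifiers
#'
#' Cultivar labels of a panel, kinship matrix or trial table, in storage
#' order.
#'
#' @param x a \code{DosagePanel}, \code{TetraKinship} or \code{TrialTable}.
#' @return character vector of cultivar ids.
#' @export
setGeneric("cultivarIds", function(x) standardGeneric("cultivarIds"))

#' @rdname TetraKinship-class
#' @param x a \code{TetraKinship}.
#' @export
setGeneric("kinshipMatrix", function(x) standardGeneric("kinshipMatrix"))

#' @rdname TrialTable-class
#' @param x a \code{TrialTable}.
#' @export
setGeneric("trialRecords", function(x) standardGeneric("trialRecords"))

#' @rdname TrialTable-class
#' @export
setGeneric("environmentNames", function(x) standardGeneric("environmentNames"))

#' @rdname TrialTable-class
#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))

#' Predictions for masked cells
#'
#' @param object a fitted model.
#' @return data.frame with one row per masked cell: cultivar,
#'   environment, trait, predictive_mean, predictive_sd.
#' @export
setGeneric("predictions", function(object) standardGeneric("predictions"))

#' Posterior summaries of a fitted model
#'
#' @param object a fitted model.
#' @return named list of posterior means/sds and retained variance draws.
#' @export
setGeneric("posteriorSummary",
    function(object) standardGeneric("posteriorSummary"))

#' @rdname CVPlan-class
#' @param x a \code{CVPlan}.
#' @export
setGeneric("cvFolds", function(x) standardGeneric("cvFolds"))
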