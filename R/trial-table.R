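#' Construct a trial table
#'
#' Builds the long-format phenotype container used by all model fits and
#' cross-validation schemes.  Records with \code{NA} values are stored as
#' masked cells (prediction targets); the \code{observed} column can also
#' be supplied explicitly.  Records are sorted into canonical order
#' (environment, cultivar, trait), the layout the multi-environment
#' models assume.
#'
#' @param records data.frame with columns \code{cultivar},
#'   \code{environment}, \code{trait}, \code{value} and optionally
#'   \code{observed}.
#' @param environments,traits optional label orderings; defaults to
#'   first-appearance order.
#'
#' @return a [TrialTable-class] object.
#' @examples
#' tt <- TrialTable(data.frame(
#'     cultivar = c("a", "b", "a"), environment = "E1",
#'     trait = c("yield", "yield", "starch"), value = c(1.2, NA, 15)))
#' sum(trialRecords(tt)$observed)
#' @export
TrialTable <- function(records, environments = NULL, traits = NULL) {
    records <- as.data.frame(records)
    for (col in c("cultivar", "environment", "trait"))
        records[[col]] <- as.character(records[[col]])
    records$value <- as.numeric(records$value)
    if (is.null(records$observed)) records$observed <- !is.na(records$value)
    key <- paste(records$cultivar, records$environment, records$trait,
                 sep = " / ")
    if (anyDuplicated(key))
        stop("duplicate (cultivar, environment, trait) records: ",
             paste(unique(key[duplicated(key)]), collapse = "; "))
    if (is.null(environments)) environments <- unique(records$environment)
    if (is.null(traits)) traits <- unique(records$trait)
    ord <- order(match(records$environment, environments),
                 records$cultivar, match(records$trait, traits))
    records <- records[ord, , drop = FALSE]
    rownames(records) <- NULL
    new("TrialTable", records = records,
        environments = as.character(environments),
        traits = as.character(traits))
}

#' @rdname TrialTable-class
#' @export
setMethod("trialRecords", "TrialTable", function(x) x@records)

#' @rdname TrialTable-class
#' @export
setMethod("environmentNames", "TrialTable", function(x) x@environments)

#' @rdname TrialTable-class
#' @export
setMethod("traitNames", "TrialTable", function(x) x@traits)

#' @rdname cultivarIds
#' @export
setMethod("cultivarIds", "TrialTable",
    function(x) sort(unique(x@records$cultivar)))

setMethod("show", "TrialTable", function(object) {
    r <- object@records
    cat("TrialTable:", length(unique(r$cultivar)), "cultivars,",
        length(object@environments), "environments,",
        length(object@traits), "traits\n")
    cat("  records:", nrow(r), " observed:", sum(r$observed),
        " masked:", sum(!r$observed), "\n")
    cat("  environments:", paste(object@environments, collapse = ", "), "\n")
    cat("  traits:", paste(object@traits, collapse = ", "), "\n")
})

#' Mask cells of a trial table
#'
#' Marks the given (cultivar, environment, trait) cells as unobserved so
#' they become prediction targets.  Cells absent from the table are
#' added as masked records with \code{NA} value, which is how the
#' Kronecker-structured models complete an unbalanced grid.
#'
#' @param table a [TrialTable-class].
#' @param cells data.frame with columns cultivar, environment, trait.
#' @return a new \code{TrialTable} with those cells masked.
#' @export
maskCells <- function(table, cells) {
    stopifnot(is(table, "TrialTable"))
    r <- trialRecords(table)
    key <- paste(r$cultivar, r$environment, r$trait, sep = "\r")
    ckey <- paste(cells$cultivar, cells$environment, cells$trait, sep = "\r")
    hit <- key %in% ckey
    r$observed[hit] <- FALSE
    newKeys <- !(ckey %in% key)
    if (any(newKeys)) {
        add <- data.frame(cultivar = cells$cultivar[newKeys],
                          environment = cells$environment[newKeys],
                          trait = cells$trait[newKeys],
                          value = NA_real_, observed = FALSE)
        r <- rbind(r, add)
    }
    TrialTable(r, environments = environmentNames(table),
               traits = traitNames(table))
}

#' Complete the cultivar x environment x trait grid
#'
#' Ensures every combination of the given cultivars, environments and
#' traits has a record, adding masked NA cells where needed.  The
#' Kronecker-structured models (M2-M4) require the complete grid; absent
#' cells are treated as masked and imputed by data augmentation.
#'
#' @param table a [TrialTable-class].
#' @param cultivars cultivars the grid must cover (default: those present).
#' @return a completed \code{TrialTable}.
#' @export
completeGrid <- function(table, cultivars = NULL) {
    if (is.null(cultivars)) cultivars <- cultivarIds(table)
    grid <- expand.grid(cultivar = cultivars,
                        environment = environmentNames(table),
                        trait = traitNames(table),
                        stringsAsFactors = FALSE)
    r <- trialRecords(table)
    key <- paste(r$cultivar, r$environment, r$trait, sep = "\r")
    gkey <- paste(grid$cultivar, grid$environment, grid$trait, sep = "\r")
    missing <- !(gkey %in% key)
    if (any(missing)) {
        add <- data.frame(cultivar = grid$cultivar[missing],
                          environment = grid$environment[missing],
                          trait = grid$trait[missing],
                          value = NA_real_, observed = FALSE)
        r <- rbind(r, add)
    }
    TrialTable(r, environments = environmentNames(table),
               traits = traitNames(table))
}
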