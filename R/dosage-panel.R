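#' Construct a tetraploid dosage panel
#'
#' @param dosages numeric or integer matrix, cultivars in rows, SNPs in
#'   columns; entries are B-allele counts in 0-4, \code{NA} = missing.
#'   Row names are cultivar ids (generated as \code{G001, ...} when
#'   absent); column names are SNP ids (\code{snp1, ...} when absent).
#'
#' @return a [DosagePanel-class] object.
#' @examples
#' p <- DosagePanel(matrix(c(0, 2, 2, 2, 4, 0), nrow = 3, byrow = TRUE))
#' nCultivars(p)
#' @export
DosagePanel <- function(dosages) {
    dosages <- as.matrix(dosages)
    storage.mode(dosages) <- "double"
    if (is.null(rownames(dosages)))
        rownames(dosages) <- sprintf("G%03d", seq_len(nrow(dosages)))
    if (is.null(colnames(dosages)))
        colnames(dosages) <- sprintf("snp%d", seq_len(ncol(dosages)))
    new("DosagePanel", dosages = dosages)
}

#' @rdname DosagePanel-class
#' @export
setMethod("dosages", "DosagePanel", function(x) x@dosages)

#' @rdname DosagePanel-class
#' @export
setMethod("missingMask", "DosagePanel", function(x) is.na(x@dosages))

#' @rdname cultivarIds
#' @export
setMethod("cultivarIds", "DosagePanel", function(x) rownames(x@dosages))

#' @rdname DosagePanel-class
#' @export
nCultivars <- function(x) nrow(dosages(x))

#' @rdname DosagePanel-class
#' @export
nSnps <- function(x) ncol(dosages(x))

setMethod("show", "DosagePanel", function(object) {
    d <- object@dosages
    cat("DosagePanel:", nrow(d), "cultivars x", ncol(d), "SNPs\n")
    miss <- mean(is.na(d))
    cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
    tab <- table(factor(d[!is.na(d)], levels = 0:4))
    cat("  dosage counts:",
        paste(sprintf("%d:%d", 0:4, as.integer(tab)), collapse = " "), "\n")
})
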