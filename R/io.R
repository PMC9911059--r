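#' Read a dosage matrix from CSV
#'
#' Expects a header row; the first column holds cultivar ids and the
#' remaining columns one SNP each, with integer cells in 0-4 and empty
#' cells for missing calls.
#'
#' @param path CSV file path.
#' @return a [DosagePanel-class].
#' @export
readDosageCsv <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("dosage CSV needs an id column plus SNPs")
    ids <- as.character(df[[1L]])
    d <- as.matrix(df[, -1L, drop = FALSE])
    suppressWarnings(storage.mode(d) <- "double")
    bad <- which(!is.na(d) & (d != round(d) | d < 0 | d > 4),
                 arr.ind = TRUE)
    if (nrow(bad))
        stop("dosage out of 0-4 at row ", ids[bad[1L, 1L]], ", column ",
             colnames(d)[bad[1L, 2L]])
    rownames(d) <- ids
    DosagePanel(d)
}

#' Read ploidy-4 genotypes from a VCF file
#'
#' Parses GT fields with four alleles (e.g. \code{0/0/1/1}, phased or
#' unphased) into B-allele dosages 0-4.  Fully missing calls
#' (\code{./././.}) become NA; genotypes with a ploidy other than 4 are
#' rejected.  Requires the \pkg{vcfR} package.
#'
#' @param path VCF file path.
#' @return a [DosagePanel-class] (cultivars x SNPs).
#' @export
readDosageVcf <- function(path) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("readDosageVcf requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    ids <- colnames(gt)
    snps <- rownames(gt)
    if (is.null(snps)) snps <- sprintf("snp%d", seq_len(nrow(gt)))
    parse1 <- function(s) {
        if (is.na(s)) return(NA_real_)
        al <- strsplit(s, "[/|]")[[1L]]
        if (all(al == ".")) return(NA_real_)
        if (length(al) != 4L)
            stop("genotype '", s, "' does not have ploidy 4")
        sum(al != "0" & al != ".")
    }
    d <- matrix(vapply(as.vector(gt), parse1, 0), nrow(gt), ncol(gt))
    d <- t(d)
    dimnames(d) <- list(ids, snps)
    DosagePanel(d)
}

#' Read a long-format phenotype table from CSV
#'
#' Expects columns \code{cultivar}, \code{environment}, \code{trait},
#' \code{value}; empty values become masked cells.  Duplicate
#' (cultivar, environment, trait) triples are rejected with a message
#' naming them.
#'
#' @param path CSV file path.
#' @return a [TrialTable-class].
#' @export
readPhenotypeCsv <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    need <- c("cultivar", "environment", "trait", "value")
    extra <- setdiff(names(df), need)
    if (length(extra))
        stop("unknown column(s) in phenotype CSV: ",
             paste(extra, collapse = ", "))
    if (!all(need %in% names(df)))
        stop("phenotype CSV needs columns: ", paste(need, collapse = ", "))
    df$value <- suppressWarnings(as.numeric(df$value))
    TrialTable(df)
}

#' Write a trial table to CSV
#'
#' Inverse of [readPhenotypeCsv()]: masked cells are written with empty
#' values.
#'
#' @param table a [TrialTable-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePhenotypeCsv <- function(table, path) {
    r <- trialRecords(table)
    out <- r[c("cultivar", "environment", "trait", "value")]
    out$value <- ifelse(r$observed, formatC(r$value, format = "g",
                                            digits = 17), "")
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    invisible(path)
}

#' Write / read a kinship matrix as CSV
#'
#' The matrix is written at full double precision (17 significant
#' digits) with cultivar ids as header row and first column, so a
#' read-back reproduces it exactly.
#'
#' @param kinship a [TetraKinship-class].
#' @param path file path.
#' @return \code{path} invisibly (write); a \code{TetraKinship} (read).
#' @export
writeKinshipCsv <- function(kinship, path) {
    K <- kinshipMatrix(kinship)
    ids <- rownames(K)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("cultivar", ids), collapse = ","), con)
    for (i in seq_len(nrow(K)))
        writeLines(paste(c(ids[i], sprintf("%.17g", K[i, ])),
                         collapse = ","), con)
    invisible(path)
}

#' @rdname writeKinshipCsv
#' @export
readKinshipCsv <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    K <- as.matrix(df[, -1L, drop = FALSE])
    rownames(K) <- df[[1L]]
    storage.mode(K) <- "double"
    K <- (K + t(K)) / 2
    new("TetraKinship", K = K, nMarkersUsed = NA_integer_)
}

#' Write a dosage panel to CSV
#'
#' @param panel a [DosagePanel-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDosageCsv <- function(panel, path) {
    d <- dosages(panel)
    out <- data.frame(cultivar = rownames(d), d, check.names = FALSE)
    utils::write.csv(out, path, row.names = FALSE, na = "")
    invisible(path)
}
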