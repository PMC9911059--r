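#' Five-class genotype indicator coding
#'
#' Expands tetraploid allele dosages into the full-tetrasomic indicator
#' matrix: each SNP contributes five binary columns, one per genotype
#' class in the order AAAA, AAAB, AABB, ABBB, BBBB, so both additive and
#' nonadditive genotype effects are representable.  A dosage of d places
#' a 1 in class column d (0-based) of that SNP's block.
#'
#' Cultivars whose fraction of missing SNP calls exceeds
#' \code{maxMissing} are dropped (mirroring the exclusion of clones
#' lacking enough SNP data); remaining missing dosages are imputed to
#' the SNP's modal genotype class before class frequencies are
#' computed.  Columns whose class frequency is 0 or 1 (monomorphic)
#' carry no information and are flagged not retained.
#'
#' @param panel a [DosagePanel-class].
#' @param maxMissing per-cultivar missingness threshold above which the
#'   cultivar is excluded (default 0.10).
#'
#' @return a list with elements \code{values} (n x 5S binary matrix),
#'   \code{classFreqs} (column means p_i), \code{retained} (logical,
#'   0 < p_i < 1), \code{M} (number of retained columns),
#'   \code{cultivarIds}, and \code{dropped} (ids of excluded cultivars).
#' @examples
#' p <- DosagePanel(rbind(c(0, 2), c(2, 2), c(4, 0)))
#' ind <- encodeIndicators(p)
#' ind$values[1, 1:5]   # dosage 0 -> AAAA column
#' @export
encodeIndicators <- function(panel, maxMissing = 0.10) {
    stopifnot(is(panel, "DosagePanel"))
    d <- dosages(panel)
    allMissSnp <- colSums(!is.na(d)) == 0L
    if (any(allMissSnp))
        stop("SNP(s) with no non-missing dosages: ",
             paste(colnames(d)[allMissSnp], collapse = ", "))
    missFrac <- rowMeans(is.na(d))
    dropped <- rownames(d)[missFrac > maxMissing]
    if (length(dropped) >= nrow(d) - 1L)
        stop("fewer than 2 cultivars remain after the missingness filter")
    d <- d[missFrac <= maxMissing, , drop = FALSE]
    # modal-dosage imputation per SNP
    if (anyNA(d)) {
        for (j in which(colSums(is.na(d)) > 0L)) {
            tab <- tabulate(d[, j] + 1L, nbins = 5L)
            d[is.na(d[, j]), j] <- which.max(tab) - 1L
        }
    }
    n <- nrow(d); S <- ncol(d)
    X <- matrix(0, n, 5L * S)
    idx <- rep(seq_len(S) - 1L, each = n) * 5L + as.integer(d) + 1L
    X[cbind(rep(seq_len(n), times = S), idx)] <- 1
    classes <- c("AAAA", "AAAB", "AABB", "ABBB", "BBBB")
    colnames(X) <- paste(rep(colnames(d), each = 5L), classes, sep = ".")
    rownames(X) <- rownames(d)
    p <- colMeans(X)
    retained <- p > 0 & p < 1
    list(values = X, classFreqs = p, retained = retained,
         M = sum(retained), cultivarIds = rownames(d), dropped = dropped)
}

#' Full-tetrasomic genomic relationship matrix
#'
#' Computes the additive-plus-nonadditive tetrasomic relationship matrix
#' from the five-class indicator coding.  With x_ji the indicator of
#' cultivar j at column i and p_i the column frequency, the off-diagonal
#' relationship is
#' \deqn{K_{jk} = \frac{1}{M} \sum_i \frac{(x_{ji}-p_i)(x_{ki}-p_i)}{p_i(1-p_i)}}
#' and the diagonal adds one:
#' \deqn{K_{jj} = 1 + \frac{1}{M} \sum_i \frac{x_{ji}^2 - 2 p_i x_{ji} + p_i^2}{p_i(1-p_i)}.}
#' Sums run over the M retained (polymorphic) columns.  Because
#' \eqn{x^2 - 2px + p^2 = (x-p)^2}, the result equals a normalized Gram
#' matrix of centered, scaled indicators plus the identity, hence is
#' symmetric positive definite with diagonal at least 1.
#'
#' @param x a [DosagePanel-class] or the list returned by
#'   [encodeIndicators()].
#' @param ... passed to [encodeIndicators()] when \code{x} is a panel.
#'
#' @return a [TetraKinship-class] object.
#' @examples
#' K <- tetraKinship(DosagePanel(rbind(c(0, 2), c(2, 2), c(4, 0))))
#' diag(kinshipMatrix(K))
#' @export
tetraKinship <- function(x, ...) {
    ind <- if (is(x, "DosagePanel")) encodeIndicators(x, ...) else x
    if (ind$M < 1L)
        stop("all indicator columns are monomorphic; K is undefined")
    X <- ind$values[, ind$retained, drop = FALSE]
    p <- ind$classFreqs[ind$retained]
    W <- sweep(X, 2L, p, "-")
    W <- sweep(W, 2L, sqrt(p * (1 - p)), "/")
    K <- tcrossprod(W) / ind$M
    K <- (K + t(K)) / 2
    diag(K) <- diag(K) + 1
    dimnames(K) <- list(ind$cultivarIds, ind$cultivarIds)
    new("TetraKinship", K = K, nMarkersUsed = as.integer(ind$M))
}

#' @rdname TetraKinship-class
#' @export
setMethod("kinshipMatrix", "TetraKinship", function(x) x@K)

#' @rdname cultivarIds
#' @export
setMethod("cultivarIds", "TetraKinship", function(x) rownames(x@K))

#' @rdname TetraKinship-class
#' @export
nMarkersUsed <- function(x) x@nMarkersUsed

setMethod("show", "TetraKinship", function(object) {
    K <- object@K
    cat("TetraKinship:", nrow(K), "x", ncol(K),
        "(", object@nMarkersUsed, "retained indicator columns )\n")
    cat(sprintf("  diag range: [%.4f, %.4f]; offdiag range: [%.4f, %.4f]\n",
        min(diag(K)), max(diag(K)),
        min(K[upper.tri(K)]), max(K[upper.tri(K)])))
})

#' Subset/align a kinship matrix to a cultivar set
#'
#' @param kin a [TetraKinship-class].
#' @param ids cultivar ids to keep, in the requested order.
#' @return a \code{TetraKinship} restricted to \code{ids}.
#' @export
subsetKinship <- function(kin, ids) {
    K <- kinshipMatrix(kin)
    miss <- setdiff(ids, rownames(K))
    if (length(miss))
        stop("cultivars absent from the kinship matrix: ",
             paste(miss, collapse = ", "))
    new("TetraKinship", K = K[ids, ids, drop = FALSE],
        nMarkersUsed = kin@nMarkersUsed)
}
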