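# MHC class I binding: best-allele Kd selection, the 500 nM binding filter,
# and the amplitude A = Kd^WT / Kd^MT (with an optional cap on the wild-type
# Kd, a hook for correcting predictor saturation at very weak binders).

#' @rdname predictKd
#' @aliases predictKd,KdTable-method
#' @export
setMethod("predictKd", "KdTable", function(object, peptide, allele) {
    n <- max(length(peptide), length(allele))
    key <- paste(rep_len(peptide, n), rep_len(allele, n), sep = "|")
    kd <- unname(object@table[key])
    if (anyNA(kd)) {
        i <- which(is.na(kd))[1L]
        stop("no Kd entry for peptide ", rep_len(peptide, n)[i],
             " / allele ", rep_len(allele, n)[i])
    }
    kd
})

setMethod("show", "KdTable", function(object) {
    cat("KdTable with", length(object@table), "(peptide, allele) entries\n")
})

#' Best (lowest) dissociation constant across a sample's alleles
#'
#' The strongest predicted binding for each peptide is the minimum Kd over
#' the sample's HLA class I alleles; mutant and wild-type peptides are
#' scored independently of each other.
#'
#' @param peptide character vector of 9-mers.
#' @param alleles character vector of the sample's HLA alleles.
#' @param kdSource a \code{\linkS4class{KdSource}}.
#' @return list with numeric \code{kd_nM} and character \code{allele} (the
#'   achieving allele, first in allele-list order on ties), both parallel
#'   to \code{peptide}.
#' @export
bestKd <- function(peptide, alleles, kdSource) {
    stopifnot(length(alleles) >= 1L)
    kd <- matrix(NA_real_, nrow = length(peptide), ncol = length(alleles))
    for (j in seq_along(alleles))
        kd[, j] <- predictKd(kdSource, peptide, alleles[j])
    j <- max.col(-kd, ties.method = "first")
    list(kd_nM = kd[cbind(seq_along(peptide), j)], allele = alleles[j])
}

#' Binding filter
#'
#' A neoantigen is "binding" when its mutant dissociation constant is
#' strictly below the threshold (default 500 nM).
#'
#' @param kdMt numeric vector of mutant Kd values (nM).
#' @param thresholdNm positive threshold in nM.
#' @return logical vector.
#' @examples
#' isBinding(c(499.9, 500, 3600))  # TRUE FALSE FALSE
#' @export
isBinding <- function(kdMt, thresholdNm = 500) {
    stopifnot(thresholdNm > 0)
    if (any(kdMt <= 0, na.rm = TRUE)) stop("Kd values must be > 0")
    kdMt < thresholdNm
}

#' MHC-binding amplitude
#'
#' The ratio of the wild-type to the mutant dissociation constant,
#' \eqn{A = K_d^{WT} / K_d^{MT}}. When \code{wtKdCap} is given, the
#' wild-type Kd is capped first (\code{min(kdWt, cap) / kdMt}), a monotone
#' correction hook for predictors that saturate at very weak binding.
#'
#' @param kdWt,kdMt positive numeric vectors (nM).
#' @param wtKdCap positive cap in nM, or \code{NA} (default) for no cap.
#' @return numeric vector of amplitudes.
#' @examples
#' bindingAmplitude(1000, 100)             # 10
#' bindingAmplitude(50000, 100, wtKdCap = 10000)  # 100
#' @export
bindingAmplitude <- function(kdWt, kdMt, wtKdCap = NA_real_) {
    if (any(kdWt <= 0 | kdMt <= 0, na.rm = TRUE))
        stop("Kd values must be > 0")
    if (!is.na(wtKdCap)) {
        if (wtKdCap <= 0) stop("wtKdCap must be > 0")
        kdWt <- pmin(kdWt, wtKdCap)
    }
    kdWt / kdMt
}
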