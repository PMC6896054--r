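#' Query a Kd source for dissociation constants
#'
#' Returns the predicted peptide:MHC dissociation constant (nM) for each
#' (peptide, allele) pair. \code{peptide} and \code{allele} are recycled
#' against each other in the usual vectorized way.
#'
#' @param object a \code{\linkS4class{KdSource}}.
#' @param peptide character vector of 9-mer peptides.
#' @param allele character vector of HLA allele names, e.g. "HLA-A*02:01".
#' @return numeric vector of Kd values in nM.
#' @examples
#' kd <- syntheticKdPredictor(seed = 1L)
#' predictKd(kd, "ACDEFGHIK", "HLA-A*02:01")
#' @export
setGeneric("predictKd", function(object, peptide, allele)
    standardGeneric("predictKd"))

#' Epitope sequences of an EpitopeSet
#'
#' @param x an \code{\linkS4class{EpitopeSet}}.
#' @return character vector of epitope sequences.
#' @export
setGeneric("epitopes", function(x) standardGeneric("epitopes"))
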