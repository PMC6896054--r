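#' Analysis configuration
#'
#' Holds every tunable threshold of the scoring pipeline. Units: dissociation
#' constants are in nM; the TCR parameters \code{tcrA} (horizontal
#' displacement of the binding curve, in alignment-score units) and
#' \code{tcrK} (steepness) are dimensionless.
#'
#' @slot kdBindingThreshold numeric(1), strict upper bound on the mutant
#'   dissociation constant for a "binding" neoantigen (default 500 nM).
#' @slot tcrA numeric(1), horizontal displacement of the TCR binding curve
#'   (default 26).
#' @slot tcrK numeric(1), steepness of the TCR binding curve (default 4.87).
#' @slot rStringentThreshold numeric(1) in [0,1], TCR recognition potential
#'   above which a neoantigen counts as "stringent" (default 0.01).
#' @slot minImmunogenicForEligibility integer(1), minimum number of
#'   immunogenic neoantigens for a sample to enter the group comparison
#'   (default 2, i.e. "more than one").
#' @slot wtKdCap numeric(1), optional cap applied to the wild-type Kd before
#'   the amplitude ratio; \code{NA_real_} disables the cap (default).
#' @slot rngSeed integer(1), seed carried through to any randomized step.
#' @slot averagingSet character(1), which records per-sample means are taken
#'   over: \code{"immunogenic"} (default) or \code{"binding"}.
#' @slot dropMagnitudeOutliers logical(1), whether eligibility additionally
#'   drops samples whose maximum fitness cost is >= 100x below the cohort
#'   mean (off by default).
#'
#' @seealso \code{\link{neoConfig}}, \code{\link{readNeoConfig}}
#' @exportClass NeoConfig
setClass("NeoConfig", representation(
    kdBindingThreshold = "numeric",
    tcrA = "numeric",
    tcrK = "numeric",
    rStringentThreshold = "numeric",
    minImmunogenicForEligibility = "integer",
    wtKdCap = "numeric",
    rngSeed = "integer",
    averagingSet = "character",
    dropMagnitudeOutliers = "logical"
))

setValidity("NeoConfig", function(object) {
    msg <- character()
    chk1 <- function(x, nm) if (length(x) != 1L) msg <<- c(msg, paste(nm, "must have length 1"))
    chk1(object@kdBindingThreshold, "kdBindingThreshold")
    chk1(object@tcrA, "tcrA"); chk1(object@tcrK, "tcrK")
    chk1(object@rStringentThreshold, "rStringentThreshold")
    chk1(object@minImmunogenicForEligibility, "minImmunogenicForEligibility")
    chk1(object@wtKdCap, "wtKdCap"); chk1(object@rngSeed, "rngSeed")
    chk1(object@averagingSet, "averagingSet")
    chk1(object@dropMagnitudeOutliers, "dropMagnitudeOutliers")
    if (length(msg)) return(msg)
    if (!is.finite(object@kdBindingThreshold) || object@kdBindingThreshold <= 0)
        msg <- c(msg, "kdBindingThreshold must be > 0")
    if (!is.finite(object@tcrK) || object@tcrK <= 0)
        msg <- c(msg, "tcrK must be > 0")
    if (!is.finite(object@rStringentThreshold) ||
        object@rStringentThreshold < 0 || object@rStringentThreshold > 1)
        msg <- c(msg, "rStringentThreshold must lie in [0,1]")
    if (is.na(object@minImmunogenicForEligibility) ||
        object@minImmunogenicForEligibility < 0L)
        msg <- c(msg, "minImmunogenicForEligibility must be >= 0")
    if (!is.na(object@wtKdCap) && object@wtKdCap <= 0)
        msg <- c(msg, "wtKdCap must be > 0 (or NA to disable)")
    if (!object@averagingSet %in% c("immunogenic", "binding"))
        msg <- c(msg, "averagingSet must be 'immunogenic' or 'binding'")
    if (length(msg)) msg else TRUE
})

#' Reference set of known T-cell epitopes
#'
#' An ordered, deduplicated set of linear peptide sequences (uppercase,
#' 20-letter amino-acid alphabet, length >= 9) used as the bound states of
#' the TCR recognition partition function.
#'
#' @slot sequences character vector of epitope sequences.
#' @seealso \code{\link{EpitopeSet}}, \code{\link{readEpitopeReference}}
#' @exportClass EpitopeSet
setClass("EpitopeSet", representation(sequences = "character"))

setValidity("EpitopeSet", function(object) {
    s <- object@sequences
    if (anyDuplicated(s)) return("epitope sequences must be unique")
    if (length(s) && any(s != toupper(s))) return("epitopes must be uppercase")
    if (length(s) && any(nchar(s) < 9L)) return("epitopes must be >= 9 residues")
    bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), s)
    if (any(bad))
        return(sprintf("non-amino-acid character in epitope(s): %s",
                       paste(head(s[bad], 3), collapse = ", ")))
    TRUE
})

#' Sources of peptide:MHC dissociation constants
#'
#' \code{KdSource} is the abstract interface the scoring pipeline queries via
#' \code{\link{predictKd}}. Two concrete sources ship with the package:
#' \code{KdTable} wraps a lookup table of predictor output (see
#' \code{\link{readKdTable}}) and raises an error for missing
#' (peptide, allele) pairs; \code{SyntheticKdPredictor} is a deterministic,
#' seeded lognormal model used by the synthetic cohorts (see
#' \code{\link{syntheticKdPredictor}}).
#'
#' @slot table named numeric vector of Kd (nM) keyed by "peptide|allele".
#' @aliases KdTable-class SyntheticKdPredictor-class
#' @exportClass KdSource
setClass("KdSource", representation("VIRTUAL"))

#' @rdname KdSource-class
#' @exportClass KdTable
setClass("KdTable", contains = "KdSource",
         representation(table = "numeric"))

setValidity("KdTable", function(object) {
    if (is.null(names(object@table))) return("Kd table must be named")
    if (length(object@table) && any(!is.finite(object@table) | object@table <= 0))
        return("all Kd values must be finite and > 0")
    if (anyDuplicated(names(object@table)))
        return("duplicate (peptide, allele) entries in Kd table")
    TRUE
})

#' @rdname KdSource-class
#' @slot meanlog,sdlog lognormal parameters of the marginal Kd distribution
#'   on the log-nM scale (SyntheticKdPredictor).
#' @slot seed integer seed entering the positional hash (SyntheticKdPredictor).
#' @exportClass SyntheticKdPredictor
setClass("SyntheticKdPredictor", contains = "KdSource",
         representation(meanlog = "numeric", sdlog = "numeric", seed = "integer"))

setValidity("SyntheticKdPredictor", function(object) {
    if (!is.finite(object@meanlog) || !is.finite(object@sdlog) || object@sdlog <= 0)
        return("meanlog must be finite and sdlog > 0")
    TRUE
})

#' Between-group comparison results
#'
#' Container returned by \code{\link{compareGroups}}.
#'
#' @slot metrics data.frame with one row per summary metric: group means,
#'   rank-sum statistic and two-sided p.
#' @slot correlations data.frame of Spearman rho and least-squares slope with
#'   95 percent CI for mutation-count versus neoantigen-count associations.
#' @slot regressions data.frame of per-covariate slopes, CIs, raw and
#'   Bonferroni-adjusted p for the cell-score (or gene-expression) family.
#' @slot groups named character vector mapping sample id to group label.
#' @exportClass CohortResult
setClass("CohortResult", representation(
    metrics = "data.frame",
    correlations = "data.frame",
    regressions = "data.frame",
    groups = "character"
))

setValidity("CohortResult", function(object) {
    r <- object@regressions
    if (nrow(r) && any(!is.na(r$p_adjusted) &
                       r$p_adjusted < pmin(1, r$p * nrow(r)) - 1e-12))
        return("adjusted p must equal min(1, m * p)")
    TRUE
})
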