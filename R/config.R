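#' Create an analysis configuration
#'
#' Defaults follow the published analysis: 500 nM binding cutoff, TCR curve
#' parameters a = 26 and k = 4.87, a stringent TCR recognition threshold of
#' 0.01, and sample eligibility requiring more than one immunogenic
#' neoantigen.
#'
#' @param kdBindingThreshold strict Kd cutoff (nM) defining binding
#'   neoantigens.
#' @param tcrA horizontal displacement of the TCR binding curve.
#' @param tcrK steepness of the TCR binding curve; must be > 0.
#' @param rStringentThreshold recognition-potential threshold for the
#'   stringent neoantigen subset.
#' @param minImmunogenicForEligibility minimum immunogenic-neoantigen count
#'   for a sample to enter between-group comparisons.
#' @param wtKdCap optional cap (nM) on the wild-type Kd entering the
#'   amplitude; \code{NA} (default) leaves the wild-type value uncorrected.
#' @param rngSeed integer seed recorded in the configuration.
#' @param averagingSet \code{"immunogenic"} or \code{"binding"}; the record
#'   subset over which per-sample means are computed.
#' @param dropMagnitudeOutliers if \code{TRUE}, samples whose maximum fitness
#'   cost is at least 100-fold below the cohort mean are flagged ineligible.
#' @return a validated \code{\linkS4class{NeoConfig}}.
#' @examples
#' cfg <- neoConfig()
#' cfg
#' @export
neoConfig <- function(kdBindingThreshold = 500, tcrA = 26, tcrK = 4.87,
                      rStringentThreshold = 0.01,
                      minImmunogenicForEligibility = 2L,
                      wtKdCap = NA_real_, rngSeed = 1L,
                      averagingSet = c("immunogenic", "binding"),
                      dropMagnitudeOutliers = FALSE) {
    averagingSet <- match.arg(averagingSet)
    new("NeoConfig",
        kdBindingThreshold = as.numeric(kdBindingThreshold),
        tcrA = as.numeric(tcrA), tcrK = as.numeric(tcrK),
        rStringentThreshold = as.numeric(rStringentThreshold),
        minImmunogenicForEligibility = as.integer(minImmunogenicForEligibility),
        wtKdCap = as.numeric(wtKdCap), rngSeed = as.integer(rngSeed),
        averagingSet = averagingSet,
        dropMagnitudeOutliers = isTRUE(dropMagnitudeOutliers))
}

#' @describeIn neoConfig Write a configuration to a YAML file. The file
#'   round-trips losslessly through \code{readNeoConfig}.
#' @param config a \code{NeoConfig}.
#' @param path file path.
#' @export
writeNeoConfig <- function(config, path) {
    stopifnot(is(config, "NeoConfig"))
    validObject(config)
    x <- list(
        kd_binding_threshold_nM = config@kdBindingThreshold,
        tcr_a = config@tcrA,
        tcr_k = config@tcrK,
        r_stringent_threshold = config@rStringentThreshold,
        min_immunogenic_for_eligibility = config@minImmunogenicForEligibility,
        wt_kd_cap_nM = if (is.na(config@wtKdCap)) "none" else config@wtKdCap,
        rng_seed = config@rngSeed,
        averaging_set = config@averagingSet,
        drop_magnitude_outliers = config@dropMagnitudeOutliers)
    yaml::write_yaml(x, path, precision = 17L)
    invisible(path)
}

#' @describeIn neoConfig Read a configuration written by
#'   \code{writeNeoConfig}.
#' @export
readNeoConfig <- function(path) {
    x <- yaml::read_yaml(path)
    need <- c("kd_binding_threshold_nM", "tcr_a", "tcr_k",
              "r_stringent_threshold", "min_immunogenic_for_eligibility",
              "rng_seed", "averaging_set")
    miss <- setdiff(need, names(x))
    if (length(miss))
        stop("config file ", path, " is missing field(s): ",
             paste(miss, collapse = ", "))
    cap <- x$wt_kd_cap_nM
    if (is.null(cap) || identical(cap, "none")) cap <- NA_real_
    neoConfig(kdBindingThreshold = x$kd_binding_threshold_nM,
              tcrA = x$tcr_a, tcrK = x$tcr_k,
              rStringentThreshold = x$r_stringent_threshold,
              minImmunogenicForEligibility = x$min_immunogenic_for_eligibility,
              wtKdCap = cap, rngSeed = x$rng_seed,
              averagingSet = x$averaging_set,
              dropMagnitudeOutliers = isTRUE(x$drop_magnitude_outliers))
}

setMethod("show", "NeoConfig", function(object) {
    cat("NeoConfig\n")
    cat("  binding threshold : <", object@kdBindingThreshold, "nM\n")
    cat("  TCR curve         : a =", object@tcrA, ", k =", object@tcrK, "\n")
    cat("  stringent R       : >=", object@rStringentThreshold, "\n")
    cat("  eligibility       : >=", object@minImmunogenicForEligibility,
        "immunogenic neoantigens\n")
    cat("  WT Kd cap         :",
        if (is.na(object@wtKdCap)) "none" else paste(object@wtKdCap, "nM"), "\n")
    cat("  averaging set     :", object@averagingSet, "\n")
})
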