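# Fitness cost F = A * R (positive sign convention: larger F = more
# predicted immune recognition), the RPKM-fraction expression adjustment,
# and reduction of per-record scores to per-sample summaries.

#' Neoantigen fitness cost
#'
#' The product of MHC-binding amplitude and TCR recognition potential,
#' \eqn{F = A \times R}, kept positive: the greater the fitness cost, the
#' more immune-mediated destruction is predicted.
#'
#' @param A non-negative amplitude.
#' @param R recognition potential in [0, 1).
#' @return numeric vector of fitness costs.
#' @examples
#' fitnessCost(2.5, 0.4)  # 1
#' @export
fitnessCost <- function(A, R) {
    if (any(A < 0, na.rm = TRUE)) stop("amplitude must be >= 0")
    if (any(R < 0 | R >= 1, na.rm = TRUE))
        stop("recognition potential must lie in [0, 1)")
    A * R
}

#' Classify scored records
#'
#' Adds the three nested flags: \code{binding} (mutant Kd strictly below the
#' threshold), \code{immunogenic} (binding with non-zero recognition
#' potential) and \code{stringent} (binding with recognition potential at or
#' above the stringent threshold).
#'
#' @param records scored record data.frame with columns \code{kd_mt_nM} and
#'   \code{recognition}.
#' @param config a \code{\linkS4class{NeoConfig}}.
#' @return \code{records} with logical columns \code{binding},
#'   \code{immunogenic}, \code{stringent} added or replaced.
#' @export
classifyNeoantigens <- function(records, config = neoConfig()) {
    records$binding <- isBinding(records$kd_mt_nM, config@kdBindingThreshold)
    r <- records$recognition
    records$immunogenic <- records$binding & !is.na(r) & r > 0
    records$stringent <- records$binding & !is.na(r) &
        r >= config@rStringentThreshold
    records
}

#' Expression fractions and adjusted fitness cost
#'
#' Within each sample, the expression of every record with non-zero fitness
#' cost is expressed as a fraction of the summed RPKM over those records;
#' the adjusted fitness cost is \eqn{F \times} fraction. Records with
#' \eqn{F = 0} (or unscored records) get no fraction. Transcripts absent
#' from the expression table contribute RPKM 0 (reported via a message);
#' when a sample's F > 0 records carry zero total RPKM its adjustment is
#' undefined and the fractions stay \code{NA}.
#'
#' @param records scored record data.frame (columns \code{sample_id},
#'   \code{transcript_id}, \code{fitness}).
#' @param rpkm expression matrix from \code{\link{readExpression}}
#'   (transcripts x samples), or a named vector treated as one column
#'   shared by all samples.
#' @return \code{records} with columns \code{rpkm},
#'   \code{expression_fraction}, \code{adjusted_fitness}.
#' @export
expressionFractions <- function(records, rpkm) {
    if (is.null(dim(rpkm)))
        rpkm <- matrix(rpkm, ncol = 1L,
                       dimnames = list(names(rpkm), "shared"))
    shared <- identical(colnames(rpkm), "shared")
    absent <- setdiff(unique(records$transcript_id), rownames(rpkm))
    if (length(absent))
        message(length(absent),
                " transcript(s) absent from expression table; RPKM set to 0")
    n <- nrow(records)
    records$rpkm <- rep(NA_real_, n)
    records$expression_fraction <- rep(NA_real_, n)
    records$adjusted_fitness <- rep(NA_real_, n)
    for (idx in split(seq_len(n), records$sample_id)) {
        sid <- records$sample_id[idx[1L]]
        col <- if (shared) 1L else match(sid, colnames(rpkm))
        if (is.na(col))
            stop("sample ", sid, " absent from expression table")
        r <- rpkm[match(records$transcript_id[idx], rownames(rpkm)), col]
        r[is.na(r)] <- 0
        records$rpkm[idx] <- r
        pos <- idx[!is.na(records$fitness[idx]) & records$fitness[idx] > 0]
        if (!length(pos)) next
        tot <- sum(records$rpkm[pos])
        if (tot <= 0) {
            warning("sample ", sid, ": all F > 0 records have zero RPKM; ",
                    "expression adjustment undefined")
            next
        }
        records$expression_fraction[pos] <- records$rpkm[pos] / tot
        records$adjusted_fitness[pos] <-
            records$fitness[pos] * records$expression_fraction[pos]
    }
    records
}

meanOrNA <- function(x) if (length(x)) mean(x) else NA_real_
maxOrNA <- function(x) if (length(x)) max(x) else NA_real_

#' Reduce one sample's records to its summary row
#'
#' Counts come from the classification flags; means of the mutant Kd,
#' amplitude, recognition potential and fitness cost are taken over the
#' configured averaging set (immunogenic records by default), the maximum
#' fitness cost over immunogenic records, and the adjusted statistics over
#' records with a defined adjustment.
#'
#' @param records one sample's classified records.
#' @param counts list or one-row data.frame with
#'   \code{n_somatic_mutations}, \code{n_peptides_21mer},
#'   \code{n_possible_9mers}.
#' @param config a \code{\linkS4class{NeoConfig}}.
#' @return one-row data.frame (see \code{\link{summarizeSamples}}).
#' @export
summarizeSample <- function(records, counts, config = neoConfig()) {
    stopifnot(length(unique(records$sample_id)) <= 1L)
    nBinding <- sum(records$binding)
    nImmuno <- sum(records$immunogenic)
    nStringent <- sum(records$stringent)
    avg <- records[records[[config@averagingSet]], , drop = FALSE]
    imm <- records[records$immunogenic, , drop = FALSE]
    adj <- records$adjusted_fitness
    adj <- adj[!is.na(adj)]
    data.frame(
        sample_id = if (nrow(records)) records$sample_id[1L]
                    else counts$sample_id,
        n_somatic_mutations = counts$n_somatic_mutations,
        n_peptides_21mer = counts$n_peptides_21mer,
        n_possible_9mers = counts$n_possible_9mers,
        n_binding = nBinding,
        n_immunogenic = nImmuno,
        n_stringent = nStringent,
        ratio_immunogenic_binding =
            if (nBinding) nImmuno / nBinding else NA_real_,
        ratio_stringent_binding =
            if (nBinding) nStringent / nBinding else NA_real_,
        mean_kd_mt = meanOrNA(avg$kd_mt_nM),
        mean_amplitude = meanOrNA(avg$amplitude),
        mean_R = meanOrNA(avg$recognition),
        mean_F = meanOrNA(avg$fitness),
        max_F = maxOrNA(imm$fitness),
        mean_F_adj = meanOrNA(adj),
        max_F_adj = maxOrNA(adj),
        adjustment_defined = length(adj) > 0L)
}

#' Per-sample summaries for a scored cohort
#'
#' @param records classified (and, if expression is available, adjusted)
#'   record data.frame for all samples.
#' @param counts data.frame with one row per sample: \code{sample_id},
#'   \code{n_somatic_mutations}, \code{n_peptides_21mer},
#'   \code{n_possible_9mers}. Samples with zero records still get a row.
#' @param config a \code{\linkS4class{NeoConfig}}.
#' @return data.frame with one row per sample including counts, ratios,
#'   averaging-set means, maximum and adjusted fitness costs, and the
#'   \code{eligible} flag from \code{\link{selectEligibleSamples}}.
#' @export
summarizeSamples <- function(records, counts, config = neoConfig()) {
    rows <- lapply(seq_len(nrow(counts)), function(i) {
        sid <- counts$sample_id[i]
        summarizeSample(records[records$sample_id == sid, , drop = FALSE],
                        counts[i, ], config)
    })
    selectEligibleSamples(do.call(rbind, rows), config)
}

#' Flag samples eligible for the between-group comparison
#'
#' A sample is eligible when it has at least
#' \code{minImmunogenicForEligibility} immunogenic neoantigens (default 2,
#' i.e. more than one). With \code{dropMagnitudeOutliers} enabled, samples
#' whose maximum fitness cost is at least 100-fold below the mean maximum
#' fitness cost of the otherwise-eligible samples are additionally dropped.
#'
#' @param summaries summary data.frame from \code{\link{summarizeSamples}}.
#' @param config a \code{\linkS4class{NeoConfig}}.
#' @return \code{summaries} with a logical \code{eligible} column.
#' @export
selectEligibleSamples <- function(summaries, config = neoConfig()) {
    elig <- summaries$n_immunogenic >= config@minImmunogenicForEligibility
    if (config@dropMagnitudeOutliers) {
        mf <- summaries$max_F
        base <- mean(mf[elig & !is.na(mf)])
        if (is.finite(base) && base > 0)
            elig <- elig & !(!is.na(mf) & mf <= base / 100)
    }
    summaries$eligible <- elig
    summaries
}
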