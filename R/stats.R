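# Small-cohort statistics: exact and normal-approximation Wilcoxon rank-sum,
# Spearman correlation, least-squares slope with t-based CI, Bonferroni
# correction, HLA binding-groove overlap flags and the two-standard-deviation
# expression check, plus the cohort-level driver compareGroups().

#' Wilcoxon rank-sum test
#'
#' The statistic is the rank sum of \code{x} (mid-ranks on ties). In
#' \code{"exact"} mode the two-sided p-value is obtained by full enumeration
#' of all \code{choose(nx + ny, nx)} assignments of the observed ranks
#' (doubled smaller tail, capped at 1). \code{"normal"} mode uses the
#' tie-corrected normal approximation without continuity correction, i.e.
#' the behaviour of the classical large-sample rank-sum test. \code{"auto"}
#' picks exact when the combined size is at most 12 and there are no ties.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param mode \code{"auto"}, \code{"exact"} or \code{"normal"}.
#' @return list with \code{statistic} (rank sum of \code{x}), \code{p}
#'   (two-sided) and \code{mode} (mode actually used).
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4), mode = "exact")$p  # 1/3
#' @export
wilcoxonRankSum <- function(x, y, mode = c("auto", "exact", "normal")) {
    mode <- match.arg(mode)
    if (!length(x) || !length(y)) stop("both groups must be non-empty")
    if (anyNA(c(x, y))) stop("missing values in input")
    nx <- length(x); ny <- length(y); n <- nx + ny
    r <- rank(c(x, y))
    W <- sum(r[seq_len(nx)])
    ties <- anyDuplicated(c(x, y)) > 0L
    if (mode == "auto") mode <- if (n <= 12L && !ties) "exact" else "normal"
    if (mode == "exact") {
        sums <- combn(r, nx, sum)
        pLow <- mean(sums <= W + 1e-9)
        pHigh <- mean(sums >= W - 1e-9)
        p <- min(1, 2 * min(pLow, pHigh))
    } else {
        mu <- nx * (n + 1) / 2
        t <- table(r)
        v <- nx * ny / 12 * ((n + 1) - sum(t^3 - t) / (n * (n - 1)))
        p <- if (v <= 0) 1 else 2 * pnorm(-abs(W - mu) / sqrt(v))
    }
    list(statistic = W, p = p, mode = mode)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (tie-aware). Constant input yields
#' \code{NA} with a warning.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return rho in [-1, 1], or \code{NA}.
#' @export
spearmanRho <- function(x, y) {
    stopifnot(length(x) == length(y), length(x) >= 3L)
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
        warning("constant vector: Spearman rho undefined")
        return(NA_real_)
    }
    cor(x, y, method = "spearman")
}

#' Least-squares slope with confidence interval
#'
#' Ordinary least squares of \code{y} on \code{x}, returning the slope, its
#' t-based confidence interval at the requested level, and the slope's
#' two-sided p-value.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @param level confidence level (default 0.95).
#' @return list with \code{slope}, \code{ci_low}, \code{ci_high}, \code{p}.
#' @export
olsSlopeCi <- function(x, y, level = 0.95) {
    stopifnot(length(x) == length(y), length(x) >= 3L)
    if (length(unique(x)) == 1L)
        stop("degenerate design: x is constant")
    fit <- lm(y ~ x)
    est <- summary(fit)$coefficients
    slope <- est["x", "Estimate"]
    se <- est["x", "Std. Error"]
    tq <- qt((1 + level) / 2, df = fit$df.residual)
    p <- est["x", "Pr(>|t|)"]
    if (!is.finite(p)) p <- NA_real_
    list(slope = unname(slope), ci_low = unname(slope - tq * se),
         ci_high = unname(slope + tq * se), p = unname(p))
}

#' Bonferroni correction
#'
#' Each p-value is mapped to \code{min(1, m * p)} with m the family size.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bonferroni <- function(pvals) {
    if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    p.adjust(pvals, method = "bonferroni")
}

#' Flag variants in HLA coding regions and the peptide-binding groove
#'
#' A variant is \code{in_coding} when its genomic position falls in any
#' annotated HLA exon interval and \code{in_groove} when that interval
#' belongs to exon 2 or 3 (the exons encoding the MHC class I
#' peptide-binding groove).
#'
#' @param variants variant data.frame with \code{chrom} and \code{pos}.
#' @param annotation \code{GRanges} from \code{\link{readGrooveAnnotation}}.
#' @return \code{variants} with logical columns \code{in_coding},
#'   \code{in_groove} and character \code{hla_gene} (\code{NA} outside
#'   coding regions).
#' @export
flagGrooveMutations <- function(variants, annotation) {
    gr <- GenomicRanges::GRanges(
        variants$chrom, IRanges::IRanges(variants$pos, variants$pos))
    hitAny <- GenomicRanges::findOverlaps(gr, annotation)
    variants$in_coding <- seq_len(nrow(variants)) %in%
        S4Vectors::queryHits(hitAny)
    variants$in_groove <- seq_len(nrow(variants)) %in%
        S4Vectors::queryHits(hitAny)[annotation$groove[
            S4Vectors::subjectHits(hitAny)]]
    variants$hla_gene <- NA_character_
    if (length(hitAny))
        variants$hla_gene[S4Vectors::queryHits(hitAny)] <-
            annotation$gene[S4Vectors::subjectHits(hitAny)]
    variants
}

#' Two-standard-deviation expression check
#'
#' Whether a value lies within \code{nSd} sample standard deviations of the
#' cohort mean (used to judge whether a mutation measurably changed a
#' gene's expression).
#'
#' @param value single expression value.
#' @param cohort numeric vector of the gene's expression across samples
#'   (length >= 2).
#' @param nSd number of standard deviations (default 2).
#' @return logical: \code{TRUE} when within range.
#' @export
expressionOutlierCheck <- function(value, cohort, nSd = 2) {
    stopifnot(length(cohort) >= 2L)
    s <- sd(cohort)
    m <- mean(cohort)
    if (s == 0) {
        warning("zero standard deviation in cohort")
        return(value == m)
    }
    abs(value - m) <= nSd * s
}

COUNT_METRICS <- c("n_somatic_mutations", "n_binding", "n_immunogenic")
FITNESS_METRICS <- c("ratio_immunogenic_binding", "ratio_stringent_binding",
                     "mean_kd_mt", "mean_amplitude", "mean_R", "mean_F",
                     "max_F", "mean_F_adj", "max_F_adj")

#' Between-group comparison of sample summaries
#'
#' Runs the rank-sum test on every summary metric between the two groups
#' (count metrics over all samples; fitness metrics over eligible samples
#' only), Spearman correlation and least-squares slope of somatic-mutation
#' counts against binding and immunogenic neoantigen counts, and, when
#' cell-type scores are supplied, a least-squares regression of the
#' adjusted maximum fitness cost on each score column with a Bonferroni
#' correction over that family. Metrics that cannot be computed (fewer than
#' two usable samples per group, constant values) yield \code{NA} entries
#' rather than an error.
#'
#' @param summaries summary data.frame from \code{\link{summarizeSamples}}.
#' @param groups named character vector (sample id -> group label) with
#'   exactly two distinct labels.
#' @param config a \code{\linkS4class{NeoConfig}}.
#' @param cellScores optional data.frame of per-sample scores (rownames =
#'   sample ids), e.g. from \code{\link{readCellScores}}.
#' @param wilcoxonMode mode passed to \code{\link{wilcoxonRankSum}};
#'   defaults to the normal approximation, the behaviour of the classical
#'   rank-sum test in mainstream statistics packages.
#' @return a \code{\linkS4class{CohortResult}}.
#' @export
compareGroups <- function(summaries, groups, config = neoConfig(),
                          cellScores = NULL,
                          wilcoxonMode = c("normal", "exact", "auto")) {
    wilcoxonMode <- match.arg(wilcoxonMode)
    lev <- sort(unique(unname(groups)))
    if (length(lev) != 2L)
        stop("exactly two group labels are required, got: ",
             paste(lev, collapse = ", "))
    g <- unname(groups[summaries$sample_id])
    if (anyNA(g)) stop("sample(s) missing from the groups table: ",
                       paste(summaries$sample_id[is.na(g)], collapse = ", "))

    oneMetric <- function(metric, useEligible) {
        keep <- !is.na(summaries[[metric]])
        if (useEligible) keep <- keep & summaries$eligible
        x <- summaries[[metric]][keep & g == lev[1L]]
        y <- summaries[[metric]][keep & g == lev[2L]]
        base <- data.frame(metric = metric,
                           mean_a = meanOrNA(x), mean_b = meanOrNA(y),
                           n_a = length(x), n_b = length(y),
                           statistic = NA_real_, p = NA_real_)
        if (length(x) < 2L || length(y) < 2L) return(base)
        w <- wilcoxonRankSum(x, y, mode = wilcoxonMode)
        base$statistic <- w$statistic
        base$p <- w$p
        base
    }
    metrics <- rbind(
        do.call(rbind, lapply(COUNT_METRICS, oneMetric, useEligible = FALSE)),
        do.call(rbind, lapply(FITNESS_METRICS, oneMetric, useEligible = TRUE)))

    oneCor <- function(yname) {
        x <- summaries$n_somatic_mutations
        y <- summaries[[yname]]
        out <- data.frame(pair = paste0("n_somatic_mutations~", yname),
                          rho = NA_real_, slope = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          p = NA_real_)
        tryCatch(suppressWarnings({
            out$rho <- spearmanRho(x, y)
            fit <- olsSlopeCi(x, y)
            out$slope <- fit$slope; out$ci_low <- fit$ci_low
            out$ci_high <- fit$ci_high; out$p <- fit$p
        }), error = function(e) NULL)
        out
    }
    correlations <- rbind(oneCor("n_binding"), oneCor("n_immunogenic"))

    regressions <- data.frame(covariate = character(), slope = numeric(),
                              ci_low = numeric(), ci_high = numeric(),
                              p = numeric(), p_adjusted = numeric())
    if (!is.null(cellScores) && ncol(cellScores)) {
        keep <- summaries$eligible & !is.na(summaries$max_F_adj) &
            summaries$sample_id %in% rownames(cellScores)
        y <- summaries$max_F_adj[keep]
        sc <- cellScores[summaries$sample_id[keep], , drop = FALSE]
        rows <- lapply(names(sc), function(cv) {
            out <- data.frame(covariate = cv, slope = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_,
                              p = NA_real_)
            tryCatch(suppressWarnings({
                fit <- olsSlopeCi(sc[[cv]], y)
                out$slope <- fit$slope; out$ci_low <- fit$ci_low
                out$ci_high <- fit$ci_high; out$p <- fit$p
            }), error = function(e) NULL)
            out
        })
        regressions <- do.call(rbind, rows)
        regressions$p_adjusted <- bonferroni(regressions$p)
    }

    new("CohortResult", metrics = metrics, correlations = correlations,
        regressions = regressions, groups = setNames(g, summaries$sample_id))
}

#' @rdname compareGroups
#' @param object a \code{CohortResult}.
#' @aliases show,CohortResult-method
#' @export
setMethod("show", "CohortResult", function(object) {
    lev <- sort(unique(object@groups))
    cat("CohortResult:", sum(object@groups == lev[1L]), lev[1L], "vs",
        sum(object@groups == lev[2L]), lev[2L], "samples\n")
    m <- object@metrics
    for (i in seq_len(nrow(m)))
        cat(sprintf("  %-26s mean %s=%.4g  %s=%.4g  p=%.4g\n",
                    m$metric[i], lev[1L], m$mean_a[i], lev[2L], m$mean_b[i],
                    m$p[i]))
    if (nrow(object@correlations))
        for (i in seq_len(nrow(object@correlations)))
            with(object@correlations[i, ],
                 cat(sprintf("  %-38s rho=%.3f slope=%.3g [%.3g, %.3g]\n",
                             pair, rho, slope, ci_low, ci_high)))
    if (nrow(object@regressions))
        cat("  ", nrow(object@regressions),
            "covariate regressions (Bonferroni-adjusted)\n")
})

#' Accessors for CohortResult components
#'
#' @param x a \code{\linkS4class{CohortResult}}.
#' @return the corresponding data.frame.
#' @name cohortResultAccessors
#' @export
resultMetrics <- function(x) { stopifnot(is(x, "CohortResult")); x@metrics }

#' @rdname cohortResultAccessors
#' @export
resultCorrelations <- function(x) {
    stopifnot(is(x, "CohortResult")); x@correlations
}

#' @rdname cohortResultAccessors
#' @export
resultRegressions <- function(x) {
    stopifnot(is(x, "CohortResult")); x@regressions
}
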