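# The scoring pipeline tying the modules together, plus file-level commands
# (simulate / score / summarize / compare) used by the command-line wrapper
# in inst/scripts/neofit. All commands are deterministic given their inputs,
# so rerunning a stage with the same seed reproduces its output files
# byte-identically.

RECORD_COLS <- c("sample_id", "gene", "transcript_id", "protein_pos",
                 "pair_index", "window_start", "mutant_9mer", "wildtype_9mer",
                 "contains_mutation", "kd_mt_nM", "kd_wt_nM", "best_allele_mt",
                 "best_allele_wt", "amplitude", "recognition", "fitness",
                 "binding", "immunogenic", "stringent", "rpkm",
                 "expression_fraction", "adjusted_fitness")

#' Score a cohort of somatic variants
#'
#' Runs the full per-record scoring chain: near-indel SNV filtering, 21-mer
#' peptide-pair construction, 9-mer window enumeration, best-allele Kd
#' assignment for mutant and wild-type windows, the binding filter,
#' amplitude, TCR recognition potential (for binding records by default;
#' see \code{computeAllR}) and fitness cost. Expression adjustment is
#' applied when an RPKM matrix is supplied.
#'
#' @param variants variant data.frame (\code{\link{readVariants}}).
#' @param proteome named character vector or \code{AAStringSet} keyed by
#'   transcript id.
#' @param alleles character vector of HLA alleles shared by all samples, or
#'   a named list with one vector per sample id.
#' @param kdSource a \code{\linkS4class{KdSource}}.
#' @param epitopeRef an \code{\linkS4class{EpitopeSet}}.
#' @param expression optional RPKM matrix (\code{\link{readExpression}}).
#' @param config a \code{\linkS4class{NeoConfig}}.
#' @param computeAllR compute the recognition potential for every window
#'   rather than only for binding records. The published analysis only
#'   considers neoantigens passing the 500 nM filter, so restricting the
#'   (expensive) recognition computation to them changes no downstream
#'   quantity; non-binding windows carry \code{NA}.
#' @param windowBp proximity window of the near-indel SNV filter.
#' @return list with \code{records} (one row per 9-mer window, columns as
#'   in the scored-records TSV), \code{counts} (per-sample somatic
#'   mutation, peptide and window counts) and \code{config}.
#' @export
scoreNeoantigens <- function(variants, proteome, alleles, kdSource,
                             epitopeRef, expression = NULL,
                             config = neoConfig(), computeAllR = FALSE,
                             windowBp = 1L) {
    variants <- filterSnvsNearIndels(variants, windowBp)
    sampleIds <- unique(variants$sample_id)
    if (!is.list(alleles))
        alleles <- setNames(rep(list(alleles), length(sampleIds)), sampleIds)
    missA <- setdiff(sampleIds, names(alleles))
    if (length(missA))
        stop("no allele list for sample(s): ", paste(missA, collapse = ", "))

    pairs <- buildPeptideTable(variants, proteome)
    records <- enumerateNineMerTable(pairs)
    counts <- data.frame(
        sample_id = sampleIds,
        n_somatic_mutations = as.integer(table(variants$sample_id)[sampleIds]),
        n_peptides_21mer = as.integer(
            table(factor(pairs$sample_id, levels = sampleIds))),
        n_possible_9mers = as.integer(
            table(factor(records$sample_id, levels = sampleIds))))

    n <- nrow(records)
    records$kd_mt_nM <- rep(NA_real_, n)
    records$kd_wt_nM <- rep(NA_real_, n)
    records$best_allele_mt <- rep(NA_character_, n)
    records$best_allele_wt <- rep(NA_character_, n)
    for (sid in sampleIds) {
        i <- which(records$sample_id == sid)
        if (!length(i)) next
        al <- alleles[[sid]]
        mt <- bestKd(records$mutant_9mer[i], al, kdSource)
        wt <- bestKd(records$wildtype_9mer[i], al, kdSource)
        records$kd_mt_nM[i] <- mt$kd_nM
        records$best_allele_mt[i] <- mt$allele
        records$kd_wt_nM[i] <- wt$kd_nM
        records$best_allele_wt[i] <- wt$allele
    }
    records$amplitude <- bindingAmplitude(records$kd_wt_nM, records$kd_mt_nM,
                                          config@wtKdCap)
    records$binding <- isBinding(records$kd_mt_nM, config@kdBindingThreshold)
    records$recognition <- rep(NA_real_, n)
    scope <- if (computeAllR) seq_len(n) else which(records$binding)
    if (length(scope)) {
        peps <- unique(records$mutant_9mer[scope])
        r <- recognitionPotential(peps, epitopeRef,
                                  a = config@tcrA, k = config@tcrK)
        records$recognition[scope] <-
            r[match(records$mutant_9mer[scope], peps)]
    }
    records$fitness <- records$amplitude * records$recognition
    records <- classifyNeoantigens(records, config)
    records$rpkm <- rep(NA_real_, n)
    records$expression_fraction <- rep(NA_real_, n)
    records$adjusted_fitness <- rep(NA_real_, n)
    if (!is.null(expression))
        records <- expressionFractions(records, expression)
    list(records = records[RECORD_COLS], counts = counts, config = config)
}

#' File-level pipeline commands
#'
#' Thin wrappers gluing the readers, the scoring pipeline and the writers
#' together; these back the \code{neofit} command-line script.
#' \code{runSimulate} writes a synthetic cohort bundle; \code{runScore}
#' scores a bundle (or any equivalently-laid-out inputs) and writes
#' \code{records.tsv} + \code{counts.tsv}; \code{runSummarize} writes the
#' per-sample \code{summaries.tsv}; \code{runCompare} writes the
#' between-group statistics.
#'
#' @param outDir,out output directory / file.
#' @param seed integer seed overriding the configuration's.
#' @param config a \code{\link{simConfig}} (simulate) or path to a YAML
#'   scoring configuration (score).
#' @return the main output path, invisibly.
#' @name pipelineCommands
#' @export
runSimulate <- function(outDir, config = simConfig(), seed = NULL) {
    if (!is.null(seed)) {
        config$seed <- as.integer(seed)
        config <- do.call(simConfig, config[setdiff(names(config), "kdMeanlog")])
    }
    generateCohort(config, outDir = outDir)
    invisible(outDir)
}

#' @rdname pipelineCommands
#' @param variants,proteins,alleles,kd,epitopes,expressionPath input files;
#'   \code{alleles} is a directory of per-sample \code{<sample>.txt} lists
#'   (or a single list shared by all samples); \code{kd} is either a Kd TSV
#'   (\code{\link{readKdTable}}) or a YAML Kd model
#'   (\code{\link{readKdModel}}).
#' @export
runScore <- function(variants, proteins, alleles, kd, epitopes,
                     expressionPath = NULL, config = NULL, outDir) {
    cfg <- if (is.null(config)) neoConfig() else readNeoConfig(config)
    v <- readVariants(variants,
                      dialect = if (grepl("\\.vcf$", variants)) "vcf" else "tsv")
    prot <- as.character(Biostrings::readAAStringSet(proteins))
    names(prot) <- sub("\\s.*$", "", names(prot))
    al <- if (dir.exists(alleles)) {
        files <- list.files(alleles, pattern = "\\.txt$", full.names = TRUE)
        setNames(lapply(files, readAlleleList),
                 sub("\\.txt$", "", basename(files)))
    } else readAlleleList(alleles)
    kdSource <- if (grepl("\\.ya?ml$", kd)) readKdModel(kd) else readKdTable(kd)
    eps <- readEpitopeReference(epitopes)
    expr <- if (!is.null(expressionPath)) readExpression(expressionPath)
    scored <- scoreNeoantigens(v, prot, al, kdSource, eps,
                               expression = expr, config = cfg)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeResultsTsv(scored$records, file.path(outDir, "records.tsv"))
    writeResultsTsv(scored$counts, file.path(outDir, "counts.tsv"))
    writeNeoConfig(cfg, file.path(outDir, "config.yaml"))
    invisible(outDir)
}

#' @rdname pipelineCommands
#' @param scoredDir directory written by \code{runScore}.
#' @export
runSummarize <- function(scoredDir, out) {
    records <- readResultsTsv(file.path(scoredDir, "records.tsv"))
    counts <- readResultsTsv(file.path(scoredDir, "counts.tsv"))
    cfg <- readNeoConfig(file.path(scoredDir, "config.yaml"))
    writeResultsTsv(summarizeSamples(records, counts, cfg), out)
    invisible(out)
}

#' @rdname pipelineCommands
#' @param summaries summaries TSV from \code{runSummarize}.
#' @param groups groups TSV (\code{\link{readGroups}}).
#' @param cellScores optional cell-score TSV (\code{\link{readCellScores}}).
#' @param configPath optional scoring-configuration YAML.
#' @export
runCompare <- function(summaries, groups, out, cellScores = NULL,
                       configPath = NULL) {
    s <- readResultsTsv(summaries)
    g <- readGroups(groups)
    cfg <- if (is.null(configPath)) neoConfig() else readNeoConfig(configPath)
    cs <- if (!is.null(cellScores)) readCellScores(cellScores)
    res <- compareGroups(s, g, cfg, cellScores = cs)
    m <- resultMetrics(res)
    m$kind <- "metric"
    cr <- resultCorrelations(res)
    rg <- resultRegressions(res)
    writeResultsTsv(m, out)
    writeResultsTsv(cr, sub("(\\.tsv)?$", "_correlations.tsv", out))
    if (nrow(rg))
        writeResultsTsv(rg, sub("(\\.tsv)?$", "_regressions.tsv", out))
    invisible(out)
}
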