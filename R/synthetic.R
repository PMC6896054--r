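# Seeded synthetic cohorts. The generator emulates the study conditions the
# analysis assumes: 3 + 4 samples in two lesion groups, per-sample somatic
# burden spanning two orders of magnitude, lognormal peptide:MHC
# dissociation constants, a small epitope reference, per-transcript RPKM
# expression, and a planted group effect in which one group suppresses the
# expression of the transcripts carrying its highest-fitness-cost
# neoantigens. Every sample additionally carries a small number of planted
# "immunodominant" driver mutations whose mutant 9-mers closely match an
# epitope in the reference (recognition potential near 1), mirroring
# recurrent driver mutations resembling validated T-cell antigens; all
# planted structure is recorded in a manifest.

ALLELE_POOL <- c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*03:01", "HLA-A*24:02",
                 "HLA-B*07:02", "HLA-B*08:01", "HLA-B*35:01", "HLA-B*44:02",
                 "HLA-C*04:01", "HLA-C*05:01", "HLA-C*07:01", "HLA-C*07:02")

withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

#' Synthetic-cohort configuration
#'
#' Study conditions of the simulated cohorts. Defaults emulate the analyzed
#' skin-lesion cohort: 3 precursor-group plus 4 invasive-group eligible
#' samples, somatic burden 50-5000 per sample, lognormal-range dissociation
#' constants calibrated so that roughly 3 percent of 9-mer windows bind
#' after best-of-six-allele selection, and an expression-suppression effect
#' of 0.05 applied in group B to the transcripts carrying each sample's
#' top-3 fitness-cost neoantigens.
#'
#' @param nSamples length-2 integer vector: samples in group A and group B.
#' @param mutationBurdenRange length-2 range of per-sample somatic mutation
#'   counts (drawn uniformly).
#' @param fractionNonsynonymous fraction of SNVs that are non-synonymous.
#' @param indelFraction fraction of the burden that are indel calls.
#' @param nearIndelFraction fraction of indels that get a planted SNV
#'   within 1 bp (artifacts the proximity filter must remove).
#' @param nProteins,proteinLengthRange size and length range of the
#'   synthetic proteome; each protein carries one candidate driver hotspot.
#' @param nDecoyEpitopes random decoy sequences added to the epitope
#'   reference on top of the hotspot-derived epitopes.
#' @param kdSdlog lognormal sd (log-nM) of the synthetic Kd model.
#' @param bindingFractionTarget target marginal probability that a single
#'   (peptide, allele) Kd is below 500 nM; the lognormal mean is calibrated
#'   from it via \code{\link{calibrateKdMeanlog}}.
#' @param expressionMeanlog,expressionSdlog lognormal RPKM parameters.
#' @param suppressionEffect multiplier applied in group B to the RPKM of
#'   suppressed transcripts (0.05 = 20-fold down; 1 = no effect/null).
#' @param suppressionTopK number of distinct top-fitness transcripts
#'   suppressed per group-B sample.
#' @param allelesPerSample HLA class I alleles drawn per sample (2 each of
#'   A, B, C from a pool of 12).
#' @param seed integer master seed; every draw derives from it.
#' @return a validated list of class \code{neoSimConfig}.
#' @export
simConfig <- function(nSamples = c(3L, 4L),
                      mutationBurdenRange = c(50L, 5000L),
                      fractionNonsynonymous = 0.5,
                      indelFraction = 0.03,
                      nearIndelFraction = 0.2,
                      nProteins = 60L,
                      proteinLengthRange = c(300L, 600L),
                      nDecoyEpitopes = 15L,
                      kdSdlog = 2,
                      bindingFractionTarget = 0.005,
                      expressionMeanlog = 1,
                      expressionSdlog = 0.5,
                      suppressionEffect = 0.05,
                      suppressionTopK = 3L,
                      allelesPerSample = 6L,
                      seed = 1L) {
    cfg <- list(nSamples = as.integer(nSamples),
                mutationBurdenRange = as.integer(mutationBurdenRange),
                fractionNonsynonymous = fractionNonsynonymous,
                indelFraction = indelFraction,
                nearIndelFraction = nearIndelFraction,
                nProteins = as.integer(nProteins),
                proteinLengthRange = as.integer(proteinLengthRange),
                nDecoyEpitopes = as.integer(nDecoyEpitopes),
                kdSdlog = kdSdlog,
                bindingFractionTarget = bindingFractionTarget,
                kdMeanlog = calibrateKdMeanlog(bindingFractionTarget, kdSdlog),
                expressionMeanlog = expressionMeanlog,
                expressionSdlog = expressionSdlog,
                suppressionEffect = suppressionEffect,
                suppressionTopK = as.integer(suppressionTopK),
                allelesPerSample = as.integer(allelesPerSample),
                seed = as.integer(seed))
    stopifnot(length(cfg$nSamples) == 2L, all(cfg$nSamples >= 1L),
              length(cfg$mutationBurdenRange) == 2L,
              diff(cfg$mutationBurdenRange) >= 0L,
              cfg$fractionNonsynonymous >= 0, cfg$fractionNonsynonymous <= 1,
              cfg$suppressionEffect >= 0, cfg$suppressionEffect <= 1,
              cfg$kdSdlog > 0, cfg$nProteins >= 0L,
              diff(cfg$proteinLengthRange) >= 0L,
              cfg$proteinLengthRange[1L] >= 50L,
              cfg$allelesPerSample %in% c(3L, 6L))
    structure(cfg, class = "neoSimConfig")
}

#' Calibrate the synthetic Kd lognormal mean
#'
#' Solves \eqn{P(Kd < threshold) = target} for the lognormal mean at the
#' given sd: \code{meanlog = log(threshold) - sdlog * qnorm(target)}.
#'
#' @param target marginal binding probability per (peptide, allele).
#' @param sdlog lognormal sd on the log-nM scale.
#' @param thresholdNm binding threshold (default 500 nM).
#' @return the calibrated meanlog.
#' @export
calibrateKdMeanlog <- function(target, sdlog, thresholdNm = 500) {
    stopifnot(target > 0, target < 1, sdlog > 0)
    log(thresholdNm) - sdlog * qnorm(target)
}

# stable, platform-independent string hash onto [0, 1). Each byte is folded
# in with a multiplicative (MINSTD) step so that single-character changes
# anywhere in the key diffuse across the whole range; all intermediate
# products stay below 2^53, so the arithmetic is exact in doubles.
stableHashUnit <- function(strings) {
    m <- 2147483647
    vapply(strings, function(s) {
        h <- 7
        for (b in utf8ToInt(s)) h <- ((h + b) * 48271) %% m
        h <- (h * 48271) %% m
        h <- (h * 48271) %% m
        (h + 0.5) / m
    }, numeric(1L), USE.NAMES = FALSE)
}

# per-(allele, position, residue) standard-normal effects of the synthetic
# Kd model; peptide log-Kd is their scaled sum, so peptides sharing 8 of 9
# residues get correlated (rho = 8/9) but distinct values. Tables are pure
# functions of (allele, seed) and are memoised.
.kdEffectCache <- new.env(parent = emptyenv())

kdEffectTable <- function(allele, seed) {
    key <- paste(seed, allele, sep = "|")
    tab <- .kdEffectCache[[key]]
    if (!is.null(tab)) return(tab)
    keys <- paste(seed, allele,
                  rep(1:9, each = 20L), rep(AA_ALPHABET, 9L), sep = "|")
    tab <- matrix(qnorm(stableHashUnit(keys)), nrow = 20L,
                  dimnames = list(AA_ALPHABET, NULL))
    .kdEffectCache[[key]] <- tab
    tab
}

#' Deterministic synthetic Kd predictor
#'
#' A pure function of (peptide, allele, seed): each (allele, position,
#' residue) combination hashes to a standard-normal effect, the nine
#' positional effects are summed and scaled to unit variance, and mapped
#' through the configured lognormal. Identical inputs always give identical
#' Kd; 9-mers differing at a single residue receive correlated
#' (rho = 8/9) but distinct values.
#'
#' @param meanlog,sdlog lognormal parameters on the log-nM scale; by
#'   default calibrated for a 0.005 marginal binding probability at 500 nM.
#' @param seed integer seed of the hash.
#' @return a \code{\linkS4class{SyntheticKdPredictor}}.
#' @examples
#' kd <- syntheticKdPredictor(seed = 7L)
#' predictKd(kd, "ACDEFGHIK", "HLA-A*02:01")
#' @export
syntheticKdPredictor <- function(meanlog = calibrateKdMeanlog(0.005, 2),
                                 sdlog = 2, seed = 1L) {
    new("SyntheticKdPredictor", meanlog = meanlog, sdlog = sdlog,
        seed = as.integer(seed))
}

#' @rdname predictKd
#' @aliases predictKd,SyntheticKdPredictor-method
#' @export
setMethod("predictKd", "SyntheticKdPredictor", function(object, peptide,
                                                        allele) {
    n <- max(length(peptide), length(allele))
    peptide <- rep_len(as.character(peptide), n)
    allele <- rep_len(as.character(allele), n)
    if (any(nchar(peptide) != 9L))
        stop("the synthetic Kd model is defined for 9-mers only")
    z <- numeric(n)
    for (al in unique(allele)) {
        tab <- kdEffectTable(al, object@seed)
        i <- which(allele == al)
        acc <- numeric(length(i))
        for (p in 1:9) {
            aa <- match(substring(peptide[i], p, p), AA_ALPHABET)
            if (anyNA(aa))
                stop("non-amino-acid character in peptide(s): ",
                     peptide[i][which(is.na(aa))[1L]])
            acc <- acc + tab[cbind(aa, p)]
        }
        z[i] <- acc / 3
    }
    exp(object@meanlog + object@sdlog * z)
})

setMethod("show", "SyntheticKdPredictor", function(object) {
    cat("SyntheticKdPredictor: lognormal(meanlog =",
        format(object@meanlog, digits = 4), ", sdlog =", object@sdlog,
        "), seed =", object@seed, "\n")
})

#' Generate a synthetic proteome
#'
#' Random protein sequences over the 20-letter alphabet with lengths drawn
#' uniformly from the configured range; deterministic given the
#' configuration seed.
#'
#' @param config a \code{\link{simConfig}}.
#' @return named character vector of protein sequences (transcript ids
#'   \code{TR0001}, ...).
#' @export
generateProteome <- function(config) {
    withSeed(config$seed, {
        L <- if (config$nProteins)
            sample(config$proteinLengthRange[1L]:config$proteinLengthRange[2L],
                   config$nProteins, replace = TRUE) else integer()
        seqs <- vapply(L, function(l)
            paste(sample(AA_ALPHABET, l, replace = TRUE,
                         prob = AA_FREQS[AA_ALPHABET]), collapse = ""),
            character(1L))
        setNames(seqs, sprintf("TR%04d", seq_len(config$nProteins)))
    })
}

# genomic layout of the synthetic transcripts: 100 kb windows, 22 chromosomes
transcriptLayout <- function(proteome) {
    i <- seq_along(proteome)
    data.frame(transcript_id = names(proteome),
               chrom = paste0("chr", 1L + (i - 1L) %% 22L),
               start = ((i - 1L) %/% 22L) * 100000L + 1L,
               length = nchar(unname(proteome)))
}

# candidate driver hotspots: one interior locus per protein. The mutated
# residue within the hotspot 9-mer is fixed per locus; the substituting
# residue is chosen per sample when a driver is planted, and the resulting
# mutant 9-mer becomes an epitope-reference entry, so the driver converts
# its wild-type window into a known epitope exactly.
makeHotspots <- function(proteome) {
    n <- length(proteome)
    L <- nchar(proteome)
    start <- vapply(L, function(l) sample(12:(l - 20L), 1L), integer(1L))
    mpos <- sample(1:9, n, replace = TRUE)
    wt9 <- substr(unname(proteome), start, start + 8L)
    data.frame(transcript_id = names(proteome), hotspot_start = start,
               mpos = mpos, protein_pos = start + mpos - 1L,
               ref_aa = substr(wt9, mpos, mpos))
}

#' Generate per-sample somatic variants
#'
#' Per-sample burden is drawn uniformly from the configured range and split
#' into non-synonymous SNVs, synonymous SNVs and indels; a fraction of
#' indels additionally get a planted SNV 1 bp away (alignment artifacts the
#' proximity filter must remove; these sit on top of the burden). Background
#' variants avoid the driver hotspot neighbourhoods so that planted
#' structure stays identifiable. Driver mutations themselves are added by
#' \code{\link{generateCohort}}.
#'
#' @param config a \code{\link{simConfig}}.
#' @param proteome from \code{\link{generateProteome}}.
#' @param hotspots internal hotspot table (excluded regions).
#' @return list with the variant data.frame, the sample table
#'   (\code{sample_id}, \code{group}, \code{burden}) and the planted
#'   near-indel SNV keys.
#' @export
generateVariants <- function(config, proteome,
                             hotspots = makeHotspots(proteome)) {
    layout <- transcriptLayout(proteome)
    # residue pool outside hotspot neighbourhoods (+-15 of the 9-mer window)
    pool <- do.call(rbind, lapply(seq_along(proteome), function(i) {
        L <- layout$length[i]
        h <- hotspots$hotspot_start[i]
        keep <- setdiff(seq_len(L), max(1L, h - 15L):min(L, h + 23L))
        data.frame(ti = i, residue = keep)
    }))
    sampleTab <- data.frame(
        sample_id = c(sprintf("A%d", seq_len(config$nSamples[1L])),
                      sprintf("B%d", seq_len(config$nSamples[2L]))),
        group = rep(c("A", "B"), config$nSamples))
    sampleTab$burden <- as.integer(round(runif(nrow(sampleTab),
        config$mutationBurdenRange[1L], config$mutationBurdenRange[2L])))
    planted <- character()
    all <- vector("list", nrow(sampleTab))
    for (s in seq_len(nrow(sampleTab))) {
        b <- sampleTab$burden[s]
        nIndel <- round(config$indelFraction * b)
        nSnv <- b - nIndel
        nNonsyn <- round(config$fractionNonsynonymous * nSnv)
        rows <- pool[sample.int(nrow(pool), nSnv), ]
        ti <- rows$ti; p <- rows$residue
        ref <- substr(unname(proteome)[ti], p, p)
        alt <- ref
        ns <- seq_len(nNonsyn)
        alt[ns] <- vapply(ref[ns], function(r)
            sample(setdiff(AA_ALPHABET, r), 1L), character(1L),
            USE.NAMES = FALSE)
        snv <- data.frame(
            sample_id = sampleTab$sample_id[s],
            chrom = layout$chrom[ti],
            pos = layout$start[ti] + 3L * (p - 1L),
            variant_class = "snv",
            gene = sub("TR", "GENE", layout$transcript_id[ti]),
            transcript_id = layout$transcript_id[ti],
            protein_pos = p, ref_aa = ref, alt_aa = alt,
            is_nonsynonymous = seq_len(nSnv) <= nNonsyn)
        ind <- NULL
        if (nIndel > 0L) {
            it <- sample.int(nrow(layout), nIndel, replace = TRUE)
            slot <- sample.int(900L, nIndel, replace = TRUE)
            ind <- data.frame(
                sample_id = sampleTab$sample_id[s],
                chrom = layout$chrom[it],
                pos = layout$start[it] + 90000L + 10L * slot,
                variant_class = "indel",
                gene = sub("TR", "GENE", layout$transcript_id[it]),
                transcript_id = layout$transcript_id[it],
                protein_pos = NA_integer_, ref_aa = NA_character_,
                alt_aa = NA_character_, is_nonsynonymous = FALSE)
            nearSel <- which(runif(nIndel) < config$nearIndelFraction)
            if (length(nearSel)) {
                pr <- pool[sample.int(nrow(pool), length(nearSel)), ]
                refp <- substr(unname(proteome)[pr$ti], pr$residue, pr$residue)
                near <- data.frame(
                    sample_id = sampleTab$sample_id[s],
                    chrom = ind$chrom[nearSel],
                    pos = ind$pos[nearSel] + 1L,
                    variant_class = "snv",
                    gene = sub("TR", "GENE",
                               layout$transcript_id[pr$ti]),
                    transcript_id = layout$transcript_id[pr$ti],
                    protein_pos = pr$residue, ref_aa = refp,
                    alt_aa = vapply(refp, function(r)
                        sample(setdiff(AA_ALPHABET, r), 1L),
                        character(1L), USE.NAMES = FALSE),
                    is_nonsynonymous = TRUE)
                planted <- c(planted, paste(near$sample_id, near$chrom,
                                            near$pos, sep = ":"))
                ind <- rbind(ind, near)
            }
        }
        all[[s]] <- rbind(snv, ind)
    }
    variants <- do.call(rbind, all)
    rownames(variants) <- NULL
    list(variants = variants, samples = sampleTab,
         planted_near_indel = planted)
}

# per-sample planted drivers: walk the hotspot list in a shuffled order,
# trying candidate substituting residues at each locus, and accept a
# (hotspot, alt) pair when one of the mutant windows close to the hotspot
# 9-mer (similarity to the epitope >= 27, so recognition potential stays
# near 1) binds one of the sample's alleles below the threshold WITH
# amplitude >= 2, i.e. the planted neoantigen is an immunodominant binder
# whose wild-type counterpart binds clearly weaker — guaranteeing driver
# fitness cost >= 2, above any background record. Returns a data.frame of
# accepted drivers (with the epitope = the mutant hotspot 9-mer).
pickDrivers <- function(config, proteome, hotspots, alleles, k,
                        kdPredictor, thresholdNm = 500) {
    ord <- sample.int(nrow(hotspots))
    out <- list()
    for (h in ord) {
        if (length(out) >= k) break
        hs <- hotspots[h, ]
        prot <- proteome[[hs$transcript_id]]
        ws <- max(1L, hs$hotspot_start - 3L):
              min(nchar(prot) - 8L, hs$hotspot_start + 3L)
        wtPeps <- substr(rep(prot, length(ws)), ws, ws + 8L)
        kdWtBest <- do.call(pmin, lapply(alleles, function(al)
            predictKd(kdPredictor, wtPeps, al)))
        alts <- sample(setdiff(AA_ALPHABET, hs$ref_aa))
        for (alt in alts) {
            mutProt <- prot
            substr(mutProt, hs$protein_pos, hs$protein_pos) <- alt
            peps <- substr(rep(mutProt, length(ws)), ws, ws + 8L)
            kdMtBest <- do.call(pmin, lapply(alleles, function(al)
                predictKd(kdPredictor, peps, al)))
            epi <- substr(mutProt, hs$hotspot_start, hs$hotspot_start + 8L)
            sim <- gaplessAlignmentScore(peps, epi)
            hit <- kdMtBest < thresholdNm & kdWtBest / kdMtBest >= 2 &
                sim >= 27L
            if (any(hit)) {
                out[[length(out) + 1L]] <- data.frame(
                    transcript_id = hs$transcript_id,
                    protein_pos = hs$protein_pos,
                    ref_aa = hs$ref_aa, alt_aa = alt, epitope = epi)
                break
            }
        }
    }
    do.call(rbind, c(out, list(data.frame(transcript_id = character(),
        protein_pos = integer(), ref_aa = character(), alt_aa = character(),
        epitope = character()))))
}

#' Generate the expression table with the planted group effect
#'
#' Baseline RPKM is lognormal per (transcript, sample). In group-B samples
#' the transcripts carrying that sample's top-k fitness-cost records (k
#' distinct transcripts in descending-fitness order) are multiplied by the
#' suppression effect; group-A samples are untouched.
#'
#' @param config a \code{\link{simConfig}}.
#' @param records scored record data.frame (needs \code{sample_id},
#'   \code{transcript_id}, \code{fitness}).
#' @param samples sample table with \code{sample_id} and \code{group}.
#' @param transcripts character vector of all transcript ids.
#' @return list with the RPKM matrix (transcripts x samples) and a named
#'   list of the suppressed transcripts per group-B sample.
#' @export
generateExpression <- function(config, records, samples, transcripts) {
    rpkm <- matrix(rlnorm(length(transcripts) * nrow(samples),
                          config$expressionMeanlog, config$expressionSdlog),
                   nrow = length(transcripts),
                   dimnames = list(transcripts, samples$sample_id))
    suppressed <- list()
    for (sid in samples$sample_id[samples$group == "B"]) {
        rec <- records[records$sample_id == sid & !is.na(records$fitness) &
                       records$fitness > 0, ]
        if (!nrow(rec)) next
        ord <- order(rec$fitness, decreasing = TRUE)
        top <- unique(rec$transcript_id[ord])
        top <- top[seq_len(min(config$suppressionTopK, length(top)))]
        rpkm[top, sid] <- rpkm[top, sid] * config$suppressionEffect
        suppressed[[sid]] <- top
    }
    list(rpkm = rpkm, suppressed = suppressed)
}

#' Generate a complete synthetic cohort
#'
#' Produces every input the scoring pipeline consumes — variants, proteome
#' FASTA, per-sample HLA allele lists, a Kd model, an epitope reference,
#' expression and group labels — plus a manifest of all planted ground
#' truth (near-indel artifact SNVs, driver mutations, suppressed
#' transcripts). Fully reproducible from the configuration seed. When
#' \code{outDir} is given the bundle is written in the formats the readers
#' consume.
#'
#' @param config a \code{\link{simConfig}}.
#' @param outDir optional output directory.
#' @param neoCfg scoring configuration used for the internal scoring pass.
#' @return (invisibly when writing) a list with the in-memory bundle:
#'   \code{variants}, \code{proteome}, \code{alleles} (named list),
#'   \code{epitopeSet}, \code{kdPredictor}, \code{rpkm}, \code{groups},
#'   \code{samples}, \code{manifest}, plus the internally scored
#'   \code{records}, \code{counts} and \code{summaries}.
#' @export
generateCohort <- function(config = simConfig(), outDir = NULL,
                           neoCfg = neoConfig(rngSeed = config$seed)) {
    proteome <- generateProteome(config)
    bundle <- withSeed(config$seed + 1L, {
        hotspots <- makeHotspots(proteome)
        gv <- generateVariants(config, proteome, hotspots)
        samples <- gv$samples
        kdPredictor <- syntheticKdPredictor(config$kdMeanlog, config$kdSdlog,
                                            seed = config$seed)
        alleles <- lapply(seq_len(nrow(samples)), function(i)
            c(sample(ALLELE_POOL[1:4], config$allelesPerSample / 3L),
              sample(ALLELE_POOL[5:8], config$allelesPerSample / 3L),
              sample(ALLELE_POOL[9:12], config$allelesPerSample / 3L)))
        names(alleles) <- samples$sample_id
        # one planted immunodominant driver per sample: the suppression of
        # the top-k fitness transcripts then covers the driver plus any
        # rare background record that happens to resemble an epitope
        k <- rep(1L, nrow(samples))
        layout <- transcriptLayout(proteome)
        driverRows <- list()
        for (i in seq_len(nrow(samples))) {
            h <- pickDrivers(config, proteome, hotspots, alleles[[i]], k[i],
                             kdPredictor, neoCfg@kdBindingThreshold)
            if (!nrow(h)) next
            li <- match(h$transcript_id, layout$transcript_id)
            driverRows[[i]] <- data.frame(
                sample_id = samples$sample_id[i],
                chrom = layout$chrom[li],
                pos = layout$start[li] + 3L * (h$protein_pos - 1L),
                variant_class = "snv",
                gene = sub("TR", "GENE", h$transcript_id),
                transcript_id = h$transcript_id,
                protein_pos = h$protein_pos,
                ref_aa = h$ref_aa, alt_aa = h$alt_aa,
                is_nonsynonymous = TRUE,
                epitope = h$epitope)
        }
        drivers <- do.call(rbind, driverRows)
        variants <- gv$variants
        if (!is.null(drivers))
            variants <- rbind(variants,
                              drivers[setdiff(names(drivers), "epitope")])
        epitopeSet <- EpitopeSet(c(
            if (!is.null(drivers)) drivers$epitope,
            vapply(seq_len(config$nDecoyEpitopes), function(i)
                paste(sample(AA_ALPHABET, sample(9:13, 1L), replace = TRUE,
                             prob = AA_FREQS[AA_ALPHABET]), collapse = ""),
                character(1L))))
        list(hotspots = hotspots, samples = samples, variants = variants,
             alleles = alleles, kdPredictor = kdPredictor,
             epitopeSet = epitopeSet, drivers = drivers,
             planted_near_indel = gv$planted_near_indel)
    })
    # internal scoring pass (deterministic; drives the expression effect)
    scored <- scoreNeoantigens(bundle$variants, proteome, bundle$alleles,
                               bundle$kdPredictor, bundle$epitopeSet,
                               config = neoCfg)
    expr <- withSeed(config$seed + 2L,
        generateExpression(config, scored$records, bundle$samples,
                           names(proteome)))
    scored$records <- expressionFractions(scored$records, expr$rpkm)
    summaries <- summarizeSamples(scored$records, scored$counts, neoCfg)

    manifest <- rbind(
        if (length(bundle$planted_near_indel))
            data.frame(type = "planted_near_indel_snv",
                       sample_id = sub(":.*", "", bundle$planted_near_indel),
                       key = sub("^[^:]+:", "", bundle$planted_near_indel)),
        if (!is.null(bundle$drivers) && nrow(bundle$drivers))
            data.frame(type = "planted_driver",
                       sample_id = bundle$drivers$sample_id,
                       key = paste(bundle$drivers$transcript_id,
                                   bundle$drivers$protein_pos, sep = ":")),
        if (length(expr$suppressed))
            data.frame(type = "suppressed_transcript",
                       sample_id = rep(names(expr$suppressed),
                                       lengths(expr$suppressed)),
                       key = unlist(expr$suppressed, use.names = FALSE)))
    if (is.null(manifest))
        manifest <- data.frame(type = character(), sample_id = character(),
                               key = character())
    rownames(manifest) <- NULL

    out <- list(config = config, variants = bundle$variants,
                proteome = proteome, alleles = bundle$alleles,
                epitopeSet = bundle$epitopeSet,
                kdPredictor = bundle$kdPredictor, rpkm = expr$rpkm,
                samples = bundle$samples,
                groups = setNames(bundle$samples$group,
                                  bundle$samples$sample_id),
                manifest = manifest, records = scored$records,
                counts = scored$counts, summaries = summaries)
    if (!is.null(outDir)) {
        writeCohort(out, outDir)
        return(invisible(out))
    }
    out
}

writeCohort <- function(bundle, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(outDir, "alleles"), showWarnings = FALSE)
    writeVariantsTsv(bundle$variants, file.path(outDir, "variants.tsv"))
    Biostrings::writeXStringSet(
        Biostrings::AAStringSet(bundle$proteome),
        file.path(outDir, "proteome.fa"))
    for (sid in names(bundle$alleles))
        writeLines(bundle$alleles[[sid]],
                   file.path(outDir, "alleles", paste0(sid, ".txt")))
    writeLines(c("sequence", epitopes(bundle$epitopeSet)),
               file.path(outDir, "epitopes.csv"))
    writeExpression(bundle$rpkm, file.path(outDir, "expression.tsv"))
    write.table(bundle$samples[c("sample_id", "group")],
                file.path(outDir, "groups.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    kd <- bundle$kdPredictor
    yaml::write_yaml(list(model = "synthetic_lognormal",
                          meanlog = kd@meanlog, sdlog = kd@sdlog,
                          seed = kd@seed),
                     file.path(outDir, "kd_model.yaml"), precision = 17L)
    write.table(bundle$manifest, file.path(outDir, "manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeNeoConfig(neoConfig(rngSeed = bundle$config$seed),
                   file.path(outDir, "config.yaml"))
    invisible(outDir)
}

#' Read a Kd model written by the cohort generator
#'
#' @param path YAML file with fields \code{model}, \code{meanlog},
#'   \code{sdlog}, \code{seed}.
#' @return a \code{\linkS4class{SyntheticKdPredictor}}.
#' @export
readKdModel <- function(path) {
    x <- yaml::read_yaml(path)
    if (!identical(x$model, "synthetic_lognormal"))
        stop("unknown Kd model: ", x$model)
    syntheticKdPredictor(x$meanlog, x$sdlog, as.integer(x$seed))
}
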