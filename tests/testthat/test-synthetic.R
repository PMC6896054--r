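test_that("proteome generation is deterministic and respects bounds", {
    cfg <- smallSimConfig(seed = 5L)
    p1 <- generateProteome(cfg)
    p2 <- generateProteome(cfg)
    expect_identical(p1, p2)
    expect_length(p1, cfg$nProteins)
    L <- nchar(p1)
    expect_true(all(L >= cfg$proteinLengthRange[1] &
                    L <= cfg$proteinLengthRange[2]))
    expect_false(identical(p1, generateProteome(smallSimConfig(seed = 6L))))
    empty <- simConfig(nProteins = 0L)
    expect_length(generateProteome(empty), 0L)
})

test_that("synthetic Kd is a pure, allele-sensitive, calibrated function", {
    kd <- syntheticKdPredictor(seed = 17L)
    p <- "ACDEFGHIK"
    expect_identical(predictKd(kd, p, "HLA-A*02:01"),
                     predictKd(kd, p, "HLA-A*02:01"))
    set.seed(2)
    peps <- replicate(1000, randomPeptide(9))
    a1 <- predictKd(kd, peps, "HLA-A*02:01")
    a2 <- predictKd(kd, peps, "HLA-B*07:02")
    expect_gt(mean(a1 != a2), 0.999)   # collision check across alleles
    # marginal binding fraction close to the calibration target, pooled
    # across alleles
    set.seed(3)
    peps2 <- replicate(5000, randomPeptide(9))
    fr <- mean(c(predictKd(kd, peps2[1:2500], "HLA-C*04:01") < 500,
                 predictKd(kd, peps2[2501:5000], "HLA-A*24:02") < 500))
    expect_lt(abs(fr - 0.005), 0.05)
    # single-residue changes give correlated but distinct values
    p2 <- p; substr(p2, 5, 5) <- "W"
    expect_false(predictKd(kd, p, "HLA-A*02:01") ==
                 predictKd(kd, p2, "HLA-A*02:01"))
    expect_error(predictKd(kd, "SHORT", "x"), "9-mer")
})

test_that("variant generation matches the proteome and the burden", {
    cfg <- smallSimConfig(seed = 8L)
    prot <- generateProteome(cfg)
    gv <- withr::with_seed(99L, generateVariants(cfg, prot))
    v <- gv$variants
    ns <- v[v$is_nonsynonymous, ]
    expect_true(all(substr(prot[ns$transcript_id], ns$protein_pos,
                           ns$protein_pos) == ns$ref_aa))
    expect_true(all(ns$ref_aa != ns$alt_aa))
    # per-sample totals = burden + planted near-indel artifacts
    planted <- table(sub(":.*", "", gv$planted_near_indel))
    for (i in seq_len(nrow(gv$samples))) {
        sid <- gv$samples$sample_id[i]
        extra <- if (sid %in% names(planted)) planted[[sid]] else 0L
        expect_equal(sum(v$sample_id == sid), gv$samples$burden[i] + extra)
    }
    # degenerate burden range pins the count exactly
    cfgF <- smallSimConfig(seed = 8L, mutationBurdenRange = c(100L, 100L),
                           indelFraction = 0, nearIndelFraction = 0)
    gvF <- withr::with_seed(1L, generateVariants(cfgF, prot))
    expect_true(all(table(gvF$variants$sample_id) == 100L))
})

test_that("the proximity filter removes exactly the planted artifact SNVs", {
    cfg <- smallSimConfig(seed = 14L, nearIndelFraction = 0.5)
    prot <- generateProteome(cfg)
    gv <- withr::with_seed(100L, generateVariants(cfg, prot))
    expect_gt(length(gv$planted_near_indel), 0L)
    v <- gv$variants
    kept <- filterSnvsNearIndels(v)
    removedKeys <- setdiff(paste(v$sample_id, v$chrom, v$pos, sep = ":"),
                           paste(kept$sample_id, kept$chrom, kept$pos,
                                 sep = ":"))
    expect_setequal(removedKeys, gv$planted_near_indel)
})

test_that("expression is positive, finite, and suppressed as recorded", {
    cfg <- smallSimConfig(seed = 23L)
    b <- generateCohort(cfg)
    expect_true(all(is.finite(b$rpkm) & b$rpkm > 0))
    sup <- b$manifest[b$manifest$type == "suppressed_transcript", ]
    expect_gt(nrow(sup), 0L)
    # suppressed transcripts are exactly the per-sample top-fitness
    # transcripts (up to k distinct), and only group B is touched
    for (sid in unique(sup$sample_id)) {
        expect_identical(unname(b$groups[sid]), "B")
        rec <- b$records[b$records$sample_id == sid &
                         !is.na(b$records$fitness) & b$records$fitness > 0, ]
        ord <- unique(rec$transcript_id[order(rec$fitness,
                                              decreasing = TRUE)])
        topK <- ord[seq_len(min(cfg$suppressionTopK, length(ord)))]
        expect_setequal(sup$key[sup$sample_id == sid], topK)
    }
})

test_that("cohort bundles are reproducible and seed-sensitive", {
    cfg <- smallSimConfig(seed = 31L)
    b1 <- generateCohort(cfg)
    b2 <- generateCohort(cfg)
    expect_identical(b1$variants, b2$variants)
    expect_identical(b1$rpkm, b2$rpkm)
    expect_identical(epitopes(b1$epitopeSet), epitopes(b2$epitopeSet))
    expect_identical(b1$summaries, b2$summaries)
    b3 <- generateCohort(smallSimConfig(seed = 32L))
    expect_false(identical(b1$variants, b3$variants))
})

test_that("planted drivers appear as high-fitness records in their samples", {
    b <- generateCohort(smallSimConfig(seed = 41L))
    drv <- b$manifest[b$manifest$type == "planted_driver", ]
    expect_gte(nrow(drv), nrow(b$samples) - 1L)  # near-always one per sample
    for (i in seq_len(nrow(drv))) {
        key <- strsplit(drv$key[i], ":")[[1L]]
        rec <- b$records[b$records$sample_id == drv$sample_id[i] &
                         b$records$transcript_id == key[1L] &
                         b$records$protein_pos == as.integer(key[2L]), ]
        expect_gt(max(rec$fitness, na.rm = TRUE), 1)
        expect_gt(max(rec$recognition, na.rm = TRUE), 0.99)
    }
})
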