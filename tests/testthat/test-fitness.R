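test_that("fitness cost is the amplitude-recognition product", {
    expect_equal(fitnessCost(5, 0), 0)
    expect_equal(fitnessCost(1, 0.5), 0.5)
    expect_equal(fitnessCost(2.5, 0.4), 1)
    expect_error(fitnessCost(-1, 0.5), ">= 0")
    expect_error(fitnessCost(1, 1), "\\[0, 1\\)")
})

test_that("classification gives nested binding/immunogenic/stringent flags", {
    r <- classifyNeoantigens(tinyRecords())
    expect_equal(r$binding, c(TRUE, TRUE, TRUE, FALSE))
    expect_equal(r$immunogenic, c(TRUE, FALSE, TRUE, FALSE))
    expect_equal(r$stringent, c(TRUE, FALSE, FALSE, FALSE))
    # R = 0.009 is immunogenic but below the stringent threshold
    expect_true(r$immunogenic[3] && !r$stringent[3])
    # kd 600, R = 0.5 fails the binding gate entirely
    x <- tinyRecords(); x$kd_mt_nM[1] <- 600; x$recognition[1] <- 0.5
    expect_false(any(unlist(classifyNeoantigens(x)[1,
        c("binding", "immunogenic", "stringent")])))
})

test_that("expression fractions normalize over F > 0 records", {
    r <- tinyRecords()
    rpkm <- setNames(c(8, 2, 5, 1), c("t1", "t3", "t2", "t4"))
    # records with F > 0: rows 1 (F=1, rpkm 8) and 3 (F=0.09 -> use F=2 for
    # the printed hand case)
    r$fitness <- c(1, 0, 2, NA)
    out <- expressionFractions(r, rpkm)
    expect_equal(out$expression_fraction, c(0.8, NA, 0.2, NA))
    expect_equal(out$adjusted_fitness, c(0.8, NA, 0.4, NA))

    # singleton F > 0 record takes the whole fraction
    r1 <- tinyRecords(); r1$fitness <- c(3, 0, 0, NA)
    out1 <- expressionFractions(r1, setNames(7, "t1"))
    expect_equal(out1$expression_fraction[1], 1)
    expect_equal(out1$adjusted_fitness[1], 3)

    # equal expression splits evenly
    r2 <- tinyRecords(); r2$fitness <- c(1, 1, 0, NA)
    out2 <- expressionFractions(r2, setNames(c(4, 4), c("t1", "t2")))
    expect_equal(out2$expression_fraction[1:2], c(0.5, 0.5))

    # all F>0 records with zero RPKM: adjustment undefined, with a warning
    r3 <- tinyRecords(); r3$fitness <- c(1, 2, 0, NA)
    expect_warning(out3 <- suppressMessages(
        expressionFractions(r3, setNames(c(0, 5), c("t1", "t3")))),
        "undefined")
    expect_true(all(is.na(out3$adjusted_fitness)))
})

test_that("per-sample fractions sum to one across random record sets", {
    set.seed(9)
    for (i in 1:25) {
        n <- sample(3:40, 1)
        r <- data.frame(sample_id = sample(c("x", "y"), n, replace = TRUE),
                        transcript_id = sprintf("t%02d", sample(1:15, n,
                                                                replace = TRUE)),
                        fitness = ifelse(runif(n) < 0.3, 0, rlnorm(n)))
        rpkm <- matrix(rlnorm(30), nrow = 15,
                       dimnames = list(sprintf("t%02d", 1:15), c("x", "y")))
        out <- expressionFractions(r, rpkm)
        for (sid in unique(out$sample_id)) {
            fr <- out$expression_fraction[out$sample_id == sid]
            if (any(!is.na(fr)))
                expect_equal(sum(fr, na.rm = TRUE), 1, tolerance = 1e-9)
        }
    }
})

test_that("sample summaries match an independent reduction", {
    r <- classifyNeoantigens(tinyRecords())
    r$rpkm <- c(8, 5, 2, 1)
    r$expression_fraction <- c(0.8, NA, 0.2, NA)
    r$adjusted_fitness <- c(0.8, NA, 0.018, NA)
    s <- summarizeSample(r, tinyCounts())
    # independent spreadsheet-style arithmetic over the immunogenic rows 1,3
    expect_equal(s$n_binding, 3L)
    expect_equal(s$n_immunogenic, 2L)
    expect_equal(s$n_stringent, 1L)
    expect_equal(s$ratio_immunogenic_binding, 2 / 3)
    expect_equal(s$ratio_stringent_binding, 1 / 3)
    expect_equal(s$mean_kd_mt, (100 + 400) / 2)
    expect_equal(s$mean_amplitude, (2 + 10) / 2)
    expect_equal(s$mean_R, (0.5 + 0.009) / 2)
    expect_equal(s$mean_F, (1 + 0.09) / 2)
    expect_equal(s$max_F, 1)
    expect_equal(s$mean_F_adj, (0.8 + 0.018) / 2)
    expect_equal(s$max_F_adj, 0.8)

    # averaging over binding records instead
    sb <- summarizeSample(r, tinyCounts(), neoConfig(averagingSet = "binding"))
    expect_equal(sb$mean_kd_mt, mean(c(100, 50, 400)))

    # degenerate sample with no binding records
    r0 <- classifyNeoantigens(tinyRecords())
    r0$kd_mt_nM <- 1e5
    r0 <- classifyNeoantigens(r0)
    r0$rpkm <- NA_real_; r0$expression_fraction <- NA_real_
    r0$adjusted_fitness <- NA_real_
    s0 <- summarizeSample(r0, tinyCounts())
    expect_equal(s0$n_binding, 0L)
    expect_true(is.na(s0$ratio_immunogenic_binding))
    expect_true(is.na(s0$mean_kd_mt))
    expect_true(is.na(s0$max_F))
})

test_that("summaries are invariant to record order", {
    r <- classifyNeoantigens(tinyRecords())
    r$rpkm <- c(8, 5, 2, 1)
    r$expression_fraction <- c(0.8, NA, 0.2, NA)
    r$adjusted_fitness <- c(0.8, NA, 0.018, NA)
    s1 <- summarizeSample(r, tinyCounts())
    s2 <- summarizeSample(r[4:1, ], tinyCounts())
    expect_equal(s1, s2)
})

test_that("eligibility requires more than one immunogenic neoantigen", {
    s <- data.frame(sample_id = c("a", "b", "c"),
                    n_immunogenic = c(1L, 2L, 5L),
                    max_F = c(2, 3, 4))
    out <- selectEligibleSamples(s)
    expect_equal(out$eligible, c(FALSE, TRUE, TRUE))

    # optional magnitude-outlier rule: 1000x below the cohort mean trips it
    s2 <- data.frame(sample_id = c("a", "b", "c", "d"),
                     n_immunogenic = c(5L, 5L, 5L, 5L),
                     max_F = c(1.2, 0.9, 0.9, 0.001))
    offDefault <- selectEligibleSamples(s2)
    expect_true(all(offDefault$eligible))
    on <- selectEligibleSamples(s2, neoConfig(dropMagnitudeOutliers = TRUE))
    expect_equal(on$eligible, c(TRUE, TRUE, TRUE, FALSE))
})
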