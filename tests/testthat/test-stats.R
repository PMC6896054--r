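test_that("exact rank-sum p-values match hand enumeration", {
    w <- wilcoxonRankSum(c(1, 2), c(3, 4), mode = "exact")
    expect_equal(w$statistic, 3)
    expect_equal(w$p, 1 / 3)
    # most central assignment of C(4,2) = 6: enumeration gives 4/6
    w2 <- wilcoxonRankSum(c(1, 3), c(2, 4), mode = "exact")
    expect_equal(w2$p, oracleWilcoxP(c(1, 3), c(2, 4)))
    expect_equal(w2$p, 2 / 3)
    # group-label symmetry
    expect_equal(wilcoxonRankSum(c(5, 9, 2), c(7, 1), mode = "exact")$p,
                 wilcoxonRankSum(c(7, 1), c(5, 9, 2), mode = "exact")$p)
    expect_error(wilcoxonRankSum(numeric(), 1:3), "non-empty")
})

test_that("exact rank-sum agrees with the full-enumeration oracle", {
    set.seed(31)
    for (i in 1:100) {
        nx <- sample(2:5, 1); ny <- sample(2:5, 1)
        x <- rnorm(nx); y <- rnorm(ny, 0.5)   # continuous: tie-free a.s.
        expect_equal(wilcoxonRankSum(x, y, mode = "exact")$p,
                     oracleWilcoxP(x, y), info = paste("trial", i))
    }
})

test_that("exact rank-sum agrees with wilcox.test on tie-free data", {
    set.seed(77)
    for (i in 1:25) {
        x <- rnorm(sample(2:5, 1)); y <- rnorm(sample(2:5, 1))
        ours <- wilcoxonRankSum(x, y, mode = "exact")$p
        ref <- wilcox.test(x, y, exact = TRUE)$p.value
        expect_equal(ours, ref, tolerance = 1e-12)
    }
})

test_that("normal-approximation mode reproduces the classical z test", {
    set.seed(13)
    x <- rnorm(8); y <- rnorm(9, 0.8)
    ours <- wilcoxonRankSum(x, y, mode = "normal")$p
    ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
    # tie-corrected variance on tied data
    xt <- c(1, 2, 2, 3); yt <- c(2, 3, 3, 4, 5)
    expect_equal(wilcoxonRankSum(xt, yt, mode = "normal")$p,
                 wilcox.test(xt, yt, exact = FALSE, correct = FALSE)$p.value,
                 tolerance = 1e-12)
    # perfect separation at 3 vs 4 gives the z = 2.12 two-sided p
    expect_equal(wilcoxonRankSum(c(7, 8, 9), c(1, 2, 3, 4),
                                 mode = "normal")$p,
                 2 * pnorm(-6 / sqrt(8)), tolerance = 1e-12)
    # identical groups: p = 1
    expect_equal(wilcoxonRankSum(c(1, 2), c(1, 2), mode = "normal")$p, 1)
})

test_that("auto mode switches between exact and normal", {
    expect_identical(wilcoxonRankSum(1:3, 4:6)$mode, "exact")
    expect_identical(wilcoxonRankSum(1:8, 9:16)$mode, "normal")
    expect_identical(wilcoxonRankSum(c(1, 2, 2), c(3, 4))$mode, "normal")
})

test_that("Spearman rho matches the rank formula", {
    expect_equal(spearmanRho(1:5, (1:5)^3), 1)
    expect_equal(spearmanRho(1:5, -(1:5)), -1)
    # d^2 = 2 over n = 4: rho = 1 - 6*2/(4*15) = 0.8
    expect_equal(spearmanRho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
    expect_warning(rc <- spearmanRho(c(1, 1, 1), c(1, 2, 3)), "constant")
    expect_true(is.na(rc))
    # self-correlation invariants
    set.seed(4); z <- rnorm(10)
    expect_equal(spearmanRho(z, z), 1)
    expect_equal(spearmanRho(z, -z), -1)
})

test_that("least-squares slope and CI match the normal equations", {
    x <- c(1, 2, 3, 4, 6)
    exact <- suppressWarnings(olsSlopeCi(x, 2 * x + 1))  # zero-residual fit
    expect_equal(exact$slope, 2)
    expect_lt(abs(exact$ci_high - 2), 1e-8)
    set.seed(21)
    xr <- rnorm(5); yr <- 1.5 * xr + rnorm(5)
    got <- olsSlopeCi(xr, yr)
    want <- oracleSlopeCi(xr, yr)
    expect_equal(got$slope, unname(want["slope"]))
    expect_equal(got$ci_low, unname(want["lo"]))
    expect_equal(got$ci_high, unname(want["hi"]))
    expect_equal(suppressWarnings(olsSlopeCi(xr, rep(3, 5)))$slope, 0)
    expect_error(olsSlopeCi(rep(1, 5), rnorm(5)), "degenerate")
})

test_that("Bonferroni caps at one and rejects bad input", {
    expect_equal(bonferroni(0.01), 0.01)
    expect_equal(bonferroni(c(0.01, 0.2)), c(0.02, 0.4))
    expect_equal(bonferroni(c(0.5, 0.9)), c(1, 1))
    p <- runif(9)
    expect_true(all(bonferroni(p) >= p & bonferroni(p) <= 1))
    expect_error(bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("groove flags follow the exon annotation", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("chr6\t99\t200\tHLA-A:exon2",
                 "chr6\t249\t300\tHLA-A:exon3",
                 "chr6\t349\t400\tHLA-A:exon4"), bed)
    ann <- readGrooveAnnotation(bed)
    v <- rbind(makeVariant(chrom = "chr6", pos = 150L),   # exon 2
               makeVariant(chrom = "chr6", pos = 380L),   # exon 4
               makeVariant(chrom = "chr6", pos = 220L),   # intron
               makeVariant(chrom = "chr1", pos = 150L))   # other chrom
    f <- flagGrooveMutations(v, ann)
    expect_equal(f$in_coding, c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(f$in_groove, c(TRUE, FALSE, FALSE, FALSE))
    expect_equal(f$hla_gene, c("HLA-A", "HLA-A", NA, NA))
})

test_that("two-standard-deviation expression check uses the sample SD", {
    expect_true(expressionOutlierCheck(2, c(1, 2, 3)))
    expect_true(expressionOutlierCheck(2.5, c(1, 2, 3)))   # sd = 1, |d| = 0.5
    expect_false(expressionOutlierCheck(2 + 3, c(1, 2, 3)))
    expect_false(expressionOutlierCheck(4.1, c(1, 2, 3)))
    expect_warning(within <- expressionOutlierCheck(5, c(5, 5)), "zero")
    expect_true(within)
})

test_that("compareGroups handles identical, degenerate and scored cohorts", {
    s <- data.frame(
        sample_id = sprintf("s%d", 1:6),
        n_somatic_mutations = c(10, 20, 30, 10, 20, 30),
        n_peptides_21mer = 5L, n_possible_9mers = 65L,
        n_binding = c(4, 6, 8, 4, 6, 8),
        n_immunogenic = c(2, 3, 4, 2, 3, 4), n_stringent = 1L,
        ratio_immunogenic_binding = 0.5, ratio_stringent_binding = 0.25,
        mean_kd_mt = c(100, 150, 200, 100, 150, 200),
        mean_amplitude = 1, mean_R = 0.1,
        mean_F = c(1, 2, 3, 1, 2, 3), max_F = c(2, 3, 4, 2, 3, 4),
        mean_F_adj = 0.01, max_F_adj = c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3),
        adjustment_defined = TRUE, eligible = TRUE)
    g <- setNames(rep(c("A", "B"), each = 3), s$sample_id)
    res <- compareGroups(s, g)
    m <- resultMetrics(res)
    expect_true(all(m$p[!is.na(m$p)] == 1))   # identical groups
    expect_equal(m$mean_a, m$mean_b)

    # correlations against a perfectly linear count relation
    cr <- resultCorrelations(res)
    expect_equal(cr$rho, c(1, 1))
    expect_equal(cr$slope[1], 0.2, tolerance = 1e-10)  # n_binding = muts/5

    # cell-score regressions get a Bonferroni family of the right size
    cs <- as.data.frame(matrix(rnorm(6 * 9), nrow = 6,
                               dimnames = list(s$sample_id,
                                               paste0("ct", 1:9))))
    res2 <- compareGroups(s, g, cellScores = cs)
    rg <- resultRegressions(res2)
    expect_equal(nrow(rg), 9L)
    expect_equal(rg$p_adjusted, pmin(1, 9 * rg$p))

    # too few eligible samples: NA entries, not an error
    s$eligible <- c(TRUE, rep(FALSE, 5))
    resNA <- compareGroups(s, g)
    expect_true(all(is.na(resultMetrics(resNA)$p[
        resultMetrics(resNA)$metric == "max_F"])))

    expect_error(compareGroups(s, setNames(rep("A", 6), s$sample_id)),
                 "two group labels")
})

test_that("compareGroups is invariant to sample order", {
    set.seed(8)
    s <- data.frame(
        sample_id = sprintf("s%d", 1:7),
        n_somatic_mutations = sample(50:500, 7),
        n_peptides_21mer = 5L, n_possible_9mers = 65L,
        n_binding = sample(5:50, 7), n_immunogenic = sample(2:20, 7),
        n_stringent = 1L, ratio_immunogenic_binding = runif(7),
        ratio_stringent_binding = runif(7, 0, 0.2),
        mean_kd_mt = runif(7, 50, 400), mean_amplitude = rlnorm(7),
        mean_R = runif(7, 0, 0.3), mean_F = rlnorm(7), max_F = rlnorm(7, 1),
        mean_F_adj = rlnorm(7, -3), max_F_adj = rlnorm(7, -2),
        adjustment_defined = TRUE, eligible = TRUE)
    g <- setNames(c(rep("A", 3), rep("B", 4)), s$sample_id)
    r1 <- compareGroups(s, g)
    perm <- sample(7)
    r2 <- compareGroups(s[perm, ], g)
    expect_equal(resultMetrics(r1), resultMetrics(r2))
    expect_equal(resultCorrelations(r1)$rho, resultCorrelations(r2)$rho)
})
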