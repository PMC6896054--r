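# Fixture builders and independent oracles shared across the test files.
# Oracles are deliberately written as direct, brute-force formulations so
# they stay independent of the package's optimized code paths.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","V","W","Y")

makeVariant <- function(sample_id = "s1", chrom = "chr1", pos = 100L,
                        variant_class = "snv", gene = "g1",
                        transcript_id = "t1", protein_pos = 5L,
                        ref_aa = "A", alt_aa = "V",
                        is_nonsynonymous = TRUE) {
    data.frame(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
               variant_class = variant_class, gene = gene,
               transcript_id = transcript_id,
               protein_pos = as.integer(protein_pos),
               ref_aa = ref_aa, alt_aa = alt_aa,
               is_nonsynonymous = is_nonsynonymous)
}

randomPeptide <- function(n) paste(sample(AA20, n, replace = TRUE),
                                   collapse = "")

# brute-force gapless local alignment: enumerate every pair of equal-length
# contiguous substrings (length >= 1) and take the maximal summed score
oracleGaplessScore <- function(s, e, mat = blosum62()) {
    a <- strsplit(s, "")[[1L]]
    b <- strsplit(e, "")[[1L]]
    best <- -Inf
    for (i in seq_along(a)) for (j in seq_along(b)) {
        L <- min(length(a) - i, length(b) - j)
        sc <- cumsum(mat[cbind(a[i:(i + L)], b[j:(j + L)])])
        best <- max(best, sc)
    }
    as.integer(best)
}

# full-enumeration two-sided rank-sum p-value: count assignments at least as
# far from the null mean as observed (symmetric-distance formulation,
# distinct from the implementation's doubled-tail formulation)
oracleWilcoxP <- function(x, y) {
    r <- rank(c(x, y))
    nx <- length(x)
    W <- sum(r[seq_len(nx)])
    mu <- nx * mean(r) * 1  # nx * (n+1)/2 for untied ranks; mean handles ties
    sums <- combn(r, nx, sum)
    mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
}

# independent least-squares slope/CI via explicit normal equations
oracleSlopeCi <- function(x, y, level = 0.95) {
    n <- length(x)
    sxx <- sum((x - mean(x))^2)
    b1 <- sum((x - mean(x)) * (y - mean(y))) / sxx
    b0 <- mean(y) - b1 * mean(x)
    s2 <- sum((y - b0 - b1 * x)^2) / (n - 2)
    se <- sqrt(s2 / sxx)
    tq <- qt((1 + level) / 2, n - 2)
    c(slope = b1, lo = b1 - tq * se, hi = b1 + tq * se)
}

# a small deterministic scored-record table covering the classification and
# averaging paths
tinyRecords <- function(sample_id = "s1") {
    data.frame(
        sample_id = sample_id,
        transcript_id = c("t1", "t2", "t3", "t4"),
        mutant_9mer = "AAAAAAAAA", wildtype_9mer = "AAAAAAAAC",
        kd_mt_nM = c(100, 50, 400, 900),
        kd_wt_nM = c(200, 25, 4000, 900),
        amplitude = c(2, 0.5, 10, 1),
        recognition = c(0.5, 0, 0.009, NA),
        fitness = c(1, 0, 0.09, NA))
}

tinyCounts <- function(sample_id = "s1")
    data.frame(sample_id = sample_id, n_somatic_mutations = 10L,
               n_peptides_21mer = 4L, n_possible_9mers = 4L)

smallSimConfig <- function(seed = 1L, ...) {
    args <- modifyList(list(mutationBurdenRange = c(50L, 400L),
                            nProteins = 30L,
                            proteinLengthRange = c(200L, 400L),
                            seed = seed),
                       list(...))
    do.call(simConfig, args)
}
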