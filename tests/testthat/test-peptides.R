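test_that("SNVs within the window of an indel are removed, others kept", {
    v <- rbind(
        makeVariant(pos = 100L),                                    # |d| = 1
        makeVariant(pos = 101L, variant_class = "indel",
                    protein_pos = NA, ref_aa = NA, alt_aa = NA,
                    is_nonsynonymous = FALSE),
        makeVariant(pos = 104L, protein_pos = 6L),                  # |d| = 3
        makeVariant(sample_id = "s2", pos = 100L),   # other sample, no indel
        makeVariant(chrom = "chr9", pos = 101L))     # other chrom
    out <- filterSnvsNearIndels(v)
    expect_equal(out$pos, c(101L, 104L, 100L, 101L))
    expect_true(all(out$variant_class[out$pos == 101 &
                                      out$chrom == "chr1"] == "indel"))
    # |d| = 2 boundary: outside the 1 bp window
    v2 <- rbind(makeVariant(pos = 100L),
                makeVariant(pos = 102L, variant_class = "indel",
                            protein_pos = NA, ref_aa = NA, alt_aa = NA,
                            is_nonsynonymous = FALSE))
    expect_equal(nrow(filterSnvsNearIndels(v2)), 2L)
    # widened window removes it
    expect_equal(sum(filterSnvsNearIndels(v2, windowBp = 2L)$variant_class ==
                     "snv"), 0L)
    # no indels: identity
    v3 <- rbind(makeVariant(), makeVariant(pos = 101L, protein_pos = 6L))
    expect_equal(filterSnvsNearIndels(v3), v3)
    expect_equal(nrow(filterSnvsNearIndels(v3[0, ])), 0L)
})

test_that("peptide pairs center the variant and truncate at termini", {
    prot <- paste(rep("ACDEFGHIKL", 20), collapse = "")  # 200 aa
    v <- makeVariant(protein_pos = 50L, ref_aa = "L", alt_aa = "P")
    p <- buildPeptidePair(prot, v)
    expect_equal(nchar(p$mutant_seq), 21L)
    expect_equal(p$mutant_offset, 11L)
    expect_equal(substr(p$mutant_seq, 11, 11), "P")
    expect_equal(substr(p$wildtype_seq, 11, 11), "L")

    v5 <- makeVariant(protein_pos = 5L, ref_aa = "F", alt_aa = "W")
    p5 <- buildPeptidePair(prot, v5)
    expect_equal(nchar(p5$mutant_seq), 15L)   # positions 1..15
    expect_equal(p5$mutant_offset, 5L)

    vC <- makeVariant(protein_pos = 198L, ref_aa = "I", alt_aa = "V")
    expect_equal(nchar(buildPeptidePair(prot, vC)$mutant_seq), 13L)

    expect_error(buildPeptidePair(prot, makeVariant(protein_pos = 50L,
                                                    ref_aa = "A")),
                 "mismatch.*t1.*50")
})

test_that("hand-constructed window matches residue by residue", {
    prot <- "ACDEFGHIKLMNPQRSTVWYA"
    v <- makeVariant(protein_pos = 13L, ref_aa = "P", alt_aa = "A")
    p <- buildPeptidePair(prot, v)
    expect_identical(p$wildtype_seq, substr(prot, 3, 21))
    wt <- strsplit(p$wildtype_seq, "")[[1L]]
    mt <- strsplit(p$mutant_seq, "")[[1L]]
    expect_equal(which(wt != mt), p$mutant_offset)
    expect_identical(mt[p$mutant_offset], "A")
})

test_that("9-mer window counts follow length - 8", {
    prot <- paste(rep("ACDEFGHIKL", 20), collapse = "")
    full <- buildPeptidePair(prot, makeVariant(protein_pos = 100L,
                                               ref_aa = "L", alt_aa = "M"))
    w <- enumerateNineMers(full)
    expect_equal(nrow(w), 13L)
    expect_true(all(nchar(w$mutant_9mer) == 9L))
    expect_true(all(nchar(w$wildtype_9mer) == 9L))

    short <- list(mutant_seq = "ACDEFGHIKLMW", wildtype_seq = "ACDEFGHIKLMC",
                  mutant_offset = 12L)
    w12 <- enumerateNineMers(short)
    expect_equal(w12$window_start, 1:4)

    tiny <- list(mutant_seq = "ACDEFGHA", wildtype_seq = "ACDEFGHC",
                 mutant_offset = 8L)
    expect_message(w0 <- enumerateNineMers(tiny), "no windows")
    expect_equal(nrow(w0), 0L)
})

test_that("windows differ from wild type exactly where they span the mutation", {
    set.seed(7)
    for (rep in 1:20) {
        L <- sample(9:21, 1)
        wt <- randomPeptide(L)
        off <- sample(seq_len(L), 1)
        ref <- substr(wt, off, off)
        alt <- sample(setdiff(AA20, ref), 1)
        mt <- wt; substr(mt, off, off) <- alt
        w <- enumerateNineMers(list(mutant_seq = mt, wildtype_seq = wt,
                                    mutant_offset = off))
        expect_equal(nrow(w), L - 8L)
        diffs <- mapply(function(a, b)
            sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]]),
            w$mutant_9mer, w$wildtype_9mer)
        expect_equal(unname(diffs), as.integer(w$contains_mutation))
    }
})

test_that("vectorized enumeration agrees with the per-pair path", {
    prot <- c(t1 = paste(rep("ACDEFGHIKL", 10), collapse = ""),
              t2 = paste(rep("MNPQRSTVWY", 8), collapse = ""))
    v <- rbind(makeVariant(protein_pos = 30L, ref_aa = "L", alt_aa = "H"),
               makeVariant(transcript_id = "t2", protein_pos = 3L,
                           ref_aa = "P", alt_aa = "L"),
               makeVariant(sample_id = "s2", transcript_id = "t2",
                           protein_pos = 78L, ref_aa = "V", alt_aa = "D"))
    pairs <- buildPeptideTable(v, prot)
    expect_equal(nrow(pairs), 3L)
    recs <- enumerateNineMerTable(pairs)
    for (i in 1:3) {
        single <- enumerateNineMers(buildPeptidePair(prot[v$transcript_id[i]],
                                                     v[i, ]))
        got <- recs[recs$pair_index == i,
                    c("window_start", "mutant_9mer", "wildtype_9mer",
                      "contains_mutation")]
        rownames(got) <- NULL
        expect_equal(got, single)
    }
    expect_error(buildPeptideTable(
        makeVariant(transcript_id = "nope"), prot), "absent from proteome")
})

test_that("enumeration is deterministic and order-independent", {
    prot <- c(t1 = paste(rep("ACDEFGHIKL", 10), collapse = ""))
    v <- rbind(makeVariant(protein_pos = 20L, ref_aa = "L", alt_aa = "F"),
               makeVariant(protein_pos = 55L, ref_aa = "F", alt_aa = "Y"))
    a <- enumerateNineMerTable(buildPeptideTable(v, prot))
    b <- enumerateNineMerTable(buildPeptideTable(v[2:1, ], prot))
    key <- function(d) d[order(d$protein_pos, d$window_start),
                         c("mutant_9mer", "wildtype_9mer")]
    expect_equal(unname(key(a)), unname(key(b)), ignore_attr = TRUE)
})
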