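# Peptide-pair construction and 9-mer window enumeration. All coordinates
# are 1-based; windows are closed intervals. A full-length 21-mer yields
# 21 - 9 + 1 = 13 windows, every one of which is counted as a possible
# neoantigen (mutation-free windows carry a contains_mutation = FALSE flag).

#' Remove SNVs adjacent to indel calls
#'
#' Single-nucleotide variants whose genomic position lies within
#' \code{windowBp} of any indel position on the same chromosome of the same
#' sample are likely alignment artifacts and are removed. Indels themselves
#' are retained and input order is preserved.
#'
#' @param variants variant data.frame (see \code{\link{readVariants}}).
#' @param windowBp non-negative integer window in base pairs (default 1).
#' @return the filtered variant data.frame.
#' @examples
#' v <- data.frame(sample_id = "s", chrom = "chr1", pos = c(100L, 101L, 500L),
#'                 variant_class = c("snv", "indel", "snv"), gene = "g",
#'                 transcript_id = "t", protein_pos = c(5L, NA, 10L),
#'                 ref_aa = c("A", NA, "G"), alt_aa = c("V", NA, "R"),
#'                 is_nonsynonymous = c(TRUE, FALSE, TRUE))
#' filterSnvsNearIndels(v)$pos  # SNV at 100 removed, indel and 500 kept
#' @export
filterSnvsNearIndels <- function(variants, windowBp = 1L) {
    stopifnot(windowBp >= 0L)
    if (!nrow(variants)) return(variants)
    drop <- logical(nrow(variants))
    key <- paste(variants$sample_id, variants$chrom, sep = "\r")
    for (idx in split(seq_len(nrow(variants)), key)) {
        ind <- idx[variants$variant_class[idx] == "indel"]
        if (!length(ind)) next
        snv <- idx[variants$variant_class[idx] == "snv"]
        if (!length(snv)) next
        ip <- sort(variants$pos[ind])
        sp <- variants$pos[snv]
        j <- findInterval(sp, ip)
        dLeft <- ifelse(j >= 1L, sp - ip[pmax(j, 1L)], Inf)
        dRight <- ifelse(j < length(ip), ip[pmin(j + 1L, length(ip))] - sp, Inf)
        drop[snv] <- pmin(dLeft, dRight) <= windowBp
    }
    out <- variants[!drop, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Build the 21-mer mutant/wild-type peptide pair for one variant
#'
#' Takes up to 10 residues on each flank of the mutated position (total
#' length at most 21), truncating at the protein termini. The mutant
#' sequence is the wild-type window with the alternate residue substituted
#' at the variant position.
#'
#' @param proteinSeq amino-acid string of the (wild-type) protein.
#' @param variant one-row variant data.frame (non-synonymous SNV).
#' @return a list with elements \code{mutant_seq}, \code{wildtype_seq},
#'   \code{mutant_offset} (1-based index of the changed residue within the
#'   window) and \code{variant}.
#' @examples
#' prot <- paste(rep("ACDEFGHIKL", 20), collapse = "")
#' v <- data.frame(sample_id = "s", chrom = "chr1", pos = 1L,
#'                 variant_class = "snv", gene = "g", transcript_id = "t",
#'                 protein_pos = 50L, ref_aa = "L", alt_aa = "P",
#'                 is_nonsynonymous = TRUE)
#' p <- buildPeptidePair(prot, v)
#' nchar(p$mutant_seq)  # 21
#' p$mutant_offset      # 11
#' @export
buildPeptidePair <- function(proteinSeq, variant) {
    stopifnot(nrow(variant) == 1L, isTRUE(variant$is_nonsynonymous))
    p <- variant$protein_pos
    L <- nchar(proteinSeq)
    if (p > L)
        stop("protein position ", p, " beyond end of ", variant$transcript_id,
             " (length ", L, ")")
    ref <- substr(proteinSeq, p, p)
    if (ref != variant$ref_aa)
        stop("reference residue mismatch for ", variant$transcript_id,
             " position ", p, ": protein has ", ref, ", variant says ",
             variant$ref_aa)
    w0 <- max(1L, p - 10L)
    w1 <- min(L, p + 10L)
    wt <- substr(proteinSeq, w0, w1)
    off <- p - w0 + 1L
    mt <- paste0(substr(wt, 1L, off - 1L), variant$alt_aa,
                 substr(wt, off + 1L, nchar(wt)))
    list(mutant_seq = mt, wildtype_seq = wt, mutant_offset = off,
         variant = variant)
}

#' Enumerate all 9-mer windows of a peptide pair
#'
#' Every contiguous 9-residue window of the pair is returned (a peptide of
#' length L yields L - 8 windows; 13 for a full 21-mer). Mutant and
#' wild-type windows are taken at identical coordinates and
#' \code{contains_mutation} records whether the window spans the mutated
#' residue. Peptides shorter than 9 residues yield zero windows.
#'
#' @param pair a peptide pair from \code{\link{buildPeptidePair}}.
#' @return data.frame with columns \code{window_start}, \code{mutant_9mer},
#'   \code{wildtype_9mer}, \code{contains_mutation}.
#' @export
enumerateNineMers <- function(pair) {
    L <- nchar(pair$mutant_seq)
    if (L < 9L) {
        message("peptide of length ", L, " (< 9) yields no windows")
        return(data.frame(window_start = integer(), mutant_9mer = character(),
                          wildtype_9mer = character(),
                          contains_mutation = logical()))
    }
    ws <- seq_len(L - 8L)
    data.frame(
        window_start = ws,
        mutant_9mer = substring(pair$mutant_seq, ws, ws + 8L),
        wildtype_9mer = substring(pair$wildtype_seq, ws, ws + 8L),
        contains_mutation = ws <= pair$mutant_offset &
            pair$mutant_offset <= ws + 8L)
}

#' Vectorized peptide-pair construction for a whole variant table
#'
#' Applies \code{\link{buildPeptidePair}} logic across all non-synonymous
#' SNVs of a variant table at once. Variants on transcripts absent from the
#' proteome, or with a reference-residue mismatch, raise an error.
#'
#' @param variants variant data.frame.
#' @param proteome named character vector (or \code{AAStringSet}) of protein
#'   sequences keyed by transcript id.
#' @return data.frame with one row per peptide pair: \code{sample_id},
#'   \code{gene}, \code{transcript_id}, \code{protein_pos},
#'   \code{mutant_seq}, \code{wildtype_seq}, \code{mutant_offset}.
#' @export
buildPeptideTable <- function(variants, proteome) {
    if (is(proteome, "AAStringSet")) proteome <- as.character(proteome)
    v <- variants[variants$is_nonsynonymous & variants$variant_class == "snv", ,
                  drop = FALSE]
    if (!nrow(v))
        return(data.frame(sample_id = character(), gene = character(),
                          transcript_id = character(), protein_pos = integer(),
                          mutant_seq = character(), wildtype_seq = character(),
                          mutant_offset = integer()))
    missing <- setdiff(unique(v$transcript_id), names(proteome))
    if (length(missing))
        stop("transcript(s) absent from proteome: ",
             paste(head(missing, 5), collapse = ", "))
    prot <- unname(proteome[v$transcript_id])
    L <- nchar(prot)
    p <- v$protein_pos
    if (any(p > L))
        stop("protein position beyond protein end for ",
             v$transcript_id[which(p > L)[1L]])
    ref <- substr(prot, p, p)
    bad <- which(ref != v$ref_aa)
    if (length(bad))
        stop("reference residue mismatch for ", v$transcript_id[bad[1L]],
             " position ", p[bad[1L]], ": protein has ", ref[bad[1L]],
             ", variant says ", v$ref_aa[bad[1L]])
    w0 <- pmax(1L, p - 10L)
    w1 <- pmin(L, p + 10L)
    wt <- substr(prot, w0, w1)
    off <- p - w0 + 1L
    mt <- paste0(substr(wt, 1L, off - 1L), v$alt_aa,
                 substr(wt, off + 1L, nchar(wt)))
    data.frame(sample_id = v$sample_id, gene = v$gene,
               transcript_id = v$transcript_id, protein_pos = p,
               mutant_seq = mt, wildtype_seq = wt,
               mutant_offset = as.integer(off))
}

#' Vectorized 9-mer enumeration for a peptide-pair table
#'
#' @param pairs data.frame from \code{\link{buildPeptideTable}}.
#' @return data.frame with one row per 9-mer window, carrying the pair's
#'   sample, gene and transcript plus \code{window_start},
#'   \code{mutant_9mer}, \code{wildtype_9mer}, \code{contains_mutation}.
#' @export
enumerateNineMerTable <- function(pairs) {
    L <- nchar(pairs$mutant_seq)
    keep <- L >= 9L
    n <- L[keep] - 8L
    idx <- rep(which(keep), n)
    ws <- sequence(n)
    off <- pairs$mutant_offset[idx]
    data.frame(
        sample_id = pairs$sample_id[idx],
        gene = pairs$gene[idx],
        transcript_id = pairs$transcript_id[idx],
        protein_pos = pairs$protein_pos[idx],
        pair_index = idx,
        window_start = ws,
        mutant_9mer = substring(pairs$mutant_seq[idx], ws, ws + 8L),
        wildtype_9mer = substring(pairs$wildtype_seq[idx], ws, ws + 8L),
        contains_mutation = ws <= off & off <= ws + 8L)
}
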