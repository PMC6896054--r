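# Readers and writers for the plain-text formats the pipeline consumes and
# emits. Data tables (variants, Kd, expression) are written with full
# precision ("%.17g") so that write -> read round-trips are bit-identical;
# result tables are written with 6 significant digits for diff-able runs.

VARIANT_COLS <- c("sample_id", "chrom", "pos", "variant_class", "gene",
                  "transcript_id", "protein_pos", "ref_aa", "alt_aa",
                  "is_nonsynonymous")

fmtNum <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
}

checkVariantFrame <- function(v) {
    miss <- setdiff(VARIANT_COLS, names(v))
    if (length(miss))
        stop("variant table is missing column(s): ", paste(miss, collapse = ", "))
    if (!all(v$variant_class %in% c("snv", "indel")))
        stop("variant_class must be 'snv' or 'indel'")
    ns <- which(v$is_nonsynonymous)
    bad <- ns[is.na(v$protein_pos[ns]) | is.na(v$ref_aa[ns]) |
              is.na(v$alt_aa[ns]) | v$ref_aa[ns] == v$alt_aa[ns]]
    if (length(bad))
        stop("non-synonymous variant(s) with missing or degenerate protein ",
             "annotation at row(s): ", paste(head(bad, 5), collapse = ", "))
    if (any(v$pos < 1L, na.rm = TRUE)) stop("genomic positions must be >= 1")
    if (any(v$protein_pos < 1L, na.rm = TRUE)) stop("protein positions must be >= 1")
    v$pos <- as.integer(v$pos)
    v$protein_pos <- as.integer(v$protein_pos)
    v$is_nonsynonymous <- as.logical(v$is_nonsynonymous)
    v[VARIANT_COLS]
}

#' Read annotated somatic variants
#'
#' Reads one record per (sample, variant) from either a TSV with the columns
#' \code{sample_id, chrom, pos, variant_class, gene, transcript_id,
#' protein_pos, ref_aa, alt_aa, is_nonsynonymous}, or a VCF 4.2 file whose
#' INFO field carries the same annotation (keys \code{SMP, VC, GENE, TRID,
#' PPOS, RAA, AAA, NSYN}; see \code{\link{writeVariantsVcf}}). Genomic and
#' protein coordinates are 1-based in both dialects.
#'
#' @param path input file.
#' @param dialect \code{"tsv"} or \code{"vcf"}.
#' @return a data.frame of variants, one row per (sample, variant).
#' @examples
#' v <- data.frame(sample_id = "s1", chrom = "chr1", pos = 100L,
#'                 variant_class = "snv", gene = "g", transcript_id = "t1",
#'                 protein_pos = 5L, ref_aa = "A", alt_aa = "V",
#'                 is_nonsynonymous = TRUE)
#' tf <- tempfile(fileext = ".tsv")
#' writeVariantsTsv(v, tf)
#' identical(readVariants(tf, "tsv"), v)
#' @export
readVariants <- function(path, dialect = c("tsv", "vcf")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("no such file: ", path)
    if (dialect == "tsv") {
        v <- read.delim(path, colClasses = "character")
        miss <- setdiff(VARIANT_COLS, names(v))
        if (length(miss))
            stop("TSV ", path, " is missing column(s): ",
                 paste(miss, collapse = ", "))
        v$pos <- as.integer(v$pos)
        v$protein_pos <- suppressWarnings(as.integer(v$protein_pos))
        v$is_nonsynonymous <- as.logical(v$is_nonsynonymous)
        v[v == ""] <- NA
        return(checkVariantFrame(v))
    }
    readVariantsVcf(path)
}

readVariantsVcf <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    info <- VariantAnnotation::info(vcf)
    need <- c("SMP", "VC", "GENE", "TRID", "PPOS", "RAA", "AAA", "NSYN")
    miss <- setdiff(need, names(info))
    if (length(miss))
        stop("VCF ", path, " lacks INFO field(s): ", paste(miss, collapse = ", "))
    nHeader <- sum(startsWith(readLines(path), "#"))
    rr <- SummarizedExperiment::rowRanges(vcf)
    pos <- BiocGenerics::start(rr)
    asChr <- function(x) {
        x <- as.character(x)
        x[!nzchar(x)] <- NA_character_
        x
    }
    v <- data.frame(
        sample_id = asChr(info$SMP),
        chrom = as.character(GenomeInfoDb::seqnames(rr)),
        pos = pos,
        variant_class = asChr(info$VC),
        gene = asChr(info$GENE),
        transcript_id = asChr(info$TRID),
        protein_pos = as.integer(info$PPOS),
        ref_aa = asChr(info$RAA),
        alt_aa = asChr(info$AAA),
        is_nonsynonymous = as.logical(info$NSYN),
        stringsAsFactors = FALSE)
    ns <- which(v$is_nonsynonymous & v$variant_class == "snv")
    bad <- ns[is.na(v$protein_pos[ns]) | is.na(v$transcript_id[ns]) |
              is.na(v$ref_aa[ns]) | is.na(v$alt_aa[ns])]
    if (length(bad))
        stop("VCF ", path, ": missing protein annotation at line ",
             nHeader + bad[1L], " (record ", bad[1L], ")")
    rownames(v) <- NULL
    checkVariantFrame(v)
}

#' @describeIn readVariants Write a variant table as TSV.
#' @param variants a variant data.frame.
#' @export
writeVariantsTsv <- function(variants, path) {
    v <- checkVariantFrame(variants)
    write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    invisible(path)
}

#' @describeIn readVariants Write a variant table as an annotated VCF 4.2
#'   file (reference and alternate bases are placeholders; the protein-level
#'   annotation lives in INFO).
#' @export
writeVariantsVcf <- function(variants, path) {
    v <- checkVariantFrame(variants)
    hdr <- c("##fileformat=VCFv4.2",
        "##INFO=<ID=SMP,Number=1,Type=String,Description=\"Sample id\">",
        "##INFO=<ID=VC,Number=1,Type=String,Description=\"Variant class\">",
        "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
        "##INFO=<ID=TRID,Number=1,Type=String,Description=\"Transcript id\">",
        "##INFO=<ID=PPOS,Number=1,Type=Integer,Description=\"1-based protein position\">",
        "##INFO=<ID=RAA,Number=1,Type=String,Description=\"Reference amino acid\">",
        "##INFO=<ID=AAA,Number=1,Type=String,Description=\"Alternate amino acid\">",
        "##INFO=<ID=NSYN,Number=0,Type=Flag,Description=\"Non-synonymous\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
              collapse = "\t"))
    ref <- ifelse(v$variant_class == "indel", "NN", "N")
    optInfo <- function(key, val)
        ifelse(is.na(val), "", paste0(";", key, "=", val))
    info <- paste0("SMP=", v$sample_id, ";VC=", v$variant_class,
                   optInfo("GENE", v$gene), optInfo("TRID", v$transcript_id),
                   optInfo("PPOS", v$protein_pos), optInfo("RAA", v$ref_aa),
                   optInfo("AAA", v$alt_aa),
                   ifelse(v$is_nonsynonymous, ";NSYN", ""))
    rows <- paste(v$chrom, v$pos, ".", ref, "A", ".", "PASS", info, sep = "\t")
    writeLines(c(hdr, rows), path)
    invisible(path)
}

#' Read a per-transcript RPKM expression table
#'
#' Expects a TSV whose first column is \code{transcript_id} followed by one
#' column per sample. All values must be present and non-negative.
#'
#' @param path input TSV.
#' @return numeric matrix, transcripts in rows, samples in columns.
#' @export
readExpression <- function(path) {
    x <- read.delim(path, check.names = FALSE)
    if (names(x)[1L] != "transcript_id")
        stop("expression table must start with a 'transcript_id' column")
    if (anyDuplicated(x$transcript_id))
        stop("duplicate transcript id(s) in expression table: ",
             paste(head(unique(x$transcript_id[duplicated(x$transcript_id)]), 3),
                   collapse = ", "))
    m <- as.matrix(x[-1L])
    if (is.logical(m) && all(is.na(m))) storage.mode(m) <- "double"
    if (!is.numeric(m)) stop("expression values must be numeric")
    if (anyNA(m)) stop("missing cells in expression table")
    if (any(m < 0)) stop("negative RPKM value(s) in expression table")
    rownames(m) <- x$transcript_id
    m
}

#' @describeIn readExpression Write an expression matrix as TSV
#'   (full-precision; round-trips bit-identically through
#'   \code{readExpression}).
#' @param rpkm numeric matrix as returned by \code{readExpression}.
#' @export
writeExpression <- function(rpkm, path) {
    stopifnot(is.matrix(rpkm), !is.null(rownames(rpkm)))
    df <- data.frame(transcript_id = rownames(rpkm),
                     apply(rpkm, 2L, fmtNum),
                     check.names = FALSE)
    colnames(df) <- c("transcript_id", colnames(rpkm))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Construct an epitope reference set
#'
#' Sequences are uppercased and deduplicated preserving first-occurrence
#' order. Sequences shorter than 9 residues are dropped with a warning; any
#' character outside the 20-letter amino-acid alphabet is an error.
#'
#' @param sequences character vector of peptide sequences.
#' @return an \code{\linkS4class{EpitopeSet}}.
#' @examples
#' EpitopeSet(c("ACDEFGHIK", "acdefghik", "WYVRNDCQE"))
#' @export
EpitopeSet <- function(sequences) {
    s <- toupper(as.character(sequences))
    bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), s)
    if (any(bad))
        stop("non-amino-acid character in epitope(s): ",
             paste(head(s[bad], 3), collapse = ", "))
    short <- nchar(s) < 9L
    if (any(short)) {
        warning(sum(short), " epitope(s) shorter than 9 residues dropped")
        s <- s[!short]
    }
    new("EpitopeSet", sequences = unique(s))
}

#' @describeIn EpitopeSet Read an epitope reference from FASTA (extensions
#'   \code{.fa/.fasta/.faa}) or CSV (one sequence per row; an optional header
#'   row named \code{sequence} is skipped).
#' @param path input file.
#' @export
readEpitopeReference <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("fa", "fasta", "faa")) {
        s <- as.character(Biostrings::readAAStringSet(path))
    } else {
        s <- read.csv(path, header = FALSE, colClasses = "character")[[1L]]
        if (length(s) && tolower(s[1L]) == "sequence") s <- s[-1L]
    }
    EpitopeSet(s)
}

#' @rdname EpitopeSet
#' @aliases epitopes,EpitopeSet-method length,EpitopeSet-method
#' @param x an \code{EpitopeSet}.
#' @export
setMethod("epitopes", "EpitopeSet", function(x) x@sequences)

setMethod("length", "EpitopeSet", function(x) length(x@sequences))

setMethod("show", "EpitopeSet", function(object) {
    cat("EpitopeSet of", length(object), "sequences\n")
    if (length(object))
        cat("  ", paste(head(object@sequences, 3), collapse = ", "),
            if (length(object) > 3) "..." else "", "\n")
})

#' Read a per-sample HLA class I allele list
#'
#' One allele per line (e.g. \code{HLA-A*02:01}); duplicates are removed
#' preserving order.
#'
#' @param path input text file.
#' @return character vector of alleles.
#' @export
readAlleleList <- function(path) {
    x <- trimws(readLines(path))
    x <- x[nzchar(x)]
    if (!length(x)) stop("allele list ", path, " is empty")
    unique(x)
}

#' Read a peptide:MHC dissociation-constant table
#'
#' TSV with columns \code{peptide, allele, kd_nM} (any binding predictor's
#' output reshaped to long form). Lookups for pairs absent from the table
#' raise an error naming the pair.
#'
#' @param path input TSV.
#' @return a \code{\linkS4class{KdTable}}.
#' @export
readKdTable <- function(path) {
    x <- read.delim(path)
    miss <- setdiff(c("peptide", "allele", "kd_nM"), names(x))
    if (length(miss))
        stop("Kd table is missing column(s): ", paste(miss, collapse = ", "))
    kdTable(x$peptide, x$allele, x$kd_nM)
}

#' @describeIn readKdTable Build a \code{KdTable} in memory.
#' @param peptide,allele,kd_nM equal-length vectors.
#' @export
kdTable <- function(peptide, allele, kd_nM) {
    if (any(!is.finite(kd_nM) | kd_nM <= 0))
        stop("all Kd values must be finite and > 0")
    new("KdTable", table = setNames(as.numeric(kd_nM),
                                    paste(peptide, allele, sep = "|")))
}

#' @describeIn readKdTable Write a \code{KdTable} as TSV (full precision).
#' @param object a \code{KdTable}.
#' @export
writeKdTable <- function(object, path) {
    stopifnot(is(object, "KdTable"))
    keys <- strsplit(names(object@table), "|", fixed = TRUE)
    df <- data.frame(peptide = vapply(keys, `[`, "", 1L),
                     allele = vapply(keys, `[`, "", 2L),
                     kd_nM = fmtNum(unname(object@table)))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read sample-to-group assignments
#'
#' TSV with columns \code{sample_id, group}; exactly two distinct group
#' labels are expected downstream.
#'
#' @param path input TSV.
#' @return named character vector mapping sample id to group label.
#' @export
readGroups <- function(path) {
    x <- read.delim(path, colClasses = "character")
    miss <- setdiff(c("sample_id", "group"), names(x))
    if (length(miss))
        stop("groups table is missing column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(x$sample_id)) stop("duplicate sample id in groups table")
    setNames(x$group, x$sample_id)
}

#' Read a per-sample cell-type score table
#'
#' TSV with a \code{sample_id} column followed by one numeric column per
#' cell type (e.g. deconvolution scores).
#'
#' @param path input TSV.
#' @return data.frame with rownames set to sample ids.
#' @export
readCellScores <- function(path) {
    x <- read.delim(path, check.names = FALSE)
    if (names(x)[1L] != "sample_id")
        stop("cell-score table must start with a 'sample_id' column")
    rownames(x) <- x$sample_id
    x[-1L]
}

#' Read an HLA exon annotation (BED)
#'
#' The BED name field must follow \code{GENE:exonN} (e.g.
#' \code{HLA-A:exon2}). On-disk BED intervals are 0-based half-open;
#' \code{rtracklayer} converts them to the package's 1-based closed
#' convention on import. Exons 2 and 3 encode the MHC class I
#' peptide-binding groove and are flagged accordingly.
#'
#' @param path BED file.
#' @return a \code{GRanges} with metadata columns \code{gene}, \code{exon}
#'   and \code{groove}.
#' @export
readGrooveAnnotation <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    nm <- gr$name
    ok <- grepl("^[^:]+:exon[0-9]+$", nm)
    if (!all(ok))
        stop("BED name field must look like 'GENE:exonN'; offending: ",
             paste(head(nm[!ok], 3), collapse = ", "))
    gr$gene <- sub(":.*$", "", nm)
    gr$exon <- as.integer(sub("^.*:exon", "", nm))
    gr$groove <- gr$exon %in% c(2L, 3L)
    gr
}

#' Write scored 9-mer records or sample summaries as TSV
#'
#' Result tables use a fixed column order and 6 significant digits for
#' floating-point values, so repeated runs diff cleanly.
#'
#' @param x data.frame of records or summaries.
#' @param path output TSV.
#' @export
writeResultsTsv <- function(x, path) {
    num <- vapply(x, is.double, TRUE)
    x[num] <- lapply(x[num], function(col) {
        out <- sprintf("%.6g", col)
        out[is.na(col)] <- "NA"
        out
    })
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    invisible(path)
}

#' @describeIn writeResultsTsv Read back a results TSV (numeric columns
#'   restored; \code{NA} preserved).
#' @export
readResultsTsv <- function(path) {
    read.delim(path, check.names = FALSE)
}
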