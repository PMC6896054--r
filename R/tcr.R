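# TCR recognition potential. The similarity |s,e| between a candidate
# neoantigen s and a known epitope e is the maximal-scoring ungapped local
# alignment under BLOSUM62; the recognition potential is
#   R = Z(k)^-1 * sum_e exp[-k (a - |s,e|)],  Z(k) = 1 + sum_e exp[-k (a - |s,e|)]
# i.e. R = S / (1 + S), evaluated in log space because k (a - |s,e|) spans
# roughly -100 .. +150 for the default a = 26, k = 4.87.

BLOSUM62_TXT <- "
   A  R  N  D  C  Q  E  G  H  I  L  K  M  F  P  S  T  W  Y  V
A  4 -1 -2 -2  0 -1 -1  0 -2 -1 -1 -1 -1 -2 -1  1  0 -3 -2  0
R -1  5  0 -2 -3  1  0 -2  0 -3 -2  2 -1 -3 -2 -1 -1 -3 -2 -3
N -2  0  6  1 -3  0  0  0  1 -3 -3  0 -2 -3 -2  1  0 -4 -2 -3
D -2 -2  1  6 -3  0  2 -1 -1 -3 -4 -1 -3 -3 -1  0 -1 -4 -3 -3
C  0 -3 -3 -3  9 -3 -4 -3 -3 -1 -1 -3 -1 -2 -3 -1 -1 -2 -2 -1
Q -1  1  0  0 -3  5  2 -2  0 -3 -2  1  0 -3 -1  0 -1 -2 -1 -2
E -1  0  0  2 -4  2  5 -2  0 -3 -3  1 -2 -3 -1  0 -1 -3 -2 -2
G  0 -2  0 -1 -3 -2 -2  6 -2 -4 -4 -2 -3 -3 -2  0 -2 -2 -3 -3
H -2  0  1 -1 -3  0  0 -2  8 -3 -3 -1 -2 -1 -2 -1 -2 -2  2 -3
I -1 -3 -3 -3 -1 -3 -3 -4 -3  4  2 -3  1  0 -3 -2 -1 -3 -1  3
L -1 -2 -3 -4 -1 -2 -3 -4 -3  2  4 -2  2  0 -3 -2 -1 -2 -1  1
K -1  2  0 -1 -3  1  1 -2 -1 -3 -2  5 -1 -3 -1  0 -1 -3 -2 -2
M -1 -1 -2 -3 -1  0 -2 -3 -2  1  2 -1  5  0 -2 -1 -1 -1 -1  1
F -2 -3 -3 -3 -2 -3 -3 -3 -1  0  0 -3  0  6 -4 -2 -2  1  3 -1
P -1 -2 -2 -1 -3 -1 -1 -2 -2 -3 -3 -1 -2 -4  7 -1 -1 -4 -3 -2
S  1 -1  1  0 -1  0  0  0 -1 -2 -2  0 -1 -2 -1  4  1 -3 -2 -2
T  0 -1  0 -1 -1 -1 -1 -2 -2 -1 -1 -1 -1 -2 -1  1  5 -2 -2  0
W -3 -3 -4 -4 -2 -2 -3 -2 -2 -3 -2 -3 -1  1 -4 -3 -2 11  2 -3
Y -2 -2 -2 -3 -2 -1 -2 -3  2 -1 -1 -2 -1  3 -3 -2 -2  2  7 -1
V  0 -3 -3 -3 -1 -2 -2 -3 -3  3  1 -2  1 -1 -2 -2  0 -3 -1  4"

parseBlosum <- function(txt) {
    lines <- strsplit(trimws(txt), "\n")[[1L]]
    tok <- lapply(trimws(lines), function(l) strsplit(l, " +")[[1L]])
    ab <- tok[[1L]]
    m <- t(vapply(tok[-1L], function(x) as.integer(x[-1L]),
                  integer(length(ab))))
    dimnames(m) <- list(ab, ab)
    m
}

BLOSUM62_MATRIX <- parseBlosum(BLOSUM62_TXT)

#' The BLOSUM62 substitution matrix
#'
#' The canonical NCBI integer BLOSUM62 matrix over the 20 standard amino
#' acids, embedded as a constant so alignment scores do not depend on any
#' external definition.
#'
#' @return symmetric 20x20 integer matrix with amino-acid dimnames.
#' @examples
#' blosum62()["A", "A"]  # 4
#' @export
blosum62 <- function() BLOSUM62_MATRIX

#' Gapless local alignment similarity
#'
#' Returns the maximum, over all ungapped local alignments (pairs of
#' equal-length contiguous substrings of \code{s} and \code{e}, length
#' >= 1), of the summed substitution scores: the sequence similarity
#' \eqn{|s,e|} used by the TCR recognition model.
#'
#' @param s character vector of candidate peptides (typically 9-mers).
#' @param e character vector of epitope sequences.
#' @param matrix symmetric integer substitution matrix with amino-acid
#'   dimnames (default \code{\link{blosum62}()}).
#' @return integer matrix of dimension \code{length(s) x length(e)};
#'   dropped to a vector/scalar when either side has length 1.
#' @examples
#' gaplessAlignmentScore("AAAAAAAAA", "AAAAAAAAA")  # 36
#' @export
gaplessAlignmentScore <- function(s, e, matrix = blosum62()) {
    stopifnot(is.matrix(matrix), identical(rownames(matrix), colnames(matrix)))
    if (!isTRUE(all.equal(matrix, t(matrix))))
        stop("substitution matrix must be symmetric")
    storage.mode(matrix) <- "integer"
    out <- cppGaplessScores(as.character(s), as.character(e), matrix,
                            paste(rownames(matrix), collapse = ""))
    dimnames(out) <- NULL
    drop(out)
}

#' TCR recognition potential
#'
#' Computes \eqn{R = S / (1 + S)} with
#' \eqn{S = \sum_{e} \exp[-k (a - |s,e|)]} over the epitope reference set,
#' evaluated by log-sum-exp for numerical stability. An empty reference
#' gives \eqn{R = 0} (unbound state only) with a warning.
#'
#' @param s character vector of candidate 9-mers.
#' @param reference an \code{\linkS4class{EpitopeSet}} (or character vector
#'   of epitopes).
#' @param a horizontal displacement of the binding curve (default 26).
#' @param k steepness of the binding curve (default 4.87), must be > 0.
#' @param matrix substitution matrix (default \code{\link{blosum62}()}).
#' @return numeric vector of recognition potentials in [0, 1).
#' @examples
#' ref <- EpitopeSet(c("ACDEFGHIK"))
#' recognitionPotential("ACDEFGHIK", ref)  # self-similarity drives R -> 1
#' @export
recognitionPotential <- function(s, reference, a = 26, k = 4.87,
                                 matrix = blosum62()) {
    stopifnot(k > 0)
    eps <- if (is(reference, "EpitopeSet")) epitopes(reference)
           else as.character(reference)
    if (!length(eps)) {
        warning("empty epitope reference: recognition potential is 0")
        return(rep(0, length(s)))
    }
    if (!length(s)) return(numeric())
    sc <- gaplessAlignmentScore(s, eps, matrix)
    lt <- k * (matrix(sc, nrow = length(s)) - a)   # log of each bound-state term
    m <- apply(lt, 1L, max)
    logS <- m + log(rowSums(exp(lt - m)))
    plogis(logS)   # S / (1 + S)
}
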