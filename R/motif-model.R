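DNA_BASES <- c("A", "C", "G", "T")

## Normalize user input (character vector or DNAStringSet) to an uppercase
## DNAStringSet over {A,C,G,T}, with unique ids. Characters outside the
## four-letter alphabet (including IUPAC N) are rejected, not matched.
.asMotifSequences <- function(x) {
    if (is.character(x))
        x <- Biostrings::DNAStringSet(toupper(x))
    if (!is(x, "DNAStringSet"))
        stop("sequences must be a character vector or a DNAStringSet")
    if (length(x) == 0L)
        stop("the sequence set is empty")
    if (is.null(names(x)) || any(names(x) == ""))
        names(x) <- paste0("seq", seq_along(x))
    if (anyDuplicated(names(x)))
        stop("sequence ids must be unique")
    freq <- Biostrings::alphabetFrequency(x)
    bad <- rowSums(freq[, setdiff(colnames(freq), DNA_BASES),
                        drop = FALSE]) > 0L
    if (any(bad))
        stop("sequence(s) contain characters outside {A,C,G,T}: ",
             paste(names(x)[bad], collapse = ", "))
    x
}

.checkWord <- function(w, arg = "word") {
    if (!is.character(w) || length(w) != 1L || is.na(w))
        stop(arg, " must be a single character string")
    w <- toupper(w)
    if (nchar(w) == 0L ||
        !all(strsplit(w, "")[[1L]] %in% DNA_BASES))
        stop(arg, " must be a non-empty word over {A,C,G,T}")
    w
}

#' Hamming distance between two equal-length DNA words
#'
#' @param u,v words over \{A,C,G,T\} of equal length.
#' @return The number of positions at which `u` and `v` differ.
#' @examples
#' hammingDistance("GATAAG", "GATCAG")  # 1
#' @export
hammingDistance <- function(u, v) {
    u <- .checkWord(u, "u"); v <- .checkWord(v, "v")
    if (nchar(u) != nchar(v))
        stop("Hamming distance is undefined for words of unequal length (",
             nchar(u), " vs ", nchar(v), ")")
    sum(strsplit(u, "")[[1L]] != strsplit(v, "")[[1L]])
}

#' Size of the Hamming neighborhood of a DNA word
#'
#' The number \eqn{\nu(e, \ell)} of words of length \eqn{\ell} within
#' Hamming distance e of any fixed word:
#' \eqn{\nu(e,\ell) = \sum_{i=0}^{e} \binom{\ell}{i} 3^i}. It is
#' independent of the centre word and bounded above by
#' \eqn{\ell^e 4^e}. This is the per-window branching factor of stage-1
#' enumeration and the driver of instance difficulty.
#'
#' @param len word length \eqn{\ell} (positive integer).
#' @param errors substitution budget e, with \eqn{0 \le e < \ell}.
#' @return The exact neighborhood size as a double (exact for all sizes
#'   representable without rounding).
#' @examples
#' neighborhoodSize(3, 1)  # 10
#' @export
neighborhoodSize <- function(len, errors) {
    if (length(len) != 1L || length(errors) != 1L ||
        is.na(len) || is.na(errors) ||
        len < 1L || errors < 0L || errors >= len)
        stop("need 0 <= errors < len")
    i <- 0:errors
    sum(choose(len, i) * 3^i)
}

#' Integer quorum threshold
#'
#' The minimum number of distinct sequences a motif must occur in:
#' \eqn{\lceil q N \rceil} for quorum fraction q over N sequences.
#'
#' @param q quorum fraction in (0, 1].
#' @param n number of input sequences.
#' @return An integer count in 1..n.
#' @examples
#' quorumThreshold(0.70, 10)  # 7
#' quorumThreshold(0.68, 23)  # 16
#' @export
quorumThreshold <- function(q, n) {
    if (length(q) != 1L || is.na(q) || q <= 0 || q > 1)
        stop("quorum must be a single value in (0, 1]")
    if (length(n) != 1L || is.na(n) || n < 1L)
        stop("n must be a positive integer")
    as.integer(ceiling(q * n - 1e-9))
}

#' Expected number of spurious simple motifs in random sequences
#'
#' Estimates how many \eqn{(\ell, e)} consensus words are expected to meet
#' a full quorum purely by chance in N i.i.d.-uniform DNA sequences of
#' length L — the quantity used to grade planted-motif instances as easy
#' (expectation much greater than one, e.g. short boxes) or hard
#' (expectation near one, e.g. the (9,2) box on 20 x 600 datasets). Under
#' an independence approximation across the \eqn{L-\ell+1} windows of a
#' sequence,
#' \deqn{E(\ell,e) = 4^\ell \left[1 - \left(1 -
#'   \nu(e,\ell)/4^\ell\right)^{L-\ell+1}\right]^N.}
#' The estimate classifies instance difficulty only; it is never used to
#' filter enumeration output.
#'
#' @param len,errors box template \eqn{(\ell, e)}.
#' @param n number of sequences N.
#' @param seqLength sequence length L (bases), with \eqn{\ell \le L}.
#' @return The expected count (a double).
#' @examples
#' expectedMotifCount(9, 2, n = 20, seqLength = 600)
#' @export
expectedMotifCount <- function(len, errors, n, seqLength) {
    if (length(n) != 1L || length(seqLength) != 1L ||
        is.na(n) || is.na(seqLength) || n < 1L || seqLength < len)
        stop("need n >= 1 and seqLength >= len")
    nu <- neighborhoodSize(len, errors)  # validates len/errors
    pWindow <- nu / 4^len
    pSeq <- 1 - (1 - pWindow)^(seqLength - len + 1)
    4^len * pSeq^n
}
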