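#' Generate i.i.d.-uniform random DNA sequences
#'
#' Background model of the planted-motif benchmark: each base is drawn
#' independently and uniformly (probability 0.25 per symbol).
#'
#' @param n number of sequences.
#' @param len sequence length in bases.
#' @param seed optional integer seed (uses the session RNG stream when
#'   `NULL`).
#' @return A [Biostrings::DNAStringSet] named `seq1..seqn`.
#' @examples
#' generateSequences(20, 600, seed = 1)
#' @export
generateSequences <- function(n, len, seed = NULL) {
    stopifnot(n >= 1L, len >= 1L)
    if (!is.null(seed)) set.seed(seed)
    seqs <- vapply(seq_len(n), function(i)
        paste(sample(DNA_BASES, len, replace = TRUE), collapse = ""),
        character(1))
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- paste0("seq", seq_len(n))
    x
}

#' Mutate a word by random substitutions
#'
#' Picks `errors` distinct positions uniformly at random and replaces
#' each with a base drawn uniformly from all four letters, so the
#' realized Hamming distance from `word` is at most `errors` (a redraw
#' may reproduce the original base). Set `forceDistance = TRUE` to draw
#' replacements from the three other letters, making the distance
#' exactly `errors`.
#'
#' @param word a word over \{A,C,G,T\}.
#' @param errors number of substituted positions,
#'   `0 <= errors < nchar(word)`.
#' @param forceDistance require the realized distance to equal `errors`.
#' @return The mutated word.
#' @export
mutateWord <- function(word, errors, forceDistance = FALSE) {
    word <- .checkWord(word)
    len <- nchar(word)
    if (errors < 0L || errors >= len)
        stop("need 0 <= errors < nchar(word)")
    if (errors == 0L) return(word)
    chars <- strsplit(word, "")[[1L]]
    pos <- sample.int(len, errors)
    for (p in pos) {
        pool <- if (forceDistance) setdiff(DNA_BASES, chars[p])
                else DNA_BASES
        chars[p] <- pool[sample.int(length(pool), 1L)]
    }
    paste(chars, collapse = "")
}

#' Generate a planted-motif benchmark dataset with ground truth
#'
#' Reproduces the planted-motif experimental design: N background
#' sequences of length L with i.i.d.-uniform bases; b consensus words
#' drawn uniformly at random; and exactly one structured-motif
#' occurrence planted per sequence, respecting box order and gap
#' constraints but otherwise at random. Per sequence, each box instance
#' is the consensus mutated at \eqn{e_i} random positions (distance
#' \eqn{\le e_i}, see [mutateWord()]), gap values are drawn uniformly
#' within \eqn{[d_i, D_i]}, and the leftmost start uniformly among
#' feasible positions; the instances then overwrite the background.
#' With `plantExact`, the first sequence receives the unmutated
#' consensus words, guaranteeing one exact structured occurrence.
#'
#' A single RNG stream drives everything, in a fixed draw order
#' (background sequences, then consensus words, then per sequence:
#' gaps, leftmost start, box instances), so datasets are reproducible
#' under a fixed seed. Background regions may contain chance extra
#' occurrences; they are not removed.
#'
#' @param n number of sequences N.
#' @param len sequence length L; must satisfy
#'   \eqn{\sum_i \ell_i + \sum_i D_i \le L} so that any drawn gap
#'   combination fits.
#' @param template a [StructuredTemplate-class].
#' @param plantExact plant the exact (unmutated) words in sequence 1.
#' @param forceDistance see [mutateWord()].
#' @param seed optional integer seed.
#' @return A [PlantedMotifData-class].
#' @examples
#' tpl <- parseTemplate("(9,2)-[5,10]-(10,2)")
#' pd <- plantDataset(20, 600, tpl, seed = 7)
#' @export
plantDataset <- function(n, len, template, plantExact = FALSE,
                         forceDistance = FALSE, seed = NULL) {
    stopifnot(is(template, "StructuredTemplate"))
    validObject(template)
    if (!is.null(seed)) set.seed(seed)
    lens <- template@boxLengths
    b <- length(lens)
    maxSpan <- sum(lens) + sum(template@gapMax)
    if (maxSpan > len)
        stop("template does not fit: total box length plus maximum gaps (",
             maxSpan, ") exceeds the sequence length (", len, ")")

    seqs <- as.character(generateSequences(n, len))
    words <- vapply(lens, function(l)
        paste(sample(DNA_BASES, l, replace = TRUE), collapse = ""),
        character(1))

    starts <- matrix(0L, n, b)
    for (s in seq_len(n)) {
        gaps <- if (b > 1L)
            template@gapMin + vapply(template@gapMax - template@gapMin,
                function(r) sample.int(r + 1L, 1L) - 1L, integer(1))
            else integer()
        span <- sum(lens) + sum(gaps)
        s1 <- sample.int(len - span + 1L, 1L)
        st <- s1 + cumsum(c(0L, head(lens, -1L) + gaps))
        starts[s, ] <- st
        for (i in seq_len(b)) {
            inst <- if (plantExact && s == 1L) words[i]
                    else mutateWord(words[i], template@boxErrors[i],
                                    forceDistance)
            substr(seqs[s], st[i], st[i] + lens[i] - 1L) <- inst
        }
    }
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- paste0("seq", seq_len(n))
    new("PlantedMotifData",
        sequences = x, template = template, consensusWords = words,
        plantedStarts = starts,
        exactSequence = if (plantExact) 1L else NA_integer_)
}
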