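#' Naive occurrence scan for one consensus word
#'
#' Slides the consensus over every window of every sequence and reports
#' all positions within Hamming distance `errors`. This is the simple
#' reference back-end for the spelling engine: slow but direct, useful
#' as an independent check and for inspecting single words.
#'
#' @param seqs sequences (character vector or
#'   [Biostrings::DNAStringSet]).
#' @param consensus a word over \{A,C,G,T\}.
#' @param errors maximum number of substitutions, `0 <= errors <
#'   nchar(consensus)`.
#' @return A two-column integer matrix (`seq`, `start`; 1-based) sorted
#'   by sequence index then start.
#' @examples
#' scanOccurrences(c("AAAA"), "AAT", errors = 1)
#' @export
scanOccurrences <- function(seqs, consensus, errors) {
    seqs <- .asMotifSequences(seqs)
    consensus <- .checkWord(consensus, "consensus")
    len <- nchar(consensus)
    if (errors < 0L || errors >= len)
        stop("need 0 <= errors < nchar(consensus)")
    w <- strsplit(consensus, "")[[1L]]
    out <- vector("list", length(seqs))
    for (s in seq_along(seqs)) {
        chars <- strsplit(as.character(seqs[[s]]), "")[[1L]]
        nwin <- length(chars) - len + 1L
        if (nwin < 1L) next
        mism <- integer(nwin)
        for (j in seq_len(len))
            mism <- mism + (chars[j:(j + nwin - 1L)] != w[j])
        hits <- which(mism <= errors)
        if (length(hits))
            out[[s]] <- cbind(seq = rep.int(s, length(hits)),
                              start = hits)
    }
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- matrix(integer(), 0L, 2L,
                      dimnames = list(NULL, c("seq", "start")))
    out
}

#' Enumerate all simple motifs for one box template
#'
#' Stage-1 enumeration: returns exactly the consensus words
#' \eqn{w \in \Sigma^\ell} that occur (with at most `boxErrors`
#' substitutions) in at least `quorumCount` distinct sequences — in
#' `"frequent"` mode additionally restricted to words with at least one
#' exact (zero-mismatch) occurrence somewhere in the input. Every
#' returned motif carries its complete occurrence list, sorted by
#' increasing sequence index and position. No significance filtering of
#' any kind is applied: structured motifs may reach quorum only because
#' they contain weak simple motifs, so every quorum-meeting word is kept.
#'
#' The engine spells candidate words base by base over the window set,
#' pruning a prefix as soon as its support falls below `quorumCount`
#' (support is non-increasing under extension), so only viable branches
#' of the \eqn{4^\ell} word space are visited.
#'
#' Candidate sets are held in memory; an allocation failure during
#' enumeration is signalled as a condition of class `stage1MemoryError`
#' so callers can tell this failure mode apart from invalid input.
#'
#' @param seqs sequences (character vector or
#'   [Biostrings::DNAStringSet]).
#' @param boxLength,boxErrors the box template \eqn{(\ell, e)},
#'   \eqn{0 \le e < \ell}.
#' @param quorumCount minimum number of distinct sequences
#'   (see [quorumThreshold()]).
#' @param mode `"unconstrained"` (default) or `"frequent"`.
#' @return A [SimpleMotifSet-class], motifs in lexicographic order.
#' @examples
#' findSimpleMotifs(c("AAAA"), 3, 1, quorumCount = 1)
#' @export
findSimpleMotifs <- function(seqs, boxLength, boxErrors, quorumCount,
                             mode = c("unconstrained", "frequent")) {
    seqs <- .asMotifSequences(seqs)
    mode <- match.arg(mode)
    boxLength <- as.integer(boxLength)
    boxErrors <- as.integer(boxErrors)
    if (is.na(boxLength) || is.na(boxErrors) ||
        boxErrors < 0L || boxErrors >= boxLength)
        stop("box template must satisfy 0 <= errors < length")
    quorumCount <- as.integer(quorumCount)
    if (is.na(quorumCount) || quorumCount < 1L)
        stop("quorumCount must be a positive integer")

    res <- tryCatch(
        .spellMotifsCpp(as.character(seqs), boxLength, boxErrors,
                        quorumCount, mode == "frequent"),
        error = function(e) {
            if (grepl("alloc|memory", conditionMessage(e),
                      ignore.case = TRUE))
                stop(structure(class = c("stage1MemoryError", "error",
                                         "condition"),
                    list(message = paste0(
                        "stage 1 ran out of memory while enumerating (",
                        boxLength, ",", boxErrors, ") candidates: ",
                        conditionMessage(e)), call = NULL)))
            stop(e)
        })
    new("SimpleMotifSet",
        boxLength = boxLength, boxErrors = boxErrors,
        quorumCount = quorumCount, nSequences = length(seqs),
        mode = mode,
        consensus = res$consensus,
        occurrences = res$occurrences,
        support = res$support)
}

#' Build per-box candidate sets for a structured template
#'
#' Runs stage-1 enumeration once per distinct \eqn{(\ell, e)} pair in the
#' template and shares the result among boxes with identical templates,
#' yielding the candidate sets \eqn{K_1, \dots, K_b} consumed by stage 2.
#'
#' @param seqs sequences (character vector or
#'   [Biostrings::DNAStringSet]).
#' @param template a [StructuredTemplate-class]; its quorum is converted
#'   to the integer threshold via [quorumThreshold()].
#' @param mode `"unconstrained"` or `"frequent"` (see
#'   [findSimpleMotifs()]).
#' @return A list of [SimpleMotifSet-class], one per box (boxes sharing a
#'   template share the same object).
#' @export
buildCandidateSets <- function(seqs, template,
                               mode = c("unconstrained", "frequent")) {
    stopifnot(is(template, "StructuredTemplate"))
    validObject(template)
    seqs <- .asMotifSequences(seqs)
    mode <- match.arg(mode)
    qmin <- quorumThreshold(template@quorum, length(seqs))
    key <- paste(template@boxLengths, template@boxErrors, sep = ",")
    cache <- list()
    sets <- vector("list", length(key))
    for (i in seq_along(key)) {
        if (is.null(cache[[key[i]]]))
            cache[[key[i]]] <- findSimpleMotifs(
                seqs, template@boxLengths[i], template@boxErrors[i],
                quorumCount = qmin, mode = mode)
        sets[[i]] <- cache[[key[i]]]
    }
    sets
}
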