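#' Structured motif template
#'
#' Describes the full search problem: an ordered set of b >= 2 boxes
#' \eqn{(\ell_i, e_i)} (box length in bases, admissible substitutions),
#' b - 1 gap constraints \eqn{[d_i, D_i]} (minimum and maximum number of
#' bases separating consecutive boxes), and the quorum q, the minimum
#' fraction of input sequences that must contain an instance.
#'
#' @slot boxLengths integer vector of box lengths \eqn{\ell_i}.
#' @slot boxErrors integer vector of per-box substitution budgets
#'   \eqn{e_i}, with \eqn{0 \le e_i < \ell_i}.
#' @slot gapMin,gapMax integer vectors of length b - 1; the gap between
#'   consecutive boxes (bases strictly between them) must lie in
#'   \eqn{[d_i, D_i]}. Boxes may not overlap (\eqn{d_i \ge 0}).
#' @slot quorum numeric in (0, 1].
#'
#' @seealso [structuredTemplate()], [parseTemplate()]
#' @export
setClass("StructuredTemplate",
    representation(
        boxLengths = "integer",
        boxErrors  = "integer",
        gapMin     = "integer",
        gapMax     = "integer",
        quorum     = "numeric"
    )
)

setValidity("StructuredTemplate", function(object) {
    b <- length(object@boxLengths)
    msg <- character()
    if (b < 2L)
        msg <- c(msg, "a structured template needs at least 2 boxes")
    if (length(object@boxErrors) != b)
        msg <- c(msg, "boxErrors must have one entry per box")
    if (length(object@gapMin) != b - 1L || length(object@gapMax) != b - 1L)
        msg <- c(msg, "gap constraints must have b - 1 entries")
    if (any(object@boxLengths < 1L))
        msg <- c(msg, "box lengths must be positive")
    if (any(object@boxErrors < 0L) ||
        any(object@boxErrors >= object@boxLengths))
        msg <- c(msg, "box errors must satisfy 0 <= e < length")
    if (length(object@gapMin) &&
        (any(object@gapMin < 0L) || any(object@gapMax < object@gapMin)))
        msg <- c(msg, "gap constraints must satisfy 0 <= d <= D")
    if (length(object@quorum) != 1L || is.na(object@quorum) ||
        object@quorum <= 0 || object@quorum > 1)
        msg <- c(msg, "quorum must be a single value in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Simple motifs for one box template, with occurrence lists
#'
#' The result of stage-1 enumeration for one box template \eqn{(\ell, e)}:
#' every consensus word meeting the quorum, each with its complete list of
#' occurrences (all sequence windows within Hamming distance e), sorted by
#' increasing sequence index and position. This is the candidate set
#' \eqn{K_i} from which box i of a structured motif is drawn.
#'
#' @slot boxLength,boxErrors the box template \eqn{(\ell, e)}.
#' @slot quorumCount minimum number of distinct sequences a motif must
#'   occur in (the integer quorum threshold used during enumeration).
#' @slot nSequences number of sequences enumerated against.
#' @slot mode `"unconstrained"` (consensus ranges over all of
#'   \eqn{\Sigma^\ell}) or `"frequent"` (consensus must occur exactly,
#'   i.e. with zero mismatches, in at least one sequence).
#' @slot consensus character vector of consensus words.
#' @slot occurrences list, parallel to `consensus`, of two-column integer
#'   matrices (`seq`, `start`; both 1-based) sorted by (seq, start).
#' @slot support integer vector: distinct sequences hit per motif.
#'
#' @seealso [findSimpleMotifs()], [buildCandidateSets()]
#' @export
setClass("SimpleMotifSet",
    representation(
        boxLength   = "integer",
        boxErrors   = "integer",
        quorumCount = "integer",
        nSequences  = "integer",
        mode        = "character",
        consensus   = "character",
        occurrences = "list",
        support     = "integer"
    )
)

setValidity("SimpleMotifSet", function(object) {
    n <- length(object@consensus)
    msg <- character()
    if (length(object@occurrences) != n || length(object@support) != n)
        msg <- c(msg, "consensus, occurrences and support must be parallel")
    if (!object@mode %in% c("unconstrained", "frequent"))
        msg <- c(msg, "mode must be 'unconstrained' or 'frequent'")
    if (n && any(nchar(object@consensus) != object@boxLength))
        msg <- c(msg, "all consensus words must have length boxLength")
    if (length(msg)) msg else TRUE
})

#' Discovered structured motifs
#'
#' The stage-2 result: every structured motif conforming to the template
#' whose support reaches the quorum threshold. Rows of `words` are motifs
#' (one column per box); `support` counts distinct sequences containing at
#' least one full occurrence; `occurrences` (kept only when requested)
#' holds per-motif integer matrices with columns `seq`, `start1`, ...,
#' `startb` (1-based), one row per occurrence tuple.
#'
#' @slot template the [StructuredTemplate-class] searched.
#' @slot nSequences number of input sequences.
#' @slot words character matrix, one row per motif, b columns.
#' @slot support integer vector of distinct-sequence counts.
#' @slot occurrences list of integer matrices (empty if not retained).
#'
#' @seealso [assembleMotifs()], [discoverMotifs()]
#' @export
setClass("StructuredMotifSet",
    representation(
        template    = "StructuredTemplate",
        nSequences  = "integer",
        words       = "matrix",
        support     = "integer",
        occurrences = "list"
    )
)

setValidity("StructuredMotifSet", function(object) {
    n <- nrow(object@words)
    msg <- character()
    if (ncol(object@words) != length(object@template@boxLengths))
        msg <- c(msg, "words must have one column per template box")
    if (length(object@support) != n)
        msg <- c(msg, "support must have one entry per motif")
    if (length(object@occurrences) &&
        length(object@occurrences) != n)
        msg <- c(msg, "occurrences, when kept, must be parallel to words")
    if (length(msg)) msg else TRUE
})

#' A planted-motif benchmark dataset with ground truth
#'
#' @slot sequences [Biostrings::DNAStringSet] of background sequences with
#'   one structured-motif occurrence planted per sequence.
#' @slot template the [StructuredTemplate-class] used for planting.
#' @slot consensusWords the b planted consensus words.
#' @slot plantedStarts integer matrix (N rows, b columns) of the 1-based
#'   planted start of each box in each sequence.
#' @slot exactSequence index of the sequence carrying an unmutated
#'   (exact) instance of every box, or `NA_integer_` if none was forced.
#'
#' @seealso [plantDataset()]
#' @export
setClass("PlantedMotifData",
    representation(
        sequences      = "DNAStringSet",
        template       = "StructuredTemplate",
        consensusWords = "character",
        plantedStarts  = "matrix",
        exactSequence  = "integer"
    )
)

setValidity("PlantedMotifData", function(object) {
    b <- length(object@template@boxLengths)
    msg <- character()
    if (length(object@consensusWords) != b)
        msg <- c(msg, "need one consensus word per box")
    if (ncol(object@plantedStarts) != b)
        msg <- c(msg, "plantedStarts must have one column per box")
    if (nrow(object@plantedStarts) != length(object@sequences))
        msg <- c(msg, "plantedStarts must have one row per sequence")
    if (length(msg)) msg else TRUE
})
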