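## Stage 2: assemble simple motifs into structured motifs by successive
## occurrence-list intersection with distance and quorum checks.
##
## A partial assembly ("prefix motif") is a plain list:
##   placed : sorted integer vector of placed box indices (contiguous
##            1..i under basic order; an arbitrary subset under box-order
##            selection, where unplaced boxes between placed ones are
##            "holes" constrained by compound gap bounds)
##   words  : character(b), NA at unplaced boxes
##   occ    : integer matrix, column 1 = seq, then one "start<j>" column
##            per placed box (ascending j), one row per occurrence tuple,
##            sorted by (seq, start of lowest placed box)

#' Occurrence starts compatible with a gap constraint
#'
#' Given the sorted start positions of a candidate box's occurrences in
#' one sequence, returns those whose distance from the previous box
#' satisfies the gap constraint: the lower bound is located by binary
#' search, then starts are taken until the first that violates the upper
#' bound. The gap is the number of bases strictly between the two boxes,
#' so a start s qualifies iff `gapMin <= s - prevEnd - 1 <= gapMax`.
#'
#' @param starts sorted integer vector of candidate starts (1-based).
#' @param prevEnd 1-based position of the last base of the previous box.
#' @param gapMin,gapMax the gap constraint, `0 <= gapMin <= gapMax`.
#' @return The compatible contiguous sub-vector of `starts`.
#' @examples
#' compatibleRange(c(5, 6, 9, 11), prevEnd = 3, gapMin = 2, gapMax = 4)
#' @export
compatibleRange <- function(starts, prevEnd, gapMin, gapMax) {
    stopifnot(gapMin >= 0L, gapMax >= gapMin)
    if (length(starts) == 0L) return(integer())
    lo <- prevEnd + 1L + gapMin
    hi <- prevEnd + 1L + gapMax
    i <- findInterval(lo - 1L, starts) + 1L  # first start >= lo
    j <- findInterval(hi, starts)            # last start <= hi
    if (i > j) integer() else starts[i:j]
}

## Compound gap bounds between placed boxes i < k of `template` when all
## boxes strictly between them are unplaced holes: the admissible
## distance from the end of box i to the start of box k is the sum of
## the intervening gap bounds plus the lengths of the intervening boxes.
.gapBounds <- function(template, i, k) {
    gaps <- i:(k - 1L)
    mids <- if (k - 1L >= i + 1L) (i + 1L):(k - 1L) else integer()
    c(lo = sum(template@gapMin[gaps]) + sum(template@boxLengths[mids]),
      hi = sum(template@gapMax[gaps]) + sum(template@boxLengths[mids]))
}

## Join a prefix's occurrence tuples with a candidate box's sorted
## occurrence matrix. Checks the constraint against the nearest placed
## box on each side, using the compound bounds when holes intervene;
## the per-sequence binary searches run in compiled code.
.joinOcc <- function(occ, placed, candOcc, j, template) {
    if (nrow(occ) == 0L || nrow(candOcc) == 0L) return(NULL)
    left  <- placed[placed < j]
    right <- placed[placed > j]
    leftCol <- 0L; offL <- loL <- hiL <- 0L
    if (length(left)) {
        jl <- max(left)
        gl <- .gapBounds(template, jl, j)
        leftCol <- 1L + match(jl, placed)
        offL <- template@boxLengths[jl]
        loL <- gl[["lo"]]; hiL <- gl[["hi"]]
    }
    rightCol <- 0L; lenJ <- loR <- hiR <- 0L
    if (length(right)) {
        jr <- min(right)
        gr <- .gapBounds(template, j, jr)
        rightCol <- 1L + match(jr, placed)
        lenJ <- template@boxLengths[j]
        loR <- gr[["lo"]]; hiR <- gr[["hi"]]
    }
    out <- .joinOccCpp(occ, candOcc, leftCol, offL, loL, hiL,
                       rightCol, lenJ, loR, hiR,
                       insertAt = sum(placed < j) + 1L)
    if (nrow(out) == 0L) return(NULL)
    colnames(out) <- c("seq", paste0("start", sort(c(placed, j))))
    out
}

#' Extend a prefix motif with a candidate simple motif
#'
#' One assembly step: joins every occurrence tuple of the prefix with
#' every occurrence of the candidate in the same sequence that satisfies
#' the gap constraints towards the nearest placed box on each side (both
#' sides when the candidate fills a hole between placed boxes; compound
#' bounds span unplaced boxes). The extended prefix is rejected — `NULL`
#' is returned — when its occurrences cover fewer than `quorumCount`
#' distinct sequences, since extension can only reduce support.
#'
#' @param prefix a prefix motif as produced by [newPrefixMotif()] or a
#'   previous `extendPrefix()` call.
#' @param candidate a [SimpleMotifSet-class] (the candidate set for box
#'   `boxIndex`).
#' @param motifIndex index of the candidate motif within `candidate`.
#' @param boxIndex the template box the candidate is placed at (must not
#'   already be placed).
#' @param template the [StructuredTemplate-class].
#' @param quorumCount integer quorum threshold.
#' @return The extended prefix motif, or `NULL` on rejection.
#' @export
extendPrefix <- function(prefix, candidate, motifIndex, boxIndex,
                         template, quorumCount) {
    if (boxIndex %in% prefix$placed)
        stop("box ", boxIndex, " is already placed in this prefix")
    occ <- .joinOcc(prefix$occ, prefix$placed,
                    candidate@occurrences[[motifIndex]], boxIndex,
                    template)
    if (is.null(occ) || length(unique(occ[, 1L])) < quorumCount)
        return(NULL)
    words <- prefix$words
    words[boxIndex] <- candidate@consensus[motifIndex]
    list(placed = sort(c(prefix$placed, boxIndex)),
         words = words, occ = occ)
}

#' Start a prefix motif from a single placed box
#'
#' @param candidate a [SimpleMotifSet-class].
#' @param motifIndex index of the motif within `candidate`.
#' @param boxIndex the template box it occupies.
#' @param nBoxes total number of boxes b in the template.
#' @return A prefix motif (see [extendPrefix()]).
#' @export
newPrefixMotif <- function(candidate, motifIndex, boxIndex, nBoxes) {
    occM <- candidate@occurrences[[motifIndex]]
    occ <- cbind(seq = occM[, 1L],
                 matrix(occM[, 2L], ncol = 1L,
                        dimnames = list(NULL, paste0("start", boxIndex))))
    words <- rep(NA_character_, nBoxes)
    words[boxIndex] <- candidate@consensus[motifIndex]
    list(placed = boxIndex, words = words, occ = occ)
}

#' Assembly order under box-index selection
#'
#' Orders boxes by ascending total occurrence count
#' \eqn{B_i = \sum_{t: m_t \in K_i} |occ_{i,t}|}, ties broken by
#' ascending box index. Assembling sparse boxes first limits the number
#' of useless intermediate prefixes.
#'
#' @param candidateSets list of per-box [SimpleMotifSet-class]
#'   (from [buildCandidateSets()]).
#' @return An integer permutation of `1..b`.
#' @examples
#' # B = (50, 10, 30) => order 2, 3, 1
#' @export
selectBoxOrder <- function(candidateSets) {
    B <- vapply(candidateSets, function(s)
        as.numeric(totalOccurrences(s)), numeric(1))
    order(B, seq_along(B))
}

#' Partition a candidate set into space-saving slices
#'
#' Splits a candidate set of m motifs into `ceiling(m / v)` subsets of at
#' most `v` motifs each, preserving motif order. Stage 2 is then run once
#' per cell of the Cartesian product of the per-box slices, bounding the
#' number of intermediate prefixes held in memory at once.
#'
#' @param candidateSet a [SimpleMotifSet-class].
#' @param v maximum motifs per slice (`v >= 1`).
#' @return A list of [SimpleMotifSet-class] slices (empty list for an
#'   empty candidate set).
#' @export
partitionSlices <- function(candidateSet, v) {
    stopifnot(is(candidateSet, "SimpleMotifSet"))
    v <- as.integer(v)
    if (is.na(v) || v < 1L)
        stop("the space-saving parameter v must be >= 1")
    m <- length(candidateSet)
    if (m == 0L) return(list())
    idx <- unname(split(seq_len(m), ceiling(seq_len(m) / v)))
    lapply(idx, function(i) candidateSet[i])
}

## One complete assembly pass over per-box candidate subsets given as
## index vectors into `prep` (per box: consensus words, occurrence
## matrices, and occurrences pre-split by sequence). Returns
## list(words = character matrix, support = integer,
## occurrences = list or NULL).
.assembleCore <- function(prep, pref1, idxList, template, orderIdx,
                          qmin, keepOcc) {
    b <- length(prep)
    empty <- list(words = matrix(character(), 0L, b),
                  support = integer(), occurrences = NULL)
    j1 <- orderIdx[1L]
    ## single-box prefixes are built once per assembly call (pref1) and
    ## shared across space-saving runs; NULL entries failed the
    ## lone-box quorum check
    prefixes <- pref1[idxList[[j1]]]
    prefixes <- prefixes[!vapply(prefixes, is.null, logical(1))]
    for (j in orderIdx[-1L]) {
        if (length(idxList[[j]]) == 0L || length(prefixes) == 0L)
            return(empty)
        nxt <- vector("list", length(prefixes) * length(idxList[[j]]))
        k <- 0L
        for (p in prefixes) {
            for (m in idxList[[j]]) {
                occ <- .joinOcc(p$occ, p$placed, prep[[j]]$occ[[m]],
                                j, template)
                if (is.null(occ) ||
                    length(unique(occ[, 1L])) < qmin)
                    next
                words <- p$words
                words[j] <- prep[[j]]$words[m]
                k <- k + 1L
                nxt[[k]] <- list(placed = sort(c(p$placed, j)),
                                 words = words, occ = occ)
            }
        }
        prefixes <- nxt[seq_len(k)]
    }
    if (length(prefixes) == 0L) return(empty)
    words <- do.call(rbind, lapply(prefixes, `[[`, "words"))
    list(words = words,
         support = vapply(prefixes, function(p)
             length(unique(p$occ[, 1L])), integer(1)),
         occurrences = if (keepOcc) lapply(prefixes, `[[`, "occ"))
}

#' Assemble structured motifs from per-box candidate sets
#'
#' Stage 2: builds structured motifs by extending prefixes one box at a
#' time, intersecting occurrence lists under the template's gap
#' constraints and discarding any prefix whose support falls below the
#' quorum threshold. The result — every b-box motif whose occurrences
#' reach quorum — is identical for every option combination; the options
#' trade time for memory only.
#'
#' @param template the [StructuredTemplate-class] searched.
#' @param candidateSets per-box candidate sets from
#'   [buildCandidateSets()].
#' @param boxOrderSelection place boxes in ascending order of total
#'   occurrence count (see [selectBoxOrder()]) instead of left to right.
#' @param spaceSaving `NULL` (off) or an integer `v >= 1`: partition each
#'   candidate set into slices of at most v motifs and run assembly once
#'   per Cartesian-product cell (see [partitionSlices()]).
#' @param printOccurrences retain the full occurrence tuples of each
#'   reported motif.
#' @return A [StructuredMotifSet-class], motifs sorted lexicographically
#'   by their concatenated box words.
#' @examples
#' tpl <- parseTemplate("(3,0)-[2,2]-(3,0)", quorum = 1)
#' ks <- buildCandidateSets(c("AAACCTTT", "AAAGGTTT"), tpl)
#' assembleMotifs(tpl, ks)
#' @export
assembleMotifs <- function(template, candidateSets,
                           boxOrderSelection = FALSE, spaceSaving = NULL,
                           printOccurrences = FALSE) {
    stopifnot(is(template, "StructuredTemplate"))
    validObject(template)
    b <- length(template@boxLengths)
    if (length(candidateSets) != b)
        stop("need one candidate set per template box")
    for (i in seq_len(b)) {
        s <- candidateSets[[i]]
        if (!is(s, "SimpleMotifSet") ||
            s@boxLength != template@boxLengths[i] ||
            s@boxErrors != template@boxErrors[i])
            stop("candidate set ", i, " does not match template box ", i)
    }
    nSeq <- unique(vapply(candidateSets, slot, integer(1), "nSequences"))
    if (length(nSeq) != 1L)
        stop("candidate sets come from different sequence sets")
    qmin <- quorumThreshold(template@quorum, nSeq)
    orderIdx <- if (boxOrderSelection) selectBoxOrder(candidateSets)
                else seq_len(b)

    ## candidate words and occurrence lists, shared across all
    ## space-saving runs
    prep <- lapply(candidateSets, function(s) list(
        words = s@consensus, occ = s@occurrences))
    j1 <- orderIdx[1L]
    pref1 <- lapply(seq_along(prep[[j1]]$occ), function(m) {
        occM <- prep[[j1]]$occ[[m]]
        ## a lone box must itself meet the quorum (guaranteed for
        ## stage-1 output, re-checked for arbitrary subsets)
        if (length(unique(occM[, 1L])) < qmin) return(NULL)
        words <- rep(NA_character_, b)
        words[j1] <- prep[[j1]]$words[m]
        list(placed = j1, words = words,
             occ = cbind(seq = occM[, 1L],
                 matrix(occM[, 2L], ncol = 1L,
                        dimnames = list(NULL, paste0("start", j1)))))
    })

    runs <- if (is.null(spaceSaving)) {
        list(lapply(candidateSets, function(s) seq_len(length(s))))
    } else {
        v <- as.integer(spaceSaving)
        if (is.na(v) || v < 1L)
            stop("the space-saving parameter v must be >= 1")
        slices <- lapply(candidateSets, function(s) {
            m <- length(s)
            if (m == 0L) list()
            else unname(split(seq_len(m), ceiling(seq_len(m) / v)))
        })
        if (any(lengths(slices) == 0L)) {
            list()
        } else {
            grid <- do.call(expand.grid,
                            c(lapply(lengths(slices), seq_len),
                              KEEP.OUT.ATTRS = FALSE))
            lapply(seq_len(nrow(grid)), function(r)
                lapply(seq_len(b), function(i)
                    slices[[i]][[grid[r, i]]]))
        }
    }

    words <- matrix(character(), 0L, b)
    support <- integer()
    occs <- list()
    for (run in runs) {
        res <- .assembleCore(prep, pref1, run, template, orderIdx,
                             qmin, keepOcc = printOccurrences)
        words <- rbind(words, res$words)
        support <- c(support, res$support)
        if (printOccurrences) occs <- c(occs, res$occurrences)
    }
    key <- if (nrow(words)) apply(words, 1L, paste, collapse = "")
           else character()
    keep <- !duplicated(key)
    ord <- order(key[keep])
    words <- words[keep, , drop = FALSE][ord, , drop = FALSE]
    support <- support[keep][ord]
    occs <- if (printOccurrences) occs[keep][ord] else list()
    colnames(words) <- paste0("box", seq_len(b))
    new("StructuredMotifSet", template = template, nSequences = nSeq,
        words = words, support = support, occurrences = occs)
}
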