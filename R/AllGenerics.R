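#' @name accessors
#' @title Accessors for StructuredMotifs classes
#'
#' @description
#' `consensusWords()` returns the consensus word(s); `motifSupport()` the
#' distinct-sequence support; `occurrenceList()` the occurrence matrices;
#' `totalOccurrences()` the total occurrence count of a candidate set
#' (the quantity \eqn{B_i} that drives box-order selection);
#' `motifTemplate()` the [StructuredTemplate-class] behind a result.
#'
#' @param x a [SimpleMotifSet-class] or [StructuredMotifSet-class].
#' @return See each accessor's description.
NULL

#' @rdname accessors
#' @export
setGeneric("consensusWords", function(x) standardGeneric("consensusWords"))

#' @rdname accessors
#' @export
setGeneric("motifSupport", function(x) standardGeneric("motifSupport"))

#' @rdname accessors
#' @export
setGeneric("occurrenceList", function(x) standardGeneric("occurrenceList"))

#' @rdname accessors
#' @export
setGeneric("totalOccurrences",
    function(x) standardGeneric("totalOccurrences"))

#' @rdname accessors
#' @export
setGeneric("motifTemplate", function(x) standardGeneric("motifTemplate"))

#' @rdname accessors
#' @export
setMethod("consensusWords", "SimpleMotifSet", function(x) x@consensus)

#' @rdname accessors
#' @export
setMethod("consensusWords", "StructuredMotifSet", function(x) x@words)

#' @rdname accessors
#' @export
setMethod("consensusWords", "PlantedMotifData",
    function(x) x@consensusWords)

#' @rdname accessors
#' @export
setMethod("motifSupport", "SimpleMotifSet", function(x) x@support)

#' @rdname accessors
#' @export
setMethod("motifSupport", "StructuredMotifSet", function(x) x@support)

#' @rdname accessors
#' @export
setMethod("occurrenceList", "SimpleMotifSet", function(x) x@occurrences)

#' @rdname accessors
#' @export
setMethod("occurrenceList", "StructuredMotifSet",
    function(x) x@occurrences)

#' @rdname accessors
#' @export
setMethod("totalOccurrences", "SimpleMotifSet",
    function(x) sum(vapply(x@occurrences, nrow, integer(1))))

#' @rdname accessors
#' @export
setMethod("motifTemplate", "StructuredMotifSet", function(x) x@template)

#' @rdname accessors
#' @export
setMethod("motifTemplate", "PlantedMotifData", function(x) x@template)

#' @describeIn SimpleMotifSet-class number of motifs in the set.
#' @param x a `SimpleMotifSet`.
#' @export
setMethod("length", "SimpleMotifSet", function(x) length(x@consensus))

#' @describeIn StructuredMotifSet-class number of structured motifs.
#' @param x a `StructuredMotifSet`.
#' @export
setMethod("length", "StructuredMotifSet", function(x) nrow(x@words))

#' @describeIn SimpleMotifSet-class subset a candidate set (used by the
#'   space-saving option to form slices).
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "SimpleMotifSet", function(x, i, j, ..., drop = FALSE) {
    initialize(x,
        consensus = x@consensus[i],
        occurrences = x@occurrences[i],
        support = x@support[i])
})

setMethod("show", "StructuredTemplate", function(object) {
    cat("StructuredTemplate:", templateToString(object),
        sprintf("(quorum %.2f)\n", object@quorum))
})

setMethod("show", "SimpleMotifSet", function(object) {
    cat(sprintf(
        "SimpleMotifSet: %d motif(s) for box (%d,%d), mode %s\n",
        length(object), object@boxLength, object@boxErrors, object@mode))
    cat(sprintf("  quorum threshold %d of %d sequences; %d occurrence(s)\n",
        object@quorumCount, object@nSequences, totalOccurrences(object)))
    if (length(object))
        cat("  first motifs:",
            paste(head(object@consensus, 5L), collapse = " "), "\n")
})

setMethod("show", "StructuredMotifSet", function(object) {
    cat(sprintf("StructuredMotifSet: %d motif(s) for template %s\n",
        length(object), templateToString(object@template)))
    if (length(object)) {
        w <- apply(head(object@words, 3L), 1L, paste, collapse = "-")
        cat("  e.g.", paste(w, collapse = ", "), "\n")
    }
    cat(sprintf("  occurrences retained: %s\n",
        if (length(object@occurrences)) "yes" else "no"))
})

setMethod("show", "PlantedMotifData", function(object) {
    cat(sprintf(
        "PlantedMotifData: %d sequence(s) of %d base(s), template %s\n",
        length(object@sequences), width(object@sequences)[1L],
        templateToString(object@template)))
    cat("  planted words:",
        paste(object@consensusWords, collapse = "-"), "\n")
})

#' Tabulate discovered structured motifs
#'
#' @param x a [StructuredMotifSet-class].
#' @param row.names,optional,... passed on conventionally; unused.
#' @return A data.frame with one row per motif: one `box<i>` column per
#'   box, a dash-joined `motif` column and `support`.
#' @method as.data.frame StructuredMotifSet
#' @export
as.data.frame.StructuredMotifSet <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
    b <- ncol(x@words)
    out <- as.data.frame(x@words, stringsAsFactors = FALSE)
    names(out) <- paste0("box", seq_len(b))
    out$motif <- if (nrow(x@words))
        apply(x@words, 1L, paste, collapse = "-") else character()
    out$support <- x@support
    rownames(out) <- NULL
    out
}
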