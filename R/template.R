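#' Construct a structured motif template
#'
#' @param boxLengths,boxErrors integer vectors (length b >= 2) of box
#'   lengths and substitution budgets, \eqn{0 \le e_i < \ell_i}.
#' @param gapMin,gapMax integer vectors (length b - 1) bounding the number
#'   of bases separating consecutive boxes, \eqn{0 \le d_i \le D_i}.
#' @param quorum minimum fraction of sequences that must contain an
#'   instance, in (0, 1].
#' @return A [StructuredTemplate-class].
#' @examples
#' structuredTemplate(c(3, 5), c(1, 2), gapMin = 1, gapMax = 4, quorum = 0.7)
#' @export
structuredTemplate <- function(boxLengths, boxErrors, gapMin, gapMax,
                               quorum = 1.0) {
    new("StructuredTemplate",
        boxLengths = as.integer(boxLengths),
        boxErrors  = as.integer(boxErrors),
        gapMin     = as.integer(gapMin),
        gapMax     = as.integer(gapMax),
        quorum     = as.numeric(quorum))
}

#' Parse a template string
#'
#' Parses the compact template notation
#' `"(l1,e1)-[d1,D1]-(l2,e2)-...-(lb,eb)"`: parenthesised boxes
#' (length, errors) alternating with bracketed gap constraints
#' (min, max), joined by dashes. Whitespace around tokens is tolerated.
#' The quorum is not part of the notation and is supplied separately.
#'
#' @param text the template string.
#' @param quorum quorum fraction in (0, 1] attached to the parsed
#'   template (default 1).
#' @return A [StructuredTemplate-class].
#' @examples
#' parseTemplate("(7,1)-[1,50]-(10,2)", quorum = 0.8)
#' @export
parseTemplate <- function(text, quorum = 1.0) {
    if (!is.character(text) || length(text) != 1L || is.na(text))
        stop("template must be a single character string")
    pos <- 1L
    n <- nchar(text)
    skipWs <- function() {
        while (pos <= n && substr(text, pos, pos) %in% c(" ", "\t"))
            pos <<- pos + 1L
    }
    expect <- function(pattern, what) {
        skipWs()
        rest <- substr(text, pos, n)
        m <- regmatches(rest, regexec(paste0("^", pattern), rest))[[1L]]
        if (length(m) == 0L)
            stop("malformed template at character ", pos, ": expected ",
                 what, call. = FALSE)
        pos <<- pos + nchar(m[1L])
        as.integer(m[-1L])
    }
    intPat <- "\\s*([0-9]+)\\s*"
    boxPat <- paste0("\\(", intPat, ",", intPat, "\\)")
    gapPat <- paste0("\\[", intPat, ",", intPat, "\\]")

    boxes <- list(expect(boxPat, "a box '(length,errors)'"))
    gaps <- list()
    repeat {
        skipWs()
        if (pos > n) break
        expect("-", "'-'")
        gaps[[length(gaps) + 1L]] <- expect(gapPat, "a gap '[min,max]'")
        expect("-", "'-'")
        boxes[[length(boxes) + 1L]] <- expect(boxPat,
                                              "a box '(length,errors)'")
    }
    if (length(boxes) < 2L)
        stop("a structured template needs at least 2 boxes, got ",
             length(boxes), call. = FALSE)
    lens <- vapply(boxes, `[`, integer(1), 1L)
    errs <- vapply(boxes, `[`, integer(1), 2L)
    bad <- which(errs >= lens)
    if (length(bad))
        stop("box ", bad[1L], " (", lens[bad[1L]], ",", errs[bad[1L]],
             "): errors must satisfy 0 <= e < length", call. = FALSE)
    dmin <- vapply(gaps, `[`, integer(1), 1L)
    dmax <- vapply(gaps, `[`, integer(1), 2L)
    bad <- which(dmax < dmin)
    if (length(bad))
        stop("gap ", bad[1L], " [", dmin[bad[1L]], ",", dmax[bad[1L]],
             "]: must satisfy 0 <= min <= max", call. = FALSE)
    structuredTemplate(lens, errs, dmin, dmax, quorum)
}

#' Render a template as its compact string notation
#'
#' Inverse of [parseTemplate()] (up to whitespace); the quorum is not
#' rendered.
#'
#' @param template a [StructuredTemplate-class].
#' @return A single string such as `"(3,1)-[1,1]-(5,2)"`.
#' @export
templateToString <- function(template) {
    stopifnot(is(template, "StructuredTemplate"))
    b <- length(template@boxLengths)
    box <- sprintf("(%d,%d)", template@boxLengths, template@boxErrors)
    if (b == 1L) return(box)
    gap <- sprintf("[%d,%d]", template@gapMin, template@gapMax)
    paste0(box[1L],
           paste0("-", gap, "-", box[-1L], collapse = ""))
}
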