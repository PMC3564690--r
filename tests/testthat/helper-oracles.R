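## Independent brute-force oracles and random-instance generators used
## across the suite. The oracles enumerate candidate word (tuples)
## exhaustively and test each with the naive window scan — no spelling,
## no prefix assembly — so they share no code path with the engines they
## check.

allWords <- function(len) {
    g <- do.call(expand.grid,
                 c(rep(list(c("A", "C", "G", "T")), len),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
    sort(apply(g, 1L, paste, collapse = ""))
}

## window scan over pre-split character vectors (no package machinery)
oracleScan <- function(charList, word, errors) {
    w <- strsplit(word, "")[[1L]]
    len <- length(w)
    out <- lapply(seq_along(charList), function(s) {
        chars <- charList[[s]]
        nwin <- length(chars) - len + 1L
        if (nwin < 1L) return(NULL)
        mism <- integer(nwin)
        for (j in seq_len(len))
            mism <- mism + (chars[j:(j + nwin - 1L)] != w[j])
        hits <- which(mism <= errors)
        if (length(hits))
            cbind(seq = rep.int(s, length(hits)), start = hits)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- matrix(integer(), 0L, 2L,
                      dimnames = list(NULL, c("seq", "start")))
    out
}

## all 4^len words with their scan occurrences; support >= qmin filter,
## plus the exact-occurrence filter in frequent mode
bruteForceSimpleMotifs <- function(seqs, len, errors, qmin,
                                   mode = "unconstrained") {
    seqs <- as.character(seqs)
    charList <- strsplit(seqs, "")
    words <- allWords(len)
    occs <- lapply(words, function(w) oracleScan(charList, w, errors))
    support <- vapply(occs, function(m)
        length(unique(m[, 1L])), integer(1))
    keep <- support >= qmin
    if (mode == "frequent") {
        exact <- vapply(words, function(w)
            any(grepl(w, seqs, fixed = TRUE)), logical(1))
        keep <- keep & exact
    }
    list(consensus = words[keep], occurrences = occs[keep],
         support = support[keep])
}

## does any occurrence chain satisfying all gap constraints exist in one
## sequence? occStarts: list of per-box start vectors for that sequence
chainExists <- function(occStarts, template) {
    feasible <- occStarts[[1L]]
    b <- length(occStarts)
    for (j in seq_len(b)[-1L]) {
        if (!length(feasible)) return(FALSE)
        ends <- feasible + template@boxLengths[j - 1L] - 1L
        s <- occStarts[[j]]
        ok <- vapply(s, function(x) any(
            x - ends - 1L >= template@gapMin[j - 1L] &
            x - ends - 1L <= template@gapMax[j - 1L]), logical(1))
        feasible <- s[ok]
    }
    length(feasible) > 0L
}

## exhaustive enumerator over all candidate word tuples; returns a
## data.frame(motif, support) sorted by motif
bruteForceAssemble <- function(seqs, template, mode = "unconstrained") {
    seqs <- as.character(seqs)
    N <- length(seqs)
    qmin <- quorumThreshold(template@quorum, N)
    b <- length(template@boxLengths)
    key <- paste(template@boxLengths, template@boxErrors)
    cache <- list()
    boxWords <- boxOccs <- vector("list", b)
    for (i in seq_len(b)) {
        if (is.null(cache[[key[i]]]))
            cache[[key[i]]] <- bruteForceSimpleMotifs(
                seqs, template@boxLengths[i], template@boxErrors[i],
                qmin, mode)
        boxWords[[i]] <- cache[[key[i]]]$consensus
        ## per word, per sequence start vectors
        boxOccs[[i]] <- lapply(cache[[key[i]]]$occurrences, function(m)
            lapply(seq_len(N), function(s) m[m[, 1L] == s, 2L]))
    }
    if (any(lengths(boxWords) == 0L))
        return(data.frame(motif = character(), support = integer()))
    grid <- do.call(expand.grid,
                    c(lapply(lengths(boxWords), seq_len),
                      KEEP.OUT.ATTRS = FALSE))
    motif <- character(); support <- integer()
    for (r in seq_len(nrow(grid))) {
        idx <- as.integer(grid[r, ])
        sup <- 0L
        for (s in seq_len(N)) {
            st <- lapply(seq_len(b), function(i) boxOccs[[i]][[idx[i]]][[s]])
            if (chainExists(st, template)) sup <- sup + 1L
        }
        if (sup >= qmin) {
            motif <- c(motif, paste(
                vapply(seq_len(b), function(i) boxWords[[i]][idx[i]],
                       character(1)), collapse = "-"))
            support <- c(support, sup)
        }
    }
    ord <- order(motif)
    data.frame(motif = motif[ord], support = support[ord],
               stringsAsFactors = FALSE)
}

## flatten a StructuredMotifSet to the oracle's data.frame shape
motifTable <- function(res) {
    df <- as.data.frame(res)[, c("motif", "support")]
    df[order(df$motif), , drop = FALSE]
}

## post-hoc validator: every occurrence tuple must satisfy every
## pairwise gap constraint and lie on a true motif occurrence
validateOccurrences <- function(res, seqs) {
    tpl <- motifTemplate(res)
    seqs <- as.character(seqs)
    b <- ncol(consensusWords(res))
    for (i in seq_len(length(res))) {
        occ <- occurrenceList(res)[[i]]
        for (r in seq_len(nrow(occ))) {
            st <- occ[r, -1L]
            for (j in seq_len(b - 1L)) {
                gap <- st[j + 1L] - (st[j] + tpl@boxLengths[j])
                if (gap < tpl@gapMin[j] || gap > tpl@gapMax[j])
                    return(FALSE)
            }
            for (j in seq_len(b)) {
                w <- substr(seqs[occ[r, 1L]], st[j],
                            st[j] + tpl@boxLengths[j] - 1L)
                if (hammingDistance(w, consensusWords(res)[i, j]) >
                    tpl@boxErrors[j])
                    return(FALSE)
            }
        }
    }
    TRUE
}

## small random instance for oracle-equivalence runs; about half carry a
## planted structured motif so that non-empty outputs are exercised
randomInstance <- function() {
    b <- sample(2:3, 1L, prob = c(0.75, 0.25))
    lens <- sample(2:3, b, replace = TRUE)
    ## mismatch-tolerant short boxes saturate the word space quickly;
    ## keep most boxes exact so the exhaustive oracle stays tractable
    errs <- ifelse(lens == 2L,
                   sample(0:1, b, replace = TRUE, prob = c(0.85, 0.15)),
                   sample(0:1, b, replace = TRUE, prob = c(0.65, 0.35)))
    ## with three boxes, keep at most one mismatch-tolerant box, else
    ## the exhaustive tuple space dwarfs what an oracle can re-check
    if (b == 3L && sum(errs) > 1L)
        errs[which(errs > 0L)[-1L]] <- 0L
    dmin <- sample(0:2, b - 1L, replace = TRUE)
    dmax <- dmin + sample(0:3, b - 1L, replace = TRUE)
    q <- sample(c(0.6, 0.8, 1.0), 1L, prob = c(0.15, 0.25, 0.6))
    n <- sample(3:5, 1L)
    L <- sample(20:40, 1L)
    tpl <- structuredTemplate(lens, errs, dmin, dmax, q)
    seqs <- if (runif(1) < 0.5 &&
                sum(lens) + sum(dmax) <= L) {
        as.character(plantDataset(n, L, tpl,
                                  plantExact = TRUE)@sequences)
    } else {
        as.character(generateSequences(n, L))
    }
    list(seqs = seqs, template = tpl)
}

## cached acceptance fixtures, computed once per test run
.suiteCache <- new.env(parent = emptyenv())

plantedBoxPairs <- matrix(c(9, 2, 10, 2, 11, 2, 11, 3, 12, 3, 13, 3),
                          ncol = 2L, byrow = TRUE)

## one planted recovery case: dataset, template, and the basic-run result
plantedCase <- function(seedOffset) {
    set.seed(202600 + seedOffset)
    b <- sample(2:5, 1L)
    pair <- plantedBoxPairs[sample(nrow(plantedBoxPairs), b,
                                   replace = TRUE), , drop = FALSE]
    dmin <- sample(0:10, b - 1L, replace = TRUE)
    dmax <- dmin + sample(0:10, b - 1L, replace = TRUE)
    tpl <- structuredTemplate(pair[, 1L], pair[, 2L], dmin, dmax, 1.0)
    pd <- plantDataset(20, 600, tpl)
    sets <- buildCandidateSets(pd@sequences, tpl)
    list(planted = pd, template = tpl, sets = sets,
         basic = assembleMotifs(tpl, sets))
}

plantedSuite <- function(nCases = 50L) {
    if (is.null(.suiteCache$planted))
        .suiteCache$planted <- lapply(seq_len(nCases), plantedCase)
    .suiteCache$planted
}
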