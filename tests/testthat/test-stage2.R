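## small hand-built candidate set: one motif with given occurrences
.oneMotifSet <- function(word, occ, len = nchar(word), err = 0L,
                         nSeq = max(occ[, 1L]), qmin = 1L) {
    new("SimpleMotifSet", boxLength = as.integer(len),
        boxErrors = as.integer(err), quorumCount = as.integer(qmin),
        nSequences = as.integer(nSeq), mode = "unconstrained",
        consensus = word,
        occurrences = list(occ),
        support = length(unique(occ[, 1L])))
}

test_that("compatibleRange keeps exactly the starts satisfying the gap", {
    ## binary search for the lower bound, scan to the upper: gap of a
    ## start s after a box ending at base 3 is s - 3 - 1
    expect_identical(compatibleRange(c(5L, 6L, 9L, 11L), 3L, 2L, 4L), 6L)
    expect_identical(compatibleRange(integer(), 3L, 0L, 5L), integer())
    expect_identical(compatibleRange(c(1L, 2L, 3L), 0L, 0L, 2L),
                     c(1L, 2L, 3L))
    ## exhaustive cross-check on random sorted lists
    set.seed(201)
    for (i in 1:50) {
        starts <- sort(sample(1:40, sample(0:10, 1L)))
        prevEnd <- sample(0:30, 1L)
        d <- sample(0:5, 1L); D <- d + sample(0:5, 1L)
        gap <- starts - prevEnd - 1L
        expect_identical(compatibleRange(starts, prevEnd, d, D),
                         starts[gap >= d & gap <= D])
    }
})

test_that("extendPrefix joins occurrences under the gap constraint", {
    tpl <- structuredTemplate(c(3, 3), c(0, 0), 2, 4, 1.0)
    ## box 1 AAA at (seq 1, start 1): box 1 ends at base 3, so box 2 may
    ## start at 6..8; candidate occurrences at 5, 6, 9 leave only 6
    p <- newPrefixMotif(.oneMotifSet("AAA",
        cbind(seq = 1L, start = 1L)), 1L, 1L, 2L)
    cand <- .oneMotifSet("TTT", cbind(seq = 1L, start = c(5L, 6L, 9L)))
    r <- extendPrefix(p, cand, 1L, 2L, tpl, quorumCount = 1L)
    expect_identical(unname(r$occ), cbind(1L, 1L, 6L))
    expect_identical(r$words, c("AAA", "TTT"))

    ## candidate only in sequences absent from the prefix: rejection
    cand2 <- .oneMotifSet("TTT", cbind(seq = 2L, start = 6L), nSeq = 2L)
    expect_null(extendPrefix(p, cand2, 1L, 2L, tpl, quorumCount = 1L))

    ## support below the threshold: rejection
    expect_null(extendPrefix(p, cand, 1L, 2L, tpl, quorumCount = 2L))
    expect_error(extendPrefix(p, cand, 1L, 1L, tpl, 1L),
                 "already placed")
})

test_that("selectBoxOrder sorts boxes by total occurrences, stably", {
    mk <- function(nOcc) .oneMotifSet("AA",
        cbind(seq = rep(1L, nOcc), start = seq_len(nOcc)))
    expect_identical(selectBoxOrder(list(mk(50), mk(10), mk(30))),
                     c(2L, 3L, 1L))
    expect_identical(selectBoxOrder(list(mk(5), mk(5))), c(1L, 2L))
    expect_identical(selectBoxOrder(list(mk(1), mk(2), mk(3))), 1:3)
})

test_that("partitionSlices covers the set in order with bounded size", {
    set.seed(202)
    s <- findSimpleMotifs(as.character(generateSequences(2, 30)),
                          2, 1, 1)
    expect_identical(length(s), 16L)
    sl <- partitionSlices(s, 7L)
    expect_identical(lengths(lapply(sl, consensusWords)), c(7L, 7L, 2L))
    expect_identical(unlist(lapply(sl, consensusWords)),
                     consensusWords(s))
    expect_identical(length(partitionSlices(s, 100L)), 1L)
    expect_error(partitionSlices(s, 0L), ">= 1")
})

test_that("assembleMotifs finds the toy planted dyad and nothing else", {
    tpl <- parseTemplate("(3,0)-[2,2]-(3,0)", quorum = 1.0)
    sets <- buildCandidateSets(c("AAACCTTT", "AAAGGTTT"), tpl)
    res <- assembleMotifs(tpl, sets, printOccurrences = TRUE)
    expect_identical(length(res), 1L)
    expect_identical(unname(consensusWords(res)[1L, ]), c("AAA", "TTT"))
    expect_identical(motifSupport(res), 2L)
    expect_identical(unname(occurrenceList(res)[[1L]]),
                     cbind(c(1L, 2L), c(1L, 1L), c(6L, 6L)))
})

test_that("assembly options change resources, never results", {
    set.seed(203)
    for (i in 1:12) {
        inst <- randomInstance()
        sets <- buildCandidateSets(inst$seqs, inst$template)
        base <- motifTable(assembleMotifs(inst$template, sets))
        for (sel in c(FALSE, TRUE)) for (v in list(1L, 3L, NULL)) {
            got <- assembleMotifs(inst$template, sets,
                                  boxOrderSelection = sel,
                                  spaceSaving = v)
            expect_identical(motifTable(got), base)
        }
    }
})

test_that("reported occurrence tuples satisfy all constraints post hoc", {
    set.seed(204)
    for (i in 1:8) {
        inst <- randomInstance()
        res <- discoverMotifs(inst$seqs, inst$template,
                              printOccurrences = TRUE)
        expect_true(validateOccurrences(res, inst$seqs))
        ## under box-order selection too (holes filled both ways)
        res2 <- discoverMotifs(inst$seqs, inst$template,
                               boxOrderSelection = TRUE,
                               printOccurrences = TRUE)
        expect_true(validateOccurrences(res2, inst$seqs))
        expect_identical(motifTable(res2), motifTable(res))
    }
})

test_that("results shrink with quorum and grow with gap slack", {
    set.seed(205)
    tpl <- function(q, D) structuredTemplate(c(3, 2), c(1, 0), 1, D, q)
    seqs <- as.character(plantDataset(5, 30, tpl(1.0, 4),
                                      plantExact = TRUE)@sequences)
    motifsAt <- function(q, D)
        motifTable(discoverMotifs(seqs, tpl(q, D)))$motif
    expect_true(all(motifsAt(1.0, 4) %in% motifsAt(0.6, 4)))
    expect_true(all(motifsAt(0.8, 4) %in% motifsAt(0.8, 6)))
})

test_that("prefix support never grows under extension", {
    set.seed(206)
    inst <- randomInstance()
    tplv <- inst$template
    sets <- buildCandidateSets(inst$seqs, tplv)
    qmin <- quorumThreshold(tplv@quorum, length(inst$seqs))
    b <- length(tplv@boxLengths)
    if (length(sets[[1L]]) && length(sets[[2L]])) {
        for (m1 in seq_len(min(4L, length(sets[[1L]])))) {
            p <- newPrefixMotif(sets[[1L]], m1, 1L, b)
            sup1 <- length(unique(p$occ[, 1L]))
            for (m2 in seq_len(min(4L, length(sets[[2L]])))) {
                r <- extendPrefix(p, sets[[2L]], m2, 2L, tplv, 1L)
                if (!is.null(r))
                    expect_lte(length(unique(r$occ[, 1L])), sup1)
            }
        }
    }
})

test_that("degenerate gap bounds beyond sequence length are tolerated", {
    tpl <- structuredTemplate(c(3, 3), c(0, 0), 2, 10000, 1.0)
    res <- discoverMotifs(c("AAACCTTT", "AAAGGTTT"), tpl)
    expect_identical(unname(consensusWords(res)[1L, ]), c("AAA", "TTT"))
})

test_that("mismatched template and candidate sets are rejected", {
    tpl <- parseTemplate("(3,0)-[2,2]-(3,0)")
    sets <- buildCandidateSets(c("AAACCTTT", "AAAGGTTT"), tpl)
    other <- parseTemplate("(4,0)-[2,2]-(3,0)")
    expect_error(assembleMotifs(other, sets), "does not match")
    expect_error(assembleMotifs(tpl, sets[1L]), "one candidate set per")
})
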