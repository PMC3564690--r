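test_that("scanOccurrences reports every window within distance e", {
    expect_equal(scanOccurrences("AAAA", "AAA", 0)[, "start"], c(1L, 2L))
    ## both windows of AAAA are at distance 1 from AAT
    expect_equal(scanOccurrences("AAAA", "AAT", 1)[, "start"], c(1L, 2L))
    expect_identical(nrow(scanOccurrences("CCCC", "AAA", 1)), 0L)
    ## sequences shorter than the word contribute nothing
    expect_identical(nrow(scanOccurrences(c("AC", "ACGT"), "ACGTA", 1)),
                     0L)
    expect_error(scanOccurrences("ACNT", "AAA", 1), "\\{A,C,G,T\\}")
})

test_that("findSimpleMotifs equals the brute-force scan oracle", {
    ## the distance-1 neighborhood of AAA, and only AAA in frequent mode
    s <- findSimpleMotifs("AAAA", 3, 1, 1)
    expect_identical(length(s), 10L)
    expect_identical(consensusWords(findSimpleMotifs("AAAA", 3, 1, 1,
                                                     "frequent")), "AAA")

    set.seed(101)
    for (i in 1:25) {
        n <- sample(2:5, 1L)
        L <- sample(8:30, 1L)
        len <- sample(2:4, 1L)
        err <- sample(0:(len - 1L), 1L)
        qmin <- sample(seq_len(n), 1L)
        seqs <- as.character(generateSequences(n, L))
        for (mode in c("unconstrained", "frequent")) {
            got <- findSimpleMotifs(seqs, len, err, qmin, mode)
            want <- bruteForceSimpleMotifs(seqs, len, err, qmin, mode)
            expect_identical(consensusWords(got), want$consensus)
            expect_identical(motifSupport(got), want$support)
            ## occurrence lists are complete, sorted, duplicate-free
            for (k in seq_along(want$consensus)) {
                o <- occurrenceList(got)[[k]]
                expect_equal(unname(o), unname(want$occurrences[[k]]))
                expect_false(is.unsorted(order(o[, 1L], o[, 2L])))
                expect_identical(anyDuplicated(as.data.frame(o)), 0L)
            }
        }
    }
})

test_that("frequent-mode output is a subset of unconstrained output", {
    set.seed(102)
    for (i in 1:10) {
        seqs <- as.character(generateSequences(3, 25))
        u <- consensusWords(findSimpleMotifs(seqs, 3, 1, 2))
        f <- consensusWords(findSimpleMotifs(seqs, 3, 1, 2, "frequent"))
        expect_true(all(f %in% u))
    }
})

test_that("output is monotone in the quorum threshold and in e", {
    set.seed(103)
    seqs <- as.character(generateSequences(5, 30))
    byQ <- lapply(1:5, function(q)
        consensusWords(findSimpleMotifs(seqs, 3, 1, q)))
    for (q in 2:5) expect_true(all(byQ[[q]] %in% byQ[[q - 1L]]))
    byE <- lapply(0:2, function(e)
        consensusWords(findSimpleMotifs(seqs, 3, e, 3)))
    for (e in 2:3) expect_true(all(byE[[e - 1L]] %in% byE[[e]]))
})

test_that("buildCandidateSets shares enumeration across equal boxes", {
    set.seed(104)
    seqs <- as.character(generateSequences(4, 30))
    tpl <- structuredTemplate(c(3, 3), c(1, 1), 1, 2, 0.75)
    sets <- buildCandidateSets(seqs, tpl)
    ## one enumeration run feeds both boxes: same object, same motifs
    expect_identical(sets[[1]], sets[[2]])
    expect_identical(sets[[1]]@quorumCount, 3L)

    ## B_i sums occurrence-list sizes over the candidate set
    expect_identical(totalOccurrences(sets[[1]]),
        sum(vapply(occurrenceList(sets[[1]]), nrow, integer(1))))
    m <- new("SimpleMotifSet", boxLength = 2L, boxErrors = 0L,
             quorumCount = 1L, nSequences = 1L, mode = "unconstrained",
             consensus = c("AA", "AC"),
             occurrences = list(cbind(seq = rep(1L, 3), start = 1:3),
                                cbind(seq = rep(1L, 4), start = 1:4)),
             support = c(1L, 1L))
    expect_identical(totalOccurrences(m), 7L)
})

test_that("an unreachable quorum yields empty candidate sets", {
    ## no trimer at distance 0 occurs in both of these sequences
    sets <- buildCandidateSets(c("AAAA", "CCCC"),
        structuredTemplate(c(3, 3), c(0, 0), 0, 1, 1.0))
    expect_identical(length(sets[[1]]), 0L)
    res <- assembleMotifs(structuredTemplate(c(3, 3), c(0, 0), 0, 1, 1.0),
                          sets)
    expect_identical(length(res), 0L)
})

test_that("every planted consensus word reaches its box's enumeration", {
    set.seed(105)
    tpl <- parseTemplate("(7,1)-[2,6]-(8,2)")
    pd <- plantDataset(10, 200, tpl)
    sets <- buildCandidateSets(pd@sequences, tpl)
    for (i in 1:2)
        expect_true(consensusWords(pd)[i] %in%
                    consensusWords(sets[[i]]))
})
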