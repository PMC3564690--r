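test_that("generateSequences draws i.i.d.-uniform reproducible DNA", {
    x <- generateSequences(20, 600, seed = 31)
    expect_identical(length(x), 20L)
    expect_true(all(Biostrings::width(x) == 600L))
    expect_identical(as.character(generateSequences(20, 600, seed = 31)),
                     as.character(x))
    ## per-base frequency within 0.25 +/- 0.01 over 1e5 bases
    y <- generateSequences(100, 1000, seed = 32)
    f <- colSums(Biostrings::alphabetFrequency(y)[, c("A", "C", "G", "T")])
    expect_true(all(abs(f / 1e5 - 0.25) < 0.01))
    ## chi-square goodness of fit against the uniform background
    expect_gt(chisq.test(f)$p.value, 0.001)
})

test_that("mutateWord substitutes e positions with uniform redraw", {
    expect_identical(mutateWord("ACGTA", 0), "ACGTA")
    set.seed(301)
    for (i in 1:50)
        expect_lte(hammingDistance(mutateWord("ACGTACGT", 3), "ACGTACGT"),
                   3L)
    ## redraw over all 4 letters: P(distance 0) = 1/4, P(distance 1) = 3/4
    set.seed(302)
    d <- replicate(1e4, hammingDistance(mutateWord("AAAA", 1), "AAAA"))
    expect_lt(abs(mean(d == 0L) - 0.25), 0.02)
    expect_lt(abs(mean(d == 1L) - 0.75), 0.02)
    ## forceDistance pins the realized distance
    set.seed(303)
    for (i in 1:20)
        expect_identical(
            hammingDistance(mutateWord("ACGTACGT", 2,
                                       forceDistance = TRUE), "ACGTACGT"),
            2L)
    expect_error(mutateWord("ACG", 3), "0 <= errors")
})

test_that("plantDataset plants one conforming occurrence per sequence", {
    tpl <- parseTemplate("(9,2)-[5,10]-(10,2)")
    pd <- plantDataset(20, 600, tpl, seed = 33)
    expect_identical(length(pd@sequences), 20L)
    seqs <- as.character(pd@sequences)
    lens <- tpl@boxLengths
    for (s in 1:20) {
        st <- pd@plantedStarts[s, ]
        gap <- st[2L] - (st[1L] + lens[1L])
        expect_gte(gap, 5L); expect_lte(gap, 10L)
        for (i in 1:2) {
            inst <- substr(seqs[s], st[i], st[i] + lens[i] - 1L)
            expect_lte(hammingDistance(inst, consensusWords(pd)[i]),
                       tpl@boxErrors[i])
        }
    }
    ## reproducible under the seed
    pd2 <- plantDataset(20, 600, tpl, seed = 33)
    expect_identical(as.character(pd2@sequences), seqs)
    expect_identical(pd2@plantedStarts, pd@plantedStarts)
})

test_that("plantExact leaves unmutated words in one sequence", {
    tpl <- parseTemplate("(7,2)-[0,4]-(6,1)")
    pd <- plantDataset(5, 60, tpl, plantExact = TRUE, seed = 34)
    s <- unname(as.character(pd@sequences)[pd@exactSequence])
    st <- pd@plantedStarts[pd@exactSequence, ]
    for (i in 1:2)
        expect_identical(
            substr(s, st[i], st[i] + tpl@boxLengths[i] - 1L),
            consensusWords(pd)[i])
})

test_that("planting handles the maximal-span boundary and rejects misfits", {
    ## total box length + maximal gaps exactly fills the sequence
    tpl <- structuredTemplate(c(4, 4), c(1, 1), 2, 2, 1.0)
    pd <- plantDataset(3, 10, tpl, seed = 35)
    expect_true(all(pd@plantedStarts[, 1L] == 1L))
    expect_error(plantDataset(3, 9, tpl), "does not fit")
})

test_that("planted motifs are recovered end to end at full quorum", {
    tpl <- parseTemplate("(9,2)-[5,10]-(10,2)")
    pd <- plantDataset(20, 600, tpl, plantExact = TRUE, seed = 36)
    target <- paste(consensusWords(pd), collapse = "-")
    for (mode in c("unconstrained", "frequent")) {
        res <- discoverMotifs(pd, tpl, mode = mode)
        expect_true(target %in% motifTable(res)$motif)
        expect_true(all(motifSupport(res) == 20L))
    }
    ## ground-truth tuples pass the post-hoc gap validator
    gt <- new("StructuredMotifSet", template = tpl, nSequences = 20L,
              words = matrix(consensusWords(pd), 1L, 2L),
              support = 20L,
              occurrences = list(cbind(1:20, pd@plantedStarts)))
    expect_true(validateOccurrences(gt, pd@sequences))
})
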