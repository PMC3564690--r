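#' Read input sequences from a FASTA file
#'
#' Reads a multi-record FASTA file, preserving record order as sequence
#' indices and normalizing to uppercase. Records containing characters
#' outside \{A,C,G,T\} (including IUPAC ambiguity codes such as N) are
#' rejected with the offending record named, since the Hamming motif
#' model is defined only over the four-letter alphabet.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
readFastaSequences <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    x <- Biostrings::readDNAStringSet(path)
    if (length(x) == 0L)
        stop("no sequences found in ", path)
    ## first word of the description line is the record id
    names(x) <- sub("\\s.*$", "", names(x))
    freq <- Biostrings::alphabetFrequency(x)
    bad <- rowSums(freq[, setdiff(colnames(freq), DNA_BASES),
                        drop = FALSE]) > 0L
    if (any(bad))
        stop("record(s) contain characters outside {A,C,G,T}: ",
             paste(names(x)[bad], collapse = ", "))
    x
}

#' Write discovered structured motifs as a tab-separated table
#'
#' One record per motif: the box words joined by `"-"`, the template
#' string, and the support count, separated by tabs. When the motif set
#' retains occurrences, each record is followed by one line per
#' occurrence tuple: the sequence id, a tab, and the comma-separated
#' 1-based start of each box.
#'
#' @param motifs a [StructuredMotifSet-class].
#' @param path output file path (or `""` for stdout).
#' @param seqIds sequence ids used on occurrence lines (defaults to
#'   `seq<i>`).
#' @return `path`, invisibly.
#' @export
writeMotifTable <- function(motifs, path,
                            seqIds = paste0("seq",
                                            seq_len(motifs@nSequences))) {
    stopifnot(is(motifs, "StructuredMotifSet"))
    tplStr <- templateToString(motifs@template)
    con <- if (identical(path, "")) stdout() else file(path, "w")
    if (!identical(path, "")) on.exit(close(con))
    for (i in seq_len(length(motifs))) {
        writeLines(paste(
            paste(motifs@words[i, ], collapse = "-"),
            tplStr, motifs@support[i], sep = "\t"), con)
        if (length(motifs@occurrences)) {
            occ <- motifs@occurrences[[i]]
            for (r in seq_len(nrow(occ)))
                writeLines(paste(seqIds[occ[r, 1L]],
                    paste(occ[r, -1L], collapse = ","), sep = "\t"), con)
        }
    }
    invisible(path)
}

#' Write planted-dataset ground truth
#'
#' Writes the planted dataset's sequences as FASTA and its ground truth
#' as a tab-separated table (`seq_id`, `box`, `consensus`,
#' `planted_start`; starts 1-based), plus the template string on the
#' first comment line.
#'
#' @param planted a [PlantedMotifData-class].
#' @param fastaPath,truthPath output paths.
#' @return `truthPath`, invisibly.
#' @export
writePlantedDataset <- function(planted, fastaPath, truthPath) {
    stopifnot(is(planted, "PlantedMotifData"))
    Biostrings::writeXStringSet(planted@sequences, fastaPath)
    b <- length(planted@consensusWords)
    n <- length(planted@sequences)
    df <- data.frame(
        seq_id = rep(names(planted@sequences), each = b),
        box = rep(seq_len(b), n),
        consensus = rep(planted@consensusWords, n),
        planted_start = as.vector(t(planted@plantedStarts)))
    con <- file(truthPath, "w")
    on.exit(close(con))
    writeLines(paste0("# template\t",
                      templateToString(planted@template)), con)
    writeLines(paste(colnames(df), collapse = "\t"), con)
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(truthPath)
}

#' Discover structured motifs in a sequence set
#'
#' The full two-stage pipeline: enumerate per-box simple-motif candidate
#' sets ([buildCandidateSets()]) and assemble them into structured
#' motifs ([assembleMotifs()]). With `verbose = TRUE`, per-stage wall
#' time and per-box candidate counts \eqn{|K_i|} and occurrence totals
#' \eqn{B_i} are reported via [message()], since these quantities are
#' what governs the cost of a run.
#'
#' @param seqs sequences (character vector, [Biostrings::DNAStringSet],
#'   or a [PlantedMotifData-class], whose sequences are used).
#' @param template a [StructuredTemplate-class].
#' @param mode `"unconstrained"` (consensus words range over all of
#'   \eqn{\Sigma^\ell}) or `"frequent"` (each box word must occur
#'   exactly somewhere in the input).
#' @param boxOrderSelection,spaceSaving,printOccurrences see
#'   [assembleMotifs()].
#' @param verbose report stage diagnostics.
#' @return A [StructuredMotifSet-class].
#' @examples
#' tpl <- parseTemplate("(3,0)-[2,2]-(3,0)", quorum = 1)
#' discoverMotifs(c("AAACCTTT", "AAAGGTTT"), tpl)
#' @export
discoverMotifs <- function(seqs, template,
                           mode = c("unconstrained", "frequent"),
                           boxOrderSelection = FALSE, spaceSaving = NULL,
                           printOccurrences = FALSE, verbose = FALSE) {
    if (is(seqs, "PlantedMotifData")) seqs <- seqs@sequences
    seqs <- .asMotifSequences(seqs)
    mode <- match.arg(mode)
    t0 <- proc.time()[["elapsed"]]
    sets <- buildCandidateSets(seqs, template, mode = mode)
    t1 <- proc.time()[["elapsed"]]
    if (verbose) {
        for (i in seq_along(sets))
            message(sprintf("box %d (%d,%d): |K| = %d, B = %d", i,
                template@boxLengths[i], template@boxErrors[i],
                length(sets[[i]]), totalOccurrences(sets[[i]])))
        message(sprintf("stage 1: %.2fs", t1 - t0))
    }
    res <- assembleMotifs(template, sets,
                          boxOrderSelection = boxOrderSelection,
                          spaceSaving = spaceSaving,
                          printOccurrences = printOccurrences)
    if (verbose)
        message(sprintf("stage 2: %.2fs; %d structured motif(s)",
                        proc.time()[["elapsed"]] - t1, length(res)))
    res
}

#' Run the discovery pipeline from files
#'
#' File-level driver used by the command-line interface: reads a FASTA
#' file, parses the template string, runs [discoverMotifs()] and writes
#' the result table. The returned status distinguishes success (0),
#' invalid input (2) and a stage-1 out-of-memory failure (3, the only
#' failure mode of the two-stage design once input is valid).
#'
#' @param fasta path to the input FASTA file.
#' @param template template string (see [parseTemplate()]).
#' @param quorum quorum fraction in (0, 1].
#' @param out output path (`""` for stdout).
#' @param mode,boxOrderSelection,spaceSaving,printOccurrences,verbose
#'   see [discoverMotifs()].
#' @return Exit status, invisibly; the result table is written to `out`.
#' @export
runPipeline <- function(fasta, template, quorum, out = "",
                        mode = c("unconstrained", "frequent"),
                        boxOrderSelection = FALSE, spaceSaving = NULL,
                        printOccurrences = FALSE, verbose = TRUE) {
    status <- tryCatch({
        seqs <- readFastaSequences(fasta)
        tpl <- parseTemplate(template, quorum = quorum)
        res <- discoverMotifs(seqs, tpl, mode = mode,
                              boxOrderSelection = boxOrderSelection,
                              spaceSaving = spaceSaving,
                              printOccurrences = printOccurrences,
                              verbose = verbose)
        writeMotifTable(res, out, seqIds = names(seqs))
        0L
    },
    stage1MemoryError = function(e) { message(conditionMessage(e)); 3L },
    error = function(e) { message(conditionMessage(e)); 2L })
    invisible(status)
}
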