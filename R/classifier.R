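#' Add-one (Laplace) smoothed log-probability of a k-mer
#'
#' The probability of k-mer w under genome G is estimated with add-one
#' smoothing as \eqn{P(w|G) = (freq_G(w) + 1) / (N_G + V)}, where
#' \eqn{N_G} is the genome's total number of counted windows and V the
#' vocabulary size of the k-mer representation. The pseudo-count of 1 on
#' every vocabulary item gives unseen k-mers a nonzero probability, and the
#' probabilities over the full vocabulary sum to exactly 1. Returned in
#' natural-log units.
#'
#' @param count observed frequency (vectorised).
#' @param total genome total N_G (>= 0).
#' @param V vocabulary size (>= 1), see [vocabularySize()].
#' @return numeric vector of log-probabilities.
#' @examples
#' smoothedLogProb(0, 0, 10)  # log(1/10)
#' smoothedLogProb(2, 3, 10)  # log(3/13)
#' @export
smoothedLogProb <- function(count, total, V) {
    stopifnot(all(total >= 0), all(V >= 1))
    log((count + 1) / (total + V))
}

#' Naive Bayes log-likelihood of one read under one genome
#'
#' Counts the read's k-mers on the fly (no temporary files) and returns
#' \eqn{\sum_w c_{read}(w) \log P(w|G)} with smoothed per-k-mer
#' probabilities; the sum runs over the read's k-mers in ascending
#' lexicographic order so the floating-point result is reproducible. A read
#' contributing no valid window (too short, or all windows hit ambiguous
#' bases) scores exactly 0 against every genome.
#'
#' @param read DNA string (may contain N).
#' @param table the genome's [KmerCounts-class].
#' @param spec the [KmerSpec-class] (defaults to the table's).
#' @param V vocabulary size (defaults to the closed form for \code{spec}).
#' @return numeric(1) log-likelihood (natural log).
#' @export
scoreRead <- function(read, table, spec = countSpec(table),
                      V = vocabularySize(spec)) {
    stopifnot(is(table, "KmerCounts"))
    rc <- countKmers(read, spec)
    if (rc@total == 0) return(0)
    freq <- table@counts[match(names(rc@counts), names(table@counts))]
    freq[is.na(freq)] <- 0L
    sum(rc@counts * smoothedLogProb(freq, table@total, V))
}

PER_READ_BUFFER_BYTES <- 256   # output row + bookkeeping per read
READ_BYTES_PER_BASE   <- 2     # sequence + window bookkeeping

#' Minimum memory estimate for a classification run
#'
#' A documented sizing model, not an allocator: the classifier streams
#' genome count tables (largest table must be resident) while holding one
#' batch of reads and its output buffer. The estimate is
#' \code{largest count file size + batch_size * (2 * read_length + 256)}
#' bytes, monotone non-decreasing in \code{batch_size} and never below the
#' largest count file. [classifyReads()] refuses budgets below this value;
#' any budget above it only changes how many tables stay cached, never the
#' arithmetic.
#'
#' @param db a persisted [KmerDatabase-class].
#' @param batch_size reads per batch.
#' @param read_length assumed read length in bases (default 300).
#' @return estimated bytes.
#' @export
minimumMemory <- function(db, batch_size, read_length = 300) {
    stopifnot(is(db, "KmerDatabase"), batch_size >= 0)
    tableBytes <- if (nrow(db@members)) max(diskFootprint(db)) else 0
    tableBytes + batch_size * (READ_BYTES_PER_BASE * read_length +
                               PER_READ_BUFFER_BYTES)
}

#' Classify query reads against every genome of a database
#'
#' Scores each read against every training genome with add-one-smoothed
#' naive Bayes log-likelihoods ([scoreRead()] semantics, vectorised) and
#' reports the best-scoring genome, its class and lineage. Evaluation is
#' genome-major within read batches: each batch's k-mers are counted once
#' on the fly, then genome count tables are streamed past the batch, which
#' keeps disk loads infrequent. Results are bit-identical for any
#' \code{batch_size >= 1}, any admissible \code{memory_budget} and any
#' \code{threads}: these knobs change residency and scheduling, never the
#' arithmetic (per read-genome pair the summation order is fixed, ascending
#' k-mer).
#'
#' Ties on the maximum are broken toward the ascending-lexicographic
#' smallest \code{genome_id}. Reads with no valid k-mer window are still
#' emitted (score 0, best genome by tie-break) and flagged.
#'
#' @param reads named character vector of read sequences (names are read
#'   ids), or a named \code{DNAStringSet}.
#' @param db a [KmerDatabase-class] with at least one member.
#' @param mode \code{"max"} (best hit only) or \code{"full"} (retain the
#'   complete read-by-genome score matrix).
#' @param batch_size reads scored per batch (default 1000).
#' @param memory_budget optional budget in bytes; must be at least
#'   [minimumMemory()] for this database and batch size.
#' @param threads number of worker processes for genome scoring (results
#'   are independent of this value).
#' @return a [ReadClassification-class].
#' @export
classifyReads <- function(reads, db, mode = c("max", "full"),
                          batch_size = 1000, memory_budget = NULL,
                          threads = 1) {
    mode <- match.arg(mode)
    stopifnot(is(db, "KmerDatabase"), batch_size >= 1, threads >= 1)
    if (is(reads, "DNAStringSet")) {
        nm <- names(reads)
        reads <- as.character(reads)
        names(reads) <- nm
    }
    if (is.null(names(reads)) || anyDuplicated(names(reads)))
        stop("reads must have unique names (read ids)", call. = FALSE)
    if (nrow(db@members) == 0L)
        stop("cannot classify against an empty database", call. = FALSE)

    minMem <- minimumMemory(db, batch_size)
    if (!is.null(memory_budget) && memory_budget < minMem)
        stop(sprintf(
            "memory_budget %.0f below the minimum %.0f bytes for this database and batch size",
            memory_budget, minMem), call. = FALSE)

    spec <- db@spec
    V <- vocabularySize(spec)
    gids <- sort(db@members$genome_id, method = "radix")  # tie-break order
    footprint <- diskFootprint(db)
    cacheCap <- if (is.null(memory_budget)) length(gids)
                else max(1L, 1L + floor((memory_budget - minMem) /
                                        max(1, max(footprint))))
    cache <- new.env(parent = emptyenv())
    cacheOrder <- character(0)
    getTable <- function(gid) {
        if (exists(gid, envir = cache, inherits = FALSE))
            return(get(gid, envir = cache, inherits = FALSE))
        tab <- genomeCounts(db, gid)
        if (length(cacheOrder) >= cacheCap) {
            rm(list = cacheOrder[1L], envir = cache)
            cacheOrder <<- cacheOrder[-1L]
        }
        cache[[gid]] <- tab
        cacheOrder <<- c(cacheOrder, gid)
        tab
    }

    n <- length(reads)
    batches <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
    best <- numeric(n); bestG <- character(n); noK <- logical(n)
    full <- if (mode == "full")
        matrix(NA_real_, n, length(gids), dimnames = list(names(reads), gids))
        else matrix(numeric(0), 0, 0)

    for (idx in batches) {
        batch <- .batchKmerMatrix(reads[idx], spec)
        scoreGenomes <- function(gs) {
            sc <- vapply(gs, function(gid) {
                tab <- getTable(gid)
                freq <- tab@counts[match(batch$vocab, names(tab@counts))]
                freq[is.na(freq)] <- 0L
                lp <- smoothedLogProb(as.numeric(freq), tab@total, V)
                as.numeric(batch$M %*% lp)
            }, numeric(length(idx)))
            matrix(sc, nrow = length(idx), dimnames = list(NULL, gs))
        }
        sc <- if (threads > 1L && length(gids) > 1L) {
            chunks <- split(gids, cut(seq_along(gids), min(threads, length(gids)),
                                      labels = FALSE))
            parts <- parallel::mclapply(chunks, scoreGenomes,
                                        mc.cores = threads)
            do.call(cbind, parts)[, gids, drop = FALSE]
        } else {
            scoreGenomes(gids)
        }
        # ascending-gid scan; strict improvement keeps the lexicographic
        # smallest genome on ties
        b <- sc[, 1L]; bg <- rep(gids[1L], length(idx))
        for (j in seq_along(gids)[-1L]) {
            better <- sc[, j] > b
            b[better] <- sc[better, j]
            bg[better] <- gids[j]
        }
        best[idx] <- b; bestG[idx] <- bg
        noK[idx] <- batch$nWindows == 0
        if (mode == "full") full[idx, ] <- sc
    }

    mrow <- db@members[match(bestG, db@members$genome_id), ]
    lineage <- do.call(paste, c(mrow[TAXONOMIC_RANKS], sep = ";"))
    res <- data.frame(read_id = names(reads), best_genome_id = bestG,
                      best_class_id = mrow$class_id,
                      max_log_likelihood = best,
                      no_kmer_flag = noK, lineage = lineage,
                      stringsAsFactors = FALSE, row.names = NULL)
    new("ReadClassification", results = res, fullScores = full)
}

# sparse reads-by-kmers count matrix for one batch; vocab ascending so each
# read's score accumulates in ascending k-mer order
.batchKmerMatrix <- function(reads, spec) {
    tabs <- lapply(reads, function(r) countKmers(r, spec)@counts)
    nWindows <- vapply(tabs, function(x) sum(as.numeric(x)), 0)
    vocab <- sort(unique(unlist(lapply(tabs, names), use.names = FALSE)),
                  method = "radix")
    if (!length(vocab)) {
        M <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(length(reads), 1L))
        return(list(M = M, vocab = "", nWindows = nWindows))
    }
    i <- rep(seq_along(tabs), lengths(tabs))
    j <- match(unlist(lapply(tabs, names), use.names = FALSE), vocab)
    x <- as.numeric(unlist(tabs, use.names = FALSE))
    M <- Matrix::sparseMatrix(i = i, j = j, x = x,
                              dims = c(length(reads), length(vocab)))
    list(M = M, vocab = vocab, nWindows = nWindows)
}

#' Read query sequences from FASTA or FASTQ
#'
#' Detects the format from the first non-empty character (\code{>} FASTA,
#' \code{@} FASTQ); gzip accepted. FASTQ qualities are read and discarded:
#' scoring is count-based. Read ids are the first whitespace-delimited
#' token of each record header.
#'
#' @param path sequence file path.
#' @return named character vector of sequences.
#' @export
readQueryReads <- function(path) {
    if (!file.exists(path)) stop("cannot read query file: ", path, call. = FALSE)
    con <- gzfile(path, open = "rt")
    first <- ""
    while (!length(first) || !nzchar(trimws(first))) {
        first <- readLines(con, n = 1L)
        if (!length(first)) break
    }
    close(con)
    fmt <- if (!length(first) || !nzchar(first)) "fasta"
           else if (startsWith(first, "@")) "fastq" else "fasta"
    dss <- if (!length(first) || !nzchar(first)) Biostrings::DNAStringSet()
           else Biostrings::readDNAStringSet(path, format = fmt)
    out <- as.character(dss)
    names(out) <- sub("\\s.*$", "", names(dss))
    if (anyDuplicated(names(out)))
        stop("duplicate read ids in ", path, call. = FALSE)
    out
}

#' Write the best-hit classification table
#'
#' Tab-separated, one row per read in input order:
#' \code{read_id best_genome_id best_class_id max_log_likelihood
#' no_kmer_flag lineage} (lineage is the 7 ranks joined with \code{;}).
#' Log-likelihoods are printed with 17 significant digits so output files
#' are byte-identical across runs.
#'
#' @param x a [ReadClassification-class].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeClassification <- function(x, path) {
    stopifnot(is(x, "ReadClassification"))
    r <- x@results
    lines <- c(
        paste(c("read_id", "best_genome_id", "best_class_id",
                "max_log_likelihood", "no_kmer_flag", "lineage"),
              collapse = "\t"),
        sprintf("%s\t%s\t%s\t%.17g\t%d\t%s", r$read_id, r$best_genome_id,
                r$best_class_id, r$max_log_likelihood,
                as.integer(r$no_kmer_flag), r$lineage))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con = con, sep = "\n")
    invisible(path)
}

#' Write the full log-likelihood matrix in bounded chunks
#'
#' Writes the reads-by-genomes matrix of a full-mode classification as one
#' or more TSV files of at most \code{r} rows by \code{c} columns each
#' (defaults approximate common spreadsheet limits), named
#' \code{<prefix>_r<i>_c<j>.tsv}. Each chunk carries a header row of genome
#' ids and a leading \code{read_id} column.
#'
#' @param x a [ReadClassification-class] produced with \code{mode="full"}.
#' @param prefix output path prefix.
#' @param r,c maximum rows and score columns per chunk.
#' @return character vector of files written, invisibly.
#' @export
writeFullScores <- function(x, prefix, r = 1000000, c = 16000) {
    stopifnot(is(x, "ReadClassification"), r >= 1, c >= 1)
    fs <- x@fullScores
    if (prod(dim(fs)) == 0)
        stop("no full scores present; run classifyReads(mode = \"full\")",
             call. = FALSE)
    rowChunks <- split(seq_len(nrow(fs)), ceiling(seq_len(nrow(fs)) / r))
    colChunks <- split(seq_len(ncol(fs)), ceiling(seq_len(ncol(fs)) / c))
    files <- character(0)
    for (ri in seq_along(rowChunks)) for (ci in seq_along(colChunks)) {
        sub <- fs[rowChunks[[ri]], colChunks[[ci]], drop = FALSE]
        path <- sprintf("%s_r%d_c%d.tsv", prefix, ri, ci)
        lines <- c(paste(c("read_id", colnames(sub)), collapse = "\t"),
                   paste(rownames(sub),
                         apply(sub, 1L, function(z)
                             paste(sprintf("%.17g", z), collapse = "\t")),
                         sep = "\t"))
        con <- file(path, open = "wb")
        writeLines(lines, con = con, sep = "\n")
        close(con)
        files <- c(files, path)
    }
    invisible(files)
}
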