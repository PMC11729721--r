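# evaluate `code` under a locally seeded RNG, restoring the caller's
# stream afterwards; seed = NULL means "use the current stream"
.withSeed <- function(seed, code) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
            get(".Random.seed", globalenv()) else NULL
        on.exit(
            if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
        set.seed(seed)
    }
    code
}

#' Parameters for the synthetic genome / read simulator
#'
#' The simulator stands in for a real read simulator on real assemblies:
#' genomes are i.i.d. base sequences with a configurable GC content, reads
#' are drawn uniformly from either strand with independent per-base
#' substitution errors (no indels — the short-read Illumina error mode),
#' and every read id carries its truth (source genome, start, strand).
#'
#' @param genome_length genome length in bases.
#' @param gc_content fraction of G+C bases, in \[0, 1\] (G and C
#'   equiprobable, likewise A and T).
#' @param n_reads number of reads to simulate per call.
#' @param read_length read length in bases (<= genome_length).
#' @param substitution_rate per-base probability of substitution to one of
#'   the 3 alternative bases (uniformly), in \[0, 1).
#' @param seed integer seed, or NULL to draw from the current RNG stream.
#' @return a validated parameter list of class \code{simParams}.
#' @export
simParams <- function(genome_length = 100000, gc_content = 0.5,
                      n_reads = 100, read_length = 200,
                      substitution_rate = 0, seed = NULL) {
    stopifnot(genome_length >= 1, gc_content >= 0, gc_content <= 1,
              n_reads >= 0, read_length >= 1,
              read_length <= genome_length,
              substitution_rate >= 0, substitution_rate < 1)
    structure(list(genome_length = genome_length, gc_content = gc_content,
                   n_reads = n_reads, read_length = read_length,
                   substitution_rate = substitution_rate, seed = seed),
              class = "simParams")
}

#' Simulate a random genome
#'
#' I.i.d. bases with \eqn{P(G) = P(C) = gc/2} and
#' \eqn{P(A) = P(T) = (1 - gc)/2}. Deterministic for a given seed.
#'
#' @param params a [simParams()] list.
#' @return a single DNA string of length \code{genome_length}.
#' @export
randomGenome <- function(params) {
    stopifnot(inherits(params, "simParams"))
    .withSeed(params$seed, {
        gc <- params$gc_content
        bases <- sample(c("A", "C", "G", "T"), params$genome_length,
                        replace = TRUE,
                        prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
        paste(bases, collapse = "")
    })
}

#' Simulate error-bearing short reads from a genome
#'
#' Start positions uniform over the valid range, strand uniform (reverse
#' strand reads are reverse-complemented), and each base substituted with
#' probability \code{substitution_rate} to one of the 3 alternatives
#' uniformly. Read ids are \code{<genome_id>|<start>|<strand>|<index>} so
#' the truth travels with the read. Deterministic for a given seed.
#'
#' @param genome a DNA string (ACGT).
#' @param params a [simParams()] list (\code{n_reads}, \code{read_length},
#'   \code{substitution_rate}, \code{seed} are used).
#' @param genome_id identifier embedded in read ids and the truth table.
#' @param class_id class label recorded in the truth table.
#' @return list with \code{reads} (named character vector) and
#'   \code{truth} (data.frame \code{read_id genome_id class_id start
#'   strand}).
#' @export
simulateReads <- function(genome, params, genome_id = "genome",
                          class_id = genome_id) {
    stopifnot(inherits(params, "simParams"))
    genome <- toupper(as.character(genome))
    L <- nchar(genome)
    rl <- params$read_length
    n <- params$n_reads
    stopifnot(rl <= L)
    .withSeed(params$seed, {
        starts <- sample.int(L - rl + 1L, n, replace = TRUE)
        strand <- sample(c("+", "-"), n, replace = TRUE)
        seqs <- substring(genome, starts, starts + rl - 1L)
        rev <- strand == "-"
        if (any(rev)) seqs[rev] <- revComp(seqs[rev])
        if (params$substitution_rate > 0 && n > 0)
            seqs <- .substituteBases(seqs, params$substitution_rate)
        ids <- sprintf("%s|%d|%s|%d", genome_id, starts, strand, seq_len(n))
        list(reads = setNames(seqs, ids),
             truth = data.frame(read_id = ids, genome_id = genome_id,
                                class_id = class_id, start = starts,
                                strand = strand, stringsAsFactors = FALSE))
    })
}

# per-base substitution to a uniformly chosen alternative base
.substituteBases <- function(seqs, rate) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    vapply(seqs, function(s) {
        chars <- strsplit(s, "", fixed = TRUE)[[1L]]
        hit <- which(runif(length(chars)) < rate)
        if (length(hit)) {
            pick <- ceiling(runif(length(hit)) * 3)
            chars[hit] <- mapply(function(b, p) alt[[b]][p],
                                 chars[hit], pick, USE.NAMES = FALSE)
        }
        paste(chars, collapse = "")
    }, "", USE.NAMES = FALSE)
}

#' Write simulated genomes to FASTA
#'
#' @param genomes named character vector (names become record headers).
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeGenomeFasta <- function(genomes, path) {
    dss <- Biostrings::DNAStringSet(genomes)
    Biostrings::writeXStringSet(dss, path)
    invisible(path)
}

#' Write simulated reads to FASTQ (constant quality 'I')
#'
#' @param reads named character vector of read sequences.
#' @param path output FASTQ path.
#' @return \code{path}, invisibly.
#' @export
writeReadsFastq <- function(reads, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    qual <- vapply(nchar(reads), function(n) strrep("I", n), "")
    writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", qual),
               con = con, sep = "\n")
    invisible(path)
}

#' Write a read truth table TSV
#'
#' Columns \code{read_id genome_id class_id}.
#'
#' @param truth a truth data.frame from [simulateReads()] (rows of several
#'   calls may be rbind-ed).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeTruth <- function(truth, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c("read_id\tgenome_id\tclass_id",
                 sprintf("%s\t%s\t%s", truth$read_id, truth$genome_id,
                         truth$class_id)),
               con = con, sep = "\n")
    invisible(path)
}
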