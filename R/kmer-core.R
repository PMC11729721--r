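#' Reverse complement of DNA strings
#'
#' Watson-Crick reverse complement. Vectorised; an involution
#' (\code{revComp(revComp(x)) == x}).
#'
#' @param seq character vector of DNA strings over \{A,C,G,T\}
#'   (lower case accepted, upper-cased on input).
#' @return character vector of reverse complements (upper case).
#' @examples
#' revComp("ACGT")  # palindromic site: "ACGT"
#' revComp(c("AAA", "GT"))
#' @export
revComp <- function(seq) {
    seq <- toupper(seq)
    .checkACGT(seq, what = "sequence")
    if (!length(seq)) return(character(0))
    out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
    names(out) <- names(seq)
    out
}

.checkACGT <- function(x, what = "sequence") {
    bad <- regexpr("[^ACGT]", x)
    hit <- which(bad > 0L)
    if (length(hit)) {
        i <- hit[1L]
        stop(sprintf("non-ACGT character '%s' at position %d of %s %d",
                     substr(x[i], bad[i], bad[i]), bad[i], what, i),
             call. = FALSE)
    }
    invisible(TRUE)
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographically smaller (order
#' \code{A < C < G < T}) of the k-mer and its reverse complement. Idempotent:
#' the canonical form is its own canonical form.
#'
#' @param kmer character vector of k-mers over \{A,C,G,T\}.
#' @return character vector of canonical k-mers.
#' @examples
#' canonicalKmer("TTT")  # "AAA"
#' canonicalKmer("AT")   # self-reverse-complementary: "AT"
#' @export
canonicalKmer <- function(kmer) {
    kmer <- toupper(kmer)
    .checkACGT(kmer, what = "k-mer")
    if (!length(kmer)) return(character(0))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmer)))
    ifelse(rc < kmer, rc, kmer)
}

#' Vocabulary size of a k-mer representation
#'
#' The number of distinct k-mers under a [KmerSpec-class]; this is the
#' Laplace-smoothing denominator term V. Non-canonical k-mers: \eqn{4^k}.
#' Canonical k-mers of even length: \eqn{(4^k + 4^{k/2})/2} (palindromic
#' k-mers are their own reverse complement and are not halved); odd length:
#' \eqn{4^k/2} (no odd-length k-mer is palindromic).
#'
#' @param spec a [KmerSpec-class].
#' @return a positive number (exact up to k = 26 in double precision).
#' @examples
#' vocabularySize(kmerSpec(2, canonical = TRUE))   # (16 + 4)/2 = 10
#' vocabularySize(kmerSpec(3, canonical = TRUE))   # 64/2 = 32
#' vocabularySize(kmerSpec(1, canonical = FALSE))  # 4
#' @export
vocabularySize <- function(spec) {
    stopifnot(is(spec, "KmerSpec"))
    k <- as.numeric(spec@k)
    if (!spec@canonical) return(4^k)
    if (k %% 2 == 0) (4^k + 4^(k / 2)) / 2 else 4^k / 2
}

#' Count k-mers in DNA sequences
#'
#' Slides a window of length k with step 1 over each input sequence
#' independently (windows never span two sequences, since contigs are not
#' physically contiguous). Windows containing any character outside
#' \{A,C,G,T\} (e.g. \code{N}) are skipped entirely. Remaining windows are
#' mapped to canonical form when the spec is canonical, and tallied. A
#' sequence shorter than k contributes nothing; if no window survives the
#' result is an empty table with total 0.
#'
#' @param seq character vector of sequences, or a
#'   \code{\link[Biostrings]{DNAStringSet}}.
#' @param spec a [KmerSpec-class].
#' @param genome_id optional identifier stored in the result.
#' @return a [KmerCounts-class].
#' @examples
#' countKmers("ACGT", kmerSpec(2))   # AC:2 (GT collapses onto AC), CG:1
#' countKmers("ANA", kmerSpec(2, canonical = FALSE))  # empty: N skips windows
#' @export
countKmers <- function(seq, spec, genome_id = "") {
    stopifnot(is(spec, "KmerSpec"))
    if (is(seq, "DNAStringSet")) seq <- as.character(seq)
    seq <- toupper(as.character(seq))
    k <- spec@k
    words <- unlist(lapply(seq, .kmerWindows, k = k, canonical = spec@canonical),
                    use.names = FALSE)
    if (!length(words))
        return(.emptyCounts(spec, genome_id))
    words <- sort(words, method = "radix")
    runs <- rle(words)
    counts <- setNames(runs$lengths, runs$values)
    new("KmerCounts", spec = spec, counts = counts,
        total = sum(as.numeric(counts)), genomeId = genome_id)
}

# All valid (ACGT-only) windows of one sequence, canonicalised on request.
# The reverse complement of the window starting at i is the window of the
# reverse-complemented sequence starting at L - i - k + 2, which avoids
# reversing each window individually.
.kmerWindows <- function(s, k, canonical) {
    L <- nchar(s)
    if (L < k) return(character(0))
    starts <- seq_len(L - k + 1L)
    w <- substring(s, starts, starts + k - 1L)
    if (grepl("[^ACGT]", s)) {
        keep <- !grepl("[^ACGT]", w)
        w <- w[keep]
        starts <- starts[keep]
        if (!length(w)) return(character(0))
    } else {
        keep <- NULL
    }
    if (!canonical) return(w)
    rs <- .revCompOne(s)
    rw <- substring(rs, L - starts - k + 2L, L - starts + 1L)
    ifelse(rw < w, rw, w)
}

# reverse complement of one string that may contain non-ACGT letters;
# non-ACGT characters map to themselves reversed, which is irrelevant
# because such windows are filtered out before comparison
.revCompOne <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
}

#' Merge two k-mer count tables
#'
#' Key-wise sum of two tables counted under the same spec; totals add.
#' Commutative and associative, with the empty table as identity. Used to
#' accumulate multi-contig genomes and incremental counts.
#'
#' @param a,b [KmerCounts-class] objects under identical specs.
#' @param genome_id identifier for the merged table (defaults to
#'   \code{a}'s).
#' @return a [KmerCounts-class].
#' @examples
#' s <- kmerSpec(2)
#' mergeCounts(countKmers("ACGT", s), countKmers("CGCG", s))
#' @export
mergeCounts <- function(a, b, genome_id = genomeId(a)) {
    stopifnot(is(a, "KmerCounts"), is(b, "KmerCounts"))
    if (a@spec@k != b@spec@k || a@spec@canonical != b@spec@canonical)
        stop("cannot merge KmerCounts built under different specs", call. = FALSE)
    keys <- sort(unique(c(names(a@counts), names(b@counts))), method = "radix")
    if (!length(keys)) return(.emptyCounts(a@spec, genome_id))
    va <- a@counts[match(keys, names(a@counts))]
    vb <- b@counts[match(keys, names(b@counts))]
    va[is.na(va)] <- 0L
    vb[is.na(vb)] <- 0L
    counts <- setNames(as.integer(va + vb), keys)
    new("KmerCounts", spec = a@spec, counts = counts,
        total = a@total + b@total, genomeId = genome_id)
}

# exhaustive vocabulary of a spec (tests and normalisation checks; small k)
.enumerateVocabulary <- function(spec) {
    k <- spec@k
    stopifnot(k <= 12L)
    grid <- do.call(expand.grid,
                    c(rep(list(c("A", "C", "G", "T")), k),
                      stringsAsFactors = FALSE))
    all <- do.call(paste0, rev(grid))
    if (spec@canonical) all <- canonicalKmer(all)
    sort(unique(all), method = "radix")
}
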