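#' @import methods
#' @importFrom stats rbinom runif sd setNames aggregate
#' @importFrom utils read.delim write.table head
NULL

#' K-mer counting specification
#'
#' A \code{KmerSpec} fixes the two parameters that define a k-mer
#' representation: the word length \code{k} and whether counting is
#' \emph{canonical}, i.e. whether each k-mer is collapsed with its reverse
#' complement onto the lexicographically smaller of the two (order
#' \code{A < C < G < T}). Canonical counting makes counts strand-independent
#' and roughly halves the vocabulary.
#'
#' @slot k integer(1), word length in bases, between 1 and 31.
#' @slot canonical logical(1), collapse reverse-complement pairs?
#'
#' @seealso [kmerSpec()], [vocabularySize()], [countKmers()]
#' @export
setClass("KmerSpec", representation(k = "integer", canonical = "logical"))

setValidity("KmerSpec", function(object) {
    if (length(object@k) != 1L || is.na(object@k))
        return("'k' must be a single non-missing integer")
    if (object@k < 1L || object@k > 31L)
        return("'k' must be between 1 and 31")
    if (length(object@canonical) != 1L || is.na(object@canonical))
        return("'canonical' must be TRUE or FALSE")
    TRUE
})

#' Construct a KmerSpec
#'
#' @param k word length in bases (1--31).
#' @param canonical logical; collapse each k-mer with its reverse complement?
#' @return A [KmerSpec-class] object.
#' @examples
#' kmerSpec(9, canonical = TRUE)
#' @export
kmerSpec <- function(k, canonical = TRUE) {
    new("KmerSpec", k = as.integer(k), canonical = as.logical(canonical))
}

#' @describeIn KmerSpec-class word length accessor
#' @param x,object a \code{KmerSpec}
#' @export
kmerLength <- function(x) x@k

#' @describeIn KmerSpec-class canonicality accessor
#' @export
isCanonical <- function(x) x@canonical

setMethod("show", "KmerSpec", function(object) {
    cat(sprintf("KmerSpec: k = %d, %s (vocabulary %s)\n", object@k,
        if (object@canonical) "canonical" else "non-canonical",
        format(vocabularySize(object), big.mark = ",", scientific = FALSE)))
})

#' Per-genome k-mer count table
#'
#' Holds the observed k-mer frequencies \eqn{freq_G(w)} of one genome (or any
#' sequence set) together with the total number of counted windows
#' \eqn{N_G}. Keys are stored sorted in ascending C-locale (lexicographic)
#' order; k-mers never observed are not stored (smoothing supplies them at
#' query time). Under a canonical spec every key equals its own canonical
#' form.
#'
#' @slot spec the [KmerSpec-class] the counts were produced under.
#' @slot counts named integer vector, k-mer -> frequency, keys sorted.
#' @slot total numeric(1), the number of counted windows (equals
#'   \code{sum(counts)}).
#' @slot genomeId character(1), identifier of the source genome ("" if
#'   unattached).
#'
#' @seealso [countKmers()], [mergeCounts()], [saveCounts()]
#' @export
setClass("KmerCounts", representation(
    spec = "KmerSpec", counts = "integer", total = "numeric",
    genomeId = "character"))

setValidity("KmerCounts", function(object) {
    cnt <- object@counts
    if (length(cnt) && is.null(names(cnt)))
        return("'counts' must be a named integer vector")
    if (any(cnt < 0L)) return("counts must be non-negative")
    if (!isTRUE(all.equal(object@total, sum(as.numeric(cnt)))))
        return("'total' must equal the sum of counts")
    if (length(cnt)) {
        keys <- names(cnt)
        if (any(nchar(keys) != object@spec@k))
            return("every key must have length spec k")
        if (any(grepl("[^ACGT]", keys)))
            return("keys must be over the alphabet {A,C,G,T}")
        if (is.unsorted(keys, strictly = TRUE))
            return("keys must be unique and sorted ascending")
    }
    TRUE
})

setMethod("show", "KmerCounts", function(object) {
    cat(sprintf("KmerCounts (k = %d, %s)%s: %d distinct k-mers, total %s\n",
        object@spec@k,
        if (object@spec@canonical) "canonical" else "non-canonical",
        if (nzchar(object@genomeId)) paste0(" for ", object@genomeId) else "",
        length(object@counts),
        format(object@total, big.mark = ",", scientific = FALSE)))
    if (length(object@counts))
        print(head(object@counts, 6L))
})

#' @describeIn KmerCounts-class the spec the table was counted under
#' @param x a \code{KmerCounts}
#' @export
countSpec <- function(x) x@spec

#' @describeIn KmerCounts-class named integer vector of k-mer frequencies
#' @export
kmerCounts <- function(x) x@counts

#' @describeIn KmerCounts-class total number of counted windows (N_G)
#' @export
totalKmers <- function(x) x@total

#' @describeIn KmerCounts-class genome identifier ("" if unattached)
#' @export
genomeId <- function(x) x@genomeId

.emptyCounts <- function(spec, genome_id = "") {
    new("KmerCounts", spec = spec, counts = setNames(integer(0), character(0)),
        total = 0, genomeId = genome_id)
}

#' Incremental per-genome k-mer count database
#'
#' A \code{KmerDatabase} is a directory on disk holding one persisted
#' [KmerCounts-class] file per training genome
#' (\code{counts/<genome_id>.nbk.tsv}) plus a manifest TSV mapping each
#' genome to its species-level class and 7-rank lineage. Genomes are added
#' incrementally: adding a genome never touches another genome's count file.
#'
#' @slot dir character(1), the database directory.
#' @slot spec the [KmerSpec-class] shared by all members.
#' @slot members data.frame with columns \code{genome_id}, \code{class_id},
#'   \code{fasta_path} and the 7 rank columns (superkingdom .. species).
#'
#' @seealso [kmerDatabase()], [addGenome()], [loadDatabase()]
#' @export
setClass("KmerDatabase", representation(
    dir = "character", spec = "KmerSpec", members = "data.frame"))

setValidity("KmerDatabase", function(object) {
    m <- object@members
    need <- c("genome_id", "class_id", "fasta_path", TAXONOMIC_RANKS)
    if (!all(need %in% names(m)))
        return(paste("manifest must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(m$genome_id))
        return("genome_id must be unique within a database")
    TRUE
})

setMethod("show", "KmerDatabase", function(object) {
    cat(sprintf("KmerDatabase at %s\n  k = %d (%s), %d genome(s), %d class(es)\n",
        object@dir, object@spec@k,
        if (object@spec@canonical) "canonical" else "non-canonical",
        nrow(object@members), length(unique(object@members$class_id))))
})

#' @describeIn KmerDatabase-class database directory
#' @param x a \code{KmerDatabase}
#' @export
dbDir <- function(x) x@dir

#' @describeIn KmerDatabase-class shared counting spec
#' @export
dbSpec <- function(x) x@spec

#' @describeIn KmerDatabase-class manifest data.frame (one row per genome)
#' @export
dbMembers <- function(x) x@members

#' The seven taxonomic ranks used throughout the package
#'
#' Ordered from superkingdom down to species; lineages, profiles and
#' per-rank evaluation all use these names.
#' @export
TAXONOMIC_RANKS <- c("superkingdom", "phylum", "class", "order",
                     "family", "genus", "species")

#' Classification result for a batch of reads
#'
#' One row per query read, in input order: the best-scoring training genome,
#' its class, the maximum log-likelihood (natural log), a flag for reads
#' that contributed no valid k-mer window (scored 0 against every genome and
#' assigned by tie-break), and the joined lineage. When classification is
#' run in full mode the complete read-by-genome log-likelihood matrix is
#' retained in \code{fullScores}.
#'
#' @slot results data.frame with columns \code{read_id},
#'   \code{best_genome_id}, \code{best_class_id}, \code{max_log_likelihood},
#'   \code{no_kmer_flag}, \code{lineage}.
#' @slot fullScores numeric matrix (reads x genomes) or a 0x0 matrix in max
#'   mode.
#' @export
setClass("ReadClassification", representation(
    results = "data.frame", fullScores = "matrix"))

setValidity("ReadClassification", function(object) {
    need <- c("read_id", "best_genome_id", "best_class_id",
              "max_log_likelihood", "no_kmer_flag", "lineage")
    if (!all(need %in% names(object@results)))
        return(paste("results must have columns:", paste(need, collapse = ", ")))
    if (prod(dim(object@fullScores)) > 0) {
        fs <- object@fullScores
        if (nrow(fs) != nrow(object@results))
            return("fullScores must have one row per read")
        best <- apply(fs, 1L, max)
        if (!identical(unname(best), unname(object@results$max_log_likelihood)))
            return("max_log_likelihood must equal the row maximum of fullScores")
    }
    TRUE
})

setMethod("show", "ReadClassification", function(object) {
    cat(sprintf("ReadClassification: %d read(s)%s\n", nrow(object@results),
        if (prod(dim(object@fullScores)) > 0)
            sprintf(", full scores vs %d genome(s)", ncol(object@fullScores))
        else ""))
    print(head(object@results, 5L))
})

#' @describeIn ReadClassification-class per-read best-hit table
#' @param x a \code{ReadClassification}
#' @export
classificationResults <- function(x) x@results

#' @describeIn ReadClassification-class reads-by-genomes log-likelihood
#'   matrix (0x0 unless full mode was requested)
#' @export
fullScores <- function(x) x@fullScores
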