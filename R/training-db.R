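#' Count the k-mers of one genome FASTA
#'
#' Reads a (possibly multi-record, possibly gzip-compressed) FASTA file and
#' tallies k-mer windows record by record; windows never span two records.
#' Training a genome for the classifier is exactly this counting step.
#'
#' @param fasta path to a FASTA file.
#' @param spec a [KmerSpec-class].
#' @param genome_id identifier stored in the result (defaults to the file
#'   base name without extension).
#' @return a [KmerCounts-class]. An empty file, or one with no valid
#'   window, yields an empty table with a warning.
#' @export
trainGenome <- function(fasta, spec,
                        genome_id = sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                                        basename(fasta))) {
    if (!file.exists(fasta))
        stop("cannot read FASTA file: ", fasta, call. = FALSE)
    recs <- if (file.size(fasta) == 0) Biostrings::DNAStringSet()
            else Biostrings::readDNAStringSet(fasta)
    tab <- countKmers(recs, spec, genome_id = genome_id)
    if (tab@total == 0)
        warning("no valid k-mer windows in ", fasta, call. = FALSE)
    tab
}

COUNT_FILE_EXT <- ".nbk.tsv"

#' Persist a k-mer count table
#'
#' Writes a plain-text, human-auditable count file: five tab-separated
#' header lines (format tag \code{#nbk 1}, \code{#k}, \code{#canonical}
#' (0/1), \code{#genome}, \code{#total}), then one \code{kmer<TAB>count}
#' line per distinct k-mer in ascending lexicographic order. The file is
#' byte-deterministic for a given table, so checksums detect any change.
#' Zero-count k-mers are never stored; Laplace smoothing supplies them at
#' query time.
#'
#' @param x a [KmerCounts-class].
#' @param path output file path (conventionally ending in
#'   \code{.nbk.tsv}).
#' @return \code{path}, invisibly.
#' @seealso [loadCounts()]
#' @export
saveCounts <- function(x, path) {
    stopifnot(is(x, "KmerCounts"))
    header <- c(
        "#nbk\t1",
        sprintf("#k\t%d", x@spec@k),
        sprintf("#canonical\t%d", as.integer(x@spec@canonical)),
        sprintf("#genome\t%s", x@genomeId),
        sprintf("#total\t%s", format(x@total, scientific = FALSE)))
    body <- if (length(x@counts))
        sprintf("%s\t%d", names(x@counts), unname(x@counts)) else character(0)
    con <- file(path, open = "wb")  # "\n" endings on every platform
    on.exit(close(con))
    writeLines(c(header, body), con = con, sep = "\n")
    invisible(path)
}

.loadFail <- function(path, line, msg) {
    stop(sprintf("malformed count file %s, line %d: %s", path, line, msg),
         call. = FALSE)
}

#' Load a persisted k-mer count table
#'
#' Reads a file written by [saveCounts()], validating the header, key
#' order, uniqueness and the declared total against the sum of counts.
#' \code{loadCounts(saveCounts(x)) } reproduces \code{x} exactly.
#'
#' @param path a count file path.
#' @return a [KmerCounts-class].
#' @export
loadCounts <- function(path) {
    if (!file.exists(path))
        stop("count file not found: ", path, call. = FALSE)
    lines <- readLines(path)
    expectHeader <- function(i, key) {
        if (length(lines) < i) .loadFail(path, i, paste("missing", key, "header"))
        parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(parts) == 1L && lines[i] == paste0(key, "\t"))
            parts <- c(key, "")   # empty value (e.g. unattached genome id)
        if (length(parts) != 2L || parts[1L] != key)
            .loadFail(path, i, sprintf("expected '%s\\t<value>'", key))
        parts[2L]
    }
    if (expectHeader(1L, "#nbk") != "1")
        .loadFail(path, 1L, "unsupported format version")
    k <- suppressWarnings(as.integer(expectHeader(2L, "#k")))
    if (is.na(k)) .loadFail(path, 2L, "k is not an integer")
    canonical <- expectHeader(3L, "#canonical")
    if (!canonical %in% c("0", "1"))
        .loadFail(path, 3L, "canonical flag must be 0 or 1")
    gid <- expectHeader(4L, "#genome")
    total <- suppressWarnings(as.numeric(expectHeader(5L, "#total")))
    if (is.na(total)) .loadFail(path, 5L, "total is not a number")
    spec <- kmerSpec(k, canonical == "1")

    body <- lines[-(1:5)]
    n <- length(body)
    counts <- setNames(integer(0), character(0))
    if (n) {
        parts <- strsplit(body, "\t", fixed = TRUE)
        bad <- which(lengths(parts) != 2L)
        if (length(bad))
            .loadFail(path, 5L + bad[1L], "expected '<kmer>\\t<count>'")
        keys <- vapply(parts, `[`, "", 1L)
        vals <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
        if (anyNA(vals))
            .loadFail(path, 5L + which(is.na(vals))[1L], "count is not an integer")
        dup <- which(duplicated(keys))
        if (length(dup)) .loadFail(path, 5L + dup[1L], "duplicate k-mer key")
        ord <- sort(keys, method = "radix")
        mis <- which(keys != ord)
        if (length(mis))
            .loadFail(path, 5L + mis[1L], "keys not in ascending order")
        counts <- setNames(vals, keys)
    }
    if (!isTRUE(all.equal(total, sum(as.numeric(counts)))))
        .loadFail(path, 5L,
                  sprintf("declared total %s != sum of counts %s",
                          format(total), format(sum(as.numeric(counts)))))
    new("KmerCounts", spec = spec, counts = counts, total = total,
        genomeId = gid)
}

MANIFEST_COLUMNS <- c("genome_id", "class_id", "fasta_path",
                      "superkingdom", "phylum", "class", "order",
                      "family", "genus", "species")

.emptyManifest <- function() {
    as.data.frame(setNames(rep(list(character(0)), length(MANIFEST_COLUMNS)),
                           MANIFEST_COLUMNS), stringsAsFactors = FALSE)
}

#' Read a genome manifest TSV
#'
#' The manifest maps each training genome to its species-level class and
#' 7-rank lineage. Required columns (header line mandatory):
#' \code{genome_id class_id fasta_path superkingdom phylum class order
#' family genus species}; empty rank cells mean "unassigned at this rank".
#'
#' @param path manifest TSV path.
#' @return a data.frame with the manifest columns, all character.
#' @export
readManifest <- function(path) {
    m <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL, quote = "")
    missing <- setdiff(MANIFEST_COLUMNS, names(m))
    if (length(missing))
        stop("manifest ", path, " is missing column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    m[MANIFEST_COLUMNS]
}

.writeManifest <- function(m, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c(paste(MANIFEST_COLUMNS, collapse = "\t"),
                 if (nrow(m)) do.call(paste, c(m[MANIFEST_COLUMNS], sep = "\t"))),
               con = con, sep = "\n")
    invisible(path)
}

.metaPath     <- function(dir) file.path(dir, "kmerdb.meta")
.manifestPath <- function(dir) file.path(dir, "manifest.tsv")
.countsDir    <- function(dir) file.path(dir, "counts")
.countPath    <- function(dir, genome_id)
    file.path(.countsDir(dir), paste0(genome_id, COUNT_FILE_EXT))

#' Create an empty k-mer count database
#'
#' Initialises a database directory: a metadata file fixing the
#' [KmerSpec-class], an empty manifest, and a \code{counts/} directory that
#' will hold one \code{.nbk.tsv} file per genome.
#'
#' @param dir directory to create (must not already hold a database).
#' @param spec a [KmerSpec-class]; all members share it.
#' @return a [KmerDatabase-class].
#' @seealso [addGenome()], [loadDatabase()]
#' @export
kmerDatabase <- function(dir, spec) {
    stopifnot(is(spec, "KmerSpec"))
    if (file.exists(.metaPath(dir)))
        stop("a database already exists at ", dir, call. = FALSE)
    dir.create(.countsDir(dir), recursive = TRUE, showWarnings = FALSE)
    con <- file(.metaPath(dir), open = "wb")
    writeLines(c("#nbkdb\t1", sprintf("k\t%d", spec@k),
                 sprintf("canonical\t%d", as.integer(spec@canonical))),
               con = con, sep = "\n")
    close(con)
    db <- new("KmerDatabase", dir = dir, spec = spec,
              members = .emptyManifest())
    .writeManifest(db@members, .manifestPath(dir))
    db
}

#' Load an existing database from disk
#'
#' Reopens a directory created by [kmerDatabase()]; counts are loaded
#' lazily at query time, so this only reads metadata and the manifest.
#' Reloading reproduces the same counts and totals bit for bit (count files
#' are byte-deterministic).
#'
#' @param dir database directory.
#' @return a [KmerDatabase-class].
#' @export
loadDatabase <- function(dir) {
    if (!file.exists(.metaPath(dir)))
        stop("no database found at ", dir, call. = FALSE)
    meta <- readLines(.metaPath(dir))
    if (meta[1L] != "#nbkdb\t1")
        stop("unsupported database format at ", dir, call. = FALSE)
    kv <- strsplit(meta[-1L], "\t", fixed = TRUE)
    vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    spec <- kmerSpec(as.integer(vals[["k"]]), vals[["canonical"]] == "1")
    members <- readManifest(.manifestPath(dir))
    missing <- members$genome_id[!file.exists(.countPath(dir, members$genome_id))]
    if (length(missing))
        stop("count file missing for genome(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    new("KmerDatabase", dir = dir, spec = spec, members = members)
}

#' Add one genome to a database incrementally
#'
#' Counts the genome's k-mers under the database spec, persists them as a
#' new count file and appends the genome to the manifest. Count files of
#' existing members are not read or written, so incremental growth never
#' perturbs earlier counts: a database built by adding genomes in any order
#' has per-genome counts identical to independent [trainGenome()] calls.
#'
#' @param db a [KmerDatabase-class].
#' @param genome_id unique identifier (also the count file base name;
#'   letters, digits, \code{._-} only).
#' @param class_id species-level class label.
#' @param fasta_path path to the genome FASTA.
#' @param lineage character vector of up to 7 rank names
#'   (superkingdom..species, in order, or named by rank); empty strings
#'   mean unassigned.
#' @param counts optional precomputed [KmerCounts-class] for this genome;
#'   its spec must match the database spec.
#' @return the updated [KmerDatabase-class].
#' @export
addGenome <- function(db, genome_id, class_id, fasta_path,
                      lineage = character(0), counts = NULL) {
    stopifnot(is(db, "KmerDatabase"))
    if (!grepl("^[A-Za-z0-9._-]+$", genome_id))
        stop("genome_id must match [A-Za-z0-9._-]+: ", genome_id, call. = FALSE)
    if (genome_id %in% db@members$genome_id)
        stop("genome_id already in database: ", genome_id, call. = FALSE)
    if (is.null(counts)) {
        counts <- trainGenome(fasta_path, db@spec, genome_id = genome_id)
    } else {
        stopifnot(is(counts, "KmerCounts"))
        if (counts@spec@k != db@spec@k ||
            counts@spec@canonical != db@spec@canonical)
            stop("counts spec does not match database spec", call. = FALSE)
    }
    lin <- .normalizeLineage(lineage)
    saveCounts(counts, .countPath(db@dir, genome_id))
    row <- data.frame(genome_id = genome_id, class_id = class_id,
                      fasta_path = fasta_path, t(lin),
                      stringsAsFactors = FALSE, check.names = FALSE)
    members <- rbind(db@members, row[MANIFEST_COLUMNS])
    db@members <- members
    .writeManifest(members, .manifestPath(db@dir))
    validObject(db)
    db
}

.normalizeLineage <- function(lineage) {
    lin <- setNames(rep("", length(TAXONOMIC_RANKS)), TAXONOMIC_RANKS)
    if (!length(lineage)) return(lin)
    if (!is.null(names(lineage)) && any(nzchar(names(lineage)))) {
        bad <- setdiff(names(lineage), TAXONOMIC_RANKS)
        if (length(bad))
            stop("unknown rank name(s): ", paste(bad, collapse = ", "),
                 call. = FALSE)
        lin[names(lineage)] <- unname(lineage)
    } else {
        if (length(lineage) > length(TAXONOMIC_RANKS))
            stop("lineage has more than 7 elements", call. = FALSE)
        lin[seq_along(lineage)] <- lineage
    }
    lin
}

#' Load the persisted count table of one database member
#'
#' @param db a [KmerDatabase-class].
#' @param genome_id a member genome id.
#' @return a [KmerCounts-class].
#' @export
genomeCounts <- function(db, genome_id) {
    stopifnot(is(db, "KmerDatabase"))
    if (!genome_id %in% db@members$genome_id)
        stop("genome not in database: ", genome_id, call. = FALSE)
    loadCounts(.countPath(db@dir, genome_id))
}

#' Per-genome on-disk footprint of a database
#'
#' Byte size of every member's count file. Canonical counting roughly
#' halves the number of stored keys for long genomes, which this measures
#' directly.
#'
#' @param db a persisted [KmerDatabase-class].
#' @return named numeric vector, genome_id -> bytes.
#' @export
diskFootprint <- function(db) {
    stopifnot(is(db, "KmerDatabase"))
    paths <- .countPath(db@dir, db@members$genome_id)
    missing <- !file.exists(paths)
    if (any(missing))
        stop("count file missing for genome(s): ",
             paste(db@members$genome_id[missing], collapse = ", "),
             call. = FALSE)
    setNames(file.size(paths), db@members$genome_id)
}
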