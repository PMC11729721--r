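#' Class-to-lineage lookup table
#'
#' Maps each species-level class to its 7-rank lineage (superkingdom down
#' to species). Built from a genome manifest (the rank columns), de-
#' duplicated by \code{class_id}; conflicting lineages for one class are an
#' error. Empty strings mean "unassigned at this rank".
#'
#' @param manifest a manifest data.frame ([readManifest()]) or a
#'   [KmerDatabase-class].
#' @return a data.frame with \code{class_id} plus the 7 rank columns, one
#'   row per class.
#' @export
lineageTable <- function(manifest) {
    if (is(manifest, "KmerDatabase")) manifest <- dbMembers(manifest)
    stopifnot(is.data.frame(manifest))
    need <- c("class_id", TAXONOMIC_RANKS)
    missing <- setdiff(need, names(manifest))
    if (length(missing))
        stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
             call. = FALSE)
    tab <- unique(manifest[need])
    dup <- tab$class_id[duplicated(tab$class_id)]
    if (length(dup))
        stop("conflicting lineages for class(es): ",
             paste(unique(dup), collapse = ", "), call. = FALSE)
    rownames(tab) <- NULL
    tab
}

#' Lineage of one class
#'
#' @param class_id a class label present in \code{table}.
#' @param table a lineage table ([lineageTable()]).
#' @return named character(7) of rank names (empty string = unassigned),
#'   in rank order; join with \code{";"} for file output.
#' @export
lineageOf <- function(class_id, table) {
    i <- match(class_id, table$class_id)
    if (anyNA(i))
        stop("unknown class_id: ",
             paste(class_id[is.na(i)], collapse = ", "), call. = FALSE)
    if (length(class_id) == 1L)
        return(setNames(unlist(table[i, TAXONOMIC_RANKS]), TAXONOMIC_RANKS))
    m <- as.matrix(table[i, TAXONOMIC_RANKS])
    rownames(m) <- class_id
    m
}

UNASSIGNED <- "unassigned"

#' Rank-level relative abundance profile of a classification
#'
#' Aggregates per-read best-class predictions at one taxonomic rank: each
#' read contributes 1/n to the taxon named at that rank in its predicted
#' class's lineage. Reads whose class has an empty name at the rank
#' accumulate under the reserved taxon \code{"unassigned"}, so weights
#' always sum to 1.
#'
#' @param results a [ReadClassification-class] or its results data.frame
#'   (needs \code{best_class_id}).
#' @param table a lineage table ([lineageTable()]).
#' @param rank one of [TAXONOMIC_RANKS].
#' @return a named list with \code{rank} and \code{weights} (named numeric,
#'   sorted decreasing, summing to 1).
#' @export
profileFromResults <- function(results, table, rank) {
    if (is(results, "ReadClassification")) results <- results@results
    rank <- match.arg(rank, TAXONOMIC_RANKS)
    if (!nrow(results))
        stop("cannot profile an empty result set", call. = FALSE)
    lin <- table[[rank]][match(results$best_class_id, table$class_id)]
    if (anyNA(lin))
        stop("unknown class_id in results: ",
             paste(unique(results$best_class_id[is.na(lin)]), collapse = ", "),
             call. = FALSE)
    lin[!nzchar(lin)] <- UNASSIGNED
    w <- table(lin) / length(lin)
    weights <- setNames(as.numeric(w), names(w))
    weights <- weights[order(-weights, names(weights))]
    list(rank = rank, weights = weights)
}

#' Bray-Curtis dissimilarity between two abundance profiles
#'
#' \eqn{BC(p, q) = 1 - 2 \sum_t \min(p_t, q_t) / (\sum_t p_t + \sum_t q_t)}
#' over the union of taxa. Symmetric; 0 for identical profiles, 1 for
#' profiles with disjoint support. Profiles must be at the same rank; the
#' comparison always uses the full (unfiltered) profiles — any display
#' filtering (e.g. dropping rare taxa) is cosmetic and must happen after.
#'
#' @param p,q profiles from [profileFromResults()] (or lists with
#'   \code{rank} and named numeric \code{weights}).
#' @return numeric(1) in \[0, 1\].
#' @examples
#' p <- list(rank = "phylum", weights = c(a = 0.5, b = 0.5))
#' q <- list(rank = "phylum", weights = c(a = 1.0))
#' brayCurtis(p, q)  # 0.5
#' @export
brayCurtis <- function(p, q) {
    if (!identical(p$rank, q$rank))
        stop(sprintf("profiles are at different ranks ('%s' vs '%s')",
                     p$rank, q$rank), call. = FALSE)
    taxa <- union(names(p$weights), names(q$weights))
    pv <- p$weights[match(taxa, names(p$weights))]
    qv <- q$weights[match(taxa, names(q$weights))]
    pv[is.na(pv)] <- 0
    qv[is.na(qv)] <- 0
    1 - 2 * sum(pmin(pv, qv)) / (sum(pv) + sum(qv))
}

#' Write an abundance profile as TSV
#'
#' Columns \code{rank taxon relative_abundance}, taxa in decreasing
#' abundance.
#'
#' @param p a profile ([profileFromResults()]).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeProfile <- function(p, path) {
    lines <- c("rank\ttaxon\trelative_abundance",
               sprintf("%s\t%s\t%.17g", p$rank, names(p$weights), p$weights))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con = con, sep = "\n")
    invisible(path)
}

#' Read a profile written by [writeProfile()]
#' @param path profile TSV path.
#' @return a profile list (\code{rank}, \code{weights}).
#' @export
readProfile <- function(path) {
    d <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "numeric"))
    if (!nrow(d)) stop("empty profile file: ", path, call. = FALSE)
    if (length(unique(d$rank)) != 1L)
        stop("profile file mixes ranks: ", path, call. = FALSE)
    list(rank = d$rank[1L],
         weights = setNames(d$relative_abundance, d$taxon))
}
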