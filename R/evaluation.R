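#' Per-rank micro/macro precision and recall with a confusion matrix
#'
#' Projects true and predicted classes onto one taxonomic rank via their
#' lineages (empty rank names become the reserved label
#' \code{"unassigned"}; \code{rank = "class_id"} evaluates the class
#' labels themselves) and computes:
#' \itemize{
#'   \item micro precision/recall pooled over all predictions. The
#'     classifier labels every read, so a false positive for one label is a
#'     false negative for another and the two micro measures coincide.
#'   \item macro precision/recall: per-label measures averaged with equal
#'     weight over the labels present in the truth set. A truth label never
#'     predicted contributes recall 0 and precision 0; labels predicted but
#'     absent from the truth are excluded from the macro average.
#'   \item a confusion matrix (rows = true labels, columns = predicted
#'     labels, counts) over the union of observed labels.
#' }
#'
#' @param preds data.frame with columns \code{true_class_id} and
#'   \code{predicted_class_id} (and optionally \code{read_id}).
#' @param table a lineage table ([lineageTable()]); may be NULL when
#'   \code{rank = "class_id"}.
#' @param rank one of [TAXONOMIC_RANKS], or \code{"class_id"}.
#' @return list with \code{rank}, \code{micro_precision},
#'   \code{micro_recall}, \code{macro_precision}, \code{macro_recall},
#'   \code{confusion} (matrix) and \code{n} (number of predictions).
#' @export
metricsAtRank <- function(preds, table, rank) {
    stopifnot(is.data.frame(preds))
    if (!nrow(preds))
        stop("cannot compute metrics on an empty prediction set", call. = FALSE)
    rank <- match.arg(rank, c("class_id", TAXONOMIC_RANKS))
    toLabel <- function(cls) {
        if (rank == "class_id") return(cls)
        lab <- table[[rank]][match(cls, table$class_id)]
        if (anyNA(lab))
            stop("class_id not in lineage table: ",
                 paste(unique(cls[is.na(lab)]), collapse = ", "),
                 call. = FALSE)
        lab[!nzchar(lab)] <- UNASSIGNED
        lab
    }
    truth <- toLabel(preds$true_class_id)
    pred <- toLabel(preds$predicted_class_id)
    n <- length(truth)
    correct <- truth == pred

    levs <- sort(unique(c(truth, pred)), method = "radix")
    confusion <- table(true = factor(truth, levels = levs),
                       predicted = factor(pred, levels = levs))
    confusion <- unclass(confusion)

    truthLabels <- sort(unique(truth), method = "radix")
    perRecall <- vapply(truthLabels, function(l)
        sum(correct & truth == l) / sum(truth == l), 0)
    perPrecision <- vapply(truthLabels, function(l) {
        npred <- sum(pred == l)
        if (npred == 0) 0 else sum(correct & pred == l) / npred
    }, 0)

    list(rank = rank,
         micro_precision = sum(correct) / n,
         micro_recall = sum(correct) / n,
         macro_precision = mean(perPrecision),
         macro_recall = mean(perRecall),
         confusion = confusion,
         n = n)
}

#' Assign classes to cross-validation folds
#'
#' Seeded shuffle of the class list, then contiguous fifths: the first
#' fifth of the shuffled order is the test set of fold 1, the second of
#' fold 2, and so on; when the class count is not divisible by the fold
#' count, the remainder classes go to the last fold. Deterministic for a
#' given seed.
#'
#' @param class_ids unique class labels (at least \code{nfolds}).
#' @param seed integer seed.
#' @param nfolds number of folds (default 5).
#' @return list of class \code{foldPlan}: \code{seed}, \code{nfolds},
#'   \code{assignments} (named integer, class_id -> test-fold index).
#' @export
makeFolds <- function(class_ids, seed, nfolds = 5) {
    class_ids <- as.character(class_ids)
    if (anyDuplicated(class_ids))
        stop("class_ids must be unique", call. = FALSE)
    if (length(class_ids) < nfolds)
        stop(sprintf("need at least %d classes for %d folds, got %d",
                     nfolds, nfolds, length(class_ids)), call. = FALSE)
    shuffled <- .withSeed(seed, sample(class_ids))
    n <- length(shuffled)
    size <- n %/% nfolds
    fold <- pmin(ceiling(seq_len(n) / size), nfolds)  # remainder -> last fold
    structure(list(seed = seed, nfolds = nfolds,
                   assignments = setNames(fold[match(class_ids, shuffled)],
                                          class_ids)),
              class = "foldPlan")
}

#' Cross-validated classification over simulated reads
#'
#' The evaluation harness: classes are split into folds with
#' [makeFolds()]; for each fold a database is trained on the training-fold
#' genomes, reads are simulated from the held-out (test-fold) classes and
#' classified, and [metricsAtRank()] is computed for all 7 ranks (plus the
#' raw class level). Because test-fold classes are absent from training,
#' class/species-level predictions cannot be correct in this open-set
#' design; metrics are meaningful at ranks above the holdout level, and a
#' closed-set control (\code{closed_set = TRUE}: test reads simulated from
#' the training-fold genomes themselves) is provided for verification.
#'
#' @param manifest genome manifest data.frame ([readManifest()] columns);
#'   each row's \code{fasta_path} must be readable.
#' @param spec a [KmerSpec-class].
#' @param reads_per_class simulated reads per test class (default 100).
#' @param read_length simulated read length (default 200).
#' @param substitution_rate per-base read error rate (default 0).
#' @param seed integer seed driving fold assignment and simulation.
#' @param nfolds number of folds (default 5).
#' @param closed_set logical; simulate test reads from training-fold
#'   genomes instead of held-out ones.
#' @param work_dir directory for per-fold databases (default a tempdir).
#' @return list with \code{plan} (the [makeFolds()] plan), \code{folds}
#'   (per-fold list: \code{metrics} data.frame over ranks,
#'   \code{confusion} list, \code{predictions}), and \code{summary}
#'   (mean and sd of each measure across folds, per rank).
#' @export
runCrossValidation <- function(manifest, spec, reads_per_class = 100,
                               read_length = 200, substitution_rate = 0,
                               seed = 1, nfolds = 5, closed_set = FALSE,
                               work_dir = tempfile("cvdb")) {
    stopifnot(is.data.frame(manifest), is(spec, "KmerSpec"))
    classes <- unique(manifest$class_id)
    plan <- makeFolds(classes, seed = seed, nfolds = nfolds)
    linTable <- lineageTable(manifest)
    dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)

    ranks <- c("class_id", TAXONOMIC_RANKS)
    foldResults <- vector("list", nfolds)
    for (f in seq_len(nfolds)) {
        testClasses <- names(plan$assignments)[plan$assignments == f]
        trainRows <- manifest[!(manifest$class_id %in% testClasses), ,
                              drop = FALSE]
        db <- kmerDatabase(file.path(work_dir, paste0("fold", f)), spec)
        for (i in seq_len(nrow(trainRows)))
            db <- addGenome(db, trainRows$genome_id[i],
                            trainRows$class_id[i], trainRows$fasta_path[i],
                            lineage = unlist(trainRows[i, TAXONOMIC_RANKS]))

        srcClasses <- if (closed_set) unique(trainRows$class_id) else testClasses
        sim <- .withSeed(seed * 1000L + f, {
            out <- lapply(srcClasses, function(cl) {
                rows <- manifest[manifest$class_id == cl, , drop = FALSE]
                pick <- rows[sample.int(nrow(rows), 1L), ]
                genome <- paste(as.character(
                    Biostrings::readDNAStringSet(pick$fasta_path)),
                    collapse = "")
                p <- simParams(genome_length = nchar(genome),
                               n_reads = reads_per_class,
                               read_length = read_length,
                               substitution_rate = substitution_rate,
                               seed = NULL)
                simulateReads(genome, p, genome_id = pick$genome_id,
                              class_id = cl)
            })
            list(reads = do.call(c, lapply(out, `[[`, "reads")),
                 truth = do.call(rbind, lapply(out, `[[`, "truth")))
        })

        cls <- classifyReads(sim$reads, db)
        preds <- data.frame(
            read_id = sim$truth$read_id,
            true_class_id = sim$truth$class_id,
            predicted_class_id =
                classificationResults(cls)$best_class_id,
            stringsAsFactors = FALSE)

        metrics <- lapply(ranks, function(r) metricsAtRank(preds, linTable, r))
        mtab <- data.frame(
            rank = ranks,
            micro_precision = vapply(metrics, `[[`, 0, "micro_precision"),
            micro_recall = vapply(metrics, `[[`, 0, "micro_recall"),
            macro_precision = vapply(metrics, `[[`, 0, "macro_precision"),
            macro_recall = vapply(metrics, `[[`, 0, "macro_recall"),
            stringsAsFactors = FALSE, row.names = NULL)
        foldResults[[f]] <- list(
            metrics = mtab,
            confusion = setNames(lapply(metrics, `[[`, "confusion"), ranks),
            predictions = preds)
    }

    all <- do.call(rbind, lapply(seq_len(nfolds), function(f)
        cbind(fold = f, foldResults[[f]]$metrics)))
    measures <- c("micro_precision", "micro_recall",
                  "macro_precision", "macro_recall")
    summary <- do.call(rbind, lapply(ranks, function(r) {
        sub <- all[all$rank == r, measures, drop = FALSE]
        data.frame(rank = r,
                   t(setNames(colMeans(sub), paste0(measures, "_mean"))),
                   t(setNames(apply(sub, 2, sd), paste0(measures, "_sd"))),
                   stringsAsFactors = FALSE, row.names = NULL)
    }))
    list(plan = plan, folds = foldResults, summary = summary)
}

#' Write a metrics table (or the CV summary) as TSV
#'
#' @param metrics a data.frame (per-fold metrics or CV summary).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeMetrics <- function(metrics, path) {
    write.table(metrics, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a confusion matrix as TSV with labelled rows and columns
#'
#' @param confusion a matrix from [metricsAtRank()].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeConfusion <- function(confusion, path) {
    write.table(cbind(true = rownames(confusion), as.data.frame(confusion)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
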