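eval_lineage_fixture <- function() {
    data.frame(
        class_id = c("cA", "cB", "cC", "cD"),
        superkingdom = c("Bacteria", "Bacteria", "Bacteria", "Archaea"),
        phylum = c("P1", "P1", "P2", "P3"),
        class = c("K1", "K2", "K3", "K4"),
        order = c("O1", "O2", "O3", ""),
        family = c("F1", "F2", "F3", "F4"),
        genus = c("G1", "G2", "G3", "G4"),
        species = c("S1", "S2", "S3", "S4"),
        stringsAsFactors = FALSE)
}

test_that("perfect predictions give unit measures and a diagonal confusion matrix", {
    tab <- eval_lineage_fixture()
    preds <- data.frame(true_class_id = c("cA", "cB", "cC"),
                        predicted_class_id = c("cA", "cB", "cC"))
    for (rank in c("class_id", "phylum", "species")) {
        m <- metricsAtRank(preds, tab, rank)
        expect_identical(m$micro_precision, 1)
        expect_identical(m$micro_recall, 1)
        expect_identical(m$macro_precision, 1)
        expect_identical(m$macro_recall, 1)
        expect_identical(sum(m$confusion), 3L)
        expect_identical(sum(diag(m$confusion)), 3L)
    }
    expect_error(metricsAtRank(preds[0, ], tab, "phylum"), "empty")
    expect_error(metricsAtRank(
        data.frame(true_class_id = "cZ", predicted_class_id = "cA"),
        tab, "phylum"), "cZ")
})

test_that("the all-A degenerate classifier matches hand-computed measures", {
    # truth: 5 A, 5 B; predictions: all A
    # micro: 5/10; macro-recall: (1 + 0)/2; macro-precision: (5/10 + 0)/2
    tab <- eval_lineage_fixture()
    preds <- data.frame(true_class_id = rep(c("cA", "cB"), each = 5),
                        predicted_class_id = rep("cA", 10))
    m <- metricsAtRank(preds, tab, "class_id")
    expect_identical(m$micro_recall, 0.5)
    expect_identical(m$micro_precision, 0.5)
    expect_identical(m$macro_recall, 0.5)
    expect_identical(m$macro_precision, 0.25)
    expect_identical(unname(m$confusion["cA", "cA"]), 5L)
    expect_identical(unname(m$confusion["cB", "cA"]), 5L)
    expect_identical(unname(m$confusion["cB", "cB"]), 0L)
})

test_that("lineage projection maps empty ranks to 'unassigned'", {
    tab <- eval_lineage_fixture()
    preds <- data.frame(true_class_id = c("cD", "cD"),
                        predicted_class_id = c("cD", "cA"))
    m <- metricsAtRank(preds, tab, "order")    # cD's order slot is empty
    expect_true("unassigned" %in% rownames(m$confusion))
    expect_identical(m$micro_recall, 0.5)
})

test_that("micro-precision equals micro-recall whenever every read is labelled", {
    tab <- eval_lineage_fixture()
    withr::with_seed(44, {
        for (i in 1:20) {
            n <- sample(5:40, 1)
            preds <- data.frame(
                true_class_id = sample(tab$class_id, n, replace = TRUE),
                predicted_class_id = sample(tab$class_id, n, replace = TRUE))
            for (rank in c("class_id", "superkingdom", "genus")) {
                m <- metricsAtRank(preds, tab, rank)
                expect_identical(m$micro_precision, m$micro_recall)
                # confusion-matrix row sums equal true-label counts
                expect_identical(sum(m$confusion), n)
                truthLab <- if (rank == "class_id") preds$true_class_id
                            else tab[[rank]][match(preds$true_class_id,
                                                   tab$class_id)]
                cnt <- table(truthLab)
                expect_identical(unname(rowSums(m$confusion)[names(cnt)]),
                                 as.numeric(cnt))
            }
        }
    })
})

test_that("macro measures are invariant to row order and duplication", {
    tab <- eval_lineage_fixture()
    preds <- withr::with_seed(45, data.frame(
        true_class_id = sample(tab$class_id, 30, replace = TRUE),
        predicted_class_id = sample(tab$class_id, 30, replace = TRUE)))
    m1 <- metricsAtRank(preds, tab, "phylum")
    m2 <- metricsAtRank(preds[rev(seq_len(nrow(preds))), ], tab, "phylum")
    m3 <- metricsAtRank(rbind(preds, preds), tab, "phylum")
    for (k in c("macro_precision", "macro_recall", "micro_recall")) {
        expect_identical(m1[[k]], m2[[k]])
        expect_identical(m1[[k]], m3[[k]])
    }
})

test_that("makeFolds partitions classes into contiguous shuffled fifths", {
    cls <- sprintf("c%02d", 1:10)
    plan <- makeFolds(cls, seed = 7)
    expect_identical(sort(names(plan$assignments)), sort(cls))
    expect_identical(as.integer(table(plan$assignments)),
                     rep(2L, 5))                        # fifths of size 2
    plan2 <- makeFolds(cls, seed = 7)
    expect_identical(plan, plan2)                        # reproducible
    expect_false(identical(plan, makeFolds(cls, seed = 8)))
    # remainder classes land in the last fold
    plan3 <- makeFolds(sprintf("c%02d", 1:13), seed = 7)
    sizes <- as.integer(table(plan3$assignments))
    expect_identical(sizes, c(2L, 2L, 2L, 2L, 5L))
    expect_error(makeFolds(sprintf("c%d", 1:4), seed = 1), "at least 5")
    expect_error(makeFolds(c("a", "a", "b", "c", "d", "e"), 1), "unique")
})

test_that("the cross-validation harness runs open- and closed-set and is seed-deterministic", {
    base <- withr::local_tempdir()
    manifest <- make_sim_manifest(file.path(base, "fa"), n_classes = 6,
                                  genome_length = 4000, seed = 46)
    spec <- kmerSpec(7, TRUE)
    cv <- runCrossValidation(manifest, spec, reads_per_class = 8,
                             read_length = 80, seed = 5,
                             work_dir = file.path(base, "cv1"))
    expect_identical(length(cv$folds), 5L)
    ranks <- c("class_id", TAXONOMIC_RANKS)
    for (f in cv$folds) {
        expect_identical(f$metrics$rank, ranks)   # all 7 ranks + class level
        expect_true(all(f$metrics$micro_recall >= 0 &
                        f$metrics$micro_recall <= 1))
        # open set: held-out classes cannot be right at class level
        expect_identical(f$metrics$micro_recall[1], 0)
        expect_identical(f$metrics$micro_precision, f$metrics$micro_recall)
    }
    expect_identical(cv$summary$rank, ranks)

    cv2 <- runCrossValidation(manifest, spec, reads_per_class = 8,
                              read_length = 80, seed = 5,
                              work_dir = file.path(base, "cv2"))
    expect_identical(cv$summary, cv2$summary)
    for (f in 1:5)
        expect_identical(cv$folds[[f]]$predictions,
                         cv2$folds[[f]]$predictions)

    # closed-set control: reads come from training genomes, so class-level
    # recall is near-perfect for well-separated random genomes
    cvc <- runCrossValidation(manifest, spec, reads_per_class = 8,
                              read_length = 80, seed = 5, closed_set = TRUE,
                              work_dir = file.path(base, "cv3"))
    classRecall <- vapply(cvc$folds,
                          function(f) f$metrics$micro_recall[1], 0)
    expect_true(all(classRecall >= 0.99))
})
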