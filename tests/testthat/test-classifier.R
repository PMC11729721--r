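test_that("smoothedLogProb implements add-one smoothing in natural log", {
    expect_equal(smoothedLogProb(0, 0, 10), log(1 / 10), tolerance = 1e-12)
    expect_equal(smoothedLogProb(2, 3, 10), log(3 / 13), tolerance = 1e-12)
    expect_identical(smoothedLogProb(c(0, 2), 3, 10),
                     log(c(1, 3) / 13))
})

test_that("smoothed probabilities over the full vocabulary sum to 1", {
    seqs <- random_dna(5, 600, rng_seed = 12)
    for (k in 2:4) for (canonical in c(TRUE, FALSE)) {
        spec <- kmerSpec(k, canonical)
        V <- vocabularySize(spec)
        for (s in seqs) {
            ct <- countKmers(s, spec)
            vocab <- kmerBayes:::.enumerateVocabulary(spec)
            freq <- kmerCounts(ct)[match(vocab, names(kmerCounts(ct)))]
            freq[is.na(freq)] <- 0L
            total <- sum(exp(smoothedLogProb(as.numeric(freq),
                                             totalKmers(ct), V)))
            expect_lt(abs(total - 1), 1e-9)
        }
    }
})

test_that("scoreRead matches direct arithmetic on worked examples", {
    spec <- kmerSpec(2, TRUE)
    tab <- countKmers("ACGT", spec)   # {AC:2, CG:1}, N = 3
    V <- 10                           # canonical 2-mer vocabulary
    expect_equal(scoreRead("AC", tab, spec, V), log(3 / 13), tolerance = 1e-12)
    # TT,TT -> canonical AA twice, unseen
    expect_equal(scoreRead("TTT", tab, spec, V), 2 * log(1 / 13),
                 tolerance = 1e-12)
    expect_identical(scoreRead("NN", tab, spec, V), 0)
    expect_identical(scoreRead("A", tab, spec, V), 0)  # shorter than k
})

test_that("classifyReads breaks score ties toward the ascending genome id", {
    base <- withr::local_tempdir()
    g <- random_dna(1, 1000, rng_seed = 9)
    fa <- write_fasta_text(list(g = g), file.path(base, "g.fa"))
    db <- kmerDatabase(file.path(base, "db"), kmerSpec(5, TRUE))
    db <- addGenome(db, "gB", "cB", fa)   # identical content, ids differ
    db <- addGenome(db, "gA", "cA", fa)
    res <- classificationResults(
        classifyReads(c(r1 = substr(g, 1, 60)), db))
    expect_identical(res$best_genome_id, "gA")
    # a no-k-mer read is still emitted, flagged, with the tie-break winner
    res2 <- classificationResults(classifyReads(c(rN = "NNNNNNNN"), db))
    expect_identical(res2$best_genome_id, "gA")
    expect_identical(res2$max_log_likelihood, 0)
    expect_true(res2$no_kmer_flag)
})

test_that("batch size, memory budget and threads never change the results", {
    base <- withr::local_tempdir()
    fx <- make_sim_db(file.path(base, "db"), n_genomes = 4,
                      genome_length = 5000, k = 7, seed = 14)
    reads <- withr::with_seed(15, {
        sim <- simulateReads(fx$genomes[[2]],
                             simParams(genome_length = 5000, n_reads = 30,
                                       read_length = 80,
                                       substitution_rate = 0.02, seed = NULL),
                             genome_id = "g002")
        sim$reads
    })
    ref <- classifyReads(reads, fx$db, mode = "full", batch_size = 1000)
    for (bs in c(1, 7)) {
        alt <- classifyReads(reads, fx$db, mode = "full", batch_size = bs)
        expect_identical(fullScores(alt), fullScores(ref))
        expect_identical(classificationResults(alt), classificationResults(ref))
    }
    minMem <- minimumMemory(fx$db, 1000)
    for (budget in c(minMem, 4 * minMem)) {
        alt <- classifyReads(reads, fx$db, mode = "full",
                             memory_budget = budget)
        expect_identical(fullScores(alt), fullScores(ref))
    }
    alt <- classifyReads(reads, fx$db, mode = "full", threads = 3)
    expect_identical(fullScores(alt), fullScores(ref))
})

test_that("classifyReads agrees with the brute-force oracle scorer", {
    base <- withr::local_tempdir()
    k <- 7
    fx <- make_sim_db(file.path(base, "db"), n_genomes = 3,
                      genome_length = 5000, k = k, seed = 16)
    reads <- random_dna(20, 100, rng_seed = 17)
    names(reads) <- sprintf("r%02d", seq_along(reads))
    res <- classifyReads(reads, fx$db, mode = "full")
    fs <- fullScores(res)
    V <- vocabularySize(dbSpec(fx$db))
    oracleCounts <- lapply(fx$genomes, oracle_count, k = k, canonical = TRUE)
    for (gid in colnames(fs)) {
        oc <- oracleCounts[[gid]]
        for (i in seq_along(reads)) {
            want <- oracle_score(reads[[i]], oc$counts, oc$total, V, k, TRUE)
            expect_lt(abs(fs[i, gid] - want), 1e-9)
        }
    }
    # argmax labels agree with the oracle's
    oracleBest <- vapply(seq_along(reads), function(i) {
        sc <- vapply(names(oracleCounts), function(gid)
            oracle_score(reads[[i]], oracleCounts[[gid]]$counts,
                         oracleCounts[[gid]]$total, V, k, TRUE), 0)
        names(sc)[which.max(sc)]
    }, "")
    expect_identical(classificationResults(res)$best_genome_id, oracleBest)
})

test_that("canonical scoring is strand-invariant end to end", {
    base <- withr::local_tempdir()
    fx <- make_sim_db(file.path(base, "db"), n_genomes = 3,
                      genome_length = 4000, k = 7, seed = 18)
    reads <- random_dna(25, 90, rng_seed = 19)
    names(reads) <- sprintf("f%02d", seq_along(reads))
    rc <- revComp(reads)
    names(rc) <- sprintf("r%02d", seq_along(rc))
    a <- fullScores(classifyReads(reads, fx$db, mode = "full"))
    b <- fullScores(classifyReads(rc, fx$db, mode = "full"))
    dimnames(a) <- dimnames(b) <- NULL
    expect_identical(a, b)
})

test_that("minimumMemory is a monotone lower bound honoured by classifyReads", {
    base <- withr::local_tempdir()
    fx <- make_sim_db(file.path(base, "db"), n_genomes = 3,
                      genome_length = 3000, k = 7, seed = 20)
    m0 <- minimumMemory(fx$db, 0)
    m1 <- minimumMemory(fx$db, 100)
    m2 <- minimumMemory(fx$db, 200)
    expect_identical(m0, max(diskFootprint(fx$db)))  # batch term vanishes
    expect_lte(m1, m2)
    expect_gte(m1, max(diskFootprint(fx$db)))
    expect_error(
        classifyReads(c(r1 = "ACGTACGTACGT"), fx$db, batch_size = 100,
                      memory_budget = m1 - 1),
        "below the minimum")
    # the error names the computed minimum
    expect_error(
        classifyReads(c(r1 = "ACGTACGTACGT"), fx$db, batch_size = 100,
                      memory_budget = 1),
        format(m1, scientific = FALSE))
})

test_that("classifyReads validates its inputs", {
    base <- withr::local_tempdir()
    db <- kmerDatabase(file.path(base, "db"), kmerSpec(5, TRUE))
    expect_error(classifyReads(c(r = "ACGT"), db), "empty database")
    fx <- make_sim_db(file.path(base, "db2"), n_genomes = 2,
                      genome_length = 2000, k = 5, seed = 22)
    expect_error(classifyReads(unname(c("ACGT")), fx$db), "unique names")
    expect_error(classifyReads(c(r = "ACGT", r = "ACGT"), fx$db),
                 "unique names")
})

test_that("full-mode output respects the row/column chunk limits", {
    base <- withr::local_tempdir()
    fx <- make_sim_db(file.path(base, "db"), n_genomes = 5,
                      genome_length = 2000, k = 5, seed = 23)
    reads <- random_dna(7, 60, rng_seed = 24)
    names(reads) <- sprintf("r%d", seq_along(reads))
    res <- classifyReads(reads, fx$db, mode = "full")
    fs <- fullScores(res)
    expect_identical(dim(fs), c(7L, 5L))
    expect_identical(apply(fs, 1, max),
                     setNames(classificationResults(res)$max_log_likelihood,
                              names(reads)))
    files <- writeFullScores(res, file.path(base, "full"), r = 3, c = 2)
    expect_identical(length(files), 9L)  # ceiling(7/3) * ceiling(5/2)
    chunk <- read.delim(files[1])
    expect_lte(nrow(chunk), 3L)
    expect_lte(ncol(chunk) - 1L, 2L)   # read_id column + <= c score columns
    # chunks reassemble to the full matrix
    expect_error(writeFullScores(classifyReads(reads, fx$db),
                                 file.path(base, "nofull")), "full")
})
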