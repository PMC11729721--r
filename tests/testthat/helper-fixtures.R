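# Build a small simulated genome database for end-to-end tests.
# Returns the database plus the raw genome strings and manifest rows.
make_sim_db <- function(dir, n_genomes, genome_length, k = 9,
                        canonical = TRUE, gc = 0.5, seed = 1,
                        ids = sprintf("g%03d", seq_len(n_genomes))) {
    spec <- kmerSpec(k, canonical)
    db <- kmerDatabase(dir, spec)
    genomes <- character(0)
    withr::with_seed(seed, {
        for (i in seq_len(n_genomes)) {
            p <- simParams(genome_length = genome_length, gc_content = gc,
                           seed = NULL)
            g <- randomGenome(p)
            genomes[ids[i]] <- g
            fa <- file.path(dir, paste0(ids[i], ".fa"))
            writeGenomeFasta(setNames(g, ids[i]), fa)
            db <- addGenome(db, ids[i], paste0("cls_", ids[i]), fa,
                            lineage = c(superkingdom = "Bacteria",
                                        phylum = paste0("phy", (i %% 3) + 1),
                                        species = paste0("sp_", ids[i])))
        }
    })
    list(db = db, genomes = genomes)
}

# manifest data.frame for simulated multi-class fixtures (one genome per
# class), writing FASTA files under `dir`
make_sim_manifest <- function(dir, n_classes, genome_length, seed = 1) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    rows <- withr::with_seed(seed, lapply(seq_len(n_classes), function(i) {
        gid <- sprintf("mg%03d", i)
        g <- randomGenome(simParams(genome_length = genome_length, seed = NULL))
        fa <- file.path(dir, paste0(gid, ".fa"))
        writeGenomeFasta(setNames(g, gid), fa)
        data.frame(genome_id = gid, class_id = sprintf("cls%03d", i),
                   fasta_path = fa,
                   superkingdom = if (i %% 2) "Bacteria" else "Archaea",
                   phylum = sprintf("phy%d", (i %% 4) + 1),
                   class = sprintf("cla%d", (i %% 3) + 1),
                   order = "", family = sprintf("fam%d", (i %% 5) + 1),
                   genus = sprintf("gen%d", i),
                   species = sprintf("spe%d", i),
                   stringsAsFactors = FALSE)
    }))
    do.call(rbind, rows)
}

write_fasta_text <- function(records, path) {
    writeLines(unlist(lapply(names(records), function(n)
        c(paste0(">", n), records[[n]]))), path)
    path
}
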