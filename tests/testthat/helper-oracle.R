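# Independent brute-force reference implementations used as oracles.
# Deliberately naive (character loops, plain dictionaries) and written
# without calling the package's counting/scoring path.

oracle_rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
}

oracle_canon <- function(w) {
    r <- oracle_rc(w)
    if (r < w) r else w
}

# valid (ACGT-only) windows of one sequence, in positional order
oracle_windows <- function(s, k, canonical) {
    s <- toupper(s)
    L <- nchar(s)
    if (L < k) return(character(0))
    out <- character(0)
    for (i in seq_len(L - k + 1L)) {
        w <- substr(s, i, i + k - 1L)
        if (grepl("[^ACGT]", w)) next
        if (canonical) w <- oracle_canon(w)
        out <- c(out, w)
    }
    out
}

# dictionary-based k-mer counting over a vector of sequences
oracle_count <- function(seqs, k, canonical) {
    env <- new.env(parent = emptyenv())
    total <- 0
    for (s in seqs) {
        s <- toupper(s)
        L <- nchar(s)
        if (L < k) next
        ambiguous <- grepl("[^ACGT]", s)
        for (i in seq_len(L - k + 1L)) {
            w <- substr(s, i, i + k - 1L)
            if (ambiguous && grepl("[^ACGT]", w)) next
            if (canonical) w <- oracle_canon(w)
            prev <- if (exists(w, envir = env, inherits = FALSE))
                get(w, envir = env) else 0
            assign(w, prev + 1, envir = env)
            total <- total + 1
        }
    }
    keys <- sort(ls(env), method = "radix")
    list(counts = setNames(vapply(keys, get, 0, envir = env), keys),
         total = total)
}

# term-by-term smoothed log-likelihood of one read under one genome's
# dictionary counts, summing in ascending k-mer order
oracle_score <- function(read, gcounts, gtotal, V, k, canonical) {
    ws <- oracle_windows(read, k, canonical)
    if (!length(ws)) return(0)
    ws <- sort(ws, method = "radix")
    f <- unname(gcounts[ws])
    f[is.na(f)] <- 0
    s <- 0
    for (i in seq_along(ws))
        s <- s + log((f[[i]] + 1) / (gtotal + V))
    s
}

random_dna <- function(n, len, rng_seed = NULL) {
    draw <- function() {
        vapply(seq_len(n), function(i)
            paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = ""), "")
    }
    if (is.null(rng_seed)) draw() else withr::with_seed(rng_seed, draw())
}
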