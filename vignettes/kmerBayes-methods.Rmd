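---
title: "Methods: naive Bayes read classification over canonical k-mers"
author: "kmerBayes"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: naive Bayes read classification over canonical k-mers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`kmerBayes` treats each reference genome $G$ as a bag of k-mers. A query
read $r$ is decomposed into its own k-mer counts $c_r(w)$ and scored
against each genome with the naive Bayes log-likelihood

$$\log L(r \mid G) \;=\; \sum_{w} c_r(w)\,\log P(w \mid G),
\qquad
P(w \mid G) \;=\; \frac{freq_G(w) + 1}{N_G + V},$$

where $freq_G(w)$ is the k-mer's count in the genome, $N_G$ the genome's
total number of counted windows, and $V$ the vocabulary size of the k-mer
representation. The read is assigned to the argmax genome; its class and
7-rank lineage (superkingdom, phylum, class, order, family, genus,
species) come from the database manifest.

The conditional-independence assumption between overlapping k-mers is of
course false in detail — adjacent windows share $k-1$ bases — but it is
what makes the model a sum of per-k-mer terms, trainable by counting alone
and extensible one genome at a time. In practice the model behaves like a
memorisation machine: a read drawn from a training genome finds all of its
k-mers at nonzero frequency there, while every k-mer absent from a
competing genome costs that genome roughly $\log\frac{1}{N_G + V}$, a
penalty so large that a handful of genome-specific k-mers dominate the
decision.

## Add-one smoothing and why the numerator carries the pseudo-count

Without smoothing, a single read k-mer unseen in a genome would send that
genome's likelihood to $-\infty$ and make scores incomparable. We use
add-one (Laplace) smoothing in its standard form: pseudo-count 1 on every
vocabulary item, denominator $N_G + V$. Two consequences are load-bearing
and are asserted by the test suite:

- $\sum_{w \in V} P(w \mid G) = 1$ exactly (checked exhaustively for
  $k \le 4$ and to $10^{-9}$ elsewhere), so scores are true
  log-likelihoods under a proper multinomial;
- unseen k-mers have probability $\frac{1}{N_G+V} > 0$, so every
  (read, genome) pair has a finite score and all reads are labelled.

One sometimes sees the smoothed estimate written with a bare $freq_G(w)$
numerator over an $N_G + V$ denominator; that variant assigns unseen
k-mers probability zero and does not normalise, so we treat it as a
notational slip of the add-one form rather than a model, and implement
$(freq+1)/(N_G+V)$ throughout.

## Vocabulary size

$V$ enters every smoothed term, so it is fixed by closed form rather than
by scanning the database:

| representation | $V$ |
|---|---|
| non-canonical | $4^k$ |
| canonical, odd $k$ | $4^k/2$ |
| canonical, even $k$ | $(4^k + 4^{k/2})/2$ |

For even $k$ the $4^{k/2}$ palindromic k-mers (equal to their own reverse
complement) have no partner to collapse with, hence the correction term;
no odd-length k-mer is palindromic. The closed forms are verified against
brute-force enumeration for $k \le 8$ in the tests. An alternative reading
would restrict $V$ to k-mers actually observed somewhere in the database;
we deliberately use the closed form — it keeps $V$ independent of database
growth, so adding a genome never silently rescales every other genome's
probabilities.

## Canonical counting

In canonical mode each window is collapsed with its reverse complement
onto the lexicographically smaller of the two (character order
`A < C < G < T` on upper-case input). This makes counting — and therefore
every score — exactly invariant to the sequenced strand:
`classifyReads(revComp(reads), db)` is bit-identical to
`classifyReads(reads, db)`. It also roughly halves the stored keys of long
genomes; on a dense random 1 Mb genome at $k=9$ the canonical count file
is ~52% of the non-canonical one (the exact fraction depends on how many
k-mers of the genome are palindromic or absent, so real genomes vary).

## Counting semantics

- Windows slide with step 1 within each FASTA record; k-mers never span
  records, because contigs are not physically contiguous.
- Any window containing a character outside `A,C,G,T` (e.g. `N`) is
  skipped entirely — not randomised, not split. This keeps counts
  deterministic and matches common k-mer tool behaviour.
- A sequence shorter than $k$ contributes nothing. A *read* with no valid
  window is still emitted in the output (score 0 against every genome,
  best genome by tie-break) with a `no_kmer_flag`, so the classifier
  labels all reads and downstream profiles conserve read mass.
- $k$ is capped at 31 so that a 2-bit packed representation remains
  possible in any future backend; typical use is $k$ around 9–15.

# The incremental database

Training is counting: one `KmerCounts` table per genome, persisted as a
plain-text `.nbk.tsv` file (five header lines — format version, k,
canonicality, genome id, total — then `kmer<TAB>count` rows in ascending
lexicographic order). The format is deliberately human-auditable and
byte-deterministic: identical counts produce identical bytes, so checksums
detect corruption and the test suite can assert that adding a genome never
rewrites an existing member's file. Zero counts are never stored;
smoothing supplies them at query time. Taxonomy lives in a separate
manifest TSV so classes and lineages can be re-assigned without
recounting.

Because each genome's file is independent, a database built by
`addGenome()` in any order is file-for-file identical to independent
`trainGenome()` runs — the incremental-equals-batch property the tests
check by checksum.

# Querying: batching, memory, determinism

Query k-mers are counted on the fly, in memory, never via temporary count
files. Reads are processed in batches (default 1000 — the input/output
buffer sizing used for short-read workloads); within a batch, evaluation
is genome-major: the batch's k-mers are assembled once into a sparse
reads-by-kmers matrix, then genome tables stream past it, each
contributing one dense log-probability vector and one sparse
matrix-vector product. This keeps each genome's table load infrequent
(once per batch at worst, once overall when the budget allows caching).

The contract that matters is *bit-identical results under all resource
settings*. Three choices enforce it:

- per (read, genome) pair the summation order is fixed: ascending
  lexicographic k-mer order (the sparse matrix's columns are the sorted
  batch vocabulary), so floating-point addition order cannot vary with
  batch composition;
- ties on the maximum break toward the ascending-lexicographic smallest
  `genome_id`, independent of evaluation order;
- threads parallelise over genome chunks and are reduced back in genome
  order; the arithmetic per pair is unchanged.

`minimumMemory()` documents the sizing model: the largest single count
file must be resident, plus a per-read input/output allowance
(`2 * read_length + 256` bytes per read in the batch). Budgets below the
minimum are refused with the computed value; larger budgets only increase
how many genome tables stay cached between batches. All log-likelihoods
are natural-log; output files print them with 17 significant digits so
repeated runs are byte-identical.

Scores are reported per *genome*, with the class attached by manifest
join, rather than pooling counts per class first: the per-genome score is
the finer-grained quantity (users can inspect the full matrix with
`mode = "full"`), and class pooling would weight genomes by length in a
way that is hard to undo downstream.

# Evaluation conventions

`metricsAtRank()` projects true and predicted classes onto one rank via
their lineages; empty rank names become the reserved label `unassigned`.

- **Micro** precision/recall pool all predictions. Since the classifier
  labels every read, each false positive for one label is a false
  negative for another, so micro-precision equals micro-recall
  identically; the suite asserts this exactly on every fixture.
- **Macro** measures average per-label values with equal weight over the
  labels *present in the truth set*. A truth label never predicted
  contributes recall 0 and precision 0; a label predicted but absent from
  the truth is excluded from the macro average. This convention must be
  stated for the numbers to be reproducible — with it, the degenerate
  all-A classifier on a balanced two-label truth gives micro 0.5,
  macro-recall 0.5, macro-precision 0.25, which the tests pin down.
- Confusion matrices are counts over the union of observed labels, rows
  true, columns predicted; row sums equal true-label counts.

`makeFolds()` shuffles the class list under a seed and takes contiguous
fifths as test folds (remainder classes to the last fold).
`runCrossValidation()` trains a per-fold database on the training-fold
genomes, simulates a fixed number of reads per test class, classifies,
and reports all 7 ranks plus the raw class level, aggregated as
mean ± sd across folds. Note an inherent property of class-holdout CV:
the held-out classes are absent from training, so class/species-level
predictions cannot be correct; those rows measure the open-set penalty,
and the informative ranks are those above the holdout level. For
verification the harness has a closed-set control
(`closed_set = TRUE`) that simulates test reads from the training-fold
genomes, where class-level recall should be — and in the tests is —
essentially 1.

# Abundance profiles and Bray–Curtis

`profileFromResults()` turns per-read best classes into a rank-level
relative-abundance vector; reads whose class has no name at the rank fall
under `unassigned`, so profiles always sum to 1 (conservation of reads).
Profiles are compared with the Bray–Curtis dissimilarity

$$BC(p, q) = 1 - \frac{2\sum_t \min(p_t, q_t)}{\sum_t p_t + \sum_t q_t}$$

over the union of taxa: 0 for identical, 1 for disjoint communities. Any
display filtering (such as hiding taxa under 2% relative abundance in a
composition plot) is applied after, never before, the comparison — the
tests cross-check the implementation against the `vegan` ecology package
to $10^{-12}$.

# The simulator: what it does and does not emulate

The generator exists so every stage is testable without downloads. It
emulates: random genomes of configurable length and GC content
(i.i.d. bases, G/C and A/T split evenly); reads of fixed length with
uniform start positions and uniform strand; independent per-base
substitutions to a uniform alternative base; and truth-tagged read ids
(`genome|start|strand|index`). Defaults are 100 reads per class, 200 bp
reads, substitution rate 0 unless specified — short-read-like conditions
where substitution is the dominant error mode.

It does **not** emulate: empirical sequencing error profiles
(position-dependent rates, indels), coverage bias, repeats or low
complexity regions, nor — most importantly — *shared evolutionary history
between genomes*. I.i.d. random genomes of this size share many k-mers by
chance at small k but have no homologous structure, so closed-set label
recovery is much easier than on real taxa: passing the recovery tests
demonstrates the scoring machinery is correct, not that the classifier
resolves closely related species. Conversely, the strand-invariance,
determinism, normalisation and incremental-equals-batch properties are
exact mathematical contracts and transfer to real data unchanged.

# Numerical and design choices, in one place

- Log base: natural. Monotone-equivalent for the argmax, but stated
  because full-mode consumers see raw values.
- Summation order per (read, genome): ascending k-mer; this is what makes
  the batching/threading/memory contract bit-exact rather than
  approximate.
- Tie-break: ascending lexicographic `genome_id`.
- Lexicographic order: C-locale byte order on upper-cased input
  (`A < C < G < T`); input sequences are upper-cased on read.
- Ambiguous-base windows skipped; zero-window reads emitted and flagged.
- Count files: sorted keys, fixed header, `\n` endings, no zero counts —
  byte-deterministic by construction.
- Degenerate inputs: empty FASTA trains an empty table with a warning
  (not an error); an empty database refuses to classify; memory budgets
  below the documented minimum are refused with the minimum in the
  message.

## Problem sizes used by the checks

The test suite and the acceptance script exercise the pipeline at sizes
chosen to be decisive yet desk-scale: vocabulary enumeration to $k = 8$;
oracle-equivalence against an independent brute-force scorer on
10 × 50 kb genomes × 100 reads at canonical 9-mers; strand invariance
over 1000 reads; closed-set recovery on 20 × 100 kb genomes × 100 reads
each; storage comparison on a 1 Mb genome; cross-validation smoke at 10
classes × 20 reads per class. At these sizes the whole suite runs in a
couple of minutes on one CPU.

# Known limitations

- Query cost grows with (number of genomes) × (reads × read k-mers);
  large databases make querying slow even though training stays cheap.
  The design optimises disk traffic, not asymptotics.
- No confidence calibration or novelty detection is built on the
  log-likelihoods yet; the full score matrix is exposed precisely so such
  measures can be computed downstream.
- No lowest-common-ancestor fallback: the classifier always predicts a
  leaf genome, and rank-level answers come from the leaf's lineage.
- The smoothing denominator makes long genomes slightly favoured a
  priori (larger $N_G$ damps the penalty of unseen k-mers more slowly
  than it boosts seen ones); with genomes of very different lengths in
  one database this bias is visible in macro measures.
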