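---
title: "Individualized germline V gene discovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized germline V gene discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vgerm)
```

## The problem

Antibody heavy chains are assembled by V(D)J recombination from germline
gene segments, and the set of V alleles differs substantially between
individuals (and is poorly catalogued outside a few model organisms).
Standard repertoire analyses assign every sequenced receptor to the
closest allele of a public database; when the individual carries an allele
the database lacks, all of its reads are misattributed to a neighbouring
allele and their germline-encoded differences are indistinguishable from
somatic hypermutation (SHM). `vgerm` infers the individualized germline V
genotype directly from an IgM (or IgK/IgL) amplicon library: IgM libraries
are dominated by naive, unmutated receptors, so every expressed germline
allele is present as a large cluster of near-identical reads that differ
only by sequencing error — separable, with enough reads, from the diffuse
cloud of SHM-mutated sequences.

## The iterative procedure

Each iteration performs four steps against the current database (which may
initially be a single sequence, or one from another species):

1. **Assignment.** Every preprocessed read is aligned to the database with
   an ends-free affine-gap aligner (match +1, mismatch −2, gap open −5,
   extend −2 per base) and assigned to the best-scoring V allele (ties:
   fewer errors, then database order); J segments are searched only 3′ of
   the V match. The percent difference to the assigned allele is computed
   over the aligned reference span, so terminal truncations do not count
   as errors. A quality filter keeps reads with both V and J assigned, no
   stop codon, E-value ≤ 10⁻³, V coverage ≥ 90% and J coverage ≥ 60%.
2. **Clustering.** Per assigned allele, reads are binned into half-open 2%
   percent-difference windows (a novel allele at, say, 3% difference forms
   a second mode to the right of the zero-difference germline peak), and a
   random subsample of up to 1,000 reads is clustered hierarchically
   (UPGMA) on pairwise Levenshtein distances. Inner tree nodes whose two
   child subtrees both hold ≥ 5 leaves are scanned: a child is reported as
   a subcluster when the ratio of its smallest internal merge height to
   its sibling's largest is < 0.8.
3. **Consensus.** Each window, subcluster, and the full per-allele read
   set yields one consensus: members are projected onto the
   highest-weight member and each column is called when a base reaches
   the inclusive 60% majority of the non-gap weight; undecided columns
   become N, gap-majority columns are deleted.
4. **Filtering.** Candidates containing N or a stop codon are discarded.
   The remaining candidates are annotated with the *exact occurrences* of
   their sequence in the full read set and the distinct CDR3 junctions and
   J genes among those reads — the signature of independent
   rearrangements that separates germline sequences from expanded clones
   and hotspot artefacts. The **germline filter** (final iteration)
   demands a cluster of ≥ 100 sequences, ≥ 10 unique CDR3s and ≥ 3 unique
   J genes; the **pregermline filter** (earlier iterations) drops the
   cluster-size gate and requires only ≥ 2 CDR3s and ≥ 2 J genes.
   Candidates within 2 internal bases of each other are collapsed (the one
   with fewer unique CDR3s is removed; ties keep the longer sequence), and
   a candidate identical to a starting-database allele is whitelisted past
   all criteria. The surviving set replaces the database.

Three iterations are run by default — a fixed count rather than a
convergence test, so runtimes are predictable; an optional early stop on
an unchanged database is available but off by default. A final assignment
pass against the finished database produces the per-allele usage profile
and the upstream (5′UTR + leader) consensus sequences used for primer
design: per allele, reads with ≤ 1% V difference whose upstream segment is
at least as long as the tenth longest contribute to a right-aligned 60%
majority consensus.

## Key parameters

| parameter | default | role |
|---|---|---|
| `iterations` | 3 | fixed iteration count; 1 suffices for a nearly complete start database |
| `window_width` | 2 (%) | percent-difference bin width for windowed clustering |
| `subsample_size` | 1000 (reads) | linkage-clustering subsample per allele |
| `min_subtree_size` / `ratio_threshold` | 5 / 0.8 | subcluster detection heuristic |
| `majority` | 0.6 | consensus majority, boundary-inclusive |
| germline gates | 100 / 10 / 3 | cluster size, unique CDR3s, unique J genes |
| pregermline gates | – / 2 / 2 | no cluster-size gate in early iterations |
| `max_near_duplicate_diff` | 2 (nt) | candidate collapse radius (internal differences) |
| `terminal_tolerance` | 10 (nt) | end-length slack when comparing candidates/databases |
| quality gates | 1e-3 / 0.90 / 0.60 | max E-value, min V coverage, min J coverage |
| `max_v_error_rate` | 0.01 | V-difference ceiling for upstream consensus support |

All thresholds are exposed as function arguments; the defaults implement
the method as published for deep (≥ ~400,000 read) IgM libraries, and a
warning (not an error) is raised for smaller inputs.

## Design choices in ambiguous corners

* **Internal aligner.** Assignment uses an internal ends-free local
  aligner plus a k-mer diagonal prescreen instead of an external
  annotation tool, keeping the package self-contained and byte-for-byte
  testable. The E-value is a Karlin–Altschul surrogate
  (`m·n·2^(−bitscore)` with the ungapped λ of the scoring scheme and K
  fixed at 0.3); it preserves the gate semantics, not BLAST's exact
  numbers.
* **Reading frame and CDR3.** The frame is inherited from the database
  allele (position 1 = codon 1, the convention of curated V databases).
  The CDR3 starts at the last cysteine within six codons upstream of the
  mapped reference FR3 end and runs to the first W-G-x-G (heavy) or
  F-G-x-G (light) anchor downstream; both motifs are configurable through
  the `chain` argument. The published description cites a regular
  expression without printing it, so this anchor definition is our
  interpretation.
* **Window bins are half-open** `[2k, 2k+2)`; the bin-edge convention is
  not stated in the original description.
* **Subcluster ratio.** "Smallest distance in one subtree / largest in the
  other" is read as the ratio of internal *merge heights* (cophenetic),
  with leaves contributing height 0 so that tight, near-identical bundles
  are maximally detectable. All qualifying subtrees are reported,
  including nested ones: fragments of one read population converge to the
  same consensus and are deduplicated (keeping the largest cluster size),
  while heterogeneous ancestor subtrees produce N-containing consensi
  that the filter discards. Enforcing disjoint subclusters instead either
  hides pure per-allele bundles behind mixed ancestors or fragments them
  below the 100-sequence gate — both demonstrably break deleted-allele
  recovery when several alleles of one family are missing from the
  starting database.
* **Consensus by center-star projection.** Members are aligned to the
  highest-weight (then longest) member rather than through a full
  progressive multiple alignment; for the near-identical members of a
  window or subcluster the two are equivalent, and insertions relative to
  the center (absent from amplicon data at these error rates) are
  ignored. The majority threshold is inclusive and dereplication counts
  weight the votes.
* **Counting conventions.** Cluster sizes count distinct member sequences
  (not raw read copies); exact-occurrence matching is strict string
  equality by default with an optional terminal-tolerant mode;
  near-duplicate collapse uses terminal-tolerant internal differences.
  The whitelist compares against the *run's* starting database
  (iteration 0), so known alleles expressed at low levels survive even
  when evidence is thin.
* **Name continuity.** A kept candidate identical to an input-database
  allele inherits that allele's name; discovered alleles are named
  `<source>_S<4-digit sequence hash>`. This is cosmetic (comparisons are
  sequence-based) but keeps converged iterations byte-identical.

## The simulator and what passing tests mean

`sim_germline_db()` builds allele families from a common ancestor (~20%
codon divergence between families, ~8 nt between same-family alleles,
drawn only at interior positions because the FR1 start and the 3′
YYC-cysteine motif are strongly conserved in real V genes; alleles are
kept ≥ 4 internal differences apart so that distinct alleles are not
merged by the near-duplicate collapse, which is a stated limitation of
the method for 1–2 nt allele pairs). `sim_repertoire()` then emits reads
of the form 5′UTR+leader / trimmed V / junction / trimmed J with a
naive/mutated mixture (naive fraction 0.55 by default), geometric SHM
counts (mean 4) at uniform V positions, and independent per-base
substitution errors (0.3%, representative of a well-behaved short-read
platform whose raw error is ~1%); junction lengths are adjusted so the J
anchor stays in frame and junctions that create stop codons are redrawn,
emulating productive rearrangements. Every read is logged in a truth
ledger (source alleles, planted CDR3, SHM and error counts, trim
lengths), which is what the test suite uses as its exact oracle.
`inject_artefacts()` adds the two confounders the germline filter exists
to reject: clonal expansions (one junction, many copies) and recurrent
hotspot substitutions spread over fewer than ten junctions.

The simulator deliberately omits indel sequencing errors, indel SHM,
biased SHM hotspot targeting in the background reads, chimeric (PCR
crossover) reads and expression skew beyond user-supplied weights. Tests
passing on this model therefore demonstrate the *logic* of the method —
recovery, specificity, invariance to the starting database and subsample
seed — not its performance on any particular instrument's error profile.

## Numerical and performance notes

Levenshtein distances use a bit-parallel dynamic program (exact; a banded
variant is used when a cheap upper bound proves the distance small, with
the full computation as fallback). UPGMA is average-linkage `hclust`;
merge heights are checked against brute-force average linkage in the test
suite. Alignment uses a 16-column band around the best k-mer diagonal
during batch assignment (full dynamic programming in `align_to_allele()`
and whenever seeding fails); assignment passes and linkage distance
matrices are memoised across iterations, which makes converged iterations
nearly free. The test-suite scenarios use a 50,000-read, 20-allele
library — large enough that every expressed allele clears the
100-sequence germline gate with a wide margin, and small enough to run
routinely on a laptop core.

## Limitations

Alleles differing by ≤ 2 internal bases are collapsed by design; alleles
expressed at very low levels can fall below the evidence gates (the
whitelist mitigates this only for known sequences); duplicated genes with
identical sequences are reported once; and D segments are not assigned
(they play no role in any filter). Shallow libraries reduce recall before
they reduce precision — the evidence gates fail closed.
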