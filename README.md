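# vgerm — individualized germline V gene discovery from repertoire sequencing

Antibody repertoires are sequenced by the million, but every analysis
starts by assigning each V(D)J read to a germline V allele from a public
database — and germline V genotypes vary so much between individuals (and
are so incomplete outside humans and mice) that the database is usually
wrong for the person or animal actually sequenced. Reads from a missing
allele are silently attributed to its nearest relative, with the
germline-encoded differences misread as somatic hypermutation (SHM).

`vgerm` infers the individualized germline V genotype directly from an
IgM (or IgK/IgL) amplicon library, starting from *any* V database — a
single sequence or a wrong-species set suffices. It is aimed at
immunogenetics and AIRR-seq researchers who need per-individual V
databases before downstream repertoire analysis, and it ships a
repertoire simulator with a per-read truth ledger so the whole method is
testable without any external data.

## The method

IgM libraries are dominated by naive, unmutated receptors, so each
expressed germline allele appears as a large cluster of near-identical
reads. Each iteration (3 by default):

1. assigns every read to its closest database allele V (ends-free affine
   alignment: match +1, mismatch −2, gap −5 − 2·L), finds J 3′ of V,
   detects the CDR3 at the amino-acid level (Cys ... W-G-x-G), and keeps
   reads with E ≤ 10⁻³, V coverage ≥ 90%, J coverage ≥ 60% and no stop;
2. clusters the reads of each allele — 2% percent-difference windows,
   plus UPGMA on Levenshtein distances of a 1,000-read subsample with a
   subtree heuristic (both children ≥ 5 leaves, height ratio < 0.8);
3. builds a 60%-majority consensus per cluster;
4. validates candidates by the evidence of independent rearrangements:
   the **germline filter** requires a cluster of ≥ 100 sequences whose
   exact occurrences use ≥ 10 distinct CDR3s and ≥ 3 distinct J genes
   (≥ 2 / ≥ 2 and no size gate for the *pregermline* filter of earlier
   iterations), collapses candidates ≤ 2 bases apart, and whitelists
   candidates identical to a starting-database sequence.

The filtered set replaces the database and the loop repeats; a final
assignment pass yields per-allele usage profiles and upstream
(5′UTR + leader) consensus sequences for primer design.

## Worked example

Simulate an 8-allele repertoire, hide one allele from the starting
database, and rediscover it:

```r
library(vgerm)

v_truth <- sim_germline_db(n_alleles = 8, n_families = 2, seed = 3)
j_db    <- sim_j_db(seed = 3)
lib     <- sim_repertoire(v_truth, j_db, n_reads = 6000, seed = 5)
reads   <- preprocess_reads(lib$reads, min_length = 300)

start <- v_truth[v_truth$name != "V1.2", ]   # pretend V1.2 is unknown
res <- discover_germline(reads, start, j_db, iterations = 1, seed = 1)
print(res)
#> Individualized germline V database
#>   1 iterations on 6000 reads, starting from 7 alleles
#>   final database: 8 alleles (7 whitelisted, 1 discovered)
#>   expressed alleles in final assignment: 8
compare_databases(res$final_db, v_truth)
#> database comparison: 8 shared, 0 only in a, 0 only in b
head(res$usage, 4)
#> # A tibble: 4 x 3
#>   name  n_reads n_unique_cdr3
#> 1 V2.4      652           635
#> 2 V2.1      664           643
#> 3 V2.3      666           634
#> 4 V1.1      691           655
```

The missing allele returns exactly (8 shared, nothing extra): its ~750
reads were assigned to a family neighbour at ~3% difference, formed a
clean window/linkage cluster whose consensus matched hundreds of exact
occurrences with hundreds of distinct CDR3s across 4 J genes — germline
evidence no SHM artefact can fake. (A run of this size warns that real
genotyping needs ~400,000 reads; `tidy(res)` shows every candidate with
its evidence counts and filter verdict, `autoplot(res)` the usage
profile.)

A thin command line wraps the same functions:

```sh
inst/exec/vgerm simulate --out sim --n-reads 50000 --seed 1
inst/exec/vgerm run --reads sim/reads.fastq --database sim/truth_V.fasta \
    --j-database sim/truth_J.fasta --iterations 3 --out run1
inst/exec/vgerm compare run1/new_V_germline.fasta sim/truth_V.fasta
```

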