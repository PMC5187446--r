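`%||%` <- function(x, y) if (is.null(x)) y else x

# memoised fixtures shared across test files (built once per test run)
.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

small_vdb <- function() fixture("small_vdb", sim_germline_db(
  n_alleles = 8, n_families = 2, seed = 3))

small_jdb <- function() fixture("small_jdb", sim_j_db(seed = 3))

small_sim <- function() fixture("small_sim", sim_repertoire(
  small_vdb(), small_jdb(), n_reads = 6000, seed = 5))

small_reads <- function() fixture("small_reads", suppressWarnings(
  preprocess_reads(small_sim()$reads, min_length = 300)))

small_assign <- function() fixture("small_assign", {
  quality_filter(assign_vj(small_reads(), small_vdb(), small_jdb()))
})

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random open reading frame (no stop codons in frame 1)
rand_orf <- function(n_codons = 96) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste,
                  collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

mutate_dna <- function(s, k) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), k)
  ch[pos] <- vapply(ch[pos], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  paste(ch, collapse = "")
}

# brute-force average-linkage oracle: returns the sorted merge heights
upgma_oracle_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, j, i)
      }
    }
    heights <- c(heights, best[1])
    i <- best[3]; j <- best[2]
    clusters[[j]] <- c(clusters[[j]], clusters[[i]])
    clusters[[i]] <- NULL
  }
  sort(heights)
}

# reference local alignment score with the package's affine gap convention
pairwise_score <- function(a, b, match = 1, mismatch = -2, gap_open = 5,
                           gap_extend = 2) {
  as.numeric(Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch),
    gapOpening = gap_open, gapExtension = gap_extend)))
}

# minimal assignment-table row for filter unit tests
fake_assignment <- function(v_name = "V1", v_coverage = 1, j_name = "J1",
                            j_coverage = 1, has_stop = FALSE,
                            v_evalue = 1e-10, v_sequence = "ACGT",
                            cdr3_nt = "TGTAAA", count = 1L,
                            v_percent_difference = 0,
                            upstream_sequence = "") {
  tibble::tibble(query_id = "q", count = count, sequence = v_sequence,
                 v_name = v_name, v_score = 100L, v_evalue = v_evalue,
                 v_coverage = v_coverage, v_errors = 0L,
                 v_percent_difference = v_percent_difference,
                 v_sequence = v_sequence,
                 upstream_sequence = upstream_sequence,
                 v_qstart = 1L, v_qend = nchar(v_sequence), v_rstart = 1L,
                 v_rend = nchar(v_sequence), j_name = j_name,
                 j_score = 50L, j_coverage = j_coverage, cdr3_nt = cdr3_nt,
                 cdr3_aa = "CX", has_stop = has_stop)
}
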