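test_that("a complete starting database is a fixpoint of discovery", {
  res <- fixture("small_run", suppressWarnings(discover_germline(
    small_reads(), small_vdb(), small_jdb(), iterations = 1, seed = 1)))
  cmp <- compare_databases(res$final_db, small_vdb())
  expect_identical(nrow(cmp$only_a), 0L)
  expect_identical(nrow(cmp$only_b), 0L)
  # final database invariants: no N, no stop codon in the reading frame
  expect_false(any(grepl("N", res$final_db$sequence, fixed = TRUE)))
  expect_false(any(grepl("\\*",
                         vgerm:::translate_nt(res$final_db$sequence))))
})

test_that("deleted alleles are re-discovered from their family neighbours", {
  db <- small_vdb()
  start <- db[db$name != "V1.2", ]
  res <- suppressWarnings(discover_germline(small_reads(), start,
                                            small_jdb(), iterations = 1,
                                            seed = 1))
  expect_true(db$sequence[db$name == "V1.2"] %in% res$final_db$sequence)
  cmp <- compare_databases(res$final_db, db)
  expect_identical(nrow(cmp$only_a), 0L)
})

test_that("usage profiles conserve read counts and include zero rows", {
  res <- fixture("small_run", suppressWarnings(discover_germline(
    small_reads(), small_vdb(), small_jdb(), iterations = 1, seed = 1)))
  expect_identical(sum(res$usage$n_reads),
                   as.integer(sum(res$final_assignments$count)))
  # an allele nothing is assigned to appears with zeros
  ghost <- dplyr::bind_rows(res$final_db,
                            tibble::tibble(name = "ghost",
                                           sequence = rand_dna(290),
                                           source = "starting"))
  u <- usage_profile(ghost, res$final_assignments)
  expect_identical(u$n_reads[u$name == "ghost"], 0L)
  expect_identical(u$n_unique_cdr3[u$name == "ghost"], 0L)
})

test_that("upstream consensus recovers the planted 5'UTR and leader", {
  sim <- fixture("upstream_sim", sim_repertoire(
    small_vdb(), small_jdb(), n_reads = 2000, error_rate = 0.001,
    seed = 19))
  asn <- quality_filter(assign_vj(sim$reads, small_vdb(), small_jdb()))
  up <- detect_upstream(asn, max_v_error_rate = 0.01)
  planted <- setNames(small_vdb()$upstream, small_vdb()$name)
  hits <- up$upstream_consensus == planted[up$name]
  expect_true(all(hits[up$n_supporting >= 50]))
  expect_false(any(grepl("N", up$upstream_consensus[up$n_supporting >= 10],
                         fixed = TRUE)))
})

test_that("the tenth-longest rule sets the upstream support cutoff", {
  mk <- function(upstreams) {
    dplyr::bind_rows(lapply(upstreams, function(u) {
      fake_assignment(upstream_sequence = u, v_percent_difference = 0)
    }))
  }
  # 15 reads: 12 share the full upstream, 3 are deeply truncated with a
  # different residual base; only reads >= the 10th longest contribute
  full <- strrep("A", 30)
  rows <- mk(c(rep(full, 12), rep(strrep("G", 5), 3)))
  up <- detect_upstream(rows)
  expect_identical(up$upstream_consensus, full)
  expect_identical(up$n_supporting, 12L)
  # with 9 reads, the shortest one sets the cutoff and all are used
  rows9 <- mk(c(rep(full, 8), strrep("G", 5)))
  up9 <- detect_upstream(rows9)
  expect_identical(up9$n_supporting, 9L)
})

test_that("database comparison partitions by tolerant identity", {
  db <- small_vdb()
  cmp <- compare_databases(db, db)
  expect_identical(nrow(cmp$shared), nrow(db))
  other <- tibble::tibble(name = c("x", "y"),
                          sequence = replicate(2, rand_dna(290)))
  cmp2 <- compare_databases(db, other)
  expect_identical(nrow(cmp2$shared), 0L)
  # a 2-nt-truncated variant counts as shared under tolerance 3
  trunc <- db
  trunc$sequence[1] <- substr(trunc$sequence[1], 1,
                              nchar(trunc$sequence[1]) - 2)
  cmp3 <- compare_databases(db, trunc, tolerance = 3)
  expect_identical(nrow(cmp3$shared), nrow(db))
})

test_that("discovery results expose tidy, glance and plot methods", {
  res <- fixture("small_run", suppressWarnings(discover_germline(
    small_reads(), small_vdb(), small_jdb(), iterations = 1, seed = 1)))
  td <- generics::tidy(res)
  expect_true(all(c("name", "sequence", "passed", "reason") %in% names(td)))
  gl <- generics::glance(res)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_final_alleles, nrow(res$final_db))
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  expect_s3_class(plot_usage(res$usage), "ggplot")
  expect_s3_class(plot_difference_histogram(res$final_assignments),
                  "ggplot")
  expect_output(print(res), "final database")
})

test_that("FASTA/FASTQ round-trips preserve sequences and counts", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  db <- small_vdb()
  write_fasta(db, fa)
  back <- read_germline_db(fa)
  expect_identical(back$name, db$name)
  expect_identical(back$sequence, db$sequence)
  # dereplication counts survive via size annotations
  reads <- tibble::tibble(id = c("a", "b"),
                          sequence = c("ACGTACGT", "GGGTTTAA"),
                          count = c(5L, 1L))
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(reads, fa2, size_annotations = TRUE)
  back2 <- read_sequences(fa2)
  expect_identical(back2$count, c(5L, 1L))
  # FASTQ with qualities
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
  r <- read_sequences(fq)
  expect_identical(r$sequence, "ACGT")
  expect_identical(r$quality, "IIII")
})

test_that("discovery writes its result files", {
  res <- fixture("small_run", suppressWarnings(discover_germline(
    small_reads(), small_vdb(), small_jdb(), iterations = 1, seed = 1)))
  dir <- withr::local_tempdir()
  write_discovery_results(res, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "new_V_germline.fasta", "candidates.tsv", "usage_profile.tsv",
    "upstream.tsv", "run_log.txt")))))
  expect_identical(nrow(read_germline_db(file.path(
    dir, "new_V_germline.fasta"))), nrow(res$final_db))
})
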