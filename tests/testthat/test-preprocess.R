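test_that("read pairs merge at the best overlap and fail without one", {
  # revcomp("AAAAACGT") = "ACGTTTTT": true overlap ACGT at offset 4
  expect_identical(merge_read_pair("ACGTACGT", "AAAAACGT", min_overlap = 4),
                   "ACGTACGTTTTT")
  # no overlap of at least min_overlap exists
  expect_true(is.na(merge_read_pair("ACGTACGT", "AAAAACGT",
                                    min_overlap = 7)))
  # overlap disagreements resolved towards the higher quality base
  fwd <- "ACGTACGT"; rev <- "AAAAACTT"  # revcomp: AAGTTTTT, mismatch at pos 2
  hi_rev <- merge_read_pair(fwd, rev, forward_quality = "!!!!!!!!",
                            reverse_quality = "IIIIIIII", min_overlap = 4,
                            max_overlap_mismatch = 0.3)
  hi_fwd <- merge_read_pair(fwd, rev, forward_quality = "IIIIIIII",
                            reverse_quality = "!!!!!!!!", min_overlap = 4,
                            max_overlap_mismatch = 0.3)
  expect_identical(substr(hi_rev, 6, 6), "A")
  expect_identical(substr(hi_fwd, 6, 6), "C")
  # forward base wins without qualities (tie rule)
  expect_identical(substr(merge_read_pair(fwd, rev, min_overlap = 4,
                                          max_overlap_mismatch = 0.3), 6, 6),
                   "C")
})

test_that("simulated 2x300 pairs from 550 nt amplicons merge accurately", {
  withr::with_seed(31, {
    amplicons <- replicate(500, rand_dna(550))
  })
  pairs <- sim_read_pairs(amplicons, read_length = 300, error_rate = 0.003,
                          seed = 32)
  merged <- merge_read_pairs(pairs$forward, pairs$reverse)
  log <- attr(merged, "merge_log")
  expect_gte(log$n_merged / log$n_pairs, 0.99)
  tr <- pairs$truth[match(merged$id, pairs$truth$id), ]
  # merging adds no error beyond the planted sequencing errors
  d <- levenshtein(merged$sequence, tr$amplicon)
  expect_true(all(d <= tr$errors_forward + tr$errors_reverse))
  expect_gte(mean(d <= 4), 0.95)
})

test_that("primer trimming is anchored, mismatch-tolerant and optional", {
  reads <- tibble::tibble(id = "r", sequence = paste0("ACGTACGTAC", "GGTT"))
  expect_identical(trim_primers(reads, primers_5p = "ACGTACGTAC")$sequence,
                   "GGTT")
  expect_identical(trim_primers(reads)$sequence, reads$sequence)
  # one mismatch in a 20-base primer is tolerated
  primer <- strrep("AC", 10)
  seq20 <- paste0(sub("^AC", "AG", primer), "TTTT")
  out <- trim_primers(tibble::tibble(id = "r", sequence = seq20),
                      primers_5p = primer)
  expect_identical(out$sequence, "TTTT")
  # but a 9-base primer tolerates none
  out2 <- trim_primers(tibble::tibble(id = "r", sequence = "ACGTACGTTTTTT"),
                       primers_5p = "ACGTACGTC")
  expect_identical(out2$sequence, "ACGTACGTTTTTT")
  # 3' trimming
  out3 <- trim_primers(tibble::tibble(id = "r", sequence = "TTTTACGT"),
                       primers_3p = "ACGT")
  expect_identical(out3$sequence, "TTTT")
})

test_that("length filter keeps exactly the reads at or above the cutoff", {
  reads <- tibble::tibble(id = c("a", "b", "c"),
                          sequence = vapply(c(299, 300, 301), rand_dna,
                                            character(1)))
  expect_identical(filter_length(reads, 300)$id, c("b", "c"))
  expect_identical(filter_length(reads, 0), tibble::as_tibble(
    vgerm:::check_reads(reads)))
  withr::with_seed(8, {
    many <- tibble::tibble(id = as.character(1:1000),
                           sequence = vapply(sample(250:350, 1000, TRUE),
                                             rand_dna, character(1)))
  })
  expect_identical(nrow(filter_length(many, 300)),
                   sum(nchar(many$sequence) >= 300))
})

test_that("dereplication collapses identical sequences and conserves reads", {
  reads <- tibble::tibble(id = c("a", "b", "c"),
                          sequence = c("ACGT", "ACGT", "GGTT"))
  out <- dereplicate(reads)
  expect_identical(out$sequence, c("ACGT", "GGTT"))
  expect_identical(out$count, c(2L, 1L))
  expect_identical(out$id, c("a", "c"))
  # all-unique input is the identity (counts 1)
  uniq <- tibble::tibble(id = as.character(1:5),
                         sequence = vapply(rep(30, 5), rand_dna,
                                           character(1)))
  expect_identical(dereplicate(uniq)$count, rep(1L, 5))
  # conservation and hash-map recount on a library with planted duplicates
  withr::with_seed(9, {
    pool <- replicate(40, rand_dna(50))
    lib <- tibble::tibble(id = as.character(1:500),
                          sequence = sample(pool, 500, replace = TRUE))
  })
  out <- dereplicate(lib)
  expect_identical(sum(out$count), 500L)
  recount <- table(lib$sequence)
  expect_identical(out$count[order(out$sequence)],
                   as.integer(recount[order(names(recount))]))
})

test_that("length filter and dereplication commute as multisets", {
  withr::with_seed(10, {
    pool <- c(replicate(10, rand_dna(295)), replicate(10, rand_dna(305)))
    lib <- tibble::tibble(id = as.character(1:300),
                          sequence = sample(pool, 300, replace = TRUE))
  })
  a <- filter_length(dereplicate(lib), 300)
  b <- dereplicate(filter_length(lib, 300))
  key <- function(x) paste(x$sequence, x$count)[order(x$sequence)]
  expect_identical(key(a), key(b))
})

test_that("preprocessing drops N-rich reads and logs stage counts", {
  good <- rand_dna(310)
  bad <- paste0(strrep("N", 50), rand_dna(260))
  reads <- tibble::tibble(id = c("g", "n"), sequence = c(good, bad))
  out <- suppressWarnings(preprocess_reads(reads, min_length = 300))
  expect_identical(out$id, "g")
  log <- attr(out, "preprocess_log")
  expect_identical(log$reads[log$stage == "input"], 2L)
  expect_identical(log$reads[log$stage == "unique"], 1L)
})
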