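test_that("percent-difference windows use half-open bins", {
  rows <- dplyr::bind_rows(lapply(c(0.0, 1.9, 2.0, 3.5), function(p) {
    fake_assignment(v_percent_difference = p, v_sequence = rand_dna(30))
  }))
  w <- windowed_clusters(rows, width = 2, min_members = 1)
  expect_identical(w$bin_lo, c(0, 2))
  expect_identical(w$n_members, c(2L, 2L))
  # every read contributes to exactly one bin
  expect_identical(sum(w$n_reads), 4L)
  # empty input, empty output
  expect_identical(nrow(windowed_clusters(rows[0, ])), 0L)
})

test_that("subsampling is uniform, reproducible and the identity when small", {
  asn <- dplyr::bind_rows(replicate(500, fake_assignment(), simplify = FALSE))
  expect_identical(subsample_assignments(asn, n = 1000, seed = 1), asn)
  big <- dplyr::bind_rows(replicate(2000, fake_assignment(),
                                    simplify = FALSE))
  big$query_id <- as.character(seq_len(nrow(big)))
  s1 <- subsample_assignments(big, n = 300, seed = 7)
  s2 <- subsample_assignments(big, n = 300, seed = 7)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 300L)
  # inclusion frequency of each element is ~ n/N across seeds
  hits <- numeric(nrow(big))
  for (s in 1:100) {
    idx <- subsample_assignments(dplyr::mutate(big, row = seq_len(nrow(big))),
                                 n = 300, seed = s)$row
    hits[idx] <- hits[idx] + 1
  }
  p <- 300 / 2000
  ci <- qbinom(c(0.0005, 0.9995), 100, p)  # binomial 99.9% envelope
  expect_gt(mean(hits >= ci[1] & hits <= ci[2]), 0.99)
})

test_that("levenshtein distance matches the DP oracle and its axioms", {
  expect_identical(levenshtein("ACGT", "ACGT"), 0L)
  expect_identical(levenshtein("ACGT", "AGT"), 1L)
  withr::with_seed(51, {
    for (i in 1:1000) {
      a <- rand_dna(sample(0:60, 1)); b <- rand_dna(sample(0:60, 1))
      expect_identical(levenshtein(a, b), as.integer(adist(a, b)))
    }
    # symmetry and triangle inequality
    s <- replicate(20, rand_dna(40))
    m <- levenshtein_matrix(s)
    expect_identical(m, t(m))
    for (k in 1:20) expect_true(all(m <= outer(m[, k], m[k, ], "+")))
  })
})

test_that("upgma reproduces closed-form and brute-force average linkage", {
  d2 <- matrix(c(0, 5, 5, 0), 2)
  expect_equal(upgma(d2)$height, 5)
  d3 <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3)
  expect_equal(sort(upgma(d3)$height), c(2, 8))
  withr::with_seed(52, {
    for (i in 1:100) {
      n <- sample(4:12, 1)
      m <- matrix(0, n, n)
      m[upper.tri(m)] <- runif(n * (n - 1) / 2, 1, 100)
      m <- m + t(m)
      tree <- upgma(m)
      expect_true(all(diff(tree$height) >= -1e-9))  # UPGMA monotone
      expect_equal(sort(tree$height), upgma_oracle_heights(m))
    }
  })
  expect_error(upgma(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("subcluster detection separates tight bundles and skips stars", {
  # two bundles of 6 near-identical leaves joined at height 10
  n <- 12
  d <- matrix(10, n, n)
  for (g in list(1:6, 7:12)) d[g, g] <- 1
  diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.5  # give each bundle some internal spread
  d[7, 8] <- d[8, 7] <- 0.5
  sub <- detect_subclusters(upgma(d))
  leafsets <- lapply(sub$members, identity)
  expect_true(any(vapply(leafsets, identical, logical(1), 1:6)))
  expect_true(any(vapply(leafsets, identical, logical(1), 7:12)))
  # star: equidistant leaves have ratio 1, nothing is reported
  star <- matrix(7, 10, 10); diag(star) <- 0
  expect_identical(nrow(detect_subclusters(upgma(star))), 0L)
  # both subtrees must have at least min_size leaves
  d46 <- matrix(10, 10, 10)
  d46[1:4, 1:4] <- 1; d46[5:10, 5:10] <- 1; diag(d46) <- 0
  d46[1, 2] <- d46[2, 1] <- 0.5; d46[5, 6] <- d46[6, 5] <- 0.5
  sub46 <- detect_subclusters(upgma(d46), min_size = 5)
  expect_false(any(vapply(sub46$members, identical, logical(1), 1:4)))
})

test_that("consensus applies the inclusive 60% majority per column", {
  expect_identical(consensus_sequence(rep("ACGTT", 10)), "ACGTT")
  members <- c(rep("AAAA", 6), rep("AGAA", 4))
  expect_identical(consensus_sequence(members), "AAAA")     # 6/10 >= 0.6
  members55 <- c(rep("AAAA", 5), rep("AGAA", 5))
  expect_identical(consensus_sequence(members55), "ANAA")   # 5/10 < 0.6
  # dereplication counts weight the votes
  expect_identical(consensus_sequence(c("AAAA", "AGAA"), weights = c(6, 4)),
                   "AAAA")
})

test_that("consensus of reads from one allele recovers it exactly", {
  withr::with_seed(53, {
    for (trial in 1:5) {
      allele <- rand_dna(290)
      members <- vapply(1:25, function(i) {
        k <- rbinom(1, 290, 0.01)
        if (k == 0) allele else mutate_dna(allele, k)
      }, character(1))
      expect_identical(consensus_sequence(members), allele)
    }
  })
})

test_that("candidate discovery finds both database and novel alleles", {
  asn <- small_assign()
  cand <- discover_candidates(asn, seed = 2)
  expect_true(all(small_vdb()$sequence %in% cand$sequence))
  expect_true(all(cand$cluster_size >= 1L))
  expect_false(any(duplicated(cand$sequence)))
})
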