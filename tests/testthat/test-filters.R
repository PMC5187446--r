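test_that("terminal-tolerant comparison ignores small end differences", {
  expect_identical(equal_with_terminal_tolerance("ACGTACGT", "ACGTACGT", 3),
                   tibble::tibble(equal = TRUE, diffs = 0L))
  # two trailing bases missing are not errors under tolerance 3
  expect_true(equal_with_terminal_tolerance("ACGTACGT", "ACGTAC", 3)$equal)
  r <- equal_with_terminal_tolerance("ACGTACGT", "ACCTACGT", 3)
  expect_false(r$equal); expect_identical(r$diffs, 1L)
  # a length difference beyond the tolerance is incomparable
  r2 <- equal_with_terminal_tolerance("ACGTACGTACGT", "ACGT", 3)
  expect_false(r2$equal); expect_true(is.na(r2$diffs))
  # overhang may be split across both ends
  expect_true(equal_with_terminal_tolerance("AAACGTACGTTT", "ACGTACGT",
                                            3)$equal)
})

make_candidates <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(name = r$name, source_allele = "V1", origin = "window",
                   sequence = r$sequence,
                   cluster_size = r$cluster_size %||% 500L,
                   exact_occurrences = r$occ %||% 500L,
                   unique_cdr3 = r$cdr3 %||% 50L,
                   unique_j = r$j %||% 4L)
  }))
}

test_that("candidate evidence is counted from exact occurrences", {
  seqs <- c(a = rand_dna(60), b = rand_dna(60))
  asn <- dplyr::bind_rows(
    fake_assignment(v_sequence = seqs["a"], cdr3_nt = "TGTAAA",
                    j_name = "J1", count = 3L),
    fake_assignment(v_sequence = seqs["a"], cdr3_nt = "TGTCCC",
                    j_name = "J2", count = 2L),
    fake_assignment(v_sequence = seqs["a"], cdr3_nt = "TGTCCC",
                    j_name = "J2", count = 1L))
  cand <- make_candidates(list(name = "hit", sequence = seqs[["a"]]),
                          list(name = "miss", sequence = seqs[["b"]]))
  ann <- annotate_candidates(cand[, 1:5], asn)
  expect_identical(ann$exact_occurrences, c(6L, 0L))
  expect_identical(ann$unique_cdr3, c(2L, 0L))
  expect_identical(ann$unique_j, c(2L, 0L))
  # a clonal expansion: many reads, a single CDR3
  clonal <- dplyr::bind_rows(replicate(200, fake_assignment(
    v_sequence = seqs["b"], cdr3_nt = "TGTGGG"), simplify = FALSE))
  ann2 <- annotate_candidates(cand[2, 1:5], clonal)
  expect_identical(ann2$exact_occurrences, 200L)
  expect_identical(ann2$unique_cdr3, 1L)
})

test_that("near-duplicate collapse keeps the best-supported candidate", {
  withr::with_seed(61, a <- rand_dna(290))
  a1 <- mutate_dna(a, 1)
  cand <- make_candidates(list(name = "A", sequence = a, cdr3 = 50L),
                          list(name = "A1", sequence = a1, cdr3 = 4L))
  expect_identical(collapse_near_duplicates(cand)$name, "A")
  # three differences apart: both kept
  far <- make_candidates(list(name = "A", sequence = a, cdr3 = 50L),
                         list(name = "B", sequence = mutate_dna(a, 3),
                              cdr3 = 4L))
  expect_identical(nrow(collapse_near_duplicates(far)), 2L)
  # chain A~B~C with pairwise <= 2: only the best survives (fixpoint)
  withr::with_seed(62, {
    b <- mutate_dna(a, 1)
    ch <- strsplit(b, "")[[1]]
    p <- which(strsplit(a, "")[[1]] == ch)[1]  # mutate a fresh position
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    cc <- paste(ch, collapse = "")
  })
  chain <- make_candidates(list(name = "A", sequence = a, cdr3 = 50L),
                           list(name = "B", sequence = b, cdr3 = 10L),
                           list(name = "C", sequence = cc, cdr3 = 5L))
  expect_identical(collapse_near_duplicates(chain)$name, "A")
  # tie on CDR3 count keeps the longer sequence
  tie <- make_candidates(list(name = "long", sequence = a, cdr3 = 5L),
                         list(name = "short",
                              sequence = substr(a, 1, 288), cdr3 = 5L))
  expect_identical(collapse_near_duplicates(tie)$name, "long")
})

test_that("the germline filter applies its thresholds boundary-inclusively", {
  withr::with_seed(63, seqs <- replicate(6, rand_orf(96)))
  at <- function(name, seq, cs, cdr3, j) {
    list(name = name, sequence = seq, cluster_size = cs, cdr3 = cdr3, j = j)
  }
  cand <- make_candidates(
    at("pass", seqs[1], 100L, 10L, 3L),
    at("small", seqs[2], 99L, 10L, 3L),
    at("fewcdr3", seqs[3], 100L, 9L, 3L),
    at("fewj", seqs[4], 100L, 10L, 2L))
  db <- apply_germline_filter(cand, "germline")
  expect_identical(db$name, "pass")
  tab <- attr(db, "candidates")
  expect_identical(tab$reason[match(c("small", "fewcdr3", "fewj"),
                                    tab$name)],
                   c("cluster_size", "unique_cdr3", "unique_j"))
  # pregermline: no cluster-size gate, >=2 CDR3s and >=2 J genes
  cand2 <- make_candidates(at("ok", seqs[1], 1L, 2L, 2L),
                           at("lone", seqs[2], 500L, 1L, 2L))
  expect_identical(apply_germline_filter(cand2, "pregermline")$name, "ok")
  # disabling the J criterion rescues exactly the low-J candidate
  db_noj <- apply_germline_filter(cand, "germline", j_criterion = FALSE)
  expect_setequal(db_noj$name, c("pass", "fewj"))
})

test_that("whitelisting bypasses the evidence criteria", {
  withr::with_seed(64, wl <- rand_orf(96))
  start <- tibble::tibble(name = "V7", sequence = wl)
  cand <- make_candidates(list(name = "V7_S0001", sequence = wl, cdr3 = 1L,
                               cluster_size = 1L, j = 0L))
  cand$exact_occurrences <- 1L
  db <- apply_germline_filter(cand, "germline", starting_db = start)
  expect_identical(db$name, "V7")           # keeps the database name
  expect_identical(db$source, "whitelisted")
})

test_that("candidates with N or stop codons are rejected up front", {
  withr::with_seed(65, good <- rand_dna(291))
  amb <- paste0(substr(good, 1, 100), "N", substr(good, 102, 291))
  stopseq <- paste0(substr(good, 1, 99), "TAA", substr(good, 103, 291))
  cand <- make_candidates(list(name = "amb", sequence = amb),
                          list(name = "stop", sequence = stopseq))
  db <- suppressWarnings(apply_germline_filter(cand, "germline"))
  expect_identical(nrow(db), 0L)
  tab <- attr(db, "candidates")
  expect_identical(tab$reason, c("ambiguous_bases", "stop_codon"))
})

test_that("the germline filter is idempotent and stricter than pregermline", {
  asn <- small_assign()
  cand <- annotate_candidates(discover_candidates(asn, seed = 2), asn)
  g <- apply_germline_filter(cand, "germline", starting_db = small_vdb())
  p <- apply_germline_filter(cand, "pregermline", starting_db = small_vdb())
  expect_true(all(g$sequence %in% p$sequence))  # monotone strictness
  # filtering the surviving candidates again changes nothing
  tab <- attr(g, "candidates")
  again <- apply_germline_filter(tab[tab$passed, names(cand)], "germline",
                                 starting_db = small_vdb())
  expect_setequal(again$sequence, g$sequence)
})
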