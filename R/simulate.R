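# Synthetic IgM-like repertoire simulation with a per-read truth ledger.
#
# Reads are built as 5'UTR+leader, a (possibly 3'-trimmed) germline V, a
# random junction insert, and a (possibly 5'-trimmed) J, with SHM
# substitutions on the V region of non-naive reads and independent per-base
# sequencing errors. Junction lengths are chosen so that the J anchor stays
# in the V reading frame (productive rearrangements), and junctions creating
# stop codons are redrawn.

STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_pool <- function() {
  all <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  setdiff(all, STOP_CODONS)
}

split_codons <- function(s) {
  n <- nchar(s) - nchar(s) %% 3L
  substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}

frame1_has_stop <- function(s) any(split_codons(s) %in% STOP_CODONS)

all_frames_stop_free <- function(s) {
  !frame1_has_stop(s) && !frame1_has_stop(substr(s, 2, nchar(s))) &&
    !frame1_has_stop(substr(s, 3, nchar(s)))
}

substitute_bases <- function(s, positions, bases) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  ch[positions] <- bases
  paste(ch, collapse = "")
}

random_other_base <- function(current) {
  vapply(current, function(b) sample(setdiff(BASES, b), 1), character(1),
         USE.NAMES = FALSE)
}

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Simulate a germline V allele database with family structure
#'
#' Alleles are organised into families derived from a common ancestral
#' sequence (about 20% codon divergence between families, mimicking
#' multi-family V loci); alleles within a family differ by interior
#' substitutions with an expected pairwise distance of
#' \code{allele_divergence}. The first 15 nt and the last 12 nt of each
#' allele (the conserved FR1 start and the YYC motif ending in the second
#' cysteine) carry no allele-distinguishing differences, as in real V genes
#' where the terminal framework regions are strongly conserved. All alleles
#' are stop-free in the V reading frame, pairwise distinct by at least 4
#' internal differences, and 288-300 nt long. Each allele also receives a
#' fixed upstream (5'UTR + leader) sequence used by the read simulator.
#'
#' @param n_alleles Total number of alleles (default 20).
#' @param n_families Number of families they are split into (default 4).
#' @param allele_divergence Expected pairwise nt differences within a family
#'   (default 8).
#' @param upstream_length Length of the per-allele upstream sequence.
#' @param seed Integer seed; the database is deterministic per seed.
#' @return A germline database tibble with extra columns \code{family} and
#'   \code{upstream}.
#' @export
sim_germline_db <- function(n_alleles = 20, n_families = 4,
                            allele_divergence = 8, upstream_length = 60,
                            seed = 1) {
  stopifnot(n_alleles >= 1, n_families >= 1, n_families <= n_alleles)
  pool <- codon_pool()
  withr::with_seed(seed, {
    sizes <- diff(round(seq(0, n_alleles, length.out = n_families + 1)))
    root <- sample(pool, 104, replace = TRUE)
    tail4 <- c("TAC", "TAT", "TGT", "GCG")  # Y Y C A, conserved FR3 end
    k_sub <- max(1L, round(allele_divergence / 2))
    out <- list()
    for (f in seq_len(n_families)) {
      n_codons <- sample(96:100, 1)
      founder <- root[seq_len(n_codons - 4L)]
      interior <- 6:(n_codons - 8L)
      nmut <- max(1L, round(0.2 * length(interior)))
      mutpos <- sample(interior, nmut)
      founder[mutpos] <- sample(pool, nmut, replace = TRUE)
      founder <- paste(c(founder, tail4), collapse = "")
      L <- nchar(founder)
      allowed <- 16:(L - 12L)
      fam <- character(0)
      for (a in seq_len(sizes[f])) {
        for (try in 1:50) {
          s <- founder
          pos <- sample(allowed, k_sub)
          for (p in pos) {
            repeat {
              b <- sample(setdiff(BASES, substr(s, p, p)), 1)
              cand <- s
              substr(cand, p, p) <- b
              c0 <- 3L * ((p - 1L) %/% 3L) + 1L
              if (!substr(cand, c0, c0 + 2L) %in% STOP_CODONS) {
                s <- cand; break
              }
            }
          }
          dmin <- if (length(fam) == 0) Inf else
            min(cpp_terminal_diffs(fam, s, 0L))
          if (dmin >= 4L) break
        }
        fam <- c(fam, s)
      }
      out[[f]] <- tibble(name = sprintf("V%d.%d", f, seq_along(fam)),
                         sequence = fam, family = f)
    }
    db <- dplyr::bind_rows(out)
    db$source <- "starting"
    db$upstream <- vapply(seq_len(nrow(db)),
                          function(i) rand_seq(upstream_length),
                          character(1))
    db[, c("name", "sequence", "source", "family", "upstream")]
  })
}

#' Simulate a germline J allele database
#'
#' Each J allele is a 45 nt segment whose W-G-x-G anchor codons start at nt
#' offset 22; the flanking segments differ between alleles and are stop-free
#' in all three frames so that 5'-trimming during rearrangement cannot
#' create stop codons.
#'
#' @param n_alleles Number of J alleles (default 4).
#' @param divergence Substitutions distinguishing each allele from the first.
#' @param seed Integer seed.
#' @return A germline database tibble; the anchor offset is stored in the
#'   \code{anchor} column (1-based nt start of the W codon).
#' @export
sim_j_db <- function(n_alleles = 4, divergence = 8, seed = 1) {
  withr::with_seed(seed, {
    anchor <- "TGGGGTACCGGG"  # W G T G
    base <- NULL
    repeat {
      pre <- rand_seq(21)
      post <- rand_seq(12)
      cand <- paste0(pre, anchor, post)
      if (all_frames_stop_free(cand)) { base <- cand; break }
    }
    alleles <- base
    editable <- c(1:21, (21 + 13):45)
    while (length(alleles) < n_alleles) {
      for (try in 1:100) {
        s <- base
        pos <- sample(editable, divergence)
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        ch[pos] <- random_other_base(ch[pos])
        s <- paste(ch, collapse = "")
        if (all_frames_stop_free(s) && !s %in% alleles) break
      }
      alleles <- c(alleles, s)
    }
    tibble(name = sprintf("J%d", seq_len(n_alleles)), sequence = alleles,
           source = "starting", anchor = 22L)
  })
}

# Assemble the rearranged core (trimmed V + junction insert + trimmed J) so
# that the J anchor is in the V reading frame and the junction introduces no
# stop codon. Returns the core plus the CDR3 coordinates within it.
build_core <- function(v_seq, j_seq, v_trim, j_trim, ins_base,
                       j_anchor = 22L) {
  vp <- substr(v_seq, 1L, nchar(v_seq) - v_trim)
  jp <- substr(j_seq, j_trim + 1L, nchar(j_seq))
  pre_w <- j_anchor - 1L - j_trim  # J bases upstream of the W codon
  ins <- ins_base + (-(nchar(vp) + ins_base + pre_w)) %% 3L
  core <- NULL
  for (try in 1:60) {
    ins_seq <- rand_seq(ins)
    cand <- paste0(vp, ins_seq, jp)
    if (!frame1_has_stop(cand)) { core <- cand; break }
  }
  if (is.null(core)) return(NULL)
  n_codons <- nchar(v_seq) %/% 3L
  cys_start <- 3L * (n_codons - 2L) + 1L  # second-last codon of V
  w_start <- nchar(vp) + ins + pre_w + 1L
  list(core = core, cys_start = cys_start, w_start = w_start,
       cdr3 = substr(core, cys_start, w_start - 1L))
}

empty_truth <- function() {
  tibble(id = character(), v_name = character(), j_name = character(),
         cdr3_nt = character(), n_shm = integer(), n_errors = integer(),
         v_trim = integer(), j_trim = integer(),
         upstream_truncation = integer(), artefact = logical(),
         artefact_kind = character())
}

#' Simulate an IgM-like repertoire sequencing library
#'
#' Generates reads of the form 5'UTR+leader / V / junction / J with a
#' naive/SHM-mutated mixture and independent per-base sequencing errors,
#' plus a per-read truth ledger. With probability \code{naive_fraction} a
#' read carries no SHM; otherwise its substitution count is
#' \code{1 + Geometric} with mean \code{shm_mean}, at uniform V positions.
#' Defaults emulate an unswitched IgM library on a low-error short-read
#' platform.
#'
#' @param v_db A V database from [sim_germline_db()] (needs the
#'   \code{upstream} column).
#' @param j_db A J database from [sim_j_db()].
#' @param n_reads Number of reads.
#' @param naive_fraction Fraction of reads without SHM (default 0.55).
#' @param shm_mean Mean SHM substitutions of mutated reads (default 4).
#' @param error_rate Per-base sequencing error probability (default 0.003).
#' @param junction_length_range Range the junction insert length is drawn
#'   from (before the +0..2 in-frame adjustment).
#' @param upstream_full_prob Probability a read keeps its full upstream
#'   sequence; otherwise 1..\code{upstream_max_truncation} leading nt are
#'   lost (5'RACE length variation).
#' @param upstream_max_truncation Maximum upstream truncation in nt.
#' @param v_trim_probs Probabilities of trimming 0-3 nt from the V 3' end.
#' @param j_max_trim Maximum 5' trim of the J segment.
#' @param weights Optional per-allele expression weights (default equal).
#' @param quality_char Constant Phred+33 quality character for the FASTQ
#'   representation.
#' @param seed Integer seed; output is deterministic per seed.
#' @return A list with \code{reads} (read table), \code{truth} (ledger:
#'   source alleles, planted CDR3, SHM/error counts, trim lengths) and the
#'   two databases.
#' @export
sim_repertoire <- function(v_db, j_db, n_reads = 10000,
                           naive_fraction = 0.55, shm_mean = 4,
                           error_rate = 0.003,
                           junction_length_range = c(15, 36),
                           upstream_full_prob = 0.5,
                           upstream_max_truncation = 30,
                           v_trim_probs = c(0.6, 0.2, 0.15, 0.05),
                           j_max_trim = 4, weights = NULL,
                           quality_char = "F", seed = 1) {
  v_db <- check_db(v_db, "v_db")
  j_db <- check_db(j_db, "j_db")
  stopifnot("upstream" %in% names(v_db), naive_fraction >= 0,
            naive_fraction <= 1, error_rate >= 0, error_rate <= 0.05)
  weights <- weights %||% rep(1, nrow(v_db))
  stopifnot(length(weights) == nrow(v_db), all(weights > 0))
  j_anchor <- if ("anchor" %in% names(j_db)) j_db$anchor[1] else 22L

  withr::with_seed(seed, {
    vi <- sample.int(nrow(v_db), n_reads, replace = TRUE, prob = weights)
    ji <- sample.int(nrow(j_db), n_reads, replace = TRUE)
    naive <- runif(n_reads) < naive_fraction
    n_shm <- ifelse(naive, 0L, 1L + rgeom(n_reads, 1 / shm_mean))
    vt <- sample(0:3, n_reads, replace = TRUE, prob = v_trim_probs)
    jt <- sample(0:j_max_trim, n_reads, replace = TRUE)
    full_up <- runif(n_reads) < upstream_full_prob
    up_tr <- ifelse(full_up, 0L,
                    sample.int(upstream_max_truncation, n_reads,
                               replace = TRUE))
    ins_base <- sample(junction_length_range[1]:junction_length_range[2],
                       n_reads, replace = TRUE)

    seqs <- character(n_reads)
    quals <- character(n_reads)
    cdr3 <- character(n_reads)
    n_err <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      bc <- build_core(v_db$sequence[vi[i]], j_db$sequence[ji[i]],
                       vt[i], jt[i], ins_base[i], j_anchor)
      up <- v_db$upstream[vi[i]]
      up <- substr(up, up_tr[i] + 1L, nchar(up))
      read <- paste0(up, bc$core)
      cdr3[i] <- bc$cdr3
      # SHM on the V region
      if (n_shm[i] > 0L) {
        vspan <- nchar(v_db$sequence[vi[i]]) - vt[i]
        k <- min(n_shm[i], vspan)
        n_shm[i] <- k
        pos <- nchar(up) + sample.int(vspan, k)
        ch <- strsplit(read, "", fixed = TRUE)[[1]]
        ch[pos] <- random_other_base(ch[pos])
        read <- paste(ch, collapse = "")
      }
      # sequencing errors anywhere on the read
      ne <- rbinom(1, nchar(read), error_rate)
      if (ne > 0L) {
        pos <- sample.int(nchar(read), ne)
        ch <- strsplit(read, "", fixed = TRUE)[[1]]
        ch[pos] <- random_other_base(ch[pos])
        read <- paste(ch, collapse = "")
      }
      n_err[i] <- ne
      seqs[i] <- read
      quals[i] <- strrep(quality_char, nchar(read))
    }

    reads <- tibble(id = sprintf("read%06d", seq_len(n_reads)),
                    sequence = seqs, quality = quals, count = 1L)
    truth <- tibble(id = reads$id, v_name = v_db$name[vi],
                    j_name = j_db$name[ji], cdr3_nt = cdr3,
                    n_shm = as.integer(n_shm), n_errors = n_err,
                    v_trim = as.integer(vt), j_trim = as.integer(jt),
                    upstream_truncation = as.integer(up_tr),
                    artefact = FALSE, artefact_kind = NA_character_)
    list(reads = reads, truth = truth, v_db = v_db, j_db = j_db)
  })
}

#' Randomly perturb a germline database
#'
#' Applies exactly \code{n_mutations} substitutions at distinct random
#' positions to every allele (used to emulate a diverged or wrong-species
#' starting database). Names get a \code{"_m"} suffix when mutations are
#' applied.
#'
#' @param db A germline database tibble.
#' @param n_mutations Substitutions per allele (default 10).
#' @param seed Integer seed.
#' @return The perturbed database.
#' @export
perturb_database <- function(db, n_mutations = 10, seed = 1) {
  if (n_mutations == 0) return(db)
  stopifnot(n_mutations < min(nchar(db$sequence)))
  withr::with_seed(seed, {
    db$sequence <- vapply(db$sequence, function(s) {
      pos <- sample.int(nchar(s), n_mutations)
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      ch[pos] <- random_other_base(ch[pos])
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    db$name <- paste0(db$name, "_m")
    db
  })
}

#' Inject non-germline artefact reads into a simulated library
#'
#' Emulates the two main confounders of germline discovery: clonal
#' expansions (many copies of one SHM-mutated rearrangement, hence a single
#' CDR3) and PCR-amplified SHM hotspot artefacts (one recurrent V
#' substitution spread over reads that use fewer distinct junctions than
#' the germline filter requires). All injected reads are flagged in the
#' truth ledger.
#'
#' @param sim A simulation as returned by [sim_repertoire()].
#' @param kind \code{"clonal_expansion"} or \code{"hotspot"}.
#' @param n Number of artefact reads to add.
#' @param n_junctions Number of distinct junctions of the hotspot artefact
#'   (default 9, one below the germline CDR3 threshold).
#' @param shm SHM substitutions of the clonally expanded rearrangement.
#' @param error_rate Per-base sequencing error rate of the new reads.
#' @param seed Integer seed.
#' @return \code{sim} with the artefact reads and ledger rows appended.
#' @export
inject_artefacts <- function(sim, kind = c("clonal_expansion", "hotspot"),
                             n = 200, n_junctions = 9, shm = 5,
                             error_rate = 0.003, seed = 1) {
  kind <- match.arg(kind)
  v_db <- sim$v_db; j_db <- sim$j_db
  j_anchor <- if ("anchor" %in% names(j_db)) j_db$anchor[1] else 22L
  withr::with_seed(seed, {
    vi <- sample.int(nrow(v_db), 1)
    vseq <- v_db$sequence[vi]
    if (kind == "clonal_expansion") {
      ji <- sample.int(nrow(j_db), 1)
      core <- NULL
      repeat {  # interior SHM so the clone passes the quality filter
        bc <- build_core(vseq, j_db$sequence[ji], 0L, 0L,
                         sample(15:36, 1), j_anchor)
        pos <- sample(16:(nchar(vseq) - 12L), shm)
        ch <- strsplit(bc$core, "", fixed = TRUE)[[1]]
        ch[pos] <- random_other_base(ch[pos])
        core <- paste(ch, collapse = "")
        if (!frame1_has_stop(core)) break
      }
      cores <- list(list(core = core,
                         cdr3 = substr(core, bc$cys_start, bc$w_start - 1L),
                         ji = ji))
      core_idx <- rep(1L, n)
      n_shm_out <- rep(as.integer(shm), n)
    } else {
      repeat {  # the recurrent substitution must not create a stop codon
        hot_pos <- sample(16:(nchar(vseq) - 12L), 1)
        hot_base <- sample(setdiff(BASES, substr(vseq, hot_pos, hot_pos)), 1)
        c0 <- 3L * ((hot_pos - 1L) %/% 3L) + 1L
        codon <- substr(vseq, c0, c0 + 2L)
        substr(codon, hot_pos - c0 + 1L, hot_pos - c0 + 1L) <- hot_base
        if (!codon %in% STOP_CODONS) break
      }
      cores <- list()
      seen <- character(0)
      while (length(cores) < n_junctions) {
        ji <- sample.int(nrow(j_db), 1)
        bc <- build_core(vseq, j_db$sequence[ji], 0L, 0L,
                         sample(15:36, 1), j_anchor)
        if (is.null(bc) || bc$cdr3 %in% seen) next
        ch <- strsplit(bc$core, "", fixed = TRUE)[[1]]
        ch[hot_pos] <- hot_base
        core <- paste(ch, collapse = "")
        if (frame1_has_stop(core)) next
        seen <- c(seen, bc$cdr3)
        cores[[length(cores) + 1L]] <-
          list(core = core, cdr3 = substr(core, bc$cys_start,
                                          bc$w_start - 1L), ji = ji)
      }
      core_idx <- sample.int(length(cores), n, replace = TRUE)
      n_shm_out <- rep(1L, n)
    }
    up_full <- v_db$upstream[vi]
    seqs <- character(n); n_err <- integer(n); up_tr <- integer(n)
    for (i in seq_len(n)) {
      tr <- if (runif(1) < 0.5) 0L else sample.int(30L, 1)
      up_tr[i] <- tr
      read <- paste0(substr(up_full, tr + 1L, nchar(up_full)),
                     cores[[core_idx[i]]]$core)
      ne <- rbinom(1, nchar(read), error_rate)
      if (ne > 0L) {
        pos <- sample.int(nchar(read), ne)
        ch <- strsplit(read, "", fixed = TRUE)[[1]]
        ch[pos] <- random_other_base(ch[pos])
        read <- paste(ch, collapse = "")
      }
      n_err[i] <- ne
      seqs[i] <- read
    }
    ids <- sprintf("art_%s_%04d", substr(kind, 1, 4), seq_len(n))
    reads <- tibble(id = ids, sequence = seqs,
                    quality = strrep("F", nchar(seqs)), count = 1L)
    truth <- tibble(id = ids, v_name = v_db$name[vi],
                    j_name = j_db$name[vapply(core_idx, function(k)
                      cores[[k]]$ji, integer(1))],
                    cdr3_nt = vapply(core_idx, function(k)
                      cores[[k]]$cdr3, character(1)),
                    n_shm = n_shm_out, n_errors = n_err,
                    v_trim = 0L, j_trim = 0L,
                    upstream_truncation = up_tr,
                    artefact = TRUE, artefact_kind = kind)
    sim$reads <- dplyr::bind_rows(sim$reads, reads)
    sim$truth <- dplyr::bind_rows(sim$truth, truth)
    sim$artefact_sequences <- unique(c(sim$artefact_sequences, vapply(
      cores, function(k) substr(k$core, 1L, nchar(vseq)), character(1))))
    sim
  })
}

#' Simulate paired-end reads from amplicon sequences
#'
#' Produces a forward read (amplicon 5' end) and a reverse read (reverse
#' complement of the amplicon 3' end) of fixed length with independent
#' substitution errors, for testing overlap merging.
#'
#' @param amplicons Character vector of amplicon sequences (or a read table).
#' @param read_length Read length in nt (default 300).
#' @param error_rate Per-base error probability.
#' @param seed Integer seed.
#' @return A list with \code{forward}, \code{reverse} read tables and
#'   \code{truth} (id + amplicon).
#' @export
sim_read_pairs <- function(amplicons, read_length = 300, error_rate = 0.003,
                           seed = 1) {
  if (is.data.frame(amplicons)) amplicons <- amplicons$sequence
  stopifnot(all(nchar(amplicons) >= read_length))
  withr::with_seed(seed, {
    n <- length(amplicons)
    ids <- sprintf("pair%05d", seq_len(n))
    add_err <- function(s) {
      ne <- rbinom(1, nchar(s), error_rate)
      if (ne == 0L) return(list(s = s, n = 0L))
      pos <- sample.int(nchar(s), ne)
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      ch[pos] <- random_other_base(ch[pos])
      list(s = paste(ch, collapse = ""), n = ne)
    }
    fwd <- lapply(substr(amplicons, 1L, read_length), add_err)
    rv <- lapply(revcomp(substr(amplicons, nchar(amplicons) - read_length +
                                  1L, nchar(amplicons))), add_err)
    q <- strrep("F", read_length)
    list(forward = tibble(id = ids,
                          sequence = vapply(fwd, `[[`, character(1), "s"),
                          quality = q, count = 1L),
         reverse = tibble(id = ids,
                          sequence = vapply(rv, `[[`, character(1), "s"),
                          quality = q, count = 1L),
         truth = tibble(id = ids, amplicon = amplicons,
                        errors_forward = vapply(fwd, `[[`, integer(1), "n"),
                        errors_reverse = vapply(rv, `[[`, integer(1), "n")))
  })
}
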