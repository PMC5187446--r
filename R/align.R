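#' Align a query sequence to a germline allele
#'
#' Optimal local alignment with affine gap costs (a gap of length L costs
#' \code{gap_open + L * gap_extend}). Both ends of both sequences are free,
#' so the reference may be truncated at either end and the query may carry
#' non-V flanks (5'UTR/leader upstream, junction and J downstream) without
#' penalty. Ties are broken towards fewer errors.
#'
#' @param query Nucleotide string.
#' @param allele A nucleotide string, or a one-row germline database tibble.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return A one-row tibble: \code{score}, 1-based \code{query_start}/
#'   \code{query_end}/\code{ref_start}/\code{ref_end}, \code{mismatches},
#'   \code{gap_bases}, \code{errors} (mismatches + gap bases) and
#'   \code{ref_coverage} (aligned fraction of the reference).
#' @examples
#' align_to_allele("TTTACGTACGTGGG", "ACGTACGT")
#' @export
align_to_allele <- function(query, allele, match = 1, mismatch = -2,
                            gap_open = -5, gap_extend = -2) {
  ref <- if (is.data.frame(allele)) allele$sequence[1] else allele
  a <- cpp_align(query, ref, as.integer(match), as.integer(mismatch),
                 as.integer(gap_open), as.integer(gap_extend))
  span <- max(0L, a$ref_end - a$ref_start + 1L)
  tibble(score = a$score, query_start = a$query_start,
         query_end = a$query_end, ref_start = a$ref_start,
         ref_end = a$ref_end, mismatches = a$mismatches,
         gap_bases = a$gap_bases, errors = a$mismatches + a$gap_bases,
         ref_coverage = span / nchar(ref))
}

# nt start (frame 1) of the conserved second-cysteine codon of each allele:
# the last Cys codon in the frame-1 translation
cys_nt_start <- function(sequences) {
  aa <- translate_nt(sequences)
  pos <- vapply(aa, function(s) {
    hits <- gregexpr("C", s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) NA_integer_ else as.integer(hits[length(hits)])
  }, integer(1), USE.NAMES = FALSE)
  ifelse(is.na(pos), NA_integer_, 3L * (pos - 1L) + 1L)
}

#' Assign reads to their closest V and J alleles
#'
#' Each read is aligned against the V database (after a k-mer diagonal
#' prescreen that selects the most promising alleles) and assigned to the
#' best-scoring allele; ties are broken towards fewer errors, then database
#' order. The J database is searched only 3' of the V alignment end. Percent
#' difference is computed over the aligned reference span, so terminal
#' truncations are not counted as errors. CDR3 detection and stop-codon
#' flagging run on the frame inherited from the V reference (position 1 of a
#' database allele is codon position 1).
#'
#' The reported E-value is a Karlin-Altschul surrogate,
#' \code{m * n * 2^-bitscore}, with the ungapped lambda for the configured
#' match/mismatch scores and K fixed at 0.3; it preserves the E <= 1e-3 gate
#' semantics of the downstream quality filter.
#'
#' @param reads A read table (see [read_sequences()]).
#' @param v_db,j_db Germline database tibbles (\code{name}, \code{sequence});
#'   \code{j_db} may be \code{NULL}, leaving the J fields absent.
#' @param chain \code{"heavy"}, \code{"kappa"} or \code{"lambda"}; selects
#'   the CDR3 J-anchor motif (W-G-x-G for heavy, F-G-x-G for light chains).
#' @param with_cdr3 Detect CDR3s and stop codons (default \code{TRUE}).
#' @param kmer K-mer length of the prescreen.
#' @param band_half Half-width of the alignment band around the best k-mer
#'   diagonal.
#' @param max_candidates Number of prescreen alleles aligned in full.
#' @inheritParams align_to_allele
#' @return One assignment row per read: \code{query_id}, \code{count},
#'   \code{sequence}, \code{v_name}, \code{v_score}, \code{v_evalue},
#'   \code{v_coverage}, \code{v_errors}, \code{v_percent_difference},
#'   \code{v_sequence}, \code{upstream_sequence}, \code{j_name},
#'   \code{j_score}, \code{j_coverage}, \code{cdr3_nt}, \code{cdr3_aa},
#'   \code{has_stop}.
#' @export
assign_vj <- function(reads, v_db, j_db = NULL,
                      chain = c("heavy", "kappa", "lambda"),
                      with_cdr3 = TRUE, match = 1, mismatch = -2,
                      gap_open = -5, gap_extend = -2, kmer = 11,
                      band_half = 16, max_candidates = 4) {
  chain <- match.arg(chain)
  reads <- check_reads(reads)
  v_db <- check_db(v_db, "v_db")
  has_j <- !is.null(j_db) && nrow(j_db) > 0
  jseqs <- if (has_j) check_db(j_db, "j_db")$sequence else character(0)
  jnames <- if (has_j) j_db$name else character(0)

  hits <- cpp_assign_batch(reads$sequence, v_db$sequence, jseqs,
                           as.integer(match), as.integer(mismatch),
                           as.integer(gap_open), as.integer(gap_extend),
                           as.integer(kmer), as.integer(band_half),
                           as.integer(max_candidates))

  v_len <- nchar(v_db$sequence)[hits$v_idx]
  v_span <- hits$v_rend - hits$v_rstart + 1L
  v_err <- hits$v_mismatches + hits$v_gap_bases
  lam <- karlin_lambda(match, mismatch)
  bit <- (lam * hits$v_score - log(0.3)) / log(2)
  evalue <- nchar(reads$sequence) * sum(nchar(v_db$sequence)) * 2^(-bit)

  out <- tibble(
    query_id = reads$id,
    count = reads$count,
    sequence = reads$sequence,
    v_name = v_db$name[hits$v_idx],
    v_score = hits$v_score,
    v_evalue = evalue,
    v_coverage = v_span / v_len,
    v_errors = v_err,
    v_percent_difference = 100 * v_err / v_span,
    v_sequence = substr(reads$sequence, hits$v_qstart, hits$v_qend),
    upstream_sequence = substr(reads$sequence, 1L, hits$v_qstart - 1L),
    v_qstart = hits$v_qstart, v_qend = hits$v_qend,
    v_rstart = hits$v_rstart, v_rend = hits$v_rend)

  if (has_j) {
    j_len <- nchar(jseqs)[hits$j_idx]
    j_span <- hits$j_rend - hits$j_rstart + 1L
    out$j_name <- jnames[hits$j_idx]
    out$j_score <- hits$j_score
    out$j_coverage <- j_span / j_len
  } else {
    out$j_name <- NA_character_
    out$j_score <- NA_integer_
    out$j_coverage <- NA_real_
  }

  if (with_cdr3) out <- detect_cdr3(out, v_db, chain)
  else {
    out$cdr3_nt <- NA_character_
    out$cdr3_aa <- NA_character_
    out$has_stop <- NA
  }
  out
}

#' Detect CDR3 junctions at the amino-acid level
#'
#' Translates each read in the frame inherited from its assigned V allele
#' and extracts the CDR3 between the conserved second cysteine (the last Cys
#' within a small window around the reference FR3 end) and the J anchor
#' motif (first W-G-x-G for heavy chains, F-G-x-G for light chains,
#' downstream of the cysteine). Also flags stop codons anywhere in the
#' translation from the V start. Reads without both motifs get \code{NA}
#' CDR3 fields.
#'
#' @param assignments An assignment table from [assign_vj()].
#' @param v_db The V database the assignments were computed against.
#' @inheritParams assign_vj
#' @return \code{assignments} with \code{cdr3_nt}, \code{cdr3_aa} and
#'   \code{has_stop} columns filled in.
#' @export
detect_cdr3 <- function(assignments, v_db,
                        chain = c("heavy", "kappa", "lambda")) {
  chain <- match.arg(chain)
  jpat <- if (chain == "heavy") "WG.G" else "FG.G"
  cys <- cys_nt_start(v_db$sequence)
  names(cys) <- v_db$name

  n <- nrow(assignments)
  cdr3_nt <- rep(NA_character_, n)
  cdr3_aa <- rep(NA_character_, n)
  has_stop <- rep(NA, n)

  ok <- !is.na(assignments$v_name)
  if (any(ok)) {
    # translation start: smallest query position >= 1 on a reference codon
    # boundary (no-indel extrapolation; indels are tolerated by the +-6
    # codon anchor search window)
    qs <- assignments$v_qstart[ok] - (assignments$v_rstart[ok] - 1L)
    qs <- ifelse(qs < 1L, qs + 3L * ((3L - qs) %/% 3L), qs)  # stay in frame
    seqs <- assignments$sequence[ok]
    aa <- translate_nt(substr(seqs, qs, nchar(seqs)))
    has_stop[ok] <- grepl("*", aa, fixed = TRUE)

    cys_q <- cys[assignments$v_name[ok]] + assignments$v_qstart[ok] -
      assignments$v_rstart[ok]
    cys_aa <- (cys_q - qs) %/% 3L + 1L
    naa <- nchar(aa)
    lo <- pmax(1L, cys_aa - 6L)
    hi <- pmin(naa, cys_aa)
    win <- substr(aa, lo, hi)
    cloc <- stringr::str_locate(win, "C[^C]*$")[, 1]  # last C in the window
    ca <- lo + cloc - 1L
    wloc <- stringr::str_locate(substr(aa, ca + 1L, naa), jpat)[, 1]
    wpos <- ca + wloc
    good <- !is.na(cys_aa) & !is.na(cloc) & !is.na(wloc)
    aa3 <- substr(aa, ca, wpos - 1L)
    nt3 <- substr(seqs, qs + 3L * (ca - 1L), qs + 3L * (wpos - 1L) - 1L)
    idx <- which(ok)
    cdr3_aa[idx[good]] <- aa3[good]
    cdr3_nt[idx[good]] <- nt3[good]
  }
  assignments$cdr3_nt <- cdr3_nt
  assignments$cdr3_aa <- cdr3_aa
  assignments$has_stop <- has_stop
  assignments
}

#' Quality-filter V/J assignments
#'
#' Keeps assignments with both V and J assigned, no stop codon, E-value at
#' most \code{max_evalue}, V reference coverage of at least
#' \code{min_v_coverage} and J coverage of at least \code{min_j_coverage}
#' (all thresholds boundary-inclusive). Applying the filter twice is a
#' no-op.
#'
#' @param assignments An assignment table from [assign_vj()].
#' @param max_evalue,min_v_coverage,min_j_coverage Thresholds (defaults
#'   1e-3, 0.90 and 0.60).
#' @param require_j Demand a J assignment (disable when running without a J
#'   database).
#' @return The passing subset of \code{assignments}.
#' @export
quality_filter <- function(assignments, max_evalue = 1e-3,
                           min_v_coverage = 0.9, min_j_coverage = 0.6,
                           require_j = TRUE) {
  keep <- !is.na(assignments$v_name) &
    !is.na(assignments$has_stop) & !assignments$has_stop &
    assignments$v_evalue <= max_evalue &
    assignments$v_coverage >= min_v_coverage
  if (require_j) {
    keep <- keep & !is.na(assignments$j_name) &
      !is.na(assignments$j_coverage) &
      assignments$j_coverage >= min_j_coverage
  }
  assignments[keep, ]
}
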