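#' Merge paired-end reads by overlap
#'
#' Aligns the reverse-complemented reverse read against the forward read at
#' every overlap offset of at least \code{min_overlap} bases and keeps the
#' offset with the most matching bases, provided the mismatch fraction inside
#' the overlap does not exceed \code{max_overlap_mismatch}. Disagreeing
#' overlap bases are resolved in favour of the higher Phred quality; without
#' qualities (and on quality ties) the forward base wins. Pairs without an
#' acceptable overlap are dropped and counted in the attached merge log.
#'
#' @param forward,reverse Read tables (\code{id}, \code{sequence}, optional
#'   \code{quality}); \code{reverse} in sequencer orientation.
#' @param min_overlap Minimum acceptable overlap length in nt.
#' @param max_overlap_mismatch Maximum mismatch fraction inside the overlap.
#' @return A tibble of merged reads with a \code{"merge_log"} attribute
#'   (counts of input, merged and failed pairs).
#' @export
merge_read_pairs <- function(forward, reverse, min_overlap = 16,
                             max_overlap_mismatch = 0.2) {
  forward <- check_reads(forward)
  reverse <- check_reads(reverse)
  stopifnot(nrow(forward) == nrow(reverse))
  res <- cpp_merge_pairs(forward$sequence, reverse$sequence,
                         forward$quality, reverse$quality,
                         as.integer(min_overlap), max_overlap_mismatch)
  ok <- res$ok
  out <- tibble(id = forward$id[ok],
                sequence = as.character(res$merged)[ok],
                quality = as.character(res$quality)[ok],
                count = forward$count[ok])
  attr(out, "merge_log") <- tibble(
    n_pairs = nrow(forward), n_merged = sum(ok), n_failed = sum(!ok))
  out
}

#' Merge a single read pair
#'
#' Scalar convenience wrapper around [merge_read_pairs()].
#'
#' @param forward,reverse Nucleotide strings (\code{reverse} in sequencer
#'   orientation, i.e. it is reverse-complemented internally).
#' @param forward_quality,reverse_quality Optional Phred+33 quality strings.
#' @inheritParams merge_read_pairs
#' @return The merged sequence, or \code{NA} if no acceptable overlap exists.
#' @examples
#' merge_read_pair("ACGTACGT", "AAAAACGT", min_overlap = 4)
#' @export
merge_read_pair <- function(forward, reverse, forward_quality = NULL,
                            reverse_quality = NULL, min_overlap = 16,
                            max_overlap_mismatch = 0.2) {
  res <- cpp_merge_pairs(forward, reverse,
                         forward_quality %||% NA_character_,
                         reverse_quality %||% NA_character_,
                         as.integer(min_overlap), max_overlap_mismatch)
  as.character(res$merged)[1]
}

#' Trim primer sequences from read ends
#'
#' Primers are matched anchored at the expected end, allowing up to one
#' mismatch per 10 primer bases; a matched span is removed. Reads without a
#' match are returned unchanged (no-match is not an error).
#'
#' @param reads A read table.
#' @param primers_5p,primers_3p Character vectors of primer sequences
#'   expected at the 5' / 3' end, or \code{NULL}.
#' @return The read table with matched primers removed.
#' @export
trim_primers <- function(reads, primers_5p = NULL, primers_3p = NULL) {
  reads <- check_reads(reads)
  if (is.null(primers_5p) && is.null(primers_3p)) return(reads)
  hamming_at <- function(seqs, primer, from) {
    frag <- substr(seqs, from, from + nchar(primer) - 1L)
    full <- nchar(frag) == nchar(primer)
    d <- rep(NA_integer_, length(seqs))
    if (any(full)) {
      d[full] <- cpp_terminal_diffs(frag[full], primer, 0L)
    }
    d
  }
  for (p in primers_5p) {
    allowed <- floor(nchar(p) / 10)
    d <- hamming_at(reads$sequence, p, 1L)
    hit <- !is.na(d) & d <= allowed
    reads$sequence[hit] <- substr(reads$sequence[hit], nchar(p) + 1L,
                                  nchar(reads$sequence[hit]))
    if (!all(is.na(reads$quality))) {
      reads$quality[hit] <- substr(reads$quality[hit], nchar(p) + 1L,
                                   nchar(reads$quality[hit]))
    }
  }
  for (p in primers_3p) {
    allowed <- floor(nchar(p) / 10)
    d <- hamming_at(reads$sequence, p,
                    pmax(1L, nchar(reads$sequence) - nchar(p) + 1L))
    hit <- !is.na(d) & d <= allowed & nchar(reads$sequence) >= nchar(p)
    reads$sequence[hit] <- substr(reads$sequence[hit], 1L,
                                  nchar(reads$sequence[hit]) - nchar(p))
    if (!all(is.na(reads$quality))) {
      reads$quality[hit] <- substr(reads$quality[hit], 1L,
                                   nchar(reads$quality[hit]) - nchar(p))
    }
  }
  reads
}

#' Keep reads of at least a minimum length
#'
#' @param reads A read table.
#' @param min_length Minimum sequence length in nt (default 300, the full-V
#'   amplicon cutoff).
#' @return The qualifying reads, input order preserved.
#' @export
filter_length <- function(reads, min_length = 300) {
  reads <- check_reads(reads)
  reads[nchar(reads$sequence) >= min_length, ]
}

#' Drop reads with too many ambiguous bases
#'
#' @param reads A read table.
#' @param max_n_fraction Maximum tolerated fraction of N bases.
#' @return The qualifying reads.
#' @export
filter_n_fraction <- function(reads, max_n_fraction = 0.1) {
  reads <- check_reads(reads)
  nfrac <- stringr::str_count(reads$sequence, "N") / nchar(reads$sequence)
  reads[nfrac <= max_n_fraction, ]
}

#' Dereplicate identical full-length sequences
#'
#' Collapses reads with identical sequence strings into one record whose
#' \code{count} is the number of collapsed reads (weighted by input counts)
#' and whose \code{id} is the first-seen id. Output is ordered by descending
#' count, then first appearance.
#'
#' @param reads A read table.
#' @return The dereplicated read table.
#' @examples
#' r <- tibble::tibble(id = c("a", "b", "c"),
#'                     sequence = c("ACGT", "ACGT", "GGTT"))
#' dereplicate(r)
#' @export
dereplicate <- function(reads) {
  reads <- check_reads(reads)
  reads$.ord <- seq_len(nrow(reads))
  out <- reads |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(id = dplyr::first(.data$id),
                     quality = dplyr::first(.data$quality),
                     count = sum(.data$count),
                     .ord = min(.data$.ord), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$.ord) |>
    dplyr::select("id", "sequence", "quality", "count")
  out
}

#' Preprocess raw reads for germline discovery
#'
#' Runs the standard preprocessing chain: optional pair merging, optional
#' primer trimming, removal of N-rich reads, the minimum-length filter and
#' full-length dereplication. A per-stage read-count log is attached as the
#' \code{"preprocess_log"} attribute.
#'
#' @param reads A read table of merged/single-end reads, or \code{NULL} when
#'   \code{forward}/\code{reverse} are given.
#' @param forward,reverse Optional paired-end read tables.
#' @inheritParams merge_read_pairs
#' @inheritParams trim_primers
#' @inheritParams filter_length
#' @inheritParams filter_n_fraction
#' @return The preprocessed, dereplicated read table.
#' @export
preprocess_reads <- function(reads = NULL, forward = NULL, reverse = NULL,
                             primers_5p = NULL, primers_3p = NULL,
                             min_length = 300, min_overlap = 16,
                             max_overlap_mismatch = 0.2,
                             max_n_fraction = 0.1) {
  log <- list()
  if (is.null(reads)) {
    stopifnot(!is.null(forward), !is.null(reverse))
    log$input <- sum(check_reads(forward)$count)
    reads <- merge_read_pairs(forward, reverse, min_overlap,
                              max_overlap_mismatch)
  } else {
    reads <- check_reads(reads)
    log$input <- sum(reads$count)
  }
  log$merged <- sum(reads$count)
  reads <- trim_primers(reads, primers_5p, primers_3p)
  reads <- filter_n_fraction(reads, max_n_fraction)
  log$n_filtered <- sum(reads$count)
  reads <- filter_length(reads, min_length)
  log$length_filtered <- sum(reads$count)
  reads <- dereplicate(reads)
  log$unique <- nrow(reads)
  attr(reads, "preprocess_log") <-
    tibble(stage = names(log), reads = unlist(log, use.names = FALSE))
  reads
}
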