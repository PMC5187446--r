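#' Compare two sequences ignoring small terminal length differences
#'
#' The shorter sequence is slid along the longer one with at most
#' \code{tolerance} overhanging bases of the longer sequence at each end;
#' the reported difference count is the minimal number of internal
#' mismatches over the allowed placements. Sequences whose length
#' difference exceeds what the tolerance allows are incomparable
#' (\code{equal = FALSE}, \code{diffs = NA}).
#'
#' @param a,b Character vectors (recycled to common length).
#' @param tolerance Maximum overhang per end, in nt.
#' @return A tibble with columns \code{equal} and \code{diffs}.
#' @examples
#' equal_with_terminal_tolerance("ACGTACGT", "ACGTAC", tolerance = 3)
#' @export
equal_with_terminal_tolerance <- function(a, b, tolerance = 3) {
  d <- cpp_terminal_diffs(a, b, as.integer(tolerance))
  tibble(equal = !is.na(d) & d == 0L, diffs = d)
}

#' Annotate candidates with independent-rearrangement evidence
#'
#' For each candidate sequence, all exact occurrences in the full
#' assignment table are counted: \code{exact_occurrences} is the number of
#' reads (weighted by dereplication counts) whose V-region sequence equals
#' the candidate, \code{unique_cdr3} the number of distinct CDR3s among
#' those reads and \code{unique_j} the number of distinct J genes. With a
#' positive \code{tolerance}, equality is terminal-tolerant instead of
#' strict (the default, matching the exact-occurrence reading).
#'
#' @param candidates A candidate tibble from [discover_candidates()].
#' @param assignments The full (quality-passing) assignment table.
#' @param tolerance Terminal tolerance for the occurrence match (default 0,
#'   strict string equality).
#' @return \code{candidates} with \code{exact_occurrences},
#'   \code{unique_cdr3} and \code{unique_j} columns.
#' @export
annotate_candidates <- function(candidates, assignments, tolerance = 0) {
  groups <- assignments |>
    dplyr::group_by(.data$v_sequence) |>
    dplyr::summarise(occ = as.integer(sum(.data$count)),
                     cdr3s = list(unique(stats::na.omit(.data$cdr3_nt))),
                     js = list(unique(stats::na.omit(.data$j_name))),
                     .groups = "drop")
  n <- nrow(candidates)
  occ <- integer(n); ncdr3 <- integer(n); nj <- integer(n)
  if (tolerance == 0) {
    # strict equality: each candidate matches at most one v_sequence group
    idx <- match(candidates$sequence, groups$v_sequence)
    hitp <- !is.na(idx)
    occ[hitp] <- groups$occ[idx[hitp]]
    ncdr3[hitp] <- lengths(groups$cdr3s[idx[hitp]])
    nj[hitp] <- lengths(groups$js[idx[hitp]])
  } else {
    for (i in seq_len(n)) {
      d <- cpp_terminal_diffs(groups$v_sequence, candidates$sequence[i],
                              as.integer(tolerance))
      hit <- which(!is.na(d) & d == 0L)
      occ[i] <- sum(groups$occ[hit])
      ncdr3[i] <- length(unique(unlist(groups$cdr3s[hit])))
      nj[i] <- length(unique(unlist(groups$js[hit])))
    }
  }
  candidates$exact_occurrences <- occ
  candidates$unique_cdr3 <- ncdr3
  candidates$unique_j <- nj
  candidates
}

#' Collapse near-duplicate candidates
#'
#' Whenever two candidates differ by at most \code{max_diff} internal bases
#' (terminal-tolerant comparison), the one with fewer unique CDR3s is
#' removed; ties keep the longer sequence, then the lexicographically
#' smaller name. The rule is applied until no such pair remains.
#'
#' @param candidates An annotated candidate tibble.
#' @param max_diff Maximum internal difference count (default 2).
#' @param tolerance Terminal tolerance of the comparison.
#' @return The surviving candidates.
#' @export
collapse_near_duplicates <- function(candidates, max_diff = 2,
                                     tolerance = 10) {
  if (nrow(candidates) <= 1L) return(candidates)
  ord <- order(-candidates$unique_cdr3, -nchar(candidates$sequence),
               candidates$name)
  keep_idx <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (j in keep_idx) {
      d <- cpp_terminal_diffs(candidates$sequence[i],
                              candidates$sequence[j],
                              as.integer(tolerance))
      if (!is.na(d) && d <= max_diff) { dup <- TRUE; break }
    }
    if (!dup) keep_idx <- c(keep_idx, i)
  }
  candidates[sort(keep_idx), ]
}

#' Validate candidates with the germline (or pregermline) evidence filter
#'
#' Keeps a candidate if it is whitelisted (sequence identical to one in the
#' run's starting database) or if it meets all evidence thresholds:
#' originating cluster size (germline mode only, default >= 100), unique
#' CDR3 count (germline >= 10, pregermline >= 2) and, unless the J
#' criterion is disabled, unique J count (germline >= 3, pregermline
#' >= 2). Candidates containing N or a stop codon in the reading frame are
#' rejected up front, and survivors pass through
#' [collapse_near_duplicates()]. Whitelisted candidates keep their database
#' name; discovered candidates are named
#' \code{<source_allele>_S<4-digit sequence hash>}.
#'
#' @param candidates An annotated candidate tibble (see
#'   [annotate_candidates()]).
#' @param mode \code{"germline"} (final iteration) or \code{"pregermline"}
#'   (earlier iterations).
#' @param starting_db The run's iteration-0 starting database (used for
#'   whitelisting); may be \code{NULL} to disable whitelisting.
#' @param input_db The database of the current iteration; a kept candidate
#'   whose sequence is identical to an input allele inherits that allele's
#'   name (name continuity across iterations), without any filter bypass.
#' @param min_cluster_size,min_unique_cdr3,min_unique_j Threshold
#'   overrides; \code{NULL} selects the mode defaults above.
#' @param j_criterion Require the unique-J threshold (default TRUE).
#' @param max_near_duplicate_diff,terminal_tolerance Passed to
#'   [collapse_near_duplicates()].
#' @return The new germline database tibble (\code{name}, \code{sequence},
#'   \code{source} of \code{"whitelisted"} or \code{"discovered"}), with
#'   the full candidate table (columns \code{whitelisted}, \code{passed},
#'   \code{reason}) attached as attribute \code{"candidates"}. An empty
#'   result triggers a warning.
#' @export
apply_germline_filter <- function(candidates,
                                  mode = c("germline", "pregermline"),
                                  starting_db = NULL, input_db = NULL,
                                  min_cluster_size = NULL,
                                  min_unique_cdr3 = NULL,
                                  min_unique_j = NULL,
                                  j_criterion = TRUE,
                                  max_near_duplicate_diff = 2,
                                  terminal_tolerance = 10) {
  mode <- match.arg(mode)
  min_cluster_size <- min_cluster_size %||%
    (if (mode == "germline") 100L else 0L)
  min_unique_cdr3 <- min_unique_cdr3 %||%
    (if (mode == "germline") 10L else 2L)
  min_unique_j <- min_unique_j %||% (if (mode == "germline") 3L else 2L)

  stopifnot(all(c("exact_occurrences", "unique_cdr3", "unique_j") %in%
                  names(candidates)))
  cand <- candidates
  cand$whitelisted <- if (!is.null(starting_db)) {
    cand$sequence %in% starting_db$sequence
  } else rep(FALSE, nrow(cand))

  ambiguous <- grepl("N", cand$sequence, fixed = TRUE)
  stopc <- !ambiguous & has_stop_codon(cand$sequence)
  evidence <- cand$cluster_size >= min_cluster_size &
    cand$unique_cdr3 >= min_unique_cdr3 &
    (!j_criterion | cand$unique_j >= min_unique_j)
  cand$passed <- !ambiguous & !stopc & (cand$whitelisted | evidence)
  cand$reason <- dplyr::case_when(
    ambiguous ~ "ambiguous_bases",
    stopc ~ "stop_codon",
    cand$whitelisted ~ "whitelisted",
    cand$cluster_size < min_cluster_size ~ "cluster_size",
    cand$unique_cdr3 < min_unique_cdr3 ~ "unique_cdr3",
    j_criterion & cand$unique_j < min_unique_j ~ "unique_j",
    TRUE ~ "passed")

  kept <- collapse_near_duplicates(cand[cand$passed, ],
                                   max_near_duplicate_diff,
                                   terminal_tolerance)
  collapsed <- setdiff(cand$name[cand$passed], kept$name)
  cand$passed[cand$name %in% collapsed] <- FALSE
  cand$reason[cand$name %in% collapsed] <- "near_duplicate"

  name <- kept$name
  if (!is.null(input_db)) {
    ip <- match(kept$sequence, input_db$sequence)
    name[!is.na(ip)] <- input_db$name[ip[!is.na(ip)]]
  }
  if (!is.null(starting_db) && any(kept$whitelisted)) {
    wl <- match(kept$sequence, starting_db$sequence)
    name[!is.na(wl)] <- starting_db$name[wl[!is.na(wl)]]
  }
  db <- tibble(name = make.unique(name, sep = "x"),
               sequence = kept$sequence,
               source = ifelse(kept$whitelisted, "whitelisted",
                               "discovered"))
  if (nrow(db) == 0L) warn("germline filter produced an empty database")
  attr(db, "candidates") <- cand
  db
}
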