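#' Iterative germline V gene discovery
#'
#' Runs the full discovery loop: in each iteration every read is assigned
#' to its closest allele of the current database, quality-filtered,
#' clustered (percent-difference windows and UPGMA linkage subclusters of a
#' random subsample), consensus sequences are built, annotated with
#' independent-rearrangement evidence over the full data set, and filtered
#' -- with the permissive pregermline filter in all but the last iteration
#' and the strict germline filter in the last. The filtered output replaces
#' the database for the next iteration. After the last iteration one
#' additional assignment pass against the final database produces the gene
#' usage profile and the upstream (5'UTR + leader) consensus sequences.
#'
#' A single-allele or wrong-species starting database is sufficient; three
#' iterations (the default) give distant starting databases time to
#' converge.
#'
#' @param reads A preprocessed (merged, length-filtered, dereplicated) read
#'   table.
#' @param v_db Starting V database tibble (\code{name}, \code{sequence}).
#' @param j_db J database tibble, or \code{NULL} to run without the J
#'   criterion and J coverage gate.
#' @param iterations Number of discovery iterations (default 3).
#' @param seed Seed for the linkage-clustering subsample.
#' @param subsample_size Linkage subsample size (default 1000).
#' @param window_width Percent-difference window width (default 2).
#' @param min_window_members,min_subtree_size,ratio_threshold,majority
#'   Clustering parameters, see [discover_candidates()].
#' @param chain Receptor chain; selects the CDR3 J anchor.
#' @param j_criterion Require the unique-J evidence criterion.
#' @param max_near_duplicate_diff,terminal_tolerance,annotation_tolerance
#'   Filter parameters, see [apply_germline_filter()] and
#'   [annotate_candidates()].
#' @param max_evalue,min_v_coverage,min_j_coverage Quality-filter gates.
#' @param early_stop Stop before the last iteration if the database did not
#'   change (off by default; the iteration count is fixed otherwise).
#' @param min_reads_warning Warn below this many input reads (the method
#'   needs deep libraries for a complete genotype; default 400,000).
#' @param cache Memoise linkage distance matrices across iterations.
#' @param verbose Print per-iteration progress.
#' @return A \code{germline_discovery} object with elements
#'   \code{final_db}, \code{usage}, \code{upstream}, \code{iterations} (per
#'   iteration: candidate table and output database),
#'   \code{final_assignments} and \code{config}. Supports [tidy()],
#'   [glance()], \code{print()} and [ggplot2::autoplot()].
#' @export
discover_germline <- function(reads, v_db, j_db = NULL, iterations = 3,
                              seed = 1, subsample_size = 1000,
                              window_width = 2, min_window_members = 5,
                              min_subtree_size = 5, ratio_threshold = 0.8,
                              majority = 0.6,
                              chain = c("heavy", "kappa", "lambda"),
                              j_criterion = TRUE,
                              max_near_duplicate_diff = 2,
                              terminal_tolerance = 10,
                              annotation_tolerance = 0,
                              max_evalue = 1e-3, min_v_coverage = 0.9,
                              min_j_coverage = 0.6, early_stop = FALSE,
                              min_reads_warning = 4e5, cache = TRUE,
                              verbose = FALSE) {
  chain <- match.arg(chain)
  stopifnot(iterations >= 1)
  reads <- check_reads(reads)
  starting_db <- check_db(v_db, "v_db")
  has_j <- !is.null(j_db) && nrow(j_db) > 0
  if (sum(reads$count) < min_reads_warning) {
    warn(sprintf(paste0("library has %d reads; a complete individualized ",
                        "genotype typically needs ~%d"),
                 sum(reads$count), as.integer(min_reads_warning)))
  }

  # assignment passes against an unchanged database are memoised (the loop
  # reassigns identical inputs once the database has converged)
  reads_key <- rlang::hash(list(reads$id, reads$sequence, reads$count,
                                if (has_j) j_db$sequence, chain))
  assign_pass <- function(db) {
    if (!cache) {
      asn <- assign_vj(reads, db, if (has_j) j_db else NULL, chain = chain)
    } else {
      key <- paste0("asn_", rlang::hash(list(reads_key, db$name,
                                             db$sequence)))
      asn <- .vgerm_env[[key]]
      if (is.null(asn)) {
        asn <- assign_vj(reads, db, if (has_j) j_db else NULL,
                         chain = chain)
        keys <- .vgerm_env$asn_keys %||% character(0)
        if (length(keys) >= 3) {  # keep at most 3 cached passes
          rm(list = keys[1], envir = .vgerm_env)
          keys <- keys[-1]
        }
        .vgerm_env$asn_keys <- c(keys, key)
        .vgerm_env[[key]] <- asn
      }
    }
    quality_filter(asn, max_evalue, min_v_coverage, min_j_coverage,
                   require_j = has_j)
  }

  db <- starting_db
  iter_results <- list()
  for (it in seq_len(iterations)) {
    mode <- if (it == iterations) "germline" else "pregermline"
    if (verbose) message(sprintf("iteration %d/%d (%s filter), %d alleles",
                                 it, iterations, mode, nrow(db)))
    asn <- assign_pass(db)
    cand <- discover_candidates(asn, subsample_size = subsample_size,
                                seed = seed + it,
                                window_width = window_width,
                                min_window_members = min_window_members,
                                min_subtree_size = min_subtree_size,
                                ratio_threshold = ratio_threshold,
                                majority = majority, cache = cache)
    cand <- annotate_candidates(cand, asn, annotation_tolerance)
    new_db <- apply_germline_filter(
      cand, mode, starting_db = starting_db, input_db = db,
      j_criterion = j_criterion,
      max_near_duplicate_diff = max_near_duplicate_diff,
      terminal_tolerance = terminal_tolerance)
    iter_results[[it]] <- list(iteration = it, mode = mode,
                               n_input_alleles = nrow(db),
                               candidates = attr(new_db, "candidates"),
                               database = new_db)
    if (nrow(new_db) == 0L) {
      abort(sprintf("database empty after iteration %d", it))
    }
    unchanged <- setequal(new_db$sequence, db$sequence)
    db <- new_db
    if (early_stop && unchanged && it < iterations) break
  }

  final_asn <- assign_pass(db)
  res <- structure(list(
    final_db = db,
    usage = usage_profile(db, final_asn),
    upstream = detect_upstream(final_asn, majority = majority),
    iterations = iter_results,
    final_assignments = final_asn,
    starting_db = starting_db,
    config = list(iterations = iterations, seed = seed,
                  subsample_size = subsample_size,
                  window_width = window_width, chain = chain,
                  j_criterion = j_criterion,
                  n_reads = sum(reads$count))),
    class = "germline_discovery")
  res
}

#' Per-allele gene usage profile
#'
#' Counts, for every allele of a database, the quality-passing reads
#' assigned to it and the distinct CDR3s among them. Unexpressed alleles
#' are reported with zeros; the read counts sum to the number of passing
#' reads.
#'
#' @param db A germline database tibble.
#' @param assignments Quality-passing assignments computed against
#'   \code{db}.
#' @return A tibble: \code{name}, \code{n_reads}, \code{n_unique_cdr3}.
#' @export
usage_profile <- function(db, assignments) {
  counts <- assignments |>
    dplyr::filter(!is.na(.data$v_name)) |>
    dplyr::group_by(name = .data$v_name) |>
    dplyr::summarise(n_reads = as.integer(sum(.data$count)),
                     n_unique_cdr3 = dplyr::n_distinct(.data$cdr3_nt,
                                                       na.rm = TRUE),
                     .groups = "drop")
  tibble(name = db$name) |>
    dplyr::left_join(counts, by = "name") |>
    dplyr::mutate(n_reads = dplyr::coalesce(.data$n_reads, 0L),
                  n_unique_cdr3 = dplyr::coalesce(.data$n_unique_cdr3, 0L))
}

#' Upstream (5'UTR + leader) consensus per allele
#'
#' For each allele, takes the reads assigned to it with a low V error rate,
#' keeps those whose upstream sequence is at least as long as the tenth
#' longest one (all of them when fewer than ten), right-aligns them at the
#' V start and calls a weighted majority consensus per column; columns that
#' most supporting reads do not reach are dropped.
#'
#' @param assignments Quality-passing assignments.
#' @param max_v_error_rate Maximum V percent difference / 100 for a read to
#'   support the consensus (default 0.01).
#' @param majority Per-column majority threshold.
#' @return A tibble: \code{name}, \code{upstream_consensus},
#'   \code{n_supporting}.
#' @export
detect_upstream <- function(assignments, max_v_error_rate = 0.01,
                            majority = 0.6) {
  asn <- assignments |>
    dplyr::filter(!is.na(.data$v_name),
                  .data$v_percent_difference <= max_v_error_rate * 100,
                  nchar(.data$upstream_sequence) > 0)
  if (nrow(asn) == 0L) {
    return(tibble(name = character(), upstream_consensus = character(),
                  n_supporting = integer()))
  }
  asn |>
    dplyr::group_by(name = .data$v_name) |>
    dplyr::group_modify(function(g, key) {
      len <- nchar(g$upstream_sequence)
      ord <- order(len, decreasing = TRUE)
      cutoff <- len[ord[min(10L, length(ord))]]
      g <- g[len >= cutoff, ]
      maxlen <- max(nchar(g$upstream_sequence))
      # right-align at the V start and vote per column
      padded <- vapply(g$upstream_sequence, function(s) {
        paste0(strrep(".", maxlen - nchar(s)), s)
      }, character(1), USE.NAMES = FALSE)
      mat <- matrix(unlist(strsplit(padded, "", fixed = TRUE)),
                    nrow = nrow(g), byrow = TRUE)
      w <- as.numeric(g$count)
      wtot <- sum(w)
      cons <- vapply(seq_len(maxlen), function(jc) {
        col <- mat[, jc]
        cover <- col != "."
        # columns most supporting reads do not reach are dropped
        if (sum(w[cover]) <= wtot / 2) return("")
        tot <- sum(w[cover])
        votes <- rowsum(w[cover], col[cover])
        b <- rownames(votes)[which.max(votes)]
        if (max(votes) >= majority * tot && b != "N") b else "N"
      }, character(1))
      tibble(upstream_consensus = paste(cons, collapse = ""),
             n_supporting = nrow(g))
    }) |>
    dplyr::ungroup()
}

#' Compare two germline databases
#'
#' Partitions the alleles of two databases into shared and
#' database-specific sets by terminal-tolerant sequence identity (small
#' length differences at the 5'/3' ends do not break a match). Each allele
#' is matched at most once; matching is deterministic (database order).
#'
#' @param a,b Germline database tibbles.
#' @param tolerance Terminal tolerance in nt (default 10).
#' @return A \code{db_comparison} list with tibbles \code{shared},
#'   \code{only_a}, \code{only_b}.
#' @export
compare_databases <- function(a, b, tolerance = 10) {
  a <- check_db(a, "a"); b <- check_db(b, "b")
  used_b <- logical(nrow(b))
  match_b <- rep(NA_integer_, nrow(a))
  for (i in seq_len(nrow(a))) {
    d <- cpp_terminal_diffs(b$sequence, a$sequence[i],
                            as.integer(tolerance))
    hit <- which(!is.na(d) & d == 0L & !used_b)
    if (length(hit) > 0L) {
      match_b[i] <- hit[1]
      used_b[hit[1]] <- TRUE
    }
  }
  shared <- tibble(name_a = a$name[!is.na(match_b)],
                   name_b = b$name[match_b[!is.na(match_b)]],
                   sequence_a = a$sequence[!is.na(match_b)],
                   sequence_b = b$sequence[match_b[!is.na(match_b)]])
  structure(list(
    shared = shared,
    only_a = a[is.na(match_b), c("name", "sequence")],
    only_b = b[!used_b, c("name", "sequence")]),
    class = "db_comparison")
}

#' @export
print.db_comparison <- function(x, ...) {
  cat(sprintf("database comparison: %d shared, %d only in a, %d only in b\n",
              nrow(x$shared), nrow(x$only_a), nrow(x$only_b)))
  invisible(x)
}

#' Write discovery results to a directory
#'
#' Writes the final database FASTA, the last-iteration candidate table, the
#' usage profile and the upstream consensus table, plus a run log with the
#' configuration.
#'
#' @param result A \code{germline_discovery} object.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_discovery_results <- function(result, dir) {
  stopifnot(inherits(result, "germline_discovery"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(result$final_db, file.path(dir, "new_V_germline.fasta"))
  readr::write_tsv(tidy(result), file.path(dir, "candidates.tsv"))
  readr::write_tsv(result$usage, file.path(dir, "usage_profile.tsv"))
  readr::write_tsv(result$upstream, file.path(dir, "upstream.tsv"))
  cfg <- result$config
  writeLines(c(paste0("vgerm ", as.character(utils::packageVersion("vgerm"))),
               paste(names(cfg), vapply(cfg, paste, character(1),
                                        collapse = ","), sep = "=")),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}
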