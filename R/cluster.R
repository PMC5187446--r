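#' Bin reads by percent difference to their assigned allele
#'
#' Reads assigned to one database allele are binned into half-open percent
#' difference windows \code{[0,w), [w,2w), ...} (default width 2). Each
#' populated bin with at least \code{min_members} distinct V-region
#' sequences becomes a window cluster whose members (with dereplication
#' counts as weights) later feed consensus building.
#'
#' @param assignments Quality-passing assignment rows (any mix of alleles;
#'   binning is per \code{v_name}).
#' @param width Window width in percent (default 2).
#' @param min_members Minimum number of distinct member sequences for a bin
#'   to be reported (default 5).
#' @return A tibble with one row per (allele, bin): \code{source_allele},
#'   \code{bin_lo}, \code{bin_hi}, \code{n_members} (distinct sequences),
#'   \code{n_reads} and a \code{members} list-column of
#'   \code{sequence}/\code{weight} tibbles.
#' @export
windowed_clusters <- function(assignments, width = 2, min_members = 5) {
  if (nrow(assignments) == 0L) {
    return(tibble(source_allele = character(), bin_lo = numeric(),
                  bin_hi = numeric(), n_members = integer(),
                  n_reads = integer(), members = list()))
  }
  assignments |>
    dplyr::filter(!is.na(.data$v_name)) |>
    dplyr::mutate(bin_lo = floor(.data$v_percent_difference / width) * width) |>
    dplyr::group_by(.data$v_name, .data$bin_lo, .data$v_sequence) |>
    dplyr::summarise(weight = sum(.data$count), .groups = "drop_last") |>
    dplyr::summarise(members = list(tibble(sequence = v_sequence,
                                           weight = weight)),
                     n_members = dplyr::n(),
                     n_reads = as.integer(sum(.data$weight)),
                     .groups = "drop") |>
    dplyr::mutate(bin_hi = .data$bin_lo + width) |>
    dplyr::filter(.data$n_members >= min_members) |>
    dplyr::select(source_allele = "v_name", "bin_lo", "bin_hi",
                  "n_members", "n_reads", "members") |>
    dplyr::arrange(.data$source_allele, .data$bin_lo)
}

#' Randomly subsample assignment rows
#'
#' Uniform sampling without replacement of at most \code{n} rows,
#' reproducible for a fixed seed; the identity when the input is already
#' small enough.
#'
#' @param assignments An assignment table.
#' @param n Target subsample size (default 1000).
#' @param seed Integer seed.
#' @return The subsampled rows (input order preserved).
#' @export
subsample_assignments <- function(assignments, n = 1000, seed = 1) {
  stopifnot(n >= 1)
  if (nrow(assignments) <= n) return(assignments)
  idx <- withr::with_seed(seed, sample.int(nrow(assignments), n))
  assignments[sort(idx), ]
}

#' Levenshtein edit distance
#'
#' Minimal number of single-base insertions, deletions and substitutions.
#' Computed with a bit-parallel dynamic programming algorithm; exact for
#' arbitrary strings.
#'
#' @param a,b Character vectors (recycled to common length).
#' @return Integer vector of distances.
#' @examples
#' levenshtein("ACGT", "AGT")
#' @export
levenshtein <- function(a, b) cpp_edit_distance(a, b)

#' Pairwise Levenshtein distance matrix
#'
#' @param sequences Character vector.
#' @return A symmetric integer matrix with zero diagonal.
#' @export
levenshtein_matrix <- function(sequences) {
  m <- cpp_edit_matrix(sequences)
  dimnames(m) <- list(names(sequences), names(sequences))
  m
}

#' UPGMA (average linkage) hierarchical clustering
#'
#' Agglomerative clustering where the height of each merge is the arithmetic
#' mean of all between-cluster pairwise distances. Merge heights are
#' monotone non-decreasing.
#'
#' @param distances A \code{dist} object or a symmetric numeric matrix with
#'   zero diagonal.
#' @return An \code{hclust} tree.
#' @export
upgma <- function(distances) {
  if (is.matrix(distances)) {
    if (nrow(distances) != ncol(distances) ||
        !isTRUE(all.equal(distances, t(distances))) ||
        any(diag(distances) != 0)) {
      abort("`distances` must be a symmetric matrix with zero diagonal")
    }
    distances <- as.dist(distances)
  }
  hclust(distances, method = "average")
}

# per-node subtree statistics of an hclust tree: leaf count, leaves, and the
# smallest/largest internal merge height (0 for leaves, per the convention
# that a leaf is maximally tight)
tree_stats <- function(tree) {
  nm <- nrow(tree$merge)
  size <- integer(nm); minh <- numeric(nm); maxh <- numeric(nm)
  leaves <- vector("list", nm)
  for (k in seq_len(nm)) {
    stats_of <- function(child) {
      if (child < 0) list(size = 1L, min = Inf, max = 0, leaves = -child)
      else list(size = size[child], min = minh[child], max = maxh[child],
                leaves = leaves[[child]])
    }
    a <- stats_of(tree$merge[k, 1]); b <- stats_of(tree$merge[k, 2])
    size[k] <- a$size + b$size
    minh[k] <- min(a$min, b$min, tree$height[k])
    maxh[k] <- max(a$max, b$max, tree$height[k])
    leaves[[k]] <- c(a$leaves, b$leaves)
  }
  list(size = size, minh = minh, maxh = maxh, leaves = leaves)
}

#' Detect subclusters in a UPGMA tree
#'
#' Scans every inner node whose two child subtrees both contain at least
#' \code{min_size} leaves. A child subtree A is reported as a subcluster
#' when the ratio of its smallest internal merge height to the largest
#' internal merge height of its sibling B is below \code{ratio_threshold}
#' (leaves and all-identical subtrees contribute height 0 and are maximally
#' detectable; a tight subtree next to another tight subtree is reported,
#' and a subtree next to a star-like sibling is not). All qualifying
#' subtrees are reported, including nested ones: fragments of one read
#' population converge to the same consensus downstream, while
#' heterogeneous ancestors produce ambiguous consensi that the germline
#' filter discards, so no overlap resolution is attempted here.
#'
#' @param tree An \code{hclust} tree from [upgma()].
#' @param min_size Minimum leaf count of both child subtrees (default 5).
#' @param ratio_threshold Detection threshold (default 0.8).
#' @return A tibble with one row per subcluster: \code{cluster_id},
#'   \code{n_members}, \code{ratio} and a \code{members} list-column of
#'   leaf indices.
#' @export
detect_subclusters <- function(tree, min_size = 5, ratio_threshold = 0.8) {
  empty <- tibble(cluster_id = integer(), n_members = integer(),
                  ratio = numeric(), members = list())
  nm <- nrow(tree$merge)
  if (is.null(nm) || nm < 1L) return(empty)
  st <- tree_stats(tree)
  cand <- list()
  for (k in order(tree$height, decreasing = TRUE)) {
    ch <- tree$merge[k, ]
    get <- function(child) {
      if (child < 0) list(size = 1L, min = 0, max = 0, leaves = -child)
      else list(size = st$size[child], min = st$minh[child],
                max = st$maxh[child], leaves = st$leaves[[child]])
    }
    a <- get(ch[1]); b <- get(ch[2])
    if (a$size < min_size || b$size < min_size) next
    ratio_ab <- if (b$max == 0) (if (a$min == 0) 0 else Inf) else a$min / b$max
    ratio_ba <- if (a$max == 0) (if (b$min == 0) 0 else Inf) else b$min / a$max
    if (ratio_ab < ratio_threshold) {
      cand[[length(cand) + 1L]] <- list(leaves = a$leaves, ratio = ratio_ab)
    }
    if (ratio_ba < ratio_threshold) {
      cand[[length(cand) + 1L]] <- list(leaves = b$leaves, ratio = ratio_ba)
    }
  }
  if (length(cand) == 0L) return(empty)
  tibble(cluster_id = seq_along(cand),
         n_members = vapply(cand, function(x) length(x$leaves), integer(1)),
         ratio = vapply(cand, function(x) x$ratio, numeric(1)),
         members = lapply(cand, function(x) sort(x$leaves)))
}

#' Majority-vote consensus of near-identical sequences
#'
#' Members are aligned to the highest-weight member (center-star projection;
#' members of equal length are projected column by column, others through
#' the banded affine aligner) and each column is called by weighted vote:
#' a base is emitted if it reaches at least \code{majority} (default 60%)
#' of the non-gap weight, columns with a gap majority are deleted, and
#' undecided columns become N.
#'
#' @param sequences Character vector of member sequences.
#' @param weights Optional numeric vote weights (dereplication counts);
#'   default 1 each.
#' @param majority Majority threshold, boundary-inclusive (default 0.6).
#' @param band_half Alignment band half-width for length-discordant members.
#' @return The consensus string (possibly containing N).
#' @examples
#' consensus_sequence(c("ACGTT", "ACGTT", "ACCTT"))
#' @export
consensus_sequence <- function(sequences, weights = NULL, majority = 0.6,
                               band_half = 16) {
  stopifnot(length(sequences) >= 1)
  weights <- weights %||% rep(1, length(sequences))
  agg <- rowsum(weights, sequences)
  as.character(cpp_consensus(rownames(agg), as.numeric(agg), majority,
                             1L, -2L, -5L, -2L, as.integer(band_half)))
}

# distance matrix with memoisation across iterations/runs (groups of reads
# recur once the database has converged)
edit_matrix_cached <- function(seqs, cache = TRUE) {
  if (!cache) return(cpp_edit_matrix(seqs))
  key <- paste0("dm_", rlang::hash(seqs))
  hit <- .vgerm_env[[key]]
  if (!is.null(hit)) return(hit)
  m <- cpp_edit_matrix(seqs)
  .vgerm_env[[key]] <- m
  m
}

#' Discover candidate germline sequences from an assignment table
#'
#' For every database allele with assigned reads, candidate consensus
#' sequences are built from three sources: the percent-difference window
#' clusters, the subclusters of a UPGMA tree over Levenshtein distances of
#' a random subsample, and (optionally) the full set of assigned reads.
#' Identical candidate sequences from different sources are merged, keeping
#' the largest originating cluster size.
#'
#' @param assignments Quality-passing assignment rows.
#' @param subsample_size Linkage-clustering subsample size (default 1000).
#' @param seed Seed for the subsampling.
#' @param window_width,min_window_members Passed to [windowed_clusters()].
#' @param min_subtree_size,ratio_threshold Passed to [detect_subclusters()].
#' @param majority Consensus majority threshold.
#' @param include_full Also build one consensus over all reads per allele.
#' @param cache Memoise distance matrices across calls (default TRUE).
#' @return A candidate tibble: \code{name}, \code{source_allele},
#'   \code{origin}, \code{sequence}, \code{cluster_size} (distinct member
#'   sequences of the originating cluster).
#' @export
discover_candidates <- function(assignments, subsample_size = 1000, seed = 1,
                                window_width = 2, min_window_members = 5,
                                min_subtree_size = 5, ratio_threshold = 0.8,
                                majority = 0.6, include_full = TRUE,
                                cache = TRUE) {
  wins <- windowed_clusters(assignments, window_width, min_window_members)
  out <- list()
  if (nrow(wins) > 0L) {
    out$window <- tibble(
      source_allele = wins$source_allele,
      origin = sprintf("window[%g,%g)", wins$bin_lo, wins$bin_hi),
      sequence = vapply(wins$members, function(m) {
        consensus_sequence(m$sequence, m$weight, majority)
      }, character(1)),
      cluster_size = wins$n_members)
  }

  alleles <- sort(unique(assignments$v_name[!is.na(assignments$v_name)]))
  link <- list(); full <- list()
  withr::with_seed(seed, for (al in alleles) {
    rows <- assignments[!is.na(assignments$v_name) &
                          assignments$v_name == al, ]
    if (include_full && nrow(rows) >= min_window_members) {
      full[[al]] <- tibble(
        source_allele = al, origin = "full",
        sequence = consensus_sequence(rows$v_sequence, rows$count, majority),
        cluster_size = dplyr::n_distinct(rows$v_sequence))
    }
    if (nrow(rows) > subsample_size) {
      rows <- rows[sort(sample.int(nrow(rows), subsample_size)), ]
    }
    agg <- rowsum(as.numeric(rows$count), rows$v_sequence)
    seqs <- rownames(agg); w <- as.numeric(agg)
    if (length(seqs) < 2L * min_subtree_size) next
    tree <- upgma(as.dist(edit_matrix_cached(seqs, cache)))
    sub <- detect_subclusters(tree, min_subtree_size, ratio_threshold)
    if (nrow(sub) == 0L) next
    link[[al]] <- tibble(
      source_allele = al,
      origin = sprintf("linkage%d", sub$cluster_id),
      sequence = vapply(sub$members, function(mi) {
        consensus_sequence(seqs[mi], w[mi], majority)
      }, character(1)),
      cluster_size = sub$n_members)
  })
  out$linkage <- dplyr::bind_rows(link)
  out$full <- dplyr::bind_rows(full)

  cand <- dplyr::bind_rows(out)
  if (nrow(cand) == 0L) {
    return(tibble(name = character(), source_allele = character(),
                  origin = character(), sequence = character(),
                  cluster_size = integer()))
  }
  cand <- cand |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(source_allele = dplyr::first(.data$source_allele),
                     origin = dplyr::first(.data$origin),
                     cluster_size = max(.data$cluster_size),
                     .groups = "drop")
  cand$name <- sprintf("%s_S%04d", cand$source_allele,
                       seq_hash4(cand$sequence))
  cand$name <- make.unique(cand$name, sep = "x")
  cand[, c("name", "source_allele", "origin", "sequence", "cluster_size")]
}
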