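#' @export
print.germline_discovery <- function(x, ...) {
  cat("Individualized germline V database\n")
  cat(sprintf("  %d iterations on %d reads, starting from %d alleles\n",
              length(x$iterations), x$config$n_reads, nrow(x$starting_db)))
  cat(sprintf("  final database: %d alleles (%d whitelisted, %d discovered)\n",
              nrow(x$final_db), sum(x$final_db$source == "whitelisted"),
              sum(x$final_db$source == "discovered")))
  expressed <- sum(x$usage$n_reads > 0)
  cat(sprintf("  expressed alleles in final assignment: %d\n", expressed))
  invisible(x)
}

#' Tidy the candidate table of a discovery run
#'
#' Returns the fully annotated candidate table of the last iteration (one
#' row per candidate consensus with its evidence counts, filter verdict and
#' reason).
#'
#' @param x A \code{germline_discovery} object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.germline_discovery <- function(x, ...) {
  last <- x$iterations[[length(x$iterations)]]
  as_tibble(last$candidates)
}

#' One-row summary of a discovery run
#'
#' @param x A \code{germline_discovery} object.
#' @param ... Unused.
#' @return A one-row tibble: input/final allele counts, read count,
#'   iteration count, and how many final alleles were newly discovered.
#' @export
glance.germline_discovery <- function(x, ...) {
  tibble(n_reads = x$config$n_reads,
         n_iterations = length(x$iterations),
         n_starting_alleles = nrow(x$starting_db),
         n_final_alleles = nrow(x$final_db),
         n_discovered = sum(x$final_db$source == "discovered"),
         n_whitelisted = sum(x$final_db$source == "whitelisted"),
         n_expressed = sum(x$usage$n_reads > 0))
}

#' Percent-difference histogram of assignments
#'
#' The windowed-clustering view: for each database allele, a histogram of
#' the percent differences of its assigned reads in half-open bins. A
#' second mode to the right of zero indicates reads from an allele missing
#' from the database.
#'
#' @param assignments An assignment table.
#' @param alleles Optional subset of allele names to show.
#' @param width Bin width in percent (default 2, the clustering window).
#' @return A ggplot object.
#' @export
plot_difference_histogram <- function(assignments, alleles = NULL,
                                      width = 2) {
  d <- assignments |> dplyr::filter(!is.na(.data$v_name))
  if (!is.null(alleles)) d <- d |> dplyr::filter(.data$v_name %in% alleles)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$v_percent_difference,
                                  weight = .data$count)) +
    ggplot2::geom_histogram(boundary = 0, binwidth = width,
                            closed = "left", fill = "grey30") +
    ggplot2::facet_wrap(~v_name, scales = "free_y") +
    ggplot2::labs(x = "% difference to assigned allele", y = "reads")
}

#' Gene usage profile plot
#'
#' Per-allele bar chart of assigned read counts and unique CDR3 counts.
#'
#' @param usage A usage profile from [usage_profile()].
#' @return A ggplot object.
#' @export
plot_usage <- function(usage) {
  d <- usage |>
    tidyr::pivot_longer(c("n_reads", "n_unique_cdr3"),
                        names_to = "metric", values_to = "n") |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
                                         n_reads = "assigned reads",
                                         n_unique_cdr3 = "unique CDR3s"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$name, y = .data$n,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c("assigned reads" = "#3366aa",
                                          "unique CDR3s" = "#aa3333")) +
    ggplot2::labs(x = NULL, y = "count", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for discovery results
#'
#' Plots the gene usage profile of the final database.
#'
#' @param object A \code{germline_discovery} object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.germline_discovery <- function(object, ...) {
  plot_usage(object$usage)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
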