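#' Read sequences from FASTA or FASTQ
#'
#' Reads a (possibly gzip-compressed) FASTA or FASTQ file into a read table.
#' Dereplication size annotations of the form \code{";size=<n>"} on FASTA
#' headers are parsed into the \code{count} column.
#'
#' @param path Path to a FASTA or FASTQ file; \code{.gz} variants are
#'   accepted. The format is taken from the file extension unless given.
#' @param format \code{"auto"} (default), \code{"fasta"} or \code{"fastq"}.
#' @return A tibble with columns \code{id}, \code{sequence}, \code{quality}
#'   (NA for FASTA) and \code{count}.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1;size=3", "ACGT", ">r2", "GGGT"), fa)
#' read_sequences(fa)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(fastq|fq)$", base)) "fastq" else "fasta"
  }
  if (format == "fastq") {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    quality <- as.character(S4Vectors::mcols(x)$qualities)
  } else {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
    quality <- rep(NA_character_, length(x))
  }
  header <- names(x)
  id <- sub("[ \t].*$", "", header)
  count <- rep(1L, length(x))
  sized <- grepl(";size=\\d+", id)
  count[sized] <- as.integer(sub("^.*;size=(\\d+).*$", "\\1", id[sized]))
  id <- sub(";size=\\d+;?", "", id)
  tibble(id = unname(id), sequence = unname(toupper(as.character(x))),
         quality = unname(quality), count = count)
}

#' Write sequences to FASTA
#'
#' Accepts either a read table (\code{id}/\code{sequence}/\code{count}) or a
#' germline database (\code{name}/\code{sequence}).
#'
#' @param x A tibble of reads or alleles.
#' @param path Output path.
#' @param size_annotations Append \code{";size=<count>"} to headers (the
#'   conventional encoding of dereplication counts).
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(x, path, size_annotations = FALSE) {
  id <- if ("name" %in% names(x)) x$name else x$id
  if (size_annotations && "count" %in% names(x)) {
    id <- paste0(id, ";size=", x$count)
  }
  seqs <- Biostrings::DNAStringSet(x$sequence)
  names(seqs) <- id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a germline V or J database from FASTA
#'
#' @param path FASTA file; the allele name is the first whitespace-delimited
#'   token of each header.
#' @param source Provenance label recorded for each allele.
#' @return A tibble with columns \code{name}, \code{sequence}, \code{source}.
#' @export
read_germline_db <- function(path, source = "starting") {
  x <- read_sequences(path, format = "fasta")
  check_db(tibble(name = x$id, sequence = x$sequence, source = source))
}
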