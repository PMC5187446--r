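# internal helpers shared across modules

BASES <- c("A", "C", "G", "T")

# stable 4-digit hash of a sequence string, used for candidate allele names
seq_hash4 <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 999983
    as.integer(h %% 10000)
  }, integer(1), USE.NAMES = FALSE)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# translate in frame 1, trimming any incomplete trailing codon; codons with
# ambiguous bases become X
translate_nt <- function(x) {
  as.character(cpp_translate(x))
}

has_stop_codon <- function(x) grepl("*", translate_nt(x), fixed = TRUE)

# Karlin-Altschul lambda for an ungapped match/mismatch scheme under uniform
# base composition; memoised. Used by the E-value surrogate.
karlin_lambda <- function(match, mismatch) {
  key <- paste0("lambda_", match, "_", mismatch)
  if (!is.null(.vgerm_env[[key]])) return(.vgerm_env[[key]])
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  lam <- stats::uniroot(f, c(1e-6, 10), tol = 1e-10)$root
  .vgerm_env[[key]] <- lam
  lam
}

check_reads <- function(reads) {
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  reads <- as_tibble(reads)
  if (!"count" %in% names(reads)) reads$count <- 1L
  if (!"quality" %in% names(reads)) reads$quality <- NA_character_
  reads
}

check_db <- function(db, arg = "database") {
  stopifnot(is.data.frame(db), all(c("name", "sequence") %in% names(db)))
  db <- as_tibble(db)
  if (nrow(db) == 0L) abort(paste0(arg, " is empty"))
  if (anyDuplicated(db$name)) abort(paste0("duplicate allele names in ", arg))
  if (anyDuplicated(db$sequence)) {
    abort(paste0("duplicate allele sequences in ", arg))
  }
  if (!"source" %in% names(db)) db$source <- "starting"
  db
}
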