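# Internal helpers. Coordinates are 0-based half-open throughout the package;
# conversions to R's 1-based substring indexing happen locally where needed.

.BASES <- c("A", "C", "G", "T")

# Phred character lookup: .QCHAR[q + 1] is the Phred+33 character for quality q
.QCHAR <- strsplit(rawToChar(as.raw(33:126)), "", fixed = TRUE)[[1]]

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T, case preserved).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("GCGCAATGTGGCTCCGGGAC")
revcomp <- function(x) {
  comp <- chartr("ACGTacgtN", "TGCAtgcaN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

phred_to_int <- function(qual, offset = 33L) {
  lapply(qual, function(q) utf8ToInt(q) - offset)
}

int_to_phred <- function(q, offset = 33L) {
  intToUtf8(q + offset)
}

# all 1-based start positions of fixed pattern `pat` in `text`, overlaps included
find_all_fixed <- function(text, pat) {
  n <- nchar(text)
  m <- nchar(pat)
  if (m > n) return(integer())
  starts <- seq_len(n - m + 1L)
  starts[substring(text, starts, starts + m - 1L) == pat]
}

random_dna <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == as.integer(x)
}

is_prob <- function(x) {
  is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x <= 1)
}

# write a data.frame as TSV with '#'-prefixed provenance comment lines
write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
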