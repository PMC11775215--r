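# Read filtering: 3' quality trimming (BWA-style suffix-sum rule, matching a
# cutadapt/bwa `-q` trim), minimum-length filtering, and optional pair merging
# by best ungapped overlap.

#' Trimming and length-filter policy
#'
#' Defaults reproduce a `-q 20 -m 100` filtering contract: 3' quality
#' trimming at Phred 20 and discarding of reads shorter than 100 bp.
#'
#' @param quality_threshold Phred threshold for 3' trimming.
#' @param min_length minimum retained read length in nt.
#' @param phred_offset quality-string offset (Phred+33 by default).
#' @return a `trim_policy` list.
#' @export
trim_policy <- function(quality_threshold = 20L, min_length = 100L,
                        phred_offset = 33L) {
  stopifnot(quality_threshold >= 0L, min_length >= 1L)
  structure(list(quality_threshold = as.integer(quality_threshold),
                 min_length = as.integer(min_length),
                 phred_offset = as.integer(phred_offset)),
            class = "trim_policy")
}

#' 3' quality trimming (suffix-sum rule)
#'
#' Implements the BWA-style rule: with `d_j = q_j - threshold`, the suffix
#' starting at the index `i` minimizing `sum_{j >= i} d_j` is removed when
#' that minimum is negative; otherwise the read is unchanged. Ties are broken
#' toward the longest retained read. The output is always a prefix of the
#' input and trimming is idempotent.
#'
#' @param seq,qual parallel character vectors of sequences and quality
#'   strings (equal lengths per element).
#' @param policy a [trim_policy()].
#' @return list with trimmed `seq` and `qual`.
#' @export
#' @examples
#' # qualities 30,30,30,10,10 at threshold 20: the last two bases are trimmed
#' quality_trim_3prime("ACGTA", rawToChar(as.raw(33 + c(30, 30, 30, 10, 10))))
quality_trim_3prime <- function(seq, qual, policy = trim_policy()) {
  if (length(seq) != length(qual)) stop("seq and qual lengths differ")
  if (any(nchar(seq) != nchar(qual))) {
    stop("sequence/quality length mismatch within a read")
  }
  keep <- cq_trim3(qual, policy$quality_threshold, policy$phred_offset)
  list(seq = substring(seq, 1L, keep), qual = substring(qual, 1L, keep))
}

#' Minimum-length filter
#'
#' Keeps reads of length `>= min_length` ("shorter than" the threshold is
#' discarded, so a read of exactly the threshold length is kept).
#'
#' @param seq character vector of (trimmed) sequences.
#' @param policy a [trim_policy()].
#' @return logical keep/discard vector.
#' @export
length_filter <- function(seq, policy = trim_policy()) {
  nchar(seq) >= policy$min_length
}

#' Merge read pairs by best ungapped overlap
#'
#' Finds the best ungapped overlap between R1 and the reverse complement of
#' R2 (best = maximal matches minus mismatches among overlaps of at least
#' `min_overlap` nt with mismatch fraction at most `max_mismatch_frac`).
#' The consensus base at a mismatch is the higher-quality call (tie: R1).
#' Pairs with no acceptable overlap are returned unmerged.
#'
#' @param r1,q1,r2,q2 parallel character vectors of mate sequences and
#'   qualities (R2 in raw sequencing orientation).
#' @param min_overlap minimum overlap length in nt.
#' @param max_mismatch_frac maximum mismatch fraction in the overlap.
#' @return list with logical `merged` and, where merged, consensus `seq` and
#'   `qual` (NA otherwise).
#' @export
merge_pairs <- function(r1, q1, r2, q2, min_overlap = 20L,
                        max_mismatch_frac = 0.25) {
  stopifnot(min_overlap >= 1L, max_mismatch_frac >= 0, max_mismatch_frac <= 1)
  cq_merge_pairs(r1, q1, r2, q2, as.integer(min_overlap), max_mismatch_frac)
}

read_fastq <- function(path) {
  out <- tryCatch(suppressWarnings({
    x <- Biostrings::readQualityScaledDNAStringSet(path)
    list(id = names(x),
         seq = as.character(x),
         qual = as.character(Biostrings::quality(x)))
  }), error = function(e) {
    stop(sprintf("failed to parse FASTQ file '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  bad <- which(nchar(out$seq) != nchar(out$qual))
  if (length(bad)) {
    stop(sprintf("failed to parse FASTQ file '%s': sequence/quality length mismatch at record %d",
                 path, bad[1]), call. = FALSE)
  }
  out
}

#' Preprocess one paired-end sample
#'
#' Trims both mates at the 3' end, applies the minimum-length filter, and
#' (for `pairing = "merge"`) merges surviving pairs by overlap consensus.
#' Downstream analysis uses the merged read where merging succeeded and R1
#' alone otherwise; with `pairing = "r1_only"` R1 is always used. Pairs whose
#' R1 fails the length filter are dropped.
#'
#' @param r1_path,r2_path FASTQ paths (gzip transparent). `r2_path = NULL`
#'   processes R1 alone.
#' @param policy a [trim_policy()].
#' @param pairing `"merge"` or `"r1_only"`.
#' @param min_overlap,max_mismatch_frac see [merge_pairs()].
#' @return list with `id`, `seq`, `qual` of the reads to analyze and a
#'   `report` of counts (pairs in, kept after trimming/length, merged,
#'   unmerged R1 used, dropped).
#' @export
preprocess_sample <- function(r1_path, r2_path = NULL, policy = trim_policy(),
                              pairing = c("merge", "r1_only"),
                              min_overlap = 20L, max_mismatch_frac = 0.25) {
  pairing <- match.arg(pairing)
  f1 <- read_fastq(r1_path)
  t1 <- quality_trim_3prime(f1$seq, f1$qual, policy)
  keep1 <- length_filter(t1$seq, policy)
  report <- list(n_pairs_in = length(f1$seq),
                 n_r1_kept = sum(keep1))
  if (is.null(r2_path) || pairing == "r1_only") {
    report$n_merged <- 0L
    report$n_r1_used <- sum(keep1)
    report$n_dropped <- sum(!keep1)
    return(list(id = f1$id[keep1], seq = t1$seq[keep1], qual = t1$qual[keep1],
                report = report))
  }
  f2 <- read_fastq(r2_path)
  if (length(f2$seq) != length(f1$seq)) {
    stop(sprintf("R1/R2 record counts differ between '%s' and '%s'",
                 r1_path, r2_path))
  }
  t2 <- quality_trim_3prime(f2$seq, f2$qual, policy)
  keep2 <- length_filter(t2$seq, policy)
  report$n_r2_kept <- sum(keep2)
  use <- keep1                       # R1 must survive; R2 optional
  both <- keep1 & keep2
  out_id <- f1$id[use]
  out_seq <- t1$seq[use]
  out_qual <- t1$qual[use]
  merged_flag <- logical(sum(use))
  if (any(both)) {
    m <- merge_pairs(t1$seq[both], t1$qual[both], t2$seq[both], t2$qual[both],
                     min_overlap, max_mismatch_frac)
    idx_in_use <- match(which(both), which(use))
    ok <- m$merged
    out_seq[idx_in_use[ok]] <- m$seq[ok]
    out_qual[idx_in_use[ok]] <- m$qual[ok]
    merged_flag[idx_in_use[ok]] <- TRUE
  }
  report$n_merged <- sum(merged_flag)
  report$n_r1_used <- sum(use) - sum(merged_flag)
  report$n_dropped <- sum(!use)
  list(id = out_id, seq = out_seq, qual = out_qual, merged = merged_flag,
       report = report)
}
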