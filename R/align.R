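# Deterministic pairwise glocal alignment: global in the read, free end gaps
# on the reference. The affine-gap dynamic program (Gotoh) lives in
# src/align.cpp; backtrace ties resolve diagonal > deletion > insertion and
# internal gaps are left-normalized afterwards, so indel placement is
# deterministic and VCF-like.

#' Alignment scoring parameters
#'
#' Affine gap scores; a gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param match,mismatch,gap_open,gap_extend integer scores (gap scores
#'   negative).
#' @return an `align_scoring` list.
#' @export
align_scoring <- function(match = 5L, mismatch = -4L,
                          gap_open = -10L, gap_extend = -1L) {
  stopifnot(match > 0L, mismatch < match, gap_open <= 0L, gap_extend <= 0L)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend)),
            class = "align_scoring")
}

#' Glocal alignment of one read against a reference
#'
#' @param read DNA string (non-empty).
#' @param ref a [reference_amplicon()] or DNA string.
#' @param scoring an [align_scoring()].
#' @return a `glocal_alignment`: `score`, `ref_start`/`ref_end` (0-based
#'   half-open reference span covered), `ops` (data.frame of `M`/`D`/`I`
#'   runs with 0-based `ref_pos`, `len`, `read_pos`; for `I` ops `ref_pos`
#'   is the gap position), and `mismatch_ref_pos`.
#' @export
#' @examples
#' aln <- align_glocal("ACGTAC", "TTACGTACTT")
#' aln$ops
align_glocal <- function(read, ref, scoring = align_scoring()) {
  refseq <- if (inherits(ref, "reference_amplicon")) ref$sequence else ref
  if (nchar(read) == 0L || nchar(refseq) == 0L) stop("read and reference must be non-empty")
  out <- cq_align_detail(toupper(read), toupper(refseq),
                         scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_extend)
  out$read <- toupper(read)
  out$ref <- toupper(refseq)
  structure(out, class = "glocal_alignment")
}

#' @export
print.glocal_alignment <- function(x, ...) {
  cat(sprintf("Glocal alignment: score %d, reference span [%d, %d)\n",
              x$score, x$ref_start, x$ref_end))
  if (nrow(x$ops)) print(x$ops) else cat("  (empty)\n")
  if (length(x$mismatch_ref_pos)) {
    cat("  mismatches at ref:", paste(x$mismatch_ref_pos, collapse = ", "), "\n")
  }
  invisible(x)
}

# vectorized alignment statistics of many reads against one reference with a
# quantification window [ws, we): score, covered ref span, and window-local
# indel event count, net indel length and substitution count
align_stats <- function(reads, refseq, window_span, scoring = align_scoring()) {
  cq_align_stats(reads, refseq, window_span[1], window_span[2],
                 scoring$match, scoring$mismatch,
                 scoring$gap_open, scoring$gap_extend)
}
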