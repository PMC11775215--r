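# Reference amplicons and Cas9 target sites.
#
# All coordinates are 0-based half-open intervals on the amplicon sequence;
# `cut_pos` is a gap coordinate naming the bond before the indexed base, so a
# blunt Cas9 cut between bases 66 and 67 has cut_pos = 67.

#' Spacer sequences of the two IgM gRNAs
#'
#' The two 20-nt spacers used to target the mu-1 exon of the duplicated
#' Atlantic salmon IgM heavy-chain loci (A and B). Both spacers match both
#' loci; which one is used is an input to the pipeline, not hard-coded.
#'
#' @return named character vector with elements `IgM_1` and `IgM_2`.
#' @export
#' @examples
#' igm_spacers()
igm_spacers <- function() {
  c(IgM_1 = "GCGCAATGTGGCTCCGGGAC",
    IgM_2 = "CTGGCTTCACGCCTGCCTCC")
}

#' Locate a protospacer + NGG PAM on a reference sequence
#'
#' Scans both strands of `reference` for the unique occurrence of the 20-nt
#' `spacer` immediately 5'-adjacent to an NGG PAM. The predicted blunt cut
#' site lies between protospacer positions 17 and 18 (3 nt from the PAM) on
#' the protospacer strand.
#'
#' @param reference DNA string (length >= 23).
#' @param spacer 20-nt DNA string over A/C/G/T.
#' @return a `target_site`: list with `spacer`, `strand` ("+" or "-"),
#'   `protospacer_span`, `pam_span` (0-based half-open), and `cut_pos`
#'   (gap coordinate).
#' @export
#' @examples
#' ref <- paste0(strrep("A", 10), "GCGCAATGTGGCTCCGGGAC", "TGG", strrep("C", 10))
#' locate_protospacer(ref, igm_spacers()[["IgM_1"]])
locate_protospacer <- function(reference, spacer) {
  reference <- toupper(reference)
  spacer <- toupper(spacer)
  if (nchar(reference) < 23L) stop("reference must be at least 23 nt")
  if (nchar(spacer) != 20L || grepl("[^ACGT]", spacer)) {
    stop("spacer must be an exact 20-mer over A/C/G/T")
  }
  n <- nchar(reference)
  hits <- list()
  # + strand: spacer followed by NGG
  for (s1 in find_all_fixed(reference, spacer)) {
    s0 <- s1 - 1L                       # 0-based protospacer start
    if (s0 + 23L > n) next
    pam <- substring(reference, s1 + 20L, s1 + 22L)
    if (substring(pam, 2L, 3L) == "GG") {
      hits[[length(hits) + 1L]] <- list(
        spacer = spacer, strand = "+",
        protospacer_span = c(s0, s0 + 20L),
        pam_span = c(s0 + 20L, s0 + 23L),
        cut_pos = s0 + 17L)
    }
  }
  # - strand: reverse complement of spacer, preceded by CCN on the + strand
  rc <- revcomp(spacer)
  for (s1 in find_all_fixed(reference, rc)) {
    s0 <- s1 - 1L
    if (s0 - 3L < 0L) next
    if (substring(reference, s1 - 3L, s1 - 3L) == "C" &&
        substring(reference, s1 - 2L, s1 - 2L) == "C") {
      hits[[length(hits) + 1L]] <- list(
        spacer = spacer, strand = "-",
        protospacer_span = c(s0, s0 + 20L),
        pam_span = c(s0 - 3L, s0),
        cut_pos = s0 + 3L)
    }
  }
  if (length(hits) == 0L) stop("target not found")
  if (length(hits) > 1L) stop("ambiguous target")
  structure(hits[[1L]], class = "target_site")
}

#' @export
print.target_site <- function(x, ...) {
  cat(sprintf("Cas9 target site: %s strand %s\n", x$spacer, x$strand))
  cat(sprintf("  protospacer [%d, %d), PAM [%d, %d), cut at %d\n",
              x$protospacer_span[1], x$protospacer_span[2],
              x$pam_span[1], x$pam_span[2], x$cut_pos))
  invisible(x)
}

#' Construct a reference amplicon
#'
#' Bundles a locus-specific amplicon sequence with its primer spans and the
#' located Cas9 target site. Primer spans may be zero-length (e.g. `c(0, 0)`)
#' when the amplicon carries no primer sequence.
#'
#' @param locus_id label, e.g. `"IgM_A"`.
#' @param sequence uppercase DNA string over A/C/G/T.
#' @param spacer 20-nt spacer; its unique protospacer/PAM occurrence is
#'   located on either strand.
#' @param primer_fwd,primer_rev 0-based half-open spans of the forward and
#'   reverse primers on `sequence`; default zero-length spans at the ends.
#' @return a `reference_amplicon` object.
#' @export
reference_amplicon <- function(locus_id, sequence, spacer,
                               primer_fwd = NULL, primer_rev = NULL) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (grepl("[^ACGT]", sequence)) stop("amplicon sequence must contain only A/C/G/T")
  primer_fwd <- as.integer(primer_fwd %||% c(0L, 0L))
  primer_rev <- as.integer(primer_rev %||% c(n, n))
  for (sp in list(primer_fwd, primer_rev)) {
    if (length(sp) != 2L || sp[1] > sp[2] || sp[1] < 0L || sp[2] > n) {
      stop("primer spans must be 0-based half-open intervals within the amplicon")
    }
  }
  site <- locate_protospacer(sequence, spacer)
  if (site$cut_pos <= primer_fwd[2] || site$cut_pos >= primer_rev[1]) {
    stop("primer spans must not overlap the cut position")
  }
  structure(list(locus_id = locus_id, sequence = sequence,
                 primer_fwd_span = primer_fwd, primer_rev_span = primer_rev,
                 target_site = site),
            class = "reference_amplicon")
}

#' @export
print.reference_amplicon <- function(x, ...) {
  cat(sprintf("Reference amplicon '%s' (%d nt)\n", x$locus_id, nchar(x$sequence)))
  cat(sprintf("  primers [%d, %d) / [%d, %d)\n",
              x$primer_fwd_span[1], x$primer_fwd_span[2],
              x$primer_rev_span[1], x$primer_rev_span[2]))
  print(x$target_site)
  invisible(x)
}

# inter-primer region of an amplicon, 0-based half-open
inter_primer_span <- function(amp) {
  c(amp$primer_fwd_span[2], amp$primer_rev_span[1])
}

#' Define the quantification window of an amplicon
#'
#' The quantification window is the reference interval in which indels and
#' substitutions are counted when classifying reads. `"full_amplicon"` uses
#' the whole inter-primer region; `"cut_centered"` uses
#' `[cut_pos - halfwidth, cut_pos + halfwidth)` clipped to the inter-primer
#' region.
#'
#' @param amp a [reference_amplicon()].
#' @param mode `"full_amplicon"` or `"cut_centered"`.
#' @param halfwidth window half-width in nt for `cut_centered` mode.
#' @return a `quant_window`: list with `span` (0-based half-open) and `mode`.
#' @export
quant_window <- function(amp, mode = c("full_amplicon", "cut_centered"),
                         halfwidth = 30L) {
  mode <- match.arg(mode)
  ip <- inter_primer_span(amp)
  cut <- amp$target_site$cut_pos
  if (mode == "full_amplicon") {
    span <- ip
  } else {
    if (halfwidth < 1L) stop("halfwidth must be >= 1 for cut_centered mode")
    span <- c(max(ip[1], cut - halfwidth), min(ip[2], cut + halfwidth))
  }
  if (span[1] >= span[2]) stop("quantification window is empty after clipping")
  if (cut < span[1] || cut > span[2]) stop("cut position not inside window")
  structure(list(span = span, mode = mode), class = "quant_window")
}

#' Generate a pair of synthetic near-identical reference amplicons
#'
#' Builds two synthetic amplicons ("IgM_A", "IgM_B") that both carry the
#' given spacer + NGG PAM at the amplicon midpoint, flanked by primer
#' sequences, with locus B differing from locus A at `divergence` positions
#' outside the target-site region. This emulates a duplicated-genome locus
#' pair (e.g. the salmonid IgM A/B paralogs); the sequences outside the
#' printed spacer are synthetic, not the real loci.
#'
#' @param seed integer seed making the pair reproducible.
#' @param length amplicon length in nt.
#' @param primer_len primer length at each end.
#' @param spacer 20-nt spacer to embed (default the IgM-1 spacer).
#' @param divergence number of paralog-distinguishing substitutions.
#' @return named list of two [reference_amplicon()] objects.
#' @export
#' @examples
#' amps <- synthetic_amplicons(seed = 101)
#' amps$IgM_A
synthetic_amplicons <- function(seed = 101L, length = 180L, primer_len = 20L,
                                spacer = igm_spacers()[["IgM_1"]],
                                divergence = 6L) {
  stopifnot(length >= 2L * primer_len + 60L)
  with_seed(seed, {
    s0 <- as.integer(floor(length / 2)) - 17L  # 0-based protospacer start; cut at mid
    repeat {
      chars <- sample(.BASES, length, replace = TRUE)
      chars[(s0 + 1L):(s0 + 20L)] <- strsplit(spacer, "", fixed = TRUE)[[1]]
      chars[(s0 + 22L):(s0 + 23L)] <- c("G", "G")  # NGG PAM (N kept random)
      seq_a <- paste(chars, collapse = "")
      # require a unique site so locate_protospacer() succeeds
      ok <- tryCatch({
        locate_protospacer(seq_a, spacer)
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
    }
    # paralog divergence outside the target-site neighbourhood and primers
    protect <- seq(s0 - 5L, s0 + 28L)
    candidates <- setdiff(seq(primer_len, length - primer_len - 1L), protect)
    div_pos <- sort(sample(candidates, divergence))   # 0-based
    chars_b <- chars
    for (p in div_pos) {
      chars_b[p + 1L] <- sample(setdiff(.BASES, chars_b[p + 1L]), 1L)
    }
    seq_b <- paste(chars_b, collapse = "")
    pf <- c(0L, primer_len)
    pr <- c(length - primer_len, length)
    list(IgM_A = reference_amplicon("IgM_A", seq_a, spacer, pf, pr),
         IgM_B = reference_amplicon("IgM_B", seq_b, spacer, pf, pr))
  })
}

#' Write reference amplicons to FASTA plus a JSON sidecar
#'
#' @param amps named list of [reference_amplicon()] objects.
#' @param fasta,sites output paths for the FASTA file and the JSON target-site
#'   sidecar (primer spans, spacer, strand, spans, cut position; all 0-based
#'   half-open).
#' @export
write_amplicons <- function(amps, fasta, sites) {
  seqs <- Biostrings::DNAStringSet(vapply(amps, `[[`, "", "sequence"))
  names(seqs) <- vapply(amps, `[[`, "", "locus_id")
  Biostrings::writeXStringSet(seqs, fasta)
  meta <- lapply(amps, function(a) {
    list(locus_id = a$locus_id,
         primer_fwd_span = a$primer_fwd_span,
         primer_rev_span = a$primer_rev_span,
         spacer = a$target_site$spacer,
         strand = a$target_site$strand,
         protospacer_span = a$target_site$protospacer_span,
         pam_span = a$target_site$pam_span,
         cut_pos = a$target_site$cut_pos)
  })
  jsonlite::write_json(meta, sites, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(fasta = fasta, sites = sites))
}

#' Read reference amplicons from FASTA plus a JSON sidecar
#'
#' Target sites are re-located from the spacer recorded in the sidecar, so the
#' sequence and the sidecar are validated against each other.
#'
#' @param fasta,sites paths written by [write_amplicons()].
#' @return named list of [reference_amplicon()] objects.
#' @export
read_amplicons <- function(fasta, sites) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  meta <- jsonlite::read_json(sites, simplifyVector = TRUE)
  amps <- list()
  for (id in names(meta)) {
    m <- meta[[id]]
    if (!m$locus_id %in% names(seqs)) {
      stop(sprintf("locus '%s' in sites file but not in FASTA", m$locus_id))
    }
    amp <- reference_amplicon(m$locus_id, as.character(seqs[[m$locus_id]]),
                              m$spacer,
                              as.integer(m$primer_fwd_span),
                              as.integer(m$primer_rev_span))
    if (amp$target_site$cut_pos != m$cut_pos) {
      stop(sprintf("located cut position disagrees with sidecar for locus '%s'",
                   m$locus_id))
    }
    amps[[m$locus_id]] <- amp
  }
  amps
}
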