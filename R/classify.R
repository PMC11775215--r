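# The analytical core: assign each read to its locus, collect the indel
# events inside the quantification window, and classify reads as wild-type,
# in-frame, or frameshift from the net indel length mod 3.

CATEGORIES <- c("WT", "IN_FRAME", "FRAMESHIFT", "SUBSTITUTION", "UNASSIGNED")

#' Classification policy
#'
#' The three-way read trichotomy requires a wild-type read to match the
#' reference perfectly (`max_subs = 0`), and defines in-frame/frameshift by
#' the net indel length mod 3. Reads with no indel but more than `max_subs`
#' substitutions have no home in the trichotomy; `substitution_policy`
#' routes them to `"inframe"` (mutated but frame-preserving, the default),
#' `"wt"`, or a `"separate"` category excluded from denominators.
#'
#' @param max_subs maximum substitutions a WT read may carry (default 0,
#'   i.e. a perfect match).
#' @param substitution_policy `"inframe"`, `"wt"`, or `"separate"`.
#' @param min_score_frac minimum alignment score, as a fraction of the
#'   maximum attainable for the read, for a locus assignment to be accepted.
#' @return a `classify_policy` list.
#' @export
classify_policy <- function(max_subs = 0L,
                            substitution_policy = c("inframe", "wt", "separate"),
                            min_score_frac = 0.5) {
  substitution_policy <- match.arg(substitution_policy)
  stopifnot(max_subs >= 0L, min_score_frac >= 0, min_score_frac <= 1)
  structure(list(max_subs = as.integer(max_subs),
                 substitution_policy = substitution_policy,
                 min_score_frac = min_score_frac),
            class = "classify_policy")
}

# category from window-local alignment statistics (vectorized)
categorize <- function(n_events, net_indel, n_subs, spans_window, policy) {
  out <- character(length(n_events))
  out[!spans_window] <- "UNASSIGNED"
  idx <- which(spans_window)
  ev <- n_events[idx]; net <- net_indel[idx]; subs <- n_subs[idx]
  cat <- ifelse(ev >= 1L,
                ifelse(net %% 3L == 0L, "IN_FRAME", "FRAMESHIFT"),
                ifelse(subs <= policy$max_subs, "WT",
                       switch(policy$substitution_policy,
                              inframe = "IN_FRAME", wt = "WT",
                              separate = "SUBSTITUTION")))
  out[idx] <- cat
  factor(out, levels = CATEGORIES)
}

#' Classify a single aligned read
#'
#' Collects the indel events of a [align_glocal()] alignment that intersect
#' the quantification window and classifies the read. A read whose alignment
#' does not span the window is `UNASSIGNED`.
#'
#' @param aln a `glocal_alignment`.
#' @param window a [quant_window()].
#' @param policy a [classify_policy()].
#' @return list with `category`, `net_indel`, `n_indel_events`,
#'   `n_substitutions`.
#' @export
classify_read <- function(aln, window, policy = classify_policy()) {
  ws <- window$span[1]; we <- window$span[2]
  ops <- aln$ops
  net <- 0L; events <- 0L
  for (i in seq_len(nrow(ops))) {
    if (ops$type[i] == "D" && ops$ref_pos[i] < we && ops$ref_pos[i] + ops$len[i] > ws) {
      events <- events + 1L; net <- net - ops$len[i]
    } else if (ops$type[i] == "I" && ops$ref_pos[i] >= ws && ops$ref_pos[i] <= we) {
      events <- events + 1L; net <- net + ops$len[i]
    }
  }
  subs <- sum(aln$mismatch_ref_pos >= ws & aln$mismatch_ref_pos < we)
  spans <- aln$ref_start <= ws && aln$ref_end >= we
  cat <- categorize(events, net, subs, spans, policy)
  list(category = as.character(cat), net_indel = net,
       n_indel_events = events, n_substitutions = subs)
}

#' Assign reads to the best-matching reference amplicon
#'
#' Each read is aligned against every amplicon and assigned to the one with
#' the highest score, provided that score reaches `min_score_frac` of the
#' maximum attainable (match score times read length) and strictly exceeds
#' the runner-up; ties and failures give `"UNASSIGNED"`.
#'
#' @param reads character vector of read sequences.
#' @param amps named list of [reference_amplicon()].
#' @param scoring an [align_scoring()].
#' @param policy a [classify_policy()] (for `min_score_frac`).
#' @return character vector of locus labels or `"UNASSIGNED"`.
#' @export
assign_locus <- function(reads, amps, scoring = align_scoring(),
                         policy = classify_policy()) {
  stopifnot(length(amps) >= 1L)
  scores <- vapply(amps, function(a) {
    align_stats(reads, a$sequence, c(0L, nchar(a$sequence)), scoring)[, "score"]
  }, numeric(length(reads)))
  scores <- matrix(scores, nrow = length(reads),
                   dimnames = list(NULL, names(amps)))
  pick_locus(scores, nchar(reads), scoring, policy)
}

# shared assignment rule given a reads x loci score matrix
pick_locus <- function(scores, read_len, scoring, policy) {
  floor_score <- policy$min_score_frac * scoring$match * read_len
  best <- max.col(scores, ties.method = "first")
  best_score <- scores[cbind(seq_len(nrow(scores)), best)]
  if (ncol(scores) == 1L) {
    runner <- rep(-Inf, nrow(scores))
  } else if (ncol(scores) == 2L) {
    runner <- ifelse(best == 1L, scores[, 2L], scores[, 1L])
  } else {
    runner <- apply(scores, 1L, function(s) max(s[-which.max(s)]))
  }
  out <- colnames(scores)[best]
  out[best_score < floor_score | best_score <= runner] <- "UNASSIGNED"
  out
}

#' Align and classify reads against a set of locus references
#'
#' The per-read pipeline core: each distinct read sequence is aligned against
#' every amplicon, assigned to its locus ([assign_locus()] rule), and
#' classified within that locus's quantification window.
#'
#' @param reads character vector of read sequences (merged reads or R1).
#' @param amps named list of [reference_amplicon()].
#' @param window_mode,halfwidth see [quant_window()].
#' @param scoring an [align_scoring()].
#' @param policy a [classify_policy()].
#' @param id optional read identifiers.
#' @return data.frame with `read_id`, `locus`, `category`, `net_indel`,
#'   `n_indel_events`, `n_substitutions`.
#' @export
classify_reads <- function(reads, amps,
                           window_mode = "full_amplicon", halfwidth = 30L,
                           scoring = align_scoring(),
                           policy = classify_policy(),
                           id = NULL) {
  stopifnot(length(amps) >= 1L)
  if (length(reads) == 0L) {
    return(data.frame(read_id = character(), locus = character(),
                      category = character(), net_indel = integer(),
                      n_indel_events = integer(), n_substitutions = integer(),
                      stringsAsFactors = FALSE))
  }
  uread <- unique(reads)
  map <- match(reads, uread)
  windows <- lapply(amps, quant_window, mode = window_mode, halfwidth = halfwidth)
  stats <- lapply(names(amps), function(l) {
    align_stats(uread, amps[[l]]$sequence, windows[[l]]$span, scoring)
  })
  names(stats) <- names(amps)
  scores <- vapply(stats, function(s) as.numeric(s[, "score"]), numeric(length(uread)))
  scores <- matrix(scores, nrow = length(uread), dimnames = list(NULL, names(amps)))
  locus <- pick_locus(scores, nchar(uread), scoring, policy)
  n <- length(uread)
  category <- rep("UNASSIGNED", n)
  net <- integer(n); events <- integer(n); subs <- integer(n)
  for (l in names(amps)) {
    idx <- which(locus == l)
    if (!length(idx)) next
    st <- stats[[l]][idx, , drop = FALSE]
    sp <- windows[[l]]$span
    spans <- st[, "ref_start"] <= sp[1] & st[, "ref_end"] >= sp[2]
    cat_l <- categorize(st[, "n_events"], st[, "net_indel"], st[, "n_subs"],
                        spans, policy)
    category[idx] <- as.character(cat_l)
    net[idx] <- st[, "net_indel"]; events[idx] <- st[, "n_events"]
    subs[idx] <- st[, "n_subs"]
  }
  data.frame(read_id = if (is.null(id)) as.character(seq_along(reads)) else id,
             locus = locus[map], category = category[map],
             net_indel = net[map], n_indel_events = events[map],
             n_substitutions = subs[map], stringsAsFactors = FALSE)
}

#' Summarize classified reads per (individual, tissue, locus)
#'
#' Counts reads per category and computes the three-way fractions; reads
#' classified `UNASSIGNED` (or `SUBSTITUTION` under the `"separate"` policy)
#' are excluded from denominators. Fractions are counts divided by the total
#' classified reads, so `f_WT + f_inframe + f_frameshift = 1`.
#'
#' @param classifications data.frame from [classify_reads()], with
#'   additional grouping columns, or a list of such data.frames.
#' @param individual,tissue,locus grouping labels; if missing, taken from
#'   columns of `classifications`.
#' @return a `locus_summary` data.frame with counts and fractions per group.
#' @export
summarize_locus <- function(classifications, individual = NULL,
                            tissue = NULL, locus = NULL) {
  df <- classifications
  if (nrow(df) == 0L) stop("no classified reads to summarize")
  if (!is.null(individual)) df$individual <- individual
  if (!is.null(tissue)) df$tissue <- tissue
  if (!is.null(locus) && !"locus" %in% names(df)) df$locus <- locus
  for (col in c("individual", "tissue")) {
    if (!col %in% names(df)) df[[col]] <- "all"
  }
  if (nrow(df) == 0L) stop("no classified reads to summarize")
  groups <- unique(df[, c("individual", "tissue", "locus")])
  groups <- groups[groups$locus != "UNASSIGNED", , drop = FALSE]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- df[df$individual == g$individual & df$tissue == g$tissue &
                df$locus == g$locus, ]
    n_wt <- sum(sub$category == "WT")
    n_if <- sum(sub$category == "IN_FRAME")
    n_fs <- sum(sub$category == "FRAMESHIFT")
    n_un <- sum(sub$category %in% c("UNASSIGNED", "SUBSTITUTION"))
    tot <- n_wt + n_if + n_fs
    if (tot == 0L) stop(sprintf("no classified reads in group %s/%s/%s",
                                g$individual, g$tissue, g$locus))
    data.frame(individual = g$individual, tissue = g$tissue, locus = g$locus,
               n_WT = n_wt, n_inframe = n_if, n_frameshift = n_fs,
               n_unassigned = n_un,
               f_WT = n_wt / tot, f_inframe = n_if / tot,
               f_frameshift = n_fs / tot, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("locus_summary", "data.frame")
  out
}

#' Cohort-level mean fractions
#'
#' Unweighted means of the per-individual category fractions, the statistic
#' behind cohort-average mutagenesis efficiency claims.
#'
#' @param summary a `locus_summary` from [summarize_locus()].
#' @param by grouping columns to average within (default per locus and
#'   tissue; use `by = character()` for a single overall mean).
#' @return data.frame of mean fractions plus the mutated fraction
#'   (`1 - f_WT`).
#' @export
cohort_means <- function(summary, by = c("locus", "tissue")) {
  df <- as.data.frame(summary)
  fr <- df[, c("f_WT", "f_inframe", "f_frameshift")]
  if (length(by) == 0L) {
    out <- as.data.frame(as.list(colMeans(fr)))
    out$n_individuals <- length(unique(df$individual))
  } else {
    out <- aggregate(fr, by = df[, by, drop = FALSE], FUN = mean)
    cnt <- aggregate(list(n_individuals = df$individual),
                     by = df[, by, drop = FALSE],
                     FUN = function(x) length(unique(x)))
    out <- merge(out, cnt, by = by)
  }
  out$f_mutated <- out$f_inframe + out$f_frameshift
  out
}

#' @export
print.locus_summary <- function(x, digits = 4, ...) {
  cat("Per-sample editing outcome summary\n")
  df <- as.data.frame(x)
  df[c("f_WT", "f_inframe", "f_frameshift")] <-
    round(df[c("f_WT", "f_inframe", "f_frameshift")], digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Per-category fraction differences between two tissues
#'
#' @param summary_a,summary_b single-row `locus_summary` slices (or
#'   data.frames with matching `individual` and `locus` columns) for the two
#'   tissues of the same individuals and loci.
#' @return data.frame of `d_WT`, `d_inframe`, `d_frameshift`
#'   (tissue A minus tissue B) per individual and locus.
#' @export
compare_tissues <- function(summary_a, summary_b) {
  a <- as.data.frame(summary_a)
  b <- as.data.frame(summary_b)
  key <- c("individual", "locus")
  m <- merge(a, b, by = key, suffixes = c("_a", "_b"))
  if (nrow(m) != nrow(a) || nrow(m) != nrow(b)) {
    stop("tissue summaries have mismatched individual/locus keys")
  }
  data.frame(individual = m$individual, locus = m$locus,
             tissue_a = m$tissue_a, tissue_b = m$tissue_b,
             d_WT = m$f_WT_a - m$f_WT_b,
             d_inframe = m$f_inframe_a - m$f_inframe_b,
             d_frameshift = m$f_frameshift_a - m$f_frameshift_b,
             stringsAsFactors = FALSE)
}
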