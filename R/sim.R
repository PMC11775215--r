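# Synthetic mosaic-crispant read simulator.
#
# The generator emulates the study design this package analyzes: per-fish
# mosaic allele spectra at two near-identical loci, Cas9 indels anchored at
# the predicted cut site, tissue-to-tissue spectrum differences, MiSeq-like
# paired-end reads with quality-dependent substitution errors and a decaying
# 3' quality tail. Every simulated sample carries a ground-truth row counting
# exactly what was emitted, so classification is testable by parameter
# recovery.

#' Simulation configuration for the mosaic-crispant read simulator
#'
#' Defaults are the study conditions of the cohort the package models:
#' 20 crispant individuals, fin tissue, 10,000 read pairs per locus, per-locus
#' editing rates 0.98/0.97 with frameshift-of-total rates 0.79/0.77, 2x300 bp
#' paired-end reads and a per-base substitution error rate of 0.003.
#'
#' @param n_individuals number of simulated fish.
#' @param tissues tissue labels; with more than one tissue each tissue redraws
#'   its allele fractions around the individual's shared allele pool.
#' @param read_depth read pairs per (individual, tissue, locus).
#' @param editing_rate named per-locus expected edited (non-WT) cell fraction.
#' @param frameshift_rate named per-locus expected frameshift fraction of all
#'   cells (must not exceed `editing_rate`).
#' @param dirichlet_concentration concentration of the Dirichlet draw of
#'   per-individual allele fractions (larger = less inter-fish variability).
#' @param tissue_concordance concentration of the per-tissue redraw around the
#'   individual pool (larger = more concordant tissues).
#' @param pool_alleles_mean mean number of distinct edited alleles per
#'   individual and locus (>= 1).
#' @param p_ins probability that an edited allele is an insertion (else
#'   deletion).
#' @param ins_p,ins_max geometric parameter and cap for insertion lengths.
#' @param del_p,del_max geometric parameter and cap for deletion lengths.
#' @param error_rate expected per-base substitution error rate in the
#'   high-quality read body; 0 disables errors.
#' @param read_length read length in nt (reads are full-amplicon when the
#'   amplicon is shorter).
#' @param tail_len,tail_q length of the decaying 3' quality tail and the
#'   quality it decays to.
#' @param phred_offset Phred offset for emitted quality strings.
#' @param seed mandatory integer seed; the simulator is byte-deterministic
#'   given the configuration.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_individuals = 20L,
                       tissues = "fin",
                       read_depth = 10000L,
                       editing_rate = c(IgM_A = 0.98, IgM_B = 0.97),
                       frameshift_rate = c(IgM_A = 0.79, IgM_B = 0.77),
                       dirichlet_concentration = 30,
                       tissue_concordance = 25,
                       pool_alleles_mean = 4,
                       p_ins = 0.3, ins_p = 0.5, ins_max = 10L,
                       del_p = 0.25, del_max = 30L,
                       error_rate = 0.003,
                       read_length = 300L,
                       tail_len = 30L, tail_q = 10L,
                       phred_offset = 33L,
                       seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory in sim_config()")
  stopifnot(is_count(n_individuals), is_count(read_depth, 1L),
            is_prob(editing_rate), is_prob(frameshift_rate),
            all(frameshift_rate <= editing_rate + 1e-12),
            is_prob(p_ins), is_prob(ins_p), is_prob(del_p),
            is_prob(error_rate),
            dirichlet_concentration > 0, tissue_concordance > 0,
            pool_alleles_mean >= 1, read_length >= 1L, tail_len >= 0L)
  structure(as.list(environment()), class = "sim_config")
}

#' Construct an edit allele
#'
#' An edit allele is a list of non-overlapping indel operations on the
#' reference; the empty operation list is the wild-type allele.
#'
#' @param ops data.frame with columns `ref_pos` (0-based; for insertions the
#'   gap position), `kind` (`"ins"`/`"del"`), `length`, and `inserted_seq`
#'   (`NA` for deletions).
#' @param label allele label.
#' @return an `edit_allele` object.
#' @export
edit_allele <- function(ops = NULL, label = "WT") {
  if (is.null(ops) || nrow(ops) == 0L) {
    ops <- data.frame(ref_pos = integer(), kind = character(),
                      length = integer(), inserted_seq = character(),
                      stringsAsFactors = FALSE)
  }
  stopifnot(all(ops$kind %in% c("ins", "del")), all(ops$length >= 1L | nrow(ops) == 0L))
  structure(list(ops = ops, label = label), class = "edit_allele")
}

#' Net indel length of an edit allele
#'
#' @param allele an [edit_allele()].
#' @return sum of insertion lengths minus sum of deletion lengths.
#' @export
net_indel <- function(allele) {
  ops <- allele$ops
  if (nrow(ops) == 0L) return(0L)
  sum(ifelse(ops$kind == "ins", ops$length, -ops$length))
}

# category implied by an allele's operations
allele_category <- function(allele) {
  if (nrow(allele$ops) == 0L) return("WT")
  if (net_indel(allele) %% 3L == 0L) "IN_FRAME" else "FRAMESHIFT"
}

# geometric length draw (support 1, 2, ...) capped, optionally constrained to
# a frame class; rejection with a deterministic fallback
sample_indel_len <- function(p, cap, inframe = FALSE) {
  for (i in 1:200) {
    len <- min(rgeom(1L, p) + 1L, cap)
    if (!inframe && len %% 3L != 0L) return(len)
    if (inframe && len %% 3L == 0L) return(len)
  }
  if (inframe) 3L else 1L
}

# one random edited allele of the requested frame class, anchored at the cut
sample_edited_allele <- function(cfg, cut_pos, window_span, frameshift = TRUE) {
  if (runif(1) < cfg$p_ins) {
    len <- sample_indel_len(cfg$ins_p, cfg$ins_max, inframe = !frameshift)
    seq <- random_dna(len)
    ops <- data.frame(ref_pos = cut_pos, kind = "ins", length = len,
                      inserted_seq = seq, stringsAsFactors = FALSE)
    label <- sprintf("ins%d@%d", len, cut_pos)
  } else {
    len <- sample_indel_len(cfg$del_p, cfg$del_max, inframe = !frameshift)
    start <- cut_pos - sample.int(len, 1L) + 1L       # deletion covers the cut
    start <- max(window_span[1], min(start, window_span[2] - len))
    ops <- data.frame(ref_pos = start, kind = "del", length = len,
                      inserted_seq = NA_character_, stringsAsFactors = FALSE)
    label <- sprintf("del%d@%d", len, start)
  }
  edit_allele(ops, label)
}

#' Draw a mosaic allele spectrum
#'
#' Draws the allele pool of one (individual, tissue, locus): the wild-type
#' allele plus K >= 1 edited alleles whose indels are anchored at the cut
#' site, with Dirichlet-distributed cell fractions. The expected wild-type
#' fraction is `1 - editing_rate` and the expected frameshift fraction of all
#' cells is `frameshift_rate`.
#'
#' @param cfg a [sim_config()] (its RNG seed is not applied here; seed the
#'   session or use [simulate_cohort()] for reproducible draws).
#' @param amp the [reference_amplicon()] being edited.
#' @param editing_rate,frameshift_rate per-locus rates; default taken from
#'   `cfg` by the amplicon's locus id (falling back to the first element).
#' @return an `allele_spectrum`: list of `alleles` and matching `fractions`
#'   (non-negative, summing to 1).
#' @export
sample_allele_spectrum <- function(cfg, amp,
                                   editing_rate = NULL, frameshift_rate = NULL) {
  e <- editing_rate %||%
    unname(cfg$editing_rate[amp$locus_id] %||% cfg$editing_rate[[1L]])
  fs <- frameshift_rate %||%
    unname(cfg$frameshift_rate[amp$locus_id] %||% cfg$frameshift_rate[[1L]])
  if (is.na(e)) e <- unname(cfg$editing_rate[[1L]])
  if (is.na(fs)) fs <- unname(cfg$frameshift_rate[[1L]])
  wt <- edit_allele()
  if (e <= 0) {
    return(structure(list(alleles = list(wt), fractions = 1), class = "allele_spectrum"))
  }
  cut <- amp$target_site$cut_pos
  win <- inter_primer_span(amp)
  k <- 1L + rpois(1L, max(0, cfg$pool_alleles_mean - 1))
  # expected cell mass per frame class is fixed at the configured rates and
  # split among that class's alleles; the Dirichlet aggregation property then
  # makes each class's realized fraction Beta-distributed around its rate,
  # independent of how many alleles carry it
  p_fs <- min(1, fs / e)
  if (p_fs > 0 && p_fs < 1) k <- max(k, 2L)  # both classes need a carrier
  n_fs <- if (p_fs >= 1) k else if (p_fs <= 0) 0L else
    max(1L, min(k - 1L, rbinom(1L, k, p_fs)))
  n_if <- k - n_fs
  classes <- c(rep(TRUE, n_fs), rep(FALSE, n_if))
  edited <- lapply(classes, function(is_fs) {
    sample_edited_allele(cfg, cut, win, frameshift = is_fs)
  })
  mean_vec <- c(1 - e,
                if (n_fs > 0) rep(e * p_fs / n_fs, n_fs),
                if (n_if > 0) rep(e * (1 - p_fs) / n_if, n_if))
  w <- rgamma(k + 1L, shape = cfg$dirichlet_concentration * mean_vec, rate = 1)
  if (sum(w) <= 0) w <- mean_vec        # degenerate draw guard
  structure(list(alleles = c(list(wt), edited), fractions = w / sum(w)),
            class = "allele_spectrum")
}

#' @export
print.allele_spectrum <- function(x, ...) {
  labs <- vapply(x$alleles, `[[`, "", "label")
  cat("Allele spectrum:\n")
  for (i in seq_along(labs)) {
    cat(sprintf("  %-12s %6.4f  [%s]\n", labs[i], x$fractions[i],
                allele_category(x$alleles[[i]])))
  }
  invisible(x)
}

#' Apply an edit allele to a reference amplicon
#'
#' Splices the allele's insertions and deletions into the reference sequence.
#' Operations must be sorted by position and non-overlapping.
#'
#' @param amp a [reference_amplicon()].
#' @param allele an [edit_allele()].
#' @return the edited amplicon sequence (length `nchar(ref) + net_indel`).
#' @export
apply_allele <- function(amp, allele) {
  ref <- amp$sequence
  ops <- allele$ops
  if (nrow(ops) == 0L) return(ref)
  ord <- order(ops$ref_pos)
  if (any(ord != seq_len(nrow(ops)))) stop("allele ops must be sorted by ref_pos")
  ends <- ifelse(ops$kind == "del", ops$ref_pos + ops$length, ops$ref_pos)
  if (nrow(ops) > 1L && any(ops$ref_pos[-1L] < ends[-nrow(ops)])) {
    stop("allele ops overlap")
  }
  if (any(ends > nchar(ref)) || any(ops$ref_pos < 0L)) stop("allele ops outside reference")
  out <- character(0)
  cur <- 0L  # 0-based
  for (i in seq_len(nrow(ops))) {
    p <- ops$ref_pos[i]
    if (p > cur) out <- c(out, substring(ref, cur + 1L, p))
    if (ops$kind[i] == "del") {
      cur <- p + ops$length[i]
    } else {
      out <- c(out, ops$inserted_seq[i])
      cur <- p
    }
  }
  if (cur < nchar(ref)) out <- c(out, substring(ref, cur + 1L, nchar(ref)))
  paste(out, collapse = "")
}

# per-base quality/error model: body quality q0 +/- 3 jitter where q0 is set
# by the configured error rate, linear decay to tail_q over the last tail_len
# bases; per-base error probability proportional to 10^(-q/10), calibrated so
# the body marginal equals error_rate exactly.
quality_error_model <- function(cfg) {
  jit <- c(-3L, 0L, 3L)
  if (cfg$error_rate <= 0) {
    q0 <- 40L
    scale <- 0
  } else {
    q0 <- as.integer(round(-10 * log10(cfg$error_rate)))
    scale <- cfg$error_rate / mean(10^(-(q0 + jit) / 10))
  }
  list(q0 = q0, jitter = jit, scale = scale)
}

# simulate one sample's reads for one allele sequence; returns seq/qual
# character vectors for n reads taken from the 5' end of `tmpl`
sim_reads_one_strand <- function(tmpl, n, cfg, qm) {
  L <- min(cfg$read_length, nchar(tmpl))
  tchars <- strsplit(substring(tmpl, 1L, L), "", fixed = TRUE)[[1]]
  qmat <- matrix(qm$q0 + sample(qm$jitter, n * L, replace = TRUE), nrow = n)
  if (cfg$tail_len > 0L && L > cfg$tail_len) {
    ramp <- as.integer(round(seq(qm$q0, cfg$tail_q, length.out = cfg$tail_len)))
    qmat[, (L - cfg$tail_len + 1L):L] <- matrix(rep(ramp, each = n), nrow = n)
  }
  smat <- matrix(rep(tchars, each = n), nrow = n)
  if (qm$scale > 0) {
    perr <- pmin(0.5, qm$scale * 10^(-qmat / 10))
    err <- which(matrix(runif(n * L), nrow = n) < perr)
    if (length(err) > 0L) {
      orig <- match(smat[err], .BASES)
      alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                    nrow = 4L, byrow = TRUE)  # row b: the three bases != .BASES[b]
      smat[err] <- alt[cbind(orig, sample.int(3L, length(err), replace = TRUE))]
    }
  }
  qchar <- matrix(.QCHAR[qmat + 1L], nrow = n)
  list(seq = do.call(paste0, as.data.frame(smat, stringsAsFactors = FALSE)),
       qual = do.call(paste0, as.data.frame(qchar, stringsAsFactors = FALSE)))
}

#' Simulate paired-end reads from an allele spectrum
#'
#' Each read pair is drawn from an allele with probability equal to its cell
#' fraction; R1 starts at the amplicon 5' end and R2 is the reverse
#' complement from the 3' end. Substitution errors are injected per base at
#' a probability determined by the base's quality character (see
#' [sim_config()]). The returned truth row counts the categories of the
#' alleles actually emitted.
#'
#' @param amp a [reference_amplicon()].
#' @param spectrum an allele spectrum from [sample_allele_spectrum()].
#' @param cfg a [sim_config()].
#' @param sample_id prefix used in read headers.
#' @return list with `id`, `r1`, `q1`, `r2`, `q2` (parallel character
#'   vectors) and `truth` (counts and fractions per category).
#' @export
simulate_reads <- function(amp, spectrum, cfg, sample_id = "sample") {
  depth <- cfg$read_depth
  counts <- as.vector(rmultinom(1L, depth, spectrum$fractions))
  qm <- quality_error_model(cfg)
  cats <- vapply(spectrum$alleles, allele_category, "")
  r1 <- q1 <- r2 <- q2 <- id <- vector("list", length(counts))
  for (a in seq_along(counts)) {
    n <- counts[a]
    if (n == 0L) next
    aseq <- apply_allele(amp, spectrum$alleles[[a]])
    fwd <- sim_reads_one_strand(aseq, n, cfg, qm)
    rev <- sim_reads_one_strand(revcomp(aseq), n, cfg, qm)
    r1[[a]] <- fwd$seq; q1[[a]] <- fwd$qual
    r2[[a]] <- rev$seq; q2[[a]] <- rev$qual
    id[[a]] <- sprintf("%s:%s:%d", sample_id, spectrum$alleles[[a]]$label, seq_len(n))
  }
  truth_counts <- c(WT = sum(counts[cats == "WT"]),
                    IN_FRAME = sum(counts[cats == "IN_FRAME"]),
                    FRAMESHIFT = sum(counts[cats == "FRAMESHIFT"]))
  list(id = unlist(id), r1 = unlist(r1), q1 = unlist(q1),
       r2 = unlist(r2), q2 = unlist(q2),
       truth = list(counts = truth_counts, fractions = truth_counts / depth))
}

write_fastq <- function(id, seq, qual, path) {
  dna <- Biostrings::DNAStringSet(seq)
  names(dna) <- id
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Simulate a full crispant cohort to disk
#'
#' For each individual and locus an allele pool is drawn once; with several
#' tissues each tissue redraws its fractions around the shared pool
#' (Dirichlet with concentration `tissue_concordance`), reproducing
#' mosaicism-driven tissue discordance. Emits gzipped R1/R2 FASTQ per sample,
#' a ground-truth table, a manifest, the references and the configuration.
#'
#' @param cfg a [sim_config()]; `cfg$seed` makes the output byte-identical
#'   across runs.
#' @param amps named list of [reference_amplicon()] (default
#'   [synthetic_amplicons()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `manifest` and `truth` data.frames.
#' @export
simulate_cohort <- function(cfg, amps = synthetic_amplicons(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fq_dir <- file.path(out_dir, "fastq")
  dir.create(fq_dir, showWarnings = FALSE)
  write_amplicons(amps, file.path(out_dir, "refs.fasta"),
                  file.path(out_dir, "sites.json"))
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "sim_config.yaml"))
  manifest <- list(); truth <- list()
  if (cfg$n_individuals == 0L) {
    warning("n_individuals = 0: empty simulation")
  }
  with_seed(cfg$seed, {
    for (i in seq_len(cfg$n_individuals)) {
      ind <- sprintf("IgM_%02d", i)
      for (locus in names(amps)) {
        pool <- sample_allele_spectrum(cfg, amps[[locus]])
        for (tissue in cfg$tissues) {
          frac <- pool$fractions
          if (length(cfg$tissues) > 1L) {
            w <- rgamma(length(frac), shape = cfg$tissue_concordance * frac, rate = 1)
            frac <- if (sum(w) > 0) w / sum(w) else pool$fractions
          }
          spec <- structure(list(alleles = pool$alleles, fractions = frac),
                            class = "allele_spectrum")
          sample_id <- sprintf("%s_%s_%s", ind, tissue, locus)
          reads <- simulate_reads(amps[[locus]], spec, cfg, sample_id)
          r1_path <- file.path(fq_dir, paste0(sample_id, "_R1.fastq.gz"))
          r2_path <- file.path(fq_dir, paste0(sample_id, "_R2.fastq.gz"))
          write_fastq(reads$id, reads$r1, reads$q1, r1_path)
          write_fastq(reads$id, reads$r2, reads$q2, r2_path)
          manifest[[length(manifest) + 1L]] <- data.frame(
            individual = ind, tissue = tissue, locus = locus,
            r1 = r1_path, r2 = r2_path, stringsAsFactors = FALSE)
          truth[[length(truth) + 1L]] <- data.frame(
            individual = ind, tissue = tissue, locus = locus,
            frac_WT = reads$truth$fractions[["WT"]],
            frac_inframe = reads$truth$fractions[["IN_FRAME"]],
            frac_frameshift = reads$truth$fractions[["FRAMESHIFT"]],
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(individual = character(), tissue = character(), locus = character(),
               r1 = character(), r2 = character(), stringsAsFactors = FALSE)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(individual = character(), tissue = character(), locus = character(),
               frac_WT = numeric(), frac_inframe = numeric(),
               frac_frameshift = numeric(), stringsAsFactors = FALSE)
  comments <- sprintf("crispantquant simulate; seed=%d", cfg$seed)
  write_tsv_commented(manifest, file.path(out_dir, "manifest.tsv"), comments)
  write_tsv_commented(truth, file.path(out_dir, "truth.tsv"), comments)
  invisible(list(manifest = manifest, truth = truth))
}
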