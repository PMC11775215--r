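# Pipeline orchestration: configuration handling and the simulate / classify /
# qpcr stage runners that tie the package together into one reproducible
# pipeline. Output tables carry the seed and a config hash in '#' comment
# lines; logging goes to stderr, data to files.

#' Pipeline configuration
#'
#' Collects all stage parameters in one serializable list. Unspecified
#' entries take the documented defaults of the underlying constructors.
#'
#' @param out_dir output directory for all stages.
#' @param refs,sites reference FASTA and target-site JSON (defaults to the
#'   files written by [run_simulate()] under `out_dir`).
#' @param fastq_dir,manifest FASTQ location / sample manifest TSV for
#'   [run_classify()].
#' @param ct_table,efficiency_table TSV inputs for [run_qpcr()].
#' @param trim list of [trim_policy()] arguments.
#' @param pairing `"merge"` or `"r1_only"`.
#' @param scoring list of [align_scoring()] arguments.
#' @param window_mode,halfwidth see [quant_window()].
#' @param classify list of [classify_policy()] arguments.
#' @param qpcr_mode see [pfaffl()].
#' @param sim list of [sim_config()] arguments (seed is filled from `seed`).
#' @param per_read_output write the per-read classification TSV (large).
#' @param seed integer seed for every stochastic stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "crispantquant_out",
                            refs = NULL, sites = NULL,
                            fastq_dir = NULL, manifest = NULL,
                            ct_table = NULL, efficiency_table = NULL,
                            trim = list(), pairing = "merge",
                            scoring = list(),
                            window_mode = "full_amplicon", halfwidth = 30L,
                            classify = list(), qpcr_mode = "single_efficiency",
                            sim = list(), per_read_output = TRUE,
                            seed = 1L) {
  cfg <- list(out_dir = out_dir, refs = refs, sites = sites,
              fastq_dir = fastq_dir, manifest = manifest,
              ct_table = ct_table, efficiency_table = efficiency_table,
              trim = trim, pairing = pairing, scoring = scoring,
              window_mode = window_mode, halfwidth = as.integer(halfwidth),
              classify = classify, qpcr_mode = qpcr_mode, sim = sim,
              per_read_output = isTRUE(per_read_output),
              seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' Configurations round-trip losslessly through serialization.
#'
#' @param config a [pipeline_config()].
#' @param path YAML path.
#' @return `config_read()` returns the `pipeline_config`.
#' @export
config_write <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname config_write
#' @export
config_read <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

provenance <- function(config) {
  c(sprintf("crispantquant %s", as.character(utils::packageVersion("crispantquant"))),
    sprintf("seed=%d config_md5=%s", config$seed, config_hash(config)))
}

log_msg <- function(...) message(sprintf(...))

#' Run the simulation stage
#'
#' Simulates the configured crispant cohort into `out_dir` (FASTQ, truth
#' table, manifest, references); deterministic per seed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest data.frame.
#' @export
run_simulate <- function(config) {
  sim_args <- config$sim
  sim_args$seed <- sim_args$seed %||% config$seed
  cfg <- do.call(sim_config, sim_args)
  log_msg("simulate: %d individuals x {%s} x 2 loci, depth %d, seed %d",
          cfg$n_individuals, paste(cfg$tissues, collapse = ","),
          cfg$read_depth, cfg$seed)
  res <- simulate_cohort(cfg, out_dir = config$out_dir)
  log_msg("simulate: wrote %d samples under %s", nrow(res$manifest), config$out_dir)
  invisible(res$manifest)
}

#' Run the classification stage
#'
#' Preprocesses every sample in the manifest (trim, length filter, optional
#' merging), aligns reads against the locus references, classifies them, and
#' writes per-read (optional), per-sample and cohort-mean tables.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `per_sample` (`locus_summary`), `cohort`,
#'   and the preprocessing `report`.
#' @export
run_classify <- function(config) {
  refs <- config$refs %||% file.path(config$out_dir, "refs.fasta")
  sites <- config$sites %||% file.path(config$out_dir, "sites.json")
  if (!file.exists(refs) || !file.exists(sites)) {
    stop(sprintf("missing reference FASTA ('%s') or target-site sidecar ('%s')",
                 refs, sites))
  }
  amps <- read_amplicons(refs, sites)
  manifest_path <- config$manifest %||% file.path(config$out_dir, "manifest.tsv")
  if (!file.exists(manifest_path)) stop(sprintf("missing manifest '%s'", manifest_path))
  manifest <- read_tsv_commented(manifest_path)
  policy <- do.call(trim_policy, config$trim)
  scoring <- do.call(align_scoring, config$scoring)
  cpolicy <- do.call(classify_policy, config$classify)
  comments <- provenance(config)
  per_read_con <- NULL
  if (config$per_read_output) {
    per_read_path <- file.path(config$out_dir, "per_read.tsv")
    per_read_con <- file(per_read_path, open = "wt")
    on.exit(close(per_read_con))
    for (cm in comments) writeLines(paste0("# ", cm), per_read_con)
  }
  summaries <- list(); reports <- list()
  first <- TRUE
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    pp <- preprocess_sample(row$r1, row$r2, policy, pairing = config$pairing)
    pr <- classify_reads(pp$seq, amps,
                         window_mode = config$window_mode,
                         halfwidth = config$halfwidth,
                         scoring = scoring, policy = cpolicy, id = pp$id)
    n_classified <- sum(pr$category %in% c("WT", "IN_FRAME", "FRAMESHIFT"))
    if (n_classified == 0L) {
      stop(sprintf("sample %s/%s/%s: zero classified reads",
                   row$individual, row$tissue, row$locus))
    }
    if (!is.null(per_read_con)) {
      write.table(cbind(individual = row$individual, tissue = row$tissue, pr),
                  per_read_con, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = first)
      first <- FALSE
    }
    summaries[[i]] <- summarize_locus(pr, individual = row$individual,
                                      tissue = row$tissue)
    reports[[i]] <- data.frame(individual = row$individual, tissue = row$tissue,
                               locus = row$locus,
                               as.data.frame(pp$report),
                               stringsAsFactors = FALSE)
    log_msg("classify: %s/%s/%s -> %d reads classified",
            row$individual, row$tissue, row$locus, n_classified)
  }
  per_sample <- do.call(rbind, summaries)
  class(per_sample) <- c("locus_summary", "data.frame")
  cohort <- cohort_means(per_sample)
  write_tsv_commented(as.data.frame(per_sample),
                      file.path(config$out_dir, "per_sample.tsv"), comments)
  write_tsv_commented(cohort, file.path(config$out_dir, "cohort_means.tsv"),
                      comments)
  write_tsv_commented(do.call(rbind, reports),
                      file.path(config$out_dir, "trim_report.tsv"), comments)
  invisible(list(per_sample = per_sample, cohort = cohort,
                 report = do.call(rbind, reports)))
}

#' Run the expression-analysis stage
#'
#' Reads the Ct and efficiency tables, fits [pfaffl()], and writes the
#' expression records and the per-gene x tissue group-comparison table.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the `pfaffl` fit.
#' @export
run_qpcr <- function(config) {
  if (is.null(config$ct_table)) stop("config$ct_table is required for run_qpcr()")
  ct <- read_ct_table(config$ct_table)
  eff <- if (is.null(config$efficiency_table)) igm_efficiencies() else
    read_tsv_commented(config$efficiency_table)
  fit <- pfaffl(ct, eff, mode = config$qpcr_mode)
  comp <- summary(fit)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  comments <- provenance(config)
  write_tsv_commented(fit$records, file.path(config$out_dir, "expression.tsv"),
                      comments)
  write_tsv_commented(as.data.frame(comp),
                      file.path(config$out_dir, "comparisons.tsv"), comments)
  log_msg("qpcr: %d expression records, %d comparisons",
          nrow(fit$records), nrow(comp))
  invisible(fit)
}

#' Run simulate, classify and qpcr in sequence
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of stage results.
#' @export
run_all <- function(config) {
  manifest <- run_simulate(config)
  cls <- run_classify(config)
  qp <- if (!is.null(config$ct_table)) run_qpcr(config) else NULL
  invisible(list(manifest = manifest, classify = cls, qpcr = qp))
}

#' Quantify editing across a cohort of samples
#'
#' High-level in-memory interface: preprocesses and classifies every sample
#' of a manifest and returns a classed fit-like object with per-sample
#' summaries and cohort means.
#'
#' @param manifest data.frame with `individual`, `tissue`, `locus`, `r1`,
#'   and optionally `r2` FASTQ paths.
#' @param amps named list of [reference_amplicon()].
#' @param trim a [trim_policy()].
#' @param pairing `"merge"` or `"r1_only"`.
#' @param window_mode,halfwidth see [quant_window()].
#' @param scoring an [align_scoring()].
#' @param policy a [classify_policy()].
#' @return an `editing_quant` object with `per_sample`, `cohort`, `report`;
#'   methods: `print`, `summary`, `plot`.
#' @export
quantify_editing <- function(manifest, amps, trim = trim_policy(),
                             pairing = "merge",
                             window_mode = "full_amplicon", halfwidth = 30L,
                             scoring = align_scoring(),
                             policy = classify_policy()) {
  summaries <- list(); reports <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    r2 <- if ("r2" %in% names(manifest)) row$r2 else NULL
    pp <- preprocess_sample(row$r1, r2, trim, pairing = pairing)
    pr <- classify_reads(pp$seq, amps, window_mode = window_mode,
                         halfwidth = halfwidth, scoring = scoring,
                         policy = policy, id = pp$id)
    summaries[[i]] <- summarize_locus(pr, individual = row$individual,
                                      tissue = row$tissue)
    reports[[i]] <- data.frame(individual = row$individual, tissue = row$tissue,
                               locus = row$locus, as.data.frame(pp$report),
                               stringsAsFactors = FALSE)
  }
  per_sample <- do.call(rbind, summaries)
  class(per_sample) <- c("locus_summary", "data.frame")
  structure(list(per_sample = per_sample,
                 cohort = cohort_means(per_sample),
                 report = do.call(rbind, reports)),
            class = "editing_quant")
}

#' @export
print.editing_quant <- function(x, ...) {
  cat(sprintf("Editing-outcome quantification: %d samples, %d individuals\n",
              nrow(x$per_sample), length(unique(x$per_sample$individual))))
  print(x$cohort, digits = 4)
  invisible(x)
}

#' @method summary editing_quant
#' @export
summary.editing_quant <- function(object, ...) {
  list(per_sample = object$per_sample, cohort = object$cohort,
       preprocess = object$report)
}

#' @method plot editing_quant
#' @export
plot.editing_quant <- function(x, ...) {
  df <- as.data.frame(x$per_sample)
  loci <- unique(df$locus)
  old <- par(mfrow = c(length(loci), 1), mar = c(6, 4, 2, 1))
  on.exit(par(old))
  for (l in loci) {
    sub <- df[df$locus == l, ]
    m <- t(as.matrix(sub[, c("f_WT", "f_inframe", "f_frameshift")]))
    colnames(m) <- paste(sub$individual, sub$tissue, sep = ":")
    barplot(100 * m, las = 2, main = l, ylab = "% of reads",
            legend.text = c("WT", "in-frame", "frameshift"),
            args.legend = list(x = "topright", bty = "n", cex = 0.7), ...)
  }
  invisible(x)
}
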