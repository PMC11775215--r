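# Efficiency-corrected relative expression (Pfaffl-style delta-delta-Ct)
# with a pooled-control calibrator, plus an exact Mann-Whitney U test for
# group comparisons.

#' Amplification efficiencies of the IgM expression assays
#'
#' Per-gene, per-tissue amplification efficiencies (fold per cycle) measured
#' for the Ef1a, secreted-IgM, membrane-IgM and IgT assays in Atlantic salmon
#' head kidney and spleen. These are inputs to [pfaffl()]; efficiencies are
#' not estimated by this package.
#'
#' @return data.frame with columns `gene`, `tissue`, `efficiency`.
#' @export
igm_efficiencies <- function() {
  data.frame(
    gene = rep(c("Ef1a", "sIgM", "mIgM", "IgT"), each = 2L),
    tissue = rep(c("head_kidney", "spleen"), times = 4L),
    efficiency = c(2.05, 2.09, 2.05, 2.02, 2.06, 2.05, 2.04, 2.02),
    stringsAsFactors = FALSE)
}

#' Collapse technical Ct replicates
#'
#' @param ct_replicates numeric vector of replicate Ct values (NAs dropped).
#' @param sd_flag_threshold flag threshold on the replicate SD, in cycles.
#' @return list with `mean`, `sd`, and logical `flag` (high replicate
#'   scatter).
#' @export
#' @examples
#' collapse_replicates(c(20.0, 20.2))
collapse_replicates <- function(ct_replicates, sd_flag_threshold = 0.5) {
  x <- ct_replicates[is.finite(ct_replicates)]
  if (length(x) == 0L) stop("all Ct replicates missing")
  s <- if (length(x) > 1L) sd(x) else 0
  list(mean = mean(x), sd = s, flag = s > sd_flag_threshold)
}

#' Read a long-format Ct table
#'
#' Expects columns `sample_id`, `group`, `tissue`, `gene` and one or more
#' `ct_rep*` replicate columns; replicates are collapsed to their mean.
#'
#' @param path TSV path.
#' @param sd_flag_threshold see [collapse_replicates()].
#' @return data.frame with columns `sample_id`, `group`, `tissue`, `gene`,
#'   `ct`, `ct_sd`, `ct_flag`.
#' @export
read_ct_table <- function(path, sd_flag_threshold = 0.5) {
  df <- read_tsv_commented(path)
  need <- c("sample_id", "group", "tissue", "gene")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("Ct table '%s' lacks required columns: %s", path,
                 paste(miss, collapse = ", ")))
  }
  repcols <- grep("^ct_rep", names(df), value = TRUE)
  if (!length(repcols)) stop(sprintf("Ct table '%s' has no ct_rep* columns", path))
  bad <- which(!vapply(seq_len(nrow(df)),
                       function(i) any(is.finite(as.numeric(df[i, repcols]))),
                       logical(1)))
  if (length(bad)) {
    stop(sprintf("Ct table '%s': no finite replicate in row(s) %s",
                 path, paste(bad + 1L, collapse = ", ")))
  }
  cc <- lapply(seq_len(nrow(df)), function(i) {
    collapse_replicates(as.numeric(df[i, repcols]), sd_flag_threshold)
  })
  out <- df[, need]
  out$ct <- vapply(cc, `[[`, numeric(1), "mean")
  out$ct_sd <- vapply(cc, `[[`, numeric(1), "sd")
  out$ct_flag <- vapply(cc, `[[`, logical(1), "flag")
  out
}

#' Efficiency-corrected relative expression (Pfaffl-style)
#'
#' Per sample and gene of interest (GOI): `delta_ct = Ct_goi - Ct_ref` in the
#' same sample and tissue; the calibrator is the mean `delta_ct` over all
#' control samples (both control groups pooled); `delta_delta_ct = delta_ct -
#' calibrator`. The fold change is computed per `mode`:
#' \describe{
#'   \item{`single_efficiency`}{`FC = E_goi^(-delta_delta_ct)` — the
#'     delta-delta-Ct workflow with the GOI's measured efficiency in place of
#'     an assumed doubling (the default).}
#'   \item{`pfaffl_full`}{`FC = E_goi^(Ct_goi,cal - Ct_goi) /
#'     E_ref^(Ct_ref,cal - Ct_ref)` with calibrator Cts equal to the mean
#'     control Ct per gene and tissue — the full efficiency-ratio form.}
#' }
#' The two modes agree whenever `E_goi == E_ref`.
#'
#' @param ct data.frame with columns `sample_id`, `group`, `tissue`, `gene`,
#'   `ct` (replicates already collapsed; see [read_ct_table()]).
#' @param efficiencies data.frame with `gene`, `tissue`, `efficiency`
#'   (`1 < E <= 2.2`), e.g. [igm_efficiencies()].
#' @param reference_gene the reference (housekeeping) gene.
#' @param control_groups group labels pooled as the calibrator.
#' @param mode `"single_efficiency"` or `"pfaffl_full"`.
#' @return a `pfaffl` fit: per sample x gene expression records with
#'   `delta_ct`, `delta_delta_ct`, `fold_change`; see [summary.pfaffl()],
#'   [coef.pfaffl()].
#' @export
pfaffl <- function(ct, efficiencies,
                   reference_gene = "Ef1a",
                   control_groups = c("control_wt", "control_albino"),
                   mode = c("single_efficiency", "pfaffl_full")) {
  mode <- match.arg(mode)
  stopifnot(all(c("sample_id", "group", "tissue", "gene", "ct") %in% names(ct)))
  stopifnot(all(c("gene", "tissue", "efficiency") %in% names(efficiencies)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  if (any(efficiencies$efficiency <= 1 | efficiencies$efficiency > 2.2)) {
    stop("amplification efficiencies must lie in (1, 2.2]")
  }
  eff <- function(gene, tissue) {
    e <- efficiencies$efficiency[efficiencies$gene == gene &
                                   efficiencies$tissue == tissue]
    if (length(e) != 1L) {
      stop(sprintf("missing amplification efficiency for gene '%s', tissue '%s'",
                   gene, tissue))
    }
    e
  }
  goi_genes <- setdiff(unique(ct$gene), reference_gene)
  recs <- list(); cals <- list()
  for (tis in unique(ct$tissue)) {
    sub <- ct[ct$tissue == tis, ]
    ref <- sub[sub$gene == reference_gene, ]
    for (gene in intersect(goi_genes, unique(sub$gene))) {
      goi <- sub[sub$gene == gene, ]
      ridx <- match(goi$sample_id, ref$sample_id)
      if (anyNA(ridx)) {
        stop(sprintf(
          "reference gene '%s' not measured for sample(s) %s in tissue '%s'",
          reference_gene,
          paste(goi$sample_id[is.na(ridx)], collapse = ", "), tis))
      }
      ct_ref <- ref$ct[ridx]
      dct <- goi$ct - ct_ref
      is_ctrl <- goi$group %in% control_groups
      if (!any(is_ctrl)) {
        stop(sprintf("no control samples for gene '%s', tissue '%s'", gene, tis))
      }
      calibrator <- mean(dct[is_ctrl])
      ddct <- dct - calibrator
      e_goi <- eff(gene, tis)
      if (mode == "single_efficiency") {
        fc <- e_goi^(-ddct)
      } else {
        e_ref <- eff(reference_gene, tis)
        cal_goi <- mean(goi$ct[is_ctrl])
        cal_ref <- mean(ct_ref[is_ctrl])
        fc <- e_goi^(cal_goi - goi$ct) / e_ref^(cal_ref - ct_ref)
      }
      recs[[length(recs) + 1L]] <- data.frame(
        sample_id = goi$sample_id, group = goi$group, tissue = tis,
        gene = gene, ct_goi = goi$ct, ct_ref = ct_ref,
        delta_ct = dct, delta_delta_ct = ddct, fold_change = fc,
        stringsAsFactors = FALSE)
      cals[[length(cals) + 1L]] <- data.frame(
        tissue = tis, gene = gene, calibrator = calibrator,
        n_controls = sum(is_ctrl), stringsAsFactors = FALSE)
    }
  }
  structure(list(records = do.call(rbind, recs),
                 calibrators = do.call(rbind, cals),
                 mode = mode, reference_gene = reference_gene,
                 control_groups = control_groups,
                 efficiencies = efficiencies),
            class = "pfaffl")
}

#' @export
print.pfaffl <- function(x, ...) {
  cat(sprintf("Efficiency-corrected relative expression (%s mode)\n", x$mode))
  cat(sprintf("  reference gene: %s; calibrator: mean delta-Ct of %s\n",
              x$reference_gene, paste(x$control_groups, collapse = " + ")))
  cat(sprintf("  %d expression records (%d genes, %d tissues, %d samples)\n",
              nrow(x$records), length(unique(x$records$gene)),
              length(unique(x$records$tissue)),
              length(unique(x$records$sample_id))))
  invisible(x)
}

#' Fold changes of a Pfaffl fit
#'
#' @param object a [pfaffl()] fit.
#' @param ... unused.
#' @return named numeric vector of fold changes
#'   (`sample_id.gene.tissue`).
#' @method coef pfaffl
#' @export
coef.pfaffl <- function(object, ...) {
  r <- object$records
  setNames(r$fold_change, paste(r$sample_id, r$gene, r$tissue, sep = "."))
}

#' Group comparison of fold changes per gene and tissue
#'
#' Mann-Whitney comparison of the case group versus all other (control)
#' samples, per gene x tissue, with group medians.
#'
#' @param object a [pfaffl()] fit.
#' @param case_group label of the comparison group (default `"crispant"`).
#' @param ... unused.
#' @return a `summary.pfaffl` data.frame with `gene`, `tissue`, group sizes,
#'   medians, `U`, and the two-sided `p`.
#' @method summary pfaffl
#' @export
summary.pfaffl <- function(object, case_group = "crispant", ...) {
  r <- object$records
  combos <- unique(r[, c("gene", "tissue")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- r[r$gene == combos$gene[i] & r$tissue == combos$tissue[i], ]
    fc_case <- sub$fold_change[sub$group == case_group]
    fc_ctrl <- sub$fold_change[sub$group != case_group]
    mw <- if (length(fc_case) && length(fc_ctrl)) {
      mann_whitney(fc_case, fc_ctrl)
    } else list(statistic = NA_real_, p.value = NA_real_)
    data.frame(gene = combos$gene[i], tissue = combos$tissue[i],
               n_case = length(fc_case), n_control = length(fc_ctrl),
               median_case = if (length(fc_case)) median(fc_case) else NA_real_,
               median_control = if (length(fc_ctrl)) median(fc_ctrl) else NA_real_,
               U = unname(mw$statistic), p = mw$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.pfaffl", "data.frame")
  out
}

#' @export
print.summary.pfaffl <- function(x, ...) {
  cat("Group comparison of fold changes (Mann-Whitney, two-sided)\n")
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @method plot pfaffl
#' @export
plot.pfaffl <- function(x, case_group = "crispant", ...) {
  r <- x$records
  r$panel <- paste(r$gene, r$tissue, sep = "\n")
  r$grp <- ifelse(r$group == case_group, case_group, "control")
  panels <- unique(r$panel)
  old <- par(mfrow = c(1, length(panels)), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (p in panels) {
    sub <- r[r$panel == p, ]
    stripchart(fold_change ~ grp, data = sub, vertical = TRUE, log = "y",
               method = "jitter", pch = 19, main = p, ylab = "fold change", ...)
  }
  invisible(x)
}

#' Mann-Whitney U test (exact for small samples)
#'
#' Two-sided rank-sum test. For `n_a + n_b <= 16` with no ties the p-value is
#' exact, computed by full enumeration of all group assignments of the ranks;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. The reported statistic is `min(U_a, U_b)`.
#'
#' @param group_a,group_b numeric vectors (each non-empty).
#' @return list of class `htest` with `statistic` (U), `p.value`, `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # exact two-sided p = 0.1
mann_whitney <- function(group_a, group_b) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_b <- na * nb - u_a
  u_min <- min(u_a, u_b)
  ties <- any(duplicated(c(a, b)))
  if (n <= 16L && !ties) {
    ranksets <- utils::combn(n, na)
    u_all <- colSums(matrix(seq_len(n)[ranksets], nrow = na)) - na * (na + 1) / 2
    p <- (sum(u_all <= u_min) + sum(u_all >= na * nb - u_min)) / ncol(ranksets)
    p <- min(1, p)
    method <- "Mann-Whitney U test (exact, full enumeration)"
  } else {
    mu <- na * nb / 2
    tie_tab <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_min - mu + 0.5) / sqrt(sigma2)   # continuity correction toward center
      p <- min(1, 2 * pnorm(z))
    }
    method <- "Mann-Whitney U test (normal approximation, tie + continuity correction)"
  }
  structure(list(statistic = c(U = u_min), p.value = p, method = method,
                 data.name = sprintf("group_a (n=%d) vs group_b (n=%d)", na, nb)),
            class = "htest")
}
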