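# builds a long-format Ct table in memory
ct_row <- function(sample_id, group, tissue, gene, ct) {
  data.frame(sample_id = sample_id, group = group, tissue = tissue,
             gene = gene, ct = ct, stringsAsFactors = FALSE)
}

flat_eff <- function(e, genes = c("Ef1a", "mIgM"), tissues = "head_kidney") {
  expand.grid(gene = genes, tissue = tissues, stringsAsFactors = FALSE) |>
    cbind(efficiency = e)
}

test_that("replicate collapsing averages and flags scattered duplicates", {
  expect_equal(collapse_replicates(c(20.0, 20.2))$mean, 20.1)
  expect_equal(collapse_replicates(20.0)$mean, 20.0)
  r <- collapse_replicates(c(20.0, 21.5))
  expect_equal(r$mean, 20.75)
  expect_true(r$flag)
  expect_false(collapse_replicates(c(20.0, 20.2))$flag)
  expect_error(collapse_replicates(c(NA_real_, NA_real_)), "missing")
})

test_that("fold changes follow E^(-ddCt) with the pooled-control calibrator", {
  # controls all at dCt 0; one crispant shifted
  ct <- rbind(
    ct_row("c1", "control_wt", "head_kidney", "Ef1a", 20),
    ct_row("c1", "control_wt", "head_kidney", "mIgM", 20),
    ct_row("c2", "control_albino", "head_kidney", "Ef1a", 21),
    ct_row("c2", "control_albino", "head_kidney", "mIgM", 21),
    ct_row("k1", "crispant", "head_kidney", "Ef1a", 20),
    ct_row("k1", "crispant", "head_kidney", "mIgM", 19))
  fit <- pfaffl(ct, flat_eff(2))
  r <- fit$records
  # ddCt = 0 for controls -> FC 1 regardless of E
  expect_equal(r$fold_change[r$group != "crispant"], c(1, 1))
  # crispant ddCt = -1, E = 2 -> FC 2
  expect_equal(r$fold_change[r$sample_id == "k1"], 2)

  # the efficiency enters as the base: E = 2.05, ddCt = +3 -> 2.05^-3
  ct$ct[ct$sample_id == "k1" & ct$gene == "mIgM"] <- 23
  fit <- pfaffl(ct, flat_eff(2.05))
  expect_equal(fit$records$fold_change[fit$records$sample_id == "k1"],
               2.05^-3)
  expect_equal(fit$records$fold_change[fit$records$sample_id == "k1"],
               0.116, tolerance = 1e-3)
})

random_ct_table <- function(n_ctrl = 6L, n_case = 8L,
                            genes = c("mIgM", "sIgM"), tissue = "spleen") {
  ids <- c(sprintf("ctrl%d", seq_len(n_ctrl)), sprintf("case%d", seq_len(n_case)))
  groups <- c(rep(c("control_wt", "control_albino"), length.out = n_ctrl),
              rep("crispant", n_case))
  do.call(rbind, lapply(seq_along(ids), function(i) {
    rows <- ct_row(ids[i], groups[i], tissue, "Ef1a", runif(1, 18, 22))
    for (g in genes) rows <- rbind(rows, ct_row(ids[i], groups[i], tissue, g,
                                                runif(1, 22, 30)))
    rows
  }))
}

test_that("the calibrator forces a unit geometric-mean control fold change", {
  set.seed(83)
  for (rep in 1:5) {
    ct <- random_ct_table()
    eff <- data.frame(gene = c("Ef1a", "mIgM", "sIgM"), tissue = "spleen",
                      efficiency = c(2.09, 2.05, 2.02))
    fit <- pfaffl(ct, eff)
    ctrl <- fit$records[fit$records$group != "crispant", ]
    for (g in unique(ctrl$gene)) {
      gm <- exp(mean(log(ctrl$fold_change[ctrl$gene == g])))
      expect_equal(gm, 1, tolerance = 1e-9)
    }
  }
})

test_that("single-efficiency and full Pfaffl modes agree when E_goi = E_ref", {
  set.seed(89)
  ct <- random_ct_table()
  eff <- data.frame(gene = c("Ef1a", "mIgM", "sIgM"), tissue = "spleen",
                    efficiency = 2.05)
  f1 <- pfaffl(ct, eff, mode = "single_efficiency")
  f2 <- pfaffl(ct, eff, mode = "pfaffl_full")
  expect_equal(f1$records$fold_change, f2$records$fold_change, tolerance = 1e-9)
})

test_that("fold change is strictly decreasing in delta-delta-Ct", {
  set.seed(97)
  ct <- random_ct_table(genes = "mIgM")
  eff <- data.frame(gene = c("Ef1a", "mIgM"), tissue = "spleen",
                    efficiency = c(2.09, 2.05))
  r <- pfaffl(ct, eff)$records
  ord <- order(r$delta_delta_ct)
  expect_true(all(diff(r$fold_change[ord]) < 0))
})

test_that("missing inputs fail with informative errors", {
  ct <- rbind(ct_row("c1", "control_wt", "head_kidney", "Ef1a", 20),
              ct_row("c1", "control_wt", "head_kidney", "mIgM", 22),
              ct_row("k9", "crispant", "head_kidney", "mIgM", 25))
  expect_error(pfaffl(ct, flat_eff(2)), "k9")          # no Ef1a for k9
  ct2 <- ct[ct$sample_id == "c1", ]
  expect_error(pfaffl(ct2, flat_eff(2, genes = "Ef1a")), "efficiency")
  expect_error(pfaffl(ct, flat_eff(2.5)), "2.2")       # efficiency out of range
})

test_that("Ct tables round-trip through the TSV reader with replicate collapsing", {
  td <- withr::local_tempdir()
  df <- data.frame(sample_id = c("a", "b"), group = c("crispant", "control_wt"),
                   tissue = "spleen", gene = "Ef1a",
                   ct_rep1 = c(20.0, 21.0), ct_rep2 = c(20.2, 22.5))
  p <- file.path(td, "ct.tsv")
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_ct_table(p)
  expect_equal(got$ct, c(20.1, 21.75))
  expect_equal(got$ct_flag, c(FALSE, TRUE))
  df$gene <- NULL
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_ct_table(p), "gene")
})

test_that("exact Mann-Whitney p-values match full enumeration", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(mw$statistic), 0)
  expect_equal(mw$p.value, 0.1)
  # symmetry: identical groups give p = 1
  expect_equal(mann_whitney(c(1, 2), c(1, 2))$p.value, 1)
  set.seed(101)
  for (rep in 1:60) {
    na <- sample(1:7, 1); nb <- sample(1:7, 1)
    x <- sample(seq(0, 1, by = 1e-4), na + nb)  # tie-free
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    p_pkg <- mann_whitney(a, b)$p.value
    expect_equal(p_pkg, oracle_mw_p(a, b))
    # independent cross-check against the standard exact implementation
    p_ref <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE)$p.value)
    expect_equal(p_pkg, p_ref)
  }
})

test_that("the exact test keeps its nominal type-I error rate", {
  set.seed(103)
  n_sim <- 1000L
  rej <- vapply(seq_len(n_sim), function(i) {
    a <- rnorm(5); b <- rnorm(5)
    mann_whitney(a, b)$p.value <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("large or tied samples use the corrected normal approximation", {
  set.seed(107)
  a <- rnorm(20); b <- rnorm(20) + 1
  got <- mann_whitney(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE,
                                             exact = FALSE)$p.value)
  expect_equal(got$p.value, ref, tolerance = 1e-8)
  expect_match(got$method, "normal approximation")
})
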