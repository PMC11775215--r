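make_read <- function(amp, ops) {
  allele <- edit_allele(ops)
  apply_allele(amp, allele)
}

test_that("read categories follow the net-indel mod-3 trichotomy", {
  amp <- synthetic_amplicons(seed = 101)$IgM_A
  w <- quant_window(amp)
  cut <- amp$target_site$cut_pos
  cl <- function(ops) {
    read <- if (is.null(ops)) amp$sequence else make_read(amp, ops)
    classify_read(align_glocal(read, amp), w)
  }
  expect_equal(cl(NULL)$category, "WT")
  # a 3-nt deletion at the cut is an in-frame mutation
  expect_equal(cl(data.frame(ref_pos = cut, kind = "del", length = 3L,
                             inserted_seq = NA))$category, "IN_FRAME")
  expect_equal(cl(data.frame(ref_pos = cut, kind = "ins", length = 1L,
                             inserted_seq = "A"))$category, "FRAMESHIFT")
  # 2-nt del + 1-nt ins: net -1 -> frameshift
  r <- cl(data.frame(ref_pos = c(cut - 10L, cut + 4L), kind = c("del", "ins"),
                     length = c(2L, 1L), inserted_seq = c(NA, "T")))
  expect_equal(r$category, "FRAMESHIFT")
  expect_equal(r$net_indel, -1L)
  # 3-nt del + 3-nt ins: net 0 with 2 events -> in-frame
  r <- cl(data.frame(ref_pos = c(cut - 12L, cut + 6L), kind = c("del", "ins"),
                     length = c(3L, 3L), inserted_seq = c(NA, "TAG")))
  expect_equal(r$category, "IN_FRAME")
  expect_gte(r$n_indel_events, 1L)
})

test_that("all one- and two-event indel combinations match the mod-3 oracle", {
  amp <- synthetic_amplicons(seed = 101)$IgM_A
  w <- quant_window(amp)
  cut <- amp$target_site$cut_pos
  for (len1 in 1:4) for (kind1 in c("ins", "del")) {
    for (second in c("none", "ins", "del")) {
      lens2 <- if (second == "none") 0L else 1:4
      for (len2 in lens2) {
        ops <- data.frame(ref_pos = cut - 15L, kind = kind1, length = len1,
                          inserted_seq = if (kind1 == "ins") strrep("A", len1) else NA,
                          stringsAsFactors = FALSE)
        if (second != "none") {
          ops <- rbind(ops, data.frame(
            ref_pos = cut + 8L, kind = second, length = len2,
            inserted_seq = if (second == "ins") strrep("C", len2) else NA))
        }
        read <- make_read(amp, ops)
        if (read == amp$sequence) next   # degenerate: edit restores the reference
        got <- classify_read(align_glocal(read, amp), w)
        net <- sum(ifelse(ops$kind == "ins", ops$length, -ops$length))
        expect_equal(got$category,
                     if (net %% 3L == 0L) "IN_FRAME" else "FRAMESHIFT",
                     info = paste(kind1, len1, second, len2))
      }
    }
  }
})

test_that("locus assignment picks the better paralog and refuses ties and junk", {
  amps <- synthetic_amplicons(seed = 101)
  set.seed(73)
  # reads simulated from each locus go home
  expect_equal(assign_locus(amps$IgM_A$sequence, amps), "IgM_A")
  expect_equal(assign_locus(amps$IgM_B$sequence, amps), "IgM_B")
  # identical references tie -> unassigned
  twins <- list(L1 = amps$IgM_A, L2 = amps$IgM_A)
  twins$L2$locus_id <- "L2"
  expect_equal(assign_locus(amps$IgM_A$sequence, twins), "UNASSIGNED")
  # unrelated random reads fall below the score floor
  junk <- vapply(1:20, function(i) rand_dna(150), "")
  expect_true(all(assign_locus(junk, amps) == "UNASSIGNED"))
})

test_that("summaries compute the three-way ratios with unassigned reads excluded", {
  df <- data.frame(
    read_id = as.character(1:110),
    locus = "IgM_A",
    category = c(rep("WT", 2), rep("IN_FRAME", 19), rep("FRAMESHIFT", 79),
                 rep("UNASSIGNED", 10)),
    net_indel = 0L, n_indel_events = 0L, n_substitutions = 0L,
    stringsAsFactors = FALSE)
  s <- summarize_locus(df, individual = "fish1", tissue = "fin")
  expect_equal(s$f_WT, 0.02)
  expect_equal(s$f_inframe, 0.19)
  expect_equal(s$f_frameshift, 0.79)
  expect_equal(s$n_unassigned, 10L)
  expect_equal(s$f_WT + s$f_inframe + s$f_frameshift, 1, tolerance = 1e-9)
  # 98 mutated of 100 reads -> mutated fraction 0.98
  expect_equal(1 - s$f_WT, 0.98)

  all_wt <- df[df$category == "WT", ]
  s2 <- summarize_locus(all_wt, individual = "fish1", tissue = "fin")
  expect_equal(s2$f_WT, 1)
  expect_equal(s2$f_inframe + s2$f_frameshift, 0)

  expect_error(summarize_locus(df[0, ], individual = "x", tissue = "y"),
               "no classified reads")
})

test_that("tissue comparison returns per-category fraction differences", {
  base <- data.frame(individual = "IgM_16", locus = "IgM_B",
                     n_WT = 0L, n_inframe = 0L, n_frameshift = 0L,
                     n_unassigned = 0L, stringsAsFactors = FALSE)
  wbc <- cbind(base, tissue = "wbc", f_WT = 0.24, f_inframe = 0.16, f_frameshift = 0.60)
  fin <- cbind(base, tissue = "fin", f_WT = 0.04, f_inframe = 0.16, f_frameshift = 0.80)
  d <- compare_tissues(wbc, fin)
  expect_equal(d$d_WT, 0.20)
  expect_equal(d$d_inframe, 0)
  expect_equal(d$d_frameshift, -0.20)
  # identical summaries -> zero differences
  d0 <- compare_tissues(wbc, wbc)
  expect_true(all(abs(c(d0$d_WT, d0$d_inframe, d0$d_frameshift)) < 1e-12))
  # mismatched keys -> error
  other <- wbc; other$individual <- "IgM_17"
  expect_error(compare_tissues(other, fin), "mismatched")
})

test_that("category does not depend on where a co-optimal gap is placed", {
  # deletion inside a homopolymer: every placement is co-optimal; the
  # classification must be identical for all of them, and the aligner's
  # left-normalized choice must agree
  set.seed(79)
  amp <- toy_amp(flank5 = 20, flank3 = 20)
  w <- list(span = c(2L, nchar(amp$sequence) - 2L), mode = "full_amplicon")
  ref <- amp$sequence
  # the spacer carries a bounded GGG run at 0-based spacer offset 15
  p <- 20L + 15L  # 0-based run start on the reference
  expect_equal(substring(ref, p + 1, p + 3), "GGG")
  for (drop in 0:2) {  # deleting any G of the run is co-optimal
    read <- paste0(substring(ref, 1, p + drop), substring(ref, p + drop + 2, nchar(ref)))
    aln <- align_glocal(read, amp)
    got <- classify_read(aln, w)
    expect_equal(got$category, "FRAMESHIFT")
    expect_equal(got$net_indel, -1L)
    # and the reported placement is the leftmost position of the run
    expect_equal(aln$ops$ref_pos[aln$ops$type == "D"], p)
  }
})

test_that("wild-type misclassification under errors matches the analytic substitution rate", {
  # strict perfect-match WT: any surviving substitution in the window moves a
  # WT read out of WT. With per-base error e and window width wlen the
  # analytic misclassification probability for a raw R1 read is 1-(1-e)^wlen.
  amp <- synthetic_amplicons(seed = 101)$IgM_A
  e <- 0.005
  cfg <- sim_config(n_individuals = 1L, read_depth = 4000L, error_rate = e,
                    tail_len = 0L, seed = 1L)
  wt_only <- structure(list(alleles = list(edit_allele()), fractions = 1),
                       class = "allele_spectrum")
  set.seed(911)
  reads <- simulate_reads(amp, wt_only, cfg)
  cls <- classify_reads(reads$r1, list(IgM_A = amp))
  mis <- mean(cls$category != "WT")
  w <- quant_window(amp)
  wlen <- w$span[2] - w$span[1]
  p_expected <- 1 - (1 - e)^wlen
  se <- sqrt(p_expected * (1 - p_expected) / 4000)
  expect_lt(abs(mis - p_expected), 4 * se)
})

test_that("category fractions are recovered from simulated samples", {
  cfg <- sim_config(n_individuals = 4L, read_depth = 1500L, seed = 404L)
  td <- withr::local_tempdir()
  res <- simulate_cohort(cfg, out_dir = td)
  amps <- read_amplicons(file.path(td, "refs.fasta"), file.path(td, "sites.json"))
  q <- quantify_editing(res$manifest, amps)
  est <- as.data.frame(q$per_sample)
  key <- paste(est$individual, est$tissue, est$locus)
  tkey <- paste(res$truth$individual, res$truth$tissue, res$truth$locus)
  truth <- res$truth[match(key, tkey), ]
  err <- abs(cbind(est$f_WT - truth$frac_WT,
                   est$f_inframe - truth$frac_inframe,
                   est$f_frameshift - truth$frac_frameshift))
  # binomial sampling at n = 1500 plus the documented WT->in-frame
  # substitution leak bound the per-sample error well below 0.04
  expect_lt(max(err), 0.04)
  expect_lt(mean(err), 0.02)
})
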