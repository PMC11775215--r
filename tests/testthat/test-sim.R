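local_cfg <- function(...) {
  args <- modifyList(list(n_individuals = 2L, read_depth = 500L, seed = 1L), list(...))
  do.call(sim_config, args)
}

test_that("sim_config validates probabilities and requires a seed", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, editing_rate = 1.2))
  expect_error(sim_config(seed = 1, editing_rate = 0.5, frameshift_rate = 0.6))
  expect_s3_class(local_cfg(), "sim_config")
})

test_that("degenerate spectra: no editing gives pure WT, forced 1-nt insertions give pure frameshift", {
  amp <- synthetic_amplicons(seed = 101)$IgM_A
  cfg <- local_cfg()
  spec0 <- sample_allele_spectrum(cfg, amp, editing_rate = 0)
  expect_length(spec0$alleles, 1L)
  expect_equal(spec0$fractions, 1)
  expect_equal(nrow(spec0$alleles[[1]]$ops), 0L)

  set.seed(5)
  cfg1 <- local_cfg(p_ins = 1, ins_p = 1, ins_max = 1L,
                    editing_rate = 1, frameshift_rate = 1)
  spec1 <- sample_allele_spectrum(cfg1, amp)
  edited <- spec1$alleles[-1L]  # first entry is the (zero-weight) WT allele
  expect_true(all(vapply(edited, function(a) a$ops$length[1], 1L) == 1L))
  expect_true(all(vapply(edited, function(a) a$ops$kind[1], "") == "ins"))
  expect_equal(spec1$fractions[1], 0)
})

test_that("spectrum fractions are a probability vector and WT mass matches the editing rate", {
  amp <- synthetic_amplicons(seed = 101)$IgM_A
  cfg <- local_cfg()
  set.seed(99)
  n <- 10000L
  wt <- numeric(n)
  for (i in seq_len(n)) {
    sp <- sample_allele_spectrum(cfg, amp, editing_rate = 0.97,
                                 frameshift_rate = 0.78)
    wt[i] <- sp$fractions[1]
    if (i <= 100) {
      expect_true(all(sp$fractions >= 0))
      expect_equal(sum(sp$fractions), 1, tolerance = 1e-9)
    }
  }
  # Dirichlet mean of the WT component is 1 - editing_rate = 0.03
  se <- sd(wt) / sqrt(n)
  expect_lt(abs(mean(wt) - 0.03), 3 * se + 1e-12)
})

test_that("apply_allele splices indels exactly", {
  amp <- synthetic_amplicons(seed = 101)$IgM_A
  ref <- amp$sequence
  cut <- amp$target_site$cut_pos
  expect_equal(apply_allele(amp, edit_allele()), ref)

  del3 <- edit_allele(data.frame(ref_pos = cut, kind = "del", length = 3L,
                                 inserted_seq = NA, stringsAsFactors = FALSE))
  expect_equal(nchar(apply_allele(amp, del3)), nchar(ref) - 3L)

  # 2-nt deletion at cut-1 plus 1-nt insertion at cut+4 against a hand-spliced
  # oracle on a 40-nt sub-reference geometry
  ops <- data.frame(ref_pos = c(cut - 1L, cut + 4L), kind = c("del", "ins"),
                    length = c(2L, 1L), inserted_seq = c(NA, "T"),
                    stringsAsFactors = FALSE)
  got <- apply_allele(amp, edit_allele(ops))
  expect_equal(nchar(got), nchar(ref) - 1L)
  expect_equal(got, oracle_splice(ref, ops))

  set.seed(17)
  for (rep in 1:20) {
    np <- sample(1:3, 1)
    pos <- sort(sample(seq(5L, nchar(ref) - 12L, by = 6L), np))
    kinds <- sample(c("ins", "del"), np, replace = TRUE)
    lens <- sample(1:4, np, replace = TRUE)
    ops <- data.frame(ref_pos = pos, kind = kinds, length = lens,
                      inserted_seq = ifelse(kinds == "ins",
                                            vapply(lens, rand_dna, ""), NA),
                      stringsAsFactors = FALSE)
    expect_equal(apply_allele(amp, edit_allele(ops)), oracle_splice(ref, ops))
  }

  bad <- data.frame(ref_pos = c(cut, cut + 1L), kind = c("del", "del"),
                    length = c(3L, 2L), inserted_seq = NA,
                    stringsAsFactors = FALSE)
  expect_error(apply_allele(amp, edit_allele(bad)), "overlap")
})

test_that("error-free reads are exact amplicon copies and truth counts what was emitted", {
  amp <- synthetic_amplicons(seed = 101)$IgM_A
  cfg <- local_cfg(error_rate = 0, read_depth = 200L)
  wt_only <- structure(list(alleles = list(edit_allele()), fractions = 1),
                       class = "allele_spectrum")
  set.seed(3)
  reads <- simulate_reads(amp, wt_only, cfg)
  expect_true(all(reads$r1 == amp$sequence))
  expect_true(all(reads$r2 == revcomp(amp$sequence)))
  expect_equal(unname(reads$truth$counts["WT"]), 200L)

  ins1 <- edit_allele(data.frame(ref_pos = amp$target_site$cut_pos, kind = "ins",
                                 length = 1L, inserted_seq = "A",
                                 stringsAsFactors = FALSE), label = "ins1")
  mix <- structure(list(alleles = list(edit_allele(), ins1),
                        fractions = c(0.25, 0.75)), class = "allele_spectrum")
  set.seed(4)
  reads <- simulate_reads(amp, mix, cfg)
  # ground truth counts the emitted reads, not the expected fractions
  emitted_ins <- sum(grepl(":ins1:", reads$id, fixed = TRUE))
  expect_equal(unname(reads$truth$counts[["FRAMESHIFT"]]), emitted_ins)
  expect_equal(sum(reads$truth$counts), 200L)
  # downstream classification of a pure 1-nt insertion spectrum is all frameshift
  pure <- structure(list(alleles = list(ins1), fractions = 1),
                    class = "allele_spectrum")
  set.seed(5)
  reads <- simulate_reads(amp, pure, cfg)
  cls <- classify_reads(reads$r1, list(IgM_A = amp))
  expect_true(all(cls$category == "FRAMESHIFT"))
})

test_that("cohort simulation is byte-deterministic under a fixed seed", {
  cfg <- local_cfg(n_individuals = 1L, read_depth = 100L, seed = 77L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- simulate_cohort(cfg, out_dir = d1)
  r2 <- simulate_cohort(cfg, out_dir = d2)
  expect_equal(r1$truth, r2$truth)
  for (f in list.files(file.path(d1, "fastq"))) {
    expect_equal(unname(tools::md5sum(file.path(d1, "fastq", f))),
                 unname(tools::md5sum(file.path(d2, "fastq", f))))
  }
  # manifest rows = individuals x tissues x loci
  expect_equal(nrow(r1$manifest), 1L * 1L * 2L)
})

test_that("expected mutated fraction increases with the editing rate", {
  amp <- synthetic_amplicons(seed = 101)$IgM_A
  set.seed(2024)
  grid <- c(0.2, 0.5, 0.8)
  mutated <- vapply(grid, function(e) {
    mean(vapply(1:400, function(i) {
      sp <- sample_allele_spectrum(local_cfg(), amp, editing_rate = e,
                                   frameshift_rate = 0.8 * e)
      1 - sp$fractions[1]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mutated) > 0))
})
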