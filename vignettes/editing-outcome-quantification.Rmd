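---
title: "Quantifying CRISPR editing outcomes in mosaic F0 crispants"
author: "crispantquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CRISPR editing outcomes in mosaic F0 crispants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crispantquant)
```

## The problem

Injecting Cas9 and a gRNA into a fertilized egg produces an F0 animal whose
cells carry a mixture of repair outcomes: unedited (wild-type) alleles,
small in-frame indels that usually preserve protein function, and frameshift
indels that usually abolish it. In salmonids this is further complicated by
the ancestral whole-genome duplication: a functional knockout of, e.g., the
IgM heavy chain requires disrupting two near-identical loci (IgM A and B).
The practical readout is deep amplicon sequencing across the gRNA target
site, per locus and per tissue, and the quantity of interest is the fraction
of reads in each of three categories — WT, in-frame, frameshift — per
individual, and their unweighted mean over the cohort.

`crispantquant` implements that readout end to end, together with the
companion efficiency-corrected RT-qPCR analysis used to confirm knockdown at
the mRNA level, and a simulator of mosaic crispant cohorts that makes every
stage verifiable by parameter recovery.

## Target-site model

A target site is the unique occurrence, on either strand of a reference
amplicon, of the 20-nt spacer immediately 5′ of an NGG PAM. The predicted
blunt cut falls between protospacer positions 17 and 18, i.e. 3 nt from the
PAM. All coordinates in the package are 0-based half-open, and the cut
position is a *gap* coordinate (it names the bond, not a base), which makes
indel placement unambiguous. Two spacers are bundled (`igm_spacers()`)
because the original design screened two candidate gRNAs against the mu-1
exon; which one generated a given data set is an input, not an assumption —
`locate_protospacer()` takes any spacer and refuses ambiguous references.

Locus demultiplexing uses separate reference amplicons per paralog: each
read is aligned against every reference and assigned to the best-scoring one
provided the score reaches `min_score_frac` (default 0.5) of the maximum
attainable and strictly beats the runner-up; ties (e.g. identical
references) and junk reads become `UNASSIGNED` and never enter denominators.

## Read filtering

Filtering reproduces a `-q 20 -m 100` contract: 3′ quality trimming by the
BWA-style suffix-sum rule (trim the suffix minimizing the running sum of
`q - 20`, ties toward the longest read, so output is always a prefix and the
operation is idempotent), then discarding of reads shorter than 100 nt
("shorter than" — a 100-nt read survives). Whether the original analyses
merged mates or used single reads is not documented anywhere we could rely
on, so pairing is a configuration switch: the default merges mates by the
best ungapped overlap (≥ 20 nt, mismatch fraction ≤ 0.25, consensus by the
higher-quality base with ties to R1) and falls back to R1 where merging
fails; `pairing = "r1_only"` disables merging entirely. Merging matters for
accuracy: in the overlap, a sequencing error survives the consensus only
when the erroneous base happens to carry the higher quality.

## Alignment and classification

The analytical core aligns each retained read to its locus reference with a
glocal affine-gap dynamic program: global in the read, free end gaps on the
reference, match +5, mismatch −4, gap open −10, gap extend −1, where a gap
of length L costs `open + L·extend`. Determinism is part of the contract:
backtrace ties resolve diagonal > deletion > insertion, co-optimal terminal
positions take the leftmost reference end, and internal gaps are
left-normalized within homopolymer runs afterwards (VCF-like placement).
The classification is invariant to the remaining ambiguity because it
depends only on the net indel length and the presence of at least one event,
not on gap placement.

Indel events intersecting a *quantification window* are collected; the
default window is the full inter-primer region (closest to whole-read
categorization), with a cut-centered mode (± 30 nt) available for noisy
data. With net indel length `L` over the window:

| events | condition | category |
|---|---|---|
| ≥ 1 | `L mod 3 != 0` | `FRAMESHIFT` |
| ≥ 1 | `L mod 3 == 0` | `IN_FRAME` |
| 0 | substitutions ≤ `max_subs` (default 0) | `WT` |
| 0 | substitutions > `max_subs` | per `substitution_policy` |

The strict `max_subs = 0` default means WT demands a perfect match, which is
the field's three-way convention — but it leaves substitution-only reads
homeless. The default policy routes them to `IN_FRAME` (mutated but
frame-preserving); `"wt"` and a `"separate"` excluded category are
available, because this choice is genuinely underdetermined. The
consequence is documented rather than hidden: at per-base error rate *e* a
true-WT read is misclassified with probability `1 − (1 − e)^w` for a window
of width *w* (a property test checks the pipeline against this closed form),
and pair merging plus the window choice keep the resulting bias on cohort WT
fractions well inside the recovery tolerances below. Reads whose alignment
does not span the window are `UNASSIGNED` and excluded from denominators.

## The simulator: what it emulates and what it does not

`sim_config()` defaults are the study conditions the package models: 20
crispant individuals, fin tissue, two duplicated 180-nt amplicons carrying
the same spacer (paralogs differing at 6 sites outside the target region),
10,000 read pairs per individual and locus, 2×300 nt reads (full-amplicon
reads, since the amplicon is shorter), per-locus editing rates 0.98 / 0.97
with frameshift-of-total rates 0.79 / 0.77, and per-base substitution error
0.003.

Per individual and locus the simulator draws a wild-type allele plus
`K ≥ 2` edited alleles (K − 1 ~ Poisson, mean 3). The *expected* cell mass
of each frame class is fixed at the configured rates — WT `1 − e`,
frameshift `fs`, in-frame `e − fs` — and split among that class's alleles;
cell fractions are then Dirichlet with concentration 30 times those means.
By Dirichlet aggregation each class fraction is Beta-distributed around its
rate (frameshift s.d. ≈ 0.07 across fish), matching the qualitative
dispersion of real per-fish outcome bars: most fish nearly fully edited,
occasional stragglers. Indel alleles are anchored at the cut site
(insertions at the cut, deletions covering it), with geometric lengths
(deletions p = 0.25 capped at 30, insertions p = 0.5 capped at 10,
P(ins) = 0.3); the real indel-size spectrum is not documented, so these are
stand-ins chosen for the qualitative dominance of short indels at Cas9
cuts, and no test depends on the exact size distribution. With several
tissues, each tissue redraws its fractions around the individual's shared
pool (Dirichlet, concentration 25) — mostly concordant tissues with
occasional large discordance, the mosaicism signature.

Base-call errors are quality-driven: body qualities jitter ± 3 around the
level implied by the configured error rate (Q ≈ 25 at 0.003), the last 30 nt
decay linearly to Q10 (so the trimming stage has realistic work), and each
base errs with probability proportional to `10^(-q/10)`, calibrated so the
body marginal equals the configured rate exactly (error rate 0 disables
errors and emits Q40 bodies). The ground-truth table counts the categories
of the reads actually emitted, not expectations, so recovery tests compare
against realized truth.

Not emulated: PCR chimeras and amplification bias, large structural
variants, HDR alleles, per-cycle error models, adapter read-through.
Passing recovery tests therefore demonstrates correctness of the
quantification machinery under a faithful-but-clean error model, not
robustness to every artifact of real libraries; the strict-WT convention's
sensitivity to substitution noise is quantified by the analytic property
test above.

## Expression analysis

`pfaffl()` follows the calibrator workflow: per sample,
`ΔCt = Ct_GOI − Ct_ref` (reference gene Ef1a); the calibrator is the mean
ΔCt of the pooled control groups (wild-type and albino-injected controls
together); `ΔΔCt = ΔCt − calibrator`. Two modes are implemented because the
field's usage mixes two formulas: the default `single_efficiency` computes
`FC = E_GOI^(−ΔΔCt)` — the literal ΔΔCt workflow with the measured per-gene
amplification efficiency in place of an assumed doubling — while
`pfaffl_full` computes the efficiency-ratio form
`E_GOI^(ΔCt_GOI,cal−sample) / E_ref^(ΔCt_ref,cal−sample)`. They agree
whenever `E_GOI = E_ref`, and the calibrator definition forces the control
group's geometric-mean fold change to 1 in either mode (both are tested
identities). Efficiencies are inputs (1 < E ≤ 2.2), not estimated;
`igm_efficiencies()` ships the measured head-kidney/spleen values for the
Ef1a, sIgM, mIgM and IgT assays. Technical duplicates are averaged, with a
flag when the replicate s.d. exceeds 0.5 cycles.

Group comparisons use a two-sided Mann–Whitney U test, exact by full
enumeration of rank assignments for tie-free samples with `n_a + n_b ≤ 16`,
otherwise the normal approximation with tie and continuity corrections;
`U = min(U_a, U_b)` is reported. No multiplicity adjustment is applied —
comparisons are reported per gene × tissue as-is.

## Numerical and design choices

- **Coordinates** 0-based half-open throughout; `cut_pos` is a gap index.
- **Gap cost** `open + L·extend`; alignment scores are integers, so
  score ties are exact and the fixed backtrace priority fully determines
  the reported alignment.
- **Insertions at window edges** count as intersecting (gap coordinate in
  the closed interval), deletions by interval overlap.
- **Degenerate inputs**: empty reads never align (length filter removes
  them first); editing rate 0 yields the pure-WT spectrum; an empty
  classification group is an error, not a silent zero.
- **Determinism**: a mandatory simulator seed makes FASTQ output
  byte-identical across runs; pipeline tables carry the seed and a
  configuration hash in comment lines.
- **Problem sizes**: the recovery suite runs the full study scale
  (20 × 2 × 10,000 read pairs, about two minutes of alignment in the
  bundled C++ core); unit tests use smaller cohorts sized so that binomial
  sampling error, not runtime, sets the tolerances.

## Known limitations

- Substitution-only reads have no category of their own under the default
  policy; analyses of hypermutated data should use `"separate"`.
- Reads are assumed to be in R1 orientation after merging; amplicons
  sequenced in mixed orientation would need a reverse-complement pass.
- The aligner is pairwise per-locus; it does not reconstruct haplotypes or
  detect HDR, microhomology signatures, or large rearrangements.
- Cohort means are unweighted over individuals, which is the convention for
  mutagenesis-efficiency reporting; depth-weighted pooling would differ
  when sample depths are very unequal.
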