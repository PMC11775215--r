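# Independent brute-force oracles and small fixture builders. These are
# deliberately written without reusing the package's implementations.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

phred_string <- function(q, offset = 33L) {
  intToUtf8(q + offset)
}

# brute-force 3' trim: enumerate every trim point, keep the one minimizing the
# suffix sum of (q - threshold); ties toward the longest retained read
oracle_trim_point <- function(q, threshold) {
  n <- length(q)
  d <- q - threshold
  sums <- vapply(seq_len(n + 1L), function(i) {
    if (i > n) 0 else sum(d[i:n])
  }, numeric(1))
  candidates <- which(sums == min(sums))
  max(candidates) - 1L  # kept length; max() breaks ties toward longest
}

# brute-force protospacer scan of both strands
oracle_locate <- function(ref, spacer) {
  rc_tab <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) {
    paste(rev(rc_tab[strsplit(s, "")[[1]]]), collapse = "")
  }
  n <- nchar(ref)
  hits <- list()
  for (s0 in 0:(n - 20L)) {
    sub <- substring(ref, s0 + 1L, s0 + 20L)
    if (sub == spacer && s0 + 23L <= n &&
        substring(ref, s0 + 22L, s0 + 23L) == "GG") {
      hits[[length(hits) + 1L]] <- list(strand = "+", start = s0, cut = s0 + 17L)
    }
    if (sub == rc(spacer) && s0 >= 3L &&
        substring(ref, s0 - 2L, s0 - 1L) == "CC") {
      hits[[length(hits) + 1L]] <- list(strand = "-", start = s0, cut = s0 + 3L)
    }
  }
  hits
}

# full-enumeration two-sided Mann-Whitney p-value (tie-free inputs)
oracle_mw_p <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_min <- min(u, na * nb - u)
  sets <- utils::combn(n, na)
  u_all <- apply(sets, 2L, sum) - na * (na + 1) / 2
  min(1, (sum(u_all <= u_min) + sum(u_all >= na * nb - u_min)) / ncol(sets))
}

# exhaustive recursive affine-gap glocal alignment score (tiny inputs only):
# read must be consumed globally; any contiguous reference window may be used
oracle_glocal_score <- function(read, ref, match = 5, mismatch = -4,
                                open = -10, ext = -1) {
  rchars <- strsplit(ref, "")[[1]]
  qchars <- strsplit(read, "")[[1]]
  m <- length(rchars); n <- length(qchars)
  best <- -Inf
  rec <- function(i, j, iend, prev, acc) {
    # i: next ref index within [istart, iend]; j: next read index; prev: last op
    if (j > n) {
      if (i == iend + 1L) best <<- max(best, acc)
      return(invisible())
    }
    if (acc + (n - j + 1L) * match < best) return(invisible())  # bound
    if (i <= iend) {
      s <- if (rchars[i] == qchars[j]) match else mismatch
      rec(i + 1L, j + 1L, iend, "M", acc + s)
      rec(i + 1L, j, iend, "D", acc + ext + if (identical(prev, "D")) 0 else open)
    }
    rec(i, j + 1L, iend, "I", acc + ext + if (identical(prev, "I")) 0 else open)
  }
  for (istart in 1:(m + 1L)) {
    for (iend in (istart - 1L):m) {
      rec(istart, 1L, iend, NULL, 0)
    }
  }
  best
}

# a small amplicon whose sequence is random flanks around the spacer + NGG PAM
toy_amp <- function(flank5 = 40L, flank3 = 40L,
                    spacer = igm_spacers()[["IgM_1"]],
                    locus_id = "toy", primer_len = 0L) {
  repeat {
    seq <- paste0(rand_dna(flank5), spacer, "TGG", rand_dna(flank3))
    amp <- tryCatch({
      pf <- if (primer_len > 0L) c(0L, primer_len) else NULL
      pr <- if (primer_len > 0L) c(nchar(seq) - primer_len, nchar(seq)) else NULL
      reference_amplicon(locus_id, seq, spacer, pf, pr)
    }, error = function(e) NULL)
    if (!is.null(amp)) return(amp)
  }
}

# hand-spliced application of indel ops, independent of apply_allele()
oracle_splice <- function(ref, ops) {
  chars <- strsplit(ref, "")[[1]]
  keep <- rep(TRUE, length(chars))
  ins_at <- rep("", length(chars) + 1L)
  for (i in seq_len(nrow(ops))) {
    p <- ops$ref_pos[i]
    if (ops$kind[i] == "del") {
      keep[(p + 1L):(p + ops$length[i])] <- FALSE
    } else {
      ins_at[p + 1L] <- paste0(ins_at[p + 1L], ops$inserted_seq[i])
    }
  }
  out <- ""
  for (p in seq_along(chars)) {
    out <- paste0(out, ins_at[p], if (keep[p]) chars[p] else "")
  }
  paste0(out, ins_at[length(chars) + 1L])
}
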