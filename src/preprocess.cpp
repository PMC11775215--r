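#include <Rcpp.h>
#include <string>
#include <algorithm>
using namespace Rcpp;

// 3' quality trimming, BWA-style suffix-sum rule: with d_j = q_j - threshold,
// trim the suffix starting at the index i minimizing sum_{j>=i} d_j when that
// minimum is negative; ties broken toward the longest retained read.
// Returns the kept length for each quality string.
// [[Rcpp::export]]
IntegerVector cq_trim3(CharacterVector quals, int threshold, int phred_offset) {
  const int n = quals.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    const char* q = CHAR(STRING_ELT(quals, r));
    const int len = (int)LENGTH(STRING_ELT(quals, r));
    long best_sum = 0, cum = 0;
    int best_i = len;
    for (int j = len - 1; j >= 0; --j) {
      cum += (long)(q[j] - phred_offset) - threshold;
      if (cum < best_sum) { best_sum = cum; best_i = j; }  // strict: keeps largest i
    }
    out[r] = best_i;
  }
  return out;
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g'; case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

// Merge read pairs by the best ungapped suffix(R1)/prefix(revcomp R2) overlap.
// Best = maximal (matches - mismatches) among overlaps of length >= min_overlap
// with mismatch fraction <= max_mismatch_frac; ties go to the longer overlap.
// Consensus base at a mismatch is the higher-quality call (tie -> R1).
// [[Rcpp::export]]
List cq_merge_pairs(CharacterVector r1, CharacterVector q1,
                    CharacterVector r2, CharacterVector q2,
                    int min_overlap, double max_mismatch_frac) {
  const int n = r1.size();
  CharacterVector mseq(n), mqual(n);
  LogicalVector merged(n);
  std::string s2, t2;
  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(r1[i]);
    std::string qa = as<std::string>(q1[i]);
    std::string b = as<std::string>(r2[i]);
    std::string qb = as<std::string>(q2[i]);
    // reverse-complement mate 2 (and reverse its qualities)
    s2.assign(b.rbegin(), b.rend());
    for (size_t k = 0; k < s2.size(); ++k) s2[k] = comp(s2[k]);
    t2.assign(qb.rbegin(), qb.rend());

    const int la = (int)a.size(), lb = (int)s2.size();
    const int Lmax = std::min(la, lb);
    int best_L = -1, best_score = INT_MIN;
    for (int L = Lmax; L >= min_overlap; --L) {
      const int max_mm = (int)(max_mismatch_frac * L);
      int mm = 0;
      const char* pa = a.data() + (la - L);
      const char* pb = s2.data();
      bool ok = true;
      for (int k = 0; k < L; ++k) {
        if (pa[k] != pb[k]) {
          if (++mm > max_mm) { ok = false; break; }
        }
      }
      if (!ok) continue;
      const int score = L - 2 * mm;  // matches - mismatches
      if (score > best_score) { best_score = score; best_L = L; }
    }
    if (best_L < 0) {
      merged[i] = false;
      mseq[i] = NA_STRING; mqual[i] = NA_STRING;
      continue;
    }
    const int L = best_L, off = la - L;
    std::string cons = a.substr(0, off);
    std::string consq = qa.substr(0, off);
    cons.reserve(la + lb - L); consq.reserve(la + lb - L);
    for (int k = 0; k < L; ++k) {
      const char ca = a[off + k], cb = s2[k];
      const char qca = qa[off + k], qcb = t2[k];
      if (ca == cb) {
        cons.push_back(ca);
        consq.push_back(std::max(qca, qcb));
      } else if (qcb > qca) {
        cons.push_back(cb); consq.push_back(qcb);
      } else {
        cons.push_back(ca); consq.push_back(qca);
      }
    }
    cons.append(s2, L, std::string::npos);
    consq.append(t2, L, std::string::npos);
    merged[i] = true;
    mseq[i] = cons; mqual[i] = consq;
  }
  return List::create(_["merged"] = merged, _["seq"] = mseq, _["qual"] = mqual);
}
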