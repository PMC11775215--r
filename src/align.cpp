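#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// Glocal affine-gap alignment (Gotoh): the read is aligned globally, the
// reference has free end gaps. Backtrace priority on score ties is
// diagonal > deletion-from-ref > insertion-to-ref; internal gaps are
// left-normalized afterwards so indel placement is deterministic and
// VCF-like. Gap cost convention: a gap of length L costs open + L * extend.

namespace {

const int NEG_INF = INT_MIN / 4;

struct Op {
  char type;     // 'M' (match/mismatch run), 'D' (deletion from ref), 'I' (insertion to ref)
  int ref_pos;   // 0-based ref start; for 'I' the gap position (before this ref base)
  int len;
  int read_pos;  // 0-based read start; for 'D' the read position of the gap
};

struct Aln {
  int score = 0;
  int ref_start = 0;  // first ref base covered by the alignment
  int ref_end = 0;    // one past the last ref base covered
  std::vector<Op> ops;
  std::vector<int> mism_ref;  // ref positions of mismatches
};

// Workspace reused across reads to avoid re-allocation.
struct Workspace {
  std::vector<int> H, D, I;
  std::vector<unsigned char> pH, pD, pI;  // backtrace pointers
  void resize(size_t n) {
    if (H.size() < n) {
      H.resize(n); D.resize(n); I.resize(n);
      pH.resize(n); pD.resize(n); pI.resize(n);
    }
  }
};

// pH codes: 0 = diagonal, 1 = from D state, 2 = from I state, 3 = start (free ref prefix)
// pD / pI: 0 = opened from H, 1 = extended

void left_normalize(const std::string& ref, const std::string& read, std::vector<Op>& ops) {
  bool changed = true;
  while (changed) {
    changed = false;
    for (size_t k = 1; k < ops.size(); ++k) {
      if (ops[k].type == 'M') continue;
      if (ops[k - 1].type != 'M') continue;
      while (ops[k - 1].len >= 1) {
        const char gt = ops[k].type;
        const int p = ops[k].ref_pos, q = ops[k].read_pos, L = ops[k].len;
        bool ok;
        if (gt == 'D') {
          // shift deletion [p, p+L) left by one: valid and score-preserving
          // iff ref[p-1] == ref[p+L-1]
          ok = (p >= 1 && ref[p - 1] == ref[p + L - 1]);
        } else {
          // shift insertion (read[q, q+L) at ref gap p) left by one:
          // valid and score-preserving iff read[q-1] == read[q+L-1]
          ok = (q >= 1 && p >= 1 && read[q - 1] == read[q + L - 1]);
        }
        if (!ok) break;
        ops[k].ref_pos -= 1; ops[k].read_pos -= 1;
        ops[k - 1].len -= 1;
        // the displaced aligned pair moves to just after the gap
        int m_ref, m_read;
        if (gt == 'D') { m_ref = ops[k].ref_pos + L; m_read = ops[k].read_pos; }
        else           { m_ref = ops[k].ref_pos;     m_read = ops[k].read_pos + L; }
        if (k + 1 < ops.size() && ops[k + 1].type == 'M') {
          ops[k + 1].ref_pos -= 1; ops[k + 1].read_pos -= 1; ops[k + 1].len += 1;
        } else {
          Op m; m.type = 'M'; m.ref_pos = m_ref; m.read_pos = m_read; m.len = 1;
          ops.insert(ops.begin() + k + 1, m);
        }
        changed = true;
      }
    }
    // drop emptied M runs
    std::vector<Op> keep;
    keep.reserve(ops.size());
    for (const Op& o : ops) if (!(o.type == 'M' && o.len == 0)) keep.push_back(o);
    ops.swap(keep);
  }
}

Aln align_one(const std::string& ref, const std::string& read,
              int match, int mismatch, int gap_open, int gap_ext,
              Workspace& ws) {
  const int m = (int)ref.size(), n = (int)read.size();
  const int W = n + 1;
  ws.resize((size_t)(m + 1) * W);
  int* H = ws.H.data(); int* D = ws.D.data(); int* I = ws.I.data();
  unsigned char* pH = ws.pH.data(); unsigned char* pD = ws.pD.data(); unsigned char* pI = ws.pI.data();

  // init row i = 0 (no ref consumed)
  H[0] = 0; D[0] = NEG_INF; I[0] = NEG_INF; pH[0] = 3;
  for (int j = 1; j <= n; ++j) {
    I[j] = (j == 1) ? (gap_open + gap_ext) : (I[j - 1] + gap_ext);
    pI[j] = (j == 1) ? 0 : 1;
    H[j] = I[j]; pH[j] = 2;
    D[j] = NEG_INF;
  }
  for (int i = 1; i <= m; ++i) {
    const int row = i * W, prow = (i - 1) * W;
    // free ref prefix: alignment may start at any ref position
    H[row] = 0; pH[row] = 3; D[row] = NEG_INF; I[row] = NEG_INF;
    const char rc = ref[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int idx = row + j;
      // D: consume ref base i-1 with a gap in the read
      int d_open = H[prow + j] + gap_open + gap_ext;
      int d_ext = D[prow + j] + gap_ext;
      if (d_open >= d_ext) { D[idx] = d_open; pD[idx] = 0; }
      else { D[idx] = d_ext; pD[idx] = 1; }
      // I: consume read base j-1 with a gap in the ref
      int i_open = H[idx - 1] + gap_open + gap_ext;
      int i_ext = I[idx - 1] + gap_ext;
      if (i_open >= i_ext) { I[idx] = i_open; pI[idx] = 0; }
      else { I[idx] = i_ext; pI[idx] = 1; }
      // H: best of diagonal / D / I, priority diag > D > I on ties
      int diag = H[prow + j - 1] + ((rc == read[j - 1]) ? match : mismatch);
      int best = diag; unsigned char ptr = 0;
      if (D[idx] > best) { best = D[idx]; ptr = 1; }
      if (I[idx] > best) { best = I[idx]; ptr = 2; }
      H[idx] = best; pH[idx] = ptr;
    }
  }

  // free ref suffix: best score over the last read column; ties -> smallest i
  int best_i = 0, best = H[n];
  for (int i = 1; i <= m; ++i) {
    if (H[i * W + n] > best) { best = H[i * W + n]; best_i = i; }
  }

  Aln out;
  out.score = best;
  out.ref_end = best_i;

  // backtrace
  std::vector<Op> rops;
  int i = best_i, j = n;
  int state = 0;  // 0 = H, 1 = D, 2 = I
  while (j > 0 || (state != 0)) {
    const int idx = i * W + j;
    if (state == 0) {
      unsigned char p = pH[idx];
      if (p == 3) break;  // alignment start (free ref prefix)
      if (p == 0) {
        if (!rops.empty() && rops.back().type == 'M') {
          rops.back().len += 1; rops.back().ref_pos -= 1; rops.back().read_pos -= 1;
        } else {
          Op o; o.type = 'M'; o.ref_pos = i - 1; o.read_pos = j - 1; o.len = 1;
          rops.push_back(o);
        }
        --i; --j;
      } else {
        state = (p == 1) ? 1 : 2;
      }
    } else if (state == 1) {  // D: consume ref base
      if (!rops.empty() && rops.back().type == 'D') {
        rops.back().len += 1; rops.back().ref_pos -= 1;
      } else {
        Op o; o.type = 'D'; o.ref_pos = i - 1; o.read_pos = j; o.len = 1;
        rops.push_back(o);
      }
      unsigned char p = pD[idx];
      --i;
      if (p == 0) state = 0;
    } else {  // I: consume read base
      if (!rops.empty() && rops.back().type == 'I') {
        rops.back().len += 1; rops.back().read_pos -= 1;
      } else {
        Op o; o.type = 'I'; o.ref_pos = i; o.read_pos = j - 1; o.len = 1;
        rops.push_back(o);
      }
      unsigned char p = pI[idx];
      --j;
      if (p == 0) state = 0;
    }
  }
  out.ref_start = i;
  out.ops.assign(rops.rbegin(), rops.rend());

  left_normalize(ref, read, out.ops);

  // collect mismatches after normalization (pairings can move within runs)
  for (const Op& o : out.ops) {
    if (o.type != 'M') continue;
    for (int k = 0; k < o.len; ++k) {
      if (ref[o.ref_pos + k] != read[o.read_pos + k]) out.mism_ref.push_back(o.ref_pos + k);
    }
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cq_align_stats(CharacterVector reads, std::string ref,
                             int window_start, int window_end,
                             int match, int mismatch, int gap_open, int gap_ext) {
  const int n = reads.size();
  IntegerMatrix out(n, 6);
  colnames(out) = CharacterVector::create("score", "ref_start", "ref_end",
                                          "n_events", "net_indel", "n_subs");
  Workspace ws;
  for (int r = 0; r < n; ++r) {
    std::string read = as<std::string>(reads[r]);
    if (read.empty()) {
      out(r, 0) = NEG_INF; out(r, 1) = 0; out(r, 2) = 0;
      out(r, 3) = 0; out(r, 4) = 0; out(r, 5) = 0;
      continue;
    }
    Aln a = align_one(ref, read, match, mismatch, gap_open, gap_ext, ws);
    int events = 0, net = 0, subs = 0;
    for (const Op& o : a.ops) {
      if (o.type == 'D') {
        if (o.ref_pos < window_end && o.ref_pos + o.len > window_start) {
          events += 1; net -= o.len;
        }
      } else if (o.type == 'I') {
        if (o.ref_pos >= window_start && o.ref_pos <= window_end) {
          events += 1; net += o.len;
        }
      }
    }
    for (int p : a.mism_ref) if (p >= window_start && p < window_end) subs += 1;
    out(r, 0) = a.score; out(r, 1) = a.ref_start; out(r, 2) = a.ref_end;
    out(r, 3) = events; out(r, 4) = net; out(r, 5) = subs;
  }
  return out;
}

// [[Rcpp::export]]
List cq_align_detail(std::string read, std::string ref,
                     int match, int mismatch, int gap_open, int gap_ext) {
  Workspace ws;
  Aln a = align_one(ref, read, match, mismatch, gap_open, gap_ext, ws);
  const int k = (int)a.ops.size();
  CharacterVector type(k);
  IntegerVector ref_pos(k), len(k), read_pos(k);
  for (int i = 0; i < k; ++i) {
    type[i] = std::string(1, a.ops[i].type);
    ref_pos[i] = a.ops[i].ref_pos;
    len[i] = a.ops[i].len;
    read_pos[i] = a.ops[i].read_pos;
  }
  return List::create(
    _["score"] = a.score,
    _["ref_start"] = a.ref_start,
    _["ref_end"] = a.ref_end,
    _["ops"] = DataFrame::create(_["type"] = type, _["ref_pos"] = ref_pos,
                                 _["len"] = len, _["read_pos"] = read_pos,
                                 _["stringsAsFactors"] = false),
    _["mismatch_ref_pos"] = IntegerVector(a.mism_ref.begin(), a.mism_ref.end()));
}
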