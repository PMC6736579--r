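#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh) over IUPAC nucleotide codes.
// A column "matches" iff the IUPAC sets of the two codes intersect.
// A gap of length L costs gap_open + L * gap_extend (both negative).
//
// Determinism: among all maximal-scoring end cells the reported alignment is
// the one whose (query start, subject start, query end, subject end) tuple is
// lexicographically smallest; traceback prefers diagonal, then up (gap in
// subject), then left (gap in query), and gap states prefer closing the gap
// (returning to the match state) over extending it.

static const int NEG_INF = std::numeric_limits<int>::min() / 4;

static inline int iupac_mask(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': case 'U': case 'u': return 8;
    case 'R': case 'r': return 1 | 4;
    case 'Y': case 'y': return 2 | 8;
    case 'S': case 's': return 2 | 4;
    case 'W': case 'w': return 1 | 8;
    case 'K': case 'k': return 4 | 8;
    case 'M': case 'm': return 1 | 2;
    case 'B': case 'b': return 2 | 4 | 8;
    case 'D': case 'd': return 1 | 4 | 8;
    case 'H': case 'h': return 1 | 2 | 8;
    case 'V': case 'v': return 1 | 2 | 4;
    case 'N': case 'n': return 15;
    default:            return 0;  // never matches anything
  }
}

struct Trace {
  int qstart, sstart, qend, send;  // 0-based half-open on query/subject
  int ncol, nmatch;
  bool better_than(const Trace& o) const {
    if (qstart != o.qstart) return qstart < o.qstart;
    if (sstart != o.sstart) return sstart < o.sstart;
    if (qend   != o.qend)   return qend   < o.qend;
    return send < o.send;
  }
};

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string q, std::string s,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int m = (int) q.size(), n = (int) s.size();
  if (m == 0 || n == 0) stop("empty sequence");

  std::vector<int> qm(m), sm(n);
  for (int i = 0; i < m; ++i) qm[i] = iupac_mask(q[i]);
  for (int j = 0; j < n; ++j) sm[j] = iupac_mask(s[j]);

  const int W = n + 1;
  std::vector<int> H((m + 1) * W, 0), E((m + 1) * W, NEG_INF),
                   F((m + 1) * W, NEG_INF);
  const int go_ge = gap_open + gap_extend;

  int best = 0;
  for (int i = 1; i <= m; ++i) {
    const int qmi = qm[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int idx = i * W + j;
      const int e = std::max(H[idx - 1] + go_ge, E[idx - 1] + gap_extend);
      const int f = std::max(H[idx - W] + go_ge, F[idx - W] + gap_extend);
      const int sub = (qmi & sm[j - 1]) ? match : mismatch;
      int h = H[idx - W - 1] + sub;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      E[idx] = e; F[idx] = f; H[idx] = h;
      if (h > best) best = h;
    }
  }

  Trace bt; bool have = false;
  if (best > 0) {
    for (int ei = 1; ei <= m; ++ei) {
      for (int ej = 1; ej <= n; ++ej) {
        if (H[ei * W + ej] != best) continue;
        // traceback with fixed preference order
        int i = ei, j = ej, ncol = 0, nmatch = 0;
        char state = 'H';
        while (true) {
          const int idx = i * W + j;
          if (state == 'H') {
            if (H[idx] == 0) break;
            const int sub = (qm[i - 1] & sm[j - 1]) ? match : mismatch;
            if (H[idx] == H[idx - W - 1] + sub) {
              ++ncol; if (qm[i - 1] & sm[j - 1]) ++nmatch;
              --i; --j;
            } else if (H[idx] == F[idx]) {
              state = 'F';
            } else {
              state = 'E';
            }
          } else if (state == 'F') {  // gap in subject, consumes query
            ++ncol;
            state = (F[idx] == H[idx - W] + go_ge) ? 'H' : 'F';
            --i;
          } else {                    // 'E': gap in query, consumes subject
            ++ncol;
            state = (E[idx] == H[idx - 1] + go_ge) ? 'H' : 'E';
            --j;
          }
        }
        Trace t; t.qstart = i; t.sstart = j; t.qend = ei; t.send = ej;
        t.ncol = ncol; t.nmatch = nmatch;
        if (!have || t.better_than(bt)) { bt = t; have = true; }
      }
    }
  }

  if (!have) {  // no positive-scoring local alignment
    return List::create(_["score"] = 0,
                        _["identity"] = 0.0, _["query_coverage"] = 0.0,
                        _["qstart"] = 0, _["qend"] = 0,
                        _["sstart"] = 0, _["send"] = 0,
                        _["ncol"] = 0, _["nmatch"] = 0);
  }
  const double identity = 100.0 * bt.nmatch / bt.ncol;
  const double qcov = 100.0 * (bt.qend - bt.qstart) / m;
  return List::create(_["score"] = best,
                      _["identity"] = identity, _["query_coverage"] = qcov,
                      _["qstart"] = bt.qstart, _["qend"] = bt.qend,
                      _["sstart"] = bt.sstart, _["send"] = bt.send,
                      _["ncol"] = bt.ncol, _["nmatch"] = bt.nmatch);
}
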