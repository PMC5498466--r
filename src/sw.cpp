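#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps.
//
// Sequences arrive as 0-based integer indices into the substitution matrix.
// A gap of length k costs gap_open + k * gap_extend (BLAST convention, so
// the first gapped residue pays open + extend).
//
// Traceback starts at the highest-scoring cell (first by row, then by
// column on ties) and prefers diagonal over up (gap in b) over left
// (gap in a) at every step, matching the documented tie-break.
//
// Score-and-stats core without traceback detail, used by the batched
// search path: returns optimal score plus traceback-derived column stats.
static void sw_core(const int* a, int m, const int* b, int n,
                    const IntegerMatrix& sub, int gap_open, int gap_extend,
                    int* out /* score, aln_length, matches, q_aligned */) {
  const int NEG = INT_MIN / 4;
  const int go = gap_open + gap_extend, ge = gap_extend;
  std::vector<int> H((m + 1) * (n + 1), 0);
  std::vector<int> E((m + 1) * (n + 1), NEG);
  std::vector<int> F((m + 1) * (n + 1), NEG);
  auto idx = [n](int i, int j) { return i * (n + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int e = std::max(H[idx(i, j - 1)] - go, E[idx(i, j - 1)] - ge);
      const int f = std::max(H[idx(i - 1, j)] - go, F[idx(i - 1, j)] - ge);
      int h = H[idx(i - 1, j - 1)] + sub(a[i - 1], b[j - 1]);
      if (f > h) h = f;
      if (e > h) h = e;
      if (h < 0) h = 0;
      E[idx(i, j)] = e; F[idx(i, j)] = f; H[idx(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int i = bi, j = bj, state = 0, matches = 0, cols = 0, qa = 0;
  while ((i > 0 || j > 0) && best > 0) {
    if (state == 0) {
      const int h = H[idx(i, j)];
      if (h == 0) break;
      const int d = (i > 0 && j > 0)
        ? H[idx(i - 1, j - 1)] + sub(a[i - 1], b[j - 1]) : NEG;
      if (i > 0 && j > 0 && h == d) {
        if (a[i - 1] == b[j - 1]) ++matches;
        ++cols; ++qa; --i; --j;
      } else if (i > 0 && h == F[idx(i, j)]) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++cols; ++qa;
      const int f = F[idx(i, j)];
      const bool opn = (H[idx(i - 1, j)] - go == f);
      --i;
      state = opn ? 0 : 1;
    } else {
      ++cols;
      const int e = E[idx(i, j)];
      const bool opn = (H[idx(i, j - 1)] - go == e);
      --j;
      state = opn ? 0 : 2;
    }
  }
  out[0] = best; out[1] = cols; out[2] = matches; out[3] = qa;
}

// Batched all-vs-all alignment of queries against targets. Returns four
// (n_query x n_target) integer matrices of score, alignment length,
// matches and aligned query residues.
//
// [[Rcpp::export(name = ".sw_align_many_cpp")]]
List sw_align_many_cpp(List queries, List targets, IntegerMatrix sub,
                       int gap_open, int gap_extend) {
  const int nq = queries.size(), nt = targets.size();
  IntegerMatrix score(nq, nt), alen(nq, nt), match(nq, nt), qal(nq, nt);
  std::vector<std::vector<int>> qs(nq), ts(nt);
  for (int i = 0; i < nq; ++i)
    qs[i] = as<std::vector<int>>(queries[i]);
  for (int j = 0; j < nt; ++j)
    ts[j] = as<std::vector<int>>(targets[j]);
  int out[4];
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nt; ++j) {
      sw_core(qs[i].data(), (int)qs[i].size(), ts[j].data(),
              (int)ts[j].size(), sub, gap_open, gap_extend, out);
      score(i, j) = out[0]; alen(i, j) = out[1];
      match(i, j) = out[2]; qal(i, j) = out[3];
    }
  }
  return List::create(_["score"] = score, _["aln_length"] = alen,
                      _["matches"] = match, _["q_aligned"] = qal);
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                  int gap_open, int gap_extend) {
  const int m = a.size(), n = b.size();
  const int NEG = INT_MIN / 4;
  const int go = gap_open + gap_extend;  // cost of opening a length-1 gap
  const int ge = gap_extend;

  // (m+1) x (n+1) DP matrices, row-major.
  std::vector<int> H((m + 1) * (n + 1), 0);
  std::vector<int> E((m + 1) * (n + 1), NEG);  // gap in a (consumes b)
  std::vector<int> F((m + 1) * (n + 1), NEG);  // gap in b (consumes a)

  auto idx = [n](int i, int j) { return i * (n + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int e = std::max(H[idx(i, j - 1)] - go, E[idx(i, j - 1)] - ge);
      const int f = std::max(H[idx(i - 1, j)] - go, F[idx(i - 1, j)] - ge);
      const int d = H[idx(i - 1, j - 1)] + sub(a[i - 1], b[j - 1]);
      int h = d;
      if (f > h) h = f;
      if (e > h) h = e;
      if (h < 0) h = 0;
      E[idx(i, j)] = e;
      F[idx(i, j)] = f;
      H[idx(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // Traceback: state 0 = H, 1 = F (up), 2 = E (left).
  int i = bi, j = bj, state = 0;
  int matches = 0, cols = 0, qa = 0, ta = 0;
  int qend = bi, tend = bj, qstart = bi, tstart = bj;
  while (i > 0 || j > 0) {
    if (state == 0) {
      const int h = H[idx(i, j)];
      if (h == 0) break;
      const int d = (i > 0 && j > 0)
        ? H[idx(i - 1, j - 1)] + sub(a[i - 1], b[j - 1]) : NEG;
      if (i > 0 && j > 0 && h == d) {
        if (a[i - 1] == b[j - 1]) ++matches;
        ++cols; ++qa; ++ta;
        qstart = i; tstart = j;
        --i; --j;
      } else if (i > 0 && h == F[idx(i, j)]) {
        state = 1;
      } else if (j > 0 && h == E[idx(i, j)]) {
        state = 2;
      } else {
        stop("traceback failure (H)");  // unreachable
      }
    } else if (state == 1) {
      // consuming a, gap in b
      ++cols; ++qa;
      qstart = i;
      const int f = F[idx(i, j)];
      const bool ext = (F[idx(i - 1, j)] - ge == f);
      const bool opn = (H[idx(i - 1, j)] - go == f);
      --i;
      if (opn) state = 0; else if (ext) state = 1;
      else stop("traceback failure (F)");
    } else {
      ++cols; ++ta;
      tstart = j;
      const int e = E[idx(i, j)];
      const bool ext = (E[idx(i, j - 1)] - ge == e);
      const bool opn = (H[idx(i, j - 1)] - go == e);
      --j;
      if (opn) state = 0; else if (ext) state = 2;
      else stop("traceback failure (E)");
    }
  }

  return List::create(
    _["score"] = best,
    _["aln_length"] = cols,
    _["matches"] = matches,
    _["qstart"] = (best > 0) ? qstart : NA_INTEGER,
    _["qend"] = (best > 0) ? qend : NA_INTEGER,
    _["tstart"] = (best > 0) ? tstart : NA_INTEGER,
    _["tend"] = (best > 0) ? tend : NA_INTEGER,
    _["q_aligned"] = qa,
    _["t_aligned"] = ta);
}
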