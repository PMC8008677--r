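#include <Rcpp.h>
using namespace Rcpp;

// Ungapped local alignment of a position-specific score matrix against every
// protein in a concatenated residue stream (Smith-Waterman restricted to a
// single diagonal band of width 0, i.e. no indels).
//
// prof:    W x A matrix of per-column residue scores (log-odds).
// aa:      residue codes, 1-based into the columns of `prof`; 0 marks an
//          unknown residue, -1 a separator between proteins. Segments never
//          cross codes <= 0.
// prot_id: 1-based protein index per stream position (constant between
//          separators).
// min_cols: minimum number of aligned profile columns for a segment to be
//          reported (domain-scale hits only).
//
// Returns, per protein, the best segment score and its 0-based start/end
// (inclusive) positions in the stream (NA when no qualifying segment).
// [[Rcpp::export]]
List cpp_profile_scan(NumericMatrix prof, IntegerVector aa,
                      IntegerVector prot_id, int n_prot, int min_cols) {
  const int W = prof.nrow();
  const int L = aa.size();
  NumericVector best(n_prot, R_NegInf);
  IntegerVector bstart(n_prot, NA_INTEGER), bend(n_prot, NA_INTEGER);

  // walk every diagonal: profile column j aligned to stream position j + d.
  // Along a diagonal, segment score = prefix[t] - prefix[s]; the best
  // segment of length >= min_cols ending at t uses the running minimum of
  // prefixes lagged by min_cols. Separators and unknown residues reset the
  // run (segments are contiguous in both profile and protein).
  std::vector<double> pref(W + 1);
  std::vector<int> pref_pos(W + 1);
  for (int d = -(W - 1); d <= L - 1; ++d) {
    int j0 = std::max(0, -d);
    int j1 = std::min(W, L - d);  // exclusive
    if (j1 - j0 < min_cols) continue;
    int t = 0;                    // steps in current run
    double minq = 0.0; int minq_pos = 0; int q_filled = 0;
    pref[0] = 0.0; pref_pos[0] = j0;
    for (int j = j0; j < j1; ++j) {
      int p = j + d;
      int a = aa[p];
      if (a <= 0) {               // reset the run
        t = 0; q_filled = 0;
        pref[0] = 0.0; pref_pos[0] = j + 1;
        continue;
      }
      pref[t + 1] = pref[t] + prof(j, a - 1);
      pref_pos[t + 1] = j + 1;
      ++t;
      // admit prefix index t - min_cols into the running minimum
      if (t >= min_cols) {
        int qi = t - min_cols;
        if (q_filled == 0 || pref[qi] < minq) {
          minq = pref[qi]; minq_pos = pref_pos[qi];
        }
        ++q_filled;
        double sc = pref[t] - minq;
        int g = prot_id[p] - 1;
        if (sc > best[g]) {
          best[g] = sc;
          bstart[g] = minq_pos + d;  // stream position of segment start
          bend[g] = p;
        }
      }
    }
  }
  return List::create(_["score"] = best, _["start"] = bstart,
                      _["end"] = bend);
}

// Ungapped repeat search between two integer-coded nucleotide sequences.
// For every alignment lag of `a` along `b`, runs a Kadane scan with score
// +1 per match and -`penalty` per mismatch (the blastn-like +1/-2 default
// sustains extension through segments above ~67% identity) and reports, per
// lag, the best-scoring segment of length >= min_len that also meets
// `min_id` identity. Code 0 (N or other ambiguity) never matches.
//
// When self = true, a and b are the same sequence: only strictly positive
// lags are scanned (each repeat pair is seen once).
//
// Returns a data frame of qualifying segments with 0-based starts.
// [[Rcpp::export]]
DataFrame cpp_lag_segments(IntegerVector a, IntegerVector b,
                           double min_id, int min_len, bool self,
                           double penalty = 2.0) {
  const int la = a.size(), lb = b.size();
  const double pen = penalty;
  std::vector<int> out_as, out_bs, out_len, out_match;

  int d_lo = self ? 1 : -(la - 1);
  for (int d = d_lo; d <= lb - 1; ++d) {
    int i0 = std::max(0, -d);
    int i1 = std::min(la, lb - d);  // exclusive
    if (i1 - i0 < min_len) continue;
    double run = 0.0; int run_start = i0, run_m = 0;
    double best = 0.0; int bs = -1, blen = 0, bm = 0;
    for (int i = i0; i < i1; ++i) {
      int ca = a[i], cb = b[i + d];
      double s = (ca > 0 && ca == cb) ? 1.0 : -pen;
      if (run <= 0) { run = s; run_start = i; run_m = (s > 0); }
      else { run += s; run_m += (s > 0); }
      int len = i - run_start + 1;
      if (len >= min_len && run > best) {
        best = run; bs = run_start; blen = len; bm = run_m;
      }
    }
    if (bs >= 0 && bm >= min_id * blen) {
      out_as.push_back(bs);
      out_bs.push_back(bs + d);
      out_len.push_back(blen);
      out_match.push_back(bm);
    }
  }
  return DataFrame::create(_["a_start"] = out_as, _["b_start"] = out_bs,
                           _["length"] = out_len, _["matches"] = out_match);
}

// Match counts for the full placement of a short query at every lag of a
// subject (used by brute-force comparisons at small scale and by the spacer
// extension step). Code 0 never matches.
// [[Rcpp::export]]
IntegerVector cpp_match_by_lag(IntegerVector a, IntegerVector b) {
  const int la = a.size(), lb = b.size();
  int nlag = lb - la + 1;
  if (nlag < 1) return IntegerVector(0);
  IntegerVector out(nlag);
  for (int d = 0; d < nlag; ++d) {
    int m = 0;
    for (int i = 0; i < la; ++i)
      if (a[i] > 0 && a[i] == b[i + d]) ++m;
    out[d] = m;
  }
  return out;
}

// Longest exact terminal direct repeat: the largest r in
// [min_len, max_scan] with prefix(r) == suffix(r). Early exit on first
// mismatch keeps the expected cost near linear. Code 0 (N) never matches.
// Returns 0 when no repeat qualifies.
// [[Rcpp::export]]
int cpp_terminal_repeat(IntegerVector v, int min_len, int max_scan) {
  const int L = v.size();
  int hi = std::min(max_scan, L / 2);
  for (int r = hi; r >= min_len; --r) {
    bool ok = true;
    const int off = L - r;
    for (int i = 0; i < r; ++i) {
      if (v[i] <= 0 || v[i] != v[off + i]) { ok = false; break; }
    }
    if (ok) return r;
  }
  return 0;
}
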