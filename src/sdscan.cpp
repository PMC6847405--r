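#include <Rcpp.h>
using namespace Rcpp;

// Watson-Crick pairing on RNA characters (A,C,G,U).
static inline bool wc(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G');
}

static inline bool pair_ok(char a, char b, bool wobble) {
  if (wc(a, b)) return true;
  return wobble && ((a == 'G' && b == 'U') || (a == 'U' && b == 'G'));
}

// Enumerate all maximal contiguous antiparallel duplexes between an upstream
// window w (5'->3') and the anti-SD tail t (5'->3'). A duplex lies on an
// anti-diagonal of the pairing matrix: window index i pairs tail index s - i,
// so extending the duplex 3' along the window walks 5' along the tail.
// Maximality is automatic: runs are flushed only when pairing breaks or the
// diagonal ends. Rows: i0, i1 (1-based window), t_lo, t_hi (1-based tail).
// [[Rcpp::export]]
IntegerMatrix scan_pair_cpp(std::string w, std::string t, int min_len, bool wobble) {
  const int W = (int) w.size(), L = (int) t.size();
  std::vector<int> out;
  for (int s = 0; s <= W + L - 2; ++s) {
    const int i_lo = std::max(0, s - L + 1), i_hi = std::min(W - 1, s);
    int run = 0;
    for (int i = i_lo; i <= i_hi + 1; ++i) {
      const bool ok = (i <= i_hi) && pair_ok(w[i], t[s - i], wobble);
      if (ok) {
        ++run;
      } else {
        if (run >= min_len) {
          const int i1 = i - 1, i0 = i - run;
          out.push_back(i0 + 1);
          out.push_back(i1 + 1);
          out.push_back(s - i1 + 1);
          out.push_back(s - i0 + 1);
        }
        run = 0;
      }
    }
  }
  const int n = (int) out.size() / 4;
  IntegerMatrix m(n, 4);
  for (int r = 0; r < n; ++r)
    for (int c = 0; c < 4; ++c) m(r, c) = out[4 * r + c];
  return m;
}

// Accumulate tail-site coverage of every maximal duplex into O (length L).
static void scan_accum(const std::string& w, const std::string& t, int min_len,
                       bool wobble, std::vector<int>& O) {
  const int W = (int) w.size(), L = (int) t.size();
  for (int s = 0; s <= W + L - 2; ++s) {
    const int i_lo = std::max(0, s - L + 1), i_hi = std::min(W - 1, s);
    int run = 0;
    for (int i = i_lo; i <= i_hi + 1; ++i) {
      const bool ok = (i <= i_hi) && pair_ok(w[i], t[s - i], wobble);
      if (ok) {
        ++run;
      } else {
        if (run >= min_len) {
          const int i1 = i - 1, i0 = i - run;
          for (int j = s - i1; j <= s - i0; ++j) O[j] += 1;
        }
        run = 0;
      }
    }
  }
}

// Observed site-specific anti-SD usage over a set of windows.
// [[Rcpp::export]]
IntegerVector site_counts_cpp(CharacterVector windows, std::string t,
                              int min_len, bool wobble) {
  const int L = (int) t.size();
  std::vector<int> O(L, 0);
  for (int k = 0; k < windows.size(); ++k) {
    const std::string w = as<std::string>(windows[k]);
    scan_accum(w, t, min_len, wobble, O);
  }
  return wrap(O);
}

// Expected site usage under per-window mononucleotide shuffling: each
// replicate permutes every window (composition preserved, R RNG), rescans,
// and accumulates. Returns the per-site mean count across replicates.
// [[Rcpp::export]]
NumericVector shuffle_counts_cpp(CharacterVector windows, std::string t,
                                 int min_len, bool wobble, int n_shuffles) {
  const int L = (int) t.size(), nw = (int) windows.size();
  std::vector<std::string> ws(nw);
  for (int i = 0; i < nw; ++i) ws[i] = as<std::string>(windows[i]);
  std::vector<double> tot(L, 0.0);
  std::vector<int> O(L);
  for (int r = 0; r < n_shuffles; ++r) {
    std::fill(O.begin(), O.end(), 0);
    for (int i = 0; i < nw; ++i) {
      std::string s = ws[i];
      for (int k = (int) s.size() - 1; k > 0; --k) {
        int j = (int) (unif_rand() * (k + 1));
        if (j > k) j = k;
        std::swap(s[k], s[j]);
      }
      scan_accum(s, t, min_len, wobble, O);
    }
    for (int j = 0; j < L; ++j) tot[j] += O[j];
  }
  NumericVector E(L);
  for (int j = 0; j < L; ++j) E[j] = tot[j] / n_shuffles;
  return E;
}

static inline char dna_comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'T': return 'A';
    case 'U': return 'A';
    case 'G': return 'C';
    case 'C': return 'G';
    default:  return 'N';
  }
}

struct Hit {
  int matchcols = -1;
  int len = 0;
  int end3 = 0;   // 1-based query position of the oriented read's 3' terminus
  bool ok = false;
};

// Best ungapped local alignment of read r against query q over all diagonals.
// Within a diagonal the best segment is found by a 1-D maximal-scoring
// subsegment scan (match +1, mismatch -19, so any optimal segment has
// identity >= 0.95); a hit qualifies when the segment spans >= min_match
// columns at >= min_ident identity. The read 3' end is extrapolated along the
// (ungapped) diagonal even when the alignment stops short of the read end.
static Hit best_hit(const std::string& r, const std::string& q,
                    int min_match, double min_ident) {
  const int rl = (int) r.size(), ql = (int) q.size();
  Hit best;
  for (int d = -(rl - 1); d <= ql - 1; ++d) {
    const int r0 = std::max(0, -d), r1 = std::min(rl - 1, ql - 1 - d);
    if (r1 - r0 + 1 < min_match) continue;
    int cur = 0, curStart = r0, bestScore = 0, bs = -1, be = -1;
    for (int i = r0; i <= r1; ++i) {
      const int sc = (r[i] == q[i + d] && r[i] != 'N') ? 1 : -19;
      if (cur <= 0) { cur = sc; curStart = i; } else { cur += sc; }
      if (cur > bestScore) { bestScore = cur; bs = curStart; be = i; }
    }
    if (bs < 0) continue;
    const int len = be - bs + 1;
    if (len < min_match) continue;
    int m = 0;
    for (int i = bs; i <= be; ++i)
      if (r[i] == q[i + d]) ++m;
    if ((double) m / len < min_ident) continue;
    if (m > best.matchcols) {
      best.matchcols = m;
      best.len = len;
      best.end3 = rl + d;  // read index rl-1 -> query index rl-1+d (0-based)
      best.ok = true;
    }
  }
  return best;
}

// Map reads (DNA, uppercase) to the query in both orientations; best hit
// only. Columns: mapped (0/1), end3 in transcript orientation (0 when the
// extrapolated end falls off the query), matching columns.
// [[Rcpp::export]]
IntegerMatrix map_reads_cpp(CharacterVector reads, std::string query,
                            int min_match, double min_ident) {
  const int n = (int) reads.size();
  IntegerMatrix res(n, 3);
  for (int i = 0; i < n; ++i) {
    const std::string r = as<std::string>(reads[i]);
    Hit f = best_hit(r, query, min_match, min_ident);
    std::string rc(r.rbegin(), r.rend());
    for (size_t k = 0; k < rc.size(); ++k) rc[k] = dna_comp(rc[k]);
    Hit g = best_hit(rc, query, min_match, min_ident);
    // A reverse-stored read's biological 3' terminus is the last base of its
    // reverse complement, so both orientations share the end3 convention.
    Hit b = (f.ok && (!g.ok || f.matchcols >= g.matchcols)) ? f : g;
    if (!b.ok) continue;
    res(i, 0) = 1;
    res(i, 2) = b.matchcols;
    if (b.end3 >= 1 && b.end3 <= (int) query.size()) res(i, 1) = b.end3;
  }
  return res;
}
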