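#include <Rcpp.h>
#include <vector>
#include <string>
#include <cctype>

using namespace Rcpp;

static inline char to_rna(char c) {
  c = std::toupper(static_cast<unsigned char>(c));
  return c == 'T' ? 'U' : c;
}

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Base-pair maximisation (Nussinov) with a minimum hairpin loop.
// Deterministic traceback: leave position i unpaired when that already
// attains the optimum, otherwise pair it with the smallest admissible k.
// [[Rcpp::export(name = ".nussinov_fold_cpp")]]
List nussinov_fold_cpp(std::string seq, int min_loop = 3) {
  const int n = static_cast<int>(seq.size());
  std::string s(n, 'N');
  for (int i = 0; i < n; ++i) s[i] = to_rna(seq[i]);
  if (n == 0)
    return List::create(_["structure"] = "", _["pairs"] = 0);

  std::vector<short> M(static_cast<size_t>(n) * n, 0);
  auto at = [&](int i, int j) -> short& { return M[static_cast<size_t>(i) * n + j]; };

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      short best = at(i + 1, j);
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(s[i], s[k])) continue;
        short v = 1;
        if (k - 1 > i + 1) v += at(i + 1, k - 1);
        else if (k - 1 >= i + 1) v += at(i + 1, k - 1);
        if (k + 1 <= j) v += at(k + 1, j);
        if (v > best) best = v;
      }
      at(i, j) = best;
    }
  }

  std::string db(n, '.');
  int pairs = 0;
  std::vector<std::pair<int, int>> stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    if (at(i, j) == at(i + 1, j)) {
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can_pair(s[i], s[k])) continue;
      short v = 1;
      if (k - 1 >= i + 1) v += at(i + 1, k - 1);
      if (k + 1 <= j) v += at(k + 1, j);
      if (v == at(i, j)) {
        db[i] = '(';
        db[k] = ')';
        ++pairs;
        stack.push_back(std::make_pair(i + 1, k - 1));
        stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }

  return List::create(_["structure"] = db, _["pairs"] = pairs);
}

// ---------------------------------------------------------------------------
// Plant miRNA target scanning (Allen/CleaveLand-style penalties).
// miRNA position 1 is its 5' end and pairs the 3'-most base of the
// transcript window. Penalties: mismatch/gap 1, G:U 0.5, doubled inside
// the core region (miRNA positions core_start..core_end). At most one
// single-nucleotide bulge (on either strand) per alignment.
// ---------------------------------------------------------------------------

static inline int pair_state(char m, char t) {
  // m = miRNA base, t = target (transcript) base, both DNA uppercase.
  // 0 = Watson-Crick, 1 = G:U wobble, 2 = mismatch.
  if ((m == 'A' && t == 'T') || (m == 'T' && t == 'A') ||
      (m == 'G' && t == 'C') || (m == 'C' && t == 'G')) return 0;
  if ((m == 'G' && t == 'T') || (m == 'T' && t == 'G')) return 1;
  return 2;
}

// [[Rcpp::export(name = ".target_scan_cpp")]]
DataFrame target_scan_cpp(std::string mirna, std::string transcript,
                          double max_score, double mismatch_penalty,
                          double gu_penalty, double gap_penalty,
                          int core_start, int core_end, int max_gap) {
  const int L = static_cast<int>(mirna.size());
  const int N = static_cast<int>(transcript.size());
  std::vector<double> w(L + 1, 1.0);
  for (int p = 1; p <= L; ++p)
    if (p >= core_start && p <= core_end) w[p] = 2.0;

  std::vector<int> starts, ends, sites, nmm, ngu, ngap;
  std::vector<double> scores;
  std::vector<std::string> state_strings;

  // config: 0 ungapped; 1 transcript bulge before miRNA pos g; 2 miRNA pos g
  // unpaired. For each window start keep the best-scoring configuration.
  for (int s = 1; s + L - 1 <= N; ++s) {
    double best = R_PosInf;
    std::string best_states;
    int best_end = 0, best_site = 0, best_mm = 0, best_gu = 0, best_gap = 0;

    for (int conf = 0; conf <= (max_gap > 0 ? 2 : 0); ++conf) {
      int g_lo = (conf == 0) ? 0 : 2;
      int g_hi = (conf == 0) ? 0 : L - 1;
      for (int g = g_lo; g <= g_hi; ++g) {
        int wlen = L + (conf == 1 ? 1 : 0) - (conf == 2 ? 1 : 0);
        int e = s + wlen - 1;
        if (e > N) continue;
        double sc = (conf == 0) ? 0.0 : gap_penalty * w[g];
        int mm = 0, gu = 0, gp = (conf == 0) ? 0 : 1;
        std::string states(L, 'M');
        if (conf == 2) states[g - 1] = '-';
        bool ok = true;
        for (int p = 1; p <= L && ok; ++p) {
          if (conf == 2 && p == g) continue; // bulged miRNA base, unpaired
          int t;
          if (conf == 0) t = e - (p - 1);
          else if (conf == 1) t = e - (p - 1) - (p >= g ? 1 : 0);
          else t = e - (p - 1) + (p > g ? 1 : 0);
          if (t < 1 || t > N) { ok = false; break; }
          int st = pair_state(mirna[p - 1], transcript[t - 1]);
          if (st == 1) { sc += gu_penalty * w[p]; ++gu; states[p - 1] = 'G'; }
          else if (st == 2) { sc += mismatch_penalty * w[p]; ++mm; states[p - 1] = 'X'; }
          if (sc > max_score + 1e-9) ok = false;
        }
        if (!ok || sc > max_score + 1e-9) continue;
        if (sc < best - 1e-9) {
          best = sc;
          best_end = e;
          // transcript position paired with miRNA position 10
          int p10 = 10 > L ? L : 10;
          int t10;
          if (conf == 0) t10 = e - (p10 - 1);
          else if (conf == 1) t10 = e - (p10 - 1) - (p10 >= g ? 1 : 0);
          else t10 = e - (p10 - 1) + (p10 > g ? 1 : 0);
          best_site = t10;
          best_mm = mm; best_gu = gu; best_gap = gp;
          best_states = states;
        }
      }
    }
    if (R_finite(best)) {
      starts.push_back(s);
      ends.push_back(best_end);
      scores.push_back(best);
      sites.push_back(best_site);
      nmm.push_back(best_mm);
      ngu.push_back(best_gu);
      ngap.push_back(best_gap);
      state_strings.push_back(best_states);
    }
  }

  return DataFrame::create(
      _["start"] = starts, _["end"] = ends, _["score"] = scores,
      _["site"] = sites, _["mismatches"] = nmm, _["gu_pairs"] = ngu,
      _["gaps"] = ngap, _["states"] = state_strings,
      _["stringsAsFactors"] = false);
}
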