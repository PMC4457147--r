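// Bundled RNA folding backend: maximum base-pairing dynamic programme with
// stacking-weighted scores.  Pair weights (kcal/mol): GC -2.0, AU -1.1,
// GU -0.6; each pair directly stacked on another contributes an extra -1.0.
// Minimum hairpin loop length is 3 unpaired bases.  This is a Nussinov-style
// recursion, not a full nearest-neighbour model; weights are calibrated so
// that genuine inverted repeats (arms >= ~20 nt, >= 80% complementarity)
// fold well below -20 kcal/mol while short or sparse complementarity does
// not.  DNA input is treated as its RNA transcript (T == U).

#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

static const double NOPAIR = 1e9;
static const double STACK_BONUS = -1.0;
static const int MIN_LOOP = 3;

static inline double pair_energy(char a, char b) {
  if (a == 'U') a = 'T';
  if (b == 'U') b = 'T';
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -2.0;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return -1.1;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return -0.6;
  return NOPAIR;
}

// [[Rcpp::export(name = ".fold_stack_cpp")]]
List fold_stack_cpp(std::string seq) {
  int n = seq.size();
  IntegerVector partner(n, 0);
  if (n < MIN_LOOP + 2) {
    return List::create(_["mfe"] = 0.0,
                        _["structure"] = std::string(n, '.'),
                        _["partner"] = partner);
  }
  for (int i = 0; i < n; ++i) seq[i] = toupper(seq[i]);

  // M[i][j]: best (most negative) energy of subsequence i..j
  // P[i][j]: best energy given that i pairs with j (NOPAIR if impossible)
  std::vector<std::vector<double> > M(n, std::vector<double>(n, 0.0));
  std::vector<std::vector<double> > P(n, std::vector<double>(n, NOPAIR));

  for (int len = MIN_LOOP + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double e = pair_energy(seq[i], seq[j]);
      if (e < NOPAIR / 2) {
        double inner = (j - 1 >= i + 1) ? M[i + 1][j - 1] : 0.0;
        double best = e + inner;
        if (P[i + 1][j - 1] < NOPAIR / 2) {
          double stacked = e + P[i + 1][j - 1] + STACK_BONUS;
          if (stacked < best) best = stacked;
        }
        P[i][j] = best;
      }
      double best = M[i][j - 1];               // j unpaired
      for (int k = i; k <= j - MIN_LOOP - 1; ++k) {
        if (P[k][j] < NOPAIR / 2) {
          double left = (k > i) ? M[i][k - 1] : 0.0;
          double cand = left + P[k][j];
          if (cand < best) best = cand;
        }
      }
      M[i][j] = best;
    }
  }

  // traceback
  const double EPS = 1e-7;
  std::stack<std::pair<std::pair<int, int>, bool> > todo; // ((i,j), inP)
  todo.push(std::make_pair(std::make_pair(0, n - 1), false));
  while (!todo.empty()) {
    std::pair<std::pair<int, int>, bool> top = todo.top();
    todo.pop();
    int i = top.first.first, j = top.first.second;
    bool inP = top.second;
    if (j - i < MIN_LOOP + 1) continue;
    if (inP) {
      partner[i] = j + 1;
      partner[j] = i + 1;
      double e = pair_energy(seq[i], seq[j]);
      if (P[i + 1][j - 1] < NOPAIR / 2 &&
          std::abs(P[i][j] - (e + P[i + 1][j - 1] + STACK_BONUS)) < EPS) {
        todo.push(std::make_pair(std::make_pair(i + 1, j - 1), true));
      } else if (j - 1 >= i + 1) {
        todo.push(std::make_pair(std::make_pair(i + 1, j - 1), false));
      }
      continue;
    }
    if (std::abs(M[i][j] - M[i][j - 1]) < EPS) {
      todo.push(std::make_pair(std::make_pair(i, j - 1), false));
      continue;
    }
    bool placed = false;
    for (int k = i; k <= j - MIN_LOOP - 1 && !placed; ++k) {
      if (P[k][j] >= NOPAIR / 2) continue;
      double left = (k > i) ? M[i][k - 1] : 0.0;
      if (std::abs(M[i][j] - (left + P[k][j])) < EPS) {
        if (k > i) todo.push(std::make_pair(std::make_pair(i, k - 1), false));
        todo.push(std::make_pair(std::make_pair(k, j), true));
        placed = true;
      }
    }
    if (!placed) {
      // numerical safety net; fall back to "j unpaired"
      todo.push(std::make_pair(std::make_pair(i, j - 1), false));
    }
  }

  std::string db(n, '.');
  for (int i = 0; i < n; ++i) {
    if (partner[i] > i + 1) db[i] = '(';
    else if (partner[i] > 0 && partner[i] < i + 1) db[i] = ')';
  }
  double mfe = M[0][n - 1];
  if (mfe > 0) mfe = 0.0;
  return List::create(_["mfe"] = mfe,
                      _["structure"] = db,
                      _["partner"] = partner);
}
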