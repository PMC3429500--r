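#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Nested-structure (pseudoknot-free) minimum-energy folding under a compact
// stacking model:
//   * a base pair contributes its stack energy only when the pair immediately
//     inside it (i+1, j-1) is also paired: G-C/C-G -3.0, A-U/U-A -2.0,
//     G-U/U-G -1.0 kcal/mol;
//   * each hairpin loop closure costs +3.0 kcal/mol;
//   * hairpin loops span at least 3 unpaired bases;
//   * interior loops, bulges and multiloops carry no explicit penalty.
// The empty structure (energy 0) is always admissible, so the reported MFE is
// never positive.

static const double INF = std::numeric_limits<double>::infinity();
static const double HAIRPIN_PENALTY = 3.0;
static const int MIN_LOOP = 3;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1;
  }
}

// stack energy by the identity of the outer pair; NA (INF) if unpairable
static inline double pair_energy(int a, int b) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return -3.0; // G-C
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return -2.0; // A-U
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return -1.0; // G-U
  return INF;
}

struct TraceItem {
  int state; // 0 = Wp, 1 = C, 2 = Wx
  int i, j;
};

// [[Rcpp::export(name = ".fold_engine")]]
List fold_engine(std::string seq) {
  const int n = (int) seq.size();
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) {
    code[i] = base_code(seq[i]);
    if (code[i] < 0) stop("invalid base '%s' at position %d", std::string(1, seq[i]), i + 1);
  }

  // flat n x n matrices
  std::vector<double> C((size_t) n * n, INF), Wp((size_t) n * n, INF), Wx((size_t) n * n, INF);
  #define IDX(i, j) ((size_t) (i) * n + (j))

  for (int span = MIN_LOOP + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      const int j = i + span;
      // Wx(i,j): >=1 pair, i and j not mutually paired
      double wx = INF;
      if (Wp[IDX(i + 1, j)] < wx) wx = Wp[IDX(i + 1, j)];
      if (Wp[IDX(i, j - 1)] < wx) wx = Wp[IDX(i, j - 1)];
      for (int k = i; k < j; ++k) {
        if (Wp[IDX(i, k)] < INF && Wp[IDX(k + 1, j)] < INF) {
          double v = Wp[IDX(i, k)] + Wp[IDX(k + 1, j)];
          if (v < wx) wx = v;
        }
      }
      Wx[IDX(i, j)] = wx;

      // C(i,j): closed by pair (i,j)
      double pe = pair_energy(code[i], code[j]);
      if (pe < INF && j - i - 1 >= MIN_LOOP) {
        double best = HAIRPIN_PENALTY; // hairpin closure
        if (C[IDX(i + 1, j - 1)] < INF) {
          double v = pe + C[IDX(i + 1, j - 1)]; // stacked on inner pair
          if (v < best) best = v;
        }
        if (Wx[IDX(i + 1, j - 1)] < INF) {
          double v = Wx[IDX(i + 1, j - 1)]; // inner structure, no stacking bonus
          if (v < best) best = v;
        }
        C[IDX(i, j)] = best;
      }

      // Wp(i,j): best structure with >=1 pair
      double wp = wx;
      if (C[IDX(i, j)] < wp) wp = C[IDX(i, j)];
      Wp[IDX(i, j)] = wp;
    }
  }

  double mfe = 0.0;
  std::vector<int> partner(n, 0); // 1-based partner, 0 = unpaired
  const double EPS = 1e-9;

  if (n > MIN_LOOP + 1 && Wp[IDX(0, n - 1)] < -EPS) {
    mfe = Wp[IDX(0, n - 1)];
    std::vector<TraceItem> stack;
    stack.push_back({0, 0, n - 1});
    while (!stack.empty()) {
      TraceItem it = stack.back();
      stack.pop_back();
      int i = it.i, j = it.j;
      if (j - i < MIN_LOOP + 1) continue;
      if (it.state == 0) { // Wp
        double target = Wp[IDX(i, j)];
        if (std::fabs(C[IDX(i, j)] - target) < EPS) {
          stack.push_back({1, i, j});
        } else {
          stack.push_back({2, i, j});
        }
      } else if (it.state == 2) { // Wx
        double target = Wx[IDX(i, j)];
        if (std::fabs(Wp[IDX(i + 1, j)] - target) < EPS) {
          stack.push_back({0, i + 1, j});
        } else if (std::fabs(Wp[IDX(i, j - 1)] - target) < EPS) {
          stack.push_back({0, i, j - 1});
        } else {
          bool found = false;
          for (int k = i; k < j && !found; ++k) {
            if (Wp[IDX(i, k)] < INF && Wp[IDX(k + 1, j)] < INF &&
                std::fabs(Wp[IDX(i, k)] + Wp[IDX(k + 1, j)] - target) < EPS) {
              stack.push_back({0, i, k});
              stack.push_back({0, k + 1, j});
              found = true;
            }
          }
          if (!found) stop("traceback failure (Wx) at %d,%d", i + 1, j + 1);
        }
      } else { // C: (i,j) paired
        partner[i] = j + 1;
        partner[j] = i + 1;
        double target = C[IDX(i, j)];
        double pe = pair_energy(code[i], code[j]);
        if (std::fabs(target - HAIRPIN_PENALTY) < EPS &&
            !(C[IDX(i + 1, j - 1)] < INF &&
              std::fabs(pe + C[IDX(i + 1, j - 1)] - target) < EPS)) {
          continue; // hairpin loop, nothing inside
        }
        if (C[IDX(i + 1, j - 1)] < INF &&
            std::fabs(pe + C[IDX(i + 1, j - 1)] - target) < EPS) {
          stack.push_back({1, i + 1, j - 1});
        } else if (Wx[IDX(i + 1, j - 1)] < INF &&
                   std::fabs(Wx[IDX(i + 1, j - 1)] - target) < EPS) {
          stack.push_back({2, i + 1, j - 1});
        } else if (std::fabs(target - HAIRPIN_PENALTY) < EPS) {
          continue;
        } else {
          stop("traceback failure (C) at %d,%d", i + 1, j + 1);
        }
      }
    }
  }

  std::string db(n, '.');
  int npairs = 0;
  for (int i = 0; i < n; ++i) {
    if (partner[i] > i + 1) { db[i] = '('; ++npairs; }
    else if (partner[i] > 0 && partner[i] < i + 1) db[i] = ')';
  }
  IntegerMatrix pairs(npairs, 2);
  int r = 0;
  for (int i = 0; i < n; ++i) {
    if (partner[i] > i + 1) {
      pairs(r, 0) = i + 1;
      pairs(r, 1) = partner[i];
      ++r;
    }
  }

  return List::create(_["structure"] = db, _["mfe"] = mfe, _["pairs"] = pairs,
                      _["partner"] = IntegerVector(partner.begin(), partner.end()));
}
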