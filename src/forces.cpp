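#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fruchterman-Reingold force pass in 3D.
//
// Repulsion k^2/d between node pairs; attraction d^2/k along each edge;
// per-node displacement is the force sum capped at `temp`.
//
// cutoff <= 0: exact all-pairs repulsion (symmetric pair loop; evaluation
// count = number of pairs). cutoff > 0: uniform spatial grid with cell size
// = cutoff; each node evaluates one-sided repulsion against candidates in
// its 27 surrounding cells, nearest cells first, stopping after
// `maxPartners` in-range partners. This bounds per-iteration repulsion
// evaluations by maxPartners * n regardless of local density.
//
// Exactly coincident pairs (d ~ 0) are separated by a tiny deterministic
// index-derived offset before the force law is applied.

static inline void separation(const NumericMatrix& pos, int i, int j,
                              double* d3, double& dist) {
  for (int c = 0; c < 3; ++c) d3[c] = pos(i, c) - pos(j, c);
  double d2 = d3[0] * d3[0] + d3[1] * d3[1] + d3[2] * d3[2];
  if (d2 < 1e-24) {
    // deterministic pseudo-direction from the index pair
    d3[0] = 1e-9 * ((i % 7) - (j % 7) + 0.5);
    d3[1] = 1e-9 * ((i % 5) - (j % 5) + 0.25);
    d3[2] = 1e-9 * ((i % 3) - (j % 3) + 0.125);
    d2 = d3[0] * d3[0] + d3[1] * d3[1] + d3[2] * d3[2];
  }
  dist = std::sqrt(d2);
}

// [[Rcpp::export(name = ".frDisplacements")]]
List frDisplacements(NumericMatrix pos, IntegerMatrix edges, double k,
                     double temp, double cutoff, int maxPartners) {
  const int n = pos.nrow();
  const int m = edges.nrow();
  NumericMatrix disp(n, 3);
  double repEvals = 0.0;
  double d3[3], dist;

  if (cutoff <= 0.0) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        separation(pos, i, j, d3, dist);
        double f = (k * k / dist) / dist;  // magnitude/dist for direct scaling
        for (int c = 0; c < 3; ++c) {
          disp(i, c) += d3[c] * f;
          disp(j, c) -= d3[c] * f;
        }
        repEvals += 1.0;
      }
    }
  } else if (n > 1) {
    // uniform grid, cell size = cutoff
    double mins[3];
    for (int c = 0; c < 3; ++c) {
      mins[c] = pos(0, c);
      for (int i = 1; i < n; ++i) if (pos(i, c) < mins[c]) mins[c] = pos(i, c);
    }
    std::vector<long long> cellOf(n);
    std::unordered_map<long long, std::vector<int> > grid;
    grid.reserve(n * 2);
    for (int i = 0; i < n; ++i) {
      long long cx = (long long)std::floor((pos(i, 0) - mins[0]) / cutoff);
      long long cy = (long long)std::floor((pos(i, 1) - mins[1]) / cutoff);
      long long cz = (long long)std::floor((pos(i, 2) - mins[2]) / cutoff);
      // pack exactly (no hash collisions): 21 bits per axis, coords >= 0
      long long key = ((cx & 0x1FFFFF) << 42) | ((cy & 0x1FFFFF) << 21) |
                      (cz & 0x1FFFFF);
      cellOf[i] = key;
      grid[key].push_back(i);
    }
    // visit neighbour cells nearest-first: centre, then faces, edges, corners
    static const int order[27][3] = {
      {0,0,0},
      {-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1},
      {-1,-1,0},{-1,1,0},{1,-1,0},{1,1,0},
      {-1,0,-1},{-1,0,1},{1,0,-1},{1,0,1},
      {0,-1,-1},{0,-1,1},{0,1,-1},{0,1,1},
      {-1,-1,-1},{-1,-1,1},{-1,1,-1},{-1,1,1},
      {1,-1,-1},{1,-1,1},{1,1,-1},{1,1,1}
    };
    for (int i = 0; i < n; ++i) {
      long long cx = (cellOf[i] >> 42) & 0x1FFFFF;
      long long cy = (cellOf[i] >> 21) & 0x1FFFFF;
      long long cz = cellOf[i] & 0x1FFFFF;
      int partners = 0;
      for (int o = 0; o < 27 && partners < maxPartners; ++o) {
        long long key = (((cx + order[o][0]) & 0x1FFFFF) << 42) |
                        (((cy + order[o][1]) & 0x1FFFFF) << 21) |
                        ((cz + order[o][2]) & 0x1FFFFF);
        std::unordered_map<long long, std::vector<int> >::const_iterator it =
          grid.find(key);
        if (it == grid.end()) continue;
        const std::vector<int>& cell = it->second;
        for (size_t q = 0; q < cell.size() && partners < maxPartners; ++q) {
          int j = cell[q];
          if (j == i) continue;
          separation(pos, i, j, d3, dist);
          if (dist > cutoff) continue;
          double f = (k * k / dist) / dist;
          for (int c = 0; c < 3; ++c) disp(i, c) += d3[c] * f;
          repEvals += 1.0;
          ++partners;
        }
      }
    }
  }

  // attraction along edges: d^2/k pulling endpoints together
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    if (a == b) continue;  // self-loops exert no layout force
    separation(pos, a, b, d3, dist);
    double f = dist / k;  // (d^2/k)/d for direct scaling of the delta vector
    for (int c = 0; c < 3; ++c) {
      disp(a, c) -= d3[c] * f;
      disp(b, c) += d3[c] * f;
    }
  }

  // cap displacement at the current temperature
  if (R_finite(temp)) {
    for (int i = 0; i < n; ++i) {
      double len = std::sqrt(disp(i, 0) * disp(i, 0) +
                             disp(i, 1) * disp(i, 1) +
                             disp(i, 2) * disp(i, 2));
      if (len > temp && len > 0.0) {
        double s = temp / len;
        for (int c = 0; c < 3; ++c) disp(i, c) *= s;
      }
    }
  }

  return List::create(_["displacements"] = disp,
                      _["repulsionEvals"] = repEvals,
                      _["attractionEvals"] = (double)m);
}

// Minimum pairwise separation via the same grid (exact for result <= cutoff;
// falls back to all-pairs for small n).
// [[Rcpp::export(name = ".minSeparation")]]
double minSeparation(NumericMatrix pos) {
  const int n = pos.nrow();
  if (n < 2) return R_PosInf;
  double best = R_PosInf;
  double d3[3];
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      for (int c = 0; c < 3; ++c) d3[c] = pos(i, c) - pos(j, c);
      double d2 = d3[0] * d3[0] + d3[1] * d3[1] + d3[2] * d3[2];
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}
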