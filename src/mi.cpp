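#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Adaptive-partitioning mutual information on copula-transformed data.
// Inputs are assumed to lie strictly in (0,1) (rank/(n+1) transform done in R).
// The unit square is split recursively into four equal-area quadrants at the
// midpoint of the current cell while the chi-square statistic of the observed
// quadrant occupancy against the uniform expectation exceeds `chi2_crit` and
// the cell holds at least `min_n` points.  MI is accumulated over the leaves
// as (n_c/N) * ln((n_c/N)/area_c), in nats.

namespace {

struct Cell {
  std::vector<double> x;
  std::vector<double> y;
  double xlo, xhi, ylo, yhi;
};

double mi_recurse(Cell cell, int N, double chi2_crit, int min_n) {
  const int n = static_cast<int>(cell.x.size());
  if (n == 0) return 0.0;

  bool split = false;
  std::vector<Cell> quads;

  if (n >= min_n) {
    const double xm = 0.5 * (cell.xlo + cell.xhi);
    const double ym = 0.5 * (cell.ylo + cell.yhi);
    quads.resize(4);
    quads[0] = Cell{{}, {}, cell.xlo, xm, cell.ylo, ym};
    quads[1] = Cell{{}, {}, xm, cell.xhi, cell.ylo, ym};
    quads[2] = Cell{{}, {}, cell.xlo, xm, ym, cell.yhi};
    quads[3] = Cell{{}, {}, xm, cell.xhi, ym, cell.yhi};
    for (int i = 0; i < n; ++i) {
      const int qx = cell.x[i] >= xm ? 1 : 0;
      const int qy = cell.y[i] >= ym ? 1 : 0;
      Cell &q = quads[qx + 2 * qy];
      q.x.push_back(cell.x[i]);
      q.y.push_back(cell.y[i]);
    }
    const double expct = n / 4.0;
    double chi2 = 0.0;
    for (int q = 0; q < 4; ++q) {
      const double d = quads[q].x.size() - expct;
      chi2 += d * d / expct;
    }
    if (chi2 > chi2_crit) split = true;
  }

  if (!split) {
    const double p = static_cast<double>(n) / N;
    const double area = (cell.xhi - cell.xlo) * (cell.yhi - cell.ylo);
    return p * std::log(p / area);
  }
  double mi = 0.0;
  for (int q = 0; q < 4; ++q) mi += mi_recurse(std::move(quads[q]), N, chi2_crit, min_n);
  return mi;
}

double mi_from_uv(const std::vector<double> &u, const std::vector<double> &v,
                  double chi2_crit, int min_n) {
  Cell root{u, v, 0.0, 1.0, 0.0, 1.0};
  return mi_recurse(std::move(root), static_cast<int>(u.size()), chi2_crit, min_n);
}

} // namespace

// [[Rcpp::export]]
double mi_ap_cpp(NumericVector u, NumericVector v,
                 double chi2_crit = 7.815, int min_n = 8) {
  const int n = u.size();
  std::vector<double> xu(u.begin(), u.end()), xv(v.begin(), v.end());
  (void)n;
  return mi_from_uv(xu, xv, chi2_crit, min_n);
}

// MI of one copula-transformed vector against every column of a matrix.
// [[Rcpp::export]]
NumericVector mi_batch_cpp(NumericVector u, NumericMatrix V,
                           double chi2_crit = 7.815, int min_n = 8) {
  const int m = V.ncol();
  std::vector<double> xu(u.begin(), u.end());
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    NumericMatrix::Column col = V(_, j);
    std::vector<double> xv(col.begin(), col.end());
    out[j] = mi_from_uv(xu, xv, chi2_crit, min_n);
  }
  return out;
}

// Null distribution of the estimator for sample size n: MI between the rank
// grid and an independent random permutation of it.  Uses R's RNG so that
// set.seed() in R controls reproducibility.
// [[Rcpp::export]]
NumericVector mi_null_cpp(int n, int n_null,
                          double chi2_crit = 7.815, int min_n = 8) {
  std::vector<double> grid(n);
  for (int i = 0; i < n; ++i) grid[i] = (i + 1.0) / (n + 1.0);
  NumericVector out(n_null);
  std::vector<double> perm(n);
  for (int r = 0; r < n_null; ++r) {
    perm = grid;
    // Fisher-Yates with R's uniform RNG
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    out[r] = mi_from_uv(grid, perm, chi2_crit, min_n);
  }
  return out;
}
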