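// Kawasaki (conserved-composition) Monte Carlo kernel for the lattice
// solution model H = -sum_<ij> J(s_i, s_j) + sum_i mu(s_i).
//
// States are stored 0-based (0 = solvent).  Proposal kernel: uniform site,
// uniform nearest neighbor, Metropolis acceptance min(1, exp(-beta dH));
// swaps of equal states are counted as accepted proposals with dH = 0.
// Uses R's RNG so set.seed() makes runs reproducible.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int wrap(int x, int L) {
  if (x < 0) return x + L;
  if (x >= L) return x - L;
  return x;
}

// neighbor table: for each site, its 2d neighbors (periodic wrap), in the
// column-major layout of R arrays (first axis fastest)
static std::vector<int> neighbor_table(const IntegerVector &dims) {
  int d = dims.size();
  int n = 1;
  for (int a = 0; a < d; ++a) n *= dims[a];
  int ndir = 2 * d;
  std::vector<int> nb((size_t)n * ndir);
  std::vector<int> coord(d);
  for (int i = 0; i < n; ++i) {
    int rem = i;
    for (int a = 0; a < d; ++a) { coord[a] = rem % dims[a]; rem /= dims[a]; }
    int stride = 1;
    for (int a = 0; a < d; ++a) {
      int c = coord[a];
      nb[(size_t)i * ndir + 2 * a] = i + (wrap(c + 1, dims[a]) - c) * stride;
      nb[(size_t)i * ndir + 2 * a + 1] = i + (wrap(c - 1, dims[a]) - c) * stride;
      stride *= dims[a];
    }
  }
  return nb;
}

// [[Rcpp::export]]
double lattice_energy_cpp(IntegerVector state, IntegerVector dims,
                          NumericMatrix J, NumericVector mu) {
  int d = dims.size();
  int n = state.size();
  int ndir = 2 * d;
  int q = J.nrow();
  std::vector<int> nb = neighbor_table(dims);
  const int *s = INTEGER(state);
  const double *Jp = REAL(J);
  const double *mup = REAL(mu);
  double E = 0.0;
  for (int i = 0; i < n; ++i) {
    int si = s[i];
    E += mup[si];
    // count each edge once: positive directions only (even slots)
    for (int a = 0; a < d; ++a)
      E -= Jp[si + q * s[nb[(size_t)i * ndir + 2 * a]]];
  }
  return E;
}

// [[Rcpp::export]]
List kawasaki_run_cpp(IntegerVector state, IntegerVector dims,
                      NumericMatrix J, NumericVector mu, double beta,
                      int nsweeps, bool record_energy) {
  int d = dims.size();
  int n = state.size();
  int ndir = 2 * d;
  int q = J.nrow();
  IntegerVector out = clone(state);
  int *s = INTEGER(out);
  const double *Jp = REAL(J);
  std::vector<int> nb = neighbor_table(dims);
  const int *nbp = nb.data();
  double E = lattice_energy_cpp(out, dims, J, mu);
  NumericVector energies(record_energy ? nsweeps : 0);
  double accepted = 0.0;
  double proposed = 0.0;

  for (int sweep = 0; sweep < nsweeps; ++sweep) {
    for (int t = 0; t < n; ++t) {
      int i = (int)(unif_rand() * n);
      if (i == n) i = n - 1;
      int dir = (int)(unif_rand() * ndir);
      if (dir == ndir) dir = ndir - 1;
      int j = nbp[(size_t)i * ndir + dir];
      proposed += 1.0;
      int si = s[i], sj = s[j];
      if (si == sj) { accepted += 1.0; continue; }
      const double *Ji = Jp + si;     // column offsets: J[si, x] = Jp[si + q x]
      const double *Jj = Jp + sj;
      double dH = 0.0;
      const int *ni = nbp + (size_t)i * ndir;
      const int *nj = nbp + (size_t)j * ndir;
      for (int k = 0; k < ndir; ++k) {
        int m = ni[k];
        if (m != j) dH -= Jj[q * s[m]] - Ji[q * s[m]];
        m = nj[k];
        if (m != i) dH -= Ji[q * s[m]] - Jj[q * s[m]];
      }
      if (dH <= 0.0 || unif_rand() < std::exp(-beta * dH)) {
        s[i] = sj; s[j] = si;
        E += dH;
        accepted += 1.0;
      }
    }
    if (record_energy) energies[sweep] = E;
  }
  return List::create(_["state"] = out, _["energy"] = E,
                      _["energies"] = energies,
                      _["accepted"] = accepted,
                      _["proposed"] = proposed);
}
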