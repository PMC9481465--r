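#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Lattice conventions shared by all routines:
//  - grid: integer matrix of cell ids, 0 = medium.
//  - cellType: cellType[id - 1] gives the type (1..3) of cell id.
//  - J: 4x4 contact-energy matrix; rows/cols 1..3 = cell types, 4 = medium.
//  - Boundary energy is summed over unordered neighbour pairs of unlike
//    ids within the interaction neighbourhood (order 1 = von Neumann,
//    order 2 = Moore). Off-lattice sites contribute nothing.
//  - Cell perimeter is the classic 4-neighbour unit-edge count,
//    independent of the interaction neighbourhood order.

static const int DX8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DY8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DX4[4] = {-1, 1, 0, 0};
static const int DY4[4] = {0, 0, -1, 1};

static inline double jval(const NumericMatrix& J, int t1, int t2) {
  int i = (t1 == 0) ? 3 : t1 - 1;
  int j = (t2 == 0) ? 3 : t2 - 1;
  return J(i, j);
}

static inline int type_of(const IntegerVector& ct, int id) {
  return id == 0 ? 0 : ct[id - 1];
}

struct CellState {
  std::vector<double> area, perim;
};

static void census(const IntegerMatrix& g, const IntegerVector& ct,
                   CellState& st) {
  int nr = g.nrow(), nc = g.ncol(), ncell = ct.size();
  st.area.assign(ncell + 1, 0.0);
  st.perim.assign(ncell + 1, 0.0);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int id = g(i, j);
      if (id == 0) continue;
      st.area[id] += 1.0;
      for (int k = 0; k < 4; ++k) {
        int ii = i + DX4[k], jj = j + DY4[k];
        int nb = (ii >= 0 && ii < nr && jj >= 0 && jj < nc) ? g(ii, jj) : 0;
        if (nb != id) st.perim[id] += 1.0;
      }
    }
  }
}

static double boundary_energy(const IntegerMatrix& g,
                              const IntegerVector& ct,
                              const NumericMatrix& J, int nbhd) {
  int nr = g.nrow(), nc = g.ncol();
  int nnb = (nbhd == 1) ? 4 : 8;
  const int* dx = (nbhd == 1) ? DX4 : DX8;
  const int* dy = (nbhd == 1) ? DY4 : DY8;
  double e = 0.0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int id = g(i, j);
      for (int k = 0; k < nnb; ++k) {
        // count each unordered pair once: forward half-plane only
        if (dx[k] < 0 || (dx[k] == 0 && dy[k] < 0)) continue;
        int ii = i + dx[k], jj = j + dy[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int nb = g(ii, jj);
        if (nb != id) e += jval(J, type_of(ct, id), type_of(ct, nb));
      }
    }
  }
  return e;
}

static double constraint_energy(const CellState& st, const IntegerVector& ct,
                                const NumericVector& lambdaA,
                                const NumericVector& targetA,
                                const NumericVector& lambdaP,
                                const NumericVector& targetP) {
  double e = 0.0;
  for (size_t id = 1; id < st.area.size(); ++id) {
    int t = ct[id - 1] - 1;
    double da = st.area[id] - targetA[t];
    double dp = st.perim[id] - targetP[t];
    e += lambdaA[t] * da * da + lambdaP[t] * dp * dp;
  }
  return e;
}

// [[Rcpp::export]]
double cpp_hamiltonian(IntegerMatrix grid, IntegerVector cellType,
                       NumericMatrix J, NumericVector lambdaA,
                       NumericVector targetA, NumericVector lambdaP,
                       NumericVector targetP, int nbhd) {
  CellState st;
  census(grid, cellType, st);
  return boundary_energy(grid, cellType, J, nbhd) +
         constraint_energy(st, cellType, lambdaA, targetA, lambdaP, targetP);
}

// Incremental energy change for copying `candidate` into site (r, c)
// (0-based). Returns NA if the copy would annihilate the occupant's last
// site (the move is forbidden).
static double delta_h_site(const IntegerMatrix& g, const IntegerVector& ct,
                           const NumericMatrix& J,
                           const NumericVector& lambdaA,
                           const NumericVector& targetA,
                           const NumericVector& lambdaP,
                           const NumericVector& targetP, int nbhd,
                           const CellState& st, int r, int c,
                           int candidate) {
  int old = g(r, c);
  if (candidate == old) return 0.0;
  if (old != 0 && st.area[old] <= 1.0) return NA_REAL;
  int nr = g.nrow(), nc = g.ncol();
  int told = type_of(ct, old), tnew = type_of(ct, candidate);

  int nnb = (nbhd == 1) ? 4 : 8;
  const int* dx = (nbhd == 1) ? DX4 : DX8;
  const int* dy = (nbhd == 1) ? DY4 : DY8;
  double dE = 0.0;
  for (int k = 0; k < nnb; ++k) {
    int ii = r + dx[k], jj = c + dy[k];
    if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
    int nb = g(ii, jj);
    int tnb = type_of(ct, nb);
    if (nb != candidate) dE += jval(J, tnew, tnb);
    if (nb != old) dE -= jval(J, told, tnb);
  }

  // 4-neighbour counts for the perimeter bookkeeping
  int m4 = 0, k_old = 0, k_new = 0;
  for (int k = 0; k < 4; ++k) {
    int ii = r + DX4[k], jj = c + DY4[k];
    if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
    ++m4;
    int nb = g(ii, jj);
    if (nb == old) ++k_old;
    if (nb == candidate) ++k_new;
  }
  // off-lattice sides always count as boundary edges for the perimeter
  m4 = 4;

  if (old != 0) {
    int t = told - 1;
    double a = st.area[old], p = st.perim[old];
    double dA = targetA[t], dP = targetP[t];
    dE += lambdaA[t] * ((a - 1 - dA) * (a - 1 - dA) - (a - dA) * (a - dA));
    double pn = p + 2 * k_old - m4;
    dE += lambdaP[t] * ((pn - dP) * (pn - dP) - (p - dP) * (p - dP));
  }
  if (candidate != 0) {
    int t = tnew - 1;
    double a = st.area[candidate], p = st.perim[candidate];
    double dA = targetA[t], dP = targetP[t];
    dE += lambdaA[t] * ((a + 1 - dA) * (a + 1 - dA) - (a - dA) * (a - dA));
    double pn = p + m4 - 2 * k_new;
    dE += lambdaP[t] * ((pn - dP) * (pn - dP) - (p - dP) * (p - dP));
  }
  return dE;
}

// [[Rcpp::export]]
double cpp_delta_h(IntegerMatrix grid, IntegerVector cellType,
                   NumericMatrix J, NumericVector lambdaA,
                   NumericVector targetA, NumericVector lambdaP,
                   NumericVector targetP, int nbhd, int row, int col,
                   int candidate) {
  CellState st;
  census(grid, cellType, st);
  return delta_h_site(grid, cellType, J, lambdaA, targetA, lambdaP,
                      targetP, nbhd, st, row - 1, col - 1, candidate);
}

static void apply_copy(IntegerMatrix& g, CellState& st, int r, int c,
                       int candidate) {
  int old = g(r, c);
  int nr = g.nrow(), nc = g.ncol();
  int m4 = 4, k_old = 0, k_new = 0;
  for (int k = 0; k < 4; ++k) {
    int ii = r + DX4[k], jj = c + DY4[k];
    if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
    int nb = g(ii, jj);
    if (nb == old) ++k_old;
    if (nb == candidate) ++k_new;
  }
  if (old != 0) {
    st.area[old] -= 1.0;
    st.perim[old] += 2 * k_old - m4;
  }
  if (candidate != 0) {
    st.area[candidate] += 1.0;
    st.perim[candidate] += m4 - 2 * k_new;
  }
  g(r, c) = candidate;
}

// One Monte Carlo step = width x height elementary copy attempts.
static void sweep(IntegerMatrix& g, const IntegerVector& ct,
                  const NumericMatrix& J, const NumericVector& lambdaA,
                  const NumericVector& targetA, const NumericVector& lambdaP,
                  const NumericVector& targetP, int nbhd, double temperature,
                  CellState& st) {
  int nr = g.nrow(), nc = g.ncol();
  int nnb = (nbhd == 1) ? 4 : 8;
  const int* dx = (nbhd == 1) ? DX4 : DX8;
  const int* dy = (nbhd == 1) ? DY4 : DY8;
  int nsite = nr * nc;
  for (int a = 0; a < nsite; ++a) {
    int s = (int)(unif_rand() * nsite);
    if (s >= nsite) s = nsite - 1;
    int r = s % nr, c = s / nr;
    int k = (int)(unif_rand() * nnb);
    if (k >= nnb) k = nnb - 1;
    int ii = r + dx[k], jj = c + dy[k];
    if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
    int cand = g(ii, jj);
    if (cand == g(r, c)) continue;
    double dE = delta_h_site(g, ct, J, lambdaA, targetA, lambdaP, targetP,
                             nbhd, st, r, c, cand);
    if (ISNAN(dE)) continue;  // annihilation guard
    bool accept;
    if (temperature <= 0.0) {
      accept = dE < 0.0;      // quench: strict descent, ties rejected
    } else {
      accept = dE <= 0.0 || unif_rand() < std::exp(-dE / temperature);
    }
    if (accept) apply_copy(g, st, r, c, cand);
  }
}

// [[Rcpp::export]]
List cpp_run(IntegerMatrix grid, IntegerVector cellType, NumericMatrix J,
             NumericVector lambdaA, NumericVector targetA,
             NumericVector lambdaP, NumericVector targetP, int nbhd,
             double temperature, int n_mcs, int record_every) {
  IntegerMatrix g = clone(grid);
  CellState st;
  census(g, cellType, st);

  std::vector<IntegerMatrix> snaps;
  std::vector<int> mcs_idx;
  std::vector<double> energies;
  IntegerMatrix s0 = clone(g);
  snaps.push_back(s0);
  mcs_idx.push_back(0);
  energies.push_back(
      boundary_energy(g, cellType, J, nbhd) +
      constraint_energy(st, cellType, lambdaA, targetA, lambdaP, targetP));

  for (int step = 1; step <= n_mcs; ++step) {
    sweep(g, cellType, J, lambdaA, targetA, lambdaP, targetP, nbhd,
          temperature, st);
    if (step % record_every == 0 || step == n_mcs) {
      IntegerMatrix s = clone(g);
      snaps.push_back(s);
      mcs_idx.push_back(step);
      energies.push_back(
          boundary_energy(g, cellType, J, nbhd) +
          constraint_energy(st, cellType, lambdaA, targetA, lambdaP,
                            targetP));
    }
  }
  return List::create(_["snapshots"] = wrap(snaps),
                      _["mcs"] = wrap(mcs_idx),
                      _["energies"] = wrap(energies));
}

// Connected-component labelling of a binary mask (BFS flood fill).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int nbhd) {
  int nr = mask.nrow(), nc = mask.ncol();
  int nnb = (nbhd == 1) ? 4 : 8;
  const int* dx = (nbhd == 1) ? DX4 : DX8;
  const int* dy = (nbhd == 1) ? DY4 : DY8;
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < nnb; ++k) {
          int ii = p.first + dx[k], jj = p.second + dy[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) != 0 && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}

// Boundary-link census by type pair: entry (a, b) counts neighbour links
// between sites of unlike cell id whose types are a and b (1..3 = cell
// types, 4 = medium; off-lattice neighbours count as medium links for
// boundary sites). Symmetric, each unordered link counted once.
// [[Rcpp::export]]
NumericMatrix cpp_contact_lengths(IntegerMatrix grid, IntegerVector cellType,
                                  int nbhd) {
  int nr = grid.nrow(), nc = grid.ncol();
  int nnb = (nbhd == 1) ? 4 : 8;
  const int* dx = (nbhd == 1) ? DX4 : DX8;
  const int* dy = (nbhd == 1) ? DY4 : DY8;
  NumericMatrix m(4, 4);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int id = grid(i, j);
      int t1 = type_of(cellType, id);
      for (int k = 0; k < nnb; ++k) {
        int ii = i + dx[k], jj = j + dy[k];
        bool off = (ii < 0 || ii >= nr || jj < 0 || jj >= nc);
        if (off) {
          if (id != 0) {  // lattice-edge link counts as medium contact
            int a = t1 - 1;
            m(a, 3) += 1.0;
            m(3, a) += 1.0;
          }
          continue;
        }
        // forward half only, so each in-lattice pair is counted once
        if (dx[k] < 0 || (dx[k] == 0 && dy[k] < 0)) continue;
        int nb = grid(ii, jj);
        if (nb == id) continue;
        int t2 = type_of(cellType, nb);
        int a = (t1 == 0) ? 3 : t1 - 1;
        int b = (t2 == 0) ? 3 : t2 - 1;
        m(a, b) += 1.0;
        if (a != b) m(b, a) += 1.0;
      }
    }
  }
  return m;
}
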