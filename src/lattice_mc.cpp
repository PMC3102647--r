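// Metropolis Monte Carlo for phantom semiflexible chains on the simple
// cubic lattice. Bending energy E = sum_v eps_v * (1 - cos theta_v) with
// cos theta in {-1, 0, 1}; temperature fixed at 1 kBT. Moves: pivot
// (octahedral group element applied to the tail), single-bead corner flip,
// and end-bond redraw. Uses R's RNG so set.seed() on the R side gives full
// reproducibility.

#include <Rcpp.h>
#include <array>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

typedef std::array<int, 3> Vec3;

inline int rint_below(double n) {
  int k = static_cast<int>(unif_rand() * n);
  return k >= static_cast<int>(n) ? static_cast<int>(n) - 1 : k;
}

const int STEPS[6][3] = {
  {1, 0, 0}, {-1, 0, 0}, {0, 1, 0}, {0, -1, 0}, {0, 0, 1}, {0, 0, -1}
};

// 48 signed permutation matrices: the full octahedral group.
std::vector<std::array<int, 9> > build_group() {
  static const int perms[6][3] = {
    {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}
  };
  std::vector<std::array<int, 9> > g;
  g.reserve(48);
  for (int p = 0; p < 6; ++p) {
    for (int s = 0; s < 8; ++s) {
      std::array<int, 9> m = {{0, 0, 0, 0, 0, 0, 0, 0, 0}};
      const int sgn[3] = {(s & 1) ? -1 : 1, (s & 2) ? -1 : 1, (s & 4) ? -1 : 1};
      for (int r = 0; r < 3; ++r) m[r * 3 + perms[p][r]] = sgn[r];
      g.push_back(m);
    }
  }
  return g;
}

struct Chain {
  std::vector<Vec3> x;
  const std::vector<double>& eps;  // per-vertex, length n_beads - 2

  Chain(std::vector<Vec3> x0, const std::vector<double>& e) : x(x0), eps(e) {}

  int nBeads() const { return static_cast<int>(x.size()); }
  int nBonds() const { return nBeads() - 1; }

  Vec3 bond(int b) const {
    Vec3 d;
    for (int k = 0; k < 3; ++k) d[k] = x[b + 1][k] - x[b][k];
    return d;
  }

  static int dot(const Vec3& a, const Vec3& b) {
    return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
  }

  // bending energy at vertex v (between bonds v and v+1), with bead v+1
  // optionally replaced by a candidate position.
  double vertexEnergy(int v, const Vec3* cand = 0, int candBead = -1) const {
    Vec3 b1, b2;
    for (int k = 0; k < 3; ++k) {
      const int* pv  = (candBead == v)     ? &(*cand)[0] : &x[v][0];
      const int* pm  = (candBead == v + 1) ? &(*cand)[0] : &x[v + 1][0];
      const int* pn  = (candBead == v + 2) ? &(*cand)[0] : &x[v + 2][0];
      b1[k] = pm[k] - pv[k];
      b2[k] = pn[k] - pm[k];
    }
    return eps[v] * (1.0 - dot(b1, b2));
  }

  // sum of vertex energies touched by moving bead i
  double localEnergy(int i, const Vec3* cand = 0) const {
    double e = 0.0;
    const int nv = nBeads() - 2;
    for (int v = i - 2; v <= i; ++v)
      if (v >= 0 && v < nv) e += vertexEnergy(v, cand, cand ? i : -1);
    return e;
  }
};

inline bool metropolis_accept(double dE) {
  return dE <= 0.0 || unif_rand() < std::exp(-dE);
}

}  // namespace

// [[Rcpp::export]]
List cpp_lattice_mc(IntegerMatrix coordsInit, NumericVector epsIn,
                    int nSamples, int equilSweeps, int intervalSweeps,
                    NumericVector moveMix, int maxSep) {
  const int nb = coordsInit.nrow();
  if (nb < 3) stop("need at least 3 beads");
  const int nBonds = nb - 1;
  const int nVert = nb - 2;
  if (epsIn.size() != nVert) stop("stiffness map length must be n_beads - 2");

  std::vector<double> eps(epsIn.begin(), epsIn.end());
  std::vector<Vec3> x0(nb);
  for (int i = 0; i < nb; ++i) {
    x0[i][0] = coordsInit(i, 0);
    x0[i][1] = coordsInit(i, 1);
    x0[i][2] = coordsInit(i, 2);
  }
  Chain ch(x0, eps);
  const std::vector<std::array<int, 9> > G = build_group();

  const double pPivot = moveMix[0];
  const double pCorner = moveMix[1];
  if (maxSep > nBonds - 1) maxSep = nBonds - 1;
  if (maxSep < 1) maxSep = 1;

  long attempts[3] = {0, 0, 0};
  long accepts[3] = {0, 0, 0};

  // One sweep = nBonds attempted moves.
  auto doMove = [&]() {
    const double u = unif_rand();
    if (u < pPivot) {
      // --- pivot: bead j in 1..nb-2, octahedral element applied to tail ---
      ++attempts[0];
      const int j = 1 + rint_below(nb - 2);
      const std::array<int, 9>& g = G[rint_below(48)];
      const Vec3 bj = ch.bond(j);
      Vec3 nbj;
      for (int r = 0; r < 3; ++r)
        nbj[r] = g[r * 3] * bj[0] + g[r * 3 + 1] * bj[1] + g[r * 3 + 2] * bj[2];
      // only the angle at vertex j-1 changes (bond j-1 vs bond j)
      const Vec3 bprev = ch.bond(j - 1);
      const double dE =
          eps[j - 1] * (Chain::dot(bprev, bj) - Chain::dot(bprev, nbj));
      if (metropolis_accept(dE)) {
        ++accepts[0];
        const Vec3 piv = ch.x[j];
        for (int k = j + 1; k < nb; ++k) {
          Vec3 d;
          for (int r = 0; r < 3; ++r) d[r] = ch.x[k][r] - piv[r];
          for (int r = 0; r < 3; ++r)
            ch.x[k][r] = piv[r] + g[r * 3] * d[0] + g[r * 3 + 1] * d[1] +
                         g[r * 3 + 2] * d[2];
        }
      }
    } else if (u < pPivot + pCorner) {
      // --- corner flip on interior bead i ---
      ++attempts[1];
      const int i = 1 + rint_below(nb - 2);
      Vec3 u1 = ch.bond(i - 1), u2 = ch.bond(i);
      Vec3 d;
      int d2 = 0;
      for (int k = 0; k < 3; ++k) {
        d[k] = u1[k] + u2[k];
        d2 += d[k] * d[k];
      }
      Vec3 cand;
      if (d2 == 2) {
        // perpendicular bonds: the opposite corner of the unit square
        for (int k = 0; k < 3; ++k) cand[k] = ch.x[i - 1][k] + u2[k];
      } else if (d2 == 0) {
        // hairpin: bead i may sit on any neighbour of its (coincident)
        // flanking beads; symmetric 1-of-6 proposal
        const int* e = STEPS[rint_below(6)];
        for (int k = 0; k < 3; ++k) cand[k] = ch.x[i - 1][k] + e[k];
      } else {
        return;  // straight segment: no corner move, count as rejected
      }
      const double dE = ch.localEnergy(i, &cand) - ch.localEnergy(i);
      if (metropolis_accept(dE)) {
        ++accepts[1];
        ch.x[i] = cand;
      }
    } else {
      // --- end-bond redraw ---
      ++attempts[2];
      const bool head = unif_rand() < 0.5;
      const int i = head ? 0 : nb - 1;
      const int anchor = head ? 1 : nb - 2;
      const int* e = STEPS[rint_below(6)];
      Vec3 cand;
      for (int k = 0; k < 3; ++k) cand[k] = ch.x[anchor][k] + e[k];
      const double dE = ch.localEnergy(i, &cand) - ch.localEnergy(i);
      if (metropolis_accept(dE)) {
        ++accepts[2];
        ch.x[i] = cand;
      }
    }
  };

  auto sweep = [&]() {
    for (int m = 0; m < nBonds; ++m) doMove();
  };

  for (int s = 0; s < equilSweeps; ++s) sweep();

  NumericVector ree2(nSamples), rg2(nSamples), meanCos(nSamples);
  NumericMatrix tcorr(nSamples, maxSep);

  std::vector<Vec3> bonds(nBonds);
  for (int s = 0; s < nSamples; ++s) {
    for (int t = 0; t < intervalSweeps; ++t) sweep();

    Vec3 dee;
    for (int k = 0; k < 3; ++k) dee[k] = ch.x[nb - 1][k] - ch.x[0][k];
    ree2[s] = Chain::dot(dee, dee);

    double cx = 0, cy = 0, cz = 0;
    for (int i = 0; i < nb; ++i) {
      cx += ch.x[i][0];
      cy += ch.x[i][1];
      cz += ch.x[i][2];
    }
    cx /= nb; cy /= nb; cz /= nb;
    double g2 = 0;
    for (int i = 0; i < nb; ++i) {
      const double dx = ch.x[i][0] - cx, dy = ch.x[i][1] - cy,
                   dz = ch.x[i][2] - cz;
      g2 += dx * dx + dy * dy + dz * dz;
    }
    rg2[s] = g2 / nb;

    for (int b = 0; b < nBonds; ++b) bonds[b] = ch.bond(b);
    for (int sep = 1; sep <= maxSep; ++sep) {
      double acc = 0;
      const int np = nBonds - sep;
      for (int b = 0; b < np; ++b) acc += Chain::dot(bonds[b], bonds[b + sep]);
      tcorr(s, sep - 1) = acc / np;
    }
    double mc = 0;
    for (int v = 0; v < nVert; ++v)
      mc += Chain::dot(bonds[v], bonds[v + 1]);
    meanCos[s] = mc / nVert;
  }

  IntegerMatrix finalCoords(nb, 3);
  for (int i = 0; i < nb; ++i)
    for (int k = 0; k < 3; ++k) finalCoords(i, k) = ch.x[i][k];

  NumericVector acc(3);
  for (int k = 0; k < 3; ++k)
    acc[k] = attempts[k] > 0 ? static_cast<double>(accepts[k]) / attempts[k]
                             : NA_REAL;
  acc.names() = CharacterVector::create("pivot", "corner", "end");

  return List::create(_["ree2"] = ree2, _["rg2"] = rg2,
                      _["tcorr"] = tcorr, _["mean_cos"] = meanCos,
                      _["acceptance"] = acc, _["final_coords"] = finalCoords);
}

// Unbiased lattice random walk used for chain initialisation and FJC
// ensembles (unconfined). Returns bead coordinates including the origin.
// [[Rcpp::export]]
IntegerMatrix cpp_lattice_walk(int nBonds) {
  IntegerMatrix out(nBonds + 1, 3);
  int p[3] = {0, 0, 0};
  for (int b = 0; b < nBonds; ++b) {
    const int* e = STEPS[rint_below(6)];
    for (int k = 0; k < 3; ++k) {
      p[k] += e[k];
      out(b + 1, k) = p[k];
    }
  }
  return out;
}

// Confined lattice walk with reflecting walls: sites 0..box-1 in each
// coordinate; steps are drawn uniformly among the valid neighbours
// (resampling rejected directions), which keeps the walk inside the box.
// [[Rcpp::export]]
IntegerMatrix cpp_confined_walk(int nBonds, int box) {
  if (box < 2) stop("box must be at least 2 lattice sites");
  IntegerMatrix out(nBonds + 1, 3);
  int p[3];
  for (int k = 0; k < 3; ++k) p[k] = rint_below(box);
  for (int k = 0; k < 3; ++k) out(0, k) = p[k];
  for (int b = 0; b < nBonds; ++b) {
    for (;;) {
      const int* e = STEPS[rint_below(6)];
      const int q0 = p[0] + e[0], q1 = p[1] + e[1], q2 = p[2] + e[2];
      if (q0 >= 0 && q0 < box && q1 >= 0 && q1 < box && q2 >= 0 && q2 < box) {
        p[0] = q0; p[1] = q1; p[2] = q2;
        break;
      }
    }
    for (int k = 0; k < 3; ++k) out(b + 1, k) = p[k];
  }
  return out;
}
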